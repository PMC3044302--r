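DNA_BASES <- c("A", "C", "G", "T")

#' HKY85 substitution model parameters
#'
#' The HKY85 model allows unequal equilibrium base frequencies and a
#' transition/transversion rate ratio `kappa`.  The rate matrix is
#' normalized to one expected substitution per site per unit time, so all
#' times in the simulator are branch lengths in expected substitutions per
#' neutral site.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param base_freqs Equilibrium frequencies of A, C, G, T (sum to 1).
#' @return An object of class `"hky_params"` with the normalized rate
#'   matrix `Q` and its spectral decomposition precomputed.
#' @export
hky_params <- function(kappa = 4, base_freqs = rep(0.25, 4)) {
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa <= 0)
    stop("kappa must be a positive scalar")
  if (length(base_freqs) != 4L || any(base_freqs <= 0) ||
      abs(sum(base_freqs) - 1) > 1e-9)
    stop("base_freqs must be 4 positive frequencies summing to 1")
  pi <- as.numeric(base_freqs)
  names(pi) <- DNA_BASES
  Q <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  is_transition <- function(i, j)
    (DNA_BASES[i] %in% c("A", "G") && DNA_BASES[j] %in% c("A", "G")) ||
    (DNA_BASES[i] %in% c("C", "T") && DNA_BASES[j] %in% c("C", "T"))
  for (i in 1:4) for (j in 1:4) if (i != j)
    Q[i, j] <- pi[j] * if (is_transition(i, j)) kappa else 1
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))             # expected substitutions per unit time
  Q <- Q / mu
  ## reversible: symmetrize with sqrt(pi) for a stable eigendecomposition
  d <- sqrt(pi)
  B <- diag(d) %*% Q %*% diag(1 / d)
  es <- eigen((B + t(B)) / 2, symmetric = TRUE)
  structure(list(kappa = kappa, base_freqs = pi, Q = Q,
                 evalues = es$values,
                 right = diag(1 / d) %*% es$vectors,
                 left = t(es$vectors) %*% diag(d)),
            class = "hky_params")
}

#' HKY85 transition probability matrix
#'
#' `P(t) = exp(Qt)` via the spectral decomposition of the reversible rate
#' matrix; `P(0)` is the identity and rows converge to the equilibrium
#' frequencies as `t` grows.
#'
#' @param params An [hky_params()].
#' @param t Branch length in expected substitutions per site (>= 0).
#' @return 4x4 row-stochastic matrix over A, C, G, T.
#' @export
hky_transition_matrix <- function(params, t) {
  if (!inherits(params, "hky_params")) stop("params must be hky_params")
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("t must be a non-negative scalar")
  P <- params$right %*% (exp(params$evalues * t) * params$left)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(DNA_BASES, DNA_BASES)
  P
}

#' Expected sequence identity after divergence time t
#'
#' Probability that a site is identical in two sequences that diverged
#' `t` substitution units ago in total (sum of both branch lengths):
#' `sum_i pi_i P_ii(t)` by reversibility.
#'
#' @inheritParams hky_transition_matrix
#' @return Expected fraction of identical sites.
#' @export
expected_identity <- function(params, t) {
  sum(params$base_freqs * diag(hky_transition_matrix(params, t)))
}

#' Calibrate total divergence time to a target identity
#'
#' Solves `expected_identity(params, T) == target_identity` by bisection.
#' The simulation driver splits `T` equally between the two descendant
#' lineages (molecular clock).  The target must exceed the equilibrium
#' identity `sum(pi^2)`, the identity of two unrelated sequences.
#'
#' @inheritParams hky_transition_matrix
#' @param target_identity Fraction in (equilibrium identity, 1].
#' @param tol Bisection tolerance on T.
#' @return Total separation time T in expected substitutions per site.
#' @export
calibrate_divergence_time <- function(target_identity, params, tol = 1e-10) {
  eq <- sum(params$base_freqs^2)
  if (!is.numeric(target_identity) || length(target_identity) != 1L ||
      target_identity > 1 || target_identity <= eq)
    stop("target identity must lie in (", signif(eq, 4),
         ", 1], the attainable range for these base frequencies")
  if (target_identity == 1) return(0)
  lo <- 0; hi <- 1
  while (expected_identity(params, hi) > target_identity) hi <- hi * 2
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (expected_identity(params, mid) > target_identity) lo <- mid
    else hi <- mid
  }
  (lo + hi) / 2
}

#' Conserved-element annotation
#'
#' Non-overlapping elements under purifying selection, with substitution
#' rate scaled by `rate_factor` relative to neutral sites.  The mask is a
#' property of positions: it is copied with duplicated segments and excised
#' with deletions.
#'
#' @param elements Integer matrix with columns `start`, `end` (0-based
#'   half-open), non-overlapping.
#' @param rate_factor Rate multiplier in (0, 1).
#' @return Object of class `"conserved_annotation"`.
#' @export
conserved_annotation <- function(elements, rate_factor = 0.7) {
  if (!is.matrix(elements)) {
    elements <- matrix(integer(), ncol = 2)
  }
  colnames(elements) <- c("start", "end")
  if (nrow(elements) > 1L) {
    o <- order(elements[, 1L])
    elements <- elements[o, , drop = FALSE]
    if (any(elements[-1L, 1L] < elements[-nrow(elements), 2L]))
      stop("conserved elements overlap")
  }
  if (rate_factor <= 0 || rate_factor >= 1)
    stop("rate_factor must be in (0,1)")
  structure(list(elements = elements, rate_factor = rate_factor),
            class = "conserved_annotation")
}

#' Place conserved elements along a sequence
#'
#' Draws element lengths from a geometric distribution with the given mean
#' (conserved elements in mammalian genomes average roughly 100-120 bp with
#' a geometric length profile) and places them uniformly without overlap
#' until the covered fraction reaches `coverage_target`; the overshoot is
#' bounded by one element length.
#'
#' @param seq_length Sequence length in bp.
#' @param coverage_target Fraction of the sequence to cover (< 0.5; denser
#'   targets would make rejection placement thrash).
#' @param mean_len Mean element length in bp.
#' @param rate_factor Purifying-selection rate multiplier.
#' @return A [conserved_annotation()].
#' @export
place_conserved_elements <- function(seq_length, coverage_target = 0.05,
                                     mean_len = 110, rate_factor = 0.7) {
  if (coverage_target >= 0.5) stop("coverage_target must be < 0.5")
  if (coverage_target <= 0)
    return(conserved_annotation(matrix(integer(), ncol = 2), rate_factor))
  mask <- logical(seq_length)
  starts <- integer(); ends <- integer()
  covered <- 0L
  tries <- 0L
  while (covered < coverage_target * seq_length) {
    len <- min(stats::rgeom(1L, 1 / mean_len) + 1L, seq_length)
    s <- sample.int(seq_length - len + 1L, 1L) - 1L
    if (any(mask[(s + 1L):(s + len)])) {
      tries <- tries + 1L
      if (tries > 1e5) stop("conserved-element placement failed to converge")
      next
    }
    mask[(s + 1L):(s + len)] <- TRUE
    starts <- c(starts, s); ends <- c(ends, s + len)
    covered <- covered + len
  }
  conserved_annotation(cbind(start = starts, end = ends), rate_factor)
}

#' Logical conserved-site mask of length n from an annotation
#'
#' @param annot A [conserved_annotation()].
#' @param n Sequence length.
#' @return Logical vector, `TRUE` at conserved positions.
#' @export
conserved_mask <- function(annot, n) {
  mask <- logical(n)
  el <- annot$elements
  if (nrow(el)) for (i in seq_len(nrow(el)))
    mask[(el[i, 1L] + 1L):el[i, 2L]] <- TRUE
  mask
}

## annotation elements from a logical mask (runs of TRUE)
elements_from_mask <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  cbind(start = as.integer(starts[keep]), end = as.integer(ends[keep]))
}
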