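#' Event property distributions
#'
#' Distributions from which the properties of duplication, deletion, and
#' conversion events are drawn: segment lengths, source-to-copy spacing,
#' copy orientation, converted-tract length and location, and conversion
#' direction.  The defaults are parametric stand-ins for empirical gene
#' cluster event-size profiles, on scales typical of primate gene
#' clusters: log-normal lengths (duplication/deletion median 5 kb,
#' conversion tract median 1 kb), geometric spacing (mean 10 kb), 20%
#' inverted copies, symmetric conversion direction.  Every field is a
#' config key.
#'
#' @param dup_len,del_len,conv_len Length distributions, each a list
#'   `list(dist = "lognormal", meanlog =, sdlog =)` or
#'   `list(dist = "fixed", value =)`.
#' @param spacing Source-to-copy spacing distribution:
#'   `list(dist = "geometric", mean =)` or fixed.
#' @param p_inverted Probability a duplicated copy is inverted.
#' @param conv_loc Distribution of the converted tract's location within
#'   the chosen paralogous map (`"uniform"`).
#' @param p_direction Probability the conversion copies a onto b
#'   (vs b onto a).
#' @return Object of class `"event_distributions"`.
#' @export
event_distributions <- function(
    dup_len  = list(dist = "lognormal", meanlog = log(5000), sdlog = 0.7),
    del_len  = list(dist = "lognormal", meanlog = log(5000), sdlog = 0.7),
    conv_len = list(dist = "lognormal", meanlog = log(1000), sdlog = 0.7),
    spacing  = list(dist = "geometric", mean = 10000),
    p_inverted = 0.2,
    conv_loc = "uniform",
    p_direction = 0.5) {
  structure(list(dup_len = dup_len, del_len = del_len, conv_len = conv_len,
                 spacing = spacing, p_inverted = p_inverted,
                 conv_loc = conv_loc, p_direction = p_direction),
            class = "event_distributions")
}

## draw n values from a length/spacing distribution spec
sample_dist <- function(spec, n = 1L) {
  switch(spec$dist,
    lognormal = pmax(1L, as.integer(round(
      stats::rlnorm(n, spec$meanlog, spec$sdlog)))),
    geometric = stats::rgeom(n, 1 / (spec$mean + 1)),
    fixed = rep(as.integer(spec$value), n),
    stop("unknown distribution: ", spec$dist))
}

## ---- simulation state -------------------------------------------------
## A cluster state bundles the per-lineage evolving sequences with the
## shared truth store; event functions take and return a state.
cluster_state <- function(seqs, store) list(seqs = seqs, store = store)

state_seq_len <- function(state, lineage) length(state$seqs[[lineage]]$seq)

#' Sample a duplication event
#'
#' The source may span any region of the current sequence, including (parts
#' of) previously duplicated tandem segments, so repeated duplication of
#' composite regions arises naturally.  The insertion point is offset from
#' a uniformly chosen side of the source by a sampled spacing, clipped to
#' the sequence bounds; a draw landing strictly inside the source is
#' resampled.
#'
#' @param state Cluster state (see [run_replicate()] internals).
#' @param lineage Lineage to mutate.
#' @param dists [event_distributions()].
#' @param time Event time (substitution units within the epoch).
#' @return Event list (kind, lineage, source, insert_at, orientation).
#' @export
sample_duplication <- function(state, lineage, dists, time = NA_real_) {
  n <- state_seq_len(state, lineage)
  if (n < 2L) stop("sequence too short to duplicate")
  for (try in 1:100) {
    len <- min(sample_dist(dists$dup_len), n)
    src_start <- sample.int(n - len + 1L, 1L) - 1L
    src <- interval(lineage, src_start, src_start + len)
    gap <- sample_dist(dists$spacing)
    insert_at <- if (stats::runif(1) < 0.5) max(0L, src$start - gap)
                 else min(n, src$end + gap)
    if (insert_at <= src$start || insert_at >= src$end)
      return(list(kind = "duplication", lineage = lineage, time = time,
                  source = src, insert_at = as.integer(insert_at),
                  orientation = if (stats::runif(1) < dists$p_inverted)
                    "inverted" else "same"))
  }
  stop("failed to sample a valid duplication")
}

#' Sample a deletion event
#'
#' @inheritParams sample_duplication
#' @param min_seq_len The sequence is never deleted below this length.
#' @return Event list (kind, lineage, region).
#' @export
sample_deletion <- function(state, lineage, dists, time = NA_real_,
                            min_seq_len = 10000L) {
  n <- state_seq_len(state, lineage)
  if (n <= min_seq_len) stop("sequence at minimum length; cannot delete")
  len <- min(sample_dist(dists$del_len), n - min_seq_len)
  s <- sample.int(n - len + 1L, 1L) - 1L
  list(kind = "deletion", lineage = lineage, time = time,
       region = interval(lineage, s, s + len))
}

#' Apply a duplication to the cluster state
#'
#' Inserts a copy of the source (reverse-complemented when inverted) at the
#' insertion point; the conserved mask is copied with the segment; the
#' truth store gains the new self map and the copy's ortholog maps.
#'
#' @inheritParams sample_duplication
#' @param event Event from [sample_duplication()].
#' @return Updated state, with attributes `source`/`copy` (post-edit).
#' @export
apply_duplication <- function(state, event) {
  lin <- event$lineage
  es <- state$seqs[[lin]]
  n <- length(es$seq)
  src <- event$source
  if (src$end > n || event$insert_at > n) stop("stale duplication coordinates")
  idx <- (src$start + 1L):src$end
  seg <- es$seq[idx]
  msk <- es$conserved[idx]
  if (event$orientation == "inverted") {
    seg <- revcomp_int(seg)
    msk <- rev(msk)
  }
  p <- event$insert_at
  es$seq <- append(es$seq, seg, after = p)
  es$conserved <- append(es$conserved, msk, after = p)
  state$seqs[[lin]] <- es
  state$store <- update_on_duplication(state$store, lin, src, p,
                                       event$orientation)
  attr(state, "source") <- attr(state$store, "source")
  attr(state, "copy") <- attr(state$store, "copy")
  state
}

#' Apply a deletion to the cluster state
#'
#' @inheritParams apply_duplication
#' @param event Event from [sample_deletion()].
#' @return Updated state.
#' @export
apply_deletion <- function(state, event) {
  lin <- event$lineage
  es <- state$seqs[[lin]]
  r <- event$region
  if (r$end > length(es$seq)) stop("stale deletion coordinates")
  idx <- (r$start + 1L):r$end
  es$seq <- es$seq[-idx]
  es$conserved <- es$conserved[-idx]
  state$seqs[[lin]] <- es
  state$store <- update_on_deletion(state$store, lin, r)
  state
}

#' Choose a paralogous pair and tract for a conversion
#'
#' The pair is chosen uniformly from the lineage's full paralogy closure
#' (all true local self-alignments formed by the preceding duplications,
#' including transitively composed ones); the tract length is drawn from
#' the conversion length distribution, truncated to the map length, and
#' placed within the map; the direction is then sampled.
#'
#' @inheritParams sample_duplication
#' @param allow_inverted Whether inverted-orientation paralog pairs are
#'   eligible conversion partners.
#' @return `NULL` when no eligible pair exists (the scheduler defers the
#'   conversion), else a list (map, k0, k1, direction) with the tract as
#'   offsets `[k0, k1)` into the map.
#' @export
select_conversion_pair <- function(state, lineage, dists,
                                   allow_inverted = TRUE) {
  cl <- paralog_closure(state$store, lineage)
  if (!allow_inverted)
    cl <- Filter(function(m) m$orientation == "same", cl)
  if (length(cl) == 0L) return(NULL)
  m <- cl[[sample.int(length(cl), 1L)]]
  len <- map_len(m)
  tract_len <- min(sample_dist(dists$conv_len), len)
  k0 <- if (identical(dists$conv_loc, "uniform"))
    sample.int(len - tract_len + 1L, 1L) - 1L
  else stop("unknown conversion location distribution")
  direction <- if (stats::runif(1) < dists$p_direction) "a_to_b" else "b_to_a"
  list(map = m, k0 = k0, k1 = k0 + tract_len, direction = direction)
}

#' Apply a gene conversion
#'
#' Overwrites the target tract with the homologous source sub-sequence
#' through the map (reverse complemented for inverted pairs).  The
#' sequence length and all coordinates are unchanged; at the instant of
#' application the two tracts are identical, the similarity signature that
#' detectors look for.  The tract pair is recorded in the truth store.
#'
#' @inheritParams sample_duplication
#' @param map Self [pairwise_map()] (the paralogous pair).
#' @param k0,k1 Tract as half-open offset range into the map.
#' @param direction `"a_to_b"` (a overwrites b) or `"b_to_a"`.
#' @param event_id Identifier recorded with the truth tract.
#' @return Updated state.
#' @export
apply_conversion <- function(state, lineage, map, k0, k1, direction,
                             time = NA_real_, event_id = NA_character_) {
  len <- map_len(map)
  if (k0 < 0L || k1 <= k0 || k1 > len) stop("conversion tract outside map")
  tract_a <- interval(lineage, map$a$start + k0, map$a$start + k1)
  tract_b <- if (map$orientation == "same")
    interval(lineage, map$b$start + k0, map$b$start + k1)
  else interval(lineage, map$b$start + (len - k1), map$b$start + (len - k0))
  src <- if (direction == "a_to_b") tract_a else tract_b
  tgt <- if (direction == "a_to_b") tract_b else tract_a
  es <- state$seqs[[lineage]]
  seg <- es$seq[(src$start + 1L):src$end]     # snapshot before overwriting
  if (map$orientation == "inverted") seg <- revcomp_int(seg)
  es$seq[(tgt$start + 1L):tgt$end] <- seg
  state$seqs[[lineage]] <- es
  tract_map <- pairwise_map(tract_a, tract_b, map$orientation, "self")
  if (tract_map$a$start != tract_a$start)  # canonical order swapped sides
    direction <- if (direction == "a_to_b") "b_to_a" else "a_to_b"
  state$store <- store_add_track(state$store, event_id, lineage, time,
                                 direction, tract_map)
  attr(state, "tract_a") <- tract_a
  attr(state, "tract_b") <- tract_b
  state
}
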