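## Scoring of conversion-detection predictions against simulation truth.
## The basepair universe is the set of positions inside cataloged
## paralogous segments; read_predictions() rejects calls outside it.

truth_ranges <- function(truth, pair, direction_aware = FALSE) {
  tt <- truth[truth$pair_id == pair, , drop = FALSE]
  if (direction_aware && nrow(tt)) {
    tgt <- ifelse(tt$direction == "a_to_b", "b", "a")
    tt <- tt[tt$side == tgt, , drop = FALSE]
  }
  if (!nrow(tt)) return(IRanges::IRanges())
  IRanges::reduce(IRanges::IRanges(tt$start + 1L, tt$end))
}

pred_ranges <- function(pred, pair) {
  pp <- pred[pred$pair_id == pair, , drop = FALSE]
  if (!nrow(pp)) return(IRanges::IRanges())
  IRanges::reduce(IRanges::IRanges(pp$start + 1L, pp$end))
}

#' Per-basepair sensitivity and false discovery rate
#'
#' Sensitivity is the fraction of truly converted basepairs that were
#' called converted; FDR is the fraction of called basepairs that are not
#' truly converted.  Basepairs are matched within each cataloged
#' paralogous pair.  With no called basepairs the FDR is reported as 0
#' with `empty_calls = TRUE`.
#'
#' @param truth Conversion truth from [build_conversion_truth()].
#' @param predictions A [read_predictions()] result (or any data.frame
#'   with pair_id, start, end).
#' @param direction_aware If `TRUE`, only the overwritten (target) side
#'   of each conversion counts as truly converted; by default both sides
#'   of the converted tract count.
#' @return List: sensitivity, fdr, tp_bp, true_bp, called_bp,
#'   empty_calls.
#' @export
per_bp_metrics <- function(truth, predictions, direction_aware = FALSE) {
  pairs <- unique(c(truth$pair_id, predictions$pair_id))
  tp <- true_bp <- called <- 0L
  for (p in pairs) {
    tr <- truth_ranges(truth, p, direction_aware)
    pr <- pred_ranges(predictions, p)
    tp <- tp + sum(IRanges::width(IRanges::intersect(tr, pr)))
    true_bp <- true_bp + sum(IRanges::width(tr))
    called <- called + sum(IRanges::width(pr))
  }
  list(sensitivity = if (true_bp) tp / true_bp else NA_real_,
       fdr = if (called) (called - tp) / called else 0,
       tp_bp = tp, true_bp = true_bp, called_bp = called,
       empty_calls = called == 0L)
}

#' Existence-level sensitivity and false discovery rate
#'
#' Pair-level detection: a truly converted pair counts as detected when at
#' least one predicted basepair falls on it, regardless of whether the
#' tract endpoints are right; a called pair with no true conversion is a
#' false discovery.
#'
#' @inheritParams per_bp_metrics
#' @return List: sensitivity, fdr, detected_pairs, true_pairs,
#'   called_pairs, empty_calls.
#' @export
existence_metrics <- function(truth, predictions) {
  true_pairs <- unique(truth$pair_id)
  called_pairs <- unique(predictions$pair_id[
    predictions$end > predictions$start])
  detected <- intersect(true_pairs, called_pairs)
  false_pairs <- setdiff(called_pairs, true_pairs)
  list(sensitivity = if (length(true_pairs))
         length(detected) / length(true_pairs) else NA_real_,
       fdr = if (length(called_pairs))
         length(false_pairs) / length(called_pairs) else 0,
       detected_pairs = length(detected),
       true_pairs = length(true_pairs),
       called_pairs = length(called_pairs),
       empty_calls = length(called_pairs) == 0L)
}

#' Score one replicate's predictions on all four metrics
#'
#' @param rep A [run_replicate()] result.
#' @param predictions A [read_predictions()] result.
#' @inheritParams per_bp_metrics
#' @return One-row data.frame: d, c, seed, the four metrics, and their
#'   numerators/denominators.
#' @export
evaluate_replicate <- function(rep, predictions, direction_aware = FALSE) {
  bp <- per_bp_metrics(rep$truth, predictions, direction_aware)
  ex <- existence_metrics(rep$truth, predictions)
  data.frame(d = rep$config$d, c = rep$config$c_conv, seed = rep$seed,
             bp_sensitivity = bp$sensitivity, bp_fdr = bp$fdr,
             existence_sensitivity = ex$sensitivity,
             existence_fdr = ex$fdr,
             tp_bp = bp$tp_bp, true_bp = bp$true_bp,
             called_bp = bp$called_bp,
             detected_pairs = ex$detected_pairs,
             true_pairs = ex$true_pairs, called_pairs = ex$called_pairs,
             stringsAsFactors = FALSE)
}

#' Aggregate metric reports over replicates
#'
#' Unweighted mean of each metric within each (d, c) setting, the layout
#' of a detector-benchmark panel grid; metrics missing for a replicate
#' (e.g. a detector not run on it) are averaged over the available ones,
#' with the count reported.
#'
#' @param reports data.frame of per-replicate rows as produced by
#'   [evaluate_replicate()] (rbind-ed).
#' @return data.frame with one row per (d, c): mean of each metric and
#'   `n_<metric>` counts of contributing replicates.
#' @export
aggregate_replicates <- function(reports) {
  if (is.null(reports) || nrow(reports) == 0L)
    stop("no reports to aggregate")
  metrics <- c("bp_sensitivity", "bp_fdr",
               "existence_sensitivity", "existence_fdr")
  groups <- split(reports, list(reports$d, reports$c), drop = TRUE)
  out <- lapply(groups, function(g) {
    row <- data.frame(d = g$d[1L], c = g$c[1L], replicates = nrow(g))
    for (m in metrics) {
      v <- g[[m]]
      row[[m]] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
      row[[paste0("n_", m)]] <- sum(!is.na(v))
    }
    row
  })
  out <- do.call(rbind, out)
  out <- out[order(out$d, out$c), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Truth reformatted as a perfect prediction set
#'
#' Feeding this back through the metrics yields sensitivity 1 and FDR 0
#' on both levels, a self-consistency identity used throughout the test
#' suite.
#'
#' @param truth From [build_conversion_truth()].
#' @return data.frame in prediction format (pair_id, species, start, end).
#' @export
truth_as_predictions <- function(truth) {
  if (!nrow(truth))
    return(data.frame(pair_id = character(), species = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  truth[, c("pair_id", "species", "start", "end")]
}
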