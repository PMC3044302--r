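#' Simulate a full dataset of replicates to disk
#'
#' Runs `config$replications` independent replicates (seeds derived from
#' `seed`) and writes each to `out/rep<k>/` via [write_outputs()].
#'
#' @param config A [simulation_config()].
#' @param out Output directory.
#' @param seed Base integer seed.
#' @return Invisibly, the vector of replicate directories.
#' @export
simulate_dataset <- function(config, out, seed = 1L) {
  dirs <- character(config$replications)
  for (k in seq_len(config$replications)) {
    rep <- run_replicate(config, seed = derive_seed(seed, "rep", k))
    dirs[k] <- file.path(out, sprintf("rep%d", k))
    write_outputs(rep, dirs[k])
  }
  invisible(dirs)
}

#' Score a prediction file against a written replicate directory
#'
#' Reads the pair catalog and conversion truth emitted by
#' [write_outputs()], validates and parses the prediction TSV, and
#' computes the four benchmark metrics.
#'
#' @param truth_dir Replicate directory (must contain `pairs.tsv` and
#'   `conversion_truth.tsv`).
#' @param pred_file Prediction TSV (pair_id, seq_id, start, end).
#' @param direction_aware Passed to [per_bp_metrics()].
#' @return One-row data.frame of metrics with numerators/denominators.
#' @export
evaluate_outputs <- function(truth_dir, pred_file,
                             direction_aware = FALSE) {
  catalog <- read_tsv(file.path(truth_dir, "pairs.tsv"))
  truth <- read_tsv(file.path(truth_dir, "conversion_truth.tsv"))
  preds <- read_predictions(pred_file, catalog)
  bp <- per_bp_metrics(truth, preds, direction_aware)
  ex <- existence_metrics(truth, preds)
  data.frame(bp_sensitivity = bp$sensitivity, bp_fdr = bp$fdr,
             existence_sensitivity = ex$sensitivity,
             existence_fdr = ex$fdr,
             tp_bp = bp$tp_bp, true_bp = bp$true_bp,
             called_bp = bp$called_bp,
             detected_pairs = ex$detected_pairs,
             true_pairs = ex$true_pairs,
             called_pairs = ex$called_pairs,
             stringsAsFactors = FALSE)
}
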