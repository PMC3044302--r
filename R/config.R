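#' Simulation configuration
#'
#' All tunable parameters of a gene-cluster simulation.  The defaults
#' reproduce the study conditions of the primate-like benchmark design: a
#' 200 kb duplication-free ancestor; `d` duplication-category events per
#' epoch and `c` conversions per lineage from the second epoch on (so each
#' terminal species experiences `3d` duplication-category and `2c`
#' conversion events); NWM-human divergence calibrated to 89% identity and
#' OWM-human to 93%; optional purifying selection on conserved elements
#' covering 5% of the ancestor with geometrically distributed lengths of
#' mean 110 bp, evolving 30% slower than neutral sites.
#'
#' @param ancestral_length Ancestor length in bp (>= 1000).
#' @param d Duplication-category events per epoch (some become deletions,
#'   see `p_del`).
#' @param c_conv Conversion events per lineage per epoch (epochs 2 and 3).
#' @param replications Number of replicates per setting.
#' @param selection_mode `"neutral"` or `"neutral+purifying"`.
#' @param identity_nwm Target NWM-human sequence identity (fraction).
#' @param identity_owm Target OWM-human sequence identity (fraction).
#' @param p_del Probability a duplication-category event is a deletion.
#' @param stem_time Substitution time on the stem above the first split.
#'   Pairwise divergences between the terminal species do not depend on
#'   it; default 0 takes the ancestor to be the sequence at the first
#'   split.
#' @param kappa HKY transition/transversion ratio.
#' @param base_freqs Equilibrium base frequencies; `NULL` means estimate
#'   from the ancestral sequence composition.
#' @param conserved_coverage Fraction of the ancestor covered by conserved
#'   elements (purifying mode).
#' @param conserved_mean_len Mean conserved-element length (bp).
#' @param rate_factor Conserved-site substitution rate multiplier.
#' @param min_map_length Minimum tracked alignment length (bp).
#' @param min_seq_len Deletions never shrink a sequence below this.
#' @param allow_inverted_conversion Whether inverted paralog pairs are
#'   eligible conversion partners.
#' @param dists [event_distributions()].
#' @return Object of class `"simulation_config"`.
#' @export
simulation_config <- function(ancestral_length = 200000L,
                              d = 3L, c_conv = 2L,
                              replications = 5L,
                              selection_mode = c("neutral",
                                                 "neutral+purifying"),
                              identity_nwm = 0.89,
                              identity_owm = 0.93,
                              p_del = 0.2,
                              stem_time = 0,
                              kappa = 4,
                              base_freqs = NULL,
                              conserved_coverage = 0.05,
                              conserved_mean_len = 110,
                              rate_factor = 0.7,
                              min_map_length = 50L,
                              min_seq_len = 10000L,
                              allow_inverted_conversion = TRUE,
                              dists = event_distributions()) {
  selection_mode <- match.arg(selection_mode)
  if (d < 0L || c_conv < 0L) stop("d and c_conv must be non-negative")
  if (identity_owm < identity_nwm)
    stop("OWM-human identity must be >= NWM-human identity ",
         "(OWM split more recently)")
  structure(list(ancestral_length = as.integer(ancestral_length),
                 d = as.integer(d), c_conv = as.integer(c_conv),
                 replications = as.integer(replications),
                 selection_mode = selection_mode,
                 identity_nwm = identity_nwm, identity_owm = identity_owm,
                 p_del = p_del, stem_time = stem_time,
                 kappa = kappa, base_freqs = base_freqs,
                 conserved_coverage = conserved_coverage,
                 conserved_mean_len = conserved_mean_len,
                 rate_factor = rate_factor,
                 min_map_length = as.integer(min_map_length),
                 min_seq_len = as.integer(min_seq_len),
                 allow_inverted_conversion = allow_inverted_conversion,
                 dists = dists),
            class = "simulation_config")
}

#' Read a simulation configuration from YAML
#'
#' Top-level keys mirror the arguments of [simulation_config()]; the
#' `dists` key mirrors [event_distributions()].
#'
#' @param path YAML file.
#' @return A [simulation_config()].
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$dists)) y$dists <- do.call(event_distributions, y$dists)
  do.call(simulation_config, y)
}

## deterministic small-integer seed derived from a base seed and labels
derive_seed <- function(seed, ...) {
  h <- as.numeric(seed) %% 2147483647
  for (s in as.character(c(...))) {
    for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
  }
  as.integer(h)
}
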