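# Shared simulation fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# moderate-size replicate at the lightest study setting
fixture_replicate <- function() {
  if (is.null(.fixtures$rep))
    .fixtures$rep <- run_replicate(simulation_config(d = 3, c_conv = 2),
                                   seed = 101)
  .fixtures$rep
}

# small, fast configuration for determinism and pipeline checks
small_config <- function(...) {
  base <- list(
    ancestral_length = 30000L, min_seq_len = 5000L,
    dists = event_distributions(
      dup_len = list(dist = "lognormal", meanlog = log(1500), sdlog = 0.5),
      del_len = list(dist = "lognormal", meanlog = log(800), sdlog = 0.5),
      conv_len = list(dist = "lognormal", meanlog = log(400), sdlog = 0.5),
      spacing = list(dist = "geometric", mean = 3000)))
  do.call(simulation_config, utils::modifyList(base, list(...)))
}
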