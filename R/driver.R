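#' Generate (or load) a duplication-free ancestral sequence
#'
#' An i.i.d. random sequence has no self-similarity by construction, the
#' property required of the starting cluster ancestor.  A user FASTA (one
#' record) reproduces the alternative of starting from a real
#' duplication-free genomic region; it is uppercased and must be pure
#' ACGT.
#'
#' @param length Sequence length (>= 1000 bp; ignored when `fasta` given).
#' @param base_freqs Generation frequencies of A, C, G, T.
#' @param fasta Optional FASTA path.
#' @return An [evolving_sequence()] with lineage `"ancestor"`.
#' @export
generate_ancestral_sequence <- function(length = 200000L,
                                        base_freqs = rep(0.25, 4),
                                        fasta = NULL) {
  if (!is.null(fasta)) {
    ss <- Biostrings::readDNAStringSet(fasta)
    if (length(ss) != 1L) stop("ancestral FASTA must hold one record")
    return(evolving_sequence("ancestor",
                             toupper(as.character(ss[[1L]]))))
  }
  if (length < 1000L) stop("ancestral length must be >= 1000 bp")
  evolving_sequence("ancestor",
                    sample.int(4L, length, replace = TRUE,
                               prob = base_freqs))
}

#' Build the per-lineage event schedule
#'
#' Epoch 1 (stem, above the NWM split) carries `d` duplication-category
#' events; epoch 2 (between the splits) carries `d` duplication-category
#' plus `c` conversion events on each of the two lineages then alive (NWM
#' and the OWM-human ancestor `HO`); epoch 3 (below the OWM split) carries
#' the same on each of NWM, OWM and human.  Event times are i.i.d. uniform
#' within each epoch; duplication-category stubs are relabeled deletion
#' with probability `p_del`.  Every terminal species thus experiences
#' `3d` duplication-category and `2c` conversion events.
#'
#' @param config A [simulation_config()].
#' @param durations Numeric vector of the three epoch substitution
#'   durations.
#' @return data.frame with columns epoch, lineage, kind, time, sorted by
#'   (epoch, lineage, time).
#' @export
build_event_schedule <- function(config, durations) {
  epoch_lineages <- list(`1` = "stem", `2` = c("NWM", "HO"),
                         `3` = c("NWM", "OWM", "human"))
  rows <- list()
  for (ep in 1:3) {
    for (lin in epoch_lineages[[ep]]) {
      n_dup <- config$d
      n_conv <- if (ep == 1L) 0L else config$c_conv
      n <- n_dup + n_conv
      if (n == 0L) next
      kinds <- c(ifelse(stats::runif(n_dup) < config$p_del,
                        "deletion", "duplication"),
                 rep("conversion", n_conv))
      u <- stats::runif(n)
      rows[[length(rows) + 1L]] <-
        data.frame(epoch = ep, lineage = lin, kind = kinds,
                   time = u * durations[[ep]], u = u,
                   stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(epoch = integer(), lineage = character(),
                      kind = character(), time = numeric()))
  out <- do.call(rbind, rows)
  out <- out[order(out$epoch, out$lineage, out$u), ]
  out$u <- NULL
  rownames(out) <- NULL
  out
}

## Process one lineage through one epoch: evolve substitutions across each
## inter-event gap, apply each event, retrying deferred conversions after
## the next event.  `env` collects the event log and counters.
process_lineage_epoch <- function(state, lineage, stubs, duration,
                                  params, config, env) {
  queue <- if (nrow(stubs)) split(stubs, seq_len(nrow(stubs))) else list()
  t_prev <- 0
  i <- 1L
  while (i <= length(queue)) {
    stub <- queue[[i]]
    dt <- max(0, stub$time - t_prev)
    state$seqs[[lineage]] <- evolve_sequence(state$seqs[[lineage]], dt,
                                             params, config$rate_factor)
    t_prev <- max(t_prev, stub$time)
    env$n_event <- env$n_event + 1L
    eid <- sprintf("e%d", env$n_event)
    if (stub$kind == "duplication") {
      ev <- sample_duplication(state, lineage, config$dists, stub$time)
      state <- apply_duplication(state, ev)
      src <- attr(state, "source"); cp <- attr(state, "copy")
      env$log[[length(env$log) + 1L]] <- data.frame(
        event_id = eid, lineage = lineage, epoch = stub$epoch,
        time = stub$time, kind = "duplication",
        src_start = src$start, src_end = src$end,
        dst_start = cp$start, dst_end = cp$end,
        orientation = ev$orientation, direction = NA_character_,
        stringsAsFactors = FALSE)
    } else if (stub$kind == "deletion") {
      ev <- sample_deletion(state, lineage, config$dists, stub$time,
                            config$min_seq_len)
      state <- apply_deletion(state, ev)
      env$log[[length(env$log) + 1L]] <- data.frame(
        event_id = eid, lineage = lineage, epoch = stub$epoch,
        time = stub$time, kind = "deletion",
        src_start = ev$region$start, src_end = ev$region$end,
        dst_start = NA_integer_, dst_end = NA_integer_,
        orientation = NA_character_, direction = NA_character_,
        stringsAsFactors = FALSE)
    } else {                                   # conversion
      sel <- select_conversion_pair(state, lineage, config$dists,
                                    config$allow_inverted_conversion)
      if (is.null(sel)) {
        env$n_event <- env$n_event - 1L        # id not consumed
        if (i < length(queue)) {               # defer past the next event
          stub$time <- queue[[i + 1L]]$time
          queue <- append(queue[-i], list(stub), after = i)
          next
        }
        env$dropped <- env$dropped + 1L
        warning("conversion dropped on ", lineage,
                ": no eligible paralogous pair ever formed")
        i <- i + 1L
        next
      }
      state <- apply_conversion(state, lineage, sel$map, sel$k0, sel$k1,
                                sel$direction, stub$time, eid)
      ta <- attr(state, "tract_a"); tb <- attr(state, "tract_b")
      env$log[[length(env$log) + 1L]] <- data.frame(
        event_id = eid, lineage = lineage, epoch = stub$epoch,
        time = stub$time, kind = "conversion",
        src_start = ta$start, src_end = ta$end,
        dst_start = tb$start, dst_end = tb$end,
        orientation = sel$map$orientation, direction = sel$direction,
        stringsAsFactors = FALSE)
    }
    i <- i + 1L
  }
  state$seqs[[lineage]] <- evolve_sequence(state$seqs[[lineage]],
                                           max(0, duration - t_prev),
                                           params, config$rate_factor)
  state
}

#' Run one simulation replicate
#'
#' Generates the ancestor, places conserved elements (purifying mode),
#' calibrates the two divergence times, builds the event schedule, and
#' walks the three-species tree: substitutions over every inter-event gap,
#' events applied in time order, lineage state copied (and the full-length
#' ortholog alignment created) at each split.  Deterministic given
#' `(config, seed)`; per-lineage, per-epoch random substreams are derived
#' from the seed so lineages are independent streams.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @param ancestral_fasta Optional FASTA for the ancestor.
#' @return Object of class `"cs_replicate"`: terminal sequences, truth
#'   store, event log, conversion truth, pair catalog, config echo.
#' @export
run_replicate <- function(config, seed = 1L, ancestral_fasta = NULL) {
  set.seed(derive_seed(seed, "setup"))
  anc <- generate_ancestral_sequence(config$ancestral_length,
                                     config$base_freqs %||% rep(0.25, 4),
                                     ancestral_fasta)
  n <- length(anc$seq)
  freqs <- config$base_freqs %||% (tabulate(anc$seq, 4L) / n)
  params <- hky_params(config$kappa, freqs)
  purifying <- config$selection_mode == "neutral+purifying"
  if (purifying) {
    annot <- place_conserved_elements(n, config$conserved_coverage,
                                      config$conserved_mean_len,
                                      config$rate_factor)
    anc$conserved <- conserved_mask(annot, n)
  }
  T1 <- calibrate_divergence_time(config$identity_nwm, params)
  T2 <- calibrate_divergence_time(config$identity_owm, params)
  durations <- c(config$stem_time, (T1 - T2) / 2, T2 / 2)

  set.seed(derive_seed(seed, "schedule"))
  sched <- build_event_schedule(config, durations)

  store <- truth_store(config$min_map_length)
  store <- store_register_lineage(store, "stem", n)
  anc$lineage <- "stem"
  state <- cluster_state(list(stem = anc), store)
  env <- new.env(parent = emptyenv())
  env$log <- list(); env$n_event <- 0L; env$dropped <- 0L

  run_epoch <- function(state, ep, lineages) {
    for (lin in lineages) {
      set.seed(derive_seed(seed, "epoch", ep, lin))
      stubs <- sched[sched$epoch == ep & sched$lineage == lin, ,
                     drop = FALSE]
      state <- process_lineage_epoch(state, lin, stubs, durations[[ep]],
                                     params, config, env)
    }
    state
  }

  state <- run_epoch(state, 1L, "stem")
  ## NWM split: stem -> NWM + ancestor of OWM and human
  state$store <- store_split_lineage(state$store, "stem", "NWM", "HO")
  for (child in c("NWM", "HO")) {
    es <- state$seqs$stem; es$lineage <- child
    state$seqs[[child]] <- es
  }
  state$seqs$stem <- NULL
  state <- run_epoch(state, 2L, c("NWM", "HO"))
  ## OWM split
  state$store <- store_split_lineage(state$store, "HO", "OWM", "human")
  for (child in c("OWM", "human")) {
    es <- state$seqs$HO; es$lineage <- child
    state$seqs[[child]] <- es
  }
  state$seqs$HO <- NULL
  state <- run_epoch(state, 3L, c("NWM", "OWM", "human"))

  events <- if (length(env$log)) do.call(rbind, env$log) else
    data.frame(event_id = character(), lineage = character(),
               epoch = integer(), time = numeric(), kind = character(),
               src_start = integer(), src_end = integer(),
               dst_start = integer(), dst_end = integer(),
               orientation = character(), direction = character(),
               stringsAsFactors = FALSE)
  catalog <- build_pair_catalog(state$store)
  truth <- build_conversion_truth(state$store, catalog)
  structure(list(config = config, seed = seed, params = params,
                 divergence = list(T1 = T1, T2 = T2,
                                   durations = durations),
                 seqs = state$seqs[c("NWM", "OWM", "human")],
                 store = state$store, events = events,
                 catalog = catalog, truth = truth,
                 dropped_conversions = env$dropped),
            class = "cs_replicate")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.cs_replicate <- function(x, ...) {
  cat(sprintf(paste0("<cs_replicate seed=%s: d=%d c=%d, %d events, ",
                     "%d paralogous pairs, %d conversion tracts>\n"),
              x$seed, x$config$d, x$config$c_conv, nrow(x$events),
              nrow(x$catalog), length(x$store$tracks)))
  invisible(x)
}

#' Final paralogous-pair catalog
#'
#' One row per self alignment in the transitive paralogy closure of each
#' terminal species, in final coordinates.  This is the universe of pairs
#' a conversion detector can call.
#'
#' @param store The final [truth_store()].
#' @return data.frame (pair_id, species, a_start, a_end, b_start, b_end,
#'   orientation) with attribute `"maps"` holding the map objects by
#'   pair_id.
#' @export
build_pair_catalog <- function(store) {
  rows <- list(); maps <- list()
  for (sp in names(store$seq_len)) {
    cl <- paralog_closure(store, sp)
    if (length(cl) == 0L) next
    o <- order(vapply(cl, function(m) m$a$start, integer(1)),
               vapply(cl, function(m) m$b$start, integer(1)),
               vapply(cl, function(m) m$a$end, integer(1)))
    cl <- cl[o]
    for (i in seq_along(cl)) {
      m <- cl[[i]]
      id <- sprintf("%s_p%d", sp, i)
      m$id <- id
      maps[[id]] <- m
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = id, species = sp,
        a_start = m$a$start, a_end = m$a$end,
        b_start = m$b$start, b_end = m$b$end,
        orientation = m$orientation, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pair_id = character(), species = character(),
               a_start = integer(), a_end = integer(),
               b_start = integer(), b_end = integer(),
               orientation = character(), stringsAsFactors = FALSE)
  attr(out, "maps") <- maps
  out
}

#' True converted basepairs per catalog pair
#'
#' Attributes every surviving conversion tract piece to the catalog pairs
#' that carry the same homologous correspondence (exact positional
#' sub-map test), yielding, per pair, the truly converted intervals on
#' both sides and the set of pairs that experienced conversion.
#'
#' @param store Final [truth_store()].
#' @param catalog From [build_pair_catalog()].
#' @return data.frame (pair_id, species, side, start, end, event_id,
#'   direction); pairs with at least one row experienced conversion.
#' @export
build_conversion_truth <- function(store, catalog) {
  maps <- attr(catalog, "maps")
  rows <- list()
  for (tr in store$tracks) {
    for (tm in tr$maps) {
      sp <- tm$a$seq_id
      if (!sp %in% names(store$seq_len)) next   # internal lineage, replaced
      for (id in catalog$pair_id[catalog$species == sp]) {
        so <- submap_overlap(tm, maps[[id]])
        if (is.null(so)) next
        rows[[length(rows) + 1L]] <- data.frame(
          pair_id = id, species = sp,
          side = c("a", "b"),
          start = c(so$a$start, so$b$start),
          end = c(so$a$end, so$b$end),
          event_id = tr$event_id, direction = tr$direction,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(pair_id = character(), species = character(),
               side = character(), start = integer(), end = integer(),
               event_id = character(), direction = character(),
               stringsAsFactors = FALSE)
}
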