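## All writers are deterministic: stable ordering, fixed number formats,
## LF line endings.  Coordinates in every emitted file are 0-based
## half-open (BED/MAF convention).

#' Write all outputs of one replicate
#'
#' Emits, under `dir`: per-species FASTA; the truth alignments as MAF
#' (one gapless block per pairwise map); the event log, conversion-tract
#' table, pair catalog and per-pair conversion truth as TSV; per-species
#' conserved-element BED (purifying mode); per-homolog-set aligned FASTA
#' and relaxed PHYLIP with a name-mangling table; and a JSON manifest
#' echoing the configuration and seed.
#'
#' @param rep A [run_replicate()] result.
#' @param dir Output directory (created if needed).
#' @param homologs Optional precomputed [build_homolog_alignments()]
#'   result; computed here when `NULL`.
#' @return Invisibly, the vector of files written.
#' @export
write_outputs <- function(rep, dir, homologs = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  files <- character()
  put <- function(f) { files <<- c(files, f); f }

  species <- names(rep$seqs)
  dss <- Biostrings::DNAStringSet(
    vapply(rep$seqs, function(es) decode_dna(es$seq), character(1)))
  for (sp in species) {
    f <- put(file.path(dir, paste0(sp, ".fa")))
    Biostrings::writeXStringSet(dss[sp], f, width = 80L)
  }

  write_maf(rep, put(file.path(dir, "truth.maf")))
  write_tsv(rep$events, put(file.path(dir, "events.tsv")))
  write_tsv(tracks_table(rep$store),
            put(file.path(dir, "conversions.tsv")))
  cat_df <- rep$catalog; attr(cat_df, "maps") <- NULL
  write_tsv(cat_df, put(file.path(dir, "pairs.tsv")))
  write_tsv(rep$truth, put(file.path(dir, "conversion_truth.tsv")))

  if (rep$config$selection_mode == "neutral+purifying") {
    for (sp in species) {
      el <- elements_from_mask(rep$seqs[[sp]]$conserved)
      f <- put(file.path(dir, sprintf("conserved_%s.bed", sp)))
      writeLines(if (nrow(el))
        sprintf("%s\t%d\t%d", sp, el[, "start"], el[, "end"])
        else character(), f)
    }
  }

  if (is.null(homologs)) homologs <- build_homolog_alignments(rep)
  hdir <- file.path(dir, "homologs")
  dir.create(hdir, showWarnings = FALSE)
  for (hs in homologs) {
    for (bi in seq_along(hs$blocks)) {
      stem <- file.path(hdir, sprintf("%s_block%d", hs$pair_id, bi))
      write_homolog_block(hs, bi, put(paste0(stem, ".fa")),
                          put(paste0(stem, ".phy")),
                          put(paste0(stem, ".names.tsv")))
    }
  }

  manifest <- list(package = "clustersim",
                   version = as.character(utils::packageVersion("clustersim")),
                   seed = rep$seed,
                   config = config_as_list(rep$config),
                   divergence = rep$divergence[c("T1", "T2")],
                   species = species,
                   sequence_lengths = lapply(rep$seqs,
                                             function(es) length(es$seq)),
                   dropped_conversions = rep$dropped_conversions)
  jsonlite::write_json(manifest, put(file.path(dir, "manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(files)
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$dists <- unclass(out$dists)
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

## final-coordinate conversion tracts, one row per surviving piece
tracks_table <- function(store) {
  rows <- list()
  for (tr in store$tracks) {
    for (tm in tr$maps) {
      rows[[length(rows) + 1L]] <- data.frame(
        event_id = tr$event_id, lineage = tm$a$seq_id,
        time = tr$time, direction = tr$direction,
        a_start = tm$a$start, a_end = tm$a$end,
        b_start = tm$b$start, b_end = tm$b$end,
        orientation = tm$orientation, stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(event_id = character(), lineage = character(),
               time = numeric(), direction = character(),
               a_start = integer(), a_end = integer(),
               b_start = integer(), b_end = integer(),
               orientation = character(), stringsAsFactors = FALSE)
}

#' Write the truth alignments as MAF
#'
#' One alignment block per pairwise map, gapless rows; inverted partners
#' are written on the `-` strand with MAF's reverse-strand start
#' convention.
#'
#' @param rep A [run_replicate()] result.
#' @param path Output file.
#' @export
write_maf <- function(rep, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("##maf version=1 scoring=none",
               "# clustersim true pairwise alignments"), con)
  lens <- vapply(rep$seqs, function(es) length(es$seq), integer(1))
  maf_s <- function(iv, strand) {
    n <- lens[[iv$seq_id]]
    s <- if (strand == "+") iv$start else n - iv$end
    seq_int <- rep$seqs[[iv$seq_id]]$seq[(iv$start + 1L):iv$end]
    if (strand == "-") seq_int <- revcomp_int(seq_int)
    sprintf("s %s %d %d %s %d %s", iv$seq_id, s, iv_len(iv), strand, n,
            decode_dna(seq_int))
  }
  ids <- names(rep$store$maps)
  ids <- ids[order(as.integer(sub("^m", "", ids)))]
  for (id in ids) {
    m <- rep$store$maps[[id]]
    if (!all(c(m$a$seq_id, m$b$seq_id) %in% names(lens))) next
    writeLines(sprintf("a id=%s kind=%s", id, m$kind), con)
    writeLines(maf_s(m$a, "+"), con)
    writeLines(maf_s(m$b, if (m$orientation == "same") "+" else "-"), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a truth MAF back into a list of maps
#'
#' Companion parser for [write_maf()]; used for round-trip checks and for
#' consuming truth alignments downstream.
#'
#' @param path MAF file.
#' @param seq_lens Named vector of sequence lengths (for strand
#'   conversion); taken from the `s` lines when `NULL`.
#' @return List of [pairwise_map()]s.
#' @export
read_maf <- function(path, seq_lens = NULL) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (startsWith(lines[i], "a ")) {
      kind <- sub(".*kind=(\\w+).*", "\\1", lines[i])
      id <- sub(".*id=(\\S+) .*", "\\1", lines[i])
      parse_s <- function(l) {
        f <- strsplit(trimws(l), "\\s+")[[1L]]
        list(seq_id = f[2L], start = as.integer(f[3L]),
             size = as.integer(f[4L]), strand = f[5L],
             src_size = as.integer(f[6L]))
      }
      s1 <- parse_s(lines[i + 1L]); s2 <- parse_s(lines[i + 2L])
      to_iv <- function(s) {
        st <- if (s$strand == "+") s$start else s$src_size - s$start - s$size
        interval(s$seq_id, st, st + s$size)
      }
      out[[id]] <- pairwise_map(
        to_iv(s1), to_iv(s2),
        if (s1$strand == s2$strand) "same" else "inverted", kind, id = id)
      i <- i + 3L
    } else i <- i + 1L
  }
  out
}

## mangle member names to <= 10 characters for PHYLIP, bijectively within
## one block; the mapping is emitted alongside
mangle_names <- function(names) {
  short <- substr(gsub("[^A-Za-z0-9]", "", names), 1L, 7L)
  out <- character(length(names))
  seen <- c()
  for (i in seq_along(names)) {
    cand <- short[i]; k <- 0L
    while (cand %in% seen) { k <- k + 1L; cand <- sprintf("%s%d", short[i], k) }
    seen <- c(seen, cand)
    out[i] <- cand
  }
  out
}

write_homolog_block <- function(hs, bi, fa_path, phy_path, names_path) {
  b <- hs$blocks[[bi]]
  rows <- b$rows
  long <- sprintf("%s_%s_%d_%d%s", rows$name, rows$species, rows$start,
                  rows$end, ifelse(rows$strand == "-", "_rc", ""))
  ds <- Biostrings::DNAStringSet(rows$text)
  names(ds) <- long
  Biostrings::writeXStringSet(ds, fa_path, width = 80L)
  short <- mangle_names(long)
  con <- file(phy_path, "w")
  writeLines(sprintf(" %d %d", nrow(rows), nchar(rows$text[1L])), con)
  writeLines(sprintf("%-10s%s", short, rows$text), con)
  close(con)
  write_tsv(data.frame(short = short, long = long,
                       stringsAsFactors = FALSE), names_path)
  invisible(NULL)
}

#' Read detector predictions
#'
#' Parses a tab-separated prediction file with columns `pair_id`,
#' `seq_id`, `start`, `end` (0-based half-open intervals of called
#' conversion on either segment of a cataloged paralogous pair).
#' Unknown pair ids or coordinates outside the pair's segments are
#' rejected with the offending line number; overlapping tracts for one
#' pair are merged.
#'
#' @param path TSV file (may be empty or header-only).
#' @param catalog Pair catalog from [build_pair_catalog()].
#' @return data.frame (pair_id, species, start, end) of class
#'   `"prediction_set"`, merged per pair.
#' @export
read_predictions <- function(path, catalog) {
  empty <- data.frame(pair_id = character(), species = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (file.size(path) == 0L)
    return(structure(empty, class = c("prediction_set", "data.frame")))
  df <- read_tsv(path)
  need <- c("pair_id", "seq_id", "start", "end")
  if (!all(need %in% names(df)))
    stop("prediction file must have columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0L)
    return(structure(empty, class = c("prediction_set", "data.frame")))
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    j <- match(r$pair_id, catalog$pair_id)
    if (is.na(j))
      stop("line ", i + 1L, ": unknown pair_id '", r$pair_id, "'")
    if (!identical(r$seq_id, catalog$species[j]))
      stop("line ", i + 1L, ": seq_id '", r$seq_id,
           "' does not match pair's species '", catalog$species[j], "'")
    if (is.na(r$start) || is.na(r$end) || r$start < 0L || r$end <= r$start)
      stop("line ", i + 1L, ": malformed coordinates")
    in_a <- r$start >= catalog$a_start[j] && r$end <= catalog$a_end[j]
    in_b <- r$start >= catalog$b_start[j] && r$end <= catalog$b_end[j]
    if (!in_a && !in_b)
      stop("line ", i + 1L, ": interval [", r$start, ",", r$end,
           ") lies outside both segments of pair ", r$pair_id)
  }
  merged <- do.call(rbind, lapply(split(df, df$pair_id), function(g) {
    ir <- IRanges::reduce(IRanges::IRanges(g$start + 1L, g$end))
    data.frame(pair_id = g$pair_id[1L], species = g$seq_id[1L],
               start = IRanges::start(ir) - 1L, end = IRanges::end(ir),
               stringsAsFactors = FALSE)
  }))
  merged <- merged[order(merged$pair_id, merged$start), , drop = FALSE]
  rownames(merged) <- NULL
  structure(merged, class = c("prediction_set", "data.frame"))
}

#' Write predictions (or truth-as-predictions) in detector format
#'
#' @param df data.frame with pair_id, species (or seq_id), start, end.
#' @param path Output TSV.
#' @export
write_predictions <- function(df, path) {
  out <- data.frame(pair_id = df$pair_id,
                    seq_id = if ("seq_id" %in% names(df)) df$seq_id
                             else df$species,
                    start = df$start, end = df$end,
                    stringsAsFactors = FALSE)
  write_tsv(out, path)
}
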