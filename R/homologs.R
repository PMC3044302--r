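#' Build true multiple alignments of each homologous set
#'
#' For every paralogous pair in the final catalog, assembles the set of
#' homologous segments a conversion detector should see: the two
#' paralogous segments themselves plus every orthologous segment in the
#' other species, found by composing the pair's sides with the tracked
#' ortholog alignments.  Because all true alignments are gapless, the
#' rows are literal substrings of the final sequences (substitution
#' differences visible, no gap characters).  Members fragmented by
#' lineage-specific events are emitted block-wise: the pair's coordinate
#' range is partitioned at every member boundary, and each block carries
#' all members that fully cover it, so every block is a rectangular
#' alignment.
#'
#' @param rep A [run_replicate()] result.
#' @return List of homolog sets, one per catalog pair; each is a list
#'   with `pair_id`, `species`, and `blocks`, where each block has the
#'   column range (`start`, `end` on the pair's first side) and a
#'   data.frame of rows (`name`, `species`, `start`, `end`, `strand`,
#'   `text`).
#' @export
build_homolog_alignments <- function(rep) {
  maps <- attr(rep$catalog, "maps")
  orths <- store_maps(rep$store, kind = "ortholog")
  lapply(names(maps), function(id) {
    P <- maps[[id]]
    sp <- P$a$seq_id
    ident <- structure(list(id = NA_character_, a = P$a, b = P$a,
                            orientation = "same", kind = "self"),
                       class = "cs_map")
    members <- list(list(name = "a", map = ident),
                    list(name = "b", map = P))
    seen <- c()
    for (O in orths) {
      om <- if (identical(O$a$seq_id, sp)) O
            else if (identical(O$b$seq_id, sp)) flip_map(O) else NULL
      if (is.null(om)) next
      for (via in list(ident, P)) {
        cm <- compose_maps(via, om, kind = "ortholog")
        if (is.null(cm)) next
        key <- map_key(cm)
        if (key %in% seen) next
        seen <- c(seen, key)
        members[[length(members) + 1L]] <-
          list(name = sprintf("%s_%d", cm$b$seq_id, length(members)),
               map = cm)
      }
    }
    ## partition the column range at every member boundary
    bounds <- sort(unique(c(P$a$start, P$a$end,
                            unlist(lapply(members, function(m)
                              c(m$map$a$start, m$map$a$end))))))
    bounds <- bounds[bounds >= P$a$start & bounds <= P$a$end]
    blocks <- list()
    for (i in seq_len(length(bounds) - 1L)) {
      x <- bounds[i]; y <- bounds[i + 1L]
      rows <- list()
      for (m in members) {
        mm <- m$map
        if (mm$a$start > x || mm$a$end < y) next
        if (mm$orientation == "same") {
          bs <- mm$b$start + (x - mm$a$start)
          be <- bs + (y - x)
        } else {
          be <- mm$b$end - (x - mm$a$start)
          bs <- be - (y - x)
        }
        seq_int <- rep$seqs[[mm$b$seq_id]]$seq[(bs + 1L):be]
        if (mm$orientation == "inverted") seq_int <- revcomp_int(seq_int)
        rows[[length(rows) + 1L]] <- data.frame(
          name = m$name, species = mm$b$seq_id,
          start = bs, end = be,
          strand = if (mm$orientation == "same") "+" else "-",
          text = decode_dna(seq_int), stringsAsFactors = FALSE)
      }
      blocks[[length(blocks) + 1L]] <-
        list(start = x, end = y, rows = do.call(rbind, rows))
    }
    structure(list(pair_id = id, species = sp, blocks = blocks),
              class = "homolog_set")
  })
}
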