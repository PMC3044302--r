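#' Genomic interval on a simulated sequence
#'
#' All coordinates in clustersim are 0-based, half-open (`[start, end)`),
#' the convention of BED and MAF.  An interval lives on one lineage's
#' current sequence, identified by `seq_id`.
#'
#' @param seq_id Character scalar, the lineage/sequence identifier.
#' @param start 0-based inclusive start.
#' @param end Exclusive end; must satisfy `start < end`.
#' @return An object of class `"cs_interval"`.
#' @export
interval <- function(seq_id, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || end <= start)
    stop("invalid interval [", start, ",", end, ") on ", seq_id)
  structure(list(seq_id = seq_id, start = start, end = end),
            class = "cs_interval")
}

#' @export
print.cs_interval <- function(x, ...) {
  cat(sprintf("<%s:[%d,%d)>\n", x$seq_id, x$start, x$end))
  invisible(x)
}

iv_len <- function(iv) iv$end - iv$start

iv_overlap <- function(iv1, iv2) {
  if (!identical(iv1$seq_id, iv2$seq_id)) return(NULL)
  s <- max(iv1$start, iv2$start); e <- min(iv1$end, iv2$end)
  if (s >= e) return(NULL)
  interval(iv1$seq_id, s, e)
}

#' Coordinate edit on one lineage's sequence
#'
#' An insertion of `len` bases at position `pos` (the first inserted base
#' occupies position `pos` afterwards), or a deletion of `[start, end)`.
#' Edits are the journal currency of the truth store: every large-scale
#' event decomposes into zero or more edits.
#'
#' @param lineage Lineage whose sequence is edited.
#' @param type `"insertion"` or `"deletion"`.
#' @param pos Insertion point (insertions only).
#' @param len Insertion length (insertions only).
#' @param start,end Deleted range (deletions only).
#' @return An object of class `"cs_edit"`.
#' @export
coordinate_edit <- function(lineage, type = c("insertion", "deletion"),
                            pos = NULL, len = NULL,
                            start = NULL, end = NULL) {
  type <- match.arg(type)
  if (type == "insertion") {
    pos <- as.integer(pos); len <- as.integer(len)
    if (is.na(pos) || pos < 0L || is.na(len) || len < 1L)
      stop("invalid insertion edit")
    e <- list(lineage = lineage, type = type, pos = pos, len = len)
  } else {
    start <- as.integer(start); end <- as.integer(end)
    if (is.na(start) || start < 0L || is.na(end) || end <= start)
      stop("invalid deletion edit")
    e <- list(lineage = lineage, type = type, start = start, end = end)
  }
  structure(e, class = "cs_edit")
}

validate_edit <- function(edit, seq_len) {
  if (edit$type == "insertion") {
    if (edit$pos > seq_len) stop("insertion point beyond sequence end")
  } else {
    if (edit$end > seq_len) stop("deletion range beyond sequence end")
  }
  invisible(TRUE)
}

## Piece decomposition of an interval under an edit on its own sequence.
## Returns a list of pieces, each list(k0, k1, new_start): offsets [k0,k1)
## of the original interval that survive, relocated so the base at offset
## k0 now sits at position new_start (coordinates increase with k).
## Pieces are never merged here even when adjacent after the edit; map
## maintenance needs the split points.
decompose_interval <- function(iv, edit) {
  s <- iv$start; e <- iv$end
  if (edit$type == "insertion") {
    p <- edit$pos; L <- edit$len
    if (e <= p) return(list(list(k0 = 0L, k1 = e - s, new_start = s)))
    if (s >= p) return(list(list(k0 = 0L, k1 = e - s, new_start = s + L)))
    list(list(k0 = 0L, k1 = p - s, new_start = s),
         list(k0 = p - s, k1 = e - s, new_start = p + L))
  } else {
    ds <- edit$start; de <- edit$end; D <- de - ds
    if (e <= ds) return(list(list(k0 = 0L, k1 = e - s, new_start = s)))
    if (s >= de) return(list(list(k0 = 0L, k1 = e - s, new_start = s - D)))
    out <- list()
    if (s < ds)                       # left flank, coordinates unchanged
      out[[length(out) + 1L]] <- list(k0 = 0L, k1 = ds - s, new_start = s)
    if (e > de)                       # right flank, shifted left
      out[[length(out) + 1L]] <- list(k0 = de - s, k1 = e - s,
                                      new_start = ds)
    out
  }
}

#' Remap an interval through a coordinate edit
#'
#' Computes the image of an interval after an insertion or deletion on the
#' same sequence: shifted if the edit lies left of it, split in two if an
#' insertion lands strictly inside it, truncated (possibly to nothing) if a
#' deletion overlaps it.  The two flanks around an internal deletion become
#' adjacent and are returned merged as one interval.
#'
#' @param iv A [interval()].
#' @param edit A [coordinate_edit()] on `iv$seq_id`.
#' @param seq_len Current (pre-edit) length of the sequence, for validation.
#' @return A list of 0, 1 or 2 intervals in post-edit coordinates.
#' @export
remap_interval <- function(iv, edit, seq_len = NULL) {
  if (!is.null(seq_len)) {
    validate_edit(edit, seq_len)
    if (iv$end > seq_len) stop("interval beyond sequence end")
  }
  pieces <- decompose_interval(iv, edit)
  if (length(pieces) == 0L) return(list())
  ivs <- lapply(pieces, function(p)
    interval(iv$seq_id, p$new_start, p$new_start + (p$k1 - p$k0)))
  ## merge pieces that are adjacent in the new coordinates (deletion flanks)
  out <- list(ivs[[1L]])
  for (x in ivs[-1L]) {
    last <- out[[length(out)]]
    if (x$start == last$end)
      out[[length(out)]] <- interval(iv$seq_id, last$start, x$end)
    else out[[length(out) + 1L]] <- x
  }
  out
}

#' Gapless pairwise alignment map
#'
#' The unit of truth alignment: an exact, gapless correspondence between two
#' equal-length intervals.  Since small-scale mutation is substitution-only,
#' homologous segments never change length relative to each other and every
#' true alignment is gapless.  `kind = "self"` maps pair two paralogous
#' segments of one sequence (stored once, lower-start interval first);
#' `kind = "ortholog"` maps segments of two different species.  With
#' `orientation = "inverted"`, offset `k` of `a` corresponds to offset
#' `length - 1 - k` of `b` (and bases are complementary).
#'
#' @param a,b [interval()]s of equal length.
#' @param orientation `"same"` or `"inverted"`.
#' @param kind `"self"` or `"ortholog"`.
#' @param id Optional stable identifier.
#' @return An object of class `"cs_map"`.
#' @export
pairwise_map <- function(a, b, orientation = c("same", "inverted"),
                         kind = c("self", "ortholog"), id = NA_character_) {
  orientation <- match.arg(orientation)
  kind <- match.arg(kind)
  if (iv_len(a) != iv_len(b))
    stop("map sides differ in length: ", iv_len(a), " vs ", iv_len(b))
  if (kind == "self") {
    if (!identical(a$seq_id, b$seq_id))
      stop("self map requires both sides on one sequence")
    if (a$start > b$start) { tmp <- a; a <- b; b <- tmp }
  } else if (identical(a$seq_id, b$seq_id))
    stop("ortholog map requires sides on different sequences")
  structure(list(id = id, a = a, b = b, orientation = orientation,
                 kind = kind),
            class = "cs_map")
}

#' @export
print.cs_map <- function(x, ...) {
  cat(sprintf("<map %s %s %s:[%d,%d) ~ %s:[%d,%d) %s>\n",
              ifelse(is.na(x$id), "", x$id), x$kind,
              x$a$seq_id, x$a$start, x$a$end,
              x$b$seq_id, x$b$start, x$b$end, x$orientation))
  invisible(x)
}

map_len <- function(m) iv_len(m$a)

## position on b homologous to position x on a
map_fwd <- function(m, x) {
  if (m$orientation == "same") m$b$start + (x - m$a$start)
  else m$b$end - 1L - (x - m$a$start)
}

flip_map <- function(m) {
  structure(list(id = m$id, a = m$b, b = m$a, orientation = m$orientation,
                 kind = m$kind), class = "cs_map")
}

map_key <- function(m) {
  paste(m$a$seq_id, m$a$start, m$a$end,
        m$b$seq_id, m$b$start, m$b$end, m$orientation, sep = ":")
}

## canonical form of a self map: lower-start side first
canonicalize_map <- function(m) {
  if (m$kind == "self" && m$a$start > m$b$start) flip_map(m) else m
}

#' Compose two pairwise maps
#'
#' If `m1` maps A to B and `m2` maps (part of) B to C, the composition maps
#' the pre-image in A of `overlap(m1$b, m2$a)` to its image in C.  This is
#' how transitive paralogy arises: when A is duplicated to B and B to C,
#' composing the two self maps yields the (A, C) paralogy, a legitimate
#' gene-conversion partner pair.
#'
#' @param m1,m2 [pairwise_map()]s with `m1$b` and `m2$a` on one sequence.
#' @param kind Kind for the result; defaults to `"self"` when all four
#'   intervals share a sequence, `"ortholog"` otherwise.
#' @return A [pairwise_map()], or `NULL` when the overlap is empty.
#' @export
compose_maps <- function(m1, m2, kind = NULL) {
  ov <- iv_overlap(m1$b, m2$a)
  if (is.null(ov)) return(NULL)
  n <- ov$end - ov$start
  ## pre-image of ov in m1$a
  if (m1$orientation == "same") {
    a_start <- m1$a$start + (ov$start - m1$b$start)
  } else {
    a_start <- m1$a$start + (m1$b$end - ov$end)
  }
  ## image of ov under m2
  if (m2$orientation == "same") {
    c_start <- m2$b$start + (ov$start - m2$a$start)
  } else {
    c_start <- m2$b$start + (m2$a$end - ov$end)
  }
  orientation <- if (m1$orientation == m2$orientation) "same" else "inverted"
  if (is.null(kind))
    kind <- if (identical(m1$a$seq_id, m2$b$seq_id)) "self" else "ortholog"
  A <- interval(m1$a$seq_id, a_start, a_start + n)
  C <- interval(m2$b$seq_id, c_start, c_start + n)
  if (kind == "self" && A$start == C$start && A$end == C$end)
    return(NULL)                      # identity composition, not a paralogy
  canonicalize_map(pairwise_map(A, C, orientation, kind))
}

## ---- map maintenance under edits ------------------------------------

## Side pieces in map-offset space: list(k0, k1, ns, dir) meaning offsets
## [k0,k1) survive and the side position at offset k is ns + dir*(k - k0).
side_pieces <- function(iv, orientation_rev, edit, edited) {
  len <- iv_len(iv)
  if (!edited)
    return(list(list(k0 = 0L, k1 = len,
                     ns = if (orientation_rev) iv$end - 1L else iv$start,
                     dir = if (orientation_rev) -1L else 1L)))
  pieces <- decompose_interval(iv, edit)
  lapply(pieces, function(p) {
    if (!orientation_rev) {
      list(k0 = p$k0, k1 = p$k1, ns = p$new_start, dir = 1L)
    } else {
      ## offset k corresponds to side position iv$start + (len - 1 - k);
      ## piece covers positions [iv$start + p$k0, iv$start + p$k1)
      k0 <- len - p$k1
      k1 <- len - p$k0
      ## at offset k0, position is iv$start + p$k1 - 1 -> relocated to
      ## new_start + (p$k1 - 1 - p$k0)
      list(k0 = k0, k1 = k1, ns = p$new_start + (p$k1 - 1L - p$k0),
           dir = -1L)
    }
  })
}

## Remap a map through an edit; returns a list of surviving sub-maps in
## post-edit coordinates (no length filtering here).
remap_map <- function(m, edit) {
  a_ed <- identical(m$a$seq_id, edit$lineage)
  b_ed <- identical(m$b$seq_id, edit$lineage)
  if (!a_ed && !b_ed) return(list(m))
  inv <- m$orientation == "inverted"
  pa <- side_pieces(m$a, FALSE, edit, a_ed)
  pb <- side_pieces(m$b, inv, edit, b_ed)
  out <- list()
  for (x in pa) for (y in pb) {
    k0 <- max(x$k0, y$k0); k1 <- min(x$k1, y$k1)
    if (k1 <= k0) next
    as_ <- x$ns + (k0 - x$k0)
    A <- interval(m$a$seq_id, as_, as_ + (k1 - k0))
    if (y$dir == 1L) {
      bs_ <- y$ns + (k0 - y$k0)
      B <- interval(m$b$seq_id, bs_, bs_ + (k1 - k0))
    } else {
      b_hi <- y$ns - (k0 - y$k0)          # position at offset k0 (largest)
      b_lo <- y$ns - (k1 - 1L - y$k0)     # position at offset k1-1
      B <- interval(m$b$seq_id, b_lo, b_hi + 1L)
    }
    out[[length(out) + 1L]] <-
      canonicalize_map(pairwise_map(A, B, m$orientation, m$kind, id = m$id))
  }
  out
}
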