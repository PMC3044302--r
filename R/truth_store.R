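#' Truth-alignment store
#'
#' Holds every true pairwise alignment of the simulation — ortholog maps
#' between species and self (paralogy) maps within a species — plus the
#' journal of coordinate edits and the true conversion tracts.  All maps
#' are maintained in the *current* coordinates of each lineage: every
#' insertion or deletion remaps every affected map, splitting it where the
#' edit falls strictly inside, exactly as the bold alignment lines of a
#' duplication diagram split.  This is what makes the final true orthologs,
#' paralogs and converted basepairs recoverable without any alignment
#' estimation.
#'
#' @param min_map_length Maps shorter than this (bp) are dropped after
#'   truncation; compositions and deletions can shred alignments into
#'   fragments too short to be meaningful paralogy.
#' @return An object of class `"truth_store"`.
#' @export
truth_store <- function(min_map_length = 50L) {
  structure(list(maps = list(), tracks = list(), journal = list(),
                 seq_len = integer(), next_id = 1L,
                 min_map_length = as.integer(min_map_length)),
            class = "truth_store")
}

#' @export
print.truth_store <- function(x, ...) {
  kinds <- vapply(x$maps, function(m) m$kind, character(1))
  cat(sprintf("<truth_store: %d ortholog maps, %d self maps, %d lineages, %d edits>\n",
              sum(kinds == "ortholog"), sum(kinds == "self"),
              length(x$seq_len), length(x$journal)))
  invisible(x)
}

store_register_lineage <- function(store, lineage, len) {
  store$seq_len[[lineage]] <- as.integer(len)
  store
}

store_add_map <- function(store, m) {
  if (map_len(m) < store$min_map_length) return(store)
  m$id <- sprintf("m%d", store$next_id)
  store$next_id <- store$next_id + 1L
  store$maps[[m$id]] <- m
  store
}

store_maps <- function(store, kind = NULL, lineage = NULL) {
  ms <- store$maps
  if (!is.null(kind))
    ms <- Filter(function(m) m$kind == kind, ms)
  if (!is.null(lineage))
    ms <- Filter(function(m) identical(m$a$seq_id, lineage) ||
                             identical(m$b$seq_id, lineage), ms)
  ms
}

## Remap every map and conversion track through one coordinate edit and
## append it to the journal.  Maps that fall below min_map_length are
## dropped; split maps get fresh ids.
store_apply_edit <- function(store, edit) {
  lin <- edit$lineage
  if (!lin %in% names(store$seq_len)) stop("unknown lineage: ", lin)
  validate_edit(edit, store$seq_len[[lin]])
  new_maps <- list()
  for (m in store$maps) {
    pieces <- remap_map(m, edit)
    pieces <- Filter(function(p) map_len(p) >= store$min_map_length, pieces)
    if (length(pieces) == 1L) {
      p <- pieces[[1L]]
      p$id <- m$id                       # survives intact or truncated
      new_maps[[p$id]] <- p
    } else if (length(pieces) > 1L) {
      for (p in pieces) {
        p$id <- sprintf("m%d", store$next_id)
        store$next_id <- store$next_id + 1L
        new_maps[[p$id]] <- p
      }
    }
  }
  store$maps <- new_maps
  store$tracks <- lapply(store$tracks, function(tr) {
    tr$maps <- unlist(lapply(tr$maps, remap_map, edit = edit),
                      recursive = FALSE)
    tr
  })
  if (edit$type == "insertion") {
    store$seq_len[[lin]] <- store$seq_len[[lin]] + edit$len
  } else {
    store$seq_len[[lin]] <- store$seq_len[[lin]] - (edit$end - edit$start)
  }
  store$journal[[length(store$journal) + 1L]] <- edit
  store
}


#' Record a duplication in the truth store
#'
#' Applies the insertion edit to every map (splitting any alignment the
#' copy lands inside), adds the new self map pairing the source with its
#' copy, and derives the copy's ortholog maps: for every ortholog alignment
#' overlapping the source, the copy is orthologous to the corresponding
#' partner segment, obtained by composition.  This reproduces the canonical
#' picture in which one duplication splits alignment a into a1 and a2 and
#' generates the additional ortholog alignment b.
#'
#' @param store A [truth_store()].
#' @param lineage Lineage in which the duplication occurs.
#' @param source Source [interval()] (pre-edit coordinates).
#' @param insert_at Insertion point (pre-edit coordinates); must not fall
#'   strictly inside `source`.
#' @param orientation `"same"` for a direct copy, `"inverted"` for a
#'   reverse-complemented copy.
#' @return The updated store, with attributes `source` and `copy` giving
#'   the post-edit source and copy intervals.
#' @export
update_on_duplication <- function(store, lineage, source, insert_at,
                                  orientation = "same") {
  L <- iv_len(source)
  if (insert_at > source$start && insert_at < source$end)
    stop("insertion point inside duplication source")
  orth_overlapping <- Filter(function(m) {
    side <- if (identical(m$a$seq_id, lineage)) m$a
            else if (identical(m$b$seq_id, lineage)) m$b else NULL
    !is.null(side) && !is.null(iv_overlap(side, source))
  }, store_maps(store, kind = "ortholog"))

  edit <- coordinate_edit(lineage, "insertion", pos = insert_at, len = L)
  store <- store_apply_edit(store, edit)

  src2 <- if (source$start >= insert_at)
    interval(lineage, source$start + L, source$end + L) else source
  copy <- interval(lineage, insert_at, insert_at + L)

  store <- store_add_map(store, pairwise_map(src2, copy, orientation, "self"))

  ## copy -> source map (uncanonicalized so composition direction is fixed)
  cp2src <- structure(list(id = NA_character_, a = copy, b = src2,
                           orientation = orientation, kind = "self"),
                      class = "cs_map")
  for (m in orth_overlapping) {
    ## re-fetch the post-edit pieces of this ortholog map by id prefix is
    ## unreliable; instead remap its lineage side through the edit directly.
    m2 <- remap_map(m, edit)
    for (p in m2) {
      pm <- if (identical(p$a$seq_id, lineage)) p else flip_map(p)
      comp <- compose_maps(cp2src, pm, kind = "ortholog")
      if (!is.null(comp)) store <- store_add_map(store, comp)
    }
  }
  attr(store, "source") <- src2
  attr(store, "copy") <- copy
  store
}

#' Record a deletion in the truth store
#'
#' Every map interval on the lineage is truncated, split, or removed, with
#' the partner side trimmed at the homologous offsets (mirrored for
#' inverted maps) so both sides stay equal length; maps falling below
#' `min_map_length` are dropped.
#'
#' @inheritParams update_on_duplication
#' @param region Deleted [interval()].
#' @return The updated store.
#' @export
update_on_deletion <- function(store, lineage, region) {
  edit <- coordinate_edit(lineage, "deletion",
                          start = region$start, end = region$end)
  store_apply_edit(store, edit)
}

## is `small` positionally contained in `big` with the same homologous
## correspondence (same pairing function on all of small)?
map_contains <- function(big, small) {
  so <- submap_overlap(small, big)
  !is.null(so) && iv_len(so$a) == map_len(small)
}

#' Transitive paralogy closure for one lineage
#'
#' Starting from the direct self maps created by duplications, repeatedly
#' composes pairs of maps (in every orientation of their sides) until no
#' new paralogy appears: when A was duplicated to B and B to C, the pairs
#' (A,B), (B,C) and (A,C) are all eligible gene-conversion partners.
#' Only maximal homologies are kept: a composition whose correspondence
#' is already contained in a retained map is redundant and dropped, which
#' keeps the closure finite and interpretable (fragments of fragments
#' carry no new paralogy).  Results are filtered to `min_map_length`.
#'
#' @inheritParams update_on_duplication
#' @param max_iter Safety bound on composition rounds.
#' @return List of self [pairwise_map()]s (the conversion pair catalog).
#' @export
paralog_closure <- function(store, lineage, max_iter = 8L) {
  base <- unname(store_maps(store, kind = "self", lineage = lineage))
  if (length(base) == 0L) return(list())
  out <- list()
  add <- function(m) {
    for (o in out) if (map_contains(o, m)) return(FALSE)
    keep <- vapply(out, function(o) !map_contains(m, o), logical(1))
    out <<- c(out[keep], list(m))
    TRUE
  }
  for (m in base) add(m)
  frontier <- out
  for (it in seq_len(max_iter)) {
    fresh <- list()
    for (m1 in frontier) for (m2 in out) {
      for (x in list(m1, flip_map(m1))) for (y in list(m2, flip_map(m2))) {
        for (pair in list(list(x, y), list(y, x))) {
          comp <- compose_maps(pair[[1L]], pair[[2L]], kind = "self")
          if (is.null(comp)) next
          if (map_len(comp) < store$min_map_length) next
          if (add(comp)) fresh[[length(fresh) + 1L]] <- comp
        }
      }
    }
    if (length(fresh) == 0L) break
    frontier <- fresh
  }
  out
}

## Record a conversion tract in the truth store.  Conversions do not change
## coordinates; the pair of homologous tract intervals is itself a gapless
## self map, stored as such and carried through all subsequent edits (and
## lineage splits), so the truly converted basepairs and their pairing are
## known exactly in final coordinates.
store_add_track <- function(store, event_id, lineage, time, direction,
                            tract_map) {
  store$tracks[[length(store$tracks) + 1L]] <-
    list(event_id = event_id, lineage = lineage, time = time,
         direction = direction, maps = list(tract_map))
  store
}

## Does tract piece T lie (partly) on catalog pair P with the *same*
## homologous correspondence?  True when the a-sides overlap, orientations
## agree, and the partner mapping coincides on the overlap (checked at one
## anchor; both maps are gapless and linear).  P is tried in both side
## orders.  Returns the agreeing sub-tract as list(a=, b=) or NULL.
submap_overlap <- function(tm, pm) {
  for (qm in list(pm, flip_map(pm))) {
    if (!identical(tm$a$seq_id, qm$a$seq_id)) next
    if (!identical(tm$b$seq_id, qm$b$seq_id)) next
    if (tm$orientation != qm$orientation) next
    ov <- iv_overlap(tm$a, qm$a)
    if (is.null(ov)) next
    if (map_fwd(tm, ov$start) != map_fwd(qm, ov$start)) next
    b_lo <- map_fwd(tm, if (tm$orientation == "same") ov$start else
                          ov$end - 1L)
    b_img <- interval(tm$b$seq_id, b_lo, b_lo + iv_len(ov))
    ## the image lies within qm's b side automatically: the overlap was
    ## taken on the a sides and the two mappings coincide there
    return(list(a = ov, b = b_img))
  }
  NULL
}

## Split a lineage into two children: clone every map and track touching
## the parent (self maps and tracks once per child; ortholog maps to a
## third species once per child), then add the full-length ortholog map
## between the children — the single long alignment two species share the
## instant they split.
store_split_lineage <- function(store, parent, child1, child2) {
  n <- store$seq_len[[parent]]
  if (is.null(n)) stop("unknown lineage: ", parent)
  retarget_iv <- function(iv, child)
    if (identical(iv$seq_id, parent)) interval(child, iv$start, iv$end) else iv
  new_maps <- list()
  for (m in store$maps) {
    touches <- identical(m$a$seq_id, parent) || identical(m$b$seq_id, parent)
    if (!touches) { new_maps[[m$id]] <- m; next }
    for (child in c(child1, child2)) {
      mm <- m
      mm$a <- retarget_iv(m$a, child)
      mm$b <- retarget_iv(m$b, child)
      mm$id <- sprintf("m%d", store$next_id)
      store$next_id <- store$next_id + 1L
      new_maps[[mm$id]] <- mm
    }
  }
  store$maps <- new_maps
  new_tracks <- list()
  for (tr in store$tracks) {
    if (!identical(tr$lineage, parent)) {
      new_tracks[[length(new_tracks) + 1L]] <- tr
      next
    }
    for (child in c(child1, child2)) {
      t2 <- tr
      t2$lineage <- child
      t2$maps <- lapply(tr$maps, function(m) {
        m$a <- retarget_iv(m$a, child)
        m$b <- retarget_iv(m$b, child)
        m
      })
      new_tracks[[length(new_tracks) + 1L]] <- t2
    }
  }
  store$tracks <- new_tracks
  store$seq_len <- store$seq_len[names(store$seq_len) != parent]
  store <- store_register_lineage(store, child1, n)
  store <- store_register_lineage(store, child2, n)
  store_add_map(store, pairwise_map(interval(child1, 0L, n),
                                    interval(child2, 0L, n),
                                    "same", "ortholog"))
}
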