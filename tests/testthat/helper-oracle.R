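# Label-replay oracle: every basepair of the starting sequence carries a
# unique integer label; duplications copy labels (reversed when inverted),
# deletions remove them, lineage splits clone the label vector, and
# conversions touch nothing.  Two positions are truly homologous iff they
# carry the same label, so any tracked alignment map can be checked
# against the oracle position by position, independently of the interval
# arithmetic under test.

oracle_new <- function(lineage, n) {
  out <- list()
  out[[lineage]] <- seq_len(n)
  out
}

oracle_dup <- function(orc, lineage, src_start, src_end, insert_at,
                       inverted = FALSE) {
  lab <- orc[[lineage]]
  seg <- lab[(src_start + 1):src_end]
  if (inverted) seg <- rev(seg)
  orc[[lineage]] <- append(lab, seg, after = insert_at)
  orc
}

oracle_del <- function(orc, lineage, start, end) {
  orc[[lineage]] <- orc[[lineage]][-((start + 1):end)]
  orc
}

oracle_split <- function(orc, parent, child1, child2) {
  orc[[child1]] <- orc[[parent]]
  orc[[child2]] <- orc[[parent]]
  orc[[parent]] <- NULL
  orc
}

# every position pair related by a store map must carry equal labels
expect_store_consistent <- function(store, orc) {
  for (m in store$maps) {
    la <- orc[[m$a$seq_id]][(m$a$start + 1):m$a$end]
    lb <- orc[[m$b$seq_id]][(m$b$start + 1):m$b$end]
    if (m$orientation == "inverted") lb <- rev(lb)
    expect_identical(la, lb)
    expect_identical(m$a$end - m$a$start, m$b$end - m$b$start)
  }
}

# per-position image of a map as a two-column matrix (a position, b position)
map_positions <- function(m) {
  xs <- m$a$start:(m$a$end - 1)
  cbind(a = xs, b = vapply(xs, function(x) {
    if (m$orientation == "same") m$b$start + (x - m$a$start)
    else m$b$end - 1 - (x - m$a$start)
  }, numeric(1)))
}

# brute-force per-position composition of two maps
compose_positions <- function(m1, m2) {
  p1 <- map_positions(m1); p2 <- map_positions(m2)
  j <- match(p1[, "b"], p2[, "a"])
  keep <- !is.na(j)
  if (!any(keep)) return(NULL)
  cbind(a = p1[keep, "a"], b = p2[j[keep], "b"])
}

store_add_map_public <- function(store, m) clustersim:::store_add_map(store, m)
encode_dna_public <- function(x) clustersim:::encode_dna(x)
decode_dna_public <- function(x) clustersim:::decode_dna(x)

# random scripted history applied in parallel to a truth store and the
# oracle; returns both for consistency checks
random_history <- function(n_events = 5, seq_len = 3000, seed = 1,
                           min_map_length = 1) {
  set.seed(seed)
  store <- truth_store(min_map_length)
  store <- clustersim:::store_register_lineage(store, "s1", seq_len)
  orc <- oracle_new("s1", seq_len)
  for (i in seq_len(n_events)) {
    n <- store$seq_len[["s1"]]
    if (runif(1) < 0.6 || n < 600) {          # duplication
      len <- sample(50:300, 1)
      s <- sample(0:(n - len), 1)
      repeat {
        p <- sample(0:n, 1)
        if (p <= s || p >= s + len) break
      }
      inv <- runif(1) < 0.3
      store <- update_on_duplication(store, "s1", interval("s1", s, s + len),
                                     p, if (inv) "inverted" else "same")
      orc <- oracle_dup(orc, "s1", s, s + len, p, inv)
    } else {                                   # deletion
      len <- sample(20:200, 1)
      s <- sample(0:(n - len), 1)
      store <- update_on_deletion(store, "s1", interval("s1", s, s + len))
      orc <- oracle_del(orc, "s1", s, s + len)
    }
  }
  list(store = store, orc = orc)
}
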