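# duplication/deletion/conversion sampling and application

make_state <- function(seq_len = 20000, seed = 5, min_map_length = 50) {
  set.seed(seed)
  store <- truth_store(min_map_length)
  store <- clustersim:::store_register_lineage(store, "s1", seq_len)
  clustersim:::cluster_state(
    list(s1 = evolving_sequence("s1", sample(1:4, seq_len, replace = TRUE))),
    store)
}

test_that("sampled duplications have valid coordinates and honored degenerate dists", {
  state <- make_state()
  set.seed(9)
  for (i in 1:50) {
    ev <- sample_duplication(state, "s1", event_distributions())
    n <- 20000
    expect_true(ev$source$start >= 0 && ev$source$end <= n)
    expect_true(ev$insert_at >= 0 && ev$insert_at <= n)
    expect_true(ev$insert_at <= ev$source$start ||
                ev$insert_at >= ev$source$end)
  }
  # fixed length/spacing, forward: copy immediately adjacent to the source
  d0 <- event_distributions(dup_len = list(dist = "fixed", value = 1000),
                            spacing = list(dist = "fixed", value = 0),
                            p_inverted = 0)
  set.seed(10)
  ev <- sample_duplication(state, "s1", d0)
  expect_equal(ev$source$end - ev$source$start, 1000)
  expect_true(ev$insert_at %in% c(ev$source$start, ev$source$end))
  expect_equal(ev$orientation, "same")
})

test_that("sampled duplication lengths recover the configured distribution", {
  dists <- event_distributions()
  set.seed(11)
  draws <- clustersim:::sample_dist(dists$dup_len, 10000)
  # jitter to break integer ties for the KS test
  ks <- suppressWarnings(
    stats::ks.test(draws + stats::runif(10000, -0.5, 0.5),
                   stats::plnorm, meanlog = log(5000), sdlog = 0.7))
  expect_gt(ks$p.value, 0.01)
})

test_that("applying a duplication inserts the (reverse-complemented) source text", {
  state <- make_state()
  ev <- list(kind = "duplication", lineage = "s1",
             source = interval("s1", 0, 10), insert_at = 20,
             orientation = "same")
  st2 <- apply_duplication(state, ev)
  expect_equal(length(st2$seqs$s1$seq), 20010)
  expect_equal(st2$seqs$s1$seq[21:30], state$seqs$s1$seq[1:10])

  evi <- list(kind = "duplication", lineage = "s1",
              source = interval("s1", 0, 8), insert_at = 20,
              orientation = "inverted")
  sti <- apply_duplication(make_state(), evi)
  expect_equal(sti$seqs$s1$seq[21:28],
               clustersim:::revcomp_int(state$seqs$s1$seq[1:8]))
  # hand-checked: "AAAACCCC" inverted-duplicates as "GGGGTTTT"
  st <- clustersim:::cluster_state(
    list(s1 = evolving_sequence("s1", "AAAACCCCGGGG")),
    clustersim:::store_register_lineage(truth_store(1), "s1", 12))
  out <- apply_duplication(st, list(kind = "duplication", lineage = "s1",
                                    source = interval("s1", 0, 8),
                                    insert_at = 12,
                                    orientation = "inverted"))
  expect_equal(substr(decode_dna_public(out$seqs$s1$seq), 13, 20),
               "GGGGTTTT")
})

test_that("deletion removes sequence, mask and affected maps coherently", {
  state <- make_state()
  state$seqs$s1$conserved[101:200] <- TRUE
  ev <- list(kind = "deletion", lineage = "s1",
             region = interval("s1", 50, 150))
  st2 <- apply_deletion(state, ev)
  expect_equal(length(st2$seqs$s1$seq), 19900)
  expect_equal(st2$seqs$s1$seq, state$seqs$s1$seq[-(51:150)])
  expect_equal(sum(st2$seqs$s1$conserved), 50)
})

test_that("conversion pair selection is uniform over the closure", {
  state <- make_state()
  # three disjoint self maps, no transitive overlap
  for (ab in list(c(0, 500, 1000), c(2000, 500, 3000), c(5000, 500, 6000))) {
    state$store <- store_add_map_public(state$store,
      pairwise_map(interval("s1", ab[1], ab[1] + ab[2]),
                   interval("s1", ab[3], ab[3] + ab[2]), "same", "self"))
  }
  set.seed(12)
  picks <- replicate(3000, {
    sel <- select_conversion_pair(state, "s1", event_distributions())
    sel$map$a$start
  })
  tab <- table(picks)
  expect_length(tab, 3)
  p <- 1 / 3
  tol <- 3 * sqrt(p * (1 - p) * 3000)
  expect_true(all(abs(tab - 3000 * p) < tol))
})

test_that("oversized tract samples truncate to the whole map", {
  state <- make_state()
  state$store <- store_add_map_public(state$store,
    pairwise_map(interval("s1", 0, 200), interval("s1", 1000, 1200),
                 "same", "self"))
  dists <- event_distributions(conv_len = list(dist = "fixed", value = 10000))
  set.seed(13)
  sel <- select_conversion_pair(state, "s1", dists)
  expect_equal(c(sel$k0, sel$k1), c(0, 200))
})

test_that("no eligible pair defers: selection returns NULL", {
  state <- make_state()
  expect_null(select_conversion_pair(state, "s1", event_distributions()))
})

test_that("conversion overwrites the tract exactly and records truth", {
  state <- make_state(seed = 6)
  m <- pairwise_map(interval("s1", 0, 100), interval("s1", 1000, 1100),
                    "same", "self")
  state$store <- store_add_map_public(state$store, m)
  st2 <- apply_conversion(state, "s1", m, 10, 60, "a_to_b", 0.1, "e1")
  s_old <- state$seqs$s1$seq; s_new <- st2$seqs$s1$seq
  expect_equal(length(s_new), length(s_old))
  # tract identical after conversion, source side untouched
  expect_equal(s_new[1011:1060], s_old[11:60])
  expect_equal(s_new[11:60], s_old[11:60])
  # outside the tract unchanged
  expect_equal(s_new[-(1011:1060)], s_old[-(1011:1060)])
  expect_length(st2$store$tracks, 1)

  # inverted pair: 12 bp hand-checked example
  st <- clustersim:::cluster_state(
    list(s1 = evolving_sequence("s1", "ACGTACGTACGTTTTTTTTTTTTT")),
    clustersim:::store_register_lineage(truth_store(1), "s1", 24))
  mi <- pairwise_map(interval("s1", 0, 12), interval("s1", 12, 24),
                     "inverted", "self")
  out <- apply_conversion(st, "s1", mi, 0, 12, "a_to_b", 0, "e1")
  expect_equal(decode_dna_public(out$seqs$s1$seq[13:24]), "ACGTACGTACGT")
})

test_that("conversions never change sequence length; tract identity is 1", {
  h <- make_state(seed = 8)
  set.seed(30)
  # build paralogy then convert repeatedly
  st <- h
  for (i in 1:3) {
    ev <- sample_duplication(st, "s1", event_distributions())
    st <- apply_duplication(st, ev)
  }
  for (i in 1:5) {
    n_before <- length(st$seqs$s1$seq)
    sel <- select_conversion_pair(st, "s1", event_distributions())
    st <- apply_conversion(st, "s1", sel$map, sel$k0, sel$k1,
                           sel$direction, i, sprintf("c%d", i))
    expect_equal(length(st$seqs$s1$seq), n_before)
    ta <- attr(st, "tract_a"); tb <- attr(st, "tract_b")
    a_seq <- st$seqs$s1$seq[(ta$start + 1):ta$end]
    b_seq <- st$seqs$s1$seq[(tb$start + 1):tb$end]
    if (sel$map$orientation == "inverted")
      b_seq <- clustersim:::revcomp_int(b_seq)
    expect_equal(percent_identity(a_seq, b_seq), 100)
  }
})

test_that("tract outside the map is rejected", {
  state <- make_state()
  m <- pairwise_map(interval("s1", 0, 100), interval("s1", 1000, 1100),
                    "same", "self")
  expect_error(apply_conversion(state, "s1", m, 50, 150, "a_to_b"),
               "outside")
})
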