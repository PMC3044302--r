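# truth-store bookkeeping: duplication/deletion updates, lineage splits,
# paralogy closure, all validated against the label-replay oracle

new_two_species_store <- function(n = 10000, min_map_length = 50) {
  store <- truth_store(min_map_length)
  store <- clustersim:::store_register_lineage(store, "anc", n)
  store <- clustersim:::store_split_lineage(store, "anc", "s1", "s2")
  store
}

test_that("one duplication splits the ortholog alignment and adds one: 1 -> 3", {
  store <- new_two_species_store()
  # copy A=[8000,9000) of s1, insert at 1000
  store <- update_on_duplication(store, "s1", interval("s1", 8000, 9000),
                                 1000, "same")
  orth <- clustersim:::store_maps(store, kind = "ortholog")
  self <- clustersim:::store_maps(store, kind = "self")
  expect_length(orth, 3)
  expect_length(self, 1)
  # oracle agreement
  orc <- oracle_new("anc", 10000)
  orc <- oracle_split(orc, "anc", "s1", "s2")
  orc <- oracle_dup(orc, "s1", 8000, 9000, 1000)
  expect_store_consistent(store, orc)
})

test_that("a second duplication in the other species yields six ortholog maps", {
  store <- new_two_species_store()
  store <- update_on_duplication(store, "s1", interval("s1", 8000, 9000),
                                 1000, "same")
  # C=[8200,8800) of s2 lies in the region orthologous to both the split
  # alignment and the copy's alignment; D inserted at 5000
  store <- update_on_duplication(store, "s2", interval("s2", 8200, 8800),
                                 5000, "same")
  orth <- clustersim:::store_maps(store, kind = "ortholog")
  expect_length(orth, 6)
  orc <- oracle_new("anc", 10000)
  orc <- oracle_split(orc, "anc", "s1", "s2")
  orc <- oracle_dup(orc, "s1", 8000, 9000, 1000)
  orc <- oracle_dup(orc, "s2", 8200, 8800, 5000)
  expect_store_consistent(store, orc)
})

test_that("degenerate duplication away from all maps only adds a self map", {
  store <- truth_store(50)
  store <- clustersim:::store_register_lineage(store, "s1", 10000)
  store <- clustersim:::store_register_lineage(store, "s2", 10000)
  store <- store_add_map_public(store,
    pairwise_map(interval("s1", 0, 1000), interval("s2", 0, 1000),
                 "same", "ortholog"))
  store <- update_on_duplication(store, "s1", interval("s1", 5000, 6000),
                                 8000, "same")
  expect_length(clustersim:::store_maps(store, kind = "ortholog"), 1)
  expect_length(clustersim:::store_maps(store, kind = "self"), 1)
})

test_that("insertion point inside the source is rejected", {
  store <- new_two_species_store()
  expect_error(update_on_duplication(store, "s1",
                                     interval("s1", 2000, 3000), 2500),
               "inside")
})

test_that("deletion inside one side of a self map splits it with mirrored trims", {
  for (orient in c("same", "inverted")) {
    store <- truth_store(50)
    store <- clustersim:::store_register_lineage(store, "s1", 10000)
    store <- store_add_map_public(store,
      pairwise_map(interval("s1", 1000, 2000), interval("s1", 5000, 6000),
                   orient, "self"))
    store <- update_on_deletion(store, "s1", interval("s1", 1200, 1500))
    self <- unname(clustersim:::store_maps(store, kind = "self"))
    expect_length(self, 2)
    # the scripted self map declares [1000,2000) homologous to [5000,6000);
    # mirror that homology in the oracle labels directly
    orc <- oracle_new("s1", 10000)
    orc[["s1"]][5001:6000] <- if (orient == "same") orc[["s1"]][1001:2000]
                              else rev(orc[["s1"]][1001:2000])
    orc <- oracle_del(orc, "s1", 1200, 1500)
    expect_store_consistent(store, orc)
    # both pieces keep equal-length sides
    for (m in self) expect_equal(clustersim:::map_len(m),
                                 m$b$end - m$b$start)
  }
})

test_that("deleting an entire map side removes the map; disjoint deletions shift", {
  store <- truth_store(50)
  store <- clustersim:::store_register_lineage(store, "s1", 10000)
  store <- store_add_map_public(store,
    pairwise_map(interval("s1", 1000, 1500), interval("s1", 5000, 5500),
                 "same", "self"))
  gone <- update_on_deletion(store, "s1", interval("s1", 900, 1600))
  expect_length(clustersim:::store_maps(gone, kind = "self"), 0)

  shifted <- update_on_deletion(store, "s1", interval("s1", 100, 300))
  m <- unname(clustersim:::store_maps(shifted, kind = "self"))[[1]]
  expect_equal(c(m$a$start, m$a$end, m$b$start, m$b$end),
               c(800, 1300, 4800, 5300))
})

test_that("maps truncated below min_map_length are dropped", {
  store <- truth_store(200)
  store <- clustersim:::store_register_lineage(store, "s1", 10000)
  store <- store_add_map_public(store,
    pairwise_map(interval("s1", 1000, 1250), interval("s1", 5000, 5250),
                 "same", "self"))
  store <- update_on_deletion(store, "s1", interval("s1", 1100, 1250))
  expect_length(clustersim:::store_maps(store, kind = "self"), 0)
})

test_that("paralogy closure finds transitive pairs and stops at empty overlap", {
  store <- truth_store(50)
  store <- clustersim:::store_register_lineage(store, "s1", 10000)
  # A=[0,500)->B=[1000,1500), B=[1000,1500)->C=[3000,3500): full overlap
  store <- store_add_map_public(store,
    pairwise_map(interval("s1", 0, 500), interval("s1", 1000, 1500),
                 "same", "self"))
  store <- store_add_map_public(store,
    pairwise_map(interval("s1", 1000, 1500), interval("s1", 3000, 3500),
                 "same", "self"))
  cl <- paralog_closure(store, "s1")
  keys <- sort(vapply(cl, clustersim:::map_key, character(1)))
  expect_length(cl, 3)
  expect_true(any(grepl("^s1:0:500:s1:3000:3500", keys)))

  # no overlap between the B intervals -> no (A,C)
  store2 <- truth_store(50)
  store2 <- clustersim:::store_register_lineage(store2, "s1", 10000)
  store2 <- store_add_map_public(store2,
    pairwise_map(interval("s1", 0, 500), interval("s1", 1000, 1500),
                 "same", "self"))
  store2 <- store_add_map_public(store2,
    pairwise_map(interval("s1", 1500, 2000), interval("s1", 3000, 3500),
                 "same", "self"))
  expect_length(paralog_closure(store2, "s1"), 2)

  # single map closure is itself
  store3 <- truth_store(50)
  store3 <- clustersim:::store_register_lineage(store3, "s1", 10000)
  store3 <- store_add_map_public(store3,
    pairwise_map(interval("s1", 0, 500), interval("s1", 1000, 1500),
                 "same", "self"))
  expect_length(paralog_closure(store3, "s1"), 1)
})

test_that("randomized histories stay consistent with the label-replay oracle", {
  for (seed in 1:12) {
    h <- random_history(n_events = 5, seq_len = 3000, seed = seed)
    expect_store_consistent(h$store, h$orc)
    # closure maps are also label-consistent
    for (m in paralog_closure(h$store, "s1")) {
      la <- h$orc[["s1"]][(m$a$start + 1):m$a$end]
      lb <- h$orc[["s1"]][(m$b$start + 1):m$b$end]
      if (m$orientation == "inverted") lb <- rev(lb)
      expect_identical(la, lb)
    }
  }
})
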