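# interval remapping and map composition against per-position oracles

# brute-force interval remap: tag positions, replay the edit on the tag
# vector, find the image positions of the surviving tags
remap_oracle <- function(iv, edit, n) {
  tags <- seq_len(n)
  mine <- tags[(iv$start + 1):iv$end]
  after <- if (edit$type == "insertion") {
    append(tags, rep(NA_integer_, edit$len), after = edit$pos)
  } else {
    tags[-((edit$start + 1):edit$end)]
  }
  which(after %in% mine) - 1L            # 0-based surviving positions
}

test_that("remap_interval matches the per-position oracle on worked cases", {
  iv <- interval("x", 30, 40)
  del <- coordinate_edit("x", "deletion", start = 10, end = 20)
  out <- remap_interval(iv, del, seq_len = 100)
  expect_length(out, 1)
  expect_equal(c(out[[1]]$start, out[[1]]$end), c(20, 30))
  expect_equal(remap_oracle(iv, del, 100), 20:29)

  expect_length(remap_interval(iv, coordinate_edit("x", "deletion",
                                                   start = 30, end = 40)), 0)

  ins <- coordinate_edit("x", "insertion", pos = 35, len = 5)
  out <- remap_interval(iv, ins)
  expect_length(out, 2)
  expect_equal(c(out[[1]]$start, out[[1]]$end), c(30, 35))
  expect_equal(c(out[[2]]$start, out[[2]]$end), c(40, 45))
  expect_equal(remap_oracle(iv, ins, 100), c(30:34, 40:44))
})

test_that("remap_interval equals the oracle on randomized edits", {
  set.seed(11)
  for (i in 1:200) {
    n <- 100
    s <- sample(0:98, 1); e <- sample((s + 1):100, 1)
    iv <- interval("x", s, e)
    edit <- if (runif(1) < 0.5) {
      p <- sample(0:100, 1)
      coordinate_edit("x", "insertion", pos = p, len = sample(1:20, 1))
    } else {
      ds <- sample(0:99, 1)
      coordinate_edit("x", "deletion", ds, start = ds,
                      end = sample((ds + 1):100, 1))
    }
    got <- unlist(lapply(remap_interval(iv, edit, n), function(v)
      v$start:(v$end - 1)))
    if (is.null(got)) got <- integer(0)
    expect_equal(as.integer(got), as.integer(remap_oracle(iv, edit, n)))
  }
})

test_that("edits beyond the sequence end are rejected", {
  iv <- interval("x", 0, 10)
  expect_error(remap_interval(iv, coordinate_edit("x", "deletion",
                                                  start = 90, end = 120),
                              seq_len = 100), "beyond")
  expect_error(remap_interval(iv, coordinate_edit("x", "insertion",
                                                  pos = 101, len = 5),
                              seq_len = 100), "beyond")
})

test_that("composition reproduces the worked examples", {
  idm <- pairwise_map(interval("x", 0, 100), interval("y", 0, 100),
                      "same", "ortholog")
  m <- pairwise_map(interval("y", 0, 30), interval("z", 200, 230),
                    "same", "ortholog")
  comp <- compose_maps(idm, m)
  expect_equal(c(comp$a$start, comp$a$end), c(0, 30))
  expect_equal(c(comp$b$start, comp$b$end), c(200, 230))

  m1 <- pairwise_map(interval("x", 0, 50), interval("x", 100, 150),
                     "same", "self")
  m2 <- pairwise_map(interval("x", 120, 150), interval("x", 200, 230),
                     "same", "self")
  comp <- compose_maps(m1, m2)
  expect_equal(c(comp$a$start, comp$a$end, comp$b$start, comp$b$end),
               c(20, 50, 200, 230))
  expect_equal(comp$orientation, "same")

  m2i <- pairwise_map(interval("x", 120, 150), interval("x", 200, 230),
                      "inverted", "self")
  ci <- compose_maps(m1, m2i)
  expect_equal(ci$orientation, "inverted")
  expect_equal(compose_positions(m1, m2i),
               map_positions(ci), ignore_attr = TRUE)
})

test_that("composition matches the per-position oracle on random maps", {
  set.seed(7)
  for (i in 1:200) {
    len1 <- sample(5:40, 1); len2 <- sample(5:40, 1)
    a0 <- sample(0:50, 1); b0 <- sample(0:50, 1)
    a20 <- sample(0:80, 1); c0 <- sample(100:150, 1)
    o1 <- sample(c("same", "inverted"), 1)
    o2 <- sample(c("same", "inverted"), 1)
    m1 <- pairwise_map(interval("p", a0, a0 + len1),
                       interval("q", b0, b0 + len1), o1, "ortholog")
    m2 <- pairwise_map(interval("q", a20, a20 + len2),
                       interval("r", c0, c0 + len2), o2, "ortholog")
    comp <- compose_maps(m1, m2)
    oracle <- compose_positions(m1, m2)
    if (is.null(oracle)) {
      expect_null(comp)
    } else {
      expect_equal(map_positions(comp)[order(map_positions(comp)[, "a"]), ],
                   oracle[order(oracle[, "a"]), ], ignore_attr = TRUE)
    }
  }
})

test_that("composition is associative on triple-overlapping maps", {
  set.seed(19)
  for (i in 1:100) {
    len <- sample(10:30, 3, replace = TRUE)
    p0 <- sample(0:10, 1)
    m1 <- pairwise_map(interval("p", 0, len[1]),
                       interval("q", p0, p0 + len[1]),
                       sample(c("same", "inverted"), 1), "ortholog")
    q0 <- sample(0:15, 1)
    m2 <- pairwise_map(interval("q", q0, q0 + len[2]),
                       interval("r", 40, 40 + len[2]),
                       sample(c("same", "inverted"), 1), "ortholog")
    s0 <- sample(35:45, 1)
    m3 <- pairwise_map(interval("r", s0, s0 + len[3]),
                       interval("s", 80, 80 + len[3]),
                       sample(c("same", "inverted"), 1), "ortholog")
    left <- compose_maps(m1, m2)
    lhs <- if (is.null(left)) NULL else compose_maps(left, m3)
    right <- compose_maps(m2, m3)
    rhs <- if (is.null(right)) NULL else compose_maps(m1, right)
    if (is.null(lhs) || is.null(rhs)) {
      p_l <- if (is.null(lhs)) NULL else map_positions(lhs)
      p_r <- if (is.null(rhs)) NULL else map_positions(rhs)
      expect_identical(is.null(p_l) || nrow(p_l) == 0,
                       is.null(p_r) || nrow(p_r) == 0)
    } else {
      expect_equal(map_positions(lhs), map_positions(rhs),
                   ignore_attr = TRUE)
    }
  }
})

test_that("map sides must be equal length and self maps canonical", {
  expect_error(pairwise_map(interval("x", 0, 10), interval("x", 20, 35),
                            "same", "self"), "length")
  m <- pairwise_map(interval("x", 50, 60), interval("x", 0, 10),
                    "same", "self")
  expect_lt(m$a$start, m$b$start)
})
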