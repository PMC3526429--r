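exact_params <- function(k, t = 2L, ...) {
  comparison_params(k = k, t = t, backend = "exact", ...)
}

test_that("greedy non-overlap counting matches hand enumeration", {
  # hits at 0 and 4; the greedy jump skips the overlapping positions
  expect_true(read_is_similar("TTTATTT", "TTT", t = 2))
  expect_false(read_is_similar("TTTATTT", "TTT", t = 3))
  expect_false(read_is_similar("AC", "ACG", t = 1))  # shorter than k
  # against a small index instead of an exact set
  idx <- bds_create(3, hash_functions(1:4))
  bds_insert(idx, "TTT")
  expect_true(read_is_similar("TTTATTT", idx, t = 2))
  expect_false(read_is_similar("TTTATTT", idx, t = 3))
})

test_that("reverse-complement scanning is off by default and opt-in", {
  # read is the reverse complement of the indexed content
  expect_false(read_is_similar("AAAA", "TTTT", t = 1))
  expect_true(read_is_similar("AAAA", "TTTT", t = 1, reverse_complement = TRUE))

  a <- read_set("q", "AAAAAAAA", sample_name = "A")
  b <- read_set("t", "TTTTTTTT", sample_name = "B")
  p_fwd <- exact_params(4, t = 1)
  p_rc <- exact_params(4, t = 1, reverse_complement = TRUE)
  expect_equal(intersect_directional(a, b, p_fwd)$matched_count, 0L)
  expect_equal(intersect_directional(a, b, p_rc)$matched_count, 1L)
})

test_that("directional intersection contracts on degenerate inputs", {
  a <- random_reads(5, 40, sample_name = "a", seed = 1)
  empty <- read_set(character(0), character(0), sample_name = "e")
  res <- intersect_directional(a, empty, exact_params(15))
  expect_equal(res$matched_count, 0L)
  expect_equal(res$chunks_used, 0L)
  expect_length(res$member_flags, 5L)

  # a read set against itself: every read carries its own k-mers
  self <- read_set("r", "ACGTACGTAC", sample_name = "s")
  res2 <- intersect_directional(self, self, exact_params(3))
  expect_true(res2$member_flags)

  # reads of only ambiguous bases contribute nothing on either side
  nn <- read_set(c("n1", "n2"), c("NNNNNNNNNN", "NNNNNNNNNN"),
                 sample_name = "n")
  expect_equal(intersect_directional(a, nn, exact_params(5))$matched_count, 0L)
  expect_equal(intersect_directional(nn, a, exact_params(5))$matched_count, 0L)
})

test_that("exact backend recovers exactly the planted reads; flags match brute force", {
  pp <- planted_pair(60, 90, k = 15L, t = 2L, planted_similarity = 0.4,
                     seed = 11)
  res <- intersect_directional(pp$a, pp$b, exact_params(15))
  expect_equal(res$member_flags, pp$expected_a)
  # dynamic-programming brute force agrees with the greedy streaming scan
  expect_equal(res$member_flags,
               oracle_similar_flags(pp$a$sequences, pp$b$sequences, 15L, 2L))
})

test_that("chunked indexing is invariant under the chunk size (exact backend)", {
  pp <- planted_pair(40, 80, k = 15L, t = 2L, planted_similarity = 0.3,
                     seed = 21)
  baseline <- intersect_directional(pp$a, pp$b, exact_params(15))
  one_read <- 80 - 15 + 1  # one read's worth of k-mers
  for (lim in c(one_read, 10 * one_read, 1e6)) {
    res <- intersect_directional(pp$a, pp$b,
                                 exact_params(15, chunk_limit = lim))
    expect_equal(res$member_flags, baseline$member_flags,
                 label = paste("chunk_limit =", lim))
  }
  # chunk accounting: whole-read granularity with uniform reads matches
  # ceil(total k-mer volume / limit)
  res_small <- intersect_directional(pp$a, pp$b,
                                     exact_params(15, chunk_limit = one_read))
  expect_equal(res_small$chunks_used, 40L)
  res_ten <- intersect_directional(pp$a, pp$b,
                                   exact_params(15, chunk_limit = 10 * one_read))
  expect_equal(res_ten$chunks_used, ceiling(40 * one_read / (10 * one_read)))
  expect_equal(baseline$chunks_used, 1L)
})

test_that("probabilistic flags contain the exact flags, and FPs only add", {
  # small k provokes index false positives; containment must still hold
  pp <- planted_pair(50, 70, k = 8L, t = 2L, planted_similarity = 0.3,
                     seed = 31)
  ex <- intersect_directional(pp$a, pp$b, exact_params(8))
  for (combo in list(hash_functions(1), hash_functions(1:4))) {
    bds <- intersect_directional(pp$a, pp$b,
                                 comparison_params(k = 8, t = 2,
                                                   backend = "bds",
                                                   functions = combo))
    expect_true(all(bds$member_flags[ex$member_flags]),
                label = paste(length(combo), "function(s)"))
  }
  # at k = 20 chance collisions are negligible: the two backends agree
  pp20 <- planted_pair(50, 90, k = 20L, t = 2L, planted_similarity = 0.3,
                       seed = 32)
  ex20 <- intersect_directional(pp20$a, pp20$b, exact_params(20))
  bd20 <- intersect_directional(pp20$a, pp20$b,
                                comparison_params(k = 20, t = 2))
  expect_equal(bd20$member_flags, ex20$member_flags)
})

test_that("raising t only removes similar reads", {
  pp <- planted_pair(40, 120, k = 12L, t = 4L, block_length = 48L,
                     planted_similarity = 0.5, seed = 41)
  prev <- rep(TRUE, 40)
  for (t in 1:5) {
    res <- intersect_directional(pp$a, pp$b, exact_params(12, t = t))
    expect_true(all(prev[res$member_flags]),
                label = paste("flags nested at t =", t))
    prev <- res$member_flags
  }
  # the planted block spans exactly 4 k-mers: flagged at t = 4, gone at 5
  expect_equal(intersect_directional(pp$a, pp$b,
                                     exact_params(12, t = 4))$member_flags,
               pp$expected_a)
  expect_equal(sum(intersect_directional(pp$a, pp$b,
                                         exact_params(12, t = 5))$member_flags),
               0L)
})

test_that("skip_flags excludes reads from querying entirely", {
  pp <- planted_pair(20, 60, k = 15L, t = 2L, planted_similarity = 0.5,
                     seed = 51)
  skip <- rep(c(TRUE, FALSE), 10)
  res <- intersect_directional(pp$a, pp$b, exact_params(15),
                               skip_flags = skip)
  expect_false(any(res$member_flags[skip]))
  expect_equal(res$member_flags[!skip], pp$expected_a[!skip])
})
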