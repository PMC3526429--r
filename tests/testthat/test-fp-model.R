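test_that("closed forms match hand and enumeration values", {
  expect_equal(p_fp_balanced(1, 1), 0.5)
  expect_equal(p_fp_balanced(5, 0), 0)
  expect_equal(p_fp_unbalanced(1, 1), 0.625)  # 3/4*3/4 + 1/4*1/4 terms
  expect_equal(p_fp_unbalanced(7, 0), 0)

  # exact enumeration oracle over all 4^k k-mers, k <= 3, n <= 4
  for (k in 1:3) for (n in 1:4) {
    expect_equal(p_fp_balanced(k, n), oracle_fp_exact(c("A", "C"), k, n),
                 tolerance = 1e-12, label = sprintf("balanced k=%d n=%d", k, n))
    expect_equal(p_fp_unbalanced(k, n), oracle_fp_exact("A", k, n),
                 tolerance = 1e-12, label = sprintf("unbalanced k=%d n=%d", k, n))
  }
})

test_that("headline operating-point rates come out as printed", {
  expect_equal(round(100 * p_fp_combo(33, 1e9, hash_functions(1:3)), 2), 0.13)
  expect_equal(round(100 * p_fp_combo(33, 1e9, hash_functions(1:4)), 2), 0.11)
  expect_lt(100 * p_fp_combo(30, 3e8, hash_functions(1:4)), 2)
  expect_equal(p_fp_balanced(33, 1e9), 0.1098945, tolerance = 1e-6)
})

test_that("combo probability is the product of per-function rates", {
  k <- 12; n <- 5000
  expect_equal(p_fp_combo(k, n, hash_functions(1)), p_fp_balanced(k, n))
  expect_equal(p_fp_combo(k, n, hash_functions(4)), p_fp_unbalanced(k, n))
  expect_equal(p_fp_combo(k, n, hash_functions(1:4)),
               p_fp_balanced(k, n)^3 * p_fp_unbalanced(k, n))
  # all four unbalanced functions share one formula (symmetry)
  expect_equal(p_fp_combo(k, n, hash_functions(5:7)),
               p_fp_unbalanced(k, n)^3)
})

test_that("FP probabilities are monotone in n, k and combo size", {
  # strict growth in n wherever the probability has not saturated to 1
  ns <- c(1, 10, 100, 1000, 1e4)
  for (k in c(12, 20, 26)) {
    expect_true(all(diff(p_fp_balanced(k, ns)) > 0))
    expect_true(all(diff(p_fp_unbalanced(k, ns)) > 0))
  }
  # strict decay in k in the same unsaturated regime
  expect_true(all(diff(vapply(c(4, 8, 16, 24), p_fp_balanced, numeric(1),
                              n = 10)) < 0))
  expect_true(all(diff(vapply(c(4, 8, 16, 24), p_fp_unbalanced, numeric(1),
                              n = 10)) < 0))
  expect_true(all(diff(vapply(c(12, 16, 24), p_fp_balanced, numeric(1),
                              n = 1e4)) < 0))
  expect_true(all(diff(vapply(c(12, 16, 24), p_fp_unbalanced, numeric(1),
                              n = 1e4)) < 0))
  for (m in 1:3) {
    expect_lte(p_fp_combo(12, 1000, hash_functions(seq_len(m + 1))),
               p_fp_combo(12, 1000, hash_functions(seq_len(m))))
  }
  # a balanced function beats an unbalanced one whenever the load n stays
  # below half the 2^k cells (at heavy saturation both tend to 1 and the
  # ordering can invert in the far tail)
  for (k in 2:12) for (n in c(1, 5, 2^(k - 1))) {
    expect_lt(p_fp_balanced(k, n), p_fp_unbalanced(k, n),
              label = sprintf("k=%d n=%d", k, n))
  }
})

test_that("unbalanced formula matches Monte-Carlo at k = 5, n = 100", {
  # the formula is a marginal over random indexed sets, so the Monte
  # Carlo redraws the indexed set every replicate and the standard error
  # is taken across replicates
  set.seed(303)
  k <- 5L; n <- 100L; n_rep <- 60L; nq <- 3000L
  rates <- vapply(seq_len(n_rep), function(r) {
    idx <- bds_create(k, hash_functions(4))
    indexed <- apply(matrix(sample(c("A", "C", "G", "T"), n * k, TRUE), n),
                     1L, paste, collapse = "")
    bds_insert(idx, indexed)
    queries <- apply(matrix(sample(c("A", "C", "G", "T"), nq * k, TRUE), nq),
                     1L, paste, collapse = "")
    mean(bds_contains(idx, queries))
  }, numeric(1))
  obs <- mean(rates)
  se <- stats::sd(rates) / sqrt(n_rep)
  expect_lt(abs(obs - p_fp_unbalanced(k, n)), 3 * se)
})

test_that("classical Bloom filter reference formulas", {
  expect_equal(bloom_fp_asymptotic(1000, 1000), 0.6185)
  expect_equal(bloom_fp_asymptotic(2000, 1000), 0.6185^2)
  expect_lt(bloom_fp_asymptotic(64e9, 1e9), 1e-12)  # m/n -> large drives FP to 0
  expect_equal(bloom_memory_bits(1, 0.5), log2(exp(1)))
  # halving epsilon costs exactly n*log2(e) extra bits
  n <- 12345
  expect_equal(bloom_memory_bits(n, 0.05) - bloom_memory_bits(n, 0.1),
               n * log2(exp(1)))
  # the ~1.8 GB classical-filter comparison point
  expect_equal(bloom_memory_bits(1e9, 0.00114) / 8 / 1e9, 1.8, tolerance = 0.05)
})

test_that("simulate_fp is deterministic, honest about n = 0, and guards 4^k", {
  a <- simulate_fp(10, 500, 500, hash_functions(1:2), seed = 9)
  b <- simulate_fp(10, 500, 500, hash_functions(1:2), seed = 9)
  expect_identical(a, b)
  expect_equal(simulate_fp(10, 0, 200, seed = 1)$fp_rate, 0)
  expect_error(simulate_fp(3, 60, 60, seed = 1), "distinct")
})

test_that("FP-vs-n curves at reduced scale: theory tracks simulation", {
  combo <- hash_functions(1:4)
  for (k in c(15L, 20L)) {
    for (n in c(1e3, 1e4, 1e5)) {
      sim <- simulate_fp(k, n, n_queries = 2e4, functions = combo,
                         seed = 404 + k)
      th <- p_fp_combo(k, n, combo)
      expect_lt(abs(sim$fp_rate - th), 3 * sim$se,
                label = sprintf("k=%d n=%g", k, n))
    }
  }
})
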