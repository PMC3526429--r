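# Closed-form false-positive model of the projection-hash index, plus
# classical Bloom-filter reference formulas and a simulation estimator.
#
# Notation: k is the k-mer length, n the number of distinct k-mers
# indexed. A balanced projection distributes codes uniformly over the 2^k
# cells, so a fresh query k-mer is a false positive with probability
# 1 - (1 - 2^-k)^n. An unbalanced projection (bit 0 on a single letter)
# sends a k-mer whose code has x zero-bits to a cell hit with probability
# a_x = (1/4)^x (3/4)^(k-x) per insertion, and a uniform query lands on an
# x-zero-bit code with probability C(k,x) a_x, giving
#   sum_x C(k,x) a_x (1 - (1 - a_x)^n).
# Combinations multiply per-function probabilities: exact as an upper
# bound for the three balanced functions (no two distinct k-mers agree on
# any two of them), and an empirically validated independence
# approximation when an unbalanced function is included.

#' False-positive probability of one balanced projection
#'
#' Probability that a uniform random query k-mer, absent from the indexed
#' set, is nonetheless reported present by a single balanced hash
#' function's bit array: `1 - (1 - 2^-k)^n`. Computed via `log1p`/`expm1`
#' so it stays accurate for large `n`.
#'
#' @param k k-mer length (>= 1).
#' @param n Number of distinct k-mers indexed (>= 0).
#' @return Probability in `[0, 1]`. Vectorized over `k` and `n`.
#' @examples
#' p_fp_balanced(1, 1)        # 0.5
#' p_fp_balanced(33, 1e9)     # ~0.11 per function
#' @export
p_fp_balanced <- function(k, n) {
  stopifnot(all(k >= 1), all(n >= 0))
  -expm1(n * log1p(-2^-k))
}

#' False-positive probability of one unbalanced projection
#'
#' Same quantity for an unbalanced function, whose codes are not uniform:
#' `sum_{x=0}^{k} C(k,x) a_x (1 - (1 - a_x)^n)` with
#' `a_x = (1/4)^x (3/4)^(k-x)`, the weight of query codes carrying `x`
#' zero bits and the per-insertion hit probability of such a cell.
#'
#' @inheritParams p_fp_balanced
#' @return Probability in `[0, 1]`.
#' @examples
#' p_fp_unbalanced(1, 1)  # 0.625
#' @export
p_fp_unbalanced <- function(k, n) {
  stopifnot(length(k) == 1L, k >= 1, all(n >= 0))
  x <- 0:k
  log_a <- x * log(1 / 4) + (k - x) * log(3 / 4)
  vapply(n, function(ni) {
    sum(exp(lchoose(k, x) + log_a) * (-expm1(ni * log1p(-exp(log_a)))))
  }, numeric(1))
}

#' False-positive probability of a function combination
#'
#' Product over the combination of each function's individual probability
#' (balanced or unbalanced as appropriate). For the three balanced
#' functions this is the exact closed-form bound, since no two distinct
#' k-mers share codes under any two of them; for combinations including
#' an unbalanced function it is the independence approximation, which
#' simulation shows to track the empirical rate closely.
#'
#' @inheritParams p_fp_balanced
#' @param functions List of `hash_function` objects (non-empty).
#' @return Probability in `[0, 1]`. Vectorized over `n`.
#' @examples
#' # the working configuration: ~0.0013 at k = 33, n = 1e9
#' p_fp_combo(33, 1e9, hash_functions(1:3))
#' @export
p_fp_combo <- function(k, n, functions = hash_functions(1:4)) {
  stopifnot(length(functions) >= 1L,
            all(vapply(functions, inherits, logical(1), "hash_function")))
  p <- rep(1, length(n))
  for (f in functions) {
    p <- p * if (f$balanced) p_fp_balanced(k, n) else p_fp_unbalanced(k, n)
  }
  p
}

#' Classical Bloom filter false-positive rate (asymptotic)
#'
#' The optimal-function-count approximation `0.6185^(m/n)` for a classical
#' single-array Bloom filter of `m_bits` bits holding `n` elements.
#'
#' @param m_bits Size of the filter in bits (>= 1).
#' @param n Number of elements stored (>= 1).
#' @return Probability.
#' @export
bloom_fp_asymptotic <- function(m_bits, n) {
  stopifnot(all(m_bits >= 1), all(n >= 1))
  0.6185^(m_bits / n)
}

#' Classical Bloom filter memory requirement
#'
#' Bits needed by a classical Bloom filter to support membership queries
#' for `n` elements at false-positive rate `epsilon`:
#' `n * log2(e) * log2(1/epsilon)`.
#'
#' @param n Number of elements (>= 1).
#' @param epsilon Target false-positive rate, in (0, 1).
#' @return Number of bits (double).
#' @export
bloom_memory_bits <- function(n, epsilon) {
  stopifnot(all(n >= 1), all(epsilon > 0), all(epsilon < 1))
  n * log2(exp(1)) * log2(1 / epsilon)
}

# Draw n_total distinct random k-mers as a character vector.
.random_kmers_distinct <- function(n_total, k) {
  if (4^k < 2 * n_total) {
    stop("4^k is too small to draw ", n_total, " distinct ", k, "-mers",
         call. = FALSE)
  }
  out <- character(0)
  while (length(out) < n_total) {
    need <- n_total - length(out)
    m <- matrix(sample(NUCS, ceiling(need * 1.1) * k, replace = TRUE),
                ncol = k)
    out <- unique(c(out, do.call(paste0, as.data.frame(m,
                                                       stringsAsFactors = FALSE))))
  }
  out[seq_len(n_total)]
}

#' Empirical false-positive rate by simulation
#'
#' Builds an index over `n` uniformly random distinct k-mers, queries
#' `n_queries` further distinct random k-mers disjoint from the indexed
#' set, and reports the fraction answered present together with its
#' binomial standard error. This is the empirical counterpart of
#' [p_fp_combo()] and the cross-check used for combinations involving
#' unbalanced functions, where the product formula is an approximation.
#'
#' @inheritParams p_fp_balanced
#' @param n_queries Number of query k-mers.
#' @param functions Hash combination to index with.
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return A list with `fp_rate`, `se` (binomial standard error),
#'   `false_positives` and `n_queries`.
#' @examples
#' sim <- simulate_fp(k = 12, n = 1000, n_queries = 1000,
#'                    functions = hash_functions(1:3), seed = 1)
#' sim$fp_rate
#' @export
simulate_fp <- function(k, n, n_queries, functions = hash_functions(1:4),
                        seed = 1L) {
  stopifnot(k >= 1, n >= 0, n_queries >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  kmers <- .random_kmers_distinct(n + n_queries, k)
  idx <- bds_create(k, functions)
  if (n > 0) bds_insert(idx, kmers[seq_len(n)])
  hits <- bds_contains(idx, kmers[n + seq_len(n_queries)])
  fp <- sum(hits)
  rate <- fp / n_queries
  list(fp_rate = rate,
       se = sqrt(max(rate * (1 - rate), 1 / n_queries) / n_queries),
       false_positives = fp,
       n_queries = n_queries)
}
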