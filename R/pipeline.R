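# The symmetric comparison pipeline. A single directional pass flags
# query reads whose t shared k-mers may be spread over several target
# reads, which is weaker than sharing t k-mers with one read. Three
# cascaded passes remove most of those spread-k-mer false positives:
#
#   1. A-hat  = A ->^ B       (candidate similar reads of A)
#   2. B-hat  = B ->^ A-hat   (target shrunk to the candidates)
#   3. final  = A-hat ->^ B-hat
#
# Step 3 over A-hat gives the same result as querying all of A against
# B-hat (a read outside A-hat cannot gain hits when the target shrinks)
# but is faster. A residual false-positive class survives: a read whose t
# shared k-mers are spread over distinct target reads that are themselves
# similar to the query set.

#' Symmetric comparison of two read sets
#'
#' Runs the three-pass pipeline and reports the retained read subsets of
#' both samples plus the similarity percentage
#' `100 * (|final A| + |B-hat|) / (|A| + |B|)`, where the denominators
#' count all reads of the input sets.
#'
#' @param A,B [read_set()] objects.
#' @param params A [comparison_params()].
#' @return A `symmetric_result`: list with logical flag vectors `a_hat`
#'   (after pass 1), `b_hat` (after pass 2), `a_final` (after pass 3),
#'   the `similarity` percentage, per-pass `chunks_used`, and `params`.
#' @examples
#' a <- random_reads(5, 60, sample_name = "a", seed = 1)
#' p <- comparison_params(k = 15, t = 2, backend = "exact")
#' symmetric_compare(a, a, p)$similarity  # 100: every read matches itself
#' @export
symmetric_compare <- function(A, B, params = comparison_params()) {
  stopifnot(inherits(A, "read_set"), inherits(B, "read_set"))
  s1 <- intersect_directional(A, B, params)
  a_hat <- s1$member_flags
  s2 <- intersect_directional(B, A[which(a_hat)], params)
  b_hat <- s2$member_flags
  s3 <- intersect_directional(A, B[which(b_hat)], params,
                              skip_flags = !a_hat)
  a_final <- s3$member_flags
  denom <- length(A) + length(B)
  structure(list(
    sample_a = A$sample_name, sample_b = B$sample_name,
    a_hat = a_hat, b_hat = b_hat, a_final = a_final,
    similarity = if (denom > 0) 100 * (sum(a_final) + sum(b_hat)) / denom else 0,
    chunks_used = c(s1$chunks_used, s2$chunks_used, s3$chunks_used),
    params = params),
    class = "symmetric_result")
}

#' @export
print.symmetric_result <- function(x, ...) {
  cat(sprintf("<symmetric comparison %s vs %s: %.2f%% similar reads (%d + %d of %d + %d)>\n",
              x$sample_a, x$sample_b, x$similarity, sum(x$a_final),
              sum(x$b_hat), length(x$a_final), length(x$b_hat)))
  invisible(x)
}

#' All-pairs similarity matrix over samples
#'
#' Runs [symmetric_compare()] for every unordered pair of samples, and
#' for each sample against itself when `include_self` is `TRUE`, then
#' mirrors the values into a symmetric matrix. With self-comparisons,
#' `n` samples take `n(n+1)/2` comparisons (15 samples: 120).
#'
#' @param samples List of [read_set()] objects with distinct sample
#'   names.
#' @param params A [comparison_params()].
#' @param include_self Also compare each sample with itself (default
#'   `TRUE`; the diagonal is `NA` otherwise).
#' @return A `similarity_matrix`: list with `sample_names`, `values`
#'   (square numeric matrix of percentages), `include_self` and
#'   `n_comparisons`.
#' @export
all_pairs <- function(samples, params = comparison_params(),
                      include_self = TRUE) {
  stopifnot(is.list(samples), length(samples) >= 1L,
            all(vapply(samples, inherits, logical(1), "read_set")))
  nm <- vapply(samples, function(s) s$sample_name, character(1))
  if (anyDuplicated(nm)) stop("duplicate sample names: ",
                              paste(nm[duplicated(nm)], collapse = ", "),
                              call. = FALSE)
  n <- length(samples)
  vals <- matrix(NA_real_, n, n, dimnames = list(nm, nm))
  n_comparisons <- 0L
  for (i in seq_len(n)) {
    jmax <- if (include_self) i else i - 1L
    for (j in seq_len(jmax)) {
      res <- symmetric_compare(samples[[j]], samples[[i]], params)
      vals[i, j] <- vals[j, i] <- res$similarity
      n_comparisons <- n_comparisons + 1L
    }
  }
  structure(list(sample_names = nm, values = vals,
                 include_self = include_self,
                 n_comparisons = n_comparisons),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity matrix: %d samples, %d comparisons>\n",
              length(x$sample_names), x$n_comparisons))
  print(round(x$values, 2))
  invisible(x)
}

#' Hierarchical clustering of samples from a similarity matrix
#'
#' Average-linkage (UPGMA) hierarchical clustering on the distance
#' `100 - similarity`, returned as an `ape` `phylo` tree with branch
#' lengths, ready for [write_newick()].
#'
#' @param matrix A `similarity_matrix` from [all_pairs()], or a square
#'   numeric matrix of similarity percentages with sample names as
#'   dimnames.
#' @return A `phylo` tree whose tips are the sample names.
#' @export
cluster_dendrogram <- function(matrix) {
  vals <- if (inherits(matrix, "similarity_matrix")) matrix$values else as.matrix(matrix)
  if (nrow(vals) < 2L) stop("clustering needs at least 2 samples", call. = FALSE)
  off <- vals[row(vals) != col(vals)]
  if (anyNA(off)) stop("similarity matrix has undefined off-diagonal cells",
                       call. = FALSE)
  d <- stats::as.dist(100 - vals)
  hc <- stats::hclust(d, method = "average")
  ape::as.phylo(hc)
}
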