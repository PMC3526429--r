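# The probabilistic k-mer membership index: one dedicated 2^k-bit array per
# hash function, addressed directly by the k-bit hash code (the hash range
# IS the array size -- there is no modular reduction anywhere). Membership
# is the AND over functions of the addressed bits, so false negatives are
# impossible and the false-positive rate is governed by the closed-form
# model in fp-model.R.
#
# The index is an environment (reference semantics): insertions mutate it
# in place, which matches how a streaming indexer uses it. Bit arrays are
# raw vectors of 2^k / 8 bytes.

#' Create an empty k-mer membership index
#'
#' Allocates one all-zero bit array of exactly `2^k` bits per hash
#' function. Total size is `length(functions) * 2^k` bits, independent of
#' how many k-mers are later inserted; with 4 functions and k = 33 that is
#' 4 GiB, the working configuration for indexing about a billion distinct
#' 33-mers at a ~0.1% false-positive rate.
#'
#' @param k k-mer length in nucleotides (1 <= k <= `max_k`).
#' @param functions List of `hash_function` objects (default: the three
#'   balanced projections plus the first unbalanced one, `f1`..`f4`).
#' @param max_k Memory budget expressed as the largest admissible k
#'   (default 33, i.e. up to `2^33` bits = 1 GiB per function).
#' @return A `bds_index` object (an environment; modified in place by
#'   [bds_insert()] and [bds_reset()]).
#' @seealso [bds_insert()], [bds_contains()], [p_fp_combo()]
#' @examples
#' idx <- bds_create(4, hash_functions(1))
#' bds_memory_bits(idx)  # 16
#' @export
bds_create <- function(k, functions = hash_functions(1:4), max_k = 33L) {
  k <- as.integer(k)
  stopifnot(k >= 1L, length(functions) >= 1L,
            all(vapply(functions, inherits, logical(1), "hash_function")))
  ids <- vapply(functions, function(f) f$id, integer(1))
  if (anyDuplicated(ids)) stop("duplicate hash functions", call. = FALSE)
  if (k > max_k) {
    stop("k = ", k, " exceeds the memory budget (max_k = ", max_k,
         ", i.e. ", format(2^max_k / 8, big.mark = ","),
         " bytes per function)", call. = FALSE)
  }
  n_bytes <- max(1, ceiling(2^k / 8))
  idx <- new.env(parent = emptyenv())
  idx$k <- k
  idx$functions <- functions
  idx$arrays <- lapply(functions, function(f) raw(n_bytes))
  idx$kmers_indexed <- 0
  class(idx) <- "bds_index"
  idx
}

#' @export
print.bds_index <- function(x, ...) {
  cat(sprintf(
    "<bds_index: k=%d, %d functions (f%s), %s bits, %g k-mer occurrences indexed>\n",
    x$k, length(x$functions),
    paste(vapply(x$functions, function(f) f$id, integer(1)), collapse = ",f"),
    format(bds_memory_bits(x), big.mark = ","), x$kmers_indexed))
  invisible(x)
}

#' Size of an index in bits
#'
#' @param index A `bds_index`.
#' @return `length(functions) * 2^k`, as a double.
#' @export
bds_memory_bits <- function(index) {
  stopifnot(inherits(index, "bds_index"))
  length(index$functions) * 2^index$k
}

# Set bits at 0-based positions `pos` (doubles; may repeat) in raw array.
.bits_set <- function(arr, pos) {
  pos <- unique(pos)
  byte <- floor(pos / 8) + 1
  mask <- 2^(pos %% 8)
  # OR of distinct power-of-two masks within one byte == their sum
  acc <- rowsum(mask, byte)
  at <- as.numeric(rownames(acc))
  arr[at] <- arr[at] | as.raw(acc[, 1L])
  arr
}

# Test bits at 0-based positions; returns logical vector.
.bits_get <- function(arr, pos) {
  byte <- floor(pos / 8) + 1
  bit <- pos %% 8
  bitwAnd(as.integer(arr[byte]), bitwShiftL(1L, bit)) != 0L
}

# Codes of length-k strings under every index function, as an
# n x n_functions matrix of doubles; NA rows for ambiguous k-mers.
.kmer_codes_matrix <- function(index, kmers) {
  k <- index$k
  if (any(nchar(kmers) != k)) {
    stop("k-mer length must equal the index k (", k, ")", call. = FALSE)
  }
  nt <- matrix(.nuc_ints(paste(kmers, collapse = "")),
               nrow = length(kmers), ncol = k, byrow = TRUE)
  pw <- 2^((k - 1):0)
  codes <- vapply(index$functions, function(f) {
    bits <- matrix(.bit_table(f)[nt + 1L], nrow = nrow(nt))
    as.numeric(bits %*% pw)
  }, numeric(length(kmers)))
  matrix(codes, nrow = length(kmers))
}

#' Insert k-mers into the index
#'
#' For each hash function, sets the bit addressed by the k-mer's code in
#' that function's own array. Inserting the same k-mer again is idempotent
#' on the arrays, but the occurrence counter `kmers_indexed` still
#' advances: it tracks the volume of k-mer occurrences streamed in, the
#' quantity the chunked indexer caps. K-mers containing an ambiguous base
#' are skipped and not counted.
#'
#' @param index A `bds_index` (modified in place).
#' @param kmers Character vector of k-mers, each of length `k`.
#' @return The index, invisibly.
#' @export
bds_insert <- function(index, kmers) {
  stopifnot(inherits(index, "bds_index"), is.character(kmers))
  if (length(kmers) == 0L) return(invisible(index))
  codes <- .kmer_codes_matrix(index, kmers)
  ok <- !is.na(codes[, 1L])
  if (any(ok)) {
    for (j in seq_along(index$functions)) {
      index$arrays[[j]] <- .bits_set(index$arrays[[j]], codes[ok, j])
    }
  }
  index$kmers_indexed <- index$kmers_indexed + sum(ok)
  invisible(index)
}

# Insert by precomputed code matrix (rows = k-mers, cols = functions);
# used by the streaming comparator, which already has rolling codes.
.bds_insert_codes <- function(index, codes) {
  ok <- !is.na(codes[, 1L])
  if (any(ok)) {
    for (j in seq_along(index$functions)) {
      index$arrays[[j]] <- .bits_set(index$arrays[[j]], codes[ok, j])
    }
  }
  index$kmers_indexed <- index$kmers_indexed + sum(ok)
  invisible(index)
}

.bds_contains_codes <- function(index, codes) {
  res <- !is.na(codes[, 1L])
  for (j in seq_along(index$functions)) {
    sel <- which(res)
    if (!length(sel)) break
    res[sel] <- .bits_get(index$arrays[[j]], codes[sel, j])
  }
  res
}

#' Query k-mers against the index
#'
#' A k-mer is reported present iff, for every hash function, the bit its
#' code addresses is set. Answers can be false positives (distinct k-mers
#' colliding under every function simultaneously) but never false
#' negatives. Ambiguous k-mers are reported absent: they are never
#' indexed.
#'
#' @inheritParams bds_insert
#' @return Logical vector, one element per k-mer.
#' @export
bds_contains <- function(index, kmers) {
  stopifnot(inherits(index, "bds_index"), is.character(kmers))
  if (length(kmers) == 0L) return(logical(0))
  .bds_contains_codes(index, .kmer_codes_matrix(index, kmers))
}

#' Reset an index to its empty state
#'
#' Zeroes every bit array and the occurrence counter, keeping the
#' allocated capacity. Used between chunks by the chunked indexer.
#'
#' @param index A `bds_index` (modified in place).
#' @return The index, invisibly.
#' @export
bds_reset <- function(index) {
  stopifnot(inherits(index, "bds_index"))
  n_bytes <- length(index$arrays[[1L]])
  # replace arrays one at a time so peak memory stays near one extra array
  for (j in seq_along(index$arrays)) {
    index$arrays[[j]] <- raw(n_bytes)
  }
  index$kmers_indexed <- 0
  invisible(index)
}

#' Serialize / restore an index (debugging aid)
#'
#' Writes a small header (magic string, k, function ids) followed by the
#' raw bit arrays. The format is specific to this package.
#'
#' @param index A `bds_index`.
#' @param path File path.
#' @return `bds_save` returns `path` invisibly; `bds_load` returns the
#'   restored `bds_index`.
#' @export
bds_save <- function(index, path) {
  stopifnot(inherits(index, "bds_index"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BDSv1"), con)
  ids <- vapply(index$functions, function(f) f$id, integer(1))
  writeBin(c(index$k, length(ids), ids), con, size = 4L)
  writeBin(as.double(index$kmers_indexed), con)
  for (a in index$arrays) writeBin(a, con)
  invisible(path)
}

#' @rdname bds_save
#' @export
bds_load <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 5L))
  if (!identical(magic, "BDSv1")) stop("not a BDS index file", call. = FALSE)
  hdr <- readBin(con, "integer", 2L, size = 4L)
  ids <- readBin(con, "integer", hdr[2L], size = 4L)
  counted <- readBin(con, "double", 1L)
  idx <- bds_create(hdr[1L], hash_functions(ids), max_k = hdr[1L])
  n_bytes <- length(idx$arrays[[1L]])
  idx$arrays <- lapply(seq_along(ids), function(i) readBin(con, "raw", n_bytes))
  idx$kmers_indexed <- counted
  idx
}
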