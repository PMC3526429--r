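# Position-wise nucleotide -> bit projection hash functions.
#
# A hash function here assigns each nucleotide a single bit, depending only
# on its letter, and maps a k-mer to the k-bit integer obtained by reading
# those bits left to right (leftmost nucleotide = most significant bit).
# Identifying each labeling with its bitwise complement and discarding the
# two constant labelings leaves exactly 7 distinct functions: 3 "balanced"
# ones sending two of the four letters to 0, and 4 "unbalanced" ones sending
# a single letter to 0.

NUCS <- c("A", "C", "G", "T")

new_hash_function <- function(id, zero_set) {
  stopifnot(length(zero_set) >= 1, length(zero_set) <= 3,
            all(zero_set %in% NUCS))
  structure(
    list(id = as.integer(id),
         zero_set = sort(zero_set),
         balanced = length(zero_set) == 2L),
    class = "hash_function"
  )
}

#' @export
print.hash_function <- function(x, ...) {
  cat(sprintf("<hash function f%d: %s; bit 0 on {%s}>\n", x$id,
              if (x$balanced) "balanced" else "unbalanced",
              paste(x$zero_set, collapse = ",")))
  invisible(x)
}

#' Enumerate the nucleotide-projection hash family
#'
#' Lists the distinct position-wise nucleotide-to-bit projections. Each
#' function labels every nucleotide with a bit depending only on its letter;
#' a labeling and its bitwise complement address the same partition of
#' k-mer space, so they count as one function, and the two constant
#' labelings hash everything to a single value and are excluded. Exactly 7
#' functions remain: `f1` (bit 0 on A,C), `f2` (A,G), `f3` (A,T) are
#' balanced (two letters on each side), and `f4`..`f7` (bit 0 on A, C, G, T
#' respectively) are unbalanced.
#'
#' @param ids Optional integer vector selecting a subset by id (1..7).
#' @return A list of `hash_function` objects with fields `id`, `zero_set`
#'   (letters mapped to bit 0) and `balanced`.
#' @examples
#' fns <- hash_functions()
#' length(fns)              # 7
#' sum(vapply(fns, function(f) f$balanced, logical(1)))  # 3
#' @export
hash_functions <- function(ids = 1:7) {
  zero_sets <- list(c("A", "C"), c("A", "G"), c("A", "T"),
                    "A", "C", "G", "T")
  stopifnot(all(ids %in% 1:7), !anyDuplicated(ids))
  lapply(ids, function(i) new_hash_function(i, zero_sets[[i]]))
}

# Integer codes 0..3 for A,C,G,T; NA for anything else (ambiguity codes).
# Case-insensitive: FASTA/FASTQ case is stylistic.
.nuc_ints <- local({
  tab <- rep(NA_integer_, 256L)
  tab[utf8ToInt("A")] <- 0L; tab[utf8ToInt("a")] <- 0L
  tab[utf8ToInt("C")] <- 1L; tab[utf8ToInt("c")] <- 1L
  tab[utf8ToInt("G")] <- 2L; tab[utf8ToInt("g")] <- 2L
  tab[utf8ToInt("T")] <- 3L; tab[utf8ToInt("t")] <- 3L
  function(sequence) tab[utf8ToInt(sequence)]
})

# Per-function bit of each of the 4 nucleotides (indexed by .nuc_ints + 1).
.bit_table <- function(f) as.numeric(!(NUCS %in% f$zero_set))

#' Hash a single k-mer
#'
#' Maps a k-mer to its k-bit integer code under one projection function:
#' bit i is 0 iff nucleotide i belongs to the function's zero set, and the
#' leftmost nucleotide contributes the most significant bit.
#'
#' @param f A `hash_function` from [hash_functions()].
#' @param kmer A single DNA string (A/C/G/T, case-insensitive).
#' @return The integer code as a double (codes can exceed 2^31 for k > 31),
#'   in `[0, 2^k)`.
#' @examples
#' f <- hash_functions()
#' hash_kmer(f[[1]], "ACGT")  # 3  (binary 0011)
#' hash_kmer(f[[4]], "ACGT")  # 7  (binary 0111)
#' @export
hash_kmer <- function(f, kmer) {
  stopifnot(inherits(f, "hash_function"), is.character(kmer),
            length(kmer) == 1L, nchar(kmer) >= 1L)
  nt <- .nuc_ints(kmer)
  if (anyNA(nt)) {
    stop("ambiguous base in k-mer '", kmer, "': only A/C/G/T can be hashed",
         call. = FALSE)
  }
  bits <- .bit_table(f)[nt + 1L]
  k <- length(bits)
  sum(bits * 2^((k - 1L):0L))
}

# Codes of every k-mer of an integer-encoded sequence (NA at ambiguous
# positions) under one function. Returns a double vector of length
# length(nt) - k + 1 with NA where the window covers an ambiguous base.
# Equivalent to the O(1) rolling update code' = (code*2 + newbit) mod 2^k,
# computed here as a vectorized moving weighted sum.
.codes_along <- function(f, nt, k) {
  L <- length(nt)
  if (L < k) return(numeric(0))
  bits <- .bit_table(f)[nt + 1L]       # NA propagates from ambiguous bases
  if (k == 1L) return(bits)
  co <- stats::filter(bits, 2^(0L:(k - 1L)), method = "convolution",
                      sides = 1L)
  as.numeric(co)[k:L]
}

#' Rolling k-mer hashes along a sequence
#'
#' Computes the code of every k-mer of a sequence in left-to-right order.
#' Successive codes obey the rolling relation
#' `code' = (code * 2 + newbit) mod 2^k` (a left shift, masked to k bits,
#' with the incoming nucleotide's bit appended). Windows containing an
#' ambiguous base are skipped; the rolling state restarts after them.
#'
#' @inheritParams hash_kmer
#' @param sequence A single DNA string.
#' @param k k-mer length (>= 1).
#' @return A data frame with columns `position` (0-based offset of the
#'   k-mer) and `code`; zero rows when the sequence is shorter than k.
#' @examples
#' f1 <- hash_functions()[[1]]
#' rolling_hashes(f1, "ACGTA", k = 4)   # codes 3 then 6
#' @export
rolling_hashes <- function(f, sequence, k) {
  stopifnot(inherits(f, "hash_function"), is.character(sequence),
            length(sequence) == 1L, k >= 1L)
  co <- .codes_along(f, .nuc_ints(sequence), as.integer(k))
  keep <- !is.na(co)
  data.frame(position = which(keep) - 1L, code = co[keep])
}

#' Reverse complement of DNA sequences
#'
#' Standard Watson-Crick reverse complement; `N` maps to `N`. Vectorized.
#'
#' @param sequence Character vector of DNA strings (A/C/G/T/N).
#' @return Character vector of the same length.
#' @examples
#' reverse_complement("AACG")  # "CGTT"
#' @export
reverse_complement <- function(sequence) {
  stopifnot(is.character(sequence))
  if (length(sequence) == 0L) return(character(0))
  bad <- grepl("[^ACGTNacgtn]", sequence)
  if (any(bad)) {
    stop("cannot reverse-complement: non-A/C/G/T/N character in sequence ",
         which(bad)[1L], call. = FALSE)
  }
  out <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(toupper(sequence))))
  unname(out)
}
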