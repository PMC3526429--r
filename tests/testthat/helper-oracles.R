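# Independent oracles the tests check the implementation against. These
# deliberately avoid the package's internal code paths: enumeration and
# brute force at tiny scale.

# All DNA strings of length k.
all_kmers <- function(k) {
  g <- do.call(expand.grid, rep(list(c("A", "C", "G", "T")), k))
  apply(as.matrix(g), 1L, paste, collapse = "")
}

# Enumerate all 16 nucleotide->bit labelings, drop the 2 constants, merge
# complement pairs; return the canonical zero sets (the side containing A,
# and for singletons not containing A, the singleton itself).
oracle_labeling_classes <- function() {
  nucs <- c("A", "C", "G", "T")
  labelings <- expand.grid(rep(list(0:1), 4))
  classes <- list()
  for (i in seq_len(nrow(labelings))) {
    bits <- as.integer(labelings[i, ])
    if (all(bits == bits[1L])) next               # constant labeling
    zero <- sort(nucs[bits == 0L])
    one <- sort(nucs[bits == 1L])
    # canonical representative: the smaller side; for balanced labelings
    # (a tie) the side containing A
    canon <- if (length(zero) != length(one)) {
      if (length(zero) < length(one)) zero else one
    } else if ("A" %in% zero) zero else one
    key <- paste(canon, collapse = "")
    classes[[key]] <- canon
  }
  classes
}

# Direct per-position hash: bits computed one nucleotide at a time, code
# assembled by Horner's rule. NULL for windows with an ambiguous base.
oracle_codes <- function(zero_set, sequence, k) {
  chars <- strsplit(toupper(sequence), "")[[1L]]
  L <- length(chars)
  if (L < k) return(data.frame(position = integer(0), code = numeric(0)))
  pos <- integer(0); code <- numeric(0)
  for (i in seq_len(L - k + 1L)) {
    win <- chars[i:(i + k - 1L)]
    if (any(!win %in% c("A", "C", "G", "T"))) next
    v <- 0
    for (ch in win) v <- v * 2 + as.numeric(!(ch %in% zero_set))
    pos <- c(pos, i - 1L); code <- c(code, v)
  }
  data.frame(position = pos, code = code)
}

# Exact false-positive probability of a single-function index under the
# i.i.d. uniform insertion model: average over all query k-mers of
# 1 - (1 - P(random insertion hits the query's cell))^n, with the cell
# hit probability obtained by exhaustive enumeration of all 4^k k-mers.
oracle_fp_exact <- function(zero_set, k, n) {
  km <- all_kmers(k)
  codes <- vapply(km, function(s) {
    v <- 0
    for (ch in strsplit(s, "")[[1L]]) v <- v * 2 + as.numeric(!(ch %in% zero_set))
    v
  }, numeric(1))
  p_hit <- as.numeric(table(factor(codes, levels = sort(unique(codes))))[
    as.character(codes)]) / length(km)
  mean(1 - (1 - p_hit)^n)
}

# Brute-force similar-read flags: a query read is similar when the
# maximum number of non-overlapping k-mer windows, each occurring
# somewhere in the target set, reaches t. Maximum computed by dynamic
# programming (not the greedy scan under test).
oracle_similar_flags <- function(query_seqs, target_seqs, k, t) {
  tk <- unlist(lapply(target_seqs, function(s) {
    L <- nchar(s)
    if (L < k) character(0) else substring(s, 1:(L - k + 1L), k:L)
  }))
  tk <- unique(tk[!grepl("[^ACGT]", tk)])
  vapply(query_seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(FALSE)
    qk <- substring(s, 1:(L - k + 1L), k:L)
    hit <- qk %in% tk
    np <- length(hit)
    # best[i] = max non-overlapping hits using windows starting at >= i
    best <- integer(np + k)
    for (i in np:1) {
      best[i] <- max(best[i + 1L], if (hit[i]) 1L + best[min(i + k, np + k)] else 0L)
    }
    best[1L] >= t
  }, logical(1), USE.NAMES = FALSE)
}

fixture_fasta <- function(path, ids, seqs) {
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}

fixture_fastq <- function(path, ids, seqs, quals = NULL) {
  if (is.null(quals)) quals <- vapply(nchar(seqs), strrep, character(1), x = "E")
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), path)
  path
}
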