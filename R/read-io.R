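# Sequence and result I/O. FASTA/FASTQ parsing and writing go through
# Biostrings; a read set is kept as a light list-of-columns object so the
# comparison code can work on plain character vectors.

#' Construct a read set
#'
#' @param ids Character vector of read identifiers.
#' @param sequences Character vector of DNA sequences (uppercased on
#'   construction).
#' @param qualities Optional character vector of Sanger-encoded quality
#'   strings (FASTQ), or `NULL`.
#' @param sample_name Name of the sample the reads belong to.
#' @param format `"fasta"` or `"fastq"`; the format reads are written
#'   back in.
#' @return A `read_set` object.
#' @export
read_set <- function(ids, sequences, qualities = NULL,
                     sample_name = "sample", format = c("fasta", "fastq")) {
  format <- match.arg(format)
  stopifnot(is.character(ids), is.character(sequences),
            length(ids) == length(sequences))
  if (!is.null(qualities)) {
    stopifnot(length(qualities) == length(sequences))
    if (any(nchar(qualities) != nchar(sequences))) {
      bad <- which(nchar(qualities) != nchar(sequences))[1L]
      stop("record ", bad, " ('", ids[bad],
           "'): quality and sequence lengths differ", call. = FALSE)
    }
  }
  if (anyDuplicated(ids)) {
    dup <- duplicated(ids)
    ids[dup] <- paste0(ids[dup], ".", which(dup))
    warning("duplicate read ids disambiguated with an appended ordinal",
            call. = FALSE)
  }
  structure(list(sample_name = sample_name, ids = ids,
                 sequences = toupper(sequences), qualities = qualities,
                 format = format),
            class = "read_set")
}

#' @export
length.read_set <- function(x) length(x$ids)

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set '%s': %d reads (%s)>\n", x$sample_name,
              length(x), x$format))
  invisible(x)
}

#' @export
`[.read_set` <- function(x, i) {
  read_set(x$ids[i], x$sequences[i],
           if (!is.null(x$qualities)) x$qualities[i],
           sample_name = x$sample_name, format = x$format)
}

.sniff_format <- function(path) {
  con <- gzfile(path, "rt")  # gzfile transparently reads plain files too
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  if (length(first) == 0L) return("fasta")  # empty file: treat as FASTA
  if (startsWith(first, ">")) "fasta"
  else if (startsWith(first, "@")) "fastq"
  else stop("cannot detect format of '", path,
            "': first byte is neither '>' nor '@'", call. = FALSE)
}

#' Read a FASTA or FASTQ file into a read set
#'
#' Auto-detects the format from the first byte (`>` FASTA, `@` FASTQ)
#' unless hinted; gzip-compressed files are handled transparently.
#' Multi-line FASTA is accepted; sequences are uppercased.
#'
#' @param path Path to the file.
#' @param format Optional `"fasta"` or `"fastq"` hint.
#' @param sample_name Sample name; defaults to the file name stripped of
#'   its extensions.
#' @return A [read_set()].
#' @export
read_sequences <- function(path, format = NULL, sample_name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(format)) format <- .sniff_format(path)
  format <- match.arg(format, c("fasta", "fastq"))
  if (is.null(sample_name)) {
    sample_name <- sub("\\.(fa|fasta|fq|fastq)(\\.gz)?$", "",
                       basename(path), ignore.case = TRUE)
  }
  if (format == "fasta") {
    ss <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                   error = function(e) stop("malformed FASTA '", path, "': ",
                                            conditionMessage(e), call. = FALSE))
    quals <- NULL
  } else {
    parsed <- tryCatch({
      ss <- Biostrings::readDNAStringSet(path, format = "fastq",
                                         with.qualities = TRUE)
      list(ss = ss, quals = as.character(S4Vectors::mcols(ss)$qualities))
    }, error = function(e) stop("malformed FASTQ '", path, "': ",
                                conditionMessage(e), call. = FALSE))
    ss <- parsed$ss
    quals <- parsed$quals
    if (any(nchar(quals) != nchar(as.character(ss)))) {
      bad <- which(nchar(quals) != nchar(as.character(ss)))[1L]
      stop("malformed FASTQ '", path, "': record ", bad,
           " has mismatched sequence and quality lengths", call. = FALSE)
    }
  }
  seqs <- as.character(ss)
  if (any(nchar(seqs) == 0L)) {
    stop("record ", which(nchar(seqs) == 0L)[1L], " of '", path,
         "' has an empty sequence", call. = FALSE)
  }
  ids <- if (is.null(names(ss))) as.character(seq_along(ss)) else names(ss)
  read_set(unname(ids), unname(seqs), quals,
           sample_name = sample_name, format = format)
}

#' Write a flagged subset of a read set
#'
#' Writes exactly the flagged reads, in their original order, in the read
#' set's source format (FASTQ stays FASTQ, with qualities). This is how
#' the pipeline materializes the similar-read subsets it returns. FASTA
#' output is wrapped at 80 columns; a `.gz` path is written compressed.
#'
#' @param readset A [read_set()].
#' @param member_flags Logical vector, one flag per read.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_subset <- function(readset, member_flags, path) {
  stopifnot(inherits(readset, "read_set"), is.logical(member_flags))
  if (length(member_flags) != length(readset)) {
    stop("member_flags length (", length(member_flags),
         ") does not match the number of reads (", length(readset), ")",
         call. = FALSE)
  }
  sub <- readset[which(member_flags)]
  ss <- Biostrings::DNAStringSet(sub$sequences)
  names(ss) <- sub$ids
  compress <- grepl("\\.gz$", path)
  if (readset$format == "fastq") {
    quals <- sub$qualities
    if (is.null(quals)) quals <- vapply(nchar(sub$sequences), strrep,
                                        character(1), x = "I")
    Biostrings::writeXStringSet(ss, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals),
                                compress = compress)
  } else {
    Biostrings::writeXStringSet(ss, path, format = "fasta", width = 80L,
                                compress = compress)
  }
  invisible(path)
}

#' Write a similarity matrix as TSV
#'
#' Tab-separated table with sample names as header row and first column;
#' cells formatted to 2 decimals.
#'
#' @param names Character vector of sample names.
#' @param similarity Square numeric matrix of percentages, dimensions
#'   matching `names`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(names, similarity, path) {
  similarity <- as.matrix(similarity)
  if (nrow(similarity) != ncol(similarity) ||
      nrow(similarity) != length(names)) {
    stop("similarity must be a square matrix matching length(names)",
         call. = FALSE)
  }
  cells <- matrix(sprintf("%.2f", similarity), nrow = nrow(similarity))
  df <- data.frame(sample = names, cells, check.names = FALSE)
  colnames(df) <- c("sample", names)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a similarity matrix TSV
#'
#' @param path Path written by [write_matrix()].
#' @return Numeric matrix with dimnames.
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Write a dendrogram in Newick format
#'
#' @param tree A `phylo` tree from [cluster_dendrogram()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}
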