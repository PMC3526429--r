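# The directional heuristic intersection: the subset of reads of a query
# set sharing at least t non-overlapping k-mers with the k-mer content of
# a target set. The target is indexed in chunks of at most chunk_limit
# k-mer occurrences so the false-positive rate of the probabilistic index
# stays bounded; the union of per-chunk results is exactly the
# whole-target result, because membership errors only ever add reads.

#' Comparison parameters
#'
#' @param k k-mer length (default 33, the working configuration for
#'   billion-k-mer samples; tests and small analyses use smaller k).
#' @param t Minimum number of non-overlapping shared k-mers for a read to
#'   count as similar (default 2).
#' @param chunk_limit Maximum number of k-mer occurrences indexed per
#'   chunk of the target set (default 1e9). Chunking caps the index
#'   false-positive rate and the result is the union over chunks.
#' @param functions Hash combination for the probabilistic index
#'   (default: three balanced projections plus one unbalanced, `f1`..`f4`).
#' @param backend `"bds"` for the probabilistic index (production) or
#'   `"exact"` for an exact k-mer set (oracle; same heuristic, no
#'   index false positives).
#' @param reverse_complement If `TRUE`, a query read whose forward scan
#'   fails is also scanned as its reverse complement, and a hit on either
#'   orientation qualifies. Off by default: sharing is literal substring
#'   sharing on the given strand.
#' @return A `comparison_params` object.
#' @export
comparison_params <- function(k = 33L, t = 2L, chunk_limit = 1e9,
                              functions = hash_functions(1:4),
                              backend = c("bds", "exact"),
                              reverse_complement = FALSE) {
  backend <- match.arg(backend)
  stopifnot(k >= 1, t >= 1, chunk_limit >= 1)
  structure(list(k = as.integer(k), t = as.integer(t),
                 chunk_limit = chunk_limit, functions = functions,
                 backend = backend,
                 reverse_complement = isTRUE(reverse_complement)),
            class = "comparison_params")
}

# All k-mers of a sequence as strings (may include ambiguous letters).
.read_kmers <- function(sequence, k) {
  L <- nchar(sequence)
  if (L < k) return(character(0))
  substring(sequence, 1:(L - k + 1L), k:L)
}

# Number of k-mer windows free of ambiguous bases (the countable k-mer
# occurrences of a read, the unit the chunk limit caps).
.n_valid_windows <- function(sequence, k) {
  nt <- .nuc_ints(sequence)
  L <- length(nt)
  if (L < k) return(0)
  ok <- as.numeric(!is.na(nt))
  if (k == 1L) return(sum(ok))
  runsum <- as.numeric(stats::filter(ok, rep(1, k), sides = 1L))[k:L]
  sum(runsum == k)
}

# --- chunk membership backends ------------------------------------------
# A backend exposes: $index(sequences) to (re)build from a chunk of target
# reads, and $member(sequence) returning one logical per k-mer position of
# a query read (FALSE at ambiguous windows).

.backend_exact <- function(k) {
  env <- new.env(parent = emptyenv())
  env$set <- character(0)
  list(
    index = function(sequences) {
      km <- unlist(lapply(sequences, .read_kmers, k = k), use.names = FALSE)
      km <- km[!grepl("[^ACGT]", km)]
      env$set <- unique(km)
    },
    member = function(sequence) .read_kmers(sequence, k) %in% env$set
  )
}

.backend_bds <- function(k, functions) {
  idx <- bds_create(k, functions)
  codes_of <- function(sequence) {
    nt <- .nuc_ints(sequence)
    co <- vapply(functions, .codes_along, numeric(max(length(nt) - k + 1L, 0L)),
                 nt = nt, k = k)
    matrix(co, ncol = length(functions))
  }
  list(
    index = function(sequences) {
      bds_reset(idx)
      for (s in sequences) {
        co <- codes_of(s)
        if (nrow(co)) .bds_insert_codes(idx, co)
      }
    },
    member = function(sequence) {
      co <- codes_of(sequence)
      if (!nrow(co)) return(logical(0))
      .bds_contains_codes(idx, co)
    }
  )
}

.make_backend <- function(params) {
  if (params$backend == "exact") .backend_exact(params$k)
  else .backend_bds(params$k, params$functions)
}

# Greedy left-to-right non-overlap count with early exit: on a hit at
# position i, resume at i + k. Greedy is optimal for equal-length
# intervals, so given exact membership this realizes the similarity
# definition exactly.
.greedy_reaches_t <- function(member, k, t) {
  i <- 1L
  count <- 0L
  L <- length(member)
  while (i <= L) {
    if (member[i]) {
      count <- count + 1L
      if (count >= t) return(TRUE)
      i <- i + k
    } else {
      i <- i + 1L
    }
  }
  FALSE
}

#' Test one read against an indexed k-mer set
#'
#' Scans the read's k-mers left to right against the index; each
#' membership hit at position `i` advances the scan to `i + k` (greedy
#' non-overlapping selection) and the read qualifies as soon as `t` hits
#' accumulate. With `reverse_complement`, a failed forward scan is
#' followed by a scan of the reverse-complemented read.
#'
#' @param read A single DNA string.
#' @param index A `bds_index`, or a character vector of equal-length
#'   k-mers used as an exact set.
#' @param t Minimum non-overlapping shared k-mers.
#' @param reverse_complement Also try the reverse complement.
#' @return `TRUE` if the read is similar to the indexed content.
#' @examples
#' read_is_similar("TTTATTT", index = c("TTT"), t = 2)  # TRUE
#' read_is_similar("TTTATTT", index = c("TTT"), t = 3)  # FALSE
#' @export
read_is_similar <- function(read, index, t = 2L, reverse_complement = FALSE) {
  stopifnot(is.character(read), length(read) == 1L)
  read <- toupper(read)
  if (inherits(index, "bds_index")) {
    k <- index$k
    member_of <- function(s) {
      nt <- .nuc_ints(s)
      if (length(nt) < k) return(logical(0))
      co <- vapply(index$functions, .codes_along,
                   numeric(length(nt) - k + 1L), nt = nt, k = k)
      .bds_contains_codes(index, matrix(co, ncol = length(index$functions)))
    }
  } else {
    stopifnot(is.character(index))
    k <- unique(nchar(index))
    if (length(k) > 1L) stop("exact k-mer set has mixed lengths", call. = FALSE)
    if (length(k) == 0L) return(FALSE)
    member_of <- function(s) .read_kmers(s, k) %in% index
  }
  if (.greedy_reaches_t(member_of(read), k, t)) return(TRUE)
  if (reverse_complement) {
    rc <- tryCatch(reverse_complement(read), error = function(e) NULL)
    if (!is.null(rc) && .greedy_reaches_t(member_of(rc), k, t)) return(TRUE)
  }
  FALSE
}

# Partition target read indices into chunks of at most chunk_limit
# countable k-mer occurrences, at whole-read granularity (a read's k-mers
# are never split across chunks; a single read larger than the limit
# forms its own chunk).
.chunk_reads <- function(counts, chunk_limit) {
  chunks <- list()
  cur <- integer(0)
  vol <- 0
  for (i in seq_along(counts)) {
    if (length(cur) > 0L && vol + counts[i] > chunk_limit) {
      chunks[[length(chunks) + 1L]] <- cur
      cur <- integer(0)
      vol <- 0
    }
    cur <- c(cur, i)
    vol <- vol + counts[i]
  }
  if (length(cur)) chunks[[length(chunks) + 1L]] <- cur
  chunks
}

#' Directional intersection of two read sets
#'
#' Flags the reads of `query` sharing at least `params$t` non-overlapping
#' k-mers with the k-mer content of `target`. The target is streamed in
#' chunks of at most `params$chunk_limit` k-mer occurrences: each chunk is
#' indexed, every not-yet-flagged query read is tested, and the index is
#' reset before the next chunk. The final flags are the union over
#' chunks, which is identical to indexing the whole target at once (a
#' read flagged by any chunk is flagged overall, and exact membership
#' makes the equivalence exact). Reads flagged in an earlier chunk are
#' not re-queried.
#'
#' @param query,target [read_set()] objects.
#' @param params A [comparison_params()].
#' @param skip_flags Optional logical vector over `query`: reads marked
#'   `TRUE` are excluded from querying entirely (used by the pipeline to
#'   restrict a pass to a previously selected subset).
#' @return A `directional_result`: list with `query_sample`,
#'   `target_sample`, `member_flags` (one logical per query read),
#'   `matched_count` and `chunks_used`.
#' @export
intersect_directional <- function(query, target, params = comparison_params(),
                                  skip_flags = NULL) {
  stopifnot(inherits(query, "read_set"), inherits(target, "read_set"),
            inherits(params, "comparison_params"))
  nq <- length(query)
  flags <- logical(nq)
  queryable <- if (is.null(skip_flags)) rep(TRUE, nq) else {
    stopifnot(is.logical(skip_flags), length(skip_flags) == nq)
    !skip_flags
  }
  counts <- vapply(target$sequences, .n_valid_windows, numeric(1),
                   k = params$k, USE.NAMES = FALSE)
  if (length(target) == 0L) {
    return(structure(list(query_sample = query$sample_name,
                          target_sample = target$sample_name,
                          member_flags = flags, matched_count = 0L,
                          chunks_used = 0L),
                     class = "directional_result"))
  }
  chunks <- .chunk_reads(counts, params$chunk_limit)
  backend <- .make_backend(params)
  member_scan <- function(sequence) {
    m <- backend$member(sequence)
    m[is.na(m)] <- FALSE
    m
  }
  for (ch in chunks) {
    todo <- which(queryable & !flags)
    if (length(todo) == 0L) next  # all remaining reads already tagged
    backend$index(target$sequences[ch])
    for (i in todo) {
      s <- query$sequences[i]
      hit <- .greedy_reaches_t(member_scan(s), params$k, params$t)
      if (!hit && params$reverse_complement) {
        rc <- tryCatch(reverse_complement(s), error = function(e) NULL)
        if (!is.null(rc)) hit <- .greedy_reaches_t(member_scan(rc),
                                                   params$k, params$t)
      }
      if (hit) flags[i] <- TRUE
    }
  }
  structure(list(query_sample = query$sample_name,
                 target_sample = target$sample_name,
                 member_flags = flags, matched_count = sum(flags),
                 chunks_used = length(chunks)),
            class = "directional_result")
}

#' @export
print.directional_result <- function(x, ...) {
  cat(sprintf("<directional intersection %s -> %s: %d/%d reads similar (%d chunk%s)>\n",
              x$query_sample, x$target_sample, x$matched_count,
              length(x$member_flags), x$chunks_used,
              if (x$chunks_used == 1L) "" else "s"))
  invisible(x)
}
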