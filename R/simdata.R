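# Deterministic synthetic-read generation. These generators exist so
# every stage of the package is testable without downloading sequencing
# data: uniform random reads give a null model with essentially no chance
# k-mer sharing at k >= 20, planted identical blocks give reads whose
# similarity status is known by construction, and a small hand-built
# scenario reproduces the three archetypes of spread-k-mer behaviour the
# cascaded pipeline is designed around.

# Evaluate expr under a temporary RNG state seeded with `seed`.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

.random_dna <- function(n_strings, len) {
  if (n_strings == 0L) return(character(0))
  m <- matrix(sample(NUCS, n_strings * len, replace = TRUE), nrow = n_strings)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Uniform random reads
#'
#' Generates i.i.d. uniform A/C/G/T reads; identical seeds give identical
#' read sets. At k >= 20 two independent such samples share essentially
#' no k-mer by chance, so these reads serve as the null model for the
#' comparison pipeline.
#'
#' @param n_reads Number of reads.
#' @param read_length Length of every read, in nucleotides.
#' @param sample_name Sample name for the resulting [read_set()].
#' @param seed Integer seed.
#' @return A [read_set()].
#' @export
random_reads <- function(n_reads, read_length, sample_name = "sim",
                         seed = 1L) {
  stopifnot(n_reads >= 0, read_length >= 1)
  seqs <- .with_seed(seed, .random_dna(n_reads, read_length))
  ids <- if (n_reads > 0) paste0(sample_name, "_r", seq_len(n_reads)) else character(0)
  read_set(ids, seqs, sample_name = sample_name)
}

#' A pair of read sets with planted shared blocks
#'
#' Builds two random samples in which a known fraction of read pairs
#' (read i of each sample) carry one identical block of length
#' `block_length` copied into otherwise-random sequence at independent
#' random offsets. A block of length `t * k` yields exactly `t`
#' non-overlapping shared k-mers under the greedy scan, so the planted
#' reads are similar at threshold `t` but not at `t + 1`; unplanted reads
#' share nothing (up to the negligible chance collision rate at the
#' default k).
#'
#' @param n_reads Reads per sample.
#' @param read_length Read length (must be >= `block_length`).
#' @param k k-mer length the ground truth is defined for.
#' @param t Similarity threshold the blocks are sized for.
#' @param planted_similarity Fraction of reads per sample carrying a
#'   planted block, in `[0, 1]`.
#' @param block_length Planted block length (default `t * k`).
#' @param seed Integer seed.
#' @param names Character vector of the two sample names.
#' @return List with read sets `a` and `b`, logical ground-truth flag
#'   vectors `expected_a` and `expected_b`, and `planted` (the planted
#'   read indices).
#' @export
planted_pair <- function(n_reads, read_length, k = 20L, t = 2L,
                         planted_similarity = 0.3,
                         block_length = t * k, seed = 1L,
                         names = c("simA", "simB")) {
  stopifnot(planted_similarity >= 0, planted_similarity <= 1,
            n_reads >= 0, length(names) == 2L)
  if (block_length > read_length) {
    stop("planted block (", block_length,
         " nt) does not fit in a read of length ", read_length, call. = FALSE)
  }
  n_planted <- round(planted_similarity * n_reads)
  .with_seed(seed, {
    seq_a <- .random_dna(n_reads, read_length)
    seq_b <- .random_dna(n_reads, read_length)
    planted <- sort(sample.int(n_reads, n_planted))
    for (i in planted) {
      block <- .random_dna(1L, block_length)
      oa <- sample.int(read_length - block_length + 1L, 1L)
      ob <- sample.int(read_length - block_length + 1L, 1L)
      substr(seq_a[i], oa, oa + block_length - 1L) <- block
      substr(seq_b[i], ob, ob + block_length - 1L) <- block
    }
    flags <- seq_len(n_reads) %in% planted
    list(a = read_set(paste0(names[1L], "_r", seq_len(n_reads)), seq_a,
                      sample_name = names[1L]),
         b = read_set(paste0(names[2L], "_r", seq_len(n_reads)), seq_b,
                      sample_name = names[2L]),
         expected_a = flags, expected_b = flags, planted = planted)
  })
}

#' The three spread-k-mer archetypes as a fixture
#'
#' Hand-built two-sample scenario (threshold `t = 2`) exercising the
#' behaviours the cascaded pipeline distinguishes:
#' * read `a1` shares 2 non-overlapping k-mers with the single read `b1`
#'   -- genuinely similar, retained by the final pass;
#' * read `a2` shares 1 k-mer each with `b2` and `b3`, which share
#'   nothing else with sample A -- a spread-k-mer false positive that
#'   pass 2 eliminates (`b2`, `b3` drop out of B-hat) so pass 3 removes
#'   `a2`;
#' * read `a3` shares 1 k-mer each with `b1` and `b4`, where `b4` itself
#'   shares 2 k-mers with read `a4` -- the residual false-positive class:
#'   both carriers survive into B-hat, so `a3` is retained.
#'
#' @param k k-mer length for the planted k-mers (default 15; large enough
#'   that background collisions are negligible).
#' @param spacer Length of the random background segments between planted
#'   k-mers (default 20).
#' @param seed Integer seed for the background sequence.
#' @return List with read sets `a` (reads a1..a4) and `b` (reads b1..b4),
#'   `expected_final_a` = (TRUE, FALSE, TRUE, TRUE), and the threshold
#'   `t = 2` the construction assumes.
#' @export
sim_fig_spread <- function(k = 15L, spacer = 20L, seed = 1L) {
  stopifnot(k >= 1, spacer >= k)
  .with_seed(seed, {
    km <- .random_dna(8L, k)  # K1 K2 K3 K4 Y1 Y2 K5 K6
    bg <- function() .random_dna(1L, spacer)
    glue <- function(...) paste0(...)
    a1 <- glue(bg(), km[1], bg(), km[2], bg())
    a2 <- glue(bg(), km[3], bg(), km[4], bg())
    a3 <- glue(bg(), km[5], bg(), km[6], bg())
    a4 <- glue(bg(), km[7], bg(), km[8], bg())
    b1 <- glue(bg(), km[1], bg(), km[2], bg(), km[5], bg())
    b2 <- glue(bg(), km[3], bg())
    b3 <- glue(bg(), km[4], bg())
    b4 <- glue(bg(), km[6], bg(), km[7], bg(), km[8], bg())
    list(a = read_set(paste0("a", 1:4), c(a1, a2, a3, a4),
                      sample_name = "figA"),
         b = read_set(paste0("b", 1:4), c(b1, b2, b3, b4),
                      sample_name = "figB"),
         expected_final_a = c(TRUE, FALSE, TRUE, TRUE),
         t = 2L)
  })
}

#' Grouped samples with planted within-group sharing
#'
#' Generates samples partitioned into groups: within a group, a fraction
#' of each sample's reads are copies of group-level reference reads, so
#' within-group similarity is high while between-group similarity is
#' near zero. Used to test that clustering recovers the group structure.
#'
#' @param group_sizes Integer vector: number of samples per group.
#' @param n_reads Reads per sample.
#' @param read_length Read length.
#' @param shared_fraction Fraction of each sample's reads copied from its
#'   group's reference reads.
#' @param seed Integer seed.
#' @return List with `samples` (list of [read_set()]) and `groups`
#'   (integer group label per sample).
#' @export
sim_sample_groups <- function(group_sizes = c(3L, 3L), n_reads = 30L,
                              read_length = 80L, shared_fraction = 0.5,
                              seed = 1L) {
  stopifnot(all(group_sizes >= 1), shared_fraction >= 0, shared_fraction <= 1)
  .with_seed(seed, {
    samples <- list()
    groups <- integer(0)
    n_shared <- round(shared_fraction * n_reads)
    s_id <- 0L
    for (g in seq_along(group_sizes)) {
      ref <- .random_dna(n_shared, read_length)
      for (m in seq_len(group_sizes[g])) {
        s_id <- s_id + 1L
        seqs <- .random_dna(n_reads, read_length)
        if (n_shared > 0) seqs[seq_len(n_shared)] <- ref
        nm <- sprintf("g%ds%d", g, m)
        samples[[s_id]] <- read_set(paste0(nm, "_r", seq_len(n_reads)),
                                    seqs, sample_name = nm)
        groups <- c(groups, g)
      }
    }
    list(samples = samples, groups = groups)
  })
}
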