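---
title: "Comparing read sets by shared k-mers: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing read sets by shared k-mers: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmercompare)
```

## The similarity model

`kmercompare` treats two reads as similar when they share at least `t`
non-overlapping k-mers — exact length-k substring matches, on the given
strand. This is deliberately rough: it tolerates no mismatches inside a
k-mer, but a single long identity region contributes several k-mers, so
reads from the same locus in two samples are caught while unrelated reads
almost never are (two random 100-mers share a 33-mer with probability
around $10^{-16}$). The unit of comparison is the *read set*: the
directional operation `A →∩ B` flags the reads of sample A sharing at
least `t` non-overlapping k-mers with the k-mer content of sample B as a
whole.

Working at set level is what makes the method scale, but it weakens the
definition: the `t` k-mers of a flagged read may be spread over several
unrelated reads of B. `symmetric_compare()` therefore cascades three
directional passes — `Â = A →∩ B`, `B̂ = B →∩ Â`, then `Â →∩ B̂` — so that
k-mers carried only by non-similar reads of B drop out before the final
pass. One false-positive class survives by construction: a read whose
shared k-mers are spread over distinct reads of B that are each,
independently, similar to A. `sim_fig_spread()` generates the three
archetypes (genuinely similar; spread over non-similar carriers, removed;
spread over similar carriers, retained) and the test suite pins the
expected outcome of each.

The reported similarity between samples is
$100\,(|\mathrm{final}(A)| + |\hat B|)/(|A| + |B|)$. The denominators
count *all* reads, including reads shorter than k or made of ambiguous
bases, which can never match; this is a deliberate choice so that the
percentage is a property of the samples, not of the filterable subset.
The published description of the measure omits the rendered formula, so
this form — the two output subsets over the two input sizes — is a
reconstruction from its surrounding text, and is documented as such.

## The membership index

K-mer membership is tested against a Bloom-filter variant with one
dedicated `2^k`-bit array per hash function, addressed directly by the
k-bit hash code; there is no modular reduction anywhere. The hash family
is the set of position-wise nucleotide→bit projections: each nucleotide
contributes one bit determined only by its letter, the leftmost
nucleotide being the most significant. Identifying complementary
labelings (a global bit-flip changes no collision structure) and dropping
the two constant ones leaves exactly seven functions: three *balanced*
(`f1`: 0 on A/C, `f2`: 0 on A/G, `f3`: 0 on A/T) and four *unbalanced*
(0 on a single letter).

Two properties make this family attractive. First, consecutive k-mers
satisfy `code' = (code·2 + newbit) mod 2^k`, so hashing a whole read is
one bit-shift per position. Second, no two distinct k-mers agree under
two balanced functions simultaneously (each nucleotide gets a distinct
bit pair), so the three balanced arrays interfere minimally and their
combined false-positive probability is simply the cube of the
single-array probability.

### False-positive model

With `n` distinct k-mers indexed, a uniform random absent query is a
false positive of a balanced array with probability
$1-(1-2^{-k})^n$ — balanced codes are uniform over the $2^k$ cells. An
unbalanced function concentrates its codes: a query whose code has $x$
zero bits occupies a cell hit with probability
$a_x = (1/4)^x(3/4)^{k-x}$ per insertion, and uniform queries put weight
$\binom{k}{x}a_x$ on such codes, giving
$\sum_x \binom{k}{x} a_x\,(1-(1-a_x)^n)$. A combination multiplies the
per-function probabilities: exact (as an upper bound) for the balanced
triple, and an independence approximation once an unbalanced function
joins — `simulate_fp()` cross-checks that approximation and the test
suite holds it to three standard errors across the k ∈ {15, 20} curves.
All `(1-p)^n` terms are evaluated via `log1p`/`expm1` so the model stays
accurate at `n = 1e9`.

```{r fp-model}
# the operating point: three balanced + one unbalanced at k = 33
p_fp_combo(33, 1e9, hash_functions(1:3))   # balanced triple bound
p_fp_combo(33, 1e9, hash_functions(1:4))   # with one unbalanced function
```

False negatives are impossible: every inserted k-mer sets exactly the
bits later queried.

## Parameters

* **k (default 33).** Larger k means fewer chance collisions, a stricter
  similarity notion, and a bigger index (`2^k` bits per function: 1 GiB
  at k = 33). k ≥ 30 keeps the false-positive rate under 2 % up to
  3×10⁸ indexed k-mers. Analyses of small samples can drop to k = 15–21
  and a kilobyte-to-megabyte index.
* **t (default 2).** Minimum non-overlapping shared k-mers per read.
  Raising t only removes reads (the flag sets are nested), sharpening
  specificity at the cost of sensitivity near read ends.
* **functions (default `f1,f2,f3,f4`).** The three balanced functions
  plus one unbalanced. The balanced triple does almost all the work; the
  unbalanced addition buys a further ~15 % reduction at the operating
  point. The four unbalanced functions are interchangeable here by
  symmetry of their formula; the first is used.
* **chunk_limit (default 1e9 occurrences).** The target set is indexed
  in chunks of at most this many k-mer occurrences, bounding `n` and
  hence the false-positive rate; query flags are OR-ed over chunks,
  which reproduces the whole-target result exactly. Occurrences — not
  distinct k-mers — are counted, since counting distinct k-mers would
  itself require an exact set.
* **backend.** `"bds"` is the probabilistic index; `"exact"` keeps a
  literal k-mer set and serves as the oracle in tests and for small
  inputs. Exact-backend results are invariant under `chunk_limit`; the
  probabilistic backend returns a superset of the exact flags (index
  collisions only ever add reads), and coincides with it whenever no
  query read accumulates `t` colliding hits.

## Numerical and procedural choices

* **Bit order.** Leftmost nucleotide → most significant bit, making the
  documented left-shift update literal. Any fixed convention gives an
  isomorphic index; only consistency matters.
* **Greedy non-overlap selection.** The scan moves left to right and
  jumps k positions after each hit, stopping at t. For equal-length
  intervals greedy selection is maximal, so with exact membership this
  realizes the similarity definition exactly, in linear time, and allows
  early exit.
* **Ambiguous bases.** Any k-mer window containing a non-A/C/G/T letter
  is skipped everywhere — not indexed, not queried, not counted toward
  the chunk volume. Input case is ignored.
* **Chunk boundaries.** Chunks break at whole-read granularity, so a
  read's k-mers are never split across chunks. With reads of uniform
  length the number of chunks equals
  `ceil(total occurrences / chunk_limit)`; heterogeneous read lengths
  can pack slightly worse, and `chunks_used` reports the actual count.
* **Reverse complements.** Off by default — the similarity definition is
  literal substring sharing. `reverse_complement = TRUE` additionally
  scans each failed read's reverse complement and accepts a hit on
  either orientation.
* **Clustering.** `all_pairs()` computes each unordered pair once
  (self-comparisons included by default, so 15 samples cost 120
  comparisons) and mirrors the matrix; `cluster_dendrogram()` applies
  average-linkage clustering to `100 − similarity`. `hclust` merge order
  is deterministic; under exact ties it follows sample index, so tied
  inputs are reproducible but not permutation-invariant.

## What the synthetic data does and does not show

The generators produce uniform i.i.d. reads (`random_reads()`), pairs
with planted identical blocks and known ground truth (`planted_pair()`;
a block of length `t·k` is similar at threshold t and not at t+1),
grouped cohorts with within-group sharing (`sim_sample_groups()`), and
the spread-k-mer archetypes (`sim_fig_spread()`). Tests on them verify
the machinery: exact recovery of planted reads, containment of exact
flags in probabilistic flags, chunking invariance, threshold
monotonicity, and agreement of observed false-positive rates with the
closed forms.

They do not emulate real metagenomes: no community abundance structure,
no sequencing-error model, no read-length distribution, no shared
low-complexity sequence. Real samples share k-mers for biological *and*
artefactual reasons (adapters, homopolymers), so passing tests here
demonstrate correctness of the algorithm, not field performance; on real
data the similarity percentage should be read comparatively across
sample pairs rather than as an absolute overlap estimate.

Test and vignette problem sizes (reads of 60–120 nt, tens to hundreds of
reads, k = 8–21, simulation loads up to 10⁵ indexed 20-mers with 10⁵
queries) were chosen so the whole suite exercises every code path —
including multi-chunk indexing and measurable false-positive rates — in
well under a minute; the closed-form model, not simulation, carries the
billion-k-mer operating point.

## Known limitations

* The spread-k-mer residual false-positive class is inherent to
  set-level comparison; its rate depends on how much sequence the
  samples genuinely share and is not modeled in closed form.
* The index false-positive model assumes unbiased nucleotide
  composition; strongly skewed genomes (extreme GC) will see higher
  per-function rates than predicted, mitigated by the balanced triple's
  exactness but not eliminated.
* The balanced-beats-unbalanced ordering of the closed forms holds in
  the operating regime (load below about half the `2^k` cells); at
  extreme saturation both rates approach 1 and the ordering can invert
  in the far tail.
* Memory is `|functions| · 2^k` bits regardless of input size — generous
  for small k, but k = 33 requires 4 GiB and the implementation keeps
  arrays in RAM.
* Paired-end structure is ignored; mates are independent reads.
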