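---
title: "chainani: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chainani: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chainani)
```

## The problem

Average nucleotide identity (ANI) between two genomes is the standard currency
of prokaryotic comparative genomics (95% is the conventional species boundary).
Pure sketching estimators (Mash-style Jaccard, containment) compare the k-mer
sets of whole assemblies, so when one assembly is incomplete the index drops
even though the underlying sequences are identical: a 50%-complete
metagenome-assembled genome (MAG) loses shared k-mers for reasons that have
nothing to do with genetic distance. Alignment-based estimators avoid this by
scoring only orthologous regions, but are orders of magnitude slower.

chainani implements the middle road: approximate orthologous regions are found
by chaining sparse k-mer anchors (no base-level alignment), and ANI is
estimated from k-mer match statistics *restricted to those regions*, together
with the aligned fraction (AF) of each genome.

## The model

Mutation model: each base of a genome `G` is independently substituted to a
different letter with probability `theta`; the true ANI of the pair is
`1 - theta`. Under this model a k-mer survives unmutated with probability
`ANI^k`, which is the identity used at every level of the estimator:

* **Screen.** Very sparse marker ℓ-mers (ℓ = 21, FracMinHash rate
  1/1000) estimate the max-containment index
  `|A ∩ B| / min(|A|, |B|)`; putative ANI is its ℓ-th root. Pairs at or
  below 80% putative ANI are filtered out (the chaining estimator is designed
  for the > 82% range). Max-containment, unlike Jaccard, is robust to
  *one-sided* incompleteness because the denominator tracks the smaller set.
* **Chunk ANI.** The query is cut into 20-kb chunks. For a chunk with `M`
  seed k-mers of which `alpha` are anchors inside orthologous chains, the
  estimate is `(alpha / M)^(1/k)`. When only part of a chunk is homologous,
  `M` overcounts; the flanked-seed variant uses `M_LR`, the seeds between the
  leftmost and rightmost anchor, and replaces the estimate when
  `(alpha / M_LR)^(1/k) > 0.95` and the flanked span exceeds `4c` bases.
* **Final ANI.** Seed-count-weighted mean over chunks, with a 100-iteration
  chunk bootstrap (5th/95th percentile) as a 90% CI when more than 10 chunks
  contribute.

Chaining: anchors are exact matches of canonical seed k-mers (k = 15,
FracMinHash rate 1/c, c = 125 by default, repetitive seeds masked above
2500/c occurrences). Within a chunk the banded DP
`f(i) = max(max_j f(j) + 20 - |Δy - Δx|, 0)` scores diagonal-consistent
increasing anchor runs; at most `A = B/c` predecessors are scanned and the
scan stops when the query gap exceeds `B = 2500`. Backtracking over a
union–find partition yields disjoint homologous chains; a greedy pass in
decreasing score order keeps chains with at least 3 anchors whose
reference-span overlap with the already-selected set is under 50% of their own
span ("orthologous" chains, suppressing paralog pile-ups). Chain coverage
(`span + 2c` per chain, the `2c` compensating subsampled edges) divided by
genome length gives AF on each side; ANI is reported only when either AF is
at least 15%.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `k` | 15 | seed k-mer length; `ANI^k` is the anchor survival probability |
| `c` | 125 | seed subsampling rate; runtime and sketch size scale as 1/c |
| `marker_k` (ℓ) | 21 | marker length for the screen |
| `marker_c` | 1000 | marker subsampling rate |
| `chunk_size` | 20 kb | per-chunk estimation window |
| `band_b` / `band_a` | 2500 / `b/c` | chaining band (bases / predecessors) |
| `mask_threshold` | `2500/c` | per-genome seed occurrence cap |
| `marker_ani_threshold` | 0.80 | screen gate (strict `>`) |
| `af_threshold` | 0.15 | report ANI only if either AF reaches this |
| `lr_ani_gate` / `lr_min_span` | 0.95 / `4c` | flanked-seed heuristic gates |

Presets map `c` to 30 (slow; fragmented/distant genomes, N50 ~ 3 kb), 70
(medium), 200 (fast; > 95% ANI, N50 > 10 kb). Lower `c` buys AF accuracy
and sensitivity at proportional cost.

## What the synthetic generator emulates — and what it does not

`sim_spec()` / `sim_genome_pair()` generate i.i.d. uniform ACGT genomes,
substitute-only mutation at a known `theta` (so truth is exact), exponential
fragmentation tuned to a target N50, random contig dropout to a completeness
fraction, and unrelated random contigs as contamination. This is the stated
world of every test: a green test establishes correct recovery of the
substitution model under assembly-quality degradation. It does **not**
establish behavior on real genomes with repeats, skewed composition,
horizontal transfer or indels; indels in particular are an extension point,
not implemented, because the mutation model is substitution-only (indel
robustness is exercised only indirectly through fragmentation, which also
breaks diagonals).

Defaults in simulations follow the regimes the estimator targets: 1-Mb
genomes for recovery experiments, N50 ≈ 30 kb and 50% completeness for the
medium-quality-MAG regime, `theta` in 0.01–0.10 (the > 82% reliable range).

## Numerical and design choices

* **Coordinates** are 0-based, half-open; a seed position is the leftmost
  base of its window.
* **Hashing.** Canonical form is the lexicographically smaller 2-bit
  encoding (A<C<G<T) of the k-mer and its reverse complement, passed through
  an invertible splitmix64 finalizer; FracMinHash selects
  `h < floor(2^64/rate)`. Invertibility makes hash equality equivalent to
  canonical k-mer equality, so anchor counts are exact match counts. Hashes
  surface in R as 16-digit hex strings (R has no 64-bit integer type).
* **Non-ACGT bases** void every window covering them; no IUPAC expansion.
* **Masking** counts occurrences per genome (not per contig) and uses integer
  division for `2500/c` with a floor of 1.
* **Reverse-strand chaining** (the natural representation for inversions and
  reverse-complemented contigs): reverse-strand anchor groups are chained in
  mirrored reference coordinates `y' = contig_length - k - y` so one
  increasing-order DP serves both strands; spans are reported in original
  coordinates. Anchors chain only within one (reference contig, strand)
  group.
* **Tie-breaks.** The DP argmax prefers the earliest predecessor; orthologous
  selection orders by (score desc, chunk, contig, span start); reference
  selection (larger of total length × mean contig length) breaks ties toward
  the lexicographically smaller genome id. Everything downstream is therefore
  deterministic, and a pair compares bit-identically in either argument
  order.
* **Chunks without orthologous chains are excluded** from the weighted mean
  (zero weight). Including them would drive ANI toward zero exactly in the
  incompleteness regime the chain-restricted statistic exists to handle; the
  aligned fraction, not the ANI, is the signal that coverage is partial.
  Trailing partial chunks are retained and weighted by their seed counts, so
  fragmented assemblies lose no sequence.
* **Overlap for orthology** is measured on reference-coordinate intervals
  (paralogy duplicates reference loci); the flanked-seed span is measured on
  query coordinates (that is where `M_LR` counts seeds); AF uses
  orthologous chains only.
* **Bootstrap RNG** is an isolated, seedable generator (global RNG state is
  saved and restored); the seed affects only the CI, never the ANI. The CI
  reflects seeding variance only, not systematic bias.
* **Screen gates are strict** (`> 0.80`, `> 10` chunks, `> 0.95` LR gate),
  matching their definitions. The marker inverted index is always used for
  all-vs-all triangles and only from 100 queries upward in dist/search,
  where building it would otherwise dominate.
* **Sketch files** are a versioned serialized container (magic, format
  version, parameters, contig table, seed table, marker set) with a bit-exact
  round trip; comparisons across different sketching parameters are refused
  via a parameter fingerprint rather than silently producing nonsense.

## Debiasing

Chains can exclude homologous-but-mutated k-mers at their edges, which
slightly inflates ANI for larger `c`. The optional correction is a
gradient-boosted regression tree ensemble with absolute-deviation loss over
five features: the chaining ANI, the SD of per-chunk ANIs, the 90th-percentile
contig length of each genome, and the mean chain span. No boosting package is
available in this stack, so the ensemble (LAD TreeBoost: trees fit to sign
residuals, leaf values set to median residuals, shrinkage 0.1) and its CART
trees are implemented in the package.

Ground truth for training is the synthetic generator's `1 - theta`; the
alignment-based truth the original approach was trained on (MUMmer over a
million MAG pairs) is out of scope here, so shipped-model parity is not
claimed. Holdout splits are grouped by base genome so evaluation pairs never
share an underlying genome with training pairs. The correction only fires
above 90% ANI and 150 kb aligned, auto-enables only for `c >= 70`, and is
clamped to ±0.02 of the raw estimate — debiasing is a small correction by
construction, and the clamp guards against extrapolation. The "putative ANI
distribution SD" feature is read as the per-chunk ANI SD (the bootstrap SD
being the other candidate reading).

## Known limitations

* Not designed below ~82% ANI (screened out by default; chain sensitivity
  drops with sparse seeds).
* Substitution-only truth model; no base-level alignment, no indel handling.
* Single-threaded; the output-ordering contract makes a thread flag a no-op.
* The spurious-anchor floor scales as `n^2 / 4^k`, so very large or highly
  repetitive (e.g. eukaryotic) genomes need larger `k` than the default 15.
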