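---
title: "Methods: dual-strategy amplicon processing and niche analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-strategy amplicon processing and niche analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapkit)
```

## Why two processing routes

Paired-end short-read sequencing reads both ends of an amplicon. When
the amplicon is shorter than twice the read length the mates overlap
and can be merged into the full-length sequence (the *assembly*
route). When it is longer — as for the 629-bp archaeal *amoA*
fragment read at 2 × 300 bp — no merge is possible. The *gap* route
reverse-complements the reverse mate and concatenates it to the
forward mate, producing a fixed-length product with an unsequenced
central region. The junction coordinate is carried as metadata rather
than marked with placeholder characters: placeholders would corrupt
identity computation against ungapped references, while a recorded
coordinate lets translation and alignment treat the two sequenced
segments correctly.

Both routes share the same per-read quality control and the same
downstream denoising, so route comparisons isolate the effect of the
gap itself.

## Per-read quality control

Parameters live in `qc_params()`:

| parameter  | default | meaning |
|------------|---------|---------|
| `trim_q`   | 15      | 3' trimming Phred threshold |
| `max_ee`   | 2.0     | maximum expected errors per mate (after truncation) |
| `max_n`    | 0       | maximum ambiguous bases per mate |
| `trunc_len`| 229     | per-mate truncation, assembly route |
| `min_len`  | 200     | per-mate truncation, gap route |

Trimming uses the partial-sum algorithm shared by BWA and cutadapt:
subtract `trim_q` from every quality, form running sums from the 3'
end and cut at the position minimising the running sum. Ties resolve
to the shortest kept prefix. Expected errors,
$\mathrm{EE} = \sum_i 10^{-q_i/10}$, are computed on the *truncated*
read, and a mate at exactly `max_ee` is kept (rejection requires
strictly greater), matching the conventional semantics of
expected-error filters. The order is always trim → truncate → EE/N
test; a useful consequence, exercised by a property test, is that
lowering `trim_q` can never decrease the number of kept reads.

The 229/229 truncation on a 448-nt amplicon is deliberate: it leaves
an engineered overlap of exactly 2 × 229 − 448 = 10 bases for the
merge step. The gap route truncates to exactly 200 (not merely
filtering at 200) so that every concatenated product has uniform
length 400 and one junction coordinate; dereplication at 100 %
identity over ragged lengths would be meaningless.

## Overlap merging

`merge_overlap()` scores every candidate ungapped overlap of length at
least `min_overlap` (default 10) between the forward 3' end and the
reverse-complemented reverse 5' end by `matches − mismatches`,
requires fractional identity ≥ `min_identity` (default 0.9) within the
overlap, and keeps the best-scoring candidate (longer overlap on score
ties). Within the overlap, a mismatch resolves to the base with the
higher Phred score (forward wins quality ties) and that quality is
kept; at matches the maximum quality is kept. This replaces the full
maximum-likelihood scoring of dedicated mergers: at an engineered
10-base overlap the simple score is the decisive quantity, and both
knobs remain configurable. Staggered (read-through) configurations are
outside the search space because candidate overlaps are capped at the
mate length, which upstream truncation guarantees to be shorter than
the amplicon.

A property test verifies that error-free mates reconstruct any
template whose length lies in the mergeable range exactly.

## Dereplication and denoising

Dereplication groups identical strings, keeps abundance as `size`, and
sorts by abundance (descending) with lexicographic tie-breaks, so the
output order is a pure function of the input multiset.

The translation filter discards any unique with an in-frame stop codon
(TAA/TAG/TGA, standard code; the codon set is configurable for other
genes). Assembly products are translated from the database's
`frame_offset`; gap products are translated as two independent
segments, the reverse one starting `rev_frame_offset` bases after the
junction so it begins on a codon boundary. No codon ever spans the
gap, by construction. Codons containing `N` are counted but treated as
neither stop nor non-stop. Trailing partial codons are ignored.

Chimera removal implements exactly the two behaviours needed here: a
perfect two-parent breakpoint model and singleton dropping. A
candidate is chimeric when two **distinct** more abundant uniques
(each at ≥ `skew` = 2 times the candidate's abundance — the standard
assumption that chimeras arise later than their parents) can be
spliced at some breakpoint to reproduce it within `max_diffs` = 0
mismatches. A candidate within `max_diffs` of a *single* parent is a
near-replicate, not a chimera, and is never flagged. The full
error-cloud clustering of abundance-based denoisers is intentionally
not reproduced: on dereplicated, translation-filtered data the
remaining artefacts of interest are chimeras and singletons, and a
transparent exhaustive model is testable against a brute-force oracle
(the suite checks agreement on instances of up to ~15 uniques).

Pipeline order is fixed: dereplicate → translation filter → chimera
flagging → singleton removal, with per-stage abundance accounting that
must telescope.

## Cluster assignment

Queries are assigned by exhaustive best-hit global alignment
(match +1, mismatch −1, gap open −2, gap extend −1; a gap of length
$L$ costs $2 + L$) over the whole reference database, rather than a
heuristic seeded search: databases of reference clusters are small
(tens to hundreds of sequences), exactness beats speed and results are
reproducible bit for bit. Identity is matches divided by alignment
columns. Gapped queries are compared segment-wise — each sequenced
segment aligned with reference end gaps free, identities pooled over
both segments — so the unsequenced region neither counts for nor
against the query; end-gap columns are excluded from the denominator.
The identity definition is stated this explicitly because tools
differ and the choice moves borderline assignments across thresholds.

Identity ties resolve to the first reference in database order, making
assignment deterministic and order-stable. The best hit is computed
once per unique and reused across thresholds, which also guarantees
the monotonicity property: raising the threshold can only move
abundance into the `unassigned` bucket. Sequences below the cut-off
are kept in that reserved bucket; the ecology layer excludes it by
default (`drop_unassigned = TRUE`), with inclusion available by flag.

## Comparison statistics

Bray–Curtis is reported as a *dissimilarity* (0 = identical
composition), the `vegan::vegdist` convention. All comparisons operate
on relative abundances by default so that sequencing-depth differences
between methods do not dominate; raw counts are available by flag.
Rarefied richness uses Hurlbert's analytic expectation with binomial
coefficients in log space, avoiding overflow at realistic depths; a
Monte-Carlo subsampling oracle (10,000 replicates, 3-standard-error
band) backs it in the test suite.

## Canonical correspondence analysis

`cca_fit()` implements ter Braak's algorithm directly: chi-square
standardisation $Q_{ij} = (p_{ij} - r_i c_j)/\sqrt{r_i c_j}$, weighted
least-squares projection of $Q$ onto the predictor space with row-mass
weights, and SVD of the fitted matrix. Eigenvalues are squared
singular values; total inertia is $\sum Q^2$; the statistic is
pseudo-$F = (\text{constrained}/q)\,/\,(\text{residual}/(n-q-1))$ with
$q$ the rank of the constraints. Aliased constraint columns are
dropped with a warning via pivoted QR. The implementation is
cross-checked in the tests against an independent reference
implementation (vegan) to 10 decimals on random matrices and on a
frozen 6 × 4 worked example.

Permutation tests are **marginal** — one factor at a time, matching
the one-row-per-factor layout in which such screens are reported — and
permute the sample rows of the tested factor; a categorical factor's
dummy columns are permuted as a block. The default 999 permutations
(the ecology convention; the choice is configurable) gives
$p \ge 1/1000$, so a strong effect reports 0.001. p-values are
reproducible bit for bit given `(seed, n_perm)` and the input row
order; reordering samples jointly leaves the observed pseudo-F and the
test's validity untouched but draws a different finite permutation
sample, which is why the seed and the input ordering are both recorded
in the result. Type-I error calibration is verified empirically: over
1,000 null communities the rejection rate at α = 0.05 must fall inside
the binomial 99 % confidence band.

## Tree and congruence metrics

"Euclidean distance between two trees" is implemented as the
Kuhner–Felsenstein branch-score metric: over the union of leaf
bipartitions of the two unrooted trees, the square root of the summed
squared branch-length differences, with zero length for an absent
bipartition. Trees are compared unrooted so rooting conventions cannot
affect the distance; differing leaf sets are pruned to the
intersection with a warning, and fewer than four shared leaves is an
error. The congruence layer tabulates, per functional-gene lineage,
the 16S lineages of its member strains and scores purity as the modal
fraction; the overall summary is the strain-weighted mean purity.

## The simulator

The generator emulates the study design the pipelines were built for:
samples on a pH gradient (3.5–8.5), cluster abundances from a Gaussian
niche model $\log a_{sk} \propto -g\,( \mathrm{pH}_s - o_k)^2$ with
lognormal noise, reference families built from a stop-free root coding
sequence with between- and within-cluster substitution divergence
(defaults 0.08 and 0.01 per site; substitutions are resampled if they
would create an in-frame stop), 2 × 300-bp reads with a linear
positional Phred decay (38 → 28 by default) and per-base substitution
errors at rate $10^{-Q/10}$, and spliced two-template chimeras at a
configurable rate. `diagnostic_positions` restricts where
between-cluster substitutions may fall, which is how the
gap-information contrast is constructed: placing all diagnostic sites
inside the unsequenced region makes the gap route blind to cluster
identity while the assembly route still resolves it.

What the simulator does *not* model: PCR amplification bias, indel
errors (available by flag but off by default, since the platform's
dominant mode is substitutions), correlated quality across positions,
and adapter read-through. Passing tests therefore demonstrate
correctness of the algorithms under controlled conditions, not
robustness to every artefact of real libraries.

An `errors = FALSE` switch produces strictly error-free reads; the
exact-recovery checks (a fixed template set recovered with abundances
summing to the full depth) are only meaningful under that condition,
since any stochastic error at depth 10,000 produces singletons that
the pipeline rightly removes.

All randomness flows from a single integer seed; references, the
community and the reads use fixed offsets of it so each layer is
independently reproducible, and identical seeds give byte-identical
FASTQ output.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale by design:
depths of 300–10,000 reads, 3–12 samples, databases of 4–12
references, 1,000-replicate null calibrations with 99 permutations
each, and 10,000-replicate Monte-Carlo oracles. Eigenvalues below
$10^{-12}$ of the leading one are treated as numerically zero;
identity thresholds are applied with a $10^{-12}$ slack so exact
matches are never lost to floating-point rounding; the trimmer, the
dereplication order, assignment tie-breaks and the permutation stream
are all deterministic.

## Known limitations

* Exhaustive all-against-all alignment scales as (uniques × references)
  and is intended for curated cluster databases, not for de-novo OTU
  clustering against large references (a provably lossless k-mer
  prefilter would be the natural extension).
* The chimera model assumes equal-length sequences (guaranteed after
  truncation) and exactly two parents.
* Gap products are never scaffolded against a reference to "fill" the
  gap; the junction is metadata only.
* The strain table and its congruence metrics describe the curated
  *Nitrosospira* reference set shipped with the package; they are
  bookkeeping over that table, not a phylogenetic inference method.
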