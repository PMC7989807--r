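# gapkit

Dual-strategy processing of Illumina paired-end amplicon data for
functional marker genes of **any** amplicon size, with the downstream
statistics needed to compare processing routes and to screen
environmental drivers of community composition.

## The problem

Short-read platforms produce 2 × 300-bp paired reads. For an amplicon
shorter than twice the read length (e.g. the ~450-bp bacterial *amoA*
fragment of soil ammonia oxidisers), the mates overlap and can be merged
into a full-length sequence — the **assembly** route. For a longer
amplicon (e.g. the 629-bp archaeal *amoA* fragment) the mates cannot
overlap; the reverse mate is reverse-complemented and concatenated to
the forward mate, leaving an unsequenced central **gap** whose
coordinate is carried as metadata through dereplication, translation
filtering and database assignment — the **gap** route. gapkit
implements both routes end to end, plus the comparison layer that
quantifies what the gap costs, and a canonical correspondence analysis
(CCA) layer for environmental niche screening.

## What is computed

* **Per-read QC** — 3' quality trimming (partial-sum algorithm at
  Phred threshold *q* = 15), truncation (229/229 for assembly, 200/200
  for gap), and filtering on expected errors
  EE = Σᵢ 10^(−qᵢ/10) (reject when EE > 2 per mate) and ambiguous
  bases (maxN = 0).
* **Joining** — scored overlap merge (`matches − mismatches`, minimum
  overlap 10, minimum identity 0.9, higher-quality base wins at
  mismatches) or reverse-complement concatenation with a fixed gap
  junction.
* **Denoising** — dereplication at 100 % identity with `;size=`
  abundance annotations, frame-aware stop-codon filtering (gap-mode
  segments are translated independently so no codon spans the gap),
  two-parent chimera flagging (parents at ≥ 2× the candidate's
  abundance, perfect breakpoint model) and singleton removal.
* **Assignment** — exhaustive best-hit Needleman–Wunsch global
  alignment (match +1, mismatch −1, gap open −2, extend −1; reference
  end gaps free for gapped queries) against a cluster-labelled
  reference database at identity thresholds 0.90/0.95/0.97/1.00,
  producing samples × clusters abundance matrices.
* **Comparison statistics** — per-sample Bray–Curtis dissimilarity
  Σ|xᵢ−yᵢ|/Σ(xᵢ+yᵢ) and Pearson correlation of relative abundances
  against a reference method; Hurlbert's analytic rarefied richness
  E[Sₙ] = Σᵢ [1 − C(N−Nᵢ, n)/C(N, n)].
* **Trees and lineages** — Kuhner–Felsenstein branch-score distance
  between Newick trees; lineage counting and amoA↔16S congruence
  purity over a curated table of 56 *Nitrosospira* strains.
* **Niche analysis** — CCA (ter Braak's chi-square standardised,
  row-weighted projection algorithm) with marginal permutation tests
  per environmental factor (pseudo-F statistic, p floor 1/(n_perm+1)).
* **Simulation** — a fully seeded generator for reference gene
  families, pH-gradient-structured communities, and paired reads with
  positional quality decay, substitution errors and spliced chimeras,
  providing ground truth for every stage.

## Worked example

```r
library(gapkit)

cfg <- sim_preset("bacterial448", n_clusters = 3, refs_per_cluster = 1,
                  n_samples = 3, depth = 500, errors = FALSE, seed = 42)
sim <- simulate_dataset(cfg)

asm <- run_pipeline(sim$samples, mode = "assembly", refdb = sim$refdb)
asm
#> pipeline_run (assembly mode): 3 sample(s)
#>   sample01: 2 uniques, 500 reads retained
#>   sample02: 3 uniques, 500 reads retained
#>   sample03: 2 uniques, 500 reads retained

ma <- build_matrices(asm$uniques, sim$refdb, thresholds = c(0.97, 1))
ma$id0.97
#>           C1  C2  C3 unassigned
#> sample01 498   2   0          0
#> sample02   2 495   3          0
#> sample03   0   3 497          0
```

Each row is a sample, each column a reference cluster; entries are
read counts assigned at ≥ 97 % identity. The pH gradient (samples at
pH 3.5, 6.0 and 8.5) drives the niche model, so each soil is dominated
by the cluster whose optimum is nearest.

The gap route on the same reads assigns identically here because the
cluster-diagnostic substitutions fall outside the unsequenced gap:

```r
gap <- run_pipeline(sim$samples, mode = "gap", refdb = sim$refdb)
mg <- build_matrices(gap$uniques, sim$refdb, thresholds = c(0.97, 1))
compare_methods(ma$id0.97, mg$id0.97,
                reference_method = "assembly", comparand_method = "gap")
#>   sample_id pearson_r bray_curtis
#> 1  sample01         1           0
#> 2  sample02         1           0
#> 3  sample03         1           0
```

A Bray–Curtis of 0 means the two routes recover the same community; a
positive value flags soils whose composition depends on sequence
information hidden in the gap.

The curated strain table ships with the package:

```r
tab <- load_strain_table(system.file("extdata", "nitrosospira_strains.tsv",
                                     package = "gapkit"))
lineage_counts(tab)
#>       n_strains n_amoa_lineages n_rrna_lineages
#>              56              17              19
congruence_table(tab)$weighted_purity
#> [1] 0.8392857
```

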