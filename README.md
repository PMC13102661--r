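# scMirEdit

miRNA mutation/editing (M/E) analysis for **single-cell small RNA
sequencing** data.

Bulk sRNA-seq has catalogued many miRNA editing events — A-to-I
deamination by ADARs (read as A>G), C-to-U deamination (C>T), and the 3′
non-templated additions (adenylation, uridylation) written by terminal
nucleotidyltransferases (TENTs) — but averages over cell populations.
scMirEdit detects and characterizes these events **per cell** and then asks
the cohort-level questions: do editing patterns distinguish cell types, which
sites are cell-type-specific, how variable is editing within a type, which
sites differ between types, and which TENT enzymes plausibly mediate which 3′
additions. It is aimed at groups analyzing single-cell sRNA-seq cohorts
(or co-sequenced miRNA + mRNA profiles) who need a tested, self-contained
re-implementation of this analysis stack, including a ground-truthed
simulator for validation.

## The method

Per cell, reads are kept when every base among the first 25 has Phred
Q ≥ 30, collapsed to unique sequences (≥ 19 nt), and aligned exactly to
pre-miRNA hairpins: at each offset the read decomposes into a templated
*body* with at most one substitution plus a 3′ *tail* of ≤ 3 non-templated
bases (terminal mismatch runs are tail, never body). Multi-mapping reads
receive cross-mapping weights by iterating

&nbsp;&nbsp;&nbsp;&nbsp;E(p) = Σ_r c_r·w_rp,&nbsp;&nbsp;
w_rp ← E(p) / Σ_{p′∈loci(r)} E(p′)

to a fixed point. From the weighted pileup, each candidate site gets an
editing level (weighted alt fraction), and a p-value under the sequencing-
error null X ~ Binomial(n, e) with e = 10^(−30/10) = 10⁻³, testing
P(X ≥ k) on raw read counts. Within each cell, p-values are BH-adjusted and
a site is **significant** iff level ≥ 5%, raw support ≥ 10 reads, and
adjusted p < 0.05. Significant sites are classified into nine types —
`A-to-I`, `C-to-U`, `3'-A`, `3'-U`, `3'-Other`, `5'-editing`, `Other`,
`SNP` (catalog match at 100% level in ≥ 1 cell), `Pseudo` (mean
cross-mapping weight < 0.5) — and named
`<precursor>_<position>_<REF>_<alt>` (e.g. `hsa-mir-376a-1_49_A_g`).

Cohort analyses: sites significant in ≥ ⌈5%·n⌉ cells form a sites × cells
editing-level matrix (`EditingExperiment`, a `SummarizedExperiment`), which
feeds centered PCA, Euclidean/complete-linkage biclustering, cell-type
specificity (Pearson r of a site's levels with each type's 0/1 indicator;
specific iff r > 0.3 and p < 0.05), per-type variance tiers (population SD:
low ≤ 0.2 < medium ≤ 0.3 < high), Mann–Whitney differential editing against
a reference type (BH within comparison), and Pearson correlation of 3′-site
levels with TENT-family expression summarized as a Table-1-style Y/N
mediation grid.

## Worked example

The built-in simulator generates a full study — 5 cell types × 20 cells,
20 hairpins, ~30 planted sites spanning all nine classes — with per-cell
FASTQs and ground truth:

```r
library(scMirEdit)
cfg <- simConfig(seed = 1)
ref <- simulateReference(cfg)
sim <- simulateCells(cfg, ref)
res <- runCohort(sim$reads, ref$precursors, sim$cells, snp = ref$snp)

res$profiles[["GBM_01"]]
#> SampleProfile GBM_01 (GBM)
#>   reads: 3597 raw, 3519 qualified, 294 unique, 14 unmapped
#>   sites: 96 candidates, 16 significant
```

A cell's significant calls show the level, raw support/coverage and the
BH-adjusted binomial p:

```r
head(siteCalls(res$profiles[["GBM_01"]], significantOnly = TRUE)
     [, c("site", "type", "level", "rawK", "rawN", "pAdj")], 5)
#>                 site   type     level rawK rawN          pAdj
#> 2  sim-mir-01_14_A_g A-to-I 0.2307692   21   91  1.322445e-42
#> 8  sim-mir-01_71_C_a   3'-A 0.9333333   28   30  4.167940e-81
#> 9  sim-mir-02_15_C_u C-to-U 0.5937500   76  128 1.156183e-190
#> 11 sim-mir-02_26_G_u   3'-U 0.7966102   47   59 1.770246e-128
#> 18 sim-mir-03_68_A_u   3'-U 0.7884615   41   52 8.195419e-112
```

The combined matrix recovers all planted classes, and the GBM-elevated
seed-region A-to-I site comes out of the differential analysis against the
naive-ESC-like reference:

```r
table(siteTypes(res$editing))
#>   3'-A 3'-Other   3'-U 5'-editing A-to-I C-to-U Other Pseudo SNP
#>      9        1      8          1      5      4     1      1   1

subset(differentialEditing(res$editing, referenceType = "nESC"),
       site == "sim-mir-07_7_A_g" & cellType == "GBM")
#>               site cellType referenceType   U            p         pAdj direction significant
#> 14 sim-mir-07_7_A_g     GBM          nESC 399 7.898034e-08 1.883377e-07    higher        TRUE
```

`sim-mir-07_7_A_g` sits at nucleotide 7 of the 5p mature — inside the seed —
so an edit there would retarget the miRNA; `higher` means GBM-like cells
edit it more than the reference. The first three PCA components explain
32/24/16% of variance and k-means on them recovers the five cell types
exactly (adjusted Rand index 1.0 at this seed).

A thin CLI covers the same workflow from a shell
(`inst/scripts/scmiredit.R` with `simulate`, `process` and `analyze`
subcommands).

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch:
it simulates the default study at the given seed, executes the full
pipeline, runs every cohort analysis and the enzyme mediation grid, and
writes the JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Limitations

The aligner targets hairpin references (no genome-wide mapping, no gapped
alignment); inputs are assumed adapter-trimmed; SNP annotation uses a
user-supplied local catalog only. See the methods vignette
(`vignettes/scMirEdit-methods.Rmd`) for the model, parameter rationale and
the simulator's stated world.
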