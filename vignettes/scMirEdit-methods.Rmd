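---
title: "scMirEdit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{scMirEdit: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

scMirEdit detects miRNA mutation/editing (M/E) sites in single-cell small
RNA sequencing profiles and analyzes their cohort-level patterns. This
vignette documents the statistical model, every tunable that matters, the
synthetic-data generator's stated world, and the design decisions taken
where the problem was genuinely open.

```{r, message = FALSE}
library(scMirEdit)
```

# The per-cell model

## Read qualification and collapsing

A read is *qualified* when every base among its first `window = 25`
nucleotides has Phred quality at least `qMin = 30`. Reads shorter than the
window are constrained over their whole length — the conservative reading
when the rule and the read disagree about what "first 25" means. Qualified
reads are never trimmed; reads shorter than `minLen = 19` nt are dropped at
collapsing. Inputs are assumed adapter-trimmed: single-cell sRNA libraries
are usually distributed that way, and no adapter logic is attempted.

## Alignment: body + tail decomposition

Unique reads are aligned exactly against the pre-miRNA hairpins. At each
candidate offset the read must decompose into a templated **body** with at
most `maxMismatch = 1` substitution followed by a 3′ **tail** of at most
`maxTail = 3` bases. Two rules resolve ambiguity:

* **Longest body wins** at an offset — a templated explanation beats a
  tail explanation, so a matching base is never pushed into the tail.
* **Terminal mismatch runs are tail, never body.** A read ending in one or
  two mismatching bases is an isomiR with a non-templated addition, not a
  body that spent its mismatch budget at the end; the mismatch budget is
  reserved for internal (editing-candidate) substitutions. Consequently a
  non-empty tail either overhangs the hairpin's 3′ end or starts with a
  mismatch.

`maxTail = 3` covers mono-, di- and tri-nucleotide 3′ additions, which is
where essentially all non-templated tailing mass lies. The aligner
deliberately replaces a genome-level BLASTN/Bowtie chain: at hairpin scale
the precursors are the only relevant targets and the body/tail
decomposition is exactly what the caller consumes downstream. The cost is
that reads from unannotated loci that happen to resemble a hairpin cannot
be recognized as such — the cross-mapping weights and the `Pseudo` class
are the guard (add decoy sequences to the reference if this is a concern).

## Cross-mapping weights

Reads mapping to several hairpins are fractionally assigned by iterative
expression-proportional reallocation: initialize uniformly, then repeat

$$E(p) = \sum_r c_r\, w_{rp}, \qquad
  w_{rp} \leftarrow \frac{E(p)}{\sum_{p' \in \mathrm{loci}(r)} E(p')}$$

until the largest weight change falls below `tol = 1e-6` (cap
`maxIter = 100`). Single-locus reads keep weight 1; a read whose loci all
have zero expression reverts to uniform weights. This is a simplified,
clearly-labeled stand-in for published cross-mapping correction methods —
it reproduces their fixed points on locus-support examples (a read shared
by loci with unique support 9 : 1 converges to weights 0.9/0.1) but does
not claim equivalence. The iteration warm-starts from existing weights, so
re-running on a converged table is a no-op (the fixed-point property the
tests assert).

## Site calling

From the weighted pileup, every (position, alternative nucleotide) with at
least one supporting read is a candidate. Its **editing level** is the
cross-mapping-weighted alt fraction. Significance combines three rules:

* level ≥ `minLevel = 0.05`;
* raw integer support ≥ `minSupport = 10` reads — raw, not weighted, which
  is the conservative reading of "at least 10 reads";
* BH-adjusted binomial p < `alpha = 0.05`, where
  $p = P(X \ge k),\; X \sim \mathrm{Binomial}(n, e)$ on raw counts with
  $e = 10^{-Q/10} = 10^{-3}$ for the Q30 threshold — the only error model
  derivable from the stated quality cutoff. The survival sum is computed in
  log space (`lchoose` + `log1p`) and matches an exact-coefficient
  summation to ~1e-15 relative error for $n \le 50$; no big-rational
  arithmetic is needed at these scales.

BH adjustment is applied per cell across all candidates; cohort-level
prevalence filtering happens later and is a separate concern.

## Nine-type classification

Decision order per candidate: **SNP** (genomic projection matches a
user-supplied catalog record, both alleles strand-aware, and the level
reaches 100% in at least one cohort cell) → **Pseudo** (mean cross-mapping
weight of supporting reads < 0.5, i.e. the reads mostly belong to another
locus) → **3′-A / 3′-U / 3′-Other** (position beyond the 3′ end of the
nearest upstream mature arm, keyed by the added nucleotide; positions in
the loop between arms attach to the upstream arm) → **5′-editing**
(position before every mature start) → within the mature body, A>G is
**A-to-I** (inosine reads as G), C>T is **C-to-U**, anything else
**Other**. Hairpins without mature annotation are treated as all-body,
with a warning. Positions beyond the hairpin's last base are tallied as
overhang but never reported as sites: a site needs a templated reference
nucleotide to be named. The 0.5 Pseudo threshold is a package decision —
it marks the point where the majority of supporting reads are assigned
elsewhere.

Site names follow `<precursor>_<position>_<REF>_<alt>` with the reference
upper-case and the alternative lower-case, both in the RNA alphabet
(`hsa-mir-376a-1_49_A_g`); the edited-miRNA display form is
`<precursor>_<position><alt>`. The codec always keeps the full,
copy-suffixed precursor name: dropping `-1`/`-2` (as display conventions
sometimes do) would conflate paralogous hairpins.

# Cohort analyses

Profiles are combined over the sites significant in at least
`ceiling(0.05 * n)` cells (23 of 448, 1 of 19). A cell's entry is its
level; 0 when the position was covered but unedited; `NA` when uncovered.
For PCA, clustering and correlation, `NA` is imputed as 0 — undetected
editing at low coverage is closest to "no observed editing" — while the
TSV output keeps `NA` so users can re-impute. PCA is column-mean-centered
and **unscaled** (levels already share the [0,1] scale; scaling would
inflate near-constant sites), with the sign convention that each loading
vector's largest-magnitude entry is positive. Clustering is Euclidean
distance with complete linkage for rows and columns independently — the
defaults of the heatmap tooling this analysis style standardizes on, fixed
here for determinism.

Cell-type specificity correlates each site with each type's 0/1 indicator
(Pearson, matching the correlation routine used throughout this analysis
family; Spearman behind `method = "spearman"`), with p from
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df; specific iff r > 0.3 and
p < 0.05. Variance tiers use the population (n-denominator) standard
deviation — immaterial at cohort n, but fixed — with boundaries resolved
downward: std ≤ 0.2 low, 0.2 < std ≤ 0.3 medium, std > 0.3 high, plus a
separate `zero` group; "low variance" conventionally reports zero ∪ low.
Differential editing runs two-sided Mann–Whitney tests per site against a
reference type, exact (via the exact U null distribution) when
n + m ≤ 16 without ties, otherwise normal approximation with tie and
continuity corrections; BH is applied within each type-vs-reference
comparison, and significance uses the adjusted p by default (raw p behind
`useAdjusted = FALSE`, since the convention is genuinely ambiguous).

## Enzyme–editing correlation

For cells with paired expression profiles, each TENT-family enzyme
(`TENT2, TENT4A/B, TENT5A–D, TUT1, TUT4, TUT7`) is Pearson-correlated with
each 3′ site's levels over the shared cells; a pair is positively
significant when r > 0 and the correlation-t p < 0.05. **No correction
across pairs** is applied by default — that matches the per-pair reporting
convention of this analysis family — so with ~dozens of null pairs a few
chance flags at the 2.5% one-sided rate are *expected*; `bhCorrect = TRUE`
exists for stricter use. The workflow mirrors the study design: the
expression-bearing cell population is combined **separately** (sites
significant in ≥ 1 of its cells), which drops out-of-type sites whose
levels are zero-plus-noise and would otherwise correlate spuriously. The
mediation grid marks an enzyme × nucleotide cell `Y` when at least one
positively significant pair supports it.

# The synthetic world

The generator exists so that every stage is testable without downloads. Its
defaults are one fixed, realistic study (chosen once):

* 5 cell types × 20 cells; 20 hairpins of 70–90 nt with 22-nt 5p/3p arms;
  one hairpin is a **decoy** whose 3p arm (±1 base) duplicates its
  neighbour's and which receives no reads of its own, so the mirrored site
  on it converges to near-zero cross-mapping weight and is classified
  `Pseudo`.
* Coverage: negative binomial, mean 200 reads/hairpin/cell, size 6 —
  reproducing the order-of-magnitude spread in valid reads across real
  single cells. Reads copy a mature arm with templated isoform offsets
  (−1 nt 5′ start with probability 0.35; +1 nt 3′ end with probability
  0.5). At a planted 3′ site the +1 isoform carries the non-templated base
  with probability equal to the cell's true level, so the measured level
  among covering reads is an unbiased binomial estimate of the planted
  one.
* ~30 planted sites spanning all nine classes: 18 type-exclusive 3′ sites
  (mostly 3′-A/3′-U, the dominant specific classes), six shared central
  sites in three variance tiers (sd 0.05/0.25/0.35) whose per-type means
  differ so shared sites carry cell-type structure, one seed-region A-to-I
  site elevated in the GBM-like type, one C-to-U, one 5′-editing, one
  central Other, one catalog-backed SNP site at level 1, and the decoy
  pair.
* Per-(site, cell) true levels are drawn from a **Beta distribution**
  parameterized by the type's mean and sd. A normal truncated to [0,1]
  cannot exceed sd ≈ 0.289 (its uniform limit), so the high-variance tier
  (sd 0.35) is unreachable under truncation; Beta matches the requested
  moments exactly and reproduces the bimodal shape real high-variance
  sites show. Edits are then planted per read independently
  (Bernoulli at the cell's level), matching the binomial model the caller
  assumes.
* Sequencing error 10⁻³ per base, uniform over the three alternatives;
  qualities are Q40 except a 2% contamination fraction carrying one Q20
  base within the first 25, so the Q30 filter is exercised.
* Enzyme couplings: TENT2 → the Leuk-type-exclusive 3′-A site and TUT7 →
  the 3′-U site, via $level = a + b\,\hat e + \varepsilon$ with
  $\hat e$ the z-scored log expression, a = 0.45, b = 0.18, and noise sd
  0.11. With the site's level sd of 0.18 this implies a true correlation
  $\rho = 0.18/\sqrt{0.18^2 + 0.11^2} \approx 0.85$ — deliberately
  stronger than the 0.4–0.6 range typical of n ≈ 19 cohorts, so that the
  default-scenario grid marks both planted couplings reliably; power at
  ρ = 0.5 and n = 19 is a separate, weaker property (detection in a
  majority of seeds) and is tested at exactly that setting. Uncoupled
  enzymes are independent log-normals. In the generator the coupling is
  realized by inversion (expression derived from the drawn levels), which
  yields the same joint law as drawing expression first.

What the generator does **not** emulate: realistic per-cycle quality
profiles, ligation bias, adapter remnants, 5′ isomiR analytics beyond ±1,
genome-scale repeat structure, or the composition of any particular real
cohort. A green end-to-end test therefore establishes that the pipeline
recovers what its own model family generates — parameter recovery and
type-I control — not that it handles every artifact of a specific
protocol.

# Numerical choices and degenerate inputs

* `minSamples()` computes `ceiling(fraction * n)` with a half-ulp guard so
  binary representation noise (0.05 × 100 = 5.000…0004) cannot bump the
  threshold.
* Zero-variance vectors: undefined correlations are returned as `NA` and
  never flagged specific/significant.
* Constant matrices: PCA warns and reports zero variance explained;
  single-row/column clustering returns a trivial dendrogram.
* Mann–Whitney switches to the exact branch only without ties and when
  n + m ≤ 16; identical samples give p = 1 (continuity-corrected z = 0).
* Editing level at zero coverage is undefined and the position is skipped;
  TPTM requires positive total reads.
* The Pseudo/SNP checks precede positional classification, so a
  catalog-matched 100%-level site is `SNP` even in the seed region.
* All RNG in the simulator derives from a single integer seed; outputs are
  byte-reproducible.

# Known limitations

Only substitutions and single-position tail additions are modeled — no
multi-nucleotide events, no gapped alignment, no quality recalibration or
strand-bias filters. SNP classification needs a local catalog (no database
downloads). The cross-mapping scheme is expression-proportional only. The
aligner is reference-complete but genome-blind: reads from loci outside
the supplied hairpin set (plus decoys) are simply unmapped.
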