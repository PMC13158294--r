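---
title: "Correlation-polarity networks for factorial qPCR studies: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation-polarity networks for factorial qPCR studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polarnet)
```

polarnet analyses two-genotype, two-treatment (control vs stress) factorial
studies that combine quantitative PCR expression profiling with phenotypic
trait measurements. Its distinctive output is a *differential correlation
network*: genotype-specific Pearson correlation networks over the target
genes, compared edge by edge, with genes classified by how their
co-expression polarity rewires between a tolerant and a susceptible
genotype. This vignette explains each model, its assumptions, the defaults,
and the choices made where the methodology was genuinely open.

## Relative quantification: 2^(−ΔΔCt)

Expression is quantified by the Livak method. Technical replicates are
averaged **on the Ct scale** (arithmetic mean of Ct = geometric mean of
abundance) before any normalisation; ΔCt = Ct(target) − Ct(reference) per
biological replicate; ΔΔCt subtracts the mean ΔCt of the *calibrator* group,
which defaults to the **same genotype's control treatment** — so "fold
change" always means "relative to this genotype's own control", the
convention under which per-genotype bar plots are drawn. Fold change is
2^(−ΔΔCt).

Two conventions deserve emphasis because published methods sections are
often silent on them:

* group summaries are the arithmetic mean ± SD (n − 1) of the
  **per-replicate** fold changes over biological replicates only, not over
  pooled biological × technical replicates;
* by construction, the geometric mean of calibrator-group fold changes is
  exactly 1 (the package tests this to 1e−9); the arithmetic mean is
  therefore ≥ 1 even for a null gene — a reason to prefer the per-replicate
  table over group summaries for downstream correlation work.

Missing-data policy: a missing technical well is dropped with a warning; a
biological replicate missing the reference gene is excluded with a warning;
a gene with *no* usable technical replicate in some cell is an error.
Efficiency-corrected (Pfaffl) quantification and multi-reference
normalisation are out of scope.

## Trait statistics

`summarize_traits()` reports cell means ± SD. `two_way_anova()` fits the
classical fixed-effects genotype × treatment decomposition. **Only balanced
designs are accepted**: with equal cell sizes all sum-of-squares types
coincide and least-squares means equal cell means, so nothing ambiguous
needs to be chosen; unbalanced inputs are rejected with guidance rather than
silently re-weighted. With zero residual variance the F ratio is undefined
and reported as `NA`.

`tukey_cld()` runs all-pairs Tukey HSD on the cell means using the pooled
residual mean square, then condenses the result into a compact letter
display by the insert-and-absorb algorithm (split every letter column that
contains a significantly different pair, absorb columns contained in
others). Letters are assigned in order of descending cell mean, which makes
the display deterministic. Two scopes exist because figure legends in this
field typically annotate "significance between treatments per genotype":

* `"within_genotype"` (default) — letters each genotype's treatments as its
  own family, matching per-genotype bar annotations;
* `"joint"` — all four cells as one family (this is the scope cross-checked
  against `multcomp::cld` in the test suite).

`percent_change()` is the headline arithmetic
100·(control − stress)/control, with a rounded-integer convenience form
using half-away-from-zero rounding (so 49.4 → 49, 56.86 → 57). It is
scale-invariant and rejects non-positive control means.

## PCA integration

`assemble_matrix()` builds, per genotype, a matrix with one row per
biological replicate per treatment (n = 6 by default) and one column per
trait plus one per gene (per-replicate fold changes). `run_pca()` performs
SVD-based PCA with **unit-variance scaling on by default**, because the
columns mix units (g/m², enzyme activities, dimensionless folds);
covariance-mode PCA of such a matrix would be dominated by whichever trait
has the largest numbers. Each loading vector is oriented so its
largest-magnitude entry is positive — a deterministic sign convention that
makes results stable across BLAS implementations and column orderings.

The variable list is configurable because the "right" trait set for a
biplot is study-specific; the default uses every trait present. Variance
fractions always total 100% and scores reconstruct the scaled data — both
are invariants in the test suite.

## The differential network

Within one genotype, the network is the matrix of pairwise Pearson
correlations among the genes' expression values. Three choices define it:

* **Sample basis** (default `"replicates"`): all biological replicates of
  the genotype, pooled across both treatments (n = 6). The treatment
  contrast then legitimately drives covariance — this is the only basis on
  which near-unity gene–trait correlations (as reported for strongly
  stress-coupled traits) are attainable, and it is recorded in the output.
  `"treatment_means"` is available for the coarser two-point basis.
* **Scale** (default `"fold_change"`): per-replicate 2^(−ΔΔCt) values; a
  `"neg_ddct"` switch gives the log2 scale. Fold change is the default
  because networks in this field are described over "expression values",
  i.e. the quantity plotted in the figures.
* **Tiers on |r|**: strong ⇔ |r| ≥ 0.75, medium ⇔ 0.25 ≤ |r| < 0.75, weak
  ⇔ |r| < 0.25 (half-open boundaries; 0.75 is strong, 0.749 is medium).
  Tiers apply to the magnitude because direction is encoded separately as
  the edge sign — thresholding signed r would make every negative edge
  "weak", which contradicts how the networks are drawn.

`compare_networks()` aligns two genotype networks edge-wise. A **polarity
reversal** is any sign change, regardless of tier; a separate `robust` flag
marks reversals whose both tiers are at least medium, and sign-preserving
tier weakenings are recorded as downgrades (e.g. `strong->medium`). An
exact r = 0 is assigned "positive" by convention, flagged, and never counted
as a reversal partner. Reversal counts are computed over the gene–gene
block only (a gene among 8 has at most 7 incident reversals); the
gene–trait block feeds the switcher criterion instead. No multiple-testing
correction is applied to correlations: they are descriptive network
statistics here, not hypothesis tests.

### Role classification

`classify_roles()` applies a deterministic cascade:

1. **hub** — reversal count ≥ θ_rev (default 3), tolerant-network
   connectivity (incident non-weak edges) ≥ θ_conn (default: the median),
   and significant up-regulation in the tolerant genotype (one-sided
   t-test of stress −ΔΔCt against 0 at α = 0.05). The up-regulation
   condition is part of the rule because reversal counts alone cannot
   separate a hub from a well-connected down-regulated gene with the same
   count; central stress-response genes are expected to be induced in the
   tolerant background.
2. **phenotypic switcher** (among non-hubs) — fraction of gene–trait
   correlation signs flipping between genotypes ≥ θ_switch (default 1.0,
   i.e. *every* measured trait flips).
3. **contextual responder** — the remainder.

Raising θ_rev can only shrink the hub set (a tested monotonicity
invariant). All thresholds in force are attached to the output.

## The synthetic-study generator

Because replicate-level laboratory data of this kind is rarely published,
the package ships a generator whose planted truth exercises every
downstream stage.

**Mechanism.** Each genotype has a loading matrix Λ (genes × k factors,
k ≤ 2·n_bio − 1). The replicate "scores" are a *fixed orthogonal design*:
column 1 is the treatment contrast (−½ control, +½ stress), the remaining
columns are symmetric and antisymmetric within-group Helmert contrasts, all
scaled to equal sum of squares. Log2 expression of gene g in replicate i is
baseline + (scores·Λᵀ)[i, g] + biological noise; Ct values are generated
reference-anchored (reference gene fixed at Ct 20; target Ct = gene
baseline − log2 expression + technical noise), so the 2^(−ΔΔCt) algebra is
exact: with zero noise the planted fold change (= the loading on column 1)
is recovered to machine precision, and the noiseless pooled-replicate
correlation matrix is exactly the cosine matrix of Λ's rows.

Fixing the scores as design constants rather than random draws is
deliberate: at n = 6, resampled latent scores would make the sample
correlation of even a strongly planted edge flip sign in a non-negligible
fraction of studies, and no generative calibration could then guarantee
whole-network recovery. With fixed scores the only across-seed randomness
is measurement noise (biological SD 0.1 cycles, technical SD 0.05 by
default), and recovery of the planted topology is a high-probability event
that the test suite measures directly.

**Why the susceptible genotype needs several factors.** A single factor
can only produce "balanced" sign patterns (two camps, positive within,
negative between), in which every gene's reversal count against another
rank-1 genotype takes at most two values. The planted topology — one gene
reversing 6 of 7 edges, others 5, 3, 3, 2, 2, 1, 0 — is *frustrated*: it
contains triangles whose sign product is negative, which no rank-1
structure realises, and which force some planted correlations to be
moderate rather than strong (a positive-semidefiniteness bound caps the
attainable uniform margin for this pattern near 0.25). The built-in truth
therefore plants the tolerant genotype as a fully polarised single-factor
network (|r| = 1, all edges strong) and the susceptible genotype as a
five-factor structure with moderate correlations — which is also exactly
the qualitative contrast the analysis is designed to detect: a coherent
network fragmenting into medium-strength, partially reversed co-expression.
The susceptible loadings were chosen by numerical optimisation so that the
noiseless fold-change-scale correlations carry the planted signs with
comfortable margins, TaPEX11.4's four non-reversed edges sit mid-medium,
and the switcher genes' trait-correlation margins are ≈ 0.6.

**Traits** respond to the treatment factor only: value = genotype-specific
control mean + stress effect (under stress) + trait noise. Gene–trait
correlation signs then follow the gene's treatment-axis response, which is
what makes "reverses with all traits" a plantable, recoverable property of
exactly the two genes whose stress response flips direction between
genotypes. The planted yield truth reproduces the headline 49%/57%
reductions. One deliberate departure from realism: photosynthetic pigments
are given small (≈ 4 SD) negative effects even though such assays are often
statistically flat, because a trait with no resolvable response has no
estimable correlation sign and would make the all-traits switcher criterion
meaningless.

**What the generator does not emulate** — and what passing tests therefore
do not certify about real data: plate and batch effects, amplification
efficiencies ≠ 2, Ct censoring at high cycles, heteroscedastic or skewed
trait noise, replicate-level biological correlation structure beyond the
planted factors, and any weather/field variation behind the stress
treatment. Recovery rates quoted by the tests are properties of this
generative model at the default design (2 × 2 × 3 × 3, 8 genes + reference,
12 traits), not of field data.

## Numerical choices and degenerate inputs

* Substream seeds are derived arithmetically from one master seed
  (Mersenne-Twister throughout); identical seeds give byte-identical
  tables.
* Tier boundaries are half-open as stated; r = 0 is "positive"-flagged;
  |r| is accepted up to 1 + 1e−12 to absorb floating error.
* Insert-and-absorb letters are assigned alphabetically by descending mean;
  zero error degrees of freedom is an error, zero residual variance reports
  `NA` F statistics.
* Headline percent figures round half away from zero; full precision is
  kept in tables.
* Single-replicate groups report SD 0 with a flag; zero-variance PCA
  columns are removed with a warning; a single-gene network has no edges
  and its gene falls through to contextual responder.

## Problem sizes used by the packaged checks

The test suite and the acceptance script run entirely on generated data at
the default design: single studies for fixture-level assertions, 20-seed
loops for sign-recovery properties, and 100-seed recovery studies for the
topology and role-partition rates (each study is 324 Ct wells and 144 trait
values). These sizes were chosen so the whole suite completes in well under
a minute while the binomial uncertainty on the reported recovery rates
(≈ ±2 percentage points) stays small relative to the margins being
demonstrated.

## Known limitations

* Published summary statistics that depend on unpublished replicate-level
  data (specific correlation coefficients, PCA variance percentages,
  per-assay group values) cannot be reproduced by any pipeline without
  those raw tables; the package's recovery claims are therefore stated
  against planted synthetic truth, not against published figures.
* The hub rule's up-regulation condition and the choice of tolerant-network
  connectivity are one reasonable formalisation of a qualitative
  description; both thresholds are exposed and logged.
* Correlation networks at n = 6 are descriptive: confidence intervals on
  individual edges are wide, and the package deliberately reports tiers
  and signs rather than significance stars. Permutation significance for
  reversal counts is a documented extension point, not implemented.
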