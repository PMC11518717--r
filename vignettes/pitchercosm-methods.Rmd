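---
title: "Methods: models, conventions, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pitchercosm)
```

This vignette is the package's own account of the statistics it implements,
the conventions it fixes where the underlying methods admit choices, and
what its synthetic-community validation does and does not establish.

## The analysis model

The package analyzes a genus-by-sample count matrix from full-length 16S
amplicon sequencing of pitcher-fluid communities, sampled under a genotype
design (two parental species and two hybrid generations; the default
replicate design is 4/3/3/2). All stages operate on the `count_matrix`
container, which carries the counts, a sample-to-group map, and a
normalization flag (`raw`, `CPM`, `TMM`).

**Why no rarefaction.** Full-length classification yields deep, reliable
genus-level counts; depth differences are handled by CPM scaling (within
sample) and TMM factors (between samples) rather than by discarding reads.
Alpha diversity is the one place raw counts are mandatory: Chao1 is defined
on singleton and doubleton *counts*, which normalization destroys. This is
asserted at the interface (`alpha_diversity()` refuses normalized input).

**Permutation tests.** PERMANOVA partitions the total sum of squared
dissimilarities, SS_T = (1/N)Σ_{i<j} d²ᵢⱼ, into within-group
(SS_W = Σ_g (1/n_g)Σ_{i<j∈g} d²ᵢⱼ) and among-group parts, and refers
pseudo-F = (SS_A/(a−1))/(SS_W/(N−a)) to its label-permutation distribution.
PERMDISP embeds the distance matrix by principal coordinates, keeps
negative-eigenvalue axes as an imaginary-part correction (squared centroid
distances are the real-axis contribution minus the imaginary-axis
contribution, floored at zero), and permutes least-squares residuals under
the intercept-only null. Both tests use the "+1" convention,
p = (1 + #{F\* ≥ F}) / (1 + B), so p can never be 0 and its floor is
1/(B+1); both take an explicit integer seed. The default B = 999.

**Membership rules.** All occupancy thresholds are strict in the same
direction the definitions are phrased: genotype-enriched needs ≥ 1 read in
*every* replicate of the genotype; the core microbiome needs CPM *strictly
above* the detection limit (default 500) in a fraction of samples *strictly
above* the prevalence cutoff (default 0.4); the functional core needs
*more than* 50 metatranscripts in *more than* 40% of samples. Prevalence is
computed over all samples, not per genotype — a core taxon is core to the
whole microcosm. Overlap percentages round half-up to one decimal, because
round-half-even produces values that disagree with conventionally reported
percentages at exact .05 boundaries.

**Discriminative taxa.** The screen is a documented, seeded variant of the
LEfSe idea: a Kruskal–Wallis filter (α = 0.05) followed by a
linear-discriminant effect size, computed over 30 stratified bootstrap
resamples (at least half of each class, never fewer than 2). With a single
taxon the unit-norm discriminant projection of the class-mean difference
equals the raw mean difference, so the per-resample score — the average of
the projected and raw mean differences on a per-million scale — stays in
abundance units; the reported effect is log₁₀(1 + mean score) against a
threshold of 2. There is no subclass (within-class Wilcoxon) stage because
the design has no subclass covariate. Comparisons are one-vs-one, and
groups with fewer than 3 replicates are excluded from pairing. The
formula choices are fixed and tested for monotonicity in the planted fold
change rather than claimed identical to any external binary.

**Networks.** Edges connect taxa with |r| ≥ 0.7 and p ≤ 0.05, where r is
Spearman correlation on CPM values (rank-based, robust to the skew of
compositional data; Pearson is available) and p comes from the t transform
t = r√((n−2)/(1−r²)). The absolute-value reading of the correlation
criterion is deliberate: compositional communities produce strong negative
associations, and those edges carry structure (see below). Community
detection runs on the unsigned, unweighted graph with greedy
Clauset–Newman–Moore agglomeration. Node scores: eigenvector-centrality hub
scores; within-module degree z (population-standardized within each
community, z = 0 where the community's κ variance is 0); participation
P = 1 − Σₛ(κ_is/kᵢ)², with P = 0 for isolated nodes. Roles follow the
standard joint thresholds z = 2.5 and P = 0.62 (both exposed as arguments,
since published role counts are threshold-dependent): module hub
(z ≥ 2.5, P ≤ 0.62), network hub (z ≥ 2.5, P > 0.62), connector
(z < 2.5, P > 0.62), else peripheral; boundaries are classified by the ≥/≤
conventions just stated.

**Metatranscriptome.** Best-hit selection keeps, per transcript, the
highest-bitscore hit with e ≤ 0.05 (ties: lowest e-value, then
lexicographic protein id). Genus abundances sum transcript counts by
best-hit genus; metaprotein abundances sum by protein id across genera —
the two matrices partition the same annotated reads, which the tests assert
as a conservation law. The enrichment filter standardizes log1p counts
within each sample across features and keeps features with a one-sided
upper-tail p ≤ cutoff (0.05 for genera, 0.01 for metaproteins) in at least
one sample, then TMM-normalizes the survivors. The one-sided tail is
intentional: the filter's purpose is to find abundant features, not
depleted ones. The within-sample axis is one of two defensible readings of
a per-sample z-score; it is the one that is invariant to per-sample depth,
and it is recorded in the output metadata. Trait-ontology rollups increment
a hit's node and all ancestors, so the root count equals the number of
mapped transcripts exactly; unresolvable paths are counted in an unmapped
bucket rather than dropped silently.

## The synthetic community generator

`simulate_counts()` draws, for taxon t in sample s,

> latent_ts = baseline_t + √ρ·σ_t·Z_{b(t),s} + √(1−ρ)·σ_t·E_ts (+ effect
> for enriched taxa in their genotype),

then counts ~ NegBin(mean = depth_s · L · softmax(latent)_s, size = θ),
with lognormal depth factors. Defaults, chosen once to mirror a realistic
study at desk scale: 60 taxa, 4/3/3/2 replicates, 3 blocks, ρ = 0.9,
σ = 1, L = 10⁵ reads/sample, θ = 10, depth-lognormal σ = 0.3, enrichment
effect 2 (natural-log units). `dispersion = Inf` switches to rounded
expected counts — the noise-free regime used for exact-recovery checks.

Three design points deserve explanation, because the compositional
(softmax) observation model forces them:

* **Block factors are orthogonalized across blocks within each dataset.**
  With few samples, raw Gaussian factor vectors have non-trivial realized
  correlations, and *every* cross-block taxon pair inherits the realized
  factor correlation — entire block pairs then connect or not as a unit,
  seed by seed. Orthogonalization removes this common-mode artifact while
  leaving marginal behavior essentially unchanged.
* **Hub taxa load on two blocks as a contrast** (+Z_b1 − Z_b2)/√2, not a
  sum. Closure makes a sum-loading "hub" correlate *negatively* with the
  third block and only weakly (≈ 0.4) with its own two: softmax subtracts a
  mass-weighted average of all factors, which a sum-loading resembles. The
  contrast is orthogonal to that average, so a contrast hub correlates
  ≈ +0.8 with one of its communities and ≈ −0.8 with the other — edges to
  both, high participation by construction, and negative hub edges, which
  is precisely the structure reported for real pitcher networks.
* **Core taxa are compositionally stable** (their latent σ is damped to
  0.3σ). Correlation structure is scale-free, so this does not weaken block
  correlations elsewhere, but it keeps total community mass — and hence the
  closure term — stable, which is both biologically sensible for a dominant
  core and necessary for prevalence-based core detection to reflect planted
  membership rather than block fluctuations.

Enriched taxa are present only in their own genotype (occupancy zero
elsewhere), so the planted enriched sets are recoverable by the
every-replicate rule; core taxa get a baseline boost of 4 natural-log units
so they dominate the composition the way the most prevalent genera dominate
real pitcher communities.

`simulate_hit_table()` emulates best-hit annotation output: a configurable
fraction of transcripts (default 0.506) carries no passing hit, annotated
transcripts get (protein, genus, trait-path) assignments with proteins
recurring across genera, and per-transcript counts follow the same
depth/dispersion model.

## Validation design and problem sizes

The test suite validates each planted feature in a scenario where that
feature is identifiable:

* *Enriched recovery* (≥ 90% over 20 seeds) runs at the study design
  (4/3/3/2) with the default generator.
* *Core recovery* (exact) runs noise-free at 400 taxa, where the detection
  threshold of 500 CPM cleanly separates a dominant core from background —
  with few taxa, everything in a community exceeds 500 CPM and the
  threshold is uninformative, which is a property of the threshold, not a
  bug.
* *Block and hub recovery* run at a doubled validation design (8/6/6/4,
  n = 24) with mild dispersion (θ = 20). The limiting quantity is the
  sampling noise of a correlation coefficient, sd ≈ 1/√(n−3): at n = 12 it
  is ≈ 0.33, so an edge rule at |r| ≥ 0.7 misclassifies too many pairs for
  *any* generator to plant sharp structure; at n = 24 it is ≈ 0.22 and the
  planted blocks dominate. Blocks are validated without core/enriched taxa
  (whose occupancy patterns add structure that is real but not
  block-shaped); hubs are validated with the stable core present, since the
  contrast geometry needs a stable closure term.
* Statistical calibration uses 1000 simulated null communities for
  PERMANOVA (rejection rate at α = 0.05 within [0.03, 0.07]; p-values
  uniform by Kolmogorov–Smirnov at 199 permutations, where the p-grid is
  fine enough for the continuous-uniform comparison) and 100 no-effect
  communities for the discriminative-taxon screen (pass rate ≤ 5%).

Passing these tests shows the pipeline recovers the structure its own
generative model plants at realistic noise. It does not show the generator
reproduces real pitcher data: real communities have far more taxa, heavier
tails, zero-inflation beyond the negative binomial, and block structure
that is neither Gaussian nor orthogonal. The generator is a validation
instrument, not a data model.

## Numerical conventions

* Hub scores are computed per connected component by exact symmetric
  eigendecomposition. Iterative power schemes are unreliable exactly where
  this package needs centrality most — two dense modules joined by few
  edges have a near-degenerate leading eigenpair, and a fixed iteration
  budget fails there by construction. Each component is normalized to
  maximum 1; isolated nodes score 0.
* Greedy modularity can stop one merge early on an exact modularity tie
  (floating-point ΔQ ≈ −1e−17; a single clique is the minimal example).
  On ties within 1e−12 the coarser connected-component partition is
  preferred.
* PCoA fixes each axis's sign so its largest-magnitude loading is
  positive; eigenvalues below 1e−12 of the leading eigenvalue are treated
  as null axes.
* Zero-variance conventions: constant taxa get Kruskal–Wallis p = 1;
  zero-variance taxa are excluded from correlation pairing with a warning;
  a zero-κ-variance community gets z = 0 throughout; a constant sample in
  the z-score filter contributes p = 1 with a warning.
* Fully tied Wilcoxon comparisons (all values identical) report p = 1
  rather than the normal-approximation NaN.
* TMM is applied to raw counts (not CPM) for the metatranscriptome; the
  trim fractions are the canonical 30% (M) and 5% (A) and factors are
  re-centered to geometric mean 1.
* All stochastic stages take integer seeds; the pipeline derives per-stage
  subseeds from one master seed, so a run report plus its config reproduces
  a run bit-identically.

## Known limitations

Correlation networks on compositional data are biased toward negative
associations; the package follows the thresholded-correlation convention
of the field rather than compositionally-aware estimators (SparCC-type
methods are out of scope). Role counts are sensitive to the z/P thresholds,
which published analyses rarely report — they are arguments, not constants.
The LEfSe-style effect size is a documented variant, not a reimplementation
of the original tool's binary. UniFrac-type phylogenetic distances are not
provided (no tree is assumed).
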