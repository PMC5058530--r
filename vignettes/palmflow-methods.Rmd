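---
title: "Methods behind palmflow: kinship, parentage and forest-cover inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind palmflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palmflow)
```

`palmflow` implements a complete landscape-genetics workflow for plant
populations genotyped at codominant microsatellite (SSR) loci and sampled in
plots nested within sites spread over a forest-cover gradient: spatial
genetic structure (SGS) from pairwise kinship, single-parent assignment from
likelihood ratios, and a layer of forest-cover inference combining
parametric GLM/LMM tests with Monte Carlo randomization tests. A
ground-truthed synthetic-data generator stands in for field genotypes.
This vignette records the models, the defaults and why they are what they
are, the numerical choices, and what the test suite does and does not
establish.

## 1. The data model

A `study_dataset` holds a locus panel (allele labels are opaque integers,
nominally fragment sizes in base pairs; no binning or size correction is
attempted), individuals with stage (`adult`/`seedling`), site membership
and planar coordinates in metres, and a site table carrying the landscape
covariate: percent native forest cover in a 2-km buffer around the site
centroid. Coordinates are projected planar metres and all distances are
Euclidean; at plot scale (400 m) and study extent (tens of km) geodesy
would change nothing measurable.

A locus call is atomic: both alleles observed or both missing. Individuals
are never dropped for missingness at this layer — each downstream analysis
skips missing loci pairwise, which is standard SSR practice. Two interchange
dialects are supported: a long CSV carrying everything, and GenePop (2- or
3-digit allele coding, `Pop` blocks mapped to sites) with a companion CSV
supplying stage and coordinates, which the format itself lacks.

## 2. Kinship and spatial genetic structure

The pairwise kinship coefficient is the Loiselle et al. (1995) estimator.
For individuals $i, j$ at locus $l$ with reference allele frequencies
$\bar p_a$ and $n$ genotyped individuals,

$$f_{ij}^{(l)} = \frac{\sum_a (p_{ia}-\bar p_a)(p_{ja}-\bar p_a)
  + \tfrac{1}{n-1}\sum_a \bar p_a(1-\bar p_a)}
  {\sum_a \bar p_a(1-\bar p_a)},$$

where $p_{ia} \in \{0, \tfrac12, 1\}$ is $i$'s allele frequency. The
multilocus value averages the per-locus values weighted by the polymorphism
index $w_l = \sum_a \bar p_a(1-\bar p_a)$, so a monomorphic locus ($w_l=0$)
cannot move the estimate — an invariant the test suite asserts. The
$1/(n-1)$ term is the finite-sample bias correction of the published
estimator; with two opposite homozygotes at a biallelic 50/50 locus the
estimator equals $-1 + 1/(n-1)$, which the tests check against the closed
form.

**Reference frequencies.** The SGS profile computes its reference
frequencies from the analysis population itself (one site $\times$ stage),
the default of the standard SGS software; a `freqs` argument overrides
this. The parentage layer instead references all sampled adults, as stated
for the paternity index.

**Distance classes and envelope.** The profile uses eight half-open 50-m
classes over 0–400 m (the within-plot design). Pairs at 400 m or beyond go
to an out-of-range bucket: excluded from the profile, included in the
overall mean. The null envelope shuffles coordinate tuples among
individuals (genotypes fixed), recomputes class means, and takes the
empirical 2.5% and 97.5% percentiles over (by default) 10,000 permutations;
the observed value is not added to the null set. A population whose
individuals are colocated, or a class with no pairs, is flagged degenerate
rather than failing — with five colocated seedlings the observed mean
coincides with both envelope bounds, a case that occurs in real sparse
sites.

**Which "mean SGS"?** Whether a population's summary SGS is the mean over
all pairs or the mean of class means is ambiguous in the field literature;
`sgs_profile` reports both (`overall_mean`, `overall_mean_classes`) and the
package treats the all-pairs mean as the default summary. Stage comparison
uses a pooled-variance two-sample Student t-test on per-population means,
and the cover relation is ordinary least squares with the usual two-sided
slope test.

## 3. Parentage

Assignment is single-parent with unknown sex: every adult is a candidate
for every seedling, across all sites, with no known-mother conditioning —
appropriate for a monoecious palm where either parent may be the sampled
one. Per locus scored in both individuals the LOD is
$\ln(T^*(g_o \mid g_c)/P(g_o))$, where $T$ is the single-parent
transmission probability (candidate transmits one allele, the other is
drawn from the reference pool), $P(g_o)$ the Hardy–Weinberg probability of
the offspring genotype, and genotyping error enters through the blend
$T^* = (1-e)^2\,T + \left(1-(1-e)^2\right)P(g_o)$ — the minimal mistyping
model consistent with the likelihood framework, applied identically in
scoring and in simulation. With $e = 0$ an excluding locus gives
$\ln 0$; it is floored at a configurable $-37$ per locus
(about $\ln$ of the smallest double), keeping totals finite while
preserving exclusion semantics: the test suite asserts that with $e=0$ the
number of floored loci equals the Mendelian mismatch count exactly.

The $\Delta$ statistic is the LOD difference between the best and
second-best candidate with positive LOD (the best LOD itself if only one is
positive; no assignment if none is). Its critical value is calibrated by
simulation: offspring are generated from a true parent plus an unrelated
Hardy–Weinberg pool, the true parent is present with probability
`prop_sampled`, and the critical value is the smallest threshold at which
the proportion of correct best-candidates among tests exceeding it reaches
the confidence level (default 95%, 10,000 simulations). Defaults for the
pool size (all sampled adults) and `prop_sampled` (0.5) are exposed
configuration, not claims about any particular study's settings, which are
typically unpublished.

One property worth recording: the critical $\Delta$ is *not* universally
monotone in the error rate. With an informative panel (13 polymorphic loci,
as in the study design this package mirrors) more error always demands a
higher threshold, and the acceptance suite asserts this over 20 seeds. With
a weakly informative panel (e.g. 8 loci with 6 equifrequent alleles),
error *softens* the exclusion floor of unrelated candidates and can lower
the empirical threshold; the package makes no monotonicity promise there.

**Paternity index.** Per locus, $PI = X/Y$: the probability that the
alleged parent transmits an allele compatible with the offspring genotype
over the probability that a random pool member does (the summed compatible
allele frequencies). The combined index is the product over scored loci and
the paternity probability is
$PP = CPI \cdot \pi / (CPI \cdot \pi + 1 - \pi)$ under prior $\pi$
(default 0.5, the convention of human paternity testing, giving
$PP = CPI/(CPI+1)$ exactly). At a locus excluding the candidate, a nonzero
error rate keeps $PI = e \cdot s$ (scale $s$ configurable, default 1)
positive, so a candidate surviving exclusion review with one or two
mismatches still gets a usable $PP$.

**Frequencies for scoring.** Reference frequencies come from all adults.
Seedlings can legitimately carry alleles absent from the adult sample
(immigrant fathers, mistyping); `assign_parents` therefore augments the
table with seedling-only alleles at $1/(2N+1)$ and renormalises, the same
pragmatic device standard parentage software uses. The low-level
`lod_single_parent` keeps the strict contract (unknown allele is an error).

**Gene-flow distance.** Within a site, individual-to-individual Euclidean
distance; across sites, centroid-to-centroid (individual coordinates in
different sites share no common datum in typical field data). The 2-km
"same landscape" radius is interpreted centroid-to-centroid.

## 4. Forest-cover inference

Three response families are related to forest cover, mirroring the study
design the package reproduces:

1. **Presence** (0/1 per landscape) of at least one seedling with an
   assigned parent — overall, same-landscape, other-landscape — via
   logistic GLM with a two-sided Wald $z$ slope test.
2. **Proportions** (events/trials per landscape) via weighted binomial GLM.
3. **Log gene-flow distance** per assigned seedling via a random-intercept
   LMM (REML, `nlme`) with landscape identity as the random factor.

Perfect and quasi-complete separation (a cover threshold exactly splitting
the 0s and 1s) is detected from a near-zero residual deviance and flagged;
the parametric $p$ is then reported unavailable while the deviance-based
randomization test below remains valid — exactly the situation the
same-landscape presence analysis produces on the published count table.

**Monte Carlo randomization tests.** For the GLMs: record the observed
residual deviance, permute the response against the covers (keeping each
proportion's total attached to it), refit, and compute
$p = \#\{\text{deviances} \le \text{observed}\} / (n_{\text{rand}}+1)$ with
the observed arrangement included (so $p \ge 1/5000$ at the default 4999
randomizations). Two numerical choices matter and are deliberate:

- Comparisons use raw `<=` with **no tie tolerance**. Identical
  arrangements refit to bit-identical deviances and count as ties, but
  *different* perfectly separated arrangements stop the IRLS iterations at
  deviances that differ around $10^{-10}$ and are treated as distinct. The
  presence tests have exactly enumerable nulls (placements of the zeros
  among nine covers), and the enumeration oracle in the test suite
  confirms the sampled $p$ matches this convention.
- Non-converged randomization fits contribute the deviance of their final
  iterate, with a logged count — never silently dropped.

For gene-flow distance the randomization reassigns covers at the
*landscape* level (a permutation of the nine cover values), refits a simple
regression of the per-seedling response, and counts randomized $R^2$
greater than or equal to the observed. Permutation without replacement was
chosen over independent reassignment with replacement: it is the standard
randomization scheme and consistent with counting the observed arrangement
as "one of the possible combinations under the null". Because each
landscape keeps all its seedlings, within-landscape dependence is respected
without a mixed model, and $R^2 = \mathrm{cor}^2$ lets the loop avoid
refitting. The LMM's slope test uses $t = \hat\beta/\mathrm{SE}$ with
$df = n_{\text{obs}} - n_{\text{landscapes}} - 1$, an explicitly
approximate choice (mixed-model df are not uniquely defined; `nlme` itself
would use $n_{\text{landscapes}} - 2$ for a landscape-level covariate).

## 5. The synthetic generator

`simulate_dataset` emulates the statistical structure the analyses assume,
with defaults equal to the published design: nine sites at 19–83% cover
with the published per-site adult and seedling counts, 13 SSR loci with 8
possible alleles (Dirichlet(1) founder frequencies), a 0.01 per-locus
mistyping rate, adults uniform in a 15 × 400 m plot and seedlings censused
in the central 2 × 400 m strip.

The dispersal model encodes the hypothesis under test: median seed
dispersal distance $\exp(a + b \cdot \text{cover})$ with a log-normal
kernel ($\sigma_{\log} = 1$, heavy right tail producing rare multi-km
events). Defaults $a = \log 20$, $b = 0.035$ give medians of roughly 40 m
at 19% cover and 370 m at 83% — chosen once as a plausible bird-dispersal
scale, not fitted to anything. Pollen stays local: fathers are drawn from
the mother's site weighted by $\exp(-d/\lambda)$ with
$\lambda = 200\,$m, reflecting a short-range stingless-bee pollinator
(< 900 m flight), so long-distance gene flow is seed-mediated. Unsampled
"ghost" parents (probability $1-$`prop_parents_sampled` each) carry founder
genotypes and generate the no-assignment background.

Censoring follows the nested-plot census. Local seeds are rejection-sampled
until the deposition point falls in the strip. A kernel draw beyond
`cross_site_threshold` (1 km) becomes a between-site event, with the source
site chosen inversely to centroid distance and realized distance equal to
the centroid distance — and it is thinned by `cross_capture_prob`
(default 0.02), because the strip is a small target for landscape-wide seed
rain. Without that thinning, immigrant seedlings would face no census
censoring at all and would dominate the sample (over half of assignments in
early trials), which no nested-plot field study shows; 0.02 puts the
cross-site share near 10–15%, and was fixed on that realism argument before
any acceptance criterion was measured.

**What the generator does not emulate:** spatially explicit cover rasters
(cover enters only through the kernel median), demographic structure across
generations, selection, null alleles, linkage, and within-landscape habitat
heterogeneity. A green recovery test therefore establishes that the
analysis recovers the stated generative structure — not that the generator
is a faithful model of palm biology.

The truth ledger records, per seedling, the true parents, whether each was
a censused adult, and the realized dispersal distance, enabling the
recovery tests: Mendelian consistency at zero error, assignment accuracy
$\ge 95\%$ on clean fully-sampled data, assigned fraction tracking the
sampling probability, and a positive Spearman correlation between cover and
mean realized dispersal distance in at least 18 of 20 replicates.

## 6. Reproducibility mechanics

Every stochastic routine takes an explicit seed. The pipeline derives
per-stage seeds from one top-level seed by a fixed linear rule (kept below
$2^{31}$), so stages are independently reproducible, and writes a JSON
manifest (config echo, config hash, versions, seed) sufficient to re-run
byte-identically — asserted by the test suite on the full CSV outputs.
Scaled-down settings are used in tests where the published constants
(10,000 permutations/simulations, 4999 randomizations) would be slow; the
acceptance tests for the published statistics layer use the full 4999.

## 7. Known limitations

- The per-locus mistyping model is a single blend parameter; no
  allele-specific error, stutter, or null-allele model.
- The critical-$\Delta$ calibration treats candidates as unrelated;
  relatives among candidates would inflate assignment confidence.
- The LMM degrees of freedom are approximate by construction.
- The GenePop writer emits one population block per site in site-table
  order; files from other software with exotic formatting (allele sizes
  over three digits, mixed coding widths) are rejected rather than guessed.
- SGS envelopes assume exchangeability of locations within the analysis
  population; habitat gradients within a plot would violate this.
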