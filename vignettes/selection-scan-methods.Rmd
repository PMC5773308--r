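---
title: "Methods: climate-dependent selection scans for dominant marker data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: climate-dependent selection scans for dominant marker data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The inference problem

Dominant multilocus fingerprints (AFLP and relatives) score each individual
at each locus as band present (1) or absent (0). Band presence is dominant:
both homozygous and heterozygous carriers show the band, so allele
frequencies cannot be counted, only inferred. Given such a matrix for a set
of populations sampled along an environmental gradient, together with
per-population climate data and quantitative traits scored on progeny in a
common garden, the package asks: *which traits diverge among populations
because of climate-dependent selection, rather than because of neutral
demographic history or chance?*

The strategy separates three signals:

1. **Locus-level selection.** Three independent detectors flag candidate
   loci: an F_ST simulation envelope (Dfdist-style), a hierarchical
   Bayesian F-model, and univariate logistic environment-allele scans.
   Their intersections partition the loci into a *selected* and a
   *neutral* set.
2. **Geography.** Mantel tests between pairwise Phi_PT differentiation and
   great-circle distances detect isolation by distance separately within
   each locus set.
3. **Traits.** For each trait, GAMOVA (distance-matrix regression)
   tests whether population trait means predict the differentiation
   pattern of the selected set and of the neutral set.

A trait associated with the selected set but *not* with the neutral set is
the signature of selection (clinal if the selected set also shows IBD,
local otherwise); association with both leaves neutral variation
unexcluded; association with the neutral set only points to neutral
geography or chance. `classify_scenario()` encodes this decision table; the
combination (both tests negative) is reported as `no_signal` rather than
forced into a scenario.

# Dominant-marker statistics

**Allele frequencies.** `estimate_band_allele_freq()` returns the posterior
mean of the band-absence allele frequency $q$ under the likelihood
$(q^2)^m(1-q^2)^{n-m}$ for $m$ band-absent individuals out of $n$
(Hardy-Weinberg, inbreeding coefficient 0) and a Beta prior. The default
prior is Uniform(0, 1) — the cited estimation method leaves the prior open,
and the uniform choice is conservative; an empirical Beta prior fitted by
moments can be supplied instead. Quadrature is adaptive with relative
tolerance 1e-8 on a log-scaled integrand, and results are memoized over the
at most $n + 1$ distinct counts per sample size, which is what makes
envelope simulations with $10^5$–$10^6$ loci affordable.

**F_ST.** `locus_fst_he()` uses the variance-of-estimated-frequencies
ratio: the weighted among-population variance of $\hat p_j$, minus the mean
binomial sampling variance $\hat p_j(1-\hat p_j)/(2n_j)$, divided by
$\bar p(1-\bar p)$. Negative corrected estimates are retained — under weak
differentiation they carry half the information about the null. The
correction term is deliberately the same in observed data and in envelope
simulations, so its small-sample imperfections cancel in the comparison
(see *Numerical behavior* below).

**Phi_PT.** `phi_pt()` performs the AMOVA decomposition of pairwise squared
Euclidean distances between band phenotypes, with significance by
permuting individuals among populations. Negative Phi_PT values are
retained, which is why downstream GAMOVA pseudo-F values can be negative.

# The three detectors

**Envelope scan** (`fdist_scan()`). Neutral loci are simulated under the
Balding-Nichols island model at a target F_ST, re-estimated *with the same
estimators* as the observed data, and the observed loci are compared
against conditional quantile curves of simulated F_ST given He (sliding
window of the 2,000 nearest simulated loci in He; the conditioning width is
not stated by the tools this mirrors, and 2,000 keeps the quantile noise
below 1% at the default simulation sizes). The neutral baseline is the
*trimmed mean F_ST*: iteratively, loci outside the envelope are discarded
and the envelope re-simulated at the mean of the remainder (tolerance 1e-4,
at most 5 iterations). Empirical p-values are the fraction of
He-neighboring simulated loci with F_ST at least the observed value;
Benjamini-Hochberg at FDR 0.05 corrects for multiplicity, and an outlier
call additionally requires the locus to lie above the upper envelope curve.
Defaults are 1,000,000 simulations and a 0.95 two-sided envelope.

**Bayesian F-model** (`fit_bayes_fmodel()`). Band-absence counts are
binomial in $(1-p_{ij})^2$; population frequencies are Beta-distributed
around an ancestral frequency with precision $(1-F_{ij})/F_{ij}$, and
$\mathrm{logit}(F_{ij}) = \alpha_i\delta_i + \beta_j$ decomposes
differentiation into locus effects (selection, gated by the indicator
$\delta_i$) and population effects (drift). Priors:
$\alpha_i \sim N(0, 1.8)$, $\beta_j \sim N(-1, 1.8)$, ancestral
frequencies uniform, prior odds 10 : 1 against selection — the documented
defaults of the software this mirrors; all exposed in
`pipeline_config()$mcmc`. The sampler is Metropolis-within-Gibbs in Rcpp.
The indicator is flipped by a Gibbs move in a Carlin-Chib composite space:
while $\delta_i = 0$, $\alpha_i$ is refreshed from a pseudo-prior fitted to
pilot-run samples, and the flip odds weigh the real prior against the
pseudo-prior. This replaces a full reversible-jump move with an equivalent
target that is simpler to verify. Pilot runs adapt every proposal scale
towards acceptance 0.25–0.45; the default schedule is 50 pilots of 5,000
iterations, then 250,000 iterations with 50,000 burn-in and thinning 20.
The posterior probability of selection is the posterior mean of
$\delta_i$, converted to q-values by the running mean of $1 -
\mathrm{PP}$ down the ranked locus list (selection at $q \le 0.05$).

**Logistic scans** (`logistic_scan()`). Each locus is regressed on each
environmental variable (individuals inherit their population's climate —
the climate table is population-level); both a likelihood-ratio G test and
a Wald test must fall below the Bonferroni-corrected threshold
$\alpha / (\text{loci} \times \text{variables})$ — the total-model-count
denominator is the documented behavior of the software this mirrors. The
derived variables PC1–PC3 of `climate_pca()` (standardized variables,
deterministic sign convention) join the 20 bioclim variables. Complete
separation is detected from diverging coefficients; such models keep their
(capped) G statistic but their Wald test is marked unusable, so they can
never satisfy the both-tests rule.

# Inference stage

`gamova()` implements single-predictor distance-matrix regression: with
Gower-centered $G = -\tfrac12 J D^{\circ 2} J$ and hat matrix $H$ from
$[1, x]$, pseudo-F $= \mathrm{tr}(HGH)/\mathrm{tr}((I-H)G(I-H)) \cdot
(n-2)$, with p-values from permuting trait values across populations
(9,999 by default). Each trait is tested in its own single-predictor model,
one per locus set, mirroring the one-row-per-variable reporting layout of
such studies; no multiplicity correction is applied across traits, again
following that practice. `mantel_test()` correlates strict lower triangles
with simultaneous row/column permutations. Whether the differentiation
matrix entering the Mantel test is Phi_PT or a mean-F_ST matrix is
switchable (`mantel_matrix`); Phi_PT is the default since the AMOVA-based
matrix is the one the GAMOVA stage also uses. Geographic distances are
haversine on a 6,371 km sphere — the distance metric is rarely stated in
field studies and this is the conventional choice.

# What the synthetic generator emulates

`gen_bundle()` produces a complete study: 12 populations along a ~250 km
transect whose 20 bioclimatic variables are affine in transect position
plus noise (the annual-precipitation-like variable spans 100–200 mm,
matching the aridity gradients such studies target); 732 loci (702 neutral
at background F_ST 0.02, 30 clinal) scored for 182 individuals (12–19 per
population); 24 replicate pairs at a 9% scoring error rate; ten traits in
three generative classes (driven by the selected loci, by transect
position, or pure noise); and leaf outlines whose aspect ratio tracks the
selected-trait driver, plus 37-point flower landmark configurations.

Design choices worth knowing:

* **Clinal loci carry drift too.** A selected locus is a Balding-Nichols
  draw shifted on the logit scale by $\pm s \cdot z_j$ ($z_j$ the
  standardized environmental value). With $s = 0$ this reduces *exactly*
  to the neutral model. The default $s = 1.4$ realizes locus F_ST around
  0.25 against the 0.02 background over the default transect — the
  contrast regime the detectors are meant for.
* **The spatial-correlation knob defaults to off.** Neutral loci can be
  given exponentially decaying inter-population correlation (Gaussian
  copula over the Balding-Nichols marginals, correlation length as a
  fraction of the transect). Averaging ~700 loci shrinks noise in the
  neutral Phi_PT matrix so far that *any* systematic geographic component
  dominates it, and every clinal trait then associates with the neutral
  set — the confounded regime. That is realistic (field studies often
  report exactly this), but it makes end-to-end recovery of the clean
  clinal-selection scenario impossible; the default therefore stays at the
  exchangeable island model, and the knob exists to study the confounded
  regime deliberately.
* **Traits have a population-level noise floor** (`pop_noise_sd`, default
  0.5 SD): common-garden population means are never a pure function of
  genotype (maternal effects, microsite variation). Without it the
  selected-trait driver explains the selected-set differentiation matrix
  essentially perfectly and the GAMOVA residual trace degenerates to ~0,
  where the pseudo-F is numerically meaningless.
* **Dominant phenotypes assume Hardy-Weinberg with no inbreeding**; the
  assumption is surfaced in configuration rather than buried, since field
  data rarely report the inbreeding level.
* **Flower configurations use 37 points** (center, 4 petal tips, 8 margin
  points per petal at 25/50/75/95% of petal length). Written sources for
  this design are internally inconsistent about 37 vs 39 points; the
  37-point arithmetic (1 + 4 + 32) is the one that adds up and is used
  throughout.
* **Missing scores** (failed lanes) default to per-locus dropping — the
  affected individual simply does not contribute to that locus's counts;
  treating missing as band absence is available but conflates technical
  failure with genotype.

What the generator does **not** emulate: linkage between loci, mixed
mating/selfing, coalescent genealogies, genotype-by-environment
interaction in traits, and scoring artifacts beyond symmetric bit-flips.
Passing tests therefore demonstrate statistical correctness of the
machinery under the island model with independent loci, not robustness to
every property of real fingerprint data.

# Morphometrics

Leaf outlines are resampled to equal arc-length spacing and decomposed
into Kuhl-Giardina elliptic Fourier coefficients from discrete chain
integrals; coefficients are normalized by the first-harmonic ellipse
(size to its semi-major axis, rotation to its orientation, start point to
its end), so normalized shapes are comparable across runs. Harmonic power
is $(a_n^2+b_n^2+c_n^2+d_n^2)/2$; power proportions are invariant to the
normalization. Note a subtlety the tests encode: only a *circle* is a pure
first harmonic under arc-length parameterization; an eccentric ellipse is
traversed non-uniformly in angle, which moves a small fraction of power
(about 0.8% at aspect 2.5) into higher harmonics. Fifteen harmonics
capture over 99.9% of the power of the default lobed-leaf shapes.

Flower configurations are aligned by generalized least-squares Procrustes
superimposition: translation to centroid, scaling to unit centroid size,
iterative rotation to the consensus via the 2-D SVD solution (rotations
only, convergence 1e-10, at most 100 iterations). Semilandmarks are *not*
slid; sliding would change the meaning of the flower-shape variables.
Shape PCA is centered, not standardized, with a deterministic sign
convention (largest-magnitude loading positive); four axes are retained
for flowers (V11–V14) and three for leaves (V15–V17), alongside the
scalar measures leaf area (shoelace formula, cm²) and mean petal length
(mm).

# Numerical behavior and problem sizes

The small-sample correction $\hat p(1-\hat p)/(2n)$ slightly
*under*-corrects for dominant data (the delta-method sampling variance of
the dominant-marker estimator is larger), while the Bayesian shrinkage of
$\hat p_j$ slightly *over*-corrects; at the default study scale the two
nearly cancel (envelope mean F_ST 0.019 at target 0.02). The residual
effect is a sampling-noise floor: as the simulated differentiation goes to
0, the upper envelope curve flattens near 0.07 for high-He loci at
$n = 15$ per population rather than collapsing to 0. Because observed data
and envelope share the estimator, this floor cancels from outlier calls —
but it is why very weakly differentiated data cannot certify F_ST below
about 0.01 at these sample sizes.

The test suite runs every stage at reduced but honest sizes: calibration
at 700 loci x 20 replicates with 50,000-locus envelopes; power at 732 loci
with the MCMC schedule 20,000/5,000/10 after 6 pilots of 400; end-to-end
scenario recovery over 10 seeded replicates with 20,000-locus envelopes and
999 permutations; scan-level error control over 200 replicate 500 x 5
scans. The published-scale defaults (10^6 simulations, 250,000 MCMC
iterations, 9,999 permutations) remain the configuration defaults.

# Known limitations

* The F-model treats populations as exchangeable; hierarchical structure
  (regions) is not modeled.
* Logistic scans inherit population-level climate, so individuals within a
  population are pseudo-replicated whenever loci are spatially structured;
  under the island-model null the Bonferroni control holds (verified), but
  under strong structure the scan is anti-conservative — one reason the
  consensus intersection with the F_ST-based methods is the default
  partition rule.
* GAMOVA fits one predictor at a time; no model selection across traits.
* Admixture-based clustering (Structure-style) is out of scope; use the
  PCoA ordination (`bray_curtis_pcoa()`) for a first look at population
  structure.
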