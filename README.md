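# aflpselect

Climate-dependent selection scans for dominant (0/1) marker data.

## The problem

Population-genomic selection studies on non-model plants often rest on
dominant multilocus fingerprints (AFLP and similar): each individual is
scored at each locus only as band present or absent, so allele frequencies
must be inferred, not counted. Given such a marker matrix for populations
sampled along an environmental gradient, per-population climate data, and
quantitative traits scored in a common garden, the question is which traits
diverge among populations because of climate-dependent selection — as
opposed to neutral demographic history (isolation by distance, founder
effects) or chance.

`aflpselect` implements the full analytical chain for that question, aimed
at researchers running landscape-genomics or common-garden studies with
dominant markers:

* **Dominant-marker statistics** — Bayesian (Zhivotovsky-style) allele
  frequency estimation with posterior-mean quadrature; locus-wise F_ST
  (variance-of-frequencies ratio with small-sample correction) and expected
  heterozygosity He; AMOVA-based Φ_PT with permutation tests; Bray–Curtis
  PCoA ordination; replicate scoring error rates.
* **Three locus-outlier detectors** —
  1. an F_ST simulation envelope: neutral loci simulated under the
     Balding–Nichols island model, an iteratively *trimmed mean F_ST* as
     neutral baseline, empirical p-values conditioned on He, and
     Benjamini–Hochberg FDR control;
  2. a hierarchical Bayesian F-model,
     logit(F_ij) = α_i δ_i + β_j, with a selection indicator per locus
     sampled by Metropolis-within-Gibbs (Rcpp), posterior selection
     probabilities and q-values;
  3. univariate logistic environment–allele scans with both
     likelihood-ratio (G) and Wald tests under Bonferroni control, with
     climate PCA components PC1–PC3 as derived predictors.
* **Geometric morphometrics** — Kuhl–Giardina elliptic Fourier analysis of
  closed leaf outlines (with first-harmonic normalization and harmonic
  power), GLS Procrustes superimposition of 37-point flower landmark
  configurations, shape PCA, leaf area and petal length.
* **Inference** — consensus partitions of loci into selected vs neutral
  sets, Mantel isolation-by-distance tests (Φ_PT vs great-circle
  distances), GAMOVA (Gower-centered distance-matrix regression with
  permutation pseudo-F) of population trait means on each locus set, and a
  scenario classifier mapping the four significance flags to clinal
  selection / local selection / confounded / neutral geography / chance.
* **A synthetic-data generator** with known ground truth (clinal loci,
  trait–environment coupling, shape variation) so every stage is testable
  without any external data.

## Worked example

```r
library(aflpselect)

# simulate a study: 12 populations on an aridity transect, 732 AFLP loci
# (30 clinal), 182 individuals, traits in three generative classes
bundle <- gen_bundle(seed = 7)

cfg <- pipeline_config(n_sims = 20000, n_perm = 999,
                       consensus_rules = list(c("fdist", "assoc")))
res <- run_pipeline(bundle$markers, bundle$meta$pops, bundle$meta$climate,
                    bundle$traits, config = cfg, run_fmodel = FALSE)
```

The run prints (numbers from this exact seed):

```
trimmed mean F_ST: 0.0251
consensus selected set: 26 loci (26 of 30 truly clinal)
      locus_set      set   r_xy p_value
1 fdist & assoc selected 0.9505   0.001
2 fdist & assoc  neutral 0.0614   0.342
 trait  scenario
   V01       1.1
   V02       1.1
   V03 no_signal
```

Reading: the trimmed mean recovers the simulated neutral background
(F_ST = 0.02) despite the planted outliers; the consensus of the envelope
scan and the logistic scan finds 26 loci, all truly clinal, with no false
positives; the selected-locus differentiation matrix is strongly
isolation-by-distance (Mantel r = 0.95) while the neutral matrix is not;
and the classifier calls the clinal traits scenario 1.1 ("divergence driven
by selection along a geographical cline") while the pure-noise trait V03 is
correctly left without signal. `run_fmodel = TRUE` (default) adds the
Bayesian F-model as a third consensus method; `write_results(res$tables,
"out/")` writes the locus table, GAMOVA/Mantel summaries and scenario calls
as TSV files with a run manifest.

A thin command-line wrapper over these functions is installed at
`inst/cli/aflpselect` (subcommands `simulate`, `popgen`, `outliers`,
`assoc`, `morpho`, `infer`, `run-all`).

## Package layout

* `R/io.R`, `R/config.R` — data containers, delimited readers/writers,
  configuration; `inst/cli/aflpselect` — command-line wrapper
* `R/simulate.R` — synthetic-data generators (`gen_metadata`, `gen_aflp`,
  `gen_traits`, `gen_shapes`, `gen_bundle`)
* `R/popgen.R` — dominant-marker statistics
* `R/outliers.R`, `src/fmodel.cpp` — envelope scan and Bayesian F-model
* `R/assoc.R` — climate PCA and logistic scans
* `R/morpho.R` — elliptic Fourier analysis, Procrustes, shape PCA
* `R/inference.R`, `R/pipeline.R` — GAMOVA, Mantel, scenario classifier,
  orchestration
* `vignettes/selection-scan-methods.Rmd` — model assumptions, parameter
  choices, generator design, numerical behavior, limitations
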