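#' Pipeline configuration with study defaults
#'
#' Returns the full default configuration of the analysis pipeline. Defaults
#' reproduce the published settings of the tools this pipeline mirrors:
#' 1,000,000 neutral envelope simulations at a 0.95 confidence interval with
#' FDR 0.05; an MCMC schedule of 250,000 iterations, 50,000 burn-in and
#' thinning 20 after 50 pilot runs of 5,000 iterations; and 9,999
#' permutations for the distance-matrix tests. Any element can be overridden
#' through `...`; tests and exploratory runs typically reduce the simulation
#' counts.
#'
#' @param ... named overrides of individual settings (nested lists are
#'   replaced wholesale).
#' @return named list of class `pipeline_config`.
#' @examples
#' cfg <- pipeline_config(n_sims = 50000, n_perm = 999)
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    # envelope / Dfdist-style scan
    n_sims = 1e6,
    ci = 0.95,
    fdr = 0.05,
    he_window = 2000L,
    trim_max_iter = 5L,
    # Bayesian F-model
    mcmc = list(pilot_runs = 50L, pilot_iter = 5000L, iter = 250000L,
                burnin = 50000L, thin = 20L, prior_odds = 10,
                alpha_sd = 1.8, beta_mean = -1, beta_sd = 1.8),
    bayes_fdr = 0.05,
    # association scan
    alpha = 0.05,
    both_tests = TRUE,
    # inference
    n_perm = 9999L,
    mantel_matrix = "phi_pt",
    # consensus rules: intersections of detector flags
    consensus_rules = list(c("fdist", "fmodel"),
                           c("fdist", "fmodel", "assoc"),
                           "assoc"),
    # missing AFLP scores: "drop" (reduce per-locus sample size) or "absent"
    missing = "drop",
    prior = c(1, 1)
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  class(cfg) <- c("pipeline_config", "list")
  cfg
}
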