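# F_ST outlier detection: neutral simulation envelope (Dfdist-style),
# iterative trimmed mean F_ST, empirical p-values conditioned on
# heterozygosity, the hierarchical Bayesian F-model, and the consensus
# partition of loci into selected vs neutral sets.

#' Simulate a neutral F_ST envelope
#'
#' Simulates `n_sims` dominant loci under the neutral Balding-Nichols island
#' model at differentiation `target_fst`: ancestral band-presence frequency
#' `p ~ U(0.01, 0.99)`, population frequencies Beta-distributed around it,
#' dominant phenotypes sampled at the observed per-population sample sizes,
#' and (He, F_ST) re-estimated with the same estimators used for observed
#' data ([estimate_band_allele_freq()], [locus_fst_he()]). Conditional
#' envelope quantile curves versus He use a sliding window of the
#' `he_window` nearest simulated loci.
#'
#' @param target_fst simulated neutral differentiation, in (0, 0.99).
#' @param pop_sizes per-population sample sizes of the observed data.
#' @param n_sims number of simulated loci (>= 1000).
#' @param ci envelope confidence level (two-sided).
#' @param seed integer seed.
#' @param prior Beta prior for the frequency estimator.
#' @param he_window sliding-window size (simulated loci nearest in He).
#' @return object of class `neutral_envelope`: sorted simulated `he` and
#'   `fst`, the window size, CI level, and a quantile-curve grid
#'   (`grid_he`, `grid_lo`, `grid_hi`).
#' @export
simulate_neutral_envelope <- function(target_fst, pop_sizes, n_sims = 50000,
                                      ci = 0.95, seed = 1L, prior = c(1, 1),
                                      he_window = 2000L) {
  stopifnot(target_fst > 0, target_fst < 0.99)
  if (n_sims < 1000) stop("n_sims below floor of 1000")
  set.seed(seed)
  K <- length(pop_sizes)
  p <- runif(n_sims, 0.01, 0.99)
  F <- target_fst
  a <- p * (1 - F) / F
  b <- (1 - p) * (1 - F) / F
  pj <- matrix(rbeta(n_sims * K, rep(a, K), rep(b, K)), n_sims, K)
  pres <- matrix(
    rbinom(n_sims * K, rep(pop_sizes, each = n_sims),
           as.vector(1 - (1 - pj)^2)),
    n_sims, K)
  m_abs <- sweep(-pres, 2, pop_sizes, "+")
  n_mat <- matrix(pop_sizes, n_sims, K, byrow = TRUE)
  phat <- 1 - matrix(zhiv_freq_table(as.vector(m_abs), as.vector(n_mat),
                                     prior), n_sims, K)
  w <- pop_sizes / sum(pop_sizes)
  p_bar <- as.vector(phat %*% w)
  he <- 2 * p_bar * (1 - p_bar)
  s2 <- as.vector(((phat - p_bar)^2) %*% w) / (1 - sum(w^2))
  corr <- rowMeans(sweep(phat * (1 - phat), 2, 2 * pop_sizes, "/"))
  fst <- (s2 - corr) / (p_bar * (1 - p_bar))
  ord <- order(he)
  he <- he[ord]
  fst <- pmin(fst[ord], 1)
  win <- as.integer(min(he_window, n_sims))
  grid_he <- seq(min(he), max(he), length.out = 60)
  qs <- envelope_window_quantiles(he, fst, grid_he, win,
                                  c((1 - ci) / 2, 1 - (1 - ci) / 2))
  structure(list(he = he, fst = fst, he_window = win, ci = ci,
                 target_fst = target_fst, n_sims = n_sims,
                 grid_he = grid_he, grid_lo = qs[, 1], grid_hi = qs[, 2]),
            class = "neutral_envelope")
}

# Conditional quantiles of simulated F_ST in a sliding He window.
# he_sim/fst_sim must be sorted by he_sim.
envelope_window_quantiles <- function(he_sim, fst_sim, he_at, window, probs) {
  n <- length(he_sim)
  half <- window %/% 2
  pos <- findInterval(he_at, he_sim)
  t(vapply(pos, function(ctr) {
    lo <- max(1, min(ctr - half, n - window + 1))
    hi <- min(n, lo + window - 1)
    quantile(fst_sim[lo:hi], probs, names = FALSE, type = 7)
  }, numeric(length(probs))))
}

# Per-locus empirical p and envelope bounds for observed loci.
envelope_locus_stats <- function(envelope, he_obs, fst_obs) {
  n <- length(envelope$he)
  win <- envelope$he_window
  half <- win %/% 2
  alpha <- 1 - envelope$ci
  pos <- findInterval(he_obs, envelope$he)
  out <- t(vapply(seq_along(he_obs), function(i) {
    if (is.na(he_obs[i]) || is.na(fst_obs[i])) {
      return(c(NA_real_, NA_real_, NA_real_))
    }
    lo <- max(1, min(pos[i] - half, n - win + 1))
    hi <- min(n, lo + win - 1)
    fw <- envelope$fst[lo:hi]
    c(mean(fw >= fst_obs[i]),
      quantile(fw, alpha / 2, names = FALSE),
      quantile(fw, 1 - alpha / 2, names = FALSE))
  }, numeric(3)))
  colnames(out) <- c("p_emp", "q_lo", "q_hi")
  out
}

#' Iterative trimmed mean F_ST
#'
#' Estimates the average neutral F_ST uninfluenced by outlier loci: starting
#' from the plain mean, an envelope is simulated at the current target, loci
#' falling outside its confidence envelope are trimmed, the mean is
#' recomputed over the remaining loci, and the envelope re-simulated, until
#' the mean changes by less than `tol` or `max_iter` iterations are reached.
#'
#' @param stats a [locus_stats()] table.
#' @param pop_sizes per-population sample sizes.
#' @param n_sims simulated loci per envelope iteration.
#' @param ci envelope confidence level.
#' @param max_iter maximum trimming iterations (default 5).
#' @param tol convergence tolerance on the trimmed mean.
#' @param seed integer seed.
#' @param prior Beta prior for the frequency estimator.
#' @param he_window envelope sliding-window size.
#' @return list with `trimmed_mean`, `plain_mean`, `iterations`, `n_trimmed`
#'   at the last iteration, and the final `envelope` (re-simulated at the
#'   trimmed mean).
#' @export
trimmed_mean_fst <- function(stats, pop_sizes, n_sims = 50000, ci = 0.95,
                             max_iter = 5, tol = 1e-4, seed = 1L,
                             prior = c(1, 1), he_window = 2000L) {
  fst <- stats$fst
  he <- stats$he
  ok <- !is.na(fst)
  plain <- mean(fst[ok])
  target <- min(max(plain, 0.001), 0.9)
  n_trim <- 0L
  env <- NULL
  for (it in seq_len(max_iter)) {
    env <- simulate_neutral_envelope(target, pop_sizes, n_sims = n_sims,
                                     ci = ci, seed = seed + it,
                                     prior = prior, he_window = he_window)
    es <- envelope_locus_stats(env, he, fst)
    inside <- ok & !is.na(es[, "q_lo"]) &
      fst >= es[, "q_lo"] & fst <= es[, "q_hi"]
    if (!any(inside)) stop("all loci trimmed; pathological input")
    n_trim <- sum(ok) - sum(inside)
    new_target <- min(max(mean(fst[inside]), 0.001), 0.9)
    done <- abs(new_target - target) < tol
    target <- new_target
    if (done) break
  }
  env <- simulate_neutral_envelope(target, pop_sizes, n_sims = n_sims,
                                   ci = ci, seed = seed, prior = prior,
                                   he_window = he_window)
  list(trimmed_mean = target, plain_mean = plain, iterations = it,
       n_trimmed = n_trim, envelope = env)
}

#' Classify loci against a neutral envelope
#'
#' Per-locus empirical p-value (fraction of simulated loci in the locus's
#' He-neighborhood with simulated F_ST at least the observed value),
#' Benjamini-Hochberg correction at `fdr` across scanned loci, and the
#' outlier call: BH-rejected *and* above the upper envelope curve. Loci with
#' missing F_ST (monomorphic) are excluded from the scan.
#'
#' @param stats a [locus_stats()] table.
#' @param envelope a [simulate_neutral_envelope()] result (built at the
#'   trimmed mean).
#' @param fdr false discovery rate for the BH step.
#' @return data.frame with `locus`, `he`, `fst`, `p_emp`, `p_bh`, `q_lo`,
#'   `q_hi`, `outside` (outside the two-sided envelope), and `outlier`
#'   (divergent-selection call).
#' @export
fdist_classify <- function(stats, envelope, fdr = 0.05) {
  es <- envelope_locus_stats(envelope, stats$he, stats$fst)
  p_emp <- es[, "p_emp"]
  p_bh <- rep(NA_real_, length(p_emp))
  ok <- !is.na(p_emp)
  p_bh[ok] <- p.adjust(p_emp[ok], method = "BH")
  outside <- !is.na(p_emp) &
    (stats$fst > es[, "q_hi"] | stats$fst < es[, "q_lo"])
  outlier <- !is.na(p_bh) & p_bh <= fdr & stats$fst > es[, "q_hi"]
  data.frame(locus = stats$locus, he = stats$he, fst = stats$fst,
             p_emp = p_emp, p_bh = p_bh, q_lo = es[, "q_lo"],
             q_hi = es[, "q_hi"], outside = outside, outlier = outlier,
             stringsAsFactors = FALSE)
}

#' F_ST-envelope outlier scan (trimmed mean + classification)
#'
#' Convenience wrapper running [locus_stats()] (unless given), the iterative
#' [trimmed_mean_fst()], and [fdist_classify()] against the final envelope.
#'
#' @param mm a [marker_matrix()].
#' @param config a [pipeline_config()]; `n_sims`, `ci`, `fdr`,
#'   `trim_max_iter`, `he_window` and `prior` are used.
#' @param stats optional precomputed [locus_stats()].
#' @return list with `table` (the [fdist_classify()] output), `trimmed_mean`,
#'   `envelope`, and `stats`.
#' @export
fdist_scan <- function(mm, config = pipeline_config(), stats = NULL) {
  if (is.null(stats)) stats <- locus_stats(mm, prior = config$prior)
  pop_sizes <- as.vector(table(mm$pop))
  tm <- trimmed_mean_fst(stats, pop_sizes, n_sims = config$n_sims,
                         ci = config$ci, max_iter = config$trim_max_iter,
                         seed = config$seed, prior = config$prior,
                         he_window = config$he_window)
  tab <- fdist_classify(stats, tm$envelope, fdr = config$fdr)
  list(table = tab, trimmed_mean = tm$trimmed_mean, envelope = tm$envelope,
       stats = stats)
}

#' Hierarchical Bayesian F-model outlier scan
#'
#' Fits the F-model for dominant data: band-absence counts
#' `m_ij ~ Binomial(n_j, (1 - p_ij)^2)`; population frequencies
#' `p_ij ~ Beta(theta_ij p_i, theta_ij (1 - p_i))` with
#' `theta_ij = (1 - FST_ij) / FST_ij` and
#' `logit(FST_ij) = alpha_i delta_i + beta_j`. Locus effects `alpha_i` carry
#' a selection indicator `delta_i` with prior odds `prior_odds` against
#' selection; the indicator is flipped by a Gibbs-style move using
#' pilot-fitted pseudo-priors for `alpha_i` (Carlin-Chib flavor of the
#' variable-selection move). Pilot runs adapt all proposal scales towards
#' acceptance rates of 0.25-0.45. The posterior probability of selection is
#' the posterior mean of `delta_i`.
#'
#' @param mm a [marker_matrix()]. Monomorphic loci are dropped from the fit
#'   (posterior probability `NA`).
#' @param config a [pipeline_config()]; the `mcmc` block holds the schedule
#'   and priors.
#' @param seed integer seed.
#' @param fix_alpha fix all locus effects at zero (no selection component);
#'   used for the reduction of the model to a single per-population F_ST.
#' @return list with per-locus `pp` (posterior selection probability),
#'   `q_value`, `alpha`, `fst_locus` (posterior mean locus F_ST averaged
#'   over populations), per-population `beta` and `fst_pop`, acceptance
#'   rates, and the chain length.
#' @export
fit_bayes_fmodel <- function(mm, config = pipeline_config(), seed = 1L,
                             fix_alpha = FALSE) {
  stopifnot(inherits(mm, "marker_matrix"))
  bands <- mm$bands
  pops <- levels(mm$pop)
  K <- length(pops)
  if (K < 2) stop("need at least two populations")
  keep <- apply(bands, 2, function(x) {
    x <- x[!is.na(x)]
    length(x) > 0L && max(x) != min(x)
  })
  m_abs <- matrix(0L, sum(keep), K)
  n_obs <- m_abs
  sub_bands <- bands[, keep, drop = FALSE]
  for (k in seq_len(K)) {
    s <- sub_bands[mm$pop == pops[k], , drop = FALSE]
    n_obs[, k] <- colSums(!is.na(s))
    m_abs[, k] <- colSums(s == 0L, na.rm = TRUE)
  }
  mc <- config$mcmc
  set.seed(seed)
  fit <- fmodel_mcmc(m_abs, n_obs, mc$pilot_runs, mc$pilot_iter,
                     mc$iter, mc$burnin, mc$thin, mc$prior_odds,
                     mc$alpha_sd, mc$beta_mean, mc$beta_sd, fix_alpha)
  acc <- unlist(fit$acceptance)
  if (all(acc < 0.05)) {
    stop("F-model chain failed to mix (all acceptance rates < 0.05)")
  }
  L_all <- ncol(bands)
  pp <- alpha <- fstl <- rep(NA_real_, L_all)
  pp[keep] <- fit$pp
  alpha[keep] <- fit$alpha_mean
  fstl[keep] <- fit$fst_locus
  names(pp) <- names(alpha) <- names(fstl) <- colnames(bands)
  qv <- rep(NA_real_, L_all)
  qv[keep] <- bayes_qvalues(fit$pp)
  names(qv) <- colnames(bands)
  list(pp = pp, q_value = qv, alpha = alpha, fst_locus = fstl,
       beta = setNames(as.vector(fit$beta_mean), pops),
       fst_pop = setNames(as.vector(fit$fst_pop), pops),
       acceptance = fit$acceptance, n_samples = fit$n_samples)
}

#' q-values from posterior selection probabilities
#'
#' Bayesian FDR control: loci are ranked by decreasing posterior probability
#' of selection and `q(i)` is the mean of `1 - PP` over all loci with
#' `PP >= PP_i` (the expected FDR of the list down to locus i). Selected
#' loci are those with `q <= 0.05` by convention.
#'
#' @param pp posterior selection probabilities in \[0, 1\].
#' @return q-value per locus, same order as `pp`.
#' @export
bayes_qvalues <- function(pp) {
  stopifnot(all(pp >= 0 & pp <= 1, na.rm = TRUE))
  q <- rep(NA_real_, length(pp))
  ok <- which(!is.na(pp))
  if (!length(ok)) return(q)
  ord <- ok[order(pp[ok], decreasing = TRUE)]
  cm <- cumsum(1 - pp[ord]) / seq_along(ord)
  # ties share the q of the last tied position
  ppo <- pp[ord]
  last_of_run <- rev(!duplicated(rev(ppo)))
  cm_shared <- cm
  cm_shared[!last_of_run] <- NA
  cm_shared <- rev(cummax_na(rev(cm_shared)))
  q[ord] <- cm_shared
  q
}

# carry last non-NA value forward (helper for tie handling)
cummax_na <- function(x) {
  for (i in seq_along(x)) {
    if (is.na(x[i]) && i > 1) x[i] <- x[i - 1]
  }
  x
}

#' Consensus partition of loci into selected and neutral sets
#'
#' Intersects the per-method outlier flags according to a rule (a character
#' vector of method names) and returns the selected set and its complement.
#' An empty selected set is legal; downstream distance-matrix tests on it
#' are skipped with a warning.
#'
#' @param flags named list of character vectors: the outlier locus ids found
#'   by each method (e.g. `fdist`, `fmodel`, `assoc`).
#' @param all_loci character vector of every scanned locus id.
#' @param rule character vector of method names to intersect; must all be
#'   present in `flags`.
#' @return list of class `locus_partition` with `label`, `selected`,
#'   `neutral`.
#' @export
consensus_partition <- function(flags, all_loci, rule) {
  if (!all(rule %in% names(flags))) {
    stop("unknown method in rule: ",
         paste(setdiff(rule, names(flags)), collapse = ", "))
  }
  sel <- Reduce(intersect, flags[rule])
  sel <- intersect(all_loci, sel)
  structure(list(label = paste(rule, collapse = " & "), selected = sel,
                 neutral = setdiff(all_loci, sel)),
            class = "locus_partition")
}
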