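# Allele-frequency and differentiation statistics for dominant 0/1 data.

#' Bayesian band-absence allele frequency estimate for a dominant locus
#'
#' Posterior mean of the recessive (band-absence) allele frequency `q` at a
#' dominant marker locus, following Zhivotovsky's approach: with `m` of `n`
#' individuals lacking the band and Hardy-Weinberg proportions, the
#' likelihood is `(q^2)^m * (1 - q^2)^(n - m)`, combined with a Beta prior on
#' `q`. The band-presence allele frequency is `1 - q`.
#'
#' The posterior mean is computed by adaptive numerical quadrature on a
#' log-scaled integrand (relative tolerance 1e-8), so the estimate is always
#' strictly inside (0, 1) - a locus can never be declared exactly fixed from
#' a finite sample.
#'
#' @param m_absent number of band-absent individuals (0 <= m_absent <= n).
#' @param n number of scored individuals. With `n = 0` the prior mean is
#'   returned.
#' @param prior length-2 vector of Beta shape parameters for `q`;
#'   `c(1, 1)` (uniform) by default.
#' @return Posterior mean of `q`, a single value in (0, 1).
#' @examples
#' estimate_band_allele_freq(5, 10)          # uniform prior
#' 1 - estimate_band_allele_freq(0, 15)      # band-presence frequency
#' @export
estimate_band_allele_freq <- function(m_absent, n, prior = c(1, 1)) {
  stopifnot(length(prior) == 2, all(prior > 0))
  if (length(m_absent) != 1L || length(n) != 1L) {
    stop("m_absent and n must be scalars; see zhiv_freq_table() for batches")
  }
  if (n < 0 || m_absent < 0 || m_absent > n) {
    stop("need 0 <= m_absent <= n")
  }
  if (n == 0) {
    return(prior[1] / sum(prior))
  }
  a <- prior[1]
  b <- prior[2]
  logf <- function(q) {
    (2 * m_absent + a - 1) * log(q) + (b - 1) * log1p(-q) +
      (n - m_absent) * log1p(-q^2)
  }
  # scale by the value at the approximate mode to avoid underflow
  q0 <- min(max(sqrt((2 * m_absent + a - 1) / (2 * n + a + b - 2)), 1e-3), 1 - 1e-3)
  c0 <- logf(q0)
  num <- integrate(function(q) q * exp(logf(q) - c0), 0, 1,
                   rel.tol = 1e-8, subdivisions = 400L)$value
  den <- integrate(function(q) exp(logf(q) - c0), 0, 1,
                   rel.tol = 1e-8, subdivisions = 400L)$value
  num / den
}

# Vectorized, memoized band-absence frequency estimates. m and n are equal
# length integer vectors; returns q-hat for each pair. Distinct (m, n) pairs
# are computed once, which makes envelope simulations with hundreds of
# thousands of loci cheap (m can only take n + 1 values per sample size).
zhiv_freq_table <- function(m, n, prior = c(1, 1)) {
  key <- paste(m, n)
  uk <- !duplicated(key)
  qs <- vapply(which(uk), function(i) {
    estimate_band_allele_freq(m[i], n[i], prior)
  }, numeric(1))
  qs[match(key, key[uk])]
}

#' Locus-wise F_ST and expected heterozygosity from population frequencies
#'
#' Differentiation at a single dominant locus from estimated per-population
#' band-presence allele frequencies. F_ST is the weighted among-population
#' variance of the frequency estimates, with a small-sample correction that
#' subtracts the mean binomial sampling variance `p_j (1 - p_j) / (2 n_j)`,
#' divided by `p_bar (1 - p_bar)`. Expected heterozygosity is
#' `He = 2 p_bar (1 - p_bar)`.
#'
#' Negative corrected estimates are retained (they are informative about the
#' null, as in the Dfdist simulation kernel). A locus with `He = 0` has
#' undefined F_ST and returns `NA`.
#'
#' @param freqs per-population band-presence allele frequency estimates.
#' @param weights per-population sample sizes (individuals scored).
#' @return list with `fst`, `he`, and `p_bar`.
#' @export
locus_fst_he <- function(freqs, weights = rep(1, length(freqs))) {
  stopifnot(length(freqs) == length(weights), length(freqs) >= 2,
            all(freqs >= 0 & freqs <= 1), all(weights > 0))
  w <- weights / sum(weights)
  p_bar <- sum(w * freqs)
  he <- 2 * p_bar * (1 - p_bar)
  if (max(freqs) - min(freqs) < 1e-15) {
    return(list(fst = if (he > 0) 0 else NA_real_, he = he, p_bar = p_bar))
  }
  if (p_bar * (1 - p_bar) < 1e-12) {
    return(list(fst = NA_real_, he = he, p_bar = p_bar))
  }
  s2 <- sum(w * (freqs - p_bar)^2) / (1 - sum(w^2))
  corr <- mean(freqs * (1 - freqs) / (2 * weights))
  fst <- (s2 - corr) / (p_bar * (1 - p_bar))
  list(fst = min(fst, 1), he = he, p_bar = p_bar)
}

#' Per-locus statistics table for a marker matrix
#'
#' Estimates per-population band-presence allele frequencies at every locus
#' (via [estimate_band_allele_freq()]), and from them locus-wise F_ST and
#' expected heterozygosity. Missing scores reduce the per-locus sample size
#' of the affected population. Loci with zero variance across all scored
#' individuals are flagged monomorphic and carry `NA` differentiation.
#'
#' @param mm a [marker_matrix()].
#' @param prior Beta prior on the band-absence allele frequency.
#' @return data.frame of class `locus_stats` with columns `locus`, `he`,
#'   `fst`, `p_bar`, `monomorphic`; per-population frequency estimates in
#'   `attr(, "pop_freq")` (loci x populations) and sample sizes in
#'   `attr(, "pop_n")`.
#' @export
locus_stats <- function(mm, prior = c(1, 1)) {
  stopifnot(inherits(mm, "marker_matrix"))
  bands <- mm$bands
  pops <- levels(mm$pop)
  L <- ncol(bands)
  K <- length(pops)
  m_abs <- matrix(0L, L, K, dimnames = list(colnames(bands), pops))
  n_obs <- m_abs
  for (k in seq_len(K)) {
    sub <- bands[mm$pop == pops[k], , drop = FALSE]
    n_obs[, k] <- colSums(!is.na(sub))
    m_abs[, k] <- colSums(sub == 0L, na.rm = TRUE)
  }
  qhat <- matrix(zhiv_freq_table(as.vector(m_abs), as.vector(n_obs), prior),
                 L, K, dimnames = dimnames(m_abs))
  phat <- 1 - qhat
  mono <- apply(bands, 2, function(x) {
    x <- x[!is.na(x)]
    length(x) == 0L || max(x) == min(x)
  })
  res <- t(vapply(seq_len(L), function(i) {
    fh <- locus_fst_he(phat[i, ], n_obs[i, ])
    c(fh$fst, fh$he, fh$p_bar)
  }, numeric(3)))
  out <- data.frame(locus = colnames(bands), he = res[, 2], fst = res[, 1],
                    p_bar = res[, 3], monomorphic = mono,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$fst[mono] <- NA_real_
  attr(out, "pop_freq") <- phat
  attr(out, "pop_n") <- n_obs
  class(out) <- c("locus_stats", "data.frame")
  out
}

# AMOVA sums of squares for squared-distance matrix d2 and a grouping factor.
amova_ss <- function(d2, grp) {
  n <- nrow(d2)
  ss_tot <- sum(d2) / (2 * n)
  ss_w <- 0
  for (g in levels(grp)) {
    idx <- which(grp == g)
    ss_w <- ss_w + sum(d2[idx, idx]) / (2 * length(idx))
  }
  c(total = ss_tot, within = ss_w, among = ss_tot - ss_w)
}

phi_from_ss <- function(ss, n_g) {
  n <- sum(n_g)
  k <- length(n_g)
  ms_a <- ss["among"] / (k - 1)
  ms_w <- ss["within"] / (n - k)
  n0 <- (n - sum(n_g^2) / n) / (k - 1)
  s2_a <- (ms_a - ms_w) / n0
  s2_w <- ms_w
  if (s2_a + s2_w <= 0) {
    return(NA_real_)
  }
  unname(s2_a / (s2_a + s2_w))
}

#' AMOVA Phi_PT for dominant band phenotypes
#'
#' Analysis of molecular variance on pairwise squared Euclidean distances
#' between binary band phenotypes. `Phi_PT = s2_among / (s2_among +
#' s2_within)` from the usual variance-component decomposition; significance
#' by permuting individuals among populations,
#' `p = (1 + #\{Phi_perm >= Phi_obs\}) / (1 + n_perm)`.
#'
#' Negative Phi_PT estimates are retained. If all individuals are identical
#' the statistic is defined as 0 with a warning.
#'
#' @param mm a [marker_matrix()].
#' @param pops optional subset of population ids to include.
#' @param n_perm number of label permutations (0 skips the test).
#' @param seed integer seed for the permutation stream.
#' @return list with `phi_pt`, `p_value`, `n_perm`, and the variance
#'   components `ss`.
#' @export
phi_pt <- function(mm, pops = NULL, n_perm = 999, seed = 1L) {
  stopifnot(inherits(mm, "marker_matrix"))
  keep <- if (is.null(pops)) rep(TRUE, nrow(mm$bands)) else mm$pop %in% pops
  bands <- mm$bands[keep, , drop = FALSE]
  grp <- droplevels(mm$pop[keep])
  if (nlevels(grp) < 2) stop("need at least two populations")
  n_g <- table(grp)
  if (any(n_g < 2)) {
    stop("population(s) with fewer than 2 individuals: ",
         paste(names(n_g)[n_g < 2], collapse = ", "))
  }
  d2 <- as.matrix(dist(bands))^2
  if (all(d2 == 0)) {
    warning("all individuals identical; Phi_PT defined as 0")
    return(list(phi_pt = 0, p_value = 1, n_perm = n_perm,
                ss = amova_ss(d2, grp)))
  }
  ss <- amova_ss(d2, grp)
  phi_obs <- phi_from_ss(ss, as.vector(n_g))
  if (is.na(phi_obs)) phi_obs <- 0
  p_val <- NA_real_
  if (n_perm > 0) {
    set.seed(seed)
    n <- nrow(d2)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      gp <- grp[sample.int(n)]
      phi_b <- phi_from_ss(amova_ss(d2, gp), as.vector(table(gp)))
      if (!is.na(phi_b) && phi_b >= phi_obs) hits <- hits + 1L
    }
    p_val <- (1 + hits) / (1 + n_perm)
  }
  list(phi_pt = phi_obs, p_value = p_val, n_perm = n_perm, ss = ss)
}

#' Pairwise Phi_PT differentiation matrix
#'
#' Applies [phi_pt()] to every pair of populations and assembles the
#' symmetric population-level differentiation matrix used by the Mantel and
#' GAMOVA stages.
#'
#' @inheritParams phi_pt
#' @param n_perm permutations per pair; 0 (default) skips per-pair p-values,
#'   which are not needed downstream.
#' @return a [dist_matrix()] of kind `"phi_pt"`; per-pair p-values (if
#'   computed) in `attr(, "p_values")`.
#' @export
pairwise_phi_pt <- function(mm, n_perm = 0, seed = 1L) {
  pops <- levels(mm$pop)
  k <- length(pops)
  m <- matrix(0, k, k, dimnames = list(pops, pops))
  pv <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      r <- phi_pt(mm, pops = pops[c(i, j)], n_perm = n_perm,
                  seed = seed + 1000L * i + j)
      m[i, j] <- m[j, i] <- r$phi_pt
      pv[i, j] <- pv[j, i] <- r$p_value
    }
  }
  out <- dist_matrix(m, kind = "phi_pt")
  attr(out, "p_values") <- pv
  out
}

#' Principal coordinates analysis on Bray-Curtis distances
#'
#' Classical scaling (PCoA) of pairwise Bray-Curtis distances between
#' individual band profiles, the standard ordination for binary fingerprint
#' data. Negative eigenvalues are reported, not corrected; axis variance
#' percentages are relative to the sum of positive eigenvalues.
#'
#' @param mm a [marker_matrix()].
#' @param n_axes number of coordinate axes to return.
#' @return list with `coords` (individuals x axes), `eig`, and `pct_var`.
#' @export
bray_curtis_pcoa <- function(mm, n_axes = 2) {
  bands <- mm$bands
  stopifnot(nrow(bands) >= 3)
  d <- suppressWarnings(vegan::vegdist(bands, method = "bray", na.rm = TRUE))
  if (anyNA(d)) {
    warning("individuals with no bands: undefined Bray-Curtis distances set to 0")
    d[is.na(d)] <- 0
  }
  if (all(d == 0)) {
    k <- min(n_axes, nrow(bands) - 1)
    return(list(coords = matrix(0, nrow(bands), k,
                                dimnames = list(rownames(bands), NULL)),
                eig = rep(0, nrow(bands) - 1), pct_var = rep(NA_real_, k)))
  }
  sc <- cmdscale(d, k = n_axes, eig = TRUE)
  pos <- sum(sc$eig[sc$eig > 0])
  k_got <- ncol(sc$points)
  list(coords = sc$points, eig = sc$eig,
       pct_var = 100 * sc$eig[seq_len(k_got)] / pos)
}

#' Replicate error rate of a band-scoring run
#'
#' Mean, over replicate pairs, of the fraction of loci at which the two
#' profiles of a pair disagree - the standard reproducibility figure for
#' automated band scoring.
#'
#' @param mm a [marker_matrix()].
#' @param pairs two-column matrix (or data.frame) of individual ids forming
#'   replicate pairs; defaults to `attr(mm, "replicate_pairs")`.
#' @return list with `rate`, per-pair rates `per_pair`, and `n_pairs`.
#' @export
replicate_error_rate <- function(mm, pairs = attr(mm, "replicate_pairs")) {
  if (is.null(pairs) || nrow(pairs) == 0) stop("no replicate pairs available")
  pairs <- as.matrix(pairs)
  per <- apply(pairs, 1, function(pr) {
    a <- mm$bands[pr[1], ]
    b <- mm$bands[pr[2], ]
    ok <- !is.na(a) & !is.na(b)
    mean(a[ok] != b[ok])
  })
  list(rate = mean(per), per_pair = per, n_pairs = nrow(pairs))
}
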