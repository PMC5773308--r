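# Dominant-marker popgen statistics: frequency estimation, F_ST/He, Phi_PT,
# PCoA, replicate error rate.

test_that("band-absence frequency estimator matches independent oracles", {
  # closed form for the uniform prior: q = B(m+1, n-m+1) / B(m+1/2, n-m+1)
  for (case in list(c(0, 4), c(5, 10), c(3, 20), c(50, 50), c(17, 18))) {
    m <- case[1]; n <- case[2]
    oracle <- exp(lbeta(m + 1, n - m + 1) - lbeta(m + 0.5, n - m + 1))
    expect_equal(estimate_band_allele_freq(m, n), oracle, tolerance = 1e-8)
  }
  # direct quadrature oracle at 1e-10, no log-scaling trick
  quad <- function(m, n) {
    num <- integrate(function(q) q * (q^2)^m * (1 - q^2)^(n - m), 0, 1,
                     rel.tol = 1e-10)$value
    den <- integrate(function(q) (q^2)^m * (1 - q^2)^(n - m), 0, 1,
                     rel.tol = 1e-10)$value
    num / den
  }
  expect_equal(estimate_band_allele_freq(5, 10), quad(5, 10),
               tolerance = 1e-8)
  expect_gt(estimate_band_allele_freq(50, 50), 0.95)
  # posterior equals the prior with no data; never exactly 0 or 1
  expect_equal(estimate_band_allele_freq(0, 0), 0.5)
  expect_equal(estimate_band_allele_freq(0, 0, prior = c(2, 6)), 0.25)
  expect_gt(estimate_band_allele_freq(0, 30), 0)
  expect_lt(estimate_band_allele_freq(30, 30), 1)
  expect_error(estimate_band_allele_freq(5, 3), "m_absent")
})

test_that("locus F_ST and He follow the variance-components formula", {
  expect_equal(locus_fst_he(c(0.3, 0.3, 0.3))$fst, 0)
  near_one <- locus_fst_he(c(0.001, 0.999), c(1000, 1000))
  expect_gt(near_one$fst, 0.98)
  # independent evaluation of the corrected variance ratio
  p <- c(0.2, 0.4, 0.6); n <- c(20, 20, 20)
  w <- n / sum(n)
  p_bar <- sum(w * p)
  s2 <- sum(w * (p - p_bar)^2) / (1 - sum(w^2))
  fst_oracle <- (s2 - mean(p * (1 - p) / (2 * n))) / (p_bar * (1 - p_bar))
  res <- locus_fst_he(p, n)
  expect_equal(res$fst, fst_oracle, tolerance = 1e-12)
  expect_equal(res$he, 2 * p_bar * (1 - p_bar))
  # rational-frequency grid, 3 populations
  for (pp in list(c(1, 2, 3) / 10, c(1, 5, 9) / 10, c(2, 2, 8) / 10)) {
    w3 <- rep(1 / 3, 3)
    pb <- mean(pp)
    or <- (sum(w3 * (pp - pb)^2) / (1 - sum(w3^2)) -
             mean(pp * (1 - pp) / 30)) / (pb * (1 - pb))
    expect_equal(locus_fst_he(pp, rep(15, 3))$fst, or, tolerance = 1e-12)
  }
})

test_that("Phi_PT matches a brute-force variance-components oracle", {
  mm <- toy_marker_matrix()
  res <- phi_pt(mm, n_perm = 999, seed = 7)
  expect_equal(res$phi_pt, brute_phi_pt(mm$bands, mm$pop), tolerance = 1e-12)
  # exhaustive permutation p over all choose(6,3) relabelings
  combs <- combn(6, 3)
  phis <- apply(combs, 2, function(idx) {
    g <- rep("B", 6); g[idx] <- "A"
    brute_phi_pt(mm$bands, g)
  })
  p_exact <- mean(phis >= res$phi_pt - 1e-12)
  expect_lt(abs(res$p_value - p_exact), 0.05)
})

test_that("Phi_PT handles degenerate and extreme configurations", {
  # all among-population variance
  bands <- rbind(matrix(0L, 3, 4), matrix(1L, 3, 4))
  rownames(bands) <- paste0("i", 1:6)
  mm <- marker_matrix(bands, setNames(rep(c("A", "B"), each = 3),
                                      rownames(bands)))
  expect_equal(phi_pt(mm, n_perm = 0)$phi_pt, 1)
  # all individuals identical
  same <- matrix(1L, 6, 4, dimnames = list(paste0("i", 1:6), NULL))
  mm2 <- marker_matrix(same, setNames(rep(c("A", "B"), each = 3),
                                      rownames(same)))
  expect_warning(res <- phi_pt(mm2, n_perm = 0), "identical")
  expect_equal(res$phi_pt, 0)
  # population of size 1 is an error naming it
  mm3 <- marker_matrix(bands, setNames(c("A", "A", "A", "B", "B", "C"),
                                       rownames(bands)))
  expect_error(phi_pt(mm3, n_perm = 0), "C")
})

test_that("pairwise Phi_PT is symmetric and order-invariant", {
  set.seed(31)
  meta <- small_meta()
  sim <- gen_aflp(meta, n_neutral = 40, n_selected = 0,
                  n_ind = rep(6L, 6), n_replicate_pairs = 0, seed = 5)
  d <- pairwise_phi_pt(sim$markers)
  expect_equal(d$mat, t(d$mat), tolerance = 1e-12)
  expect_true(all(diag(d$mat) == 0))
  expect_equal(length(d$labels) * (length(d$labels) - 1) / 2, 15)
  # permute individuals and loci: identical matrix
  perm_i <- sample(nrow(sim$markers$bands))
  perm_l <- sample(ncol(sim$markers$bands))
  mm2 <- marker_matrix(sim$markers$bands[perm_i, perm_l],
                       sim$markers$pop[perm_i])
  d2 <- pairwise_phi_pt(mm2)
  expect_equal(d$mat, d2$mat, tolerance = 1e-12)
})

test_that("Bray-Curtis PCoA reproduces hand-computable geometries", {
  # hand formula: BC = 1 - 2W / (A + B)
  bands <- rbind(c(1L, 1L, 0L), c(0L, 1L, 1L), c(1L, 1L, 0L))
  rownames(bands) <- paste0("i", 1:3)
  mm <- marker_matrix(bands, setNames(c("A", "A", "B"), rownames(bands)))
  d <- vegan::vegdist(bands, "bray")
  expect_equal(as.vector(d)[1], 0.5)
  # identical individuals: zero coordinates
  same <- matrix(1L, 4, 3, dimnames = list(paste0("i", 1:4), NULL))
  mm2 <- marker_matrix(same, setNames(rep(c("A", "B"), 2), rownames(same)))
  res <- bray_curtis_pcoa(mm2)
  expect_true(all(res$coords == 0))
  # three equidistant individuals: two equal positive eigenvalues
  tri <- rbind(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))
  rownames(tri) <- paste0("i", 1:3)
  mm3 <- marker_matrix(tri, setNames(c("A", "A", "B"), rownames(tri)))
  res3 <- bray_curtis_pcoa(mm3, n_axes = 2)
  pos <- res3$eig[res3$eig > 1e-10]
  expect_equal(length(pos), 2)
  expect_equal(pos[1], pos[2], tolerance = 1e-10)
})

test_that("replicate error rate counts mismatches", {
  bands <- matrix(0L, 4, 100, dimnames = list(paste0("i", 1:4), NULL))
  bands[2, 1:9] <- 1L   # pair (1,2) differs at 9 of 100
  mm <- marker_matrix(bands, setNames(rep("A", 4), rownames(bands)),
                      replicate_pairs = cbind(c("i1", "i3"), c("i2", "i4")))
  res <- replicate_error_rate(mm)
  expect_equal(res$per_pair, c(0.09, 0))
  expect_equal(res$rate, 0.045)
  expect_error(replicate_error_rate(toy_marker_matrix()), "pairs")
})

test_that("simulated replicate pairs recover the generating error rate", {
  meta <- gen_metadata(seed = 2)
  sim <- gen_aflp(meta, n_neutral = 732, n_selected = 0, error_rate = 0.09,
                  n_replicate_pairs = 24, seed = 9)
  res <- replicate_error_rate(sim$replicates)
  # binomial CI for 24 * 732 Bernoulli flips at 0.09
  se <- sqrt(0.09 * 0.91 / (24 * 732))
  expect_lt(abs(res$rate - 0.09), 4 * se)
})

test_that("mean pairwise Phi_PT increases with the simulated background F", {
  meta <- small_meta()
  means <- vapply(c(0.01, 0.05, 0.2), function(f) {
    sim <- gen_aflp(meta, n_neutral = 500, n_selected = 0,
                    fst_background = f, n_ind = rep(8L, 6),
                    n_replicate_pairs = 0, seed = 400 + round(1000 * f))
    d <- pairwise_phi_pt(sim$markers)
    mean(d$mat[lower.tri(d$mat)])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
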