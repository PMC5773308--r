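# Elliptic Fourier analysis, Procrustes alignment, shape PCA, scalars.

unit_circle <- function(n = 256) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cos(th), sin(th))
}

test_that("outline resampling is uniform, idempotent and length-true", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  r8 <- resample_outline(sq, 8)
  expect_equal(r8[c(1, 3, 5, 7), ], sq, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(r8[2, ], c(0.5, 0), tolerance = 1e-12)
  # perimeter of a circle preserved within 0.1%
  rc <- resample_outline(unit_circle(512), 256)
  per <- sum(sqrt(rowSums(diff(rbind(rc, rc[1, ]))^2)))
  expect_lt(abs(per - 2 * pi) / (2 * pi), 0.001)
  # idempotency on an already-uniform outline
  r2 <- resample_outline(rc, 256)
  expect_equal(r2, rc, tolerance = 1e-10)
  expect_error(resample_outline(rbind(c(0, 0), c(0, 0), c(0, 0)), 8),
               "degenerate")
})

test_that("first-harmonic power dominates for elliptical outlines", {
  # a circle is a pure first harmonic under arc-length parameterization
  efc0 <- efa_transform(unit_circle(256), n_harmonics = 64,
                        normalize = FALSE)
  expect_gt(efc0$power[1] / sum(efc0$power), 1 - 1e-9)
  # an eccentric ellipse is traversed non-uniformly in angle by arc
  # length, so a small part of the power moves to higher harmonics; the
  # first harmonic still dominates overwhelmingly
  th <- seq(0, 2 * pi, length.out = 257)[-257]
  for (a in c(1.2, 2.5)) {
    ell <- cbind(a * cos(th), sin(th))
    ef <- efa_transform(ell, n_harmonics = 64, normalize = FALSE)
    expect_gt(ef$power[1] / sum(ef$power), 0.98)
  }
  # circle: coefficients match the closed-form parameterization
  efc <- efa_transform(unit_circle(1024), n_harmonics = 8,
                       normalize = FALSE)
  expect_equal(efc$an[1], 1, tolerance = 1e-4)
  expect_equal(efc$dn[1], 1, tolerance = 1e-4)
  expect_equal(efc$bn[1], 0, tolerance = 1e-6)
  expect_equal(efc$cn[1], 0, tolerance = 1e-6)
  expect_lt(max(abs(c(efc$an[-1], efc$dn[-1]))), 1e-4)
})

test_that("first-harmonic normalization leaves a canonical ellipse", {
  th <- seq(0, 2 * pi, length.out = 257)[-257]
  rot <- function(xy, ang) xy %*% matrix(c(cos(ang), sin(ang),
                                           -sin(ang), cos(ang)), 2)
  ell <- rot(cbind(2.5 * cos(th + 0.7), sin(th + 0.7)), 0.9) * 3.2
  ef <- efa_transform(ell, n_harmonics = 10)
  expect_equal(ef$an[1], 1, tolerance = 1e-9)
  expect_lt(abs(ef$bn[1]), 1e-8)
  expect_lt(abs(ef$cn[1]), 1e-8)
  # the recorded scale tracks the first-harmonic semi-major axis: exactly
  # linear in outline size, close to the geometric semi-major axis
  ef_unit <- efa_transform(ell / 3.2, n_harmonics = 10)
  expect_equal(ef$norm$scale / ef_unit$norm$scale, 3.2, tolerance = 1e-9)
  expect_equal(ef$norm$scale, 2.5 * 3.2, tolerance = 0.15)
})

test_that("cumulative power is monotone and high for lobed leaves", {
  sh <- gen_shapes(n_per_pop = 3, aspect_by_pop = c(p = 2.5), lobing = 0.2,
                   n_lobes = 9, n_points = 512, seed = 51)
  for (leaf in sh$leaves) {
    out <- resample_outline(leaf, 512)
    ef <- efa_transform(out, n_harmonics = 256, normalize = FALSE)
    expect_true(all(diff(ef$cum_power_frac) >= -1e-15))
    expect_equal(ef$cum_power_frac[256], 1, tolerance = 1e-12)
    expect_gte(ef$cum_power_frac[15], 0.99)
  }
})

test_that("Fourier reconstruction error shrinks with harmonic count", {
  circ <- unit_circle(256)
  ef1 <- efa_transform(circ, n_harmonics = 1, normalize = FALSE)
  rec <- efa_reconstruct(ef1, n_points = 256)
  expect_lt(max(abs(rec - circ)), 1e-4)
  leaf <- gen_shapes(1, c(p = 2.5), lobing = 0.2, seed = 52)$leaves[[1]]
  out <- resample_outline(leaf, 256)
  ef <- efa_transform(out, n_harmonics = 15, normalize = FALSE)
  err <- function(h) {
    rec <- efa_reconstruct(ef, n_points = 256, n_harmonics = h)
    mean(sqrt(rowSums((rec - out)^2)))
  }
  expect_lt(err(15), err(5))
})

test_that("Procrustes alignment removes similarity transforms", {
  set.seed(53)
  base <- matrix(rnorm(20), 10, 2)
  ang <- 37 * pi / 180
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  copy <- sweep(base %*% R * 3, 2, c(5, -2), "+")
  g <- gpa_align(list(base, copy))
  expect_lt(max(abs(g$aligned[[1]] - g$aligned[[2]])), 1e-8)
  # consensus of two shapes is their aligned average (up to unit scaling)
  avg <- (g$aligned[[1]] + g$aligned[[2]]) / 2
  expect_equal(g$consensus, avg / sqrt(sum(avg^2)), tolerance = 1e-8)
  # classic pair with a closed-form solution: the second triangle is the
  # first rotated 90 degrees and doubled, so the Procrustes distance is 0
  t1 <- rbind(c(0, 0), c(1, 0), c(0, 1))
  t2 <- rbind(c(0, 0), c(0, 2), c(-2, 0))
  g2 <- gpa_align(list(t1, t2))
  expect_lt(sqrt(sum((g2$aligned[[1]] - g2$aligned[[2]])^2)), 1e-8)
  expect_error(gpa_align(list(t1, matrix(1, 3, 2))), "centroid")
})

test_that("alignment result does not depend on configuration order", {
  set.seed(54)
  shapes <- lapply(1:5, function(i) matrix(rnorm(16), 8, 2))
  g1 <- gpa_align(shapes)
  g2 <- gpa_align(shapes[c(3, 1, 5, 2, 4)])
  d1 <- as.vector(dist(t(sapply(g1$aligned, as.vector))))
  d2 <- as.vector(dist(t(sapply(g2$aligned[order(c(3, 1, 5, 2, 4))],
                                as.vector))))
  expect_equal(d1, d2, tolerance = 1e-8)
})

test_that("GPA is invariant to rotation of a noise-free flower", {
  f <- aflpselect:::flower_template(5)
  ang <- pi / 2
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  f90 <- f %*% R
  g <- gpa_align(list(f, f90))
  expect_lt(max(abs(g$aligned[[1]] - g$aligned[[2]])), 1e-8)
})

test_that("shape PCA matches a direct covariance eigensolve", {
  set.seed(55)
  x <- matrix(rnorm(5 * 6), 5, 6)
  res <- shape_pca(x, n_axes = 3)
  ev <- eigen(cov(x))
  expect_equal(res$pct_var, 100 * ev$values[1:3] / sum(ev$values),
               tolerance = 1e-10)
  ctr <- scale(x, scale = FALSE)
  for (j in 1:3) {
    expect_equal(abs(res$scores[, j]), abs(as.vector(ctr %*% ev$vectors[, j])),
                 ignore_attr = TRUE, tolerance = 1e-8)
  }
  # degenerate cases
  same <- matrix(1, 4, 6)
  expect_warning(r0 <- shape_pca(same, n_axes = 2), "axes")
  expect_true(all(abs(r0$scores) < 1e-12))
  two <- rbind(matrix(0, 2, 4), matrix(1, 2, 4))
  r2 <- shape_pca(two, n_axes = 3)
  expect_equal(sum(r2$pct_var > 1e-8), 1)
})

test_that("scalar measures are calibrated", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(leaf_area(sq), 1)
  expect_equal(leaf_area(sq, scale = 2.5), 6.25)
  expect_lt(abs(leaf_area(unit_circle(256)) - pi) / pi, 0.001)
  f <- aflpselect:::flower_template(5)
  expect_equal(petal_length(f), 5, tolerance = 1e-12)
  expect_equal(petal_length(f, scale = 2), 10, tolerance = 1e-12)
})

test_that("shape files round trip through the sidecar format", {
  sh <- gen_shapes(n_per_pop = 2, aspect_by_pop = c(pA = 2, pB = 3),
                   n_points = 64, seed = 56)
  dir <- tempfile()
  write_shape_files(sh$leaves, dir, scale = 1)
  back <- read_shape_files(dir)
  expect_setequal(names(back), names(sh$leaves))
  for (id in names(back)) {
    expect_equal(back[[id]], sh$leaves[[id]], ignore_attr = TRUE,
                 tolerance = 1e-8)
    expect_equal(attr(back[[id]], "population"),
                 attr(sh$leaves[[id]], "population"))
  }
  unlink(dir, recursive = TRUE)
})
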