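# Geographic distances, GAMOVA, Mantel, trait-climate regression, scenario
# classification.

test_that("great-circle distances use the 6371 km sphere", {
  pops <- data.frame(population_id = c("a", "b", "c"),
                     latitude = c(0, 0, 0), longitude = c(0, 90, 0))
  d <- geo_distance_matrix(pops)
  expect_equal(d$mat["a", "c"], 0)
  expect_lt(abs(d$mat["a", "b"] - 10007.5), 1)
  expect_equal(d$mat, t(d$mat))
  pops$latitude[2] <- NA
  expect_error(geo_distance_matrix(pops), "coordinate")
})

test_that("GAMOVA pseudo-F equals the classical regression F on 1-D data", {
  set.seed(61)
  for (rep in 1:3) {
    y <- rnorm(6)
    x <- rnorm(6)
    names(y) <- names(x) <- paste0("p", 1:6)
    D <- as.matrix(dist(y))
    dimnames(D) <- list(names(y), names(y))
    g <- gamova(dist_matrix(D, kind = "euclid"), x, n_perm = 99, seed = 62)
    f_lm <- summary(lm(y ~ x))$fstatistic[["value"]]
    expect_equal(g$pseudo_f, f_lm, tolerance = 1e-8)
  }
  # degenerate inputs
  tr <- setNames(rep(1, 6), paste0("p", 1:6))
  D <- as.matrix(dist(rnorm(6)))
  dimnames(D) <- list(names(tr), names(tr))
  expect_error(gamova(dist_matrix(D, "euclid"), tr), "constant")
  D3 <- D[1:3, 1:3]
  expect_error(gamova(dist_matrix(D3, "euclid"),
                      setNames(1:3, rownames(D3))), "4 populations")
})

test_that("GAMOVA agrees with an independent distance-matrix regression", {
  set.seed(63)
  pts <- matrix(rnorm(24), 8, 3)
  D <- as.matrix(dist(pts))
  dimnames(D) <- list(paste0("p", 1:8), paste0("p", 1:8))
  x <- setNames(rnorm(8), rownames(D))
  g <- gamova(dist_matrix(D, "euclid"), x, n_perm = 99, seed = 64)
  ad <- vegan::adonis2(as.dist(D) ~ x, permutations = 9,
                       data = data.frame(x = x))
  expect_equal(g$pseudo_f, ad$F[1], tolerance = 1e-8)
})

test_that("GAMOVA permutation p is calibrated under the null", {
  set.seed(65)
  D <- as.matrix(dist(rnorm(12)))
  dimnames(D) <- list(paste0("p", 1:12), paste0("p", 1:12))
  dm <- dist_matrix(D, "euclid")
  rej <- mean(vapply(1:400, function(b) {
    x <- setNames(rnorm(12), rownames(D))
    gamova(dm, x, n_perm = 99, seed = 1000 + b)$p_value <= 0.05
  }, logical(1)))
  expect_gte(rej, 0.02)
  expect_lte(rej, 0.08)
})

test_that("non-Euclidean differentiation matrices can go negative", {
  # strongly non-Euclidean: one huge off-block entry
  m <- matrix(0.01, 6, 6)
  diag(m) <- 0
  m[1, 2] <- m[2, 1] <- 5
  dimnames(m) <- list(paste0("p", 1:6), paste0("p", 1:6))
  tr <- setNames(c(0, 0, 1, 2, 3, 4), rownames(m))
  g <- gamova(dist_matrix(m, "phi_pt"), tr, n_perm = 199, seed = 66)
  expect_lt(g$pseudo_f, 0)
  expect_gt(g$p_value, 0.5)
})

test_that("Mantel r and p match exhaustive enumeration on 4 populations", {
  m1 <- matrix(c(0, 1, 4, 3,
                 1, 0, 2, 5,
                 4, 2, 0, 1,
                 3, 5, 1, 0), 4, 4)
  m2 <- matrix(c(0, 2, 3, 1,
                 2, 0, 1, 4,
                 3, 1, 0, 2,
                 1, 4, 2, 0), 4, 4)
  dimnames(m1) <- dimnames(m2) <- list(paste0("p", 1:4), paste0("p", 1:4))
  lt <- lower.tri(m1)
  r_obs <- cor(m1[lt], m2[lt])
  perms <- rbind(1:4)
  for (p in combinat_perms(4)) perms <- rbind(perms, p)
  perms <- unique(perms)
  r_all <- apply(perms, 1, function(idx) cor(m1[idx, idx][lt], m2[lt]))
  p_exact <- mean(r_all >= r_obs - 1e-12)
  res <- mantel_test(dist_matrix(m1, "phi_pt"), dist_matrix(m2, "geo_km"),
                     n_perm = 9999, seed = 67)
  expect_equal(res$r_xy, r_obs, tolerance = 1e-12)
  expect_lt(abs(res$p_value - p_exact), 0.02)
})

test_that("Mantel is exact under identity and affine maps", {
  D <- as.matrix(dist(rnorm(7)))
  dimnames(D) <- list(paste0("p", 1:7), paste0("p", 1:7))
  d1 <- dist_matrix(D, "geo_km")
  expect_equal(mantel_test(d1, d1, n_perm = 99, seed = 68)$r_xy, 1)
  d2 <- dist_matrix(3 * D, "geo_km")
  expect_equal(mantel_test(d1, d2, n_perm = 99, seed = 69)$r_xy, 1)
  flat <- dist_matrix(matrix(0, 7, 7,
                             dimnames = dimnames(D)), "phi_pt")
  expect_error(mantel_test(d1, flat, n_perm = 99), "constant")
})

test_that("Mantel agrees with the vegan implementation", {
  set.seed(70)
  m1 <- as.matrix(dist(rnorm(9)))
  m2 <- as.matrix(dist(rnorm(9)))
  dimnames(m1) <- dimnames(m2) <- list(paste0("p", 1:9), paste0("p", 1:9))
  ours <- mantel_test(dist_matrix(m1, "geo_km"), dist_matrix(m2, "geo_km"),
                      n_perm = 999, seed = 71)
  ref <- vegan::mantel(as.dist(m1), as.dist(m2), permutations = 999)
  expect_equal(ours$r_xy, unname(ref$statistic), tolerance = 1e-10)
})

test_that("trait-climate regression matches hand-computed OLS", {
  x <- c(p1 = 100, p2 = 130, p3 = 150, p4 = 180, p5 = 200)
  y <- c(p1 = 2.1, p2 = 2.8, p3 = 3.1, p4 = 4.0, p5 = 4.2)
  # normal equations by hand
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxx <- sum((x - mean(x))^2)
  b <- sxy / sxx
  a <- mean(y) - b * mean(x)
  r2 <- sxy^2 / (sxx * sum((y - mean(y))^2))
  res <- trait_env_regression(y, x)
  expect_equal(res$slope, b, tolerance = 1e-12)
  expect_equal(res$intercept, a, tolerance = 1e-12)
  expect_equal(res$r_squared, r2, tolerance = 1e-12)
  # collinear points
  y2 <- 0.01 * x + 3
  expect_equal(trait_env_regression(y2, x)$r_squared, 1, tolerance = 1e-12)
  # drop list honored
  res_d <- trait_env_regression(y, x, drop = "p1")
  expect_equal(res_d$n, 4)
  expect_equal(res_d$dropped, "p1")
  expect_error(trait_env_regression(y[1:2], x[1:2]), "3 populations")
})

test_that("scenario classification is a total deterministic decision table", {
  expect_equal(classify_scenario(TRUE, FALSE, TRUE, TRUE)$scenario, "1.1")
  expect_equal(classify_scenario(TRUE, FALSE, TRUE, FALSE)$scenario, "1.1")
  expect_equal(classify_scenario(TRUE, FALSE, FALSE, TRUE)$scenario, "1.2")
  expect_equal(classify_scenario(TRUE, TRUE, TRUE, TRUE)$scenario, "2")
  expect_equal(classify_scenario(TRUE, TRUE, FALSE, FALSE)$scenario, "2")
  expect_equal(classify_scenario(FALSE, TRUE, FALSE, TRUE)$scenario, "3.1")
  expect_equal(classify_scenario(FALSE, TRUE, TRUE, FALSE)$scenario, "3.2")
  expect_equal(classify_scenario(FALSE, FALSE, FALSE, FALSE)$scenario,
               "no_signal")
  # totality: all 16 combinations map to exactly one scenario
  grid <- expand.grid(a = c(TRUE, FALSE), b = c(TRUE, FALSE),
                      c = c(TRUE, FALSE), d = c(TRUE, FALSE))
  calls <- apply(grid, 1, function(r) {
    classify_scenario(r[1], r[2], r[3], r[4])$scenario
  })
  expect_equal(length(calls), 16)
  expect_true(all(calls %in% c("1.1", "1.2", "2", "3.1", "3.2",
                               "no_signal")))
  expect_true(all(nzchar(vapply(
    calls, function(s) aflpselect:::scenario_interpretations[[s]], ""))))
})
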