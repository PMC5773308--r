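# Distance-matrix inference: geographic distances, GAMOVA (multivariate
# distance-matrix regression with permutation pseudo-F), Mantel tests,
# trait-climate regression, and the scenario classifier.

#' Great-circle distance matrix between populations
#'
#' Pairwise haversine distances (Earth radius 6371 km) from population
#' coordinates.
#'
#' @param pops population map with `population_id`, `latitude`, `longitude`.
#' @return a [dist_matrix()] of kind `"geo_km"`.
#' @export
geo_distance_matrix <- function(pops) {
  if (anyNA(pops$latitude) || anyNA(pops$longitude)) {
    stop("missing coordinate(s)")
  }
  xy <- cbind(pops$longitude, pops$latitude)
  m <- geosphere::distm(xy, xy,
                        fun = function(a, b)
                          geosphere::distHaversine(a, b, r = 6371000)) / 1000
  m[abs(m) < 1e-9] <- 0
  m <- (m + t(m)) / 2
  dimnames(m) <- list(pops$population_id, pops$population_id)
  dist_matrix(m, kind = "geo_km")
}

#' GAMOVA: distance-matrix regression with permutation pseudo-F
#'
#' Regresses a population-level distance matrix (typically pairwise Phi_PT)
#' on a single quantitative trait (population means) via Gower-centered
#' inner products: with `G = -1/2 J D^2 J` (J the centering matrix) and hat
#' matrix `H` from the design `[1, trait]`, the statistic is
#' `pseudo-F = tr(H G H) / tr((I-H) G (I-H)) * (n - 2)`. Significance is
#' assessed by permuting trait values across populations;
#' `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm)`. Non-Euclidean distance
#' matrices can yield negative pseudo-F values; they are retained.
#'
#' @param D a [dist_matrix()] (or square symmetric matrix) over populations.
#' @param trait named numeric vector of per-population trait values, labels
#'   matching `D`.
#' @param n_perm number of trait permutations.
#' @param seed integer seed for the permutation stream.
#' @return list of class `gamova_result`: `pseudo_f`, `p_value`, `n_perm`.
#' @export
gamova <- function(D, trait, n_perm = 9999, seed = 1L) {
  m <- if (inherits(D, "dist_matrix")) D$mat else as.matrix(D)
  labs <- rownames(m)
  if (!is.null(names(trait))) trait <- trait[labs]
  n <- nrow(m)
  if (n < 4) stop("need at least 4 populations (no residual df)")
  if (anyNA(trait) || length(trait) != n) stop("trait does not match matrix")
  if (sd(trait) == 0) stop("constant trait")
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% (m * m) %*% J
  f_stat <- function(x) {
    X <- cbind(1, x)
    H <- X %*% solve(crossprod(X), t(X))
    IH <- diag(n) - H
    num <- sum(diag(H %*% G %*% H))
    den <- sum(diag(IH %*% G %*% IH))
    num / den * (n - 2)
  }
  f_obs <- f_stat(trait)
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    if (f_stat(trait[sample.int(n)]) >= f_obs) hits <- hits + 1L
  }
  structure(list(pseudo_f = f_obs, p_value = (1 + hits) / (1 + n_perm),
                 n_perm = n_perm), class = "gamova_result")
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation `r_xy` over the strict lower triangles of two
#' distance matrices with matching labels, with significance from
#' simultaneous row/column permutations of one matrix;
#' `p = (1 + #\{r_perm >= r_obs\}) / (1 + n_perm)` (one-sided, positive
#' association).
#'
#' @param D1,D2 [dist_matrix()] objects (or square symmetric matrices) with
#'   identical labels in identical order.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list of class `mantel_result`: `r_xy`, `p_value`, `n_perm`.
#' @export
mantel_test <- function(D1, D2, n_perm = 9999, seed = 1L) {
  m1 <- if (inherits(D1, "dist_matrix")) D1$mat else as.matrix(D1)
  m2 <- if (inherits(D2, "dist_matrix")) D2$mat else as.matrix(D2)
  stopifnot(identical(dim(m1), dim(m2)))
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2))) {
    stop("matrix labels do not match")
  }
  n <- nrow(m1)
  lt <- lower.tri(m1)
  if (sd(m1[lt]) == 0 || sd(m2[lt]) == 0) {
    stop("constant lower triangle; correlation undefined")
  }
  r_obs <- cor(m1[lt], m2[lt])
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    hits <- hits + (cor(m1[idx, idx][lt], m2[lt]) >= r_obs)
  }
  structure(list(r_xy = r_obs, p_value = (1 + hits) / (1 + n_perm),
                 n_perm = n_perm), class = "mantel_result")
}

#' Ordinary least-squares regression of trait means on a climate variable
#'
#' Simple linear regression of per-population trait means on one bioclimatic
#' variable, optionally after dropping named populations (outlying sites are
#' sometimes omitted to reveal the underlying trend; the drop list is
#' recorded in the result).
#'
#' @param trait_means named numeric vector (population ids as names).
#' @param env_values named numeric vector of the climate variable.
#' @param drop optional population ids to omit.
#' @return list with `slope`, `intercept`, `r_squared`, `n`, `dropped`.
#' @export
trait_env_regression <- function(trait_means, env_values, drop = NULL) {
  common <- intersect(names(trait_means), names(env_values))
  common <- setdiff(common, drop)
  if (length(common) < 3) stop("fewer than 3 populations after drops")
  y <- trait_means[common]
  x <- env_values[common]
  fit <- lm(y ~ x)
  ssr <- sum(residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = 1 - ssr / sst, n = length(common),
       dropped = if (is.null(drop)) character(0) else drop)
}

scenario_interpretations <- c(
  "1.1" = "phenotypic divergence driven by selection along a geographical cline",
  "1.2" = "phenotypic divergence driven by local (non-clinal) selection",
  "2" = "selection and neutral processes confounded; neutral variation cannot be excluded",
  "3.1" = "phenotypic divergence driven by neutral geographical processes (IBD, founder effects, phylogeography)",
  "3.2" = "phenotypic divergence attributable to chance",
  "no_signal" = "no significant association with either locus set")

#' Classify a trait into a divergence scenario
#'
#' Total, deterministic decision table over the four significance flags that
#' the dual-GAMOVA / Mantel design produces for a trait: GAMOVA against the
#' selected-locus and the neutral-locus differentiation matrices, and Mantel
#' isolation-by-distance tests for the two locus sets.
#'
#' * selected +, neutral -, Mantel(selected) + : scenario 1.1 (clinal
#'   selection)
#' * selected +, neutral -, Mantel(selected) - : scenario 1.2 (local
#'   selection)
#' * selected +, neutral + : scenario 2 (confounded; neutral variation not
#'   excluded)
#' * selected -, neutral +, Mantel(neutral) + : scenario 3.1 (neutral
#'   geography)
#' * selected -, neutral +, Mantel(neutral) - : scenario 3.2 (chance)
#' * selected -, neutral - : no_signal (no test reaches significance)
#'
#' @param gamova_sel,gamova_neut significance flags of the GAMOVA tests on
#'   the selected and neutral locus sets.
#' @param mantel_sel,mantel_neut significance flags of the Mantel tests.
#' @return list of class `scenario_call`: `scenario`, `interpretation`, and
#'   the four `flags`.
#' @export
classify_scenario <- function(gamova_sel, gamova_neut, mantel_sel,
                              mantel_neut) {
  stopifnot(is.logical(gamova_sel), is.logical(gamova_neut),
            is.logical(mantel_sel), is.logical(mantel_neut))
  scenario <- if (gamova_sel && !gamova_neut) {
    if (mantel_sel) "1.1" else "1.2"
  } else if (gamova_sel && gamova_neut) {
    "2"
  } else if (!gamova_sel && gamova_neut) {
    if (mantel_neut) "3.1" else "3.2"
  } else {
    "no_signal"
  }
  structure(list(scenario = scenario,
                 interpretation = unname(scenario_interpretations[scenario]),
                 flags = c(gamova_sel = gamova_sel,
                           gamova_neut = gamova_neut,
                           mantel_sel = mantel_sel,
                           mantel_neut = mantel_neut)),
            class = "scenario_call")
}

#' @export
print.scenario_call <- function(x, ...) {
  cat(sprintf("scenario %s: %s\n", x$scenario, x$interpretation))
  invisible(x)
}
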