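# Environment-allele association: climate PCA and univariate logistic scans
# with likelihood-ratio (G) and Wald tests.

#' Principal component analysis of climate variables
#'
#' Standardizes the bioclimatic columns (zero mean, unit variance), performs
#' the decomposition by singular values, and applies a deterministic sign
#' convention (the largest-magnitude loading of each component is positive).
#' Constant columns are dropped with a warning. The leading components
#' (PC1-PC3 by convention) serve as derived environmental variables for the
#' association scan.
#'
#' @param climate a climate table (one row per population) with a
#'   `population_id` column.
#' @param include_coords also include `latitude` and `longitude` as input
#'   variables (default TRUE, mirroring the usual practice of adding the
#'   sample coordinates).
#' @return object of class `climate_pca`: list with `scores` (populations x
#'   components, rownames = population ids), `loadings`, `pct_var`, and
#'   `variables`.
#' @export
climate_pca <- function(climate, include_coords = TRUE) {
  stopifnot(nrow(climate) >= 3)
  vars <- grep("^bio[0-9]+$", names(climate), value = TRUE)
  if (include_coords) {
    vars <- c(vars, intersect(c("latitude", "longitude"), names(climate)))
  }
  x <- as.matrix(climate[vars])
  stopifnot(is.numeric(x))
  keep <- apply(x, 2, function(col) sd(col) > 0)
  if (!all(keep)) {
    warning("dropping constant column(s): ",
            paste(vars[!keep], collapse = ", "))
    x <- x[, keep, drop = FALSE]
    vars <- vars[keep]
  }
  if (ncol(x) < 1) stop("no variable with positive variance")
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  scores <- pc$x
  load <- pc$rotation
  for (j in seq_len(ncol(load))) {
    if (load[which.max(abs(load[, j])), j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- climate$population_id
  structure(list(scores = scores, loadings = load,
                 pct_var = 100 * pc$sdev^2 / sum(pc$sdev^2),
                 variables = vars),
            class = "climate_pca")
}

# one logistic fit y ~ 1 + x with G and Wald statistics; IRLS via glm.fit
logistic_one <- function(y, x) {
  if (sd(x) == 0) {
    # null model equals full model
    p0 <- mean(y)
    return(c(intercept = if (p0 > 0 && p0 < 1) log(p0 / (1 - p0)) else NA,
             beta = 0, g = 0, wald = 0, converged = 1))
  }
  X <- cbind(1, x)
  fit <- suppressWarnings(
    glm.fit(X, y, family = binomial(),
            control = list(epsilon = 1e-8, maxit = 50L)))
  beta <- unname(fit$coefficients[2])
  eta <- fit$linear.predictors
  separated <- !fit$converged || max(abs(eta)) > 25 || abs(beta) > 15
  g <- fit$null.deviance - fit$deviance
  g <- max(g, 0)
  wald <- NA_real_
  if (!separated) {
    w <- fit$weights
    xtwx <- crossprod(X * sqrt(w))
    cov <- tryCatch(chol2inv(chol(xtwx)), error = function(e) NULL)
    if (!is.null(cov)) wald <- unname(beta^2 / cov[2, 2])
  }
  c(intercept = unname(fit$coefficients[1]), beta = beta,
    g = g, wald = wald, converged = as.numeric(!separated))
}

#' Univariate logistic environment-allele scans
#'
#' For every (locus, variable) pair, fits a logistic regression of
#' individual band presence/absence on the environmental value the
#' individual inherits from its population, and evaluates the association
#' with both a log-likelihood-ratio test (`G = 2 (l_full - l_null)`) and a
#' Wald test (`(beta / SE)^2`), each against chi-squared with 1 df. The
#' per-model significance threshold is Bonferroni-corrected by the total
#' number of models (loci x variables); a pair is significant only if both
#' tests pass (configurable). Loci fixed across all individuals are
#' skipped, as are constant environmental variables. Complete separation is
#' detected from diverging coefficients: the model is flagged non-converged
#' and its Wald test marked unusable, with G reported from the capped fit.
#'
#' @param mm a [marker_matrix()].
#' @param env data.frame of environmental variables: one row per population
#'   (with `population_id`) or one row per individual (with `individual`).
#'   Typically the bioclim columns plus the first three [climate_pca()]
#'   scores.
#' @param alpha family significance level before Bonferroni correction.
#' @param both_tests require both G and Wald to pass (default TRUE).
#' @param skip_loci locus ids to exclude from the scan.
#' @return list with `table` (one row per locus x variable: coefficients,
#'   `g`, `wald`, p-values, `significant`, `converged`), `threshold` (the
#'   per-model level), `n_models`, and `selected` (locus ids significant for
#'   at least one variable).
#' @export
logistic_scan <- function(mm, env, alpha = 0.05, both_tests = TRUE,
                          skip_loci = character(0)) {
  bands <- mm$bands
  if ("individual" %in% names(env)) {
    env_ind <- env[match(rownames(bands), env$individual), , drop = FALSE]
  } else if ("population_id" %in% names(env)) {
    env_ind <- env[match(as.character(mm$pop), env$population_id), ,
                   drop = FALSE]
  } else {
    stop("env needs a population_id or individual column")
  }
  vars <- names(env)[vapply(env, is.numeric, logical(1))]
  const <- vars[vapply(vars, function(v) sd(env_ind[[v]]) == 0, logical(1))]
  if (length(const)) {
    warning("skipping constant environmental variable(s): ",
            paste(const, collapse = ", "))
    vars <- setdiff(vars, const)
  }
  if (!length(vars)) stop("no usable environmental variable")
  poly <- setdiff(colnames(bands)[apply(bands, 2, function(x) {
    x <- x[!is.na(x)]
    length(x) > 0 && max(x) != min(x)
  })], skip_loci)
  n_models <- length(poly) * length(vars)
  threshold <- alpha / n_models
  stats <- matrix(NA_real_, n_models, 5)
  r <- 0L
  for (v in vars) {
    xv <- env_ind[[v]]
    for (loc in poly) {
      y <- bands[, loc]
      ok <- !is.na(y)
      r <- r + 1L
      stats[r, ] <- logistic_one(y[ok], xv[ok])
    }
  }
  tab <- data.frame(
    locus = rep(poly, times = length(vars)),
    variable = rep(vars, each = length(poly)),
    intercept = stats[, 1], beta = stats[, 2], g = stats[, 3],
    wald = stats[, 4], converged = stats[, 5] == 1,
    stringsAsFactors = FALSE)
  tab$p_g <- pchisq(tab$g, df = 1, lower.tail = FALSE)
  tab$p_wald <- pchisq(tab$wald, df = 1, lower.tail = FALSE)
  sig_g <- tab$p_g < threshold
  sig_w <- !is.na(tab$p_wald) & tab$p_wald < threshold
  tab$significant <- if (both_tests) sig_g & sig_w else sig_g
  sel <- sort(unique(tab$locus[tab$significant]))
  list(table = tab, threshold = threshold, n_models = n_models,
       selected = sel)
}
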