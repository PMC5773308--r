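# End-to-end orchestration: detectors -> consensus partitions -> Phi_PT /
# Mantel / GAMOVA per locus set -> scenario call per trait.

# Population-level pairwise mean F_ST matrix from per-population frequency
# estimates (alternative differentiation matrix for the Mantel stage).
pairwise_fst_matrix <- function(stats) {
  pf <- attr(stats, "pop_freq")
  pn <- attr(stats, "pop_n")
  pops <- colnames(pf)
  k <- length(pops)
  m <- matrix(0, k, k, dimnames = list(pops, pops))
  ok <- !stats$monomorphic
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      f <- vapply(which(ok), function(l) {
        locus_fst_he(pf[l, c(i, j)], pn[l, c(i, j)])$fst
      }, numeric(1))
      m[i, j] <- m[j, i] <- max(mean(f, na.rm = TRUE), 0)
    }
  }
  dist_matrix(m, kind = "phi_pt")
}

#' Population means of individual trait values
#'
#' Arithmetic means over non-missing individuals, per population, of every
#' numeric trait column.
#'
#' @param traits data.frame with `population` and numeric trait columns.
#' @return matrix populations x traits.
#' @export
trait_population_means <- function(traits) {
  vars <- names(traits)[vapply(traits, is.numeric, logical(1))]
  pops <- sort(unique(traits$population))
  out <- sapply(vars, function(v) {
    tapply(traits[[v]], traits$population, mean, na.rm = TRUE)[pops]
  })
  rownames(out) <- pops
  as.matrix(out)
}

#' Run the full selection-scan pipeline
#'
#' Orchestrates the analytical chain on a cross-referenced dataset: locus
#' statistics, the F_ST-envelope scan ([fdist_scan()]), optionally the
#' Bayesian F-model ([fit_bayes_fmodel()]), the logistic environment
#' association scan ([logistic_scan()]) with [climate_pca()] components
#' PC1-PC3 added, consensus partitions of loci into selected/neutral sets,
#' pairwise Phi_PT matrices per locus set, Mantel isolation-by-distance
#' tests against great-circle distances, per-trait GAMOVA on each locus set,
#' and the scenario classification of every trait.
#'
#' @param markers a [marker_matrix()].
#' @param pops population map (population_id, latitude, longitude).
#' @param climate climate table.
#' @param traits individual-level trait table (`population` column plus
#'   numeric trait columns), or NULL to skip the inference stage.
#' @param config a [pipeline_config()].
#' @param run_fmodel fit the Bayesian F-model (slowest stage; TRUE by
#'   default). When FALSE, consensus rules referring to `fmodel` are
#'   dropped.
#' @param verbose print stage banners.
#' @return list with the stage results (`stats`, `fdist`, `fmodel`,
#'   `assoc`, `climate_pca`, `partitions`, `geo`, and per-partition
#'   `inference` tables) plus `tables`, a set of flat data.frames suitable
#'   for [write_results()].
#' @export
run_pipeline <- function(markers, pops, climate, traits = NULL,
                         config = pipeline_config(), run_fmodel = TRUE,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(format(Sys.time(), "%H:%M:%S "),
                                            sprintf(...))
  say("locus statistics (%d loci, %d populations)", ncol(markers$bands),
      nlevels(markers$pop))
  stats <- locus_stats(markers, prior = config$prior)
  say("F_ST envelope scan (%g simulations, CI %.2f)", config$n_sims,
      config$ci)
  fd <- fdist_scan(markers, config, stats = stats)
  fm <- NULL
  if (run_fmodel) {
    say("Bayesian F-model (%d iterations)", config$mcmc$iter)
    fm <- fit_bayes_fmodel(markers, config, seed = config$seed)
  }
  say("climate PCA and logistic association scan")
  cpca <- climate_pca(climate)
  env <- climate[c("population_id",
                   grep("^bio[0-9]+$", names(climate), value = TRUE))]
  pcs <- as.data.frame(cpca$scores[, seq_len(min(3, ncol(cpca$scores))),
                                   drop = FALSE])
  names(pcs) <- paste0("PC", seq_len(ncol(pcs)))
  env <- cbind(env, pcs[match(env$population_id, rownames(cpca$scores)), ,
                        drop = FALSE])
  as_res <- logistic_scan(markers, env, alpha = config$alpha,
                          both_tests = config$both_tests,
                          skip_loci = stats$locus[stats$monomorphic])
  flags <- list(fdist = fd$table$locus[fd$table$outlier],
                assoc = as_res$selected)
  if (run_fmodel) {
    flags$fmodel <- names(fm$q_value)[!is.na(fm$q_value) &
                                        fm$q_value <= config$bayes_fdr]
  }
  scanned <- stats$locus[!stats$monomorphic]
  rules <- Filter(function(r) all(r %in% names(flags)),
                  config$consensus_rules)
  partitions <- lapply(rules, consensus_partition, flags = flags,
                       all_loci = scanned)
  names(partitions) <- vapply(partitions, `[[`, "", "label")
  geo <- geo_distance_matrix(pops)
  inference <- NULL
  tables <- list()
  if (!is.null(traits)) {
    tm <- trait_population_means(traits)
    tm <- tm[levels(markers$pop), , drop = FALSE]
    inference <- lapply(partitions, function(part) {
      say("inference for locus set '%s' (%d selected)", part$label,
          length(part$selected))
      infer_locus_set(markers, part, tm, geo, config)
    })
    gam_rows <- do.call(rbind, lapply(names(inference), function(lbl) {
      inf <- inference[[lbl]]
      if (is.null(inf$gamova)) return(NULL)
      cbind(locus_set = lbl, inf$gamova)
    }))
    man_rows <- do.call(rbind, lapply(names(inference), function(lbl) {
      inf <- inference[[lbl]]
      data.frame(locus_set = lbl,
                 set = c("selected", "neutral"),
                 r_xy = c(inf$mantel_sel$r_xy %||% NA,
                          inf$mantel_neut$r_xy %||% NA),
                 p_value = c(inf$mantel_sel$p_value %||% NA,
                             inf$mantel_neut$p_value %||% NA),
                 stringsAsFactors = FALSE)
    }))
    scen_rows <- do.call(rbind, lapply(names(inference), function(lbl) {
      inf <- inference[[lbl]]
      if (is.null(inf$scenarios)) return(NULL)
      cbind(locus_set = lbl, inf$scenarios)
    }))
    tables$gamova <- gam_rows
    tables$mantel <- man_rows
    tables$scenarios <- scen_rows
  }
  locus_table <- data.frame(
    locus = stats$locus, he = stats$he, fst = stats$fst,
    p_emp = fd$table$p_emp, p_bh = fd$table$p_bh,
    fdist_outlier = fd$table$outlier, stringsAsFactors = FALSE)
  if (run_fmodel) {
    locus_table$posterior_prob <- unname(fm$pp[locus_table$locus])
    locus_table$q_value <- unname(fm$q_value[locus_table$locus])
  }
  assoc_vars <- tapply(as_res$table$variable[as_res$table$significant],
                       as_res$table$locus[as_res$table$significant],
                       paste, collapse = ",")
  locus_table$assoc_variables <- unname(assoc_vars[locus_table$locus])
  tables$locus_table <- locus_table
  list(stats = stats, fdist = fd, fmodel = fm, assoc = as_res,
       climate_pca = cpca, partitions = partitions, geo = geo,
       inference = inference, tables = tables, config = config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Mantel + per-trait GAMOVA + scenario calls for one locus partition.
infer_locus_set <- function(markers, partition, trait_means, geo, config) {
  subset_mm <- function(loci) {
    marker_matrix(markers$bands[, loci, drop = FALSE], markers$pop)
  }
  out <- list(partition = partition)
  if (length(partition$selected) == 0) {
    warning("empty selected set for rule '", partition$label,
            "'; selected-set tests skipped")
    d_sel <- NULL
  } else {
    d_sel <- pairwise_phi_pt(subset_mm(partition$selected))
  }
  d_neut <- pairwise_phi_pt(subset_mm(partition$neutral))
  if (config$mantel_matrix == "fst") {
    sts_sel <- if (is.null(d_sel)) NULL else
      locus_stats(subset_mm(partition$selected), prior = config$prior)
    sts_neut <- locus_stats(subset_mm(partition$neutral),
                            prior = config$prior)
    m_sel <- if (is.null(sts_sel)) NULL else pairwise_fst_matrix(sts_sel)
    m_neut <- pairwise_fst_matrix(sts_neut)
  } else {
    m_sel <- d_sel
    m_neut <- d_neut
  }
  out$mantel_sel <- if (is.null(m_sel)) NULL else
    mantel_test(m_sel, geo, n_perm = config$n_perm, seed = config$seed)
  out$mantel_neut <- mantel_test(m_neut, geo, n_perm = config$n_perm,
                                 seed = config$seed + 1L)
  gam <- NULL
  scen <- NULL
  for (v in colnames(trait_means)) {
    tv <- trait_means[, v]
    if (sd(tv) == 0) next
    g_sel <- if (is.null(d_sel)) NULL else
      gamova(d_sel, tv, n_perm = config$n_perm, seed = config$seed + 2L)
    g_neut <- gamova(d_neut, tv, n_perm = config$n_perm,
                     seed = config$seed + 3L)
    gam <- rbind(gam, data.frame(
      trait = v,
      pseudo_f_sel = g_sel$pseudo_f %||% NA, p_sel = g_sel$p_value %||% NA,
      pseudo_f_neut = g_neut$pseudo_f, p_neut = g_neut$p_value,
      stringsAsFactors = FALSE))
    if (!is.null(g_sel)) {
      call <- classify_scenario(
        g_sel$p_value <= config$alpha, g_neut$p_value <= config$alpha,
        out$mantel_sel$p_value <= config$alpha,
        out$mantel_neut$p_value <= config$alpha)
      scen <- rbind(scen, data.frame(
        trait = v, scenario = call$scenario,
        gamova_sel = call$flags[["gamova_sel"]],
        gamova_neut = call$flags[["gamova_neut"]],
        mantel_sel = call$flags[["mantel_sel"]],
        mantel_neut = call$flags[["mantel_neut"]],
        interpretation = call$interpretation, stringsAsFactors = FALSE))
    }
  }
  out$phi_sel <- d_sel
  out$phi_neut <- d_neut
  out$gamova <- gam
  out$scenarios <- scen
  out
}
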