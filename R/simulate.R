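# Synthetic-data generators with known ground truth. The defaults emulate a
# 12-population dominant-marker study along a coastal-to-semidesert aridity
# transect: 732 loci (30 of them clinal in an environmental variable),
# 12-19 individuals per population (182 in total), background F_ST 0.02,
# 24 replicate scoring pairs at a 9% per-locus error rate, and an
# annual-precipitation-like variable spanning 100-200 mm.

default_pop_sizes <- function(n_pops) {
  if (n_pops == 12L) {
    c(15L, 16L, 15L, 15L, 15L, 16L, 15L, 15L, 15L, 15L, 15L, 15L)  # 182
  } else {
    rep(15L, n_pops)
  }
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Generate population map and climate table along a transect
#'
#' Places populations on a one-dimensional transect with jitter and derives
#' 20 bioclimatic variables (`bio01`-`bio20`) as affine functions of transect
#' position plus independent noise, so that a leading climate principal
#' component exists. `bio12` is an annual-precipitation-like variable that
#' spans `precip_range` exactly (wet end at the transect origin); the other
#' variables mix temperature-like and precipitation-like scales with
#' alternating gradient signs.
#'
#' @param n_pops number of populations (>= 2).
#' @param gradient_length_km transect length; 0 co-locates all populations
#'   and makes every climate column constant.
#' @param seed integer seed.
#' @param precip_range range of the precipitation-like variable `bio12`, mm.
#' @param noise_sd standard deviation of the independent noise added to each
#'   climate variable, on the scale of its gradient amplitude; 0 makes all
#'   variables perfectly collinear.
#' @param base_lat,base_lon geographic anchor of the transect (WGS84).
#' @return list with `pops` (population_id, latitude, longitude,
#'   n_individuals, transect_km) and `climate` (population_id, bio01-bio20,
#'   latitude, longitude).
#' @export
gen_metadata <- function(n_pops = 12, gradient_length_km = 250, seed = 1L,
                         precip_range = c(100, 200), noise_sd = 0.15,
                         base_lat = 33.8, base_lon = 9.0) {
  if (n_pops < 2) stop("n_pops must be >= 2")
  set.seed(seed)
  L <- gradient_length_km
  if (L > 0) {
    spacing <- L / (n_pops - 1)
    pos <- seq(0, L, length.out = n_pops) +
      runif(n_pops, -0.25, 0.25) * spacing
    pos <- pmin(pmax(pos, 0), L)
    pos_norm <- pos / L
  } else {
    pos <- rep(0, n_pops)
    pos_norm <- rep(0, n_pops)
  }
  lat <- base_lat + rnorm(n_pops, 0, 0.03)
  lon <- base_lon + pos / (111.32 * cos(base_lat * pi / 180))
  ids <- sprintf("pop%02d", seq_len(n_pops))
  pops <- data.frame(population_id = ids, latitude = lat, longitude = lon,
                     n_individuals = NA_integer_, transect_km = pos,
                     stringsAsFactors = FALSE)
  # variable "templates": (intercept, gradient amplitude, sign)
  temp_like <- 1:11     # temperature-ish scales
  prec_like <- 12:20    # precipitation-ish scales
  clim <- matrix(NA_real_, n_pops, 20)
  colnames(clim) <- sprintf("bio%02d", 1:20)
  signs <- rep(c(1, -1), length.out = 20)
  for (k in 1:20) {
    if (k == 12) next
    if (k %in% temp_like) {
      base <- 15 + k; amp <- 8
    } else {
      base <- 120 - 3 * k; amp <- 40
    }
    clim[, k] <- base + signs[k] * amp * pos_norm +
      amp * noise_sd * rnorm(n_pops)
  }
  clim[, 12] <- precip_range[2] - diff(precip_range) * pos_norm
  climate <- data.frame(population_id = ids, clim, latitude = lat,
                        longitude = lon, stringsAsFactors = FALSE)
  list(pops = pops, climate = climate)
}

#' Generate a dominant marker matrix with known selected loci
#'
#' Neutral loci follow the Balding-Nichols island model: ancestral
#' band-presence allele frequency `p ~ U(0.1, 0.9)`, population frequencies
#' `p_j ~ Beta(p (1-F)/F, (1-p)(1-F)/F)` with `F = fst_background`. Selected
#' loci are clinal on top of the same drift background:
#' `logit(p_j) = logit(b_j) + s_i * z_j` where `b_j` is a Balding-Nichols
#' draw, `z_j` the standardized value of `env_var` in population `j`, and
#' `s_i = +/- slope` (random sign per locus), so `slope = 0` reduces
#' exactly to the neutral model; frequencies outside (0, 1) after the
#' transform are clipped to \[0.001, 0.999\] with a warning. Individual band phenotypes
#' are dominant under Hardy-Weinberg: presence with probability
#' `1 - (1 - p_j)^2`. Optional spatial autocorrelation of neutral
#' frequencies ("IBD knob") uses a Gaussian copula with exponential
#' correlation `exp(-d / (ibd_corr_length * transect))` between populations,
#' preserving the Balding-Nichols marginals.
#'
#' Replicate scoring pairs are produced by copying individuals and flipping
#' each band with probability `error_rate`; they are returned as a separate
#' small marker matrix (originals + copies) so that the analysis matrix
#' stays free of pseudo-replicated individuals.
#'
#' @param meta output of [gen_metadata()].
#' @param n_neutral,n_selected locus counts (defaults 702 + 30 = 732).
#' @param fst_background background differentiation, in (0, 0.5].
#' @param slope clinal slope magnitude on the logit scale; the default 1.4
#'   makes clinal loci realize F_ST around 0.25 against the 0.02 background
#'   over a 12-population transect.
#' @param n_ind per-population individual counts (default 12-19 per
#'   population, 182 total for 12 populations).
#' @param error_rate per-locus bit-flip probability for replicate pairs.
#' @param n_replicate_pairs number of replicate pairs.
#' @param ibd_corr_length spatial correlation length as a fraction of the
#'   transect; 0 (default) turns the knob off, giving the exchangeable
#'   island model the outlier detectors assume.
#' @param env_var climate column driving the clinal loci.
#' @param seed integer seed.
#' @return list with `markers` ([marker_matrix()]), `truth` (class
#'   `sim_truth`: selected locus ids, per-locus slopes, background F,
#'   per-population clinal driver and standardized environment), and
#'   `replicates` (marker matrix of replicate pairs, or NULL).
#' @export
gen_aflp <- function(meta, n_neutral = 702, n_selected = 30,
                     fst_background = 0.02, slope = 1.4,
                     n_ind = default_pop_sizes(nrow(meta$pops)),
                     error_rate = 0.09, n_replicate_pairs = 24,
                     ibd_corr_length = 0, env_var = "bio12", seed = 1L) {
  stopifnot(fst_background > 0, fst_background <= 0.5, all(n_ind >= 2))
  set.seed(seed)
  K <- nrow(meta$pops)
  stopifnot(length(n_ind) == K)
  L <- n_neutral + n_selected
  env <- meta$climate[[env_var]]
  z <- if (sd(env) > 0) as.vector(scale(env)) else rep(0, K)

  freq <- matrix(NA_real_, L, K)
  # neutral loci
  p_anc <- runif(n_neutral, 0.1, 0.9)
  F <- fst_background
  a <- p_anc * (1 - F) / F
  b <- (1 - p_anc) * (1 - F) / F
  if (n_neutral > 0) {
    if (ibd_corr_length > 0) {
      d <- abs(outer(meta$pops$transect_km, meta$pops$transect_km, "-"))
      len <- ibd_corr_length * max(max(d), 1e-9)
      S <- exp(-d / len)
      Ch <- chol(S + diag(1e-10, K))
      zmat <- matrix(rnorm(n_neutral * K), n_neutral, K) %*% Ch
      u <- pnorm(zmat)
      freq[seq_len(n_neutral), ] <- qbeta(u, matrix(a, n_neutral, K),
                                          matrix(b, n_neutral, K))
    } else {
      freq[seq_len(n_neutral), ] <- matrix(
        rbeta(n_neutral * K, rep(a, K), rep(b, K)),
        n_neutral, K)
    }
  }
  # selected (clinal) loci
  sel_idx <- if (n_selected > 0) seq(n_neutral + 1, L) else integer(0)
  sel_slopes <- numeric(0)
  if (n_selected > 0) {
    p_anc_sel <- runif(n_selected, 0.1, 0.9)
    as_ <- p_anc_sel * (1 - F) / F
    bs_ <- (1 - p_anc_sel) * (1 - F) / F
    drift <- matrix(rbeta(n_selected * K, rep(as_, K), rep(bs_, K)),
                    n_selected, K)
    drift <- pmin(pmax(drift, 1e-6), 1 - 1e-6)
    sel_slopes <- slope * sample(c(-1, 1), n_selected, replace = TRUE)
    eta <- logit(drift) + outer(sel_slopes, z)
    ps <- inv_logit(eta)
    if (any(ps < 0.001 | ps > 0.999)) {
      warning("clinal frequencies clipped to [0.001, 0.999]")
      ps <- pmin(pmax(ps, 0.001), 0.999)
    }
    freq[sel_idx, ] <- ps
  }
  # dominant phenotypes
  N <- sum(n_ind)
  pop_of <- rep(seq_len(K), n_ind)
  pres_prob <- 1 - (1 - freq)^2
  bands <- matrix(0L, N, L)
  for (k in seq_len(K)) {
    rows <- which(pop_of == k)
    bands[rows, ] <- matrix(
      rbinom(length(rows) * L, 1L, rep(pres_prob[, k], each = length(rows))),
      length(rows), L)
  }
  locus_ids <- sprintf("L%03d", seq_len(L))
  ind_ids <- sprintf("%s_i%02d", meta$pops$population_id[pop_of],
                     unlist(lapply(n_ind, seq_len)))
  dimnames(bands) <- list(ind_ids, locus_ids)
  mm <- marker_matrix(bands, setNames(meta$pops$population_id[pop_of],
                                      ind_ids))
  # replicate pairs (kept out of the analysis matrix)
  reps <- NULL
  if (n_replicate_pairs > 0) {
    pick <- sample.int(N, min(n_replicate_pairs, N))
    orig <- bands[pick, , drop = FALSE]
    flip <- matrix(rbinom(length(orig), 1L, error_rate), nrow(orig))
    copy <- ifelse(flip == 1L, 1L - orig, orig)
    rn <- c(rownames(orig), paste0(rownames(orig), "_rep"))
    rb <- rbind(orig, copy)
    rownames(rb) <- rn
    reps <- marker_matrix(
      rb, setNames(rep(meta$pops$population_id[pop_of[pick]], 2), rn),
      replicate_pairs = cbind(rownames(orig), paste0(rownames(orig), "_rep")))
  }
  # clinal driver: population mean selected frequency, aligned by slope sign
  driver <- if (n_selected > 0) {
    aligned <- freq[sel_idx, , drop = FALSE]
    aligned[sel_slopes < 0, ] <- 1 - aligned[sel_slopes < 0, ]
    colMeans(aligned)
  } else {
    rep(NA_real_, K)
  }
  truth <- structure(list(
    selected_loci = locus_ids[sel_idx],
    slopes = setNames(sel_slopes, locus_ids[sel_idx]),
    fst_background = fst_background,
    env_var = env_var, env_z = z, sel_driver = driver,
    pop_freq = freq, pop_sizes = n_ind, error_rate = error_rate,
    seed = seed), class = "sim_truth")
  list(markers = mm, truth = truth, replicates = reps)
}

#' Generate individual trait values in three generative classes
#'
#' Produces stand-ins for scored life-history/morphological traits in three
#' flavors: `"selected"` traits are linear in the per-population mean
#' selected-locus allele frequency (the clinal driver recorded in the
#' simulation truth); `"neutral_ibd"` traits are linear in transect position
#' (tracking neutral geographic structure); `"random"` traits are pure
#' noise. Population-level drivers are standardized, so `coupling` is the
#' among-population effect size in driver standard deviations and
#' `noise_sd` the within-population individual standard deviation. Each
#' population additionally receives a random intercept with standard
#' deviation `pop_noise_sd` (common-garden trait means are never a pure
#' function of genotype: maternal and microsite effects leave
#' population-level residual variation), so the genetic driver explains
#' most, not all, of the among-population trait variance.
#'
#' @param meta output of [gen_metadata()].
#' @param truth `sim_truth` from [gen_aflp()].
#' @param coupling among-population effect size (>= 0; 0 makes every trait
#'   behave as class random).
#' @param noise_sd individual-level noise standard deviation.
#' @param pop_noise_sd population-level random-intercept standard deviation.
#' @param classes generative class per trait; defaults to ten traits cycling
#'   selected / neutral_ibd / random.
#' @param seed integer seed.
#' @return data.frame with `individual`, `population` and one column per
#'   trait (`V01`, `V02`, ...); generative classes in `attr(, "classes")`.
#' @export
gen_traits <- function(meta, truth, coupling = 1, noise_sd = 1,
                       pop_noise_sd = 0.5,
                       classes = rep(c("selected", "neutral_ibd", "random"),
                                     length.out = 10),
                       seed = 1L) {
  stopifnot(coupling >= 0,
            all(classes %in% c("selected", "neutral_ibd", "random")))
  set.seed(seed)
  K <- nrow(meta$pops)
  n_ind <- truth$pop_sizes
  pop_of <- rep(seq_len(K), n_ind)
  std <- function(x) {
    if (anyNA(x) || sd(x) == 0) rep(0, length(x)) else as.vector(scale(x))
  }
  drivers <- list(
    selected = std(truth$sel_driver),
    neutral_ibd = std(meta$pops$transect_km),
    random = rep(0, K))
  n <- sum(n_ind)
  vals <- sapply(seq_along(classes), function(i) {
    mu <- coupling * drivers[[classes[i]]] + rnorm(K, 0, pop_noise_sd)
    mu[pop_of] + rnorm(n, 0, noise_sd)
  })
  colnames(vals) <- sprintf("V%02d", seq_along(classes))
  ind_ids <- sprintf("%s_i%02d", meta$pops$population_id[pop_of],
                     unlist(lapply(n_ind, seq_len)))
  out <- data.frame(individual = ind_ids,
                    population = meta$pops$population_id[pop_of],
                    vals, stringsAsFactors = FALSE)
  attr(out, "classes") <- setNames(classes, colnames(vals))
  out
}

#' Generate synthetic leaf outlines and flower landmark configurations
#'
#' Leaf outlines are ellipse-based closed polygons (semi-axes `aspect` and
#' 1) whose radius is modulated by a sinusoidal lobing term
#' `1 + lobing * sin(n_lobes * theta)`; each leaf draws its length/width
#' ratio around its population target. Being radial functions, the outlines
#' are simple (non-self-intersecting) for `lobing < 0.5`. Flower
#' configurations are 37 points - flower center, 4 petal tips, and 8 margin
#' points per petal at 25/50/75/95% of the petal length on both sides -
#' perturbed by Gaussian landmark noise.
#'
#' @param n_per_pop leaves/flowers per population.
#' @param aspect_by_pop per-population target length/width ratio.
#' @param lobing lobing amplitude, in \[0, 0.5).
#' @param n_lobes number of lobes (default 9, a pinnately-lobed look).
#' @param n_points outline points (>= 64).
#' @param aspect_cv coefficient of variation of individual aspect ratios
#'   around the population target.
#' @param leaf_size_cm mean square-root leaf area, cm (sets the calibration
#'   scale of the outlines).
#' @param petal_len_mm mean petal length, mm.
#' @param landmark_noise landmark noise standard deviation as a fraction of
#'   petal length.
#' @param seed integer seed.
#' @return list with `leaves` and `flowers`: lists (one element per
#'   individual) of two-column coordinate matrices with `population` and
#'   `individual` attributes; flower matrices have exactly 37 rows.
#' @export
gen_shapes <- function(n_per_pop, aspect_by_pop, lobing = 0.2, n_lobes = 9,
                       n_points = 512, aspect_cv = 0.05, leaf_size_cm = 2,
                       petal_len_mm = 5, landmark_noise = 0.01, seed = 1L) {
  stopifnot(n_points >= 64, lobing >= 0, lobing < 0.5)
  set.seed(seed)
  K <- length(aspect_by_pop)
  pops <- names(aspect_by_pop)
  if (is.null(pops)) pops <- sprintf("pop%02d", seq_len(K))
  leaves <- list()
  flowers <- list()
  for (k in seq_len(K)) {
    for (i in seq_len(n_per_pop)) {
      id <- sprintf("%s_i%02d", pops[k], i)
      aspect <- aspect_by_pop[k] * exp(rnorm(1, 0, aspect_cv))
      size <- leaf_size_cm * exp(rnorm(1, 0, 0.1))
      theta <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
      mod <- 1 + lobing * sin(n_lobes * theta)
      xy <- cbind(aspect * cos(theta) * mod, sin(theta) * mod) *
        size / sqrt(aspect)
      attr(xy, "population") <- pops[k]
      attr(xy, "individual") <- id
      leaves[[id]] <- xy
      lp <- petal_len_mm * exp(rnorm(1, 0, 0.1))
      flowers[[id]] <- flower_template(lp, noise = landmark_noise * lp,
                                       population = pops[k], individual = id)
    }
  }
  list(leaves = leaves, flowers = flowers)
}

# 37-point flower configuration: center, 4 petal tips, 8 margin points per
# petal (25/50/75/95% of petal length, both sides, elliptic width profile).
flower_template <- function(petal_len, width_frac = 0.35, noise = 0,
                            population = NA, individual = NA) {
  s <- c(0.25, 0.5, 0.75, 0.95)
  h <- width_frac * petal_len * sin(pi * s)
  pts <- matrix(0, 1, 2)                     # center
  tips <- NULL
  margins <- NULL
  for (ang in c(0, pi / 2, pi, 3 * pi / 2)) {
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
    tips <- rbind(tips, c(petal_len, 0) %*% R)
    left <- cbind(s * petal_len, h) %*% R
    right <- cbind(s * petal_len, -h) %*% R
    margins <- rbind(margins, left, right)
  }
  out <- rbind(pts, tips, margins)
  if (noise > 0) out <- out + matrix(rnorm(length(out), 0, noise), nrow(out))
  attr(out, "population") <- population
  attr(out, "individual") <- individual
  out
}

#' Generate a complete synthetic study bundle
#'
#' Convenience wrapper producing every input of the pipeline with one seed:
#' population map and climate ([gen_metadata()]), marker matrix with known
#' selected loci and replicate pairs ([gen_aflp()]), trait table
#' ([gen_traits()]), and shapes ([gen_shapes()]) whose per-population leaf
#' aspect ratio tracks the selected-trait driver (so leaf-shape PC1 carries
#' the clinal signal).
#'
#' @param seed integer seed.
#' @param n_pops number of populations.
#' @param ... passed on to [gen_aflp()].
#' @return list with `meta`, `markers`, `truth`, `replicates`, `traits`,
#'   `shapes`.
#' @export
gen_bundle <- function(seed = 1L, n_pops = 12, ...) {
  meta <- gen_metadata(n_pops = n_pops, seed = seed)
  sim <- gen_aflp(meta, seed = seed + 1L, ...)
  traits <- gen_traits(meta, sim$truth, seed = seed + 2L)
  drv <- sim$truth$sel_driver
  drv <- (drv - min(drv)) / max(diff(range(drv)), 1e-9)
  aspects <- setNames(1.5 + 2 * drv, meta$pops$population_id)
  shapes <- gen_shapes(n_per_pop = 5, aspect_by_pop = aspects,
                       seed = seed + 3L)
  list(meta = meta, markers = sim$markers, truth = sim$truth,
       replicates = sim$replicates, traits = traits, shapes = shapes)
}
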