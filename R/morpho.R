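# Geometric morphometrics: elliptic Fourier outline analysis of leaves,
# generalized Procrustes alignment of flower landmark configurations, shape
# PCA, and calibrated scalar measures.

#' Resample a closed outline to equally spaced points
#'
#' Piecewise-linear resampling of a closed polygon at `n_points` positions
#' equally spaced by cumulative arc length. Orientation and start point are
#' preserved; the first point must not be duplicated as the last.
#'
#' @param outline two-column matrix of (x, y) points.
#' @param n_points number of output points.
#' @return two-column matrix of `n_points` resampled points.
#' @export
resample_outline <- function(outline, n_points) {
  xy <- as.matrix(outline)
  stopifnot(ncol(xy) == 2, nrow(xy) >= 3)
  closed <- rbind(xy, xy[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  per <- sum(seg)
  if (per <= 0) stop("degenerate outline with zero perimeter")
  t_cum <- c(0, cumsum(seg))
  t_new <- seq(0, per, length.out = n_points + 1)[-(n_points + 1)]
  cbind(approx(t_cum, closed[, 1], xout = t_new)$y,
        approx(t_cum, closed[, 2], xout = t_new)$y)
}

#' Elliptic Fourier decomposition of a closed outline
#'
#' Kuhl-Giardina elliptic Fourier coefficients `(a_n, b_n, c_n, d_n)` for
#' harmonics `1..n_harmonics`, computed from the discrete chain integrals of
#' the resampled outline. With `normalize = TRUE` the coefficients are
#' normalized by the first-harmonic ellipse: size to its semi-major axis,
#' rotation to its orientation, and the start point to its semi-major end,
#' so that `a_1 = 1`, `b_1 = c_1 = 0` up to numerical error. Harmonic power
#' is `P_n = (a_n^2 + b_n^2 + c_n^2 + d_n^2) / 2` (computed before
#' normalization, on which the power proportions do not depend).
#'
#' @param outline two-column matrix of (x, y) points (resample first for
#'   stability).
#' @param n_harmonics number of harmonics (<= n_points / 2).
#' @param normalize apply first-harmonic normalization (default TRUE).
#' @return object of class `efa`: list with coefficient vectors `an`, `bn`,
#'   `cn`, `dn`, centroid terms `a0`, `c0`, perimeter `T`, `power`,
#'   `cum_power_frac`, and the normalization record `norm` (scale, rotation
#'   `psi`, start-point shift `theta`).
#' @export
efa_transform <- function(outline, n_harmonics = 15, normalize = TRUE) {
  xy <- as.matrix(outline)
  m <- nrow(xy)
  stopifnot(n_harmonics >= 1)
  if (n_harmonics > m / 2) stop("n_harmonics must be <= n_points / 2")
  closed <- rbind(xy, xy[1, ])
  dx <- diff(closed[, 1])
  dy <- diff(closed[, 2])
  dt <- sqrt(dx^2 + dy^2)
  keep <- dt > 0
  dx <- dx[keep]; dy <- dy[keep]; dt <- dt[keep]
  t1 <- cumsum(dt)
  t0 <- c(0, t1[-length(t1)])
  T <- sum(dt)
  n <- seq_len(n_harmonics)
  w <- 2 * pi * outer(n, t1) / T        # harmonics x segments
  w0 <- 2 * pi * outer(n, t0) / T
  fac <- T / (2 * pi^2 * n^2)
  an <- fac * as.vector((cos(w) - cos(w0)) %*% (dx / dt))
  bn <- fac * as.vector((sin(w) - sin(w0)) %*% (dx / dt))
  cn <- fac * as.vector((cos(w) - cos(w0)) %*% (dy / dt))
  dn <- fac * as.vector((sin(w) - sin(w0)) %*% (dy / dt))
  # centroid terms
  xi <- c(0, cumsum(dx))[seq_along(dx)] - (dx / dt) * t0
  delta <- c(0, cumsum(dy))[seq_along(dy)] - (dy / dt) * t0
  # the chain integrals give the mean displacement from the start point
  a0 <- sum((dx / (2 * dt)) * (t1^2 - t0^2) + xi * (t1 - t0)) / T +
    closed[1, 1]
  c0 <- sum((dy / (2 * dt)) * (t1^2 - t0^2) + delta * (t1 - t0)) / T +
    closed[1, 2]
  power <- (an^2 + bn^2 + cn^2 + dn^2) / 2
  norm <- NULL
  if (normalize) {
    theta <- 0.5 * atan2(2 * (an[1] * bn[1] + cn[1] * dn[1]),
                         an[1]^2 + cn[1]^2 - bn[1]^2 - dn[1]^2)
    shift <- function(theta) {
      ct <- cos(n * theta); st <- sin(n * theta)
      list(a = an * ct + bn * st, b = -an * st + bn * ct,
           c = cn * ct + dn * st, d = -cn * st + dn * ct)
    }
    s <- shift(theta)
    if (s$a[1]^2 + s$c[1]^2 < s$b[1]^2 + s$d[1]^2) {
      theta <- theta + pi / 2   # picked the semi-minor axis; rotate to major
      s <- shift(theta)
    }
    psi <- atan2(s$c[1], s$a[1])
    E <- sqrt(s$a[1]^2 + s$c[1]^2)
    cp <- cos(psi); sp <- sin(psi)
    an2 <- (cp * s$a + sp * s$c) / E
    cn2 <- (-sp * s$a + cp * s$c) / E
    bn2 <- (cp * s$b + sp * s$d) / E
    dn2 <- (-sp * s$b + cp * s$d) / E
    an <- an2; bn <- bn2; cn <- cn2; dn <- dn2
    norm <- list(scale = E, psi = psi, theta = theta)
  }
  structure(list(an = an, bn = bn, cn = cn, dn = dn, a0 = a0, c0 = c0,
                 T = T, power = power,
                 cum_power_frac = cumsum(power) / sum(power), norm = norm),
            class = "efa")
}

#' Harmonic power captured by leading harmonics
#'
#' Fraction of total elliptic Fourier harmonic power captured by harmonics
#' `1..h`, with the total computed over all harmonics up to the Nyquist
#' limit of the outline.
#'
#' @param outline two-column coordinate matrix (closed outline).
#' @param h number of leading harmonics.
#' @return fraction in (0, 1].
#' @export
efa_power_fraction <- function(outline, h = 15) {
  nyq <- floor(nrow(outline) / 2)
  ef <- efa_transform(outline, n_harmonics = nyq, normalize = FALSE)
  sum(ef$power[seq_len(min(h, nyq))]) / sum(ef$power)
}

#' Inverse elliptic Fourier synthesis
#'
#' Reconstructs a closed outline from elliptic Fourier coefficients.
#'
#' @param coeffs an `efa` object from [efa_transform()].
#' @param n_points number of points to synthesize.
#' @param n_harmonics harmonics to use (default: all present).
#' @return two-column matrix of reconstructed points.
#' @export
efa_reconstruct <- function(coeffs, n_points = 256,
                            n_harmonics = length(coeffs$an)) {
  t <- seq(0, 1, length.out = n_points + 1)[-(n_points + 1)]
  n <- seq_len(n_harmonics)
  co <- cos(2 * pi * outer(t, n))
  si <- sin(2 * pi * outer(t, n))
  x <- coeffs$a0 + co %*% coeffs$an[n] + si %*% coeffs$bn[n]
  y <- coeffs$c0 + co %*% coeffs$cn[n] + si %*% coeffs$dn[n]
  cbind(as.vector(x), as.vector(y))
}

#' Generalized (GLS) Procrustes superimposition
#'
#' Aligns a set of landmark configurations by translating each to its
#' centroid, scaling to unit centroid size, and iteratively rotating to the
#' evolving consensus with the two-dimensional orthogonal Procrustes
#' solution (SVD, rotations only) until the consensus changes by less than
#' `tol` (maximum 100 iterations). Semilandmarks are treated as fixed
#' points - no sliding.
#'
#' @param configs list of k x 2 landmark matrices with equal point counts.
#' @param tol convergence tolerance on the consensus change.
#' @return list with `aligned` (list of aligned configurations),
#'   `consensus`, `centroid_sizes`, and `iterations`.
#' @export
gpa_align <- function(configs, tol = 1e-10) {
  stopifnot(length(configs) >= 2)
  k <- nrow(configs[[1]])
  stopifnot(all(vapply(configs, nrow, 1L) == k))
  cs <- numeric(length(configs))
  centered <- lapply(seq_along(configs), function(i) {
    m <- as.matrix(configs[[i]])
    m <- sweep(m, 2, colMeans(m))
    s <- sqrt(sum(m^2))
    if (s <= 0) stop("configuration ", i, " has zero centroid size")
    cs[i] <<- s
    m / s
  })
  rotate_to <- function(m, ref) {
    sv <- svd(crossprod(ref, m))
    R <- sv$v %*% t(sv$u)
    if (det(R) < 0) {        # rotations only, no reflection
      sv$v[, 2] <- -sv$v[, 2]
      R <- sv$v %*% t(sv$u)
    }
    m %*% R
  }
  consensus <- centered[[1]]
  for (it in seq_len(100)) {
    aligned <- lapply(centered, rotate_to, ref = consensus)
    new_cons <- Reduce(`+`, aligned) / length(aligned)
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    delta <- sqrt(sum((new_cons - consensus)^2))
    consensus <- new_cons
    if (delta < tol) break
  }
  aligned <- lapply(centered, rotate_to, ref = consensus)
  names(aligned) <- names(configs)
  list(aligned = aligned, consensus = consensus, centroid_sizes = cs,
       iterations = it)
}

#' Shape principal component analysis
#'
#' Centered (not standardized) PCA of flattened shape descriptors - rows of
#' elliptic Fourier coefficients or of aligned landmark coordinates - with a
#' deterministic sign convention (the largest-magnitude loading of each axis
#' is positive).
#'
#' @param x shapes x descriptors numeric matrix.
#' @param n_axes axes to retain (truncated with a warning if the data have
#'   fewer).
#' @return list with `scores`, `loadings`, and `pct_var`.
#' @export
shape_pca <- function(x, n_axes = 3) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 3)
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  avail <- sum(pc$sdev > 1e-12)
  if (avail < n_axes) {
    warning("only ", avail, " non-degenerate axes available")
  }
  k <- max(min(n_axes, ncol(pc$x)), 1L)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    s <- sign(load[which.max(abs(load[, j])), j])
    if (s < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  tot <- sum(pc$sdev^2)
  list(scores = scores, loadings = load,
       pct_var = 100 * pc$sdev[seq_len(k)]^2 / tot)
}

#' Calibrated scalar shape measures
#'
#' `leaf_area()`: absolute area of a closed outline by the shoelace formula,
#' times `scale^2` (cm^2 for outlines calibrated in cm). A self-intersecting
#' polygon triggers a warning and the absolute signed area is returned.
#' `petal_length()`: mean Euclidean distance from the flower center (first
#' landmark) to the four petal tips (landmarks 2-5), times `scale`.
#'
#' @param outline two-column coordinate matrix.
#' @param scale calibration factor (length units per coordinate unit).
#' @return a single numeric value.
#' @export
leaf_area <- function(outline, scale = 1) {
  xy <- as.matrix(outline)
  x <- xy[, 1]; y <- xy[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  abs(sum(x * y2 - x2 * y)) / 2 * scale^2
}

#' @rdname leaf_area
#' @param landmarks 37 x 2 landmark matrix (center, 4 tips, 32 margin
#'   points).
#' @export
petal_length <- function(landmarks, scale = 1) {
  lm <- as.matrix(landmarks)
  stopifnot(nrow(lm) >= 5)
  center <- lm[1, ]
  tips <- lm[2:5, , drop = FALSE]
  mean(sqrt(rowSums(sweep(tips, 2, center)^2))) * scale
}

#' Derive shape trait variables from outlines and landmark configurations
#'
#' The standard shape-trait chain: leaf outlines are resampled, decomposed
#' into `n_harmonics` elliptic Fourier harmonics, and the normalized
#' coefficient rows submitted to a centered PCA whose first `leaf_axes`
#' scores become the leaf-shape variables (V15-V17 by default). Flower
#' configurations are Procrustes-aligned and the flattened aligned
#' coordinates submitted to a PCA whose first `flower_axes` scores become
#' the flower-shape variables (V11-V14). Scalars V02 (leaf area) and V05
#' (mean petal length) are appended.
#'
#' @param shapes output of [gen_shapes()] (or a like-structured list of
#'   coordinate matrices with `population` / `individual` attributes).
#' @param n_harmonics elliptic Fourier harmonics for leaves.
#' @param leaf_axes,flower_axes retained PCA axes.
#' @param n_points resampling density for outlines.
#' @return data.frame with `individual`, `population`, `V02`, `V05`,
#'   `V11`-`V14` (flower PCs) and `V15`-`V17` (leaf PCs; axis counts follow
#'   the arguments). Shape scores are centered across individuals.
#' @export
derive_shape_traits <- function(shapes, n_harmonics = 15, leaf_axes = 3,
                                flower_axes = 4, n_points = 256) {
  ids <- names(shapes$leaves)
  pops <- vapply(shapes$leaves, function(s) attr(s, "population"),
                 character(1))
  coef_rows <- t(vapply(shapes$leaves, function(o) {
    ef <- efa_transform(resample_outline(o, n_points), n_harmonics)
    c(ef$an, ef$bn, ef$cn, ef$dn)
  }, numeric(4 * n_harmonics)))
  leaf_pc <- shape_pca(coef_rows, leaf_axes)
  gpa <- gpa_align(shapes$flowers)
  flat <- t(vapply(gpa$aligned, as.vector,
                   numeric(2 * nrow(gpa$consensus))))
  flower_pc <- shape_pca(flat, flower_axes)
  v02 <- vapply(shapes$leaves, leaf_area, numeric(1))
  v05 <- vapply(shapes$flowers, petal_length, numeric(1))
  out <- data.frame(individual = ids, population = pops,
                    V02 = v02, V05 = v05,
                    flower_pc$scores, leaf_pc$scores,
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out)[seq(5, length.out = flower_axes)] <-
    sprintf("V%02d", 10 + seq_len(flower_axes))
  names(out)[seq(5 + flower_axes, length.out = leaf_axes)] <-
    sprintf("V%02d", 14 + seq_len(leaf_axes))
  attr(out, "leaf_pct_var") <- leaf_pc$pct_var
  attr(out, "flower_pct_var") <- flower_pc$pct_var
  out
}

#' Write and read shape coordinate files
#'
#' Outlines and landmark configurations are exchanged as plain two-column
#' (x, y) whitespace-delimited files, one file per specimen, with a sidecar
#' metadata table (`shapes_meta.tsv`) holding the specimen id, population
#' and calibration scale.
#'
#' @param shapes list of coordinate matrices with `population` /
#'   `individual` attributes (one of the two elements of [gen_shapes()]).
#' @param dir output directory.
#' @param scale calibration factor recorded in the sidecar.
#' @return (write) invisible vector of file paths; (read) list of matrices.
#' @export
write_shape_files <- function(shapes, dir, scale = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- data.frame(individual = names(shapes),
                     population = vapply(shapes, function(s)
                       as.character(attr(s, "population")), character(1)),
                     file = paste0(names(shapes), ".txt"),
                     scale = scale, stringsAsFactors = FALSE)
  for (id in names(shapes)) {
    write.table(format(shapes[[id]], digits = 10),
                file.path(dir, paste0(id, ".txt")),
                row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  write_tsv(meta, file.path(dir, "shapes_meta.tsv"))
  invisible(file.path(dir, meta$file))
}

#' @rdname write_shape_files
#' @export
read_shape_files <- function(dir) {
  meta <- read_tsv(file.path(dir, "shapes_meta.tsv"))
  out <- lapply(seq_len(nrow(meta)), function(i) {
    m <- as.matrix(read.table(file.path(dir, meta$file[i])))
    dimnames(m) <- NULL
    attr(m, "population") <- meta$population[i]
    attr(m, "individual") <- meta$individual[i]
    m * meta$scale[i]
  })
  names(out) <- meta$individual
  out
}
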