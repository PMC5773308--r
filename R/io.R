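# Data model and delimited readers/writers. All tables are tab-separated
# UTF-8 text with '.' decimal and "NA" as the missing token.

#' Marker matrix of dominant band phenotypes
#'
#' Container for an individuals x loci binary (0/1) band matrix with a
#' population assignment per individual. Entries may be `NA` (failed lane).
#'
#' @param bands integer matrix of 0/1/NA with individual row names and locus
#'   column names.
#' @param pop population id per individual (character or factor), named by or
#'   ordered as the rows of `bands`.
#' @param replicate_pairs optional two-column matrix of individual ids that
#'   are scoring replicates of one another.
#' @return object of class `marker_matrix`: list with `bands` and `pop`
#'   (factor), plus the replicate pairs as an attribute.
#' @export
marker_matrix <- function(bands, pop, replicate_pairs = NULL) {
  bands <- as.matrix(bands)
  if (is.null(rownames(bands))) {
    rownames(bands) <- paste0("ind", seq_len(nrow(bands)))
  }
  if (is.null(colnames(bands))) {
    colnames(bands) <- paste0("L", sprintf("%03d", seq_len(ncol(bands))))
  }
  if (anyDuplicated(colnames(bands))) {
    stop("duplicated locus id: ",
         colnames(bands)[anyDuplicated(colnames(bands))])
  }
  bad <- !(bands %in% c(0L, 1L, NA))
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(bands)), arr.ind = TRUE)[1, ]
    stop(sprintf("non-binary band value at individual '%s', locus '%s'",
                 rownames(bands)[idx[1]], colnames(bands)[idx[2]]))
  }
  storage.mode(bands) <- "integer"
  if (!is.null(names(pop))) {
    if (!all(rownames(bands) %in% names(pop))) {
      miss <- setdiff(rownames(bands), names(pop))
      stop("individual(s) with no population assignment: ",
           paste(miss, collapse = ", "))
    }
    pop <- pop[rownames(bands)]
  } else if (length(pop) != nrow(bands)) {
    stop("pop must be named or match the number of individuals")
  }
  if (anyNA(pop)) {
    stop("individual(s) with no population assignment: ",
         paste(rownames(bands)[is.na(pop)], collapse = ", "))
  }
  obj <- list(bands = bands, pop = factor(as.character(pop)))
  names(obj$pop) <- rownames(bands)
  class(obj) <- "marker_matrix"
  attr(obj, "replicate_pairs") <- replicate_pairs
  obj
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("marker_matrix: %d individuals x %d loci, %d populations\n",
              nrow(x$bands), ncol(x$bands), nlevels(x$pop)))
  invisible(x)
}

#' Symmetric population-level distance matrix
#'
#' @param m square symmetric numeric matrix with population labels as
#'   dimnames; the diagonal must be (numerically) zero.
#' @param kind one of `"phi_pt"`, `"geo_km"`, `"bray_curtis_individual"`,
#'   or `"euclid"`.
#' @return object of class `dist_matrix`.
#' @export
dist_matrix <- function(m, kind = c("phi_pt", "geo_km",
                                    "bray_curtis_individual", "euclid")) {
  kind <- match.arg(kind)
  m <- as.matrix(m)
  stopifnot(nrow(m) == ncol(m), !is.null(rownames(m)))
  if (max(abs(m - t(m))) > 1e-12) stop("matrix not symmetric")
  if (max(abs(diag(m))) > 1e-12) stop("non-zero diagonal")
  structure(list(labels = rownames(m), mat = m, kind = kind),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("dist_matrix (%s): %d populations\n", x$kind, length(x$labels)))
  invisible(x)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
             na.strings = "NA", strip.white = TRUE,
             stringsAsFactors = FALSE)
}

write_tsv <- function(df, path, digits = 6) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) trimws(formatC(x, digits = digits,
                                                        format = "g")))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
}

#' Read a marker matrix from a delimited file
#'
#' Tab-separated file with an `individual` column, a `population` column and
#' one 0/1 column per locus. Values other than 0, 1 or the missing token are
#' a hard error with coordinates.
#'
#' @param path file path.
#' @return a [marker_matrix()].
#' @export
read_marker_matrix <- function(path) {
  df <- read_tsv(path)
  stopifnot(all(c("individual", "population") %in% names(df)))
  loci <- setdiff(names(df), c("individual", "population"))
  bands <- as.matrix(df[loci])
  bad <- which(!(bands %in% c(0, 1, NA)), arr.ind = FALSE)
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(bands))
    stop(sprintf("non-binary band value '%s' at row %d, locus '%s' in %s",
                 bands[bad[1]], rc[1], loci[rc[2]], path))
  }
  rownames(bands) <- df$individual
  marker_matrix(bands, setNames(df$population, df$individual))
}

#' Write a marker matrix to a delimited file
#' @param mm a [marker_matrix()].
#' @param path output file path.
#' @export
write_marker_matrix <- function(mm, path) {
  df <- data.frame(individual = rownames(mm$bands),
                   population = as.character(mm$pop),
                   mm$bands, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Load and cross-reference a full dataset
#'
#' Reads the marker matrix, population map, climate table and (optionally)
#' individual trait table, and validates referential integrity: every
#' individual must map to a known population, every population must have
#' coordinates and climate values, and climate cells must be complete
#' (imputation is an error, not a silent default). Loci with zero variance
#' are flagged (retained, but excluded from outlier scans).
#'
#' @param paths named list/vector with elements `markers`, `pops`, `climate`
#'   and optionally `traits`.
#' @param config a [pipeline_config()].
#' @return list with `markers` ([marker_matrix()]), `pops`, `climate`,
#'   `traits` (or NULL), and `zero_variance_loci`.
#' @export
load_dataset <- function(paths, config = pipeline_config()) {
  mm <- read_marker_matrix(paths[["markers"]])
  pops <- read_tsv(paths[["pops"]])
  stopifnot(all(c("population_id", "latitude", "longitude") %in% names(pops)))
  if (anyDuplicated(pops$population_id)) stop("duplicated population ids")
  if (any(abs(pops$latitude) > 90) || any(abs(pops$longitude) > 180)) {
    stop("coordinates out of range")
  }
  unknown <- setdiff(levels(mm$pop), pops$population_id)
  if (length(unknown)) {
    bad_ind <- names(mm$pop)[mm$pop %in% unknown][1]
    stop(sprintf("individual '%s' maps to unknown population '%s'",
                 bad_ind, as.character(mm$pop[bad_ind])))
  }
  climate <- read_tsv(paths[["climate"]])
  stopifnot("population_id" %in% names(climate))
  missing_pop <- setdiff(levels(mm$pop), climate$population_id)
  if (length(missing_pop)) {
    stop("population(s) without climate data: ",
         paste(missing_pop, collapse = ", "))
  }
  if (anyNA(climate)) stop("missing climate cells are an error, not imputed")
  traits <- NULL
  if (!is.null(paths[["traits"]]) && !is.na(paths[["traits"]])) {
    traits <- read_tsv(paths[["traits"]])
    stopifnot("individual" %in% names(traits))
  }
  zv <- colnames(mm$bands)[apply(mm$bands, 2, function(x) {
    x <- x[!is.na(x)]
    length(x) == 0L || max(x) == min(x)
  })]
  list(markers = mm, pops = pops, climate = climate, traits = traits,
       zero_variance_loci = zv)
}

#' Write pipeline result tables
#'
#' Writes tab-delimited result files with stable column order and fixed
#' float precision, plus a run manifest recording configuration, seed and
#' package version. Result layout mirrors the reporting tables of an outlier
#' study: a per-locus outlier table, per-trait GAMOVA tables per locus set,
#' a Mantel summary and the scenario calls.
#'
#' @param results named list of data.frames (e.g. `locus_table`, `gamova`,
#'   `mantel`, `scenarios`); every element is written as `<name>.tsv`.
#' @param out_dir output directory, created if needed.
#' @param config the [pipeline_config()] used, echoed into the manifest.
#' @return invisible vector of written paths.
#' @export
write_results <- function(results, out_dir, config = pipeline_config()) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  if (file.access(out_dir, 2) != 0) stop("output directory not writable: ", out_dir)
  paths <- character(0)
  for (nm in names(results)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write_tsv(as.data.frame(results[[nm]]), p)
    paths <- c(paths, p)
  }
  manifest <- list(package = "aflpselect",
                   version = as.character(packageVersion("aflpselect")),
                   config = config)
  mp <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(paths, mp))
}
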