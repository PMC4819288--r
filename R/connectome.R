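#' Structural connectome container
#'
#' A `connectome` bundles the two square region-by-region matrices produced
#' by diffusion tractography: `weights` (streamline "capacities",
#' dimensionless, symmetric, zero diagonal) and `lengths` (mean streamline
#' length of each edge, in mm), plus per-region metadata.  File order
#' defines region identity; all region indices are taken in file order.
#'
#' Invariants enforced by [validate_connectome()]:
#' * both matrices square, same dimension >= 2;
#' * `weights` symmetric within 1e-9 (matrices are symmetrized as
#'   `(M + t(M))/2` on construction, with a warning when the relative
#'   asymmetry exceeds 1e-6 -- probabilistic tractography output is near-
#'   but not exactly symmetric);
#' * nonnegative weights, zero diagonal;
#' * `lengths[i, j] > 0` wherever `weights[i, j] > 0`.
#'
#' @param weights square numeric matrix of connection capacities
#' @param lengths square numeric matrix of tract lengths (mm)
#' @param region_ids character vector of region labels (defaults to
#'   `"r001"...`)
#' @param centres optional n x 3 matrix of region centre coordinates (mm)
#' @param hemisphere optional per-region factor/character (`"L"`/`"R"`)
#' @param lesion optional per-region logical lesion flag
#' @return an object of class `connectome`
#' @export
connectome <- function(weights, lengths, region_ids = NULL, centres = NULL,
                       hemisphere = NULL, lesion = NULL) {
  if (!is_square(weights) || !is_square(lengths) ||
      nrow(weights) != nrow(lengths) || nrow(weights) < 2L)
    vs_abort("weights and lengths must be square matrices of equal dimension >= 2",
             "nonsquare")
  n <- nrow(weights)
  rel_asym <- function(m) {
    denom <- max(abs(m), 1e-300)
    max(abs(m - t(m))) / denom
  }
  if (rel_asym(weights) > 1e-6)
    vs_warn("weights asymmetry above 1e-6 relative; symmetrizing", "asymmetry")
  weights <- (weights + t(weights)) / 2
  lengths <- (lengths + t(lengths)) / 2
  dimnames(weights) <- NULL
  dimnames(lengths) <- NULL
  if (is.null(region_ids)) region_ids <- sprintf("r%03d", seq_len(n))
  obj <- structure(
    list(region_ids = as.character(region_ids), weights = weights,
         lengths = lengths, centres = centres,
         hemisphere = hemisphere, lesion = lesion),
    class = "connectome")
  validate_connectome(obj)
  obj
}

#' Validate connectome invariants
#'
#' Rejects exactly the four invariant violations of the container, each
#' with a distinct condition class: `vs_error_nonsquare`,
#' `vs_error_negative_weight`, `vs_error_nonzero_diagonal`,
#' `vs_error_zero_length_edge` (plus `vs_error_asymmetry` for matrices
#' asymmetric beyond tolerance after construction-time symmetrization).
#'
#' @param conn a `connectome`
#' @return `conn`, invisibly
#' @export
validate_connectome <- function(conn) {
  w <- conn$weights
  l <- conn$lengths
  if (!is_square(w) || !is_square(l) || nrow(w) != nrow(l) || nrow(w) < 2L)
    vs_abort("matrices must be square, equal dimension >= 2", "nonsquare")
  if (length(conn$region_ids) != nrow(w))
    vs_abort("region_ids length must match matrix dimension", "nonsquare")
  if (max(abs(w - t(w))) > 1e-9)
    vs_abort("weights not symmetric within 1e-9", "asymmetry")
  neg <- which(w < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    vs_abort(sprintf("negative weights at indices (%s)",
                     paste(sprintf("%d,%d", neg[, 1], neg[, 2])[seq_len(min(5, nrow(neg)))],
                           collapse = "; ")),
             "negative_weight")
  if (any(diag(w) != 0))
    vs_abort("weights diagonal must be zero", "nonzero_diagonal")
  bad <- which(w > 0 & l <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    vs_abort(sprintf("zero/negative length on %d nonzero-weight edge(s), first at (%d,%d)",
                     nrow(bad), bad[1, 1], bad[1, 2]),
             "zero_length_edge")
  invisible(conn)
}

#' @export
print.connectome <- function(x, ...) {
  n <- nrow(x$weights)
  ne <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("connectome: %d regions, %d edges (density %.3f)\n",
              n, ne, ne / (n * (n - 1) / 2)))
  invisible(x)
}

n_regions <- function(conn) nrow(conn$weights)

#' Summarize the nonzero connection weights of a connectome
#'
#' Moments are computed over the nonzero upper-triangle weights after a
#' configured transform.  The default transform is the natural log of the
#' capacities: raw streamline capacities span orders of magnitude, and
#' cohort-level weight summaries in this pipeline live on the log scale.
#' Skewness is the standardized third central moment (biased, n-denominator
#' form).
#'
#' @param conn a `connectome`
#' @param transform `"log"` (default) or `"identity"`
#' @return a `weight_summary` list with fields `n_edges`, `mean`, `sd`,
#'   `min`, `max`, `skewness`, `transform`
#' @export
summarize_weights <- function(conn, transform = c("log", "identity")) {
  transform <- match.arg(transform)
  w <- conn$weights[upper.tri(conn$weights)]
  w <- w[w > 0]
  if (length(w) == 0)
    vs_abort("all-zero weight matrix: nothing to summarize", "empty_summary")
  x <- if (transform == "log") log(w) else w
  m <- mean(x)
  s <- sd(x)
  skew <- if (s == 0 || length(x) < 3) 0 else {
    mean((x - m)^3) / (sqrt(mean((x - m)^2)))^3
  }
  structure(list(n_edges = length(x), mean = m, sd = if (is.na(s)) 0 else s,
                 min = min(x), max = max(x), skewness = skew,
                 transform = transform),
            class = "weight_summary")
}

#' Read a structural connectome from disk
#'
#' Two dialects are supported:
#' * `"connectivity-zip"`: a zip archive holding whitespace-delimited
#'   `weights.txt`, `tract_lengths.txt` and optionally `centres.txt`
#'   (label x y z per row) -- the de-facto layout used by whole-brain
#'   simulation platforms;
#' * `"delimited-pair"`: `<base>_weights.csv` and `<base>_lengths.csv`
#'   (comma-delimited matrices) plus a JSON sidecar `<base>_regions.json`
#'   with region labels and optional centres/hemisphere/lesion flags.
#'   `path` is the `<base>` stem.
#'
#' @param path archive path (zip) or file stem (delimited-pair)
#' @param format `"connectivity-zip"` or `"delimited-pair"`
#' @return a validated `connectome`, region order as in the file
#' @export
read_connectome <- function(path, format = c("connectivity-zip", "delimited-pair")) {
  format <- match.arg(format)
  if (format == "connectivity-zip") {
    if (!file.exists(path)) vs_abort(paste("no such file:", path), "io")
    exdir <- tempfile("connzip")
    dir.create(exdir)
    on.exit(unlink(exdir, recursive = TRUE))
    utils::unzip(path, exdir = exdir)
    wf <- file.path(exdir, "weights.txt")
    lf <- file.path(exdir, "tract_lengths.txt")
    if (!file.exists(wf) || !file.exists(lf))
      vs_abort("archive must contain weights.txt and tract_lengths.txt", "format")
    weights <- parse_matrix_lines(readLines(wf))
    lengths <- parse_matrix_lines(readLines(lf))
    centres <- NULL; ids <- NULL
    cf <- file.path(exdir, "centres.txt")
    if (file.exists(cf)) {
      toks <- strsplit(trimws(readLines(cf)), "[[:space:]]+")
      toks <- toks[vapply(toks, length, 1L) > 0]
      ids <- vapply(toks, `[[`, "", 1L)
      centres <- do.call(rbind, lapply(toks, function(t) as.numeric(t[2:4])))
    }
  } else {
    wf <- paste0(path, "_weights.csv")
    lf <- paste0(path, "_lengths.csv")
    jf <- paste0(path, "_regions.json")
    if (!file.exists(wf) || !file.exists(lf))
      vs_abort(paste("missing matrix file(s) for stem", path), "io")
    weights <- as.matrix(utils::read.csv(wf, header = FALSE))
    lengths <- as.matrix(utils::read.csv(lf, header = FALSE))
    dimnames(weights) <- NULL; dimnames(lengths) <- NULL
    ids <- NULL; centres <- NULL; hemi <- NULL; les <- NULL
    if (file.exists(jf)) {
      meta <- jsonlite::read_json(jf, simplifyVector = TRUE)
      ids <- meta$region_ids
      if (!is.null(meta$centres)) centres <- matrix(unlist(meta$centres), ncol = 3)
      hemi <- meta$hemisphere
      les <- meta$lesion
    }
    if (!is_square(weights) || !is_square(lengths) ||
        nrow(weights) != nrow(lengths))
      vs_abort("matrices must parse to equal square dimensions", "nonsquare")
    return(connectome(weights, lengths, region_ids = ids, centres = centres,
                      hemisphere = hemi, lesion = les))
  }
  if (!is_square(weights) || !is_square(lengths) ||
      nrow(weights) != nrow(lengths))
    vs_abort("matrices must parse to equal square dimensions", "nonsquare")
  connectome(weights, lengths, region_ids = ids, centres = centres)
}

#' Write a structural connectome to disk
#'
#' Inverse of [read_connectome()]; numeric values are written at 17
#' significant digits so `read_connectome(write_connectome(c))` reproduces
#' `c` to full double precision.  Region reordering on write is not
#' supported: file order is region identity.
#'
#' @param conn a validated `connectome`
#' @param path archive path (zip) or file stem (delimited-pair)
#' @param format `"connectivity-zip"` or `"delimited-pair"`
#' @param reorder must be `NULL`; any permutation request errors
#' @return `path`, invisibly
#' @export
write_connectome <- function(conn, path,
                             format = c("connectivity-zip", "delimited-pair"),
                             reorder = NULL) {
  format <- match.arg(format)
  if (!is.null(reorder))
    vs_abort("region reordering on write is unsupported", "unsupported_option")
  validate_connectome(conn)
  if (format == "connectivity-zip") {
    entries <- list(
      "weights.txt" = paste0(format_matrix_lines(conn$weights), "\n"),
      "tract_lengths.txt" = paste0(format_matrix_lines(conn$lengths), "\n")
    )
    centres <- conn$centres
    if (is.null(centres)) centres <- matrix(0, n_regions(conn), 3)
    entries[["centres.txt"]] <- paste0(
      sprintf("%s %.17g %.17g %.17g\n", conn$region_ids,
              centres[, 1], centres[, 2], centres[, 3]), collapse = "")
    entries <- lapply(entries, function(e) paste0(e, collapse = ""))
    zip_write(path, entries)
  } else {
    wl <- vapply(seq_len(nrow(conn$weights)), function(i)
      paste(sprintf("%.17g", conn$weights[i, ]), collapse = ","), "")
    ll <- vapply(seq_len(nrow(conn$lengths)), function(i)
      paste(sprintf("%.17g", conn$lengths[i, ]), collapse = ","), "")
    writeLines(wl, paste0(path, "_weights.csv"))
    writeLines(ll, paste0(path, "_lengths.csv"))
    meta <- list(region_ids = conn$region_ids)
    if (!is.null(conn$centres)) meta$centres <- unname(apply(conn$centres, 1, as.list))
    if (!is.null(conn$hemisphere)) meta$hemisphere <- conn$hemisphere
    if (!is.null(conn$lesion)) meta$lesion <- conn$lesion
    jsonlite::write_json(meta, paste0(path, "_regions.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
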