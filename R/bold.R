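#' Gamma-kernel hemodynamic response function
#'
#' Discretized gamma density `t^(shape-1) exp(-t/scale)`, truncated at
#' `length` seconds and renormalized to unit sum, so a constant neural
#' input maps to the same constant BOLD level.  The kernel peaks at
#' `(shape - 1) * scale` seconds; defaults (shape 6, scale 1 s, support
#' 25 s) are the canonical single-gamma response peaking near 5 s.
#'
#' @param shape gamma shape (> 1)
#' @param scale gamma scale in seconds (> 0)
#' @param length kernel support in seconds (must exceed the peak time)
#' @param dt kernel sampling step in seconds
#' @return an `hrf_kernel` with fields `shape`, `scale`, `length`, `dt`,
#'   `values` (unit sum)
#' @export
make_gamma_hrf <- function(shape = 6, scale = 1, length = 25, dt = 0.001) {
  if (shape <= 1 || scale <= 0) vs_abort("need shape > 1 and scale > 0", "parameter")
  if (length < (shape - 1) * scale)
    vs_abort("kernel support shorter than its peak time", "configuration")
  tt <- seq(0, length, by = dt)
  v <- dgamma(tt, shape = shape, scale = scale)
  v <- v / sum(v)
  structure(list(shape = shape, scale = scale, length = length, dt = dt,
                 values = v, times = tt),
            class = "hrf_kernel")
}

#' BOLD series container
#'
#' @param values regions x samples numeric matrix
#' @param tr repetition time in seconds
#' @param region_ids optional labels
#' @return a `bold_series`
#' @export
bold_series <- function(values, tr = 2, region_ids = NULL) {
  if (!is.matrix(values)) values <- matrix(values, nrow = 1)
  if (any(!is.finite(values))) vs_abort("non-finite BOLD values", "input")
  structure(list(values = values, tr = tr,
                 duration = ncol(values) * tr,
                 region_ids = region_ids),
            class = "bold_series")
}

#' Convolve a neural trajectory with an HRF and sample at the TR
#'
#' Per-region causal convolution with the (resampled) kernel, then
#' decimation to one sample per repetition time (sample-at-grid: the
#' convolved signal is read at `t = k * TR`; the HRF itself is the
#' anti-alias filter).  Output length is `floor(duration / tr)`.  The
#' first kernel-length seconds after the simulator burn-in are part of the
#' hemodynamic transient; downstream metrics drop them via
#' `transient_samples`.
#'
#' @param traj a `neural_trajectory` (or any list with `values` matrix and
#'   `dt_record` in ms)
#' @param hrf an `hrf_kernel`; its `dt` must be >= the trajectory step and
#'   is re-discretized onto the trajectory grid
#' @param tr repetition time in seconds (default 2)
#' @return a `bold_series` with attribute field `transient_samples`
#' @export
neural_to_bold <- function(traj, hrf = make_gamma_hrf(), tr = 2) {
  x <- traj$values
  if (is.null(x) || length(x) == 0) vs_abort("empty trajectory", "input")
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  step_s <- traj$dt_record / 1000
  if (step_s > hrf$dt + 1e-12)
    vs_abort("trajectory sampling step exceeds hrf.dt", "input")
  n_t <- ncol(x)
  dur <- n_t * step_s
  if (dur < tr) vs_abort("trajectory shorter than one TR", "input")
  # kernel on the trajectory grid, renormalized
  kt <- seq(0, hrf$length, by = step_s)
  k <- dgamma(kt, shape = hrf$shape, scale = hrf$scale)
  k <- k / sum(k)
  nk <- length(k)
  nfft <- 2^ceiling(log2(n_t + nk - 1))
  K <- fft(c(k, rep(0, nfft - nk)))
  n_out <- floor(dur / tr)
  idx <- as.integer(round(seq_len(n_out) * tr / step_s))
  idx[idx > n_t] <- n_t
  y <- matrix(0, nrow(x), n_out)
  for (i in seq_len(nrow(x))) {
    X <- fft(c(x[i, ], rep(0, nfft - n_t)))
    conv <- Re(fft(X * K, inverse = TRUE)) / nfft
    y[i, ] <- conv[idx]
  }
  out <- bold_series(y, tr = tr, region_ids = traj$region_ids)
  out$transient_samples <- ceiling(hrf$length / tr)
  out
}

#' Write / read a BOLD series as delimited text plus JSON header
#'
#' The same format is accepted for empirical series used as fitting
#' targets: `<path>.tsv` holds the regions x samples matrix, `<path>.json`
#' the TR, duration and provenance.
#'
#' @param bold a `bold_series`
#' @param path file stem
#' @param provenance optional list stored in the header
#' @return `read_bold` returns a `bold_series`
#' @export
write_bold <- function(bold, path, provenance = NULL) {
  writeLines(vapply(seq_len(nrow(bold$values)), function(i)
    paste(sprintf("%.17g", bold$values[i, ]), collapse = "\t"), ""),
    paste0(path, ".tsv"))
  hdr <- list(tr = bold$tr, duration = bold$duration,
              region_ids = bold$region_ids, provenance = provenance)
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_bold
#' @export
read_bold <- function(path) {
  lines <- readLines(paste0(path, ".tsv"))
  vals <- do.call(rbind, lapply(strsplit(lines, "\t"), as.numeric))
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  b <- bold_series(vals, tr = hdr$tr, region_ids = hdr$region_ids)
  b
}
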