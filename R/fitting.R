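#' Amplitude range of a BOLD series
#'
#' Scans every region for local extrema (interior samples that are
#' turning points) and reports the global minimum and maximum across all
#' regions' extrema, plus the mean amplitude: the mean over regions of
#' `(max - min)/2` of that region's extrema.  Monotone or constant
#' regions contribute their overall range (zero for a constant series --
#' not an error).
#'
#' @param bold a `bold_series`
#' @return list with `min`, `max`, `mean_amplitude`
#' @export
amplitude_range <- function(bold) {
  x <- bold$values
  if (ncol(x) < 2) vs_abort("need at least 2 samples", "input")
  per_region <- apply(x, 1L, function(v) {
    n <- length(v)
    d <- diff(v)
    turning <- which(d[-length(d)] * d[-1] < 0) + 1L
    ext <- v[turning]
    if (length(ext) == 0) ext <- range(v)
    c(min(ext), max(ext))
  })
  mins <- per_region[1, ]; maxs <- per_region[2, ]
  list(min = min(mins), max = max(maxs),
       mean_amplitude = mean((maxs - mins) / 2))
}

#' One-sided power spectrum of a BOLD series
#'
#' Each region is mean-removed, transformed with the FFT at sampling
#' frequency `1/tr` (0.5 Hz at the default TR of 2 s), and the one-sided
#' power profiles are averaged across regions.  The peak frequency is the
#' argmax over nonzero bins; the resolvable range is (0, fs/2], i.e.
#' 0-0.25 Hz at TR 2 s.
#'
#' @param bold a `bold_series`
#' @return a `spectrum_summary` with `freqs` (Hz), `power` (mean across
#'   regions), `peak_freq` (Hz), `fs`
#' @export
spectrum <- function(bold) {
  x <- bold$values
  n <- ncol(x)
  if (n < 8) vs_abort("need at least 8 samples for a spectrum", "input")
  fs <- 1 / bold$tr
  nb <- floor(n / 2) + 1L
  freqs <- (seq_len(nb) - 1) * fs / n
  pow <- rep(0, nb)
  for (i in seq_len(nrow(x))) {
    v <- x[i, ] - mean(x[i, ])
    P <- Mod(fft(v))^2 / n
    pow <- pow + P[seq_len(nb)]
  }
  pow <- pow / nrow(x)
  peak <- freqs[-1][which.max(pow[-1])]
  structure(list(freqs = freqs, power = pow, peak_freq = peak, fs = fs),
            class = "spectrum_summary")
}

#' Functional connectivity matrix
#'
#' Pairwise Pearson correlation of the regional time series.  Regions
#' with zero variance yield `NA` rows/columns (flagged with a warning);
#' the diagonal is always 1.
#'
#' @param bold a `bold_series`
#' @return an `fc_matrix` (square correlation matrix with class attribute)
#' @export
fc_matrix <- function(bold) {
  x <- bold$values
  if (ncol(x) < 3) vs_abort("need at least 3 samples for FC", "input")
  sds <- apply(x, 1, sd)
  if (any(sds == 0))
    vs_warn(sprintf("%d zero-variance region(s): FC entries undefined",
                    sum(sds == 0)), "zero_variance")
  fc <- suppressWarnings(cor(t(x)))
  diag(fc) <- 1
  structure(fc, class = c("fc_matrix", "matrix", "array"))
}

#' Similarity between two FC matrices
#'
#' Pearson correlation of the upper-triangle (diagonal excluded) entries,
#' plus its Fisher z transform for pooling across subjects.
#'
#' @param sim,ref `fc_matrix` (or plain square matrices) of equal dimension
#' @return list with `similarity` (in [-1, 1]) and `fisher_z`
#' @export
fc_similarity <- function(sim, ref) {
  if (!all(dim(sim) == dim(ref)))
    vs_abort("FC dimension mismatch", "input")
  ut <- upper.tri(sim)
  a <- sim[ut]; b <- ref[ut]
  keep <- is.finite(a) & is.finite(b)
  r <- cor(a[keep], b[keep])
  list(similarity = r, fisher_z = atanh(min(max(r, -1 + 1e-15), 1 - 1e-15)))
}

#' Pool control FC matrices into a group reference
#'
#' Entrywise Fisher-z average back-transformed to the correlation scale
#' (`tanh(mean(atanh(r)))`); the diagonal stays 1.
#'
#' @param controls list of square FC matrices of equal dimension
#' @return an `fc_matrix`
#' @export
pool_fc_reference <- function(controls) {
  if (length(controls) == 0) vs_abort("empty FC list", "input")
  d <- dim(controls[[1]])
  for (m in controls) if (!all(dim(m) == d)) vs_abort("FC dimension mismatch", "input")
  eps <- 1e-15
  z <- Reduce(`+`, lapply(controls, function(m)
    atanh(pmin(pmax(unclass(m), -1 + eps), 1 - eps)))) / length(controls)
  out <- tanh(z)
  diag(out) <- 1
  structure(out, class = c("fc_matrix", "matrix", "array"))
}

#' Explore global variance over a (coupling, velocity) grid
#'
#' One short stochastic simulation per grid cell, each with a
#' deterministic per-cell seed derived from the base seed and the cell
#' counter, measuring the global variance: the mean across regions of the
#' per-region temporal variance of the recorded mean field.  This is the
#' heat-map stage used to locate dynamically rich regimes before any BOLD
#' derivation.  Diverging cells are marked `NA`; the map completes.
#'
#' @param conn a `connectome`
#' @param p an `sj3d_params`
#' @param coupling_grid,velocity_grid numeric axes (within 0.01-1.0 and
#'   10-100 respectively)
#' @param cfg a `sim_config` (exploration runs are typically short, e.g.
#'   `duration = 30`)
#' @return a `variance_map`: `variance` is |velocity| x |coupling|
#' @export
explore_global <- function(conn, p, coupling_grid, velocity_grid, cfg) {
  if (any(coupling_grid < 0.01 - 1e-12) || any(coupling_grid > 1 + 1e-12))
    vs_abort("coupling grid outside exploration bounds [0.01, 1]", "parameter")
  if (any(velocity_grid < 10 - 1e-9) || any(velocity_grid > 100 + 1e-9))
    vs_abort("velocity grid outside exploration bounds [10, 100]", "parameter")
  nv <- length(velocity_grid); nc <- length(coupling_grid)
  vmap <- matrix(NA_real_, nv, nc)
  cell <- 0L
  for (ci in seq_len(nc)) for (vi in seq_len(nv)) {
    cell <- cell + 1L
    cfg_cell <- cfg
    cfg_cell$seed <- derive_seed(cfg$seed, 100L + cell)
    tr_res <- tryCatch(
      simulate_network(conn, p,
                       global_params(coupling_grid[ci], velocity_grid[vi]),
                       cfg_cell),
      error = function(e) NULL)
    if (!is.null(tr_res))
      vmap[vi, ci] <- mean(apply(tr_res$values, 1, var))
  }
  structure(list(coupling_axis = coupling_grid, velocity_axis = velocity_grid,
                 variance = vmap, seed = cfg$seed, config = cfg),
            class = "variance_map")
}

#' Select parameter ranges from a variance map
#'
#' High-variance cells are those at or above the `quantile_threshold`
#' quantile of the (finite) map.  Bifurcation-like boundaries are grid
#' locations where the discrete derivative along an axis exceeds
#' `jump_factor` times the median absolute derivative of the map.  The
#' selection is the largest contiguous run of high-variance columns
#' (coupling) crossed with the largest contiguous run of high-variance
#' rows (velocity); ties break toward lower coupling / lower velocity.
#' Because the threshold is a quantile, the selection is invariant to
#' monotone rescaling of the map.
#'
#' @param map a `variance_map`
#' @param quantile_threshold high-variance quantile (default 0.75)
#' @param jump_factor boundary jump multiple of the median absolute
#'   derivative (default 5)
#' @return a `range_selection` with `coupling_range`, `velocity_range`,
#'   `boundary_cells`, `quality`, `empty`
#' @export
select_range <- function(map, quantile_threshold = 0.75, jump_factor = 5) {
  v <- map$variance
  if (nrow(v) < 2 || ncol(v) < 2)
    vs_abort("need at least 2 cells per axis", "input")
  fin <- v[is.finite(v)]
  if (length(fin) == 0 || all(fin == 0)) {
    thr <- Inf
  } else {
    thr <- quantile(fin, quantile_threshold, names = FALSE)
  }
  high <- is.finite(v) & v >= thr
  if (!any(high)) {
    return(structure(list(coupling_range = NULL, velocity_range = NULL,
                          boundary_cells = NULL, quality = 0, empty = TRUE),
                     class = "range_selection"))
  }
  longest_run <- function(active) {
    r <- rle(active)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cand <- which(r$values)
    best <- cand[which.max(r$lengths[cand])]  # ties: first = lower axis value
    c(starts[best], ends[best])
  }
  col_run <- longest_run(apply(high, 2, any))
  row_run <- longest_run(apply(high, 1, any))
  dc <- abs(matrix(t(apply(v, 1, diff)), nrow = nrow(v)))   # along coupling
  dv <- abs(matrix(apply(v, 2, diff), ncol = ncol(v)))      # along velocity
  alld <- c(dc, dv)
  alld <- alld[is.finite(alld)]
  boundaries <- NULL
  if (length(alld) == 0 || all(alld == 0)) {
    vs_warn("flat map: no boundaries detectable", "no_boundary")
  } else {
    thr_j <- jump_factor * median(alld)
    # mostly-flat maps have zero median derivative; any jump comparable to
    # the largest one then counts as a boundary
    if (thr_j == 0) thr_j <- 0.5 * max(alld)
    bc <- which(dc > thr_j, arr.ind = TRUE)
    bv <- which(dv > thr_j, arr.ind = TRUE)
    boundaries <- list(coupling_jumps = bc, velocity_jumps = bv)
    if (nrow(bc) == 0 && nrow(bv) == 0)
      vs_warn("no bifurcation-scale jumps detected in the map", "no_boundary")
  }
  box <- high[row_run[1]:row_run[2], col_run[1]:col_run[2], drop = FALSE]
  structure(list(
    coupling_range = range(map$coupling_axis[col_run[1]:col_run[2]]),
    velocity_range = range(map$velocity_axis[row_run[1]:row_run[2]]),
    coupling_idx = col_run, velocity_idx = row_run,
    boundary_cells = boundaries,
    quality = mean(box), empty = FALSE),
    class = "range_selection")
}

# Drop the hemodynamic transient (when flagged on the series) and return
# the three per-series fit quantities.
drop_transient <- function(bold) {
  ts <- if (!is.null(bold$transient_samples)) bold$transient_samples else 0L
  vals <- bold$values
  if (ncol(vals) - ts >= 8) vals <- vals[, (ts + 1):ncol(vals), drop = FALSE]
  b <- bold_series(vals, tr = bold$tr)
  b$transient_samples <- 0L
  b
}

metric_inputs <- function(bold) {
  b <- drop_transient(bold)
  list(amplitude = amplitude_range(b)$mean_amplitude,
       peak = spectrum(b)$peak_freq,
       fc = suppressWarnings(fc_matrix(b)))
}

#' Serialize / deserialize a variance map
#'
#' `<stem>.tsv` holds the velocity-by-coupling variance matrix,
#' `<stem>.json` the axes and seed provenance.
#'
#' @param map a `variance_map`
#' @param stem file stem
#' @return `read_variance_map` returns a `variance_map`
#' @export
write_variance_map <- function(map, stem) {
  writeLines(vapply(seq_len(nrow(map$variance)), function(i)
    paste(sprintf("%.17g", map$variance[i, ]), collapse = "\t"), ""),
    paste0(stem, ".tsv"))
  jsonlite::write_json(list(coupling_axis = map$coupling_axis,
                            velocity_axis = map$velocity_axis,
                            seed = map$seed),
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_variance_map
#' @export
read_variance_map <- function(stem) {
  v <- do.call(rbind, lapply(strsplit(readLines(paste0(stem, ".tsv")), "\t"),
                             as.numeric))
  hdr <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  structure(list(coupling_axis = hdr$coupling_axis,
                 velocity_axis = hdr$velocity_axis,
                 variance = v, seed = hdr$seed),
            class = "variance_map")
}

#' Heat-map rendering of a global-variance exploration
#'
#' @param x a `variance_map`
#' @param ... passed to [graphics::image()]
#' @export
plot.variance_map <- function(x, ...) {
  graphics::image(x$coupling_axis, x$velocity_axis, t(x$variance),
                  xlab = "global coupling", ylab = "conduction velocity (m/s)",
                  main = "global variance", ...)
  invisible(x)
}

#' @export
print.variance_map <- function(x, ...) {
  cat(sprintf("variance map: %d velocity x %d coupling cells (%d invalid)\n",
              nrow(x$variance), ncol(x$variance), sum(!is.finite(x$variance))))
  invisible(x)
}

#' @export
print.fit_report <- function(x, ...) {
  s <- x$selected
  cat(sprintf(
    "fit report: %d candidates; selected coupling=%.3g velocity=%.3g K12=%.3g K21=%.3g K11=%.3g\n",
    nrow(x$candidates), s$coupling, s$velocity, s$K12, s$K21, s$K11))
  invisible(x)
}

bold_metrics <- function(bold, target_amp, target_peak, ref_fc) {
  mi <- metric_inputs(bold)
  sim <- fc_similarity(mi$fc, ref_fc)$similarity
  c(amplitude_distance = abs(mi$amplitude - target_amp),
    frequency_distance = abs(mi$peak - target_peak),
    phase_similarity = if (is.na(sim)) -1 else sim)
}

#' Fit global and local parameters against a target BOLD series
#'
#' Grid fitting by the three validation metrics: amplitude (absolute
#' difference of mean amplitudes), frequency (absolute difference of
#' spectral peak frequencies) and phase (correlation between the
#' candidate's FC matrix and `ref_fc`).  Per candidate the network is
#' simulated and converted to BOLD; metrics are ranked (amplitude and
#' frequency ascending, phase descending) and summed into a combined
#' rank; the minimal combined rank wins, ties breaking toward lower
#' coupling, then lower velocity, then lower K values.
#'
#' Stages are sequential: first the (coupling, velocity) grid with the
#' local gains held at `p`, then 1-D sweeps of `K12`, `K21`, `K11` (in
#' that order, each holding the current best).  Every candidate
#' simulation reuses the same seed (`cfg$seed`): common random numbers
#' make candidates directly comparable and the procedure deterministic
#' given `(seed, grids, target)`.
#'
#' @param conn a `connectome`
#' @param p an `sj3d_params` (starting local gains)
#' @param grids named list of candidate vectors; recognized names:
#'   `coupling`, `velocity`, `K12`, `K21`, `K11` (missing local axes are
#'   skipped)
#' @param target a `bold_series` to match
#' @param ref_fc reference FC matrix for the phase metric (e.g. pooled
#'   controls, or the target's own FC)
#' @param cfg a `sim_config` for candidate simulations
#' @param hrf HRF kernel for the BOLD stage
#' @return a `fit_report`: `candidates` data.frame (one row per evaluated
#'   candidate with metrics and ranks), `selected` named list of parameter
#'   values, `selected_params` an `sj3d_params`, `selected_global` a
#'   `global_params`
#' @export
fit_parameters <- function(conn, p, grids, target, ref_fc, cfg,
                           hrf = make_gamma_hrf()) {
  ti <- metric_inputs(target)
  target_amp <- ti$amplitude
  target_peak <- ti$peak
  eval_candidate <- function(cp, vv, K12, K21, K11) {
    p2 <- p; p2$K12 <- K12; p2$K21 <- K21; p2$K11 <- K11
    tr_res <- tryCatch(
      simulate_network(conn, p2, global_params(cp, vv), cfg),
      error = function(e) NULL)
    if (is.null(tr_res)) return(c(NA_real_, NA_real_, NA_real_))
    bold_metrics(neural_to_bold(tr_res, hrf, tr = target$tr),
                 target_amp, target_peak, ref_fc)
  }
  rank_table <- function(df) {
    ok <- stats::complete.cases(df[, c("amplitude_distance",
                                       "frequency_distance",
                                       "phase_similarity")])
    if (!any(ok)) vs_abort("all candidates diverged", "fit_failure")
    df$rank_amplitude <- NA_real_
    df$rank_frequency <- NA_real_
    df$rank_phase <- NA_real_
    df$rank_amplitude[ok] <- rank(df$amplitude_distance[ok], ties.method = "min")
    df$rank_frequency[ok] <- rank(df$frequency_distance[ok], ties.method = "min")
    df$rank_phase[ok] <- rank(-df$phase_similarity[ok], ties.method = "min")
    df$combined_rank <- df$rank_amplitude + df$rank_frequency + df$rank_phase
    df
  }
  pick_best <- function(df) {
    df <- df[order(df$combined_rank, df$coupling, df$velocity,
                   df$K12, df$K21, df$K11), ]
    df[1, ]
  }
  cps <- if (!is.null(grids$coupling)) grids$coupling else 0.05
  vvs <- if (!is.null(grids$velocity)) grids$velocity else 60
  g1 <- expand.grid(coupling = cps, velocity = vvs,
                    K12 = p$K12, K21 = p$K21, K11 = p$K11)
  g1$stage <- "global"
  mets <- t(mapply(eval_candidate, g1$coupling, g1$velocity,
                   g1$K12, g1$K21, g1$K11))
  g1$amplitude_distance <- mets[, 1]
  g1$frequency_distance <- mets[, 2]
  g1$phase_similarity <- mets[, 3]
  g1 <- rank_table(g1)
  best <- pick_best(g1)
  tables <- list(g1)
  cur <- list(coupling = best$coupling, velocity = best$velocity,
              K12 = best$K12, K21 = best$K21, K11 = best$K11)
  for (kname in c("K12", "K21", "K11")) {
    axis <- grids[[kname]]
    if (is.null(axis) || length(axis) < 1) next
    gk <- data.frame(coupling = cur$coupling, velocity = cur$velocity,
                     K12 = cur$K12, K21 = cur$K21, K11 = cur$K11)
    gk <- gk[rep(1, length(axis)), ]
    gk[[kname]] <- axis
    gk$stage <- kname
    mets <- t(mapply(eval_candidate, gk$coupling, gk$velocity,
                     gk$K12, gk$K21, gk$K11))
    gk$amplitude_distance <- mets[, 1]
    gk$frequency_distance <- mets[, 2]
    gk$phase_similarity <- mets[, 3]
    gk <- rank_table(gk)
    bk <- pick_best(gk)
    cur[[kname]] <- bk[[kname]]
    tables <- c(tables, list(gk))
  }
  candidates <- do.call(rbind, tables)
  rownames(candidates) <- NULL
  p_sel <- p; p_sel$K12 <- cur$K12; p_sel$K21 <- cur$K21; p_sel$K11 <- cur$K11
  structure(list(candidates = candidates, selected = cur,
                 selected_params = p_sel,
                 selected_global = global_params(cur$coupling, cur$velocity),
                 target_amplitude = target_amp, target_peak = target_peak,
                 seed = cfg$seed),
            class = "fit_report")
}
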