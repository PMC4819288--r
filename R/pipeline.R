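#' End-to-end pipeline configuration
#'
#' Gathers every tunable of the subject-level analysis with the protocol
#' defaults: exploration over coupling 0.01-1.0 and velocity 10-100 m/s,
#' short exploration simulations, longer fitting/validation simulations
#' at the acquisition-matched duration (240 s, TR 2 s), and a single base
#' seed expanded into per-stage seeds via [derive_seed()] (stage counters:
#' 1 exploration, 2 fitting, 3 validation simulation).
#'
#' Unknown configuration keys are rejected rather than silently ignored.
#'
#' @param seed base seed
#' @param explore_coupling,explore_velocity exploration grid axes
#' @param fit_points grid points per axis for the fitting stage
#' @param local_grid candidate values for each local gain sweep
#' @param explore_cfg,fit_cfg `sim_config`s for the two stages
#' @param tr repetition time (s)
#' @param hrf an `hrf_kernel`
#' @param ... rejected
#' @return a `pipeline_config`
#' @export
pipeline_config <- function(seed = 42L,
                            explore_coupling = seq(0.01, 1, length.out = 8),
                            explore_velocity = seq(10, 100, length.out = 8),
                            fit_points = 5L,
                            local_grid = seq(0.1, 1, length.out = 10),
                            explore_cfg = sim_config(dt = 0.1, duration = 30,
                                                     burn_in = 5, seed = seed),
                            fit_cfg = sim_config(dt = 0.1, duration = 240,
                                                 burn_in = 10, seed = seed),
                            tr = 2, hrf = make_gamma_hrf(), ...) {
  extra <- list(...)
  if (length(extra) > 0)
    vs_abort(paste("unknown configuration key(s):",
                   paste(names(extra), collapse = ", ")), "config")
  structure(list(seed = as.integer(seed),
                 explore_coupling = explore_coupling,
                 explore_velocity = explore_velocity,
                 fit_points = as.integer(fit_points),
                 local_grid = local_grid,
                 explore_cfg = explore_cfg, fit_cfg = fit_cfg,
                 tr = tr, hrf = hrf),
            class = "pipeline_config")
}

grid_in_range <- function(rng, n, lo, hi) {
  g <- seq(max(rng[1], lo), min(rng[2], hi), length.out = n)
  unique(g)
}

#' Run the subject-level modelling pipeline
#'
#' Executes the sequential per-subject protocol: (1) import the
#' connectome, (2) local model selection (SJ3D), (3) parameter-space
#' exploration over (coupling, velocity) with global-variance maps and
#' bifurcation-flanked range selection, then parameter fitting against
#' the target BOLD by amplitude/frequency/phase, (4-5) stochastic network
#' simulation at the selected parameters and BOLD derivation, (6)
#' validation metrics against the target.  Without a target the pipeline
#' stops after exploration with status `"no-fit"`.
#'
#' @param conn a `connectome`
#' @param config a `pipeline_config`
#' @param target optional `bold_series` fitting target
#' @param ref_fc optional reference FC for the phase metric; defaults to
#'   the target's own FC
#' @param p starting `sj3d_params`
#' @return a subject bundle: `status`, `variance_map`, `range`,
#'   `fit` (a `fit_report` or `NULL`), `selected`, `bold`, `fc`,
#'   `manifest` (stage seeds and wall-clock seconds)
#' @export
run_subject <- function(conn, config, target = NULL, ref_fc = NULL,
                        p = sj3d_params()) {
  t0 <- proc.time()[["elapsed"]]
  manifest <- list(base_seed = config$seed)
  ecfg <- config$explore_cfg
  ecfg$seed <- derive_seed(config$seed, 1L)
  manifest$explore_seed <- ecfg$seed
  vmap <- explore_global(conn, p, config$explore_coupling,
                         config$explore_velocity, ecfg)
  sel <- withCallingHandlers(
    select_range(vmap),
    warning = function(w) invokeRestart("muffleWarning"))
  manifest$explore_s <- proc.time()[["elapsed"]] - t0
  if (is.null(target)) {
    return(structure(list(status = "no-fit", variance_map = vmap,
                          range = sel, fit = NULL, selected = NULL,
                          bold = NULL, fc = NULL, manifest = manifest),
                     class = "subject_bundle"))
  }
  if (is.null(ref_fc))
    ref_fc <- suppressWarnings(fc_matrix(drop_transient(target)))
  fcfg <- config$fit_cfg
  fcfg$seed <- derive_seed(config$seed, 2L)
  manifest$fit_seed <- fcfg$seed
  crng <- if (!sel$empty) sel$coupling_range else range(config$explore_coupling)
  vrng <- if (!sel$empty) sel$velocity_range else range(config$explore_velocity)
  grids <- list(
    coupling = grid_in_range(crng, config$fit_points, 0.01, 1),
    velocity = grid_in_range(vrng, config$fit_points, 10, 100),
    K12 = config$local_grid, K21 = config$local_grid, K11 = config$local_grid)
  fit <- fit_parameters(conn, p, grids, target, ref_fc, fcfg,
                        hrf = config$hrf)
  manifest$fit_s <- proc.time()[["elapsed"]] - t0 - manifest$explore_s
  vcfg <- config$fit_cfg
  vcfg$seed <- derive_seed(config$seed, 3L)
  manifest$validate_seed <- vcfg$seed
  traj <- simulate_network(conn, fit$selected_params, fit$selected_global, vcfg)
  bold <- neural_to_bold(traj, config$hrf, tr = config$tr)
  fc <- suppressWarnings(fc_matrix(drop_transient(bold)))
  manifest$total_s <- proc.time()[["elapsed"]] - t0
  structure(list(status = "fitted", variance_map = vmap, range = sel,
                 fit = fit, selected = fit$selected, bold = bold, fc = fc,
                 manifest = manifest),
            class = "subject_bundle")
}

#' Aggregate subject bundles into the cohort report
#'
#' Builds the per-subject parameter table, runs the group contrasts
#' (Wilcoxon rank-sum, Bonferroni-corrected) when both groups have at
#' least 2 fitted subjects, and, when a clinical table is supplied, the
#' parameter-outcome regressions for each formula.
#'
#' @param bundles named-group list: each element a list with `group`
#'   (`"control"` / `"stroke"`) and either a fitted subject bundle
#'   (`bundle`) or a `selected` parameter list
#' @param clinical optional clinical data.frame (stroke subjects, same
#'   order as the stroke bundles)
#' @param formulas optional list of regression formulas passed to
#'   [regress_outcomes()]
#' @param out_dir optional directory for the JSON + CSV report
#' @return a `cohort_report`: `parameter_table`, `contrasts`,
#'   `regressions`, `warnings`
#' @export
run_cohort <- function(bundles, clinical = NULL, formulas = NULL,
                       out_dir = NULL) {
  rows <- lapply(seq_along(bundles), function(i) {
    b <- bundles[[i]]
    sel <- if (!is.null(b$selected)) b$selected else b$bundle$selected
    if (is.null(sel)) return(NULL)
    data.frame(subject = i, group = b$group,
               coupling_c = sel$coupling, velocity_v = sel$velocity,
               K12 = sel$K12, K21 = sel$K21, K11 = sel$K11)
  })
  ptab <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  warnings_out <- character(0)
  contrasts <- NULL
  counts <- table(ptab$group)
  if (length(counts) == 2 && all(counts >= 2)) {
    contrasts <- compare_parameters(ptab)
  } else {
    warnings_out <- c(warnings_out,
                      "contrast stage skipped: need two groups with >= 2 subjects")
  }
  regressions <- NULL
  if (!is.null(clinical) && !is.null(formulas)) {
    stroke_pars <- ptab[ptab$group == "stroke", , drop = FALSE]
    if (nrow(stroke_pars) == nrow(clinical)) {
      regressions <- lapply(formulas, function(f)
        tryCatch(regress_outcomes(stroke_pars, clinical, f),
                 error = function(e) {
                   warnings_out <<- c(warnings_out, conditionMessage(e))
                   NULL
                 }))
    } else {
      warnings_out <- c(warnings_out,
                        "regression skipped: clinical rows do not match stroke subjects")
    }
  }
  rep_obj <- structure(list(parameter_table = ptab, contrasts = contrasts,
                            regressions = regressions,
                            warnings = warnings_out),
                       class = "cohort_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(ptab, file.path(out_dir, "parameter_table.csv"),
                     row.names = FALSE)
    if (!is.null(contrasts))
      utils::write.csv(contrasts, file.path(out_dir, "contrasts.csv"),
                       row.names = FALSE)
    jsonlite::write_json(
      list(parameter_table = ptab, contrasts = contrasts,
           regressions = lapply(regressions, function(r)
             if (is.null(r)) NULL else r[, c("term", "estimate", "t", "p")]),
           warnings = warnings_out),
      file.path(out_dir, "cohort_report.json"),
      auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  rep_obj
}
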