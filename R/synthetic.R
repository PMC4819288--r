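#' Specification for a synthetic structural connectome
#'
#' The generator emulates a 96-region whole-brain parcellation: region
#' centres on two mirrored hemispheric shells, distance-dependent edge
#' probability calibrated to the requested density, and edge weights
#' whose log-scale summary statistics are calibrated to a printed cohort
#' summary.  `weight_mean`, `weight_sd` and `weight_range` describe the
#' across-subject distribution of the per-connectome mean log-weight
#' summary (that is how cohort weight summaries are reported): each
#' connectome draws its subject-level mean from a truncated normal over
#' `weight_range` whose parent mean is solved so the truncated mean
#' equals `weight_mean`; individual edge log-weights then scatter around
#' it with `edge_sd`.
#'
#' @param n_regions number of regions (even; default 96)
#' @param density fraction of nonzero edges in (0, 1]
#' @param weight_mean target mean of the per-connectome log-weight summary
#' @param weight_sd across-connectome SD of that summary
#' @param weight_range truncation interval for the subject-level mean
#' @param edge_sd within-connectome SD of edge log-weights
#' @param shell_radius mean shell radius (mm)
#' @param lambda distance decay of edge probability (mm)
#' @param tortuosity multiplier turning Euclidean centre distance into
#'   tract length
#' @param seed RNG seed
#' @return a `connectome_spec`
#' @export
connectome_spec <- function(n_regions = 96L, density = 0.35,
                            weight_mean = 10.16, weight_sd = 1.03,
                            weight_range = c(8.75, 12.07),
                            edge_sd = 1.0, shell_radius = 70,
                            lambda = 60, tortuosity = 1.2, seed = 1L) {
  if (density <= 0 || density > 1) vs_abort("density must be in (0, 1]", "spec")
  if (n_regions < 4 || n_regions %% 2 != 0)
    vs_abort("n_regions must be an even number >= 4", "spec")
  if (weight_mean < weight_range[1] || weight_mean > weight_range[2])
    vs_abort("weight_range must contain weight_mean", "spec")
  if (diff(weight_range) < 0.1 * weight_sd)
    vs_abort("weight_range too narrow for the requested sd", "spec")
  structure(list(n_regions = as.integer(n_regions), density = density,
                 weight_mean = weight_mean, weight_sd = weight_sd,
                 weight_range = weight_range, edge_sd = edge_sd,
                 shell_radius = shell_radius, lambda = lambda,
                 tortuosity = tortuosity, seed = as.integer(seed)),
            class = "connectome_spec")
}

# parent mean of a truncated normal (fixed sd, bounds) whose truncated
# mean equals `target`
truncnorm_parent_mean <- function(target, sd, lo, hi) {
  tmean <- function(mu) {
    al <- (lo - mu) / sd; be <- (hi - mu) / sd
    Z <- pnorm(be) - pnorm(al)
    mu + sd * (stats::dnorm(al) - stats::dnorm(be)) / Z
  }
  stats::uniroot(function(mu) tmean(mu) - target,
                 c(lo - 6 * sd, hi + 6 * sd), tol = 1e-12)$root
}

rtruncnorm1 <- function(mu, sd, lo, hi) {
  u <- runif(1, pnorm((lo - mu) / sd), pnorm((hi - mu) / sd))
  mu + sd * qnorm(u)
}

#' Generate a synthetic control-like structural connectome
#'
#' Centres are sampled on two mirrored hemispheric shells (right
#' hemisphere drawn, left mirrored through the midline).  Edge presence
#' follows a distance-dependent probability `min(1, k exp(-d/lambda))`
#' with `k` solved so the expected density matches the spec.  Nonzero
#' edge weights are `exp` of Gaussian log-weights around the
#' subject-level mean (see [connectome_spec()]); tract lengths are the
#' Euclidean centre distances times the tortuosity factor.  Pure function
#' of `(spec, spec$seed)`.
#'
#' @param spec a `connectome_spec`
#' @return a validated `connectome` with `hemisphere` flags and region
#'   labels carrying a cortical/subcortical class
#' @export
generate_connectome <- function(spec) {
  with_seed(spec$seed, {
    n <- spec$n_regions
    nh <- n %/% 2L
    # right-hemisphere shell: random directions with x > 0, radius ~ shell
    u <- matrix(rnorm(nh * 3), nh, 3)
    u <- u / sqrt(rowSums(u^2))
    u[, 1] <- abs(u[, 1])
    rad <- spec$shell_radius * (1 + runif(nh, -0.1, 0.1))
    # last fifth of each hemisphere is "subcortical": pulled toward centre
    n_sub <- max(1L, nh %/% 5L)
    sub_idx <- (nh - n_sub + 1L):nh
    rad[sub_idx] <- rad[sub_idx] * 0.35
    right <- u * rad
    left <- right
    left[, 1] <- -left[, 1]
    centres <- rbind(right, left)
    cls <- rep(c("cort", "subcort"), c(nh - n_sub, n_sub))
    ids <- c(sprintf("R_%s_%02d", cls, seq_len(nh)),
             sprintf("L_%s_%02d", cls, seq_len(nh)))
    hemi <- rep(c("R", "L"), each = nh)
    d <- as.matrix(stats::dist(centres))
    ut <- upper.tri(d)
    pfun <- function(k) pmin(1, k * exp(-d[ut] / spec$lambda))
    k <- stats::uniroot(function(lk) mean(pfun(exp(lk))) - spec$density,
                        c(-10, 20), tol = 1e-10)$root
    p_edge <- pfun(exp(k))
    present <- runif(length(p_edge)) < p_edge
    mu0 <- truncnorm_parent_mean(spec$weight_mean, spec$weight_sd,
                                 spec$weight_range[1], spec$weight_range[2])
    m_subject <- rtruncnorm1(mu0, spec$weight_sd,
                             spec$weight_range[1], spec$weight_range[2])
    logw <- rnorm(sum(present), m_subject, spec$edge_sd)
    w <- matrix(0, n, n)
    wv <- numeric(length(p_edge))
    wv[present] <- exp(logw)
    w[ut] <- wv
    w <- w + t(w)
    lengths <- d * spec$tortuosity
    diag(lengths) <- 0
    connectome(w, lengths, region_ids = ids, centres = centres,
               hemisphere = hemi, lesion = rep(FALSE, n))
  })
}

#' Specification of a virtual lesion
#'
#' Emulates middle-cerebral-artery-territory damage: every edge incident
#' to the target regions is attenuated by `1 - severity`, and edges
#' falling below `weight_floor` afterwards are removed.  The default
#' severity 0.867 is calibrated so that a 10-of-96-region lesion shifts
#' the expected mean log-weight summary from the control value 10.16 to
#' the stroke cohort value 9.76 (expected incident-edge fraction 0.1985;
#' `0.1985 * log(1 - 0.867) = -0.40`).
#'
#' @param target_regions integer indices of lesioned regions (nonempty)
#' @param severity fractional attenuation in [0, 1]
#' @param weight_floor raw-weight threshold below which attenuated edges
#'   are zeroed
#' @return a `lesion_spec`
#' @export
lesion_spec <- function(target_regions, severity = 0.867, weight_floor = 1) {
  if (length(target_regions) == 0) vs_abort("target_regions empty", "spec")
  if (severity < 0 || severity > 1) vs_abort("severity must be in [0, 1]", "spec")
  structure(list(target_regions = as.integer(target_regions),
                 severity = severity, weight_floor = weight_floor),
            class = "lesion_spec")
}

#' Default MCA-like lesion for a synthetic connectome
#'
#' Selects a contiguous block of `size` regions in one hemisphere: the
#' most lateral left-hemisphere region and its nearest same-hemisphere
#' neighbours, which spans cortical and subcortical labels like the
#' cortical/subcortical lesion classes seen clinically.
#'
#' @param conn a `connectome` with centres and hemisphere flags
#' @param size number of lesioned regions (default 10)
#' @param severity passed to [lesion_spec()]
#' @return a `lesion_spec`
#' @export
default_mca_lesion <- function(conn, size = 10L, severity = 0.867) {
  hemi <- conn$hemisphere
  if (is.null(hemi) || is.null(conn$centres))
    vs_abort("connectome lacks hemisphere flags or centres", "spec")
  left <- which(hemi == "L")
  seed_region <- left[which.min(conn$centres[left, 1])]  # most lateral left
  dists <- sqrt(rowSums((conn$centres[left, , drop = FALSE] -
                           matrix(conn$centres[seed_region, ], length(left), 3,
                                  byrow = TRUE))^2))
  lesion_spec(left[order(dists)][seq_len(min(size, length(left)))],
              severity = severity)
}

#' Apply a virtual lesion to a connectome
#'
#' @param conn a `connectome`
#' @param lesion a `lesion_spec`
#' @return a `connectome` with attenuated weights and updated lesion flags
#' @export
apply_virtual_lesion <- function(conn, lesion) {
  n <- n_regions(conn)
  if (any(lesion$target_regions < 1 | lesion$target_regions > n))
    vs_abort("lesion target regions out of range", "spec")
  w <- conn$weights
  tr <- lesion$target_regions
  w[tr, ] <- w[tr, ] * (1 - lesion$severity)
  w[, tr] <- w[, tr] * (1 - lesion$severity)
  w[tr, tr] <- conn$weights[tr, tr] * (1 - lesion$severity)  # once, not twice
  w[w > 0 & w < lesion$weight_floor] <- 0
  flags <- if (is.null(conn$lesion)) rep(FALSE, n) else conn$lesion
  flags[tr] <- TRUE
  connectome(w, conn$lengths, region_ids = conn$region_ids,
             centres = conn$centres, hemisphere = conn$hemisphere,
             lesion = flags)
}

#' Ground-truth record for parameter-recovery experiments
#'
#' @param coupling_c,velocity_v global truth
#' @param K12,K21,K11 local truth
#' @param seed generation seed for the target simulation
#' @return a `ground_truth` list
#' @export
ground_truth <- function(coupling_c, velocity_v, K12 = 0.5, K21 = 0.5,
                         K11 = 0.5, seed = 1L) {
  if (coupling_c < 0.01 || coupling_c > 1 || velocity_v < 10 || velocity_v > 100)
    vs_abort("truth outside exploration bounds", "spec")
  structure(list(coupling_c = coupling_c, velocity_v = velocity_v,
                 K12 = K12, K21 = K21, K11 = K11, seed = as.integer(seed)),
            class = "ground_truth")
}

#' Generate ground-truth BOLD at known parameters
#'
#' Runs the network simulation and hemodynamic forward model at the true
#' parameters with the truth's own seed, providing the fitting target
#' that empirical resting-state fMRI would otherwise provide.  On
#' divergence the initial condition is jittered and the run retried (up
#' to 3 attempts).
#'
#' @param conn a `connectome`
#' @param truth a `ground_truth`
#' @param cfg a `sim_config` (its seed is overridden by `truth$seed`)
#' @param hrf HRF kernel
#' @param tr repetition time (s)
#' @return list with `bold` (a `bold_series`), `fc` (its FC matrix after
#'   the hemodynamic transient), `truth`
#' @export
generate_ground_truth_bold <- function(conn, truth, cfg,
                                       hrf = make_gamma_hrf(), tr = 2) {
  p <- sj3d_params(K12 = truth$K12, K21 = truth$K21, K11 = truth$K11)
  g <- global_params(truth$coupling_c, truth$velocity_v)
  cfg$seed <- truth$seed
  last_err <- NULL
  for (attempt in 1:3) {
    cfg_try <- cfg
    cfg_try$seed <- derive_seed(truth$seed, attempt - 1L)
    if (attempt == 1) cfg_try$seed <- truth$seed
    traj <- tryCatch(simulate_network(conn, p, g, cfg_try),
                     error = function(e) { last_err <<- e; NULL })
    if (!is.null(traj)) {
      bold <- neural_to_bold(traj, hrf, tr = tr)
      fc <- suppressWarnings(fc_matrix(drop_transient(bold)))
      return(list(bold = bold, fc = fc, truth = truth))
    }
  }
  stop(last_err)
}

#' Generate a synthetic clinical table with planted effects
#'
#' Model parameters are drawn uniformly within the stroke cohort's fitted
#' ranges (coupling 0.04-0.09, velocity 12-80 m/s, K12 0.1-0.8, K21
#' 0.1-0.9, K11 0.1-0.99).  Motor outcomes are linear in the parameters
#' with configurable planted slopes plus Gaussian noise: by default the
#' excitatory-on-inhibitory gain K12 depresses post-therapy and
#' maintenance Fugl-Meyer scores (slope -20 points per unit K12) and
#' global coupling raises the maintenance Wolf Motor Function Test score
#' (slope +24 points per unit coupling); both correspond to moderate
#' correlations (|r| ~ 0.6) at the default noise level.  Demographics and
#' lesion characteristics are drawn from documented plausible ranges and
#' carry no planted effect.
#'
#' @param n_subjects number of stroke subjects (>= 10)
#' @param effects named list of planted slopes: `K12_fuglmeyer`
#'   (negative), `coupling_wmft` (positive)
#' @param noise_sd multiplier on the per-outcome baseline noise
#'   (Fugl-Meyer 5 points, WMFT 0.4 points); 0 gives noiseless outcomes
#' @param seed RNG seed
#' @return list with `clinical` (data.frame of outcomes at
#'   pre/post/maintenance plus demographics) and `parameters` (data.frame
#'   with `group = "stroke"` and the five model parameters), plus the
#'   planted `effects`
#' @export
generate_clinical_table <- function(n_subjects = 20L,
                                    effects = list(K12_fuglmeyer = -20,
                                                   coupling_wmft = 24),
                                    noise_sd = 1, seed = 1L) {
  if (n_subjects < 10) vs_abort("need n_subjects >= 10", "spec")
  with_seed(seed, {
    n <- n_subjects
    pars <- data.frame(
      subject = seq_len(n), group = "stroke",
      coupling_c = runif(n, 0.04, 0.09),
      velocity_v = runif(n, 12, 80),
      K12 = runif(n, 0.1, 0.8),
      K21 = runif(n, 0.1, 0.9),
      K11 = runif(n, 0.1, 0.99))
    sd_fm <- 5 * noise_sd
    sd_wm <- 0.4 * noise_sd
    fm_pre <- pmin(66, pmax(0, rnorm(n, 28, 8)))
    fm_post <- 40 + effects$K12_fuglmeyer * (pars$K12 - 0.45) + rnorm(n, 0, sd_fm)
    fm_main <- 42 + effects$K12_fuglmeyer * (pars$K12 - 0.45) + rnorm(n, 0, sd_fm)
    wm_pre <- pmin(5, pmax(0, rnorm(n, 2.2, 0.6)))
    wm_post <- pmin(5, pmax(0, rnorm(n, 2.8, 0.6)))
    wm_main <- 3 + effects$coupling_wmft * (pars$coupling_c - 0.065) +
      rnorm(n, 0, sd_wm)
    clin <- data.frame(
      subject = seq_len(n),
      fuglmeyer_pre = fm_pre, fuglmeyer_post = fm_post,
      fuglmeyer_maintenance = fm_main,
      wmft_pre = wm_pre, wmft_post = wm_post, wmft_maintenance = wm_main,
      ninehole_pre = rnorm(n, 45, 12), ninehole_post = rnorm(n, 38, 12),
      ninehole_maintenance = rnorm(n, 36, 12),
      mal14_pre = runif(n, 0.5, 3), mal14_post = runif(n, 1, 4),
      mal14_maintenance = runif(n, 1, 4.5),
      age = round(runif(n, 23, 74)),
      sex = sample(c("F", "M"), n, replace = TRUE),
      depression = runif(n) < 0.3,
      lesion_size_mm3 = round(exp(rnorm(n, 9.5, 1.5))),
      lesion_location = sample(c("Cort", "Subcort", "Cort/subcort"), n,
                               replace = TRUE),
      time_after_stroke_y = round(runif(n, 0.5, 10), 1),
      lesion_side = sample(c("L", "R"), n, replace = TRUE))
    list(clinical = clin, parameters = pars, effects = effects, seed = seed)
  })
}
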