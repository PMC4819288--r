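#' Compare model parameters between groups
#'
#' One two-sided Wilcoxon rank-sum test per parameter column
#' (`coupling_c`, `velocity_v`, `K12`, `K21`, `K11`), Bonferroni-corrected
#' for the five simultaneous tests (`corrected_p = min(1, 5 * raw_p)`).
#' The exact null distribution is used when the combined group size is at
#' most 20 (and no ties); otherwise the normal approximation with tie
#' correction.
#'
#' @param table data.frame with a `group` column (two levels, e.g.
#'   control/stroke) and the five parameter columns
#' @param params character vector of parameter columns to test
#' @return data.frame of test results: `parameter`, `statistic`, `raw_p`,
#'   `corrected_p`, `test`, `n1`, `n2`, `undefined`
#' @export
compare_parameters <- function(table,
                               params = c("coupling_c", "velocity_v",
                                          "K12", "K21", "K11")) {
  stopifnot(is.data.frame(table), "group" %in% names(table))
  params <- params[params %in% names(table)]
  groups <- unique(as.character(table$group))
  if (length(groups) != 2)
    vs_abort("need exactly two groups", "input")
  g1 <- table[table$group == groups[1], , drop = FALSE]
  g2 <- table[table$group == groups[2], , drop = FALSE]
  if (nrow(g1) < 2 || nrow(g2) < 2)
    vs_abort("need >= 2 subjects per group", "input")
  m <- length(params)
  res <- lapply(params, function(pp) {
    x <- g1[[pp]]; y <- g2[[pp]]
    if (length(unique(c(x, y))) == 1) {
      # constant across all subjects: no evidence of a difference (p = 1)
      # but the test statistic is undefined; both facts are reported
      return(data.frame(parameter = pp, statistic = NA_real_, raw_p = 1,
                        corrected_p = 1, test = "wilcoxon-rank-sum",
                        n1 = length(x), n2 = length(y), undefined = TRUE))
    }
    exact <- (length(x) + length(y)) <= 20
    wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
    data.frame(parameter = pp, statistic = unname(wt$statistic),
               raw_p = wt$p.value, corrected_p = min(1, wt$p.value * m),
               test = "wilcoxon-rank-sum",
               n1 = length(x), n2 = length(y), undefined = FALSE)
  })
  do.call(rbind, res)
}

#' Compare edge-weight distributions between two groups
#'
#' Two-sample Kolmogorov-Smirnov test on the pooled transformed weights
#' plus a two-sample t test on the per-subject skewness values
#' (distribution-shape comparison used for structural-connectome
#' cohorts).
#'
#' @param a,b lists of numeric vectors: one vector of (transformed)
#'   nonzero weights per subject
#' @return list with `ks` (statistic, p), `skewness` (per-group means,
#'   t statistic, p), `degenerate` flag
#' @export
compare_weight_distributions <- function(a, b) {
  pool_a <- unlist(a); pool_b <- unlist(b)
  if (length(pool_a) < 5 || length(pool_b) < 5)
    vs_abort("need >= 5 values per group", "input")
  degenerate <- sd(pool_a) == 0 || sd(pool_b) == 0
  ks <- if (degenerate) list(statistic = NA_real_, p.value = NA_real_) else
    suppressWarnings(ks.test(pool_a, pool_b))
  skew1 <- function(x) {
    mu <- mean(x); s2 <- mean((x - mu)^2)
    if (s2 == 0) 0 else mean((x - mu)^3) / s2^1.5
  }
  sk_a <- vapply(a, skew1, 1)
  sk_b <- vapply(b, skew1, 1)
  tt <- if (length(sk_a) > 1 && length(sk_b) > 1 &&
            (sd(sk_a) > 0 || sd(sk_b) > 0))
    t.test(sk_a, sk_b) else list(statistic = NA_real_, p.value = NA_real_)
  list(ks = list(statistic = unname(ks$statistic), p = ks$p.value),
       skewness = list(mean_a = mean(sk_a), mean_b = mean(sk_b),
                       t = unname(tt$statistic), p = tt$p.value),
       degenerate = degenerate)
}

#' Regress model parameters on clinical variables
#'
#' Ordinary least squares per the analysis orientation of this pipeline:
#' model parameters as dependent variables, clinical measures as
#' predictors (`orientation = "parameters_on_clinical"`, the default); the
#' natural predictive direction is also exposed.  Exactly collinear
#' predictors are dropped with a warning; regression p values are
#' reported uncorrected.
#'
#' @param params data.frame of per-subject model parameters
#' @param clin data.frame of per-subject clinical variables (same row
#'   order)
#' @param formula model formula referring to columns of the merged table
#' @return data.frame of coefficients: `term`, `estimate`, `std_error`,
#'   `t`, `p`, plus attributes `r_squared` and `n`
#' @export
regress_outcomes <- function(params, clin, formula) {
  dat <- cbind(params, clin[, setdiff(names(clin), names(params)), drop = FALSE])
  mf <- stats::model.frame(formula, dat)
  X <- stats::model.matrix(formula, mf)
  if (nrow(X) <= ncol(X))
    vs_abort("need n > number of predictors + 1", "input")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    vs_warn(paste("dropping collinear column(s):",
                  paste(dropped, collapse = ", ")), "collinearity")
  }
  fit <- lm(formula, dat)
  sm <- summary(fit)
  co <- sm$coefficients
  out <- data.frame(term = rownames(co), estimate = co[, 1],
                    std_error = co[, 2], t = co[, 3], p = co[, 4],
                    row.names = NULL)
  attr(out, "r_squared") <- sm$r.squared
  attr(out, "n") <- nrow(mf)
  attr(out, "fit") <- fit
  out
}
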