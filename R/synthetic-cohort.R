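#' Deterministic seed streams
#'
#' All randomness in the package flows through seeds derived from one
#' master seed, so any stage (cohort draw, outcome draw, per-replication
#' predictor draw, bootstrap) can be re-run in isolation. Derived seeds
#' stay inside the positive 32-bit integer range.
#'
#' @param master Master seed (integer).
#' @param ... Integer stream indices (stage id, cell id, replication id,
#'   ...); any number of them.
#' @return A positive integer seed.
#' @export
derive_seed <- function(master, ...) {
  idx <- c(master, ...)
  m <- 2147483647
  h <- 0
  for (v in idx) h <- (h * 48271 + (as.numeric(v) %% m) + 1) %% m
  as.integer(h + 1)
}

new_cohort <- function(design, outcome = NULL, true_risk = NULL) {
  structure(list(design = design, outcome = outcome, true_risk = true_risk),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d individuals, %d design columns, outcome %s\n",
              nrow(x$design), ncol(x$design),
              if (is.null(x$outcome)) "not drawn"
              else sprintf("drawn (incidence %.4f)", mean(x$outcome))))
  invisible(x)
}

#' Sample baseline predictor columns
#'
#' Each predictor is drawn independently from its categorical marginal
#' distribution and expanded to indicator columns (one per non-reference
#' level). The outcome is left unset.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed for the draw.
#' @return A `cohort` with the design matrix filled in and `outcome`,
#'   `true_risk` unset.
#' @export
sample_predictors <- function(spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  n <- spec$n
  cols <- lapply(spec$predictors, function(p) {
    lev <- sample.int(length(p$levels), n, replace = TRUE,
                      prob = p$level_prevalences)
    ind <- matrix(0L, n, length(p$levels) - 1L,
                  dimnames = list(NULL, paste(p$name, p$levels[-1L], sep = "_")))
    for (j in seq_len(ncol(ind))) ind[, j] <- as.integer(lev == j + 1L)
    ind
  })
  new_cohort(do.call(cbind, cols))
}

#' Calibrate the model intercept to the target incidence
#'
#' Finds the intercept b0 such that the population mean of
#' `plogis(b0 + lp_scale * X %*% coefficients)` over the sampled design
#' equals the spec's target incidence. The mean risk is strictly
#' increasing in b0, so the root is unique; it is found by monotone
#' root-finding to within 1e-6 on the incidence scale.
#'
#' @param spec A `cohort_spec` (supplies the incidence target).
#' @param cohort A `cohort` with sampled predictors.
#' @param coefficients Named log-OR vector matching the design columns
#'   (default [spec_coefficients()]).
#' @param lp_scale Linear-predictor multiplier (default the spec's).
#' @return The intercept (scalar).
#' @export
calibrate_intercept <- function(spec, cohort,
                                coefficients = spec_coefficients(spec),
                                lp_scale = spec$lp_scale) {
  stopifnot(inherits(cohort, "cohort"), all(is.finite(coefficients)))
  lp <- drop(cohort$design %*% coefficients[colnames(cohort$design)]) * lp_scale
  target <- spec$target_incidence
  f <- function(b0) mean(stats::plogis(b0 + lp)) - target
  lo <- -30; hi <- 30
  if (f(lo) > 0 || f(hi) < 0)
    stop("intercept calibration failed: target incidence unreachable")
  r <- stats::uniroot(f, c(lo, hi), tol = 1e-9)
  if (abs(f(r$root)) > 1e-6)
    stop("intercept calibration did not converge")
  r$root
}

#' Draw outcomes from the calibrated risk model
#'
#' Sets each individual's true risk to
#' `plogis(intercept + lp_scale * X %*% coefficients)` and draws the
#' binary outcome Bernoulli(true risk).
#'
#' @param cohort A `cohort` with sampled predictors.
#' @param intercept Calibrated intercept.
#' @param coefficients Named log-OR vector matching the design columns.
#' @param lp_scale Linear-predictor multiplier.
#' @param seed Integer seed for the outcome draw.
#' @return The `cohort` with `true_risk` and `outcome` set.
#' @export
draw_outcomes <- function(cohort, intercept, coefficients, lp_scale, seed) {
  stopifnot(inherits(cohort, "cohort"))
  lp <- drop(cohort$design %*% coefficients[colnames(cohort$design)]) * lp_scale
  risk <- stats::plogis(intercept + lp)
  set.seed(seed)
  cohort$true_risk <- risk
  cohort$outcome <- stats::rbinom(length(risk), 1L, risk)
  cohort
}

#' Calibrate the linear-predictor scale to the target AUC
#'
#' Discrimination of the generative model is governed by the spread of
#' the linear predictor: scaling all predictor coefficients by a factor
#' gamma >= 0 moves the AUC of true risk against the drawn outcome
#' monotonically from 0.5 (gamma = 0) upward. This searches for the
#' gamma whose Monte Carlo AUC (averaged over `n_seeds` outcome draws on
#' one fixed design, intercept recalibrated at every candidate so the
#' incidence target is maintained) matches `spec$target_auc` within
#' `tol`.
#'
#' @param spec A `cohort_spec` with `target_auc` set.
#' @param seed Master seed (design draw and the outcome-draw streams are
#'   derived from it).
#' @param n_seeds Number of outcome draws averaged per candidate gamma
#'   (default 5).
#' @param tol AUC tolerance (default 0.005).
#' @param gamma_range Search interval (default `c(0, 10)`).
#' @return List with `lp_scale` (gamma), `intercept` (at that gamma),
#'   `achieved_auc`, and the design `cohort` used.
#' @export
calibrate_lp_scale <- function(spec, seed, n_seeds = 5L, tol = 0.005,
                               gamma_range = c(0, 10)) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.na(spec$target_auc)) stop("spec has no target_auc to calibrate to")
  coefs <- spec_coefficients(spec)
  cohort <- sample_predictors(spec, derive_seed(seed, 1L))
  out_seeds <- vapply(seq_len(n_seeds), function(i) derive_seed(seed, 2L, i),
                      integer(1))
  mc_auc <- function(gamma) {
    b0 <- calibrate_intercept(spec, cohort, coefs, gamma)
    aucs <- vapply(out_seeds, function(s) {
      ch <- draw_outcomes(cohort, b0, coefs, gamma, s)
      auc(ch$true_risk, ch$outcome)
    }, numeric(1))
    mean(aucs)
  }
  target <- spec$target_auc
  if (target <= 0.5 + tol) {
    b0 <- calibrate_intercept(spec, cohort, coefs, 0)
    return(list(lp_scale = 0, intercept = b0, achieved_auc = 0.5,
                cohort = cohort))
  }
  lo <- gamma_range[1]; hi <- gamma_range[2]
  f_lo <- mc_auc(lo) - target
  f_hi <- mc_auc(hi) - target
  if (f_lo > 0 || f_hi < 0)
    stop(sprintf(
      "target AUC %.3f unreachable: achievable range on gamma in [%g, %g] is [%.3f, %.3f]",
      target, lo, hi, f_lo + target, f_hi + target))
  r <- stats::uniroot(function(g) mc_auc(g) - target, c(lo, hi),
                      tol = 1e-4)
  gamma <- r$root
  b0 <- calibrate_intercept(spec, cohort, coefs, gamma)
  achieved <- mc_auc(gamma)
  if (abs(achieved - target) > tol)
    warning(sprintf("AUC calibration reached %.4f for target %.4f", achieved, target))
  list(lp_scale = gamma, intercept = b0, achieved_auc = achieved,
       cohort = cohort)
}

#' Generate a fully calibrated synthetic cohort
#'
#' Convenience wrapper: sample the design, calibrate the scale (if a
#' target AUC is set) and the intercept, and draw outcomes — all from
#' one master seed.
#'
#' @param spec A `cohort_spec`.
#' @param seed Master seed.
#' @param calibration Optional result of a previous
#'   [calibrate_lp_scale()] call (reused to skip the gamma search; the
#'   design is redrawn from `seed` and the intercept recalibrated).
#' @return A `cohort` with outcome and true risk set, carrying the
#'   calibrated `intercept` and `lp_scale` as attributes.
#' @export
synthesize_cohort <- function(spec, seed, calibration = NULL) {
  coefs <- spec_coefficients(spec)
  if (is.null(calibration)) {
    if (!is.na(spec$target_auc)) {
      calibration <- calibrate_lp_scale(spec, seed)
    } else {
      calibration <- list(lp_scale = spec$lp_scale)
    }
  }
  gamma <- calibration$lp_scale
  cohort <- sample_predictors(spec, derive_seed(seed, 1L))
  b0 <- calibrate_intercept(spec, cohort, coefs, gamma)
  cohort <- draw_outcomes(cohort, b0, coefs, gamma, derive_seed(seed, 3L))
  attr(cohort, "intercept") <- b0
  attr(cohort, "lp_scale") <- gamma
  cohort
}

#' Export a cohort as CSV
#'
#' One indicator column per non-reference level, outcome column last.
#' If the cohort carries simulated predictors, their provenance (target
#' prevalence and the solved case/non-case prevalences) is written to a
#' `<path>.meta` sidecar.
#'
#' @param cohort A `cohort` with outcomes drawn.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"), !is.null(cohort$outcome))
  df <- as.data.frame(cohort$design)
  df$outcome <- cohort$outcome
  utils::write.csv(df, path, row.names = FALSE)
  cond <- attr(cohort, "sim_conditional")
  if (!is.null(cond)) {
    k <- length(grep("^sim_", colnames(cohort$design)))
    writeLines(c(sprintf("sim_columns: %d", k),
                 sprintf("q0: %.17g", cond$q0),
                 sprintf("q1: %.17g", cond$q1),
                 sprintf("pi: %.17g", cond$pi)),
               paste0(path, ".meta"))
  }
  invisible(path)
}
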