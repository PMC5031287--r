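#' Area under the ROC curve (c statistic)
#'
#' Mann-Whitney estimator: the proportion of case/non-case pairs in
#' which the case has the higher score, ties counted half. Computed via
#' the rank-sum identity in O(n log n).
#'
#' @param score Numeric predicted risks or scores.
#' @param outcome 0/1 outcome vector.
#' @return AUC in [0,1].
#' @export
auc <- function(score, outcome) {
  stopifnot(length(score) == length(outcome))
  y <- as.integer(outcome)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: both outcome classes must be present")
  r <- rank(score, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Likelihood ratio of a risk stratum
#'
#' LR = (stratum cases / total cases) / (stratum non-cases / total
#' non-cases): the factor by which membership in the stratum multiplies
#' the prior odds of the outcome. The 95% CI uses the log method with
#' SE = sqrt(1/a - 1/C + 1/b - 1/N). A stratum with no non-cases gets an
#' infinite LR sentinel with a one-sided CI.
#'
#' @param a Cases in the stratum.
#' @param C Total cases.
#' @param b Non-cases in the stratum.
#' @param N Total non-cases.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `lr`, `ci_low`, `ci_high`.
#' @export
stratum_lr <- function(a, C, b, N, conf_level = 0.95) {
  stopifnot(a <= C, b <= N, C > 0, N > 0)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (b == 0) {
    if (a == 0) return(list(lr = NaN, ci_low = NaN, ci_high = NaN))
    # one-sided lower bound from substituting the smallest detectable b
    lr_low <- (a / C) / (1 / N) * exp(-z * sqrt(1 / a - 1 / C + 1 - 1 / N))
    return(list(lr = Inf, ci_low = lr_low, ci_high = Inf))
  }
  if (a == 0) return(list(lr = 0, ci_low = 0, ci_high = 0))
  lr <- (a / C) / (b / N)
  se <- sqrt(1 / a - 1 / C + 1 / b - 1 / N)
  list(lr = lr, ci_low = lr * exp(-z * se), ci_high = lr * exp(z * se))
}

#' Assign individuals to predicted-risk strata
#'
#' Strata are half-open `[lower, upper)` intervals delimited by the
#' boundary vector, with the first stratum starting at 0 and the last
#' closed above at 1; a risk exactly equal to a boundary goes to the
#' upper stratum. Each stratum carries its observed risk and likelihood
#' ratio.
#'
#' @param predicted_risk Numeric vector of predicted risks.
#' @param outcome 0/1 outcome vector.
#' @param boundaries Strictly increasing boundaries in (0,1); default
#'   the clinical strata `c(0.03, 0.055, 0.12, 0.15)`.
#' @return A `risk_stratum_table` data frame: per stratum `lower`,
#'   `upper`, `n`, `cases`, `observed_risk`, `lr`, `lr_ci_low`,
#'   `lr_ci_high`.
#' @export
stratify <- function(predicted_risk, outcome,
                     boundaries = c(0.03, 0.055, 0.12, 0.15)) {
  if (!length(boundaries)) stop("at least one stratum boundary is required")
  if (is.unsorted(boundaries, strictly = TRUE) ||
      any(boundaries <= 0) || any(boundaries >= 1))
    stop("boundaries must be strictly increasing and lie in (0,1)")
  stopifnot(length(predicted_risk) == length(outcome))
  y <- as.integer(outcome)
  brk <- c(0, boundaries, 1 + 1e-9)
  idx <- findInterval(predicted_risk, brk, rightmost.closed = TRUE)
  g <- length(brk) - 1L
  n_s <- tabulate(idx, g)
  cases_s <- vapply(seq_len(g), function(i) sum(y[idx == i]), integer(1))
  C <- sum(y); N <- length(y) - C
  lrs <- lapply(seq_len(g), function(i)
    stratum_lr(cases_s[i], C, n_s[i] - cases_s[i], N))
  out <- data.frame(
    lower = brk[-length(brk)],
    upper = c(boundaries, 1),
    n = n_s,
    cases = cases_s,
    observed_risk = ifelse(n_s > 0, cases_s / n_s, NaN),
    lr = vapply(lrs, `[[`, numeric(1), "lr"),
    lr_ci_low = vapply(lrs, `[[`, numeric(1), "ci_low"),
    lr_ci_high = vapply(lrs, `[[`, numeric(1), "ci_high"))
  class(out) <- c("risk_stratum_table", "data.frame")
  out
}

#' Proportion assigned to a clinically distinct risk group
#'
#' Fraction of individuals whose predicted risk falls strictly below the
#' low threshold or strictly above the high threshold — i.e. outside the
#' band considered clinically equivalent to the population baseline.
#'
#' @param predicted_risk Numeric vector.
#' @param low Low-risk threshold (default 0.03).
#' @param high High-risk threshold (default 0.15).
#' @return List with `distinct`, `low`, `high` proportions.
#' @export
prop_distinct <- function(predicted_risk, low = 0.03, high = 0.15) {
  stopifnot(low > 0, high < 1, low < high)
  p_low <- mean(predicted_risk < low)
  p_high <- mean(predicted_risk > high)
  list(distinct = p_low + p_high, low = p_low, high = p_high)
}

#' Proportion in strata with an informative likelihood ratio
#'
#' Population share of strata whose likelihood ratio exceeds 10 or falls
#' below 0.1 — strata in which the model's assignment materially shifts
#' the pre-test odds.
#'
#' @param stratum_table A [stratify()] result.
#' @param lr_low Lower informativeness bound (default 0.1).
#' @param lr_high Upper informativeness bound (default 10).
#' @return Proportion in [0,1].
#' @export
prop_informative_lr <- function(stratum_table, lr_low = 0.1, lr_high = 10) {
  st <- stratum_table
  informative <- !is.nan(st$lr) & (st$lr < lr_low | st$lr > lr_high)
  sum(st$n[informative]) / sum(st$n)
}

hl_groups <- function(predicted_risk, g) {
  # equal-count groups on sorted risk; stable order breaks ties
  ord <- order(predicted_risk)  # stable sort
  n <- length(predicted_risk)
  sizes <- diff(round(seq(0, n, length.out = g + 1)))
  grp <- integer(n)
  grp[ord] <- rep.int(seq_len(g), sizes)
  grp
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Individuals are split into `g` equal-count groups of sorted predicted
#' risk (deciles of risk by default; ties broken by stable order). The
#' statistic sums `(O - E)^2 / (E * (1 - E/n_g))` over groups, which
#' folds both outcome levels into one term per group, and is referred to
#' a chi-square distribution with `g - 2` degrees of freedom.
#'
#' @param predicted_risk Numeric predicted risks.
#' @param outcome 0/1 outcomes.
#' @param g Number of groups (default 10, minimum 3).
#' @return List with `statistic`, `df`, `p_value`, `g`.
#' @export
hosmer_lemeshow <- function(predicted_risk, outcome, g = 10L) {
  if (g < 3L) stop("'g' must be at least 3")
  stopifnot(length(predicted_risk) == length(outcome))
  grp <- hl_groups(predicted_risk, g)
  y <- as.integer(outcome)
  O <- vapply(seq_len(g), function(i) sum(y[grp == i]), integer(1))
  E <- vapply(seq_len(g), function(i) sum(predicted_risk[grp == i]), numeric(1))
  n_g <- tabulate(grp, g)
  if (any(E <= 0) || any(E >= n_g))
    stop("a group has degenerate expected count; use fewer groups")
  statistic <- sum((O - E)^2 / (E * (1 - E / n_g)))
  df <- g - 2L
  list(statistic = statistic, df = df,
       p_value = stats::pchisq(statistic, df, lower.tail = FALSE), g = g)
}

#' Observed versus expected risk per group
#'
#' The tabular counterpart of a calibration plot: mean predicted risk
#' and observed outcome proportion per equal-count group of sorted
#' predicted risk (same grouping as [hosmer_lemeshow()]).
#'
#' @inheritParams hosmer_lemeshow
#' @return Data frame with `group`, `n`, `mean_predicted`, `observed`,
#'   `expected_cases`, `observed_cases`.
#' @export
calibration_table <- function(predicted_risk, outcome, g = 10L) {
  if (g < 2L) stop("'g' must be at least 2")
  grp <- hl_groups(predicted_risk, g)
  y <- as.integer(outcome)
  data.frame(
    group = seq_len(g),
    n = tabulate(grp, g),
    mean_predicted = vapply(seq_len(g), function(i) mean(predicted_risk[grp == i]), numeric(1)),
    observed = vapply(seq_len(g), function(i) mean(y[grp == i]), numeric(1)),
    expected_cases = vapply(seq_len(g), function(i) sum(predicted_risk[grp == i]), numeric(1)),
    observed_cases = vapply(seq_len(g), function(i) sum(y[grp == i]), integer(1)))
}

#' Bootstrap optimism-corrected AUC
#'
#' Internal validation by the bootstrap: for each of `B` resamples drawn
#' with replacement, the full model-building recipe is re-run on the
#' resample; optimism is the AUC of that model on its own resample minus
#' its AUC on the original sample, and the mean optimism is subtracted
#' from the apparent AUC. A resample containing a single outcome class
#' is redrawn (and counted in `n_redrawn`).
#'
#' @param cohort A `cohort` with outcomes drawn.
#' @param fit_procedure Function `(cohort) -> fitted_risk_model`
#'   embodying the complete model-building recipe; default fits all
#'   design columns via [fit_logistic()].
#' @param B Number of bootstrap resamples (default 200).
#' @param seed Integer seed.
#' @return List with `auc_apparent`, `auc_corrected`, `mean_optimism`,
#'   `optimism` (per-resample vector), `n_redrawn`.
#' @export
optimism_corrected_auc <- function(cohort, fit_procedure = fit_logistic,
                                   B = 200L, seed = 1L) {
  stopifnot(inherits(cohort, "cohort") || is.list(cohort))
  if (is.null(cohort$outcome)) stop("cohort has no outcome")
  model <- fit_procedure(cohort)
  auc_apparent <- auc(model$predicted_risk, cohort$outcome)
  n <- length(cohort$outcome)
  set.seed(seed)
  optimism <- numeric(B)
  n_redrawn <- 0L
  Xfull <- cohort$design
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(cohort$outcome[idx])) == 2L) break
      n_redrawn <- n_redrawn + 1L
    }
    boot <- new_cohort(Xfull[idx, , drop = FALSE], cohort$outcome[idx])
    bm <- suppressWarnings(fit_procedure(boot))
    # evaluate the bootstrap model on the original sample
    keep <- names(bm$coefficients)
    eta_orig <- bm$intercept +
      drop(Xfull[, keep, drop = FALSE] %*% bm$coefficients)
    optimism[b] <- auc(bm$predicted_risk, boot$outcome) -
      auc(eta_orig, cohort$outcome)
  }
  list(auc_apparent = auc_apparent,
       auc_corrected = auc_apparent - mean(optimism),
       mean_optimism = mean(optimism),
       optimism = optimism,
       n_redrawn = n_redrawn)
}

#' Full performance report for a fitted model
#'
#' Bundles every evaluation criterion: AUC (optionally
#' optimism-corrected), Nagelkerke's r2, Hosmer-Lemeshow calibration,
#' the clinical risk-stratum table with likelihood ratios, and the
#' distinct-group and informative-LR proportions.
#'
#' @param model A `fitted_risk_model`.
#' @param thresholds Length-2 numeric `c(low, high)` clinical risk
#'   thresholds (default `c(0.03, 0.15)`).
#' @param boundaries Full stratum boundary vector for the stratum table;
#'   default inserts the interior boundaries `c(0.055, 0.12)` between
#'   the thresholds when they are the defaults, otherwise just the
#'   thresholds.
#' @param cohort Optional `cohort`; required for optimism correction.
#' @param optimism_B Bootstrap resamples for optimism correction; 0
#'   disables it (default 0, since optimism is near zero at large n).
#' @param seed Seed for the bootstrap.
#' @return An object of class `metrics_report`.
#' @export
metrics_report <- function(model, thresholds = c(0.03, 0.15),
                           boundaries = NULL, cohort = NULL,
                           optimism_B = 0L, seed = 1L) {
  stopifnot(inherits(model, "fitted_risk_model"))
  risk <- model$predicted_risk
  y <- model$outcome
  if (is.null(boundaries)) {
    boundaries <-
      if (isTRUE(all.equal(thresholds, c(0.03, 0.15))))
        c(0.03, 0.055, 0.12, 0.15)
      else thresholds
  }
  st <- stratify(risk, y, boundaries)
  hl <- hosmer_lemeshow(risk, y)
  pd <- prop_distinct(risk, thresholds[1], thresholds[2])
  auc_app <- auc(risk, y)
  auc_corr <- NA_real_
  if (optimism_B > 0L) {
    if (is.null(cohort)) stop("optimism correction needs the cohort")
    auc_corr <- optimism_corrected_auc(cohort, B = optimism_B,
                                       seed = seed)$auc_corrected
  }
  structure(
    list(auc = auc_app, auc_optimism_corrected = auc_corr,
         nagelkerke_r2 = nagelkerke_r2(model),
         hl_statistic = hl$statistic, hl_df = hl$df, hl_p = hl$p_value,
         stratum_table = st,
         prop_distinct = pd$distinct, prop_low = pd$low, prop_high = pd$high,
         prop_informative_lr = prop_informative_lr(st),
         thresholds = thresholds),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Model performance report\n")
  cat(sprintf("  AUC %.3f%s | Nagelkerke r2 %.3f | HL X2 %.2f (df %d, p %.3f)\n",
              x$auc,
              if (is.na(x$auc_optimism_corrected)) ""
              else sprintf(" (optimism-corrected %.3f)", x$auc_optimism_corrected),
              x$nagelkerke_r2, x$hl_statistic, x$hl_df, x$hl_p))
  cat(sprintf("  clinically distinct: %.1f%% (low %.1f%%, high %.1f%%); informative LR: %.1f%%\n",
              100 * x$prop_distinct, 100 * x$prop_low, 100 * x$prop_high,
              100 * x$prop_informative_lr))
  print(x$stratum_table)
  invisible(x)
}

#' Flatten a metrics report to a long-format data frame
#'
#' @param report A `metrics_report`.
#' @return Data frame with columns `metric`, `value`.
#' @export
report_to_long <- function(report) {
  stopifnot(inherits(report, "metrics_report"))
  keep <- c("auc", "auc_optimism_corrected", "nagelkerke_r2",
            "hl_statistic", "hl_p", "prop_distinct", "prop_low",
            "prop_high", "prop_informative_lr")
  data.frame(metric = keep,
             value = vapply(keep, function(k) as.numeric(report[[k]]), numeric(1)),
             row.names = NULL)
}
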