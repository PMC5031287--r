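#' Fit a logistic risk prediction model
#'
#' Full-model approach: every requested design column is entered; no
#' data-driven variable selection is performed. Constant columns are the
#' only exclusion (dropped with a warning, since they carry no
#' information and break the MLE). Maximum-likelihood estimates come
#' from iteratively reweighted least squares; model and null
#' log-likelihoods are recomputed by direct Bernoulli evaluation.
#'
#' @param cohort A `cohort` with outcomes drawn, or a list with a
#'   numeric design matrix `design` and 0/1 vector `outcome`.
#' @param columns Character vector of design columns to use (default:
#'   all).
#' @return An object of class `fitted_risk_model`: `intercept`,
#'   `coefficients` (named, per design column), `linear_predictor`,
#'   `predicted_risk`, `loglik_model`, `loglik_null`, `n`,
#'   `separation` flag, and `dropped` (constant columns removed).
#' @export
fit_logistic <- function(cohort, columns = NULL) {
  y <- cohort$outcome
  if (is.null(y)) stop("cohort has no outcome; draw outcomes first")
  X <- cohort$design
  if (!is.null(columns)) {
    missing_cols <- setdiff(columns, colnames(X))
    if (length(missing_cols))
      stop("unknown design columns: ", paste(missing_cols, collapse = ", "))
    X <- X[, columns, drop = FALSE]
  }
  const <- apply(X, 2L, function(v) min(v) == max(v))
  dropped <- colnames(X)[const]
  if (length(dropped)) {
    warning("dropping constant columns: ", paste(dropped, collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  if (!ncol(X)) stop("no non-constant design columns to fit")
  fit <- suppressWarnings(
    stats::glm.fit(cbind(`(Intercept)` = 1, X), y,
                   family = stats::binomial(),
                   control = list(epsilon = 1e-10, maxit = 100L)))
  beta <- fit$coefficients
  eta <- drop(cbind(1, X) %*% beta)
  risk <- stats::plogis(eta)
  # direct Bernoulli log-likelihood (contract: 1e-8 agreement with MLE
  # deviance), numerically stable on the linear-predictor scale
  ll <- function(e) sum(y * e - log1p(exp(e)))
  loglik_model <- ll(eta)
  p0 <- mean(y)
  loglik_null <- ll(rep(stats::qlogis(p0), length(y)))
  separation <- !fit$converged || any(abs(beta[-1L]) > 15) ||
    any(risk > 1 - 1e-12) && any(risk < 1e-12) && min(risk[y == 1]) > max(risk[y == 0])
  p <- length(beta)
  R <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
  R[lower.tri(R)] <- 0
  se <- sqrt(diag(chol2inv(R)))  # observed-information standard errors
  names(se) <- names(beta)
  structure(
    list(intercept = unname(beta[1L]),
         coefficients = beta[-1L],
         se = se,
         linear_predictor = eta,
         predicted_risk = risk,
         loglik_model = loglik_model,
         loglik_null = loglik_null,
         n = length(y),
         outcome = y,
         separation = separation,
         dropped = dropped),
    class = "fitted_risk_model")
}

#' @export
print.fitted_risk_model <- function(x, ...) {
  cat(sprintf("Logistic risk model: n = %d, %d predictors\n",
              x$n, length(x$coefficients)))
  cat(sprintf("  logLik %.2f (null %.2f), Nagelkerke r2 = %.4f\n",
              x$loglik_model, x$loglik_null, nagelkerke_r2(x)))
  if (x$separation) cat("  WARNING: possible separation; estimates unreliable\n")
  invisible(x)
}

#' Nagelkerke's pseudo R-squared
#'
#' Cox-Snell R2 `1 - exp(2*(loglik_null - loglik_model)/n)` rescaled by
#' its maximum attainable value `1 - exp(2*loglik_null/n)`, giving a
#' statistic in [0,1] interpretable as the proportion of outcome
#' variability explained.
#'
#' @param model A `fitted_risk_model` (or any list with `loglik_model`,
#'   `loglik_null`, `n`).
#' @return Proportion in [0,1].
#' @export
nagelkerke_r2 <- function(model) {
  if (is.null(model$n) || model$n == 0) stop("model has no observations")
  r2_cs <- 1 - exp(2 * (model$loglik_null - model$loglik_model) / model$n)
  r2_max <- 1 - exp(2 * model$loglik_null / model$n)
  min(max(r2_cs / r2_max, 0), 1)
}

#' Variance inflation factors of design columns
#'
#' Per-column VIF = 1 / (1 - R2) from the linear regression of that
#' column on all the others; VIF > 3 flags multicollinearity. Exactly
#' collinear columns get an infinite VIF.
#'
#' @param cohort A `cohort` (or list with a `design` matrix).
#' @param columns Columns to assess (default all); at least 2.
#' @param flag_threshold Flagging threshold (default 3).
#' @return Data frame with `column`, `vif`, `flagged`.
#' @export
variance_inflation_factors <- function(cohort, columns = NULL,
                                       flag_threshold = 3) {
  X <- cohort$design
  if (!is.null(columns)) X <- X[, columns, drop = FALSE]
  if (ncol(X) < 2L) stop("need at least two columns for VIF")
  vifs <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(column = colnames(X), vif = vifs,
             flagged = vifs > flag_threshold, row.names = NULL)
}

#' Export a model summary as CSV
#'
#' @param model A `fitted_risk_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_model_csv <- function(model, path) {
  est <- c(model$intercept, model$coefficients)
  df <- data.frame(term = c("(Intercept)", names(model$coefficients)),
                   estimate = unname(est), se = unname(model$se))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
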