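# Shared fixtures. Expensive objects (the full-size calibrated cohort)
# are built once per test run and memoised in this environment.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, expr, envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# small spec for fast property tests: two binary predictors, one with a
# strong effect, plus a three-level category
small_spec <- function(n = 20000L, target_auc = NA_real_) {
  cohort_spec(
    list(binary_predictor("exposure", 0.3, 3.0),
         binary_predictor("rare_risk", 0.05, 2.0),
         predictor_def("grade", c("a", "b", "c"),
                       c(0.5, 0.3, 0.2), c(1.5, 0.8))),
    n = n, target_incidence = 0.10, target_auc = target_auc)
}

small_cohort <- function(seed = 11L, n = 20000L) {
  spec <- small_spec(n)
  synthesize_cohort(spec, seed)
}

# full-size calibration of the preeclampsia spec, shared across files
full_calibration <- function() {
  memo("full_cal", calibrate_lp_scale(preeclampsia_cohort_spec(), 101L))
}

full_cohort <- function(seed = 101L) {
  memo(paste0("full_cohort_", seed),
       synthesize_cohort(preeclampsia_cohort_spec(), seed, full_calibration()))
}

# brute-force Mann-Whitney AUC: all case/non-case pairs, ties half
auc_bruteforce <- function(score, outcome) {
  s1 <- score[outcome == 1]
  s0 <- score[outcome == 0]
  tot <- 0
  for (a in s1) tot <- tot + sum(a > s0) + 0.5 * sum(a == s0)
  tot / (length(s1) * length(s0))
}

# crude odds ratio from the 2x2 table of a binary predictor vs outcome
crude_or <- function(x, y) {
  a <- sum(x == 1 & y == 1); b <- sum(x == 1 & y == 0)
  c_ <- sum(x == 0 & y == 1); d <- sum(x == 0 & y == 0)
  (a * d) / (b * c_)
}

# individual-level realization of an observed-vs-predicted stratum table:
# `n` individuals per stratum at a representative risk, `cases` of them
# positive
cohort_from_strata <- function(risks, n, cases) {
  list(risk = rep(risks, n),
       outcome = unlist(mapply(function(ni, ci) c(rep(1L, ci), rep(0L, ni - ci)),
                               n, cases, SIMPLIFY = FALSE)))
}
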