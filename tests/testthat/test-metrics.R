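test_that("rank-formula AUC equals brute-force pair enumeration exactly", {
  expect_equal(auc(c(0.8, 0.4, 0.6, 0.3, 0.2), c(1, 1, 0, 0, 0)), 5 / 6)
  expect_equal(auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  expect_equal(auc(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auc(1:5, rep(1, 5)), "both outcome classes")
  set.seed(14)
  for (i in 1:25) {
    n <- sample(10:1000, 1)
    # coarse scores force plenty of ties
    score <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)
    y <- rbinom(n, 1, 0.3)
    if (length(unique(y)) < 2) next
    expect_identical(auc(score, y), auc_bruteforce(score, y))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  score <- rnorm(500)
  y <- rbinom(500, 1, plogis(score))
  expect_equal(auc(score, y),
               as.numeric(pROC::auc(pROC::roc(y, score, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("stratification conserves counts and follows the half-open convention", {
  st <- stratify(c(0.01, 0.02, 0.10, 0.20), c(0, 0, 1, 1),
                 boundaries = c(0.03, 0.15))
  expect_equal(st$n, c(2L, 1L, 1L))
  # a risk exactly on a boundary goes to the upper stratum
  st2 <- stratify(c(0.03, 0.15), c(0, 1), boundaries = c(0.03, 0.15))
  expect_equal(st2$n, c(0L, 1L, 1L))
  expect_error(stratify(0.5, 1, boundaries = numeric(0)), "boundary")
  expect_error(stratify(0.5, 1, boundaries = c(0.5, 0.2)), "increasing")
  # conservation on random instances
  set.seed(8)
  for (i in 1:10) {
    n <- sample(50:2000, 1)
    risk <- runif(n)
    y <- rbinom(n, 1, risk)
    if (length(unique(y)) < 2) next
    st <- stratify(risk, y)
    expect_equal(sum(st$n), n)
    expect_equal(sum(st$cases), sum(y))
  }
})

test_that("stratum likelihood ratios reproduce the published table row", {
  # 12.0-15.0% stratum: 5,960 women, 800 cases; 6,313 cases and 68,912
  # non-cases overall
  lr <- stratum_lr(800, 6313, 5160, 68912)
  expect_equal(round(lr$lr, 1), 1.7)
  expect_equal(round(lr$ci_low, 1), 1.6)
  expect_equal(round(lr$ci_high, 1), 1.8)
  # a stratum at the overall risk has LR 1
  expect_equal(stratum_lr(50, 500, 450, 4500)$lr, 1)
  # boundary sentinel: all cases, no non-cases
  inf_lr <- stratum_lr(10, 10, 0, 100)
  expect_identical(inf_lr$lr, Inf)
  expect_true(is.finite(inf_lr$ci_low))
})

test_that("stratum LR equals posterior over prior odds (algebraic identity)", {
  set.seed(6)
  risk <- runif(3000)
  y <- rbinom(3000, 1, risk)
  st <- stratify(risk, y)
  prior_odds <- sum(y) / sum(1 - y)
  for (i in seq_len(nrow(st))) {
    if (st$n[i] == 0 || st$cases[i] %in% c(0L, st$n[i])) next
    post_odds <- st$cases[i] / (st$n[i] - st$cases[i])
    expect_equal(st$lr[i], post_odds / prior_odds, tolerance = 1e-12)
  }
})

test_that("distinct-group proportion behaves at thresholds and complements the band", {
  risk <- c(0.01, 0.03, 0.08, 0.15, 0.2)
  pd <- prop_distinct(risk)
  expect_equal(pd$distinct, 2 / 5)  # 0.03 and 0.15 are uninformative
  expect_equal(prop_distinct(rep(0.084, 100))$distinct, 0)
  set.seed(10)
  r <- runif(500)
  pd2 <- prop_distinct(r)
  in_band <- mean(r >= 0.03 & r <= 0.15)
  expect_equal(pd2$distinct + in_band, 1)
  # widening the uninformative band cannot increase the proportion
  expect_lte(prop_distinct(r, 0.02, 0.18)$distinct, pd2$distinct)
})

test_that("informative-LR proportion picks out only extreme strata", {
  # a published-table analogue: all LRs between 0.1 and 10
  tab <- cohort_from_strata(c(0.02, 0.04, 0.08, 0.13, 0.19),
                            c(5788, 21654, 33178, 5960, 8645),
                            c(134, 876, 2846, 800, 1660))
  st <- stratify(tab$risk, tab$outcome)
  expect_equal(prop_informative_lr(st), 0)
  # a stratum holding cases only (infinite LR) is informative; a mixed
  # stratum with moderate LR is not
  risk <- c(rep(0.1, 80), rep(0.9, 10))
  y <- c(rep(0, 72), rep(1, 8), rep(1, 10))
  st2 <- stratify(risk, y, boundaries = c(0.5))
  expect_equal(st2$lr[2], Inf)
  expect_equal(prop_informative_lr(st2), 10 / 90)
})

test_that("Hosmer-Lemeshow is zero under exact fit and uniform when well specified", {
  # exact agreement: O = E in every decile
  risk <- rep(0.5, 200)
  y <- rep(c(0L, 1L), 100)
  hl <- hosmer_lemeshow(risk, y)
  expect_equal(hl$statistic, 0)
  expect_equal(hl$p_value, 1)
  expect_equal(hl$df, 8L)
  expect_error(hosmer_lemeshow(risk, y, g = 2), "at least 3")
  # well-specified model: p-values uniform over replications
  set.seed(19)
  n <- 2000L
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.3)
  eta <- -2.2 + 0.8 * x1 + 0.7 * x2
  pvals <- vapply(1:200, function(i) {
    y <- rbinom(n, 1, plogis(eta))
    fit <- fit_logistic(list(design = cbind(x1 = x1, x2 = x2), outcome = y))
    hosmer_lemeshow(fit$predicted_risk, y)$p_value
  }, numeric(1))
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("calibration tables recover observed risks from grouped data", {
  # published-table analogue rebuilt from its counts
  tab <- cohort_from_strata(c(0.02, 0.04, 0.08, 0.13, 0.19),
                            c(5788, 21654, 33178, 5960, 8645),
                            c(134, 876, 2846, 800, 1660))
  st <- stratify(tab$risk, tab$outcome)
  expect_equal(st$observed_risk,
               c(134 / 5788, 876 / 21654, 2846 / 33178, 800 / 5960, 1660 / 8645))
  # observed tracks expected for calibrated risks; reverses for
  # anti-calibrated ones
  set.seed(23)
  risk <- sort(runif(5000, 0.01, 0.6))
  y <- rbinom(5000, 1, risk)
  ct <- calibration_table(risk, y)
  expect_equal(ct$observed, ct$mean_predicted, tolerance = 0.08)
  expect_true(all(diff(ct$mean_predicted) > 0))
  # groups are ordered by the (anti-calibrated) predictions, so observed
  # risk now falls as predictions rise
  ct_rev <- calibration_table(1 - risk, y)
  expect_lt(cor(ct_rev$mean_predicted, ct_rev$observed), -0.9)
  expect_equal(sum(ct$n), 5000L)
})

test_that("bootstrap optimism is zero for constant models and positive when overfit", {
  set.seed(31)
  n <- 300L
  X <- cbind(x = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, 0.3)
  cohort <- list(design = X, outcome = y)
  # seed-independent constant-risk recipe: optimism exactly zero
  const_fit <- function(ch) {
    structure(list(intercept = qlogis(0.3),
                   coefficients = setNames(numeric(0), character(0)),
                   predicted_risk = rep(0.3, length(ch$outcome)),
                   outcome = ch$outcome),
              class = "fitted_risk_model")
  }
  res <- optimism_corrected_auc(cohort, const_fit, B = 20L, seed = 5L)
  expect_equal(res$mean_optimism, 0)
  expect_equal(res$auc_corrected, res$auc_apparent)
  # small n with several noise predictors: corrected < apparent
  set.seed(32)
  Xn <- matrix(rbinom(200 * 5, 1, 0.4), 200, 5,
               dimnames = list(NULL, paste0("z", 1:5)))
  yn <- rbinom(200, 1, 0.25)
  over <- optimism_corrected_auc(list(design = Xn, outcome = yn),
                                 B = 60L, seed = 6L)
  expect_lt(over$auc_corrected, over$auc_apparent)
  expect_gt(over$mean_optimism, 0)
})

test_that("metrics reports assemble consistent summaries", {
  cohort <- small_cohort(n = 4000L)
  model <- fit_logistic(cohort)
  rep <- metrics_report(model, cohort = cohort, optimism_B = 25L, seed = 2L)
  expect_s3_class(rep, "metrics_report")
  for (f in c("prop_distinct", "prop_low", "prop_high", "prop_informative_lr"))
    expect_true(rep[[f]] >= 0 && rep[[f]] <= 1)
  expect_true(rep$auc >= 0 && rep$auc <= 1)
  expect_lte(rep$auc_optimism_corrected, rep$auc + 1e-9)
  expect_equal(sum(rep$stratum_table$n), 4000L)
  long <- report_to_long(rep)
  expect_equal(long$value[long$metric == "auc"], rep$auc)
  # custom thresholds flow through to the stratum boundaries
  rep2 <- metrics_report(model, thresholds = c(0.02, 0.18))
  expect_equal(rep2$stratum_table$upper, c(0.02, 0.18, 1))
})
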