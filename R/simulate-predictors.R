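#' Specification of injected binary predictors
#'
#' Describes `k` independent binary predictors to add to a cohort, each
#' with target marginal prevalence `p` and target univariable (crude)
#' odds ratio `theta` against the outcome.
#'
#' @param p Target marginal prevalence, in (0,1).
#' @param theta Target univariable odds ratio, > 0.
#' @param k Number of predictors to inject (>= 1).
#' @return An object of class `sim_predictor_spec`.
#' @export
sim_predictor_spec <- function(p, theta, k = 1L) {
  if (p <= 0 || p >= 1) stop("'p' must lie in (0,1)")
  if (theta <= 0) stop("'theta' must be positive")
  if (k < 1) stop("'k' must be at least 1")
  structure(list(p = p, theta = theta, k = as.integer(k)),
            class = "sim_predictor_spec")
}

#' Solve case/non-case prevalences for a target prevalence and odds ratio
#'
#' A binary predictor drawn Bernoulli(q1) in cases and Bernoulli(q0) in
#' non-cases has univariable odds ratio `q1(1-q0) / (q0(1-q1))` and
#' marginal prevalence `pi*q1 + (1-pi)*q0`, where `pi` is the outcome
#' prevalence. Given targets (p, theta) this solves the unique
#' (q0, q1) in (0,1)^2. Substituting `q1 = theta*q0 / (1 + q0*(theta-1))`
#' into the marginal constraint gives a quadratic in q0:
#' `(1-pi)*a*q0^2 + (pi*theta + (1-pi) - p*a)*q0 - p = 0`, with
#' `a = theta - 1`; the product of its roots is `-p / ((1-pi)*a)`, so
#' exactly one root is positive (and it lies in (0,1)).
#'
#' @param p Target marginal prevalence, in (0,1).
#' @param theta Target univariable odds ratio, > 0.
#' @param pi Outcome prevalence used in the solve, in (0,1); use the
#'   realized cohort incidence for exact recovery on the cohort at hand.
#' @return List with `q0`, `q1`, `pi`.
#' @examples
#' solve_conditional_prevalences(0.4, 1, 0.084)   # q0 = q1 = 0.4
#' solve_conditional_prevalences(0.5, 4, 0.5)     # q0 = 1/3, q1 = 2/3
#' @export
solve_conditional_prevalences <- function(p, theta, pi) {
  if (p <= 0 || p >= 1) stop("'p' must lie in (0,1)")
  if (pi <= 0 || pi >= 1) stop("'pi' must lie in (0,1)")
  if (theta <= 0) stop("'theta' must be positive")
  a <- theta - 1
  if (abs(a) < 1e-12) {
    q0 <- p
  } else {
    A <- (1 - pi) * a
    B <- pi * theta + (1 - pi) - p * a
    C <- -p
    disc <- B^2 - 4 * A * C
    roots <- c((-B + sqrt(disc)) / (2 * A), (-B - sqrt(disc)) / (2 * A))
    inside <- roots[roots > 0 & roots < 1]
    if (length(inside) != 1L)
      stop("no conditional-prevalence solution in (0,1); infeasible target")
    q0 <- inside
    # Newton polish of the monotone marginal equation for 1e-10 accuracy
    f <- function(q) pi * theta * q / (1 + a * q) + (1 - pi) * q - p
    fp <- function(q) pi * theta / (1 + a * q)^2 + (1 - pi)
    for (i in 1:3) q0 <- q0 - f(q0) / fp(q0)
  }
  q1 <- theta * q0 / (1 + q0 * (theta - 1))
  if (q0 <= 0 || q0 >= 1 || q1 <= 0 || q1 >= 1)
    stop("no conditional-prevalence solution in (0,1); infeasible target")
  stopifnot(abs(pi * q1 + (1 - pi) * q0 - p) < 1e-8)
  list(q0 = q0, q1 = q1, pi = pi)
}

#' Inject simulated binary predictors into a cohort
#'
#' Adds `spec$k` binary columns (`sim_1`, ..., `sim_k`), each drawn
#' conditionally on the outcome — Bernoulli(q1) for cases, Bernoulli(q0)
#' for non-cases — independently across predictors and individuals. The
#' conditional prevalences are solved from the target (p, theta) using
#' the realized cohort incidence, so the expected empirical prevalence
#' and crude OR equal the targets exactly. Predictors are conditionally
#' independent given the outcome; marginally they share only the
#' outcome-induced association.
#'
#' @param cohort A `cohort` with outcomes drawn.
#' @param spec A [sim_predictor_spec()].
#' @param seed Integer seed.
#' @return The `cohort` with `k` extra design columns; the solved
#'   `(q0, q1)` is attached as attribute `sim_conditional`.
#' @export
simulate_predictors <- function(cohort, spec, seed) {
  stopifnot(inherits(cohort, "cohort"), inherits(spec, "sim_predictor_spec"))
  if (is.null(cohort$outcome))
    stop("cohort outcomes must be drawn before simulating predictors")
  y <- cohort$outcome
  n <- length(y)
  cond <- solve_conditional_prevalences(spec$p, spec$theta, mean(y))
  set.seed(seed)
  prob <- ifelse(y == 1L, cond$q1, cond$q0)
  sims <- matrix(0L, n, spec$k,
                 dimnames = list(NULL, paste0("sim_", seq_len(spec$k))))
  for (j in seq_len(spec$k))
    sims[, j] <- stats::rbinom(n, 1L, prob)
  cohort$design <- cbind(cohort$design, sims)
  attr(cohort, "sim_conditional") <- cond
  cohort
}
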