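#' Configuration of the factorial simulation grid
#'
#' The full factorial design crosses simulated-predictor prevalence,
#' univariable odds ratio, and the number of predictors added; each cell
#' is replicated with fresh predictor draws. Defaults give the
#' 4 x 10 x 3 = 120-cell grid.
#'
#' @param prevalences Prevalence grid (default `c(0.05, 0.10, 0.20, 0.40)`).
#' @param or_grid Odds-ratio grid (default
#'   `c(1, 1.5, 2, 3, 4, 6, 8, 10, 12, 16)`).
#' @param k_values Numbers of added predictors (default `c(1, 3, 5)`).
#' @param replications Replications per cell (default 100; increase for
#'   tighter Monte Carlo error).
#' @param n Cohort size (default 75225).
#' @param thresholds Clinical risk thresholds `c(low, high)` (default
#'   `c(0.03, 0.15)`; sensitivity values 0.02/0.025 and 0.18/0.20 can be
#'   substituted).
#' @param optimism_B Bootstrap resamples for optimism correction inside
#'   a cell (default 0 = disabled; optimism is near zero at this n).
#' @param optimism_cells Optional data frame (`p`, `theta`, `k`) naming
#'   the cells on which to run the optimism correction when
#'   `optimism_B > 0`; `NULL` means all cells.
#' @param redraw_cohort If `TRUE`, the baseline cohort (design and
#'   outcome) is redrawn every replication; default `FALSE` redraws only
#'   the simulated predictors against one fixed calibrated cohort.
#' @param seed Master seed.
#' @return An object of class `grid_config`.
#' @export
grid_config <- function(prevalences = c(0.05, 0.10, 0.20, 0.40),
                        or_grid = c(1, 1.5, 2, 3, 4, 6, 8, 10, 12, 16),
                        k_values = c(1L, 3L, 5L),
                        replications = 100L,
                        n = 75225L,
                        thresholds = c(0.03, 0.15),
                        optimism_B = 0L,
                        optimism_cells = NULL,
                        redraw_cohort = FALSE,
                        seed = 20160921L) {
  stopifnot(all(prevalences > 0 & prevalences < 1), all(or_grid > 0),
            all(k_values >= 1), replications >= 1, length(thresholds) == 2L)
  structure(
    list(prevalences = prevalences, or_grid = or_grid,
         k_values = as.integer(k_values),
         replications = as.integer(replications), n = as.integer(n),
         thresholds = thresholds, optimism_B = as.integer(optimism_B),
         optimism_cells = optimism_cells,
         redraw_cohort = isTRUE(redraw_cohort), seed = as.integer(seed)),
    class = "grid_config")
}

#' Enumerate the grid cells
#'
#' @param config A `grid_config`.
#' @return Data frame with `cell`, `p`, `theta`, `k`, ordered by
#'   (theta, k, p).
#' @export
grid_cells <- function(config) {
  cells <- expand.grid(p = config$prevalences, k = config$k_values,
                       theta = config$or_grid, KEEP.OUT.ATTRS = FALSE)
  cells <- cells[order(cells$theta, cells$k, cells$p), c("p", "theta", "k")]
  cells$cell <- seq_len(nrow(cells))
  rownames(cells) <- NULL
  cells[, c("cell", "p", "theta", "k")]
}

#' Run one grid cell
#'
#' For each replication: draw `k` fresh simulated predictors with target
#' (prevalence, odds ratio) against the (fixed or redrawn) calibrated
#' cohort, refit the logistic model on baseline plus simulated columns,
#' and compute the full performance report.
#'
#' @param p Simulated-predictor prevalence.
#' @param theta Simulated-predictor univariable odds ratio.
#' @param k Number of simulated predictors.
#' @param cohort The calibrated baseline `cohort` (ignored when
#'   `redraw_cohort = TRUE`).
#' @param reps Number of replications.
#' @param seed Cell seed (per-replication seeds are derived from it).
#' @param thresholds Clinical risk thresholds.
#' @param optimism_B Bootstrap resamples per replication (0 = none).
#' @param spec,calibration Needed only when `redraw_cohort = TRUE`.
#' @param redraw_cohort Redraw the baseline cohort each replication.
#' @return List of `metrics_report`s, one per replication; failures are
#'   recorded as `NULL` with attribute `failures` listing messages.
#' @export
run_cell <- function(p, theta, k, cohort, reps, seed,
                     thresholds = c(0.03, 0.15), optimism_B = 0L,
                     spec = NULL, calibration = NULL,
                     redraw_cohort = FALSE) {
  failures <- character(0)
  reports <- vector("list", reps)
  for (r in seq_len(reps)) {
    res <- tryCatch({
      ch <- if (redraw_cohort)
        synthesize_cohort(spec, derive_seed(seed, 7L, r), calibration)
      else cohort
      ch <- simulate_predictors(ch, sim_predictor_spec(p, theta, k),
                                derive_seed(seed, 4L, r))
      model <- fit_logistic(ch)
      metrics_report(model, thresholds = thresholds, cohort = ch,
                     optimism_B = optimism_B,
                     seed = derive_seed(seed, 5L, r))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("replication %d: %s", r, conditionMessage(res)))
      reports[r] <- list(NULL)
    } else reports[[r]] <- res
  }
  if (length(failures)) attr(reports, "failures") <- failures
  reports
}

#' Run the full simulation grid
#'
#' Executes every cell of the factorial design with deterministic
#' per-cell seeds derived from the master seed, and aggregates each
#' metric across replications by its arithmetic mean with a Monte Carlo
#' standard error.
#'
#' @param config A [grid_config()].
#' @param spec Cohort specification (default
#'   [preeclampsia_cohort_spec()] at `config$n`).
#' @param calibration Optional precomputed [calibrate_lp_scale()]
#'   result; computed once if missing.
#' @param progress Print one line per completed cell.
#' @return An object of class `grid_result`: `results` (long data frame
#'   of cell x replication x metric), `summary` (per-cell means and MC
#'   SEs), `cells`, `config`, `calibration`, `incomplete` (cells with
#'   failed replications).
#' @export
run_grid <- function(config, spec = NULL, calibration = NULL,
                     progress = FALSE) {
  stopifnot(inherits(config, "grid_config"))
  if (is.null(spec))
    spec <- preeclampsia_cohort_spec(n = config$n)
  if (is.null(calibration)) {
    calibration <- if (is.na(spec$target_auc))
      list(lp_scale = spec$lp_scale)
    else calibrate_lp_scale(spec, derive_seed(config$seed, 11L))
  }
  cohort <- synthesize_cohort(spec, config$seed, calibration)
  cells <- grid_cells(config)
  long <- vector("list", nrow(cells))
  incomplete <- integer(0)
  for (i in seq_len(nrow(cells))) {
    ci <- cells[i, ]
    opt_B <- config$optimism_B
    if (opt_B > 0L && !is.null(config$optimism_cells)) {
      oc <- config$optimism_cells
      hit <- any(oc$p == ci$p & oc$theta == ci$theta & oc$k == ci$k)
      if (!hit) opt_B <- 0L
    }
    reports <- run_cell(ci$p, ci$theta, ci$k, cohort,
                        reps = config$replications,
                        seed = derive_seed(config$seed, 13L, ci$cell),
                        thresholds = config$thresholds,
                        optimism_B = opt_B,
                        spec = spec, calibration = calibration,
                        redraw_cohort = config$redraw_cohort)
    if (!is.null(attr(reports, "failures"))) incomplete <- c(incomplete, ci$cell)
    rep_rows <- lapply(seq_along(reports), function(r) {
      if (is.null(reports[[r]])) return(NULL)
      df <- report_to_long(reports[[r]])
      cbind(cell = ci$cell, p = ci$p, theta = ci$theta, k = ci$k,
            replication = r, df)
    })
    long[[i]] <- do.call(rbind, rep_rows)
    if (progress)
      message(sprintf("cell %d/%d (p=%.2f, OR=%g, k=%d) done",
                      ci$cell, nrow(cells), ci$p, ci$theta, ci$k))
  }
  results <- do.call(rbind, long)
  summary <- aggregate_grid(results)
  structure(list(results = results, summary = summary, cells = cells,
                 config = config, calibration = calibration,
                 incomplete = incomplete),
            class = "grid_result")
}

#' Aggregate long-format grid results to per-cell means
#'
#' @param results Long data frame from [run_grid()].
#' @return Data frame with one row per cell x metric: `mean` and the
#'   Monte Carlo standard error `mc_se`.
#' @export
aggregate_grid <- function(results) {
  results <- results[!is.na(results$value), ]
  agg <- stats::aggregate(value ~ cell + p + theta + k + metric,
                          data = results,
                          FUN = function(v) c(mean = mean(v),
                                              mc_se = stats::sd(v) / sqrt(length(v)),
                                              reps = length(v)))
  out <- cbind(agg[, c("cell", "p", "theta", "k", "metric")],
               as.data.frame(agg$value))
  out[order(out$theta, out$k, out$p, out$metric), ]
}

#' Binned predicted-risk histogram with clinical tagging
#'
#' Bins one replication's predicted risks and tags each bin as low,
#' uninformative, or high relative to the clinical thresholds (a bin
#' straddling a threshold is tagged by its midpoint).
#'
#' @param predicted_risk Numeric predicted risks.
#' @param bin_width Bin width on the risk scale (> 0; default 0.005).
#' @param thresholds `c(low, high)` clinical thresholds.
#' @return Data frame with `bin_low`, `bin_high`, `count`, `region`.
#' @export
histogram_data <- function(predicted_risk, bin_width = 0.005,
                           thresholds = c(0.03, 0.15)) {
  if (bin_width <= 0) stop("'bin_width' must be positive")
  brk <- seq(0, 1 + bin_width, by = bin_width)
  idx <- findInterval(predicted_risk, brk, rightmost.closed = TRUE)
  nb <- max(idx)
  counts <- tabulate(idx, nb)
  mid <- (brk[seq_len(nb)] + brk[seq_len(nb) + 1L]) / 2
  region <- ifelse(mid < thresholds[1], "low",
                   ifelse(mid > thresholds[2], "high", "uninformative"))
  keep <- counts > 0
  data.frame(bin_low = brk[seq_len(nb)][keep],
             bin_high = brk[seq_len(nb) + 1L][keep],
             count = counts[keep], region = region[keep])
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf("Simulation grid result: %d cells x %d replications\n",
              nrow(x$cells), x$config$replications))
  if (length(x$incomplete))
    cat("  incomplete cells:", paste(x$incomplete, collapse = ", "), "\n")
  auc_rows <- x$summary[x$summary$metric == "auc", ]
  cat(sprintf("  mean AUC range %.3f - %.3f\n",
              min(auc_rows$mean), max(auc_rows$mean)))
  invisible(x)
}
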