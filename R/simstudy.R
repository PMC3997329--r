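# Monte-Carlo performance harness: repeatedly simulate, fit each estimator on
# the observed subset, form the Horvitz-Thompson estimate and interval, and
# aggregate bias / RMSE / coverage.

#' Performance metrics for a set of replicate estimates
#'
#' Aggregates replicate abundance estimates into the usual Monte-Carlo
#' performance table: `AVE` (mean estimate), `SE` (sample SD across
#' replicates, denominator r - 1), `PRB` (percentage relative bias,
#' `100 * (AVE - N) / N`), `CV` (`100 * SE / AVE`), `RMSE`
#' (`sqrt(mean((est - N)^2))`) and `COV` (percent of confidence intervals
#' containing the true `N`).  With a single replicate the SD is undefined and
#' `SE`, `CV` are reported as `NA`, not zero.
#'
#' @param N_true true population size.
#' @param estimates replicate abundance estimates.
#' @param ses replicate standard errors (optional, reported as `mean_se`).
#' @param covered logical vector: did the replicate CI contain `N_true`?
#' @return one-row data frame of metrics.
#' @export
performance_metrics <- function(N_true, estimates, ses = NULL, covered = NULL) {
  r <- length(estimates)
  stopifnot(r >= 1)
  ave <- mean(estimates)
  se <- if (r > 1) stats::sd(estimates) else NA_real_
  data.frame(
    reps = r,
    AVE = ave,
    SE = se,
    PRB = 100 * (ave - N_true) / N_true,
    CV = if (r > 1) 100 * se / ave else NA_real_,
    RMSE = sqrt(mean((estimates - N_true)^2)),
    COV = if (!is.null(covered)) 100 * mean(covered) else NA_real_,
    mean_se = if (!is.null(ses)) mean(ses) else NA_real_
  )
}

#' Run a Monte-Carlo performance study
#'
#' For each scenario and estimator: simulate `reps` independent populations,
#' fit the capture model with `formula` to each observed subset, estimate
#' abundance by Horvitz-Thompson with a Wald interval, and aggregate with
#' [performance_metrics()].  All estimators see the same simulated data
#' within a replicate.  Replicates where an estimator fails to converge, hits
#' a boundary (any fitted logit beyond 10 in absolute value) or errors are
#' excluded from that estimator's metrics and tallied in `excluded`.
#'
#' Per-replicate seeds are drawn once from the master `seed`, so any single
#' replicate can be regenerated in isolation.
#'
#' @param scenarios a [scenario()] or list of scenarios.
#' @param estimators subset of `c("ql-gee", "pl-glm", "pl-glmm")`.
#' @param reps number of Monte-Carlo replicates (>= 1).
#' @param seed master RNG seed.
#' @param formula capture-model formula (default `~ sex + weight`, the
#'   data-generating covariates).
#' @param level confidence level for coverage.
#' @param mean_form,corr passed to the GEE estimator.
#' @return data frame of class `"simstudy_result"`, one row per
#'   (scenario, estimator): scenario descriptors, `n_bar` (mean number
#'   captured), the [performance_metrics()] columns and `excluded`.
#' @examples
#' run_study(scenario("high", N = 100, m = 6), "ql-gee", reps = 20, seed = 1)
#' @export
run_study <- function(scenarios, estimators = c("ql-gee", "pl-glm"),
                      reps, seed = 1L, formula = ~ sex + weight,
                      level = 0.95,
                      mean_form = "conditional", corr = "independence") {
  if (inherits(scenarios, "cr_scenario")) scenarios <- list(scenarios)
  estimators <- match.arg(estimators, c("ql-gee", "pl-glm", "pl-glmm"),
                          several.ok = TRUE)
  stopifnot(reps >= 1)
  set.seed(seed)
  rows <- list()
  for (sc in scenarios) {
    rep_seeds <- sample.int(.Machine$integer.max, reps)
    est <- lapply(estimators, function(e)
      list(N = numeric(0), se = numeric(0), cov = logical(0), excl = 0L))
    names(est) <- estimators
    n_captured <- numeric(reps)
    for (r in seq_len(reps)) {
      sim <- simulate_capture(sc, seed = rep_seeds[r])
      n_captured[r] <- sum(sim$captured)
      if (is.null(sim$observed)) {
        for (e in estimators) est[[e]]$excl <- est[[e]]$excl + 1L
        next
      }
      for (e in estimators) {
        res <- tryCatch({
          fit <- crfit(formula, sim$observed, method = e,
                       mean_form = mean_form, corr = corr)
          if (!fit$converged || fit$boundary) NULL else
            horvitz_thompson(fit, level = level)
        }, error = function(err) NULL)
        if (is.null(res) || !is.finite(res$N_hat)) {
          est[[e]]$excl <- est[[e]]$excl + 1L
        } else {
          est[[e]]$N <- c(est[[e]]$N, res$N_hat)
          est[[e]]$se <- c(est[[e]]$se, res$se)
          est[[e]]$cov <- c(est[[e]]$cov,
                            res$ci_low <= sc$N && sc$N <= res$ci_high)
        }
      }
    }
    for (e in estimators) {
      pm <- performance_metrics(sc$N, est[[e]]$N, est[[e]]$se, est[[e]]$cov)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(scenario = if (is.na(sc$preset)) "custom" else sc$preset,
                   N = sc$N, m = sc$m, estimator = e,
                   n_bar = mean(n_captured)),
        pm,
        data.frame(excluded = est[[e]]$excl)
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("simstudy_result", "data.frame")
  out
}

#' @export
print.simstudy_result <- function(x, digits = 2, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  print(df, row.names = FALSE)
  invisible(x)
}
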