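#' Simulation scenarios for heterogeneous capture probabilities
#'
#' A scenario bundles the data-generating design of the package's simulation
#' study: population size `N`, `m` occasions, logistic capture model
#' `logit(p_i) = beta0 + beta1 * sex_i + beta2 * weight_i + sigma_b * z_i`
#' with sex ~ Bernoulli(0.5), weight ~ Normal(mean 15, variance 4) and
#' `z_i ~ N(0, 1)` a latent individual effect.  The named presets set the
#' intercept to -3.5 (`"high"`), -4.0 (`"medium"`) or -4.5 (`"low"`) with
#' `beta1 = 0.1`, `beta2 = 0.2` and `sigma_b = 0.1`, spanning average
#' capture probabilities from about 0.4 down to about 0.2 at weight 15.
#'
#' @param preset `"high"`, `"medium"` or `"low"`, or `NULL` to give the
#'   coefficients explicitly.
#' @param N population size.
#' @param m number of occasions.
#' @param beta0,beta1,beta2 model coefficients (overriding the preset).
#' @param sigma_b random-effect SD (>= 0).
#' @param sex_prob,weight_mean,weight_sd covariate distribution parameters.
#' @return An object of class `"cr_scenario"`.
#' @examples
#' scenario("low", N = 100, m = 6)
#' @export
scenario <- function(preset = NULL, N = 100, m = 6,
                     beta0 = NULL, beta1 = NULL, beta2 = NULL,
                     sigma_b = NULL, sex_prob = 0.5,
                     weight_mean = 15, weight_sd = 2) {
  defaults <- list(high = -3.5, medium = -4.0, low = -4.5)
  if (!is.null(preset)) {
    preset <- match.arg(preset, names(defaults))
    if (is.null(beta0)) beta0 <- defaults[[preset]]
    if (is.null(beta1)) beta1 <- 0.1
    if (is.null(beta2)) beta2 <- 0.2
    if (is.null(sigma_b)) sigma_b <- 0.1
  }
  stopifnot(!is.null(beta0), !is.null(beta1), !is.null(beta2),
            !is.null(sigma_b), sigma_b >= 0, N >= 1, m >= 2,
            sex_prob >= 0, sex_prob <= 1, weight_sd >= 0)
  structure(
    list(preset = if (is.null(preset)) NA_character_ else preset,
         N = as.integer(N), m = as.integer(m),
         beta = c(beta0 = beta0, beta1 = beta1, beta2 = beta2),
         sigma_b = sigma_b, sex_prob = sex_prob,
         weight_mean = weight_mean, weight_sd = weight_sd),
    class = "cr_scenario"
  )
}

#' @export
print.cr_scenario <- function(x, ...) {
  cat(sprintf(
    "Scenario%s: N = %d, m = %d, beta = (%.2f, %.2f, %.2f), sigma_b = %.2f\n",
    if (is.na(x$preset)) "" else paste0(" (", x$preset, ")"),
    x$N, x$m, x$beta[1], x$beta[2], x$beta[3], x$sigma_b))
  invisible(x)
}

#' Simulate a capture-recapture experiment
#'
#' Draws covariates, latent effects and the full `N x m` Bernoulli capture
#' matrix under a [scenario()]; capture probability is constant over
#' occasions for each individual, so within-individual dependence enters
#' only through the shared covariates and random effect.  The observed data
#' are the rows with at least one capture.
#'
#' @param sc a [scenario()].
#' @param seed optional RNG seed for exact reproducibility.
#' @return An object of class `"cr_simulation"`: list with `full_y`
#'   (`N x m`), `covariates`, `z`, `p` (true capture probabilities),
#'   `observed` (a [capture_history()] of the captured rows), `captured`
#'   (logical index) and `true_N`.
#' @export
simulate_capture <- function(sc, seed = NULL) {
  stopifnot(inherits(sc, "cr_scenario"))
  if (!is.null(seed)) set.seed(seed)
  N <- sc$N
  sex <- stats::rbinom(N, 1L, sc$sex_prob)
  weight <- stats::rnorm(N, sc$weight_mean, sc$weight_sd)
  z <- stats::rnorm(N)
  p <- stats::plogis(sc$beta[1] + sc$beta[2] * sex + sc$beta[3] * weight +
                       sc$sigma_b * z)
  y <- matrix(stats::rbinom(N * sc$m, 1L, rep(p, sc$m)), N, sc$m)
  captured <- rowSums(y) > 0
  covs <- data.frame(sex = sex, weight = weight)
  structure(
    list(full_y = y, covariates = covs, z = z, p = p,
         observed = if (any(captured)) {
           capture_history(y[captured, , drop = FALSE],
                           covs[captured, , drop = FALSE])
         } else NULL,
         captured = captured, true_N = N, scenario = sc),
    class = "cr_simulation"
  )
}

#' Analytic capture probabilities of a scenario
#'
#' `analytic_mean_p()` is the capture probability at a reference covariate
#' value (weight 15 by default) with the random effect at zero:
#' `h(beta0 + beta1 * sex + beta2 * weight)`.  `analytic_pi()` is the
#' corresponding probability of at least one capture in `m` occasions,
#' `1 - (1 - p)^m`.
#'
#' @param sc a [scenario()].
#' @param sex 1 = male, 0 = female.
#' @param weight reference weight (default 15).
#' @param m number of occasions (defaults to the scenario's).
#' @return a probability.
#' @export
analytic_mean_p <- function(sc, sex, weight = 15) {
  stopifnot(inherits(sc, "cr_scenario"))
  stats::plogis(sc$beta[[1]] + sc$beta[[2]] * sex + sc$beta[[3]] * weight)
}

#' @rdname analytic_mean_p
#' @export
analytic_pi <- function(sc, sex, m = sc$m, weight = 15) {
  prob_ever_captured(analytic_mean_p(sc, sex, weight), m)
}
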