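#' Logistic capture probability
#'
#' Per-occasion capture probability under the logistic individual-covariate
#' model `logit(p_i) = x_i' beta` (a covariate-restricted heterogeneity
#' model).
#'
#' @param beta coefficient vector (intercept first).
#' @param x covariate row(s) excluding the intercept: a numeric vector of
#'   length `length(beta) - 1`, or a matrix with that many columns.
#' @return capture probability/probabilities in (0, 1).
#' @examples
#' capture_prob(c(-3.5, 0.1, 0.2), c(1, 15))  # male of weight 15 g
#' @export
capture_prob <- function(beta, x = numeric(0)) {
  if (length(beta) == 1L && !length(x)) return(stats::plogis(beta))
  if (is.null(dim(x))) x <- matrix(x, ncol = max(length(beta) - 1L, 1L))
  if (ncol(x) != length(beta) - 1L) {
    stop("covariate row length must match length(beta) - 1", call. = FALSE)
  }
  drop(stats::plogis(cbind(1, x) %*% beta))
}

#' Probability of being captured at least once
#'
#' `pi = 1 - (1 - p)^m` for per-occasion capture probability `p` and `m`
#' occasions, computed in log space (`-expm1(m * log1p(-p))`) so that small
#' `p` does not lose precision to cancellation.  Strictly increasing in both
#' arguments.
#'
#' @param p per-occasion capture probability (vectorized).
#' @param m number of occasions.
#' @return probability of at least one capture.
#' @export
prob_ever_captured <- function(p, m) {
  stopifnot(all(p >= 0 & p <= 1), m >= 1)
  -expm1(m * log1p(-p))
}

# d pi / d p for pi = 1 - (1-p)^m
dpi_dp <- function(p, m) m * (1 - p)^(m - 1)

#' Variance weight for penalized partial-likelihood coefficient variance
#'
#' The per-individual weight `eta_i = pi_i^-2 * m * p_i * (1 - pi_i)` entering
#' the penalized-information variance of the GLMM coefficient estimates,
#' where `pi_i = 1 - (1 - p_i)^m`.  Always nonnegative.
#'
#' @param p per-occasion capture probability.
#' @param m number of occasions.
#' @return eta weight(s).
#' @export
eta_weight <- function(p, m) {
  pi_ <- prob_ever_captured(p, m)
  pi_^(-2) * m * p * (1 - pi_)
}

#' Horvitz-Thompson abundance estimate
#'
#' Population size estimated as `N_hat = sum(w_i / pi_hat_i)` over captured
#' individuals (weights are 1 for individual-level fits, group counts for
#' grouped fits).  The variance combines a binomial term
#' `sum(w_i (1 - pi_i) / pi_i^2)` with a delta-method term
#' `d' vcov(beta) d`, `d = dN_hat/dbeta`, following the conditional-likelihood
#' tradition for covariate models.
#'
#' @param fit a [crfit()] object (any method).
#' @param level confidence level for the interval.
#' @param ci_method `"wald"` (default) for `N_hat +/- z * SE`, or
#'   `"lognormal"` for an interval log-normal in `N_hat - n`.
#' @return An object of class `"cr_abundance"`: list with `N_hat`, `se`,
#'   `ci_low`, `ci_high`, `n`, and the variance decomposition.
#' @examples
#' ch <- synthetic_chipmunk_history()
#' fit <- crfit(~ 1, ch, method = "ql-gee", mean_form = "marginal")
#' horvitz_thompson(fit)
#' @export
horvitz_thompson <- function(fit, level = 0.95, ci_method = c("wald", "lognormal")) {
  ci_method <- match.arg(ci_method)
  stopifnot(inherits(fit, "crfit"))
  pi_hat <- fit$pi_hat
  if (any(!is.finite(pi_hat)) || any(pi_hat <= 0)) {
    stop("fitted capture-at-least-once probabilities must be positive",
         call. = FALSE)
  }
  w <- fit$weights
  N_hat <- sum(w / pi_hat)
  var_binom <- sum(w * (1 - pi_hat) / pi_hat^2)
  # dN/dbeta = -sum w pi^-2 dpi/dp p(1-p) x
  p <- fit$p_hat
  d <- -colSums(fit$X * (w * pi_hat^(-2) * dpi_dp(p, fit$m) * p * (1 - p)))
  var_beta <- drop(t(d) %*% fit$vcov %*% d)
  se <- sqrt(var_binom + var_beta)
  n <- sum(w)
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (ci_method == "wald") {
    ci <- c(N_hat - z * se, N_hat + z * se)
  } else {
    # log-normal interval on N_hat - n (Chao-style), guards against ci_low < n
    f0 <- max(N_hat - n, 1e-8)
    C <- exp(z * sqrt(log1p(se^2 / f0^2)))
    ci <- c(n + f0 / C, n + f0 * C)
  }
  structure(
    list(N_hat = N_hat, se = se, ci_low = ci[1], ci_high = ci[2],
         level = level, ci_method = ci_method, n = n,
         var_binomial = var_binom, var_coefficient = var_beta),
    class = "cr_abundance"
  )
}

#' @export
print.cr_abundance <- function(x, ...) {
  cat(sprintf("Horvitz-Thompson abundance: N_hat = %.2f (SE %.2f)\n",
              x$N_hat, x$se))
  cat(sprintf("%d%% %s CI: [%.2f, %.2f]   (n = %.0f captured)\n",
              round(100 * x$level), x$ci_method, x$ci_low, x$ci_high, x$n))
  invisible(x)
}
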