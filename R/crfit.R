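#' Fit a closed-population capture-recapture model
#'
#' The single fitting front-end of the package.  Capture probabilities follow
#' the logistic individual-covariate model `logit(p_i) = x_i' beta` (plus a
#' Gaussian random intercept `sigma_b z_i` for the GLMM); population size is
#' then estimated from the fit by [horvitz_thompson()].  Three estimators are
#' available:
#'
#' * `"ql-gee"` — quasi-likelihood generalized estimating equations across
#'   capture occasions ([gee_solve()]), with independence (default) or
#'   exchangeable working correlation and either the conditional
#'   (`mu_ij = p_i / pi_i`, default) or marginal (`mu_ij = p_i`) mean form;
#' * `"pl-glm"` — partial-likelihood binomial GLM of recaptures after first
#'   capture ([fit_pl_glm()]);
#' * `"pl-glmm"` — partial-likelihood GLMM with Gaussian random intercept
#'   fitted by penalized quasi-likelihood ([fit_pl_glmm()]).
#'
#' `data` may be a [capture_history()] (full individual histories) or a
#' [grouped_summary()] (printed group-level sufficient statistics).  Grouped
#' data support only `"ql-gee"`: the partial-likelihood estimators need
#' per-individual first-capture times, which grouped summaries do not carry.
#'
#' @param formula model formula on the covariates, e.g. `~ 1` (equal
#'   catchability) or `~ sex + weight`.
#' @param data a [capture_history()] or [grouped_summary()].
#' @param method estimator: `"ql-gee"`, `"pl-glm"` or `"pl-glmm"`.
#' @param mean_form GEE mean form, `"conditional"` (default) or `"marginal"`.
#' @param corr GEE working correlation, `"independence"` (default) or
#'   `"exchangeable"`.
#' @param sigma_b GLMM random-effect SD: `NULL` (estimate) or a fixed value.
#' @param ... passed on to the underlying engine (e.g. `tol`, `maxit`).
#' @return An object of class `"crfit"` with components `coefficients`,
#'   `sigma_b` (GLMM only), `vcov`, `p_hat`, `pi_hat`, `X`, `weights`
#'   (1 per individual, group counts for grouped data), `m`, `n`,
#'   `converged`, `boundary`, `method` and the call.
#' @examples
#' fit <- crfit(~ sex, chipmunk_summary(), method = "ql-gee")
#' summary(fit)
#' @export
crfit <- function(formula, data, method = c("ql-gee", "pl-glm", "pl-glmm"),
                  mean_form = c("conditional", "marginal"),
                  corr = c("independence", "exchangeable"),
                  sigma_b = NULL, ...) {
  method <- match.arg(method)
  mean_form <- match.arg(mean_form)
  corr <- match.arg(corr)
  UseMethod("crfit", data)
}

#' @export
crfit.capture_history <- function(formula, data,
                                  method = c("ql-gee", "pl-glm", "pl-glmm"),
                                  mean_form = c("conditional", "marginal"),
                                  corr = c("independence", "exchangeable"),
                                  sigma_b = NULL, ...) {
  method <- match.arg(method)
  mean_form <- match.arg(mean_form)
  corr <- match.arg(corr)
  cs <- summary(data)
  terms_obj <- stats::terms(formula)
  vars <- all.vars(formula)
  missing_cov <- setdiff(vars, names(data$covariates))
  if (length(missing_cov)) {
    stop("covariate(s) not found: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  }
  if (length(vars) && anyNA(data$covariates[vars])) {
    stop("missing covariate values for fitted terms", call. = FALSE)
  }
  X <- stats::model.matrix(formula, data$covariates)

  if (method == "ql-gee") {
    eng <- gee_solve(cs$T, X, cs$m, mean_form = mean_form, corr = corr, ...)
    out <- list(coefficients = eng$beta, vcov = eng$vcov,
                vcov_sandwich = eng$vcov_sandwich, alpha = eng$alpha)
    eta <- drop(X %*% eng$beta)
    out$p_hat <- stats::plogis(eta)
  } else {
    pl <- build_pl_data(cs, X)
    eng <- if (method == "pl-glm") fit_pl_glm(pl, ...)
           else fit_pl_glmm(pl, sigma_b = sigma_b, ...)
    out <- list(coefficients = eng$beta, vcov = eng$vcov,
                deviance = eng$deviance)
    out$p_hat <- eng$p_hat
    if (method == "pl-glmm") {
      out$sigma_b <- eng$sigma_b
      out$z <- eng$z
      out$lambda <- eng$lambda
      out$eta_weights <- eng$eta_weights
      out$trace <- eng$trace
    }
    out$pl_data <- pl
  }
  out$pi_hat <- prob_ever_captured(out$p_hat, cs$m)
  out$X <- X
  out$weights <- rep(1, cs$n)
  out$T <- cs$T
  out$m <- cs$m
  out$n <- cs$n
  out$converged <- eng$converged
  out$boundary <- eng$boundary
  out$iterations <- eng$iterations
  out$method <- method
  out$mean_form <- if (method == "ql-gee") mean_form else NA_character_
  out$corr <- if (method == "ql-gee") corr else NA_character_
  out$formula <- formula
  out$call <- match.call()
  class(out) <- "crfit"
  out
}

#' @export
crfit.grouped_summary <- function(formula, data,
                                  method = c("ql-gee", "pl-glm", "pl-glmm"),
                                  mean_form = c("conditional", "marginal"),
                                  corr = c("independence", "exchangeable"),
                                  sigma_b = NULL, ...) {
  method <- match.arg(method)
  mean_form <- match.arg(mean_form)
  corr <- match.arg(corr)
  if (method != "ql-gee") {
    stop("first-capture times required: partial-likelihood estimators ",
         "cannot be fitted to grouped summary data", call. = FALSE)
  }
  vars <- all.vars(formula)
  if (length(vars) && !identical(vars, data$covariate_name)) {
    stop("grouped data carry only the covariate '", data$covariate_name, "'",
         call. = FALSE)
  }
  m <- data$m
  if (!length(vars)) {
    # pooled intercept-only fit via the closed forms
    p0 <- if (mean_form == "marginal") {
      solve_m0_marginal(data$n, m, data$total_captures)
    } else {
      solve_conditional_group(data$n, m, data$total_captures)
    }
    X <- matrix(1, 1, 1, dimnames = list(NULL, "(Intercept)"))
    beta <- stats::setNames(stats::qlogis(as.numeric(p0)), "(Intercept)")
    vcov <- group_info_vcov(X, counts = data$n, p = as.numeric(p0), m = m,
                            mean_form = mean_form)
    p_hat <- rep(as.numeric(p0), 1)
    weights <- data$n
    boundary <- isTRUE(attr(p0, "boundary"))
  } else {
    X <- cbind("(Intercept)" = 1, data$covariate)
    colnames(X)[2] <- data$covariate_name
    p_g <- vapply(seq_along(data$count), function(g) {
      as.numeric(if (mean_form == "marginal") {
        solve_m0_marginal(data$count[g], m, data$captures[g])
      } else {
        solve_conditional_group(data$count[g], m, data$captures[g])
      })
    }, numeric(1))
    boundary <- any(p_g <= 0 | p_g >= 1)
    logits <- stats::qlogis(pmin(pmax(p_g, 1e-12), 1 - 1e-12))
    beta <- stats::setNames(
      c(logits[1], logits[2] - logits[1]),
      c("(Intercept)", data$covariate_name)
    )
    vcov <- group_info_vcov(X, counts = data$count, p = p_g, m = m,
                            mean_form = mean_form)
    p_hat <- p_g
    weights <- data$count
  }
  out <- list(coefficients = beta, vcov = vcov, p_hat = p_hat,
              pi_hat = prob_ever_captured(p_hat, m),
              X = X, weights = weights, m = m, n = data$n,
              converged = TRUE, boundary = boundary, iterations = 0L,
              method = "ql-gee", mean_form = mean_form, corr = corr,
              formula = formula, grouped = TRUE, call = match.call())
  class(out) <- "crfit"
  out
}

# Model-based covariance of beta for a (saturated) grouped fit: per-group
# information m * c^2 / v on the logit scale, weighted by group counts.
group_info_vcov <- function(X, counts, p, m, mean_form) {
  if (mean_form == "marginal") {
    cc <- p * (1 - p)
    v <- cc
  } else {
    pi_ <- prob_ever_captured(p, m)
    g <- p / pi_
    cc <- (pi_ - p * dpi_dp(p, m)) / pi_^2 * p * (1 - p)
    v <- g * (1 - g)
  }
  J <- crossprod(X * sqrt(counts * m * cc^2 / pmax(v, 1e-12)))
  V <- solve(J)
  dimnames(V) <- list(colnames(X), colnames(X))
  V
}

#' @export
print.crfit <- function(x, digits = 2, ...) {
  lab <- c("ql-gee" = "Quasi-likelihood GEE",
           "pl-glm" = "Partial-likelihood GLM",
           "pl-glmm" = "Partial-likelihood GLMM (PQL)")[x$method]
  cat(lab, "capture-probability fit\n")
  se <- sqrt(diag(x$vcov))
  co <- sprintf("%.*f (%.*f)", digits, x$coefficients, digits, se)
  cat(paste(names(x$coefficients), co, sep = " = ", collapse = ", "), "\n")
  if (!is.null(x$sigma_b)) {
    cat(sprintf("Random-intercept SD sigma_b = %.*f\n", digits, x$sigma_b))
  }
  if (!x$converged) cat("WARNING: estimation did not converge\n")
  if (isTRUE(x$boundary)) cat("WARNING: boundary fit (non-estimable)\n")
  invisible(x)
}

#' @export
summary.crfit <- function(object, level = 0.95, ...) {
  se <- sqrt(diag(object$vcov))
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               z = object$coefficients / se)
  ab <- horvitz_thompson(object, level = level)
  structure(list(fit = object, coef_table = tab, abundance = ab),
            class = "summary.crfit")
}

#' @export
print.summary.crfit <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients:\n")
  stats::printCoefmat(x$coef_table, digits = 3)
  cat("\n")
  print(x$abundance)
  invisible(x)
}

#' @export
coef.crfit <- function(object, ...) object$coefficients

#' @export
vcov.crfit <- function(object, ...) object$vcov

#' Predicted capture probabilities
#'
#' @param object a [crfit()] object.
#' @param newdata optional data frame of covariates; default: the fitted
#'   individuals.
#' @param type `"p"` for the per-occasion capture probability, `"pi"` for the
#'   probability of at least one capture over the `m` occasions.
#' @param ... unused.
#' @export
predict.crfit <- function(object, newdata = NULL, type = c("p", "pi"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    return(if (type == "p") object$p_hat else object$pi_hat)
  }
  X <- stats::model.matrix(object$formula, as.data.frame(newdata))
  p <- stats::plogis(drop(X %*% object$coefficients))
  if (type == "p") p else prob_ever_captured(p, object$m)
}

#' @export
residuals.crfit <- function(object, ...) {
  if (isTRUE(object$grouped)) {
    stop("individual-level residuals unavailable for grouped fits",
         call. = FALSE)
  }
  # individual-level Pearson residuals of the capture counts
  mu <- object$m * object$p_hat
  (object$T - mu) / sqrt(pmax(object$m * object$p_hat * (1 - object$p_hat),
                              1e-12))
}

#' Simulate capture histories from a fitted model
#'
#' Parametric simulation: draws full Bernoulli capture histories at the
#' fitted per-occasion probabilities of the `n` fitted individuals (random
#' effects, where present, held at their predictions).  Rows that happen to
#' be all-zero are dropped, as they would be unobserved in the field.
#'
#' @param object a [crfit()] object (individual-level).
#' @param nsim number of simulated datasets.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return list of [capture_history()] objects of length `nsim`.
#' @export
simulate.crfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (isTRUE(object$grouped)) {
    stop("simulation requires an individual-level fit", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  covs <- as.data.frame(object$X[, -1, drop = FALSE])
  lapply(seq_len(nsim), function(r) {
    y <- matrix(stats::rbinom(object$n * object$m, 1L,
                              rep(object$p_hat, object$m)),
                object$n, object$m)
    keep <- rowSums(y) > 0
    capture_history(y[keep, , drop = FALSE], covs[keep, , drop = FALSE])
  })
}

#' @export
plot.crfit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::hist(x$p_hat, main = "Fitted capture probabilities",
                 xlab = "p_hat", col = "grey85", border = "white")
  if (!isTRUE(x$grouped)) {
    graphics::plot(x$p_hat, residuals(x), xlab = "p_hat",
                   ylab = "Pearson residual (capture count)",
                   main = "Residuals vs fitted")
    graphics::abline(h = 0, lty = 2)
  } else {
    graphics::barplot(x$pi_hat, names.arg = seq_along(x$pi_hat),
                      main = "Group pi_hat", ylab = "P(captured >= once)")
  }
  invisible(x)
}
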