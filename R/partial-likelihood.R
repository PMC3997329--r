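# Partial-likelihood estimation from recaptures after first capture:
# given the first-capture occasion t_i, the number of recaptures satisfies
# (T_i - 1) | t_i ~ Binomial(m - t_i, p_i), free of the unknown N.

#' Build partial-likelihood records
#'
#' One record per captured individual: `successes = T_i - 1` recaptures out of
#' `trials = m - t_i` occasions after first capture.  Individuals first caught
#' on the last occasion have zero trials; they are retained (they still enter
#' the Horvitz-Thompson sum through their fitted capture probability) but
#' contribute nothing to the likelihood.
#'
#' @param cs a `capture_summary` (from [summary.capture_history()]).
#' @param X design matrix (intercept included), one row per individual.
#' @return An object of class `"pl_data"`: list with `successes`, `trials`,
#'   `X`, `m`.
#' @export
build_pl_data <- function(cs, X) {
  stopifnot(inherits(cs, "capture_summary"))
  X <- as.matrix(X)
  stopifnot(nrow(X) == cs$n)
  structure(
    list(successes = cs$T - 1L, trials = cs$m - cs$t_first, X = X, m = cs$m),
    class = "pl_data"
  )
}

#' Partial-likelihood GLM fit
#'
#' Maximizes the binomial-logit partial likelihood of recaptures after first
#' capture.  This is an ordinary weighted binomial logistic regression on
#' (successes, trials); records with zero trials are inert in the fit but
#' receive fitted probabilities.
#'
#' @param pl a [build_pl_data()] object.
#' @return list with `beta`, `vcov` (inverse observed information), `p_hat`
#'   and `pi_hat` for all individuals, `deviance`, `converged`, `boundary`
#'   (separation / fitted logits beyond 10 in absolute value) and
#'   `iterations`.
#' @export
fit_pl_glm <- function(pl) {
  stopifnot(inherits(pl, "pl_data"))
  act <- pl$trials > 0L
  if (!any(act)) {
    stop("all individuals first captured on the last occasion: ",
         "no recapture information to fit", call. = FALSE)
  }
  X <- pl$X[act, , drop = FALSE]
  tr <- pl$trials[act]
  fit <- suppressWarnings(stats::glm.fit(
    x = X, y = pl$successes[act] / tr, weights = tr,
    family = stats::binomial()
  ))
  beta <- fit$coefficients
  if (anyNA(beta)) {
    stop("singular information matrix: collinear model terms", call. = FALSE)
  }
  w <- fit$weights * 1  # trials * p * (1-p) at convergence
  vcov <- solve(crossprod(X * sqrt(pmax(w, 1e-12)) / 1))
  dimnames(vcov) <- list(colnames(pl$X), colnames(pl$X))
  eta_all <- drop(pl$X %*% beta)
  p_hat <- stats::plogis(eta_all)
  list(beta = stats::setNames(beta, colnames(pl$X)), vcov = vcov,
       p_hat = p_hat, pi_hat = prob_ever_captured(p_hat, pl$m),
       deviance = fit$deviance, converged = fit$converged,
       boundary = any(abs(eta_all) > 10), iterations = fit$iter)
}

# binomial deviance of (successes, trials) records at probabilities p
binom_deviance <- function(y, tr, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  ll <- y * log(p) + (tr - y) * log1p(-p)
  ysat <- ifelse(tr > 0, y / tr, 0)
  lsat <- ifelse(y > 0, y * log(ysat), 0) +
    ifelse(tr - y > 0, (tr - y) * log1p(-ysat), 0)
  2 * sum(lsat - ll)
}

# One penalized-quasi-likelihood inner solve at fixed random-effect variance
# sigma2.  Working model: u_i = x_i'beta + b_i + e_i with Var(b_i) = sigma2,
# Var(e_i) = 1/w_i; diagonal GLS is closed-form.
pql_inner <- function(y, tr, X, sigma2, beta, b, maxit = 100L, tol = 1e-8) {
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta) + b
    p <- stats::plogis(eta)
    w <- pmax(tr * p * (1 - p), 1e-10)
    u <- eta + (y - tr * p) / w
    s <- sigma2 + 1 / w
    XtS <- X / s
    beta_new <- drop(solve(crossprod(X, XtS), crossprod(XtS, u)))
    b_new <- sigma2 / s * (u - drop(X %*% beta_new))
    delta <- max(abs(beta_new - beta), abs(b_new - b))
    beta <- beta_new
    b <- b_new
    if (delta < tol) break
  }
  eta <- drop(X %*% beta) + b
  p <- stats::plogis(eta)
  w <- pmax(tr * p * (1 - p), 1e-10)
  list(beta = beta, b = b, w = w, u = eta + (y - tr * p) / w,
       eta = eta, p = p, iterations = it)
}

# Negative working-REML criterion for sigma2 given working response u and
# weights w (diagonal marginal variance sigma2 + 1/w).
neg_working_reml <- function(sigma2, u, w, X) {
  s <- sigma2 + 1 / w
  XtS <- X / s
  XtSX <- crossprod(X, XtS)
  beta <- drop(solve(XtSX, crossprod(XtS, u)))
  r <- u - drop(X %*% beta)
  sum(log(s)) + determinant(XtSX, logarithm = TRUE)$modulus + sum(r^2 / s)
}

#' Partial-likelihood GLMM fit by penalized quasi-likelihood
#'
#' Adds a Gaussian random intercept to the partial-likelihood model:
#' `logit(p_i) = x_i' beta + sigma_b z_i`, `z_i ~ N(0, 1)`, capturing
#' heterogeneity not explained by the covariates.  Fitting alternates a
#' penalized working least-squares solve for `(beta, b)` with a working-REML
#' update of the random-effect variance (penalized quasi-likelihood).
#' Individuals with zero recapture trials carry no information on their
#' random effect; their predicted `z_i` is 0.
#'
#' @param pl a [build_pl_data()] object.
#' @param sigma_b if `NULL` (default) the random-effect SD is estimated; a
#'   fixed value (e.g. 0) skips the variance update, and `sigma_b = 0`
#'   reproduces the [fit_pl_glm()] fit.
#' @param tol convergence tolerance on `beta` and `sigma_b`.
#' @param maxit maximum outer iterations.
#' @return list with `beta`, `sigma_b`, `z` (predicted standardized random
#'   effects, 0 for zero-trial individuals), `lambda` (= 1 / sigma_b^2, the
#'   equivalent ridge penalty; `Inf` at sigma_b = 0), `vcov` (working GLS
#'   covariance of `beta`), `eta_weights` (the `eta_i` variance weights of
#'   [eta_weight()]), conditional `p_hat` / `pi_hat`, `deviance`
#'   (conditional binomial deviance), `converged`, `boundary`, `iterations`
#'   and the iteration `trace`.
#' @export
fit_pl_glmm <- function(pl, sigma_b = NULL, tol = 1e-6, maxit = 200L) {
  stopifnot(inherits(pl, "pl_data"))
  act <- pl$trials > 0L
  if (!any(act)) {
    stop("all individuals first captured on the last occasion: ",
         "no recapture information to fit", call. = FALSE)
  }
  X <- pl$X[act, , drop = FALSE]
  y <- pl$successes[act]
  tr <- pl$trials[act]
  estimate_sigma <- is.null(sigma_b)
  sigma2 <- if (estimate_sigma) 0.01 else sigma_b^2
  beta <- fit_pl_glm(pl)$beta
  b <- numeric(length(y))
  trace <- data.frame(iter = integer(0), sigma_b = numeric(0),
                      max_abs_beta_step = numeric(0))
  converged <- FALSE
  for (it in seq_len(maxit)) {
    inner <- pql_inner(y, tr, X, sigma2, beta, b)
    sigma2_new <- sigma2
    if (estimate_sigma) {
      opt <- stats::optimize(neg_working_reml, c(0, 25),
                             u = inner$u, w = inner$w, X = X, tol = 1e-10)
      sigma2_new <- opt$minimum
      if (neg_working_reml(0, inner$u, inner$w, X) <= opt$objective) {
        sigma2_new <- 0   # boundary: no extra-binomial variation
      }
    }
    dbeta <- max(abs(inner$beta - beta))
    dsig <- abs(sqrt(sigma2_new) - sqrt(sigma2))
    trace <- rbind(trace, data.frame(iter = it, sigma_b = sqrt(sigma2_new),
                                     max_abs_beta_step = dbeta))
    beta <- inner$beta
    b <- inner$b
    sigma2 <- sigma2_new
    if (dbeta < tol && dsig < tol) {
      converged <- TRUE
      break
    }
  }
  inner <- pql_inner(y, tr, X, sigma2, beta, b)
  beta <- inner$beta
  sigma_b_hat <- sqrt(sigma2)
  z <- numeric(length(pl$trials))
  z[act] <- if (sigma_b_hat > 0) inner$b / sigma_b_hat else 0
  eta_all <- drop(pl$X %*% beta) + sigma_b_hat * z
  p_hat <- stats::plogis(eta_all)
  s <- sigma2 + 1 / inner$w
  vcov <- solve(crossprod(X, X / s))
  dimnames(vcov) <- list(colnames(pl$X), colnames(pl$X))
  list(beta = stats::setNames(beta, colnames(pl$X)),
       sigma_b = sigma_b_hat, z = z,
       lambda = if (sigma2 > 0) 1 / sigma2 else Inf,
       vcov = vcov, eta_weights = eta_weight(p_hat, pl$m),
       p_hat = p_hat, pi_hat = prob_ever_captured(p_hat, pl$m),
       deviance = binom_deviance(y, tr, inner$p),
       converged = converged, boundary = any(abs(eta_all) > 10),
       iterations = it, trace = trace)
}

#' Penalized-information coefficient variance for the GLMM
#'
#' Sandwich variance of the joint coefficient vector (fixed effects, then
#' random intercepts) from the ridge-penalized working information: with
#' `C = [X, Z]`, working weights `W` and penalty `lambda` on the
#' random-intercept block, `A = C'WC + lambda P` and
#' `Var = A^-1 C' diag(eta) C A^-1`, where `eta_i` are the [eta_weight()]
#' variance weights evaluated at the fit.  As `lambda` grows the variance of
#' the penalized (random-effect) directions shrinks to zero.
#'
#' @param fit a [fit_pl_glmm()] result.
#' @param pl the [build_pl_data()] object the fit was computed from.
#' @param lambda ridge penalty; defaults to the fit's `lambda`.
#' @return covariance matrix over (fixed effects, random intercepts of the
#'   individuals with positive trials).
#' @export
glmm_variance <- function(fit, pl, lambda = fit$lambda) {
  stopifnot(inherits(pl, "pl_data"))
  act <- pl$trials > 0L
  X <- pl$X[act, , drop = FALSE]
  p <- fit$p_hat[act]
  w <- pmax(pl$trials[act] * p * (1 - p), 1e-10)
  q <- nrow(X)
  C <- cbind(X, diag(q))
  P <- diag(c(rep(0, ncol(X)), rep(1, q)))
  lam <- if (is.finite(lambda)) lambda else 1e12
  A <- crossprod(C * sqrt(w)) + lam * P
  eta_w <- fit$eta_weights[act]
  Ainv <- solve(A)
  V <- Ainv %*% crossprod(C * sqrt(pmax(eta_w, 0))) %*% Ainv
  rn <- c(colnames(pl$X), paste0("z_", which(act)))
  dimnames(V) <- list(rn, rn)
  V
}

#' Generalized cross-validation for the ridge penalty
#'
#' Grid search for the penalty `lambda` (equivalently the random-effect
#' variance `1/lambda`) minimizing the GCV score
#' `n * deviance(lambda) / (n - edf(lambda))^2`, where `edf` is the effective
#' number of parameters of the penalized working smoother.  Ties are broken
#' toward the smallest `lambda`.
#'
#' @param pl a [build_pl_data()] object.
#' @param grid candidate penalties; default 25 points log-spaced in
#'   `[1e-4, 1e4]`.
#' @return the selected `lambda`, with the score path in attribute `"path"`.
#' @export
select_lambda_gcv <- function(pl,
                              grid = exp(seq(log(1e-4), log(1e4), length.out = 25))) {
  stopifnot(inherits(pl, "pl_data"))
  grid <- sort(grid)
  act <- pl$trials > 0L
  X <- pl$X[act, , drop = FALSE]
  y <- pl$successes[act]
  tr <- pl$trials[act]
  n_act <- length(y)
  beta0 <- fit_pl_glm(pl)$beta
  score <- vapply(grid, function(lam) {
    inner <- pql_inner(y, tr, X, 1 / lam, beta0, numeric(n_act))
    edf <- ncol(X) + sum(inner$w / lam / (inner$w / lam + 1))
    dev <- binom_deviance(y, tr, inner$p)
    n_act * dev / (n_act - min(edf, n_act - 1e-6))^2
  }, numeric(1))
  lambda <- grid[which.min(score)]
  attr(lambda, "path") <- data.frame(lambda = grid, gcv = score)
  lambda
}
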