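# Quasi-likelihood GEE estimation of the logistic capture model.
#
# Because the per-occasion mean is constant within an individual, the
# per-individual score collapses onto the sufficient statistic T_i (capture
# count), and an exchangeable working correlation rescales every individual's
# score by the same factor 1/(1 + (m-1) alpha): the root is unchanged, only
# the model-based covariance inflates.  The solver therefore iterates on
# (T_i, x_i) regardless of the working structure.

#' Solve the capture-probability estimating equations
#'
#' Fisher scoring for the quasi-likelihood GEE estimator of the logistic
#' capture model, using either the conditional mean of an occasion indicator
#' given capture at least once (`mu_ij = p_i / pi_i`, the default, since the
#' data contain captured individuals only) or the marginal mean
#' (`mu_ij = p_i`).  With an independence working correlation and the
#' marginal form this reduces to the Bernoulli GLM score equations.
#'
#' @param T integer vector of per-individual capture counts (each >= 1).
#' @param X design matrix (intercept column included), one row per individual.
#' @param m number of occasions.
#' @param mean_form `"conditional"` or `"marginal"`.
#' @param corr working correlation: `"independence"` or `"exchangeable"`.
#' @param weights optional per-row multiplicities (used for grouped data).
#' @param tol convergence tolerance on both the coefficient step and the
#'   estimating-function norm.
#' @param maxit maximum Fisher-scoring iterations.
#' @param start starting coefficients (default all zero).
#' @return list with `beta`, `vcov` (model-based), `vcov_sandwich`, `alpha`
#'   (estimated exchangeable correlation; 0 under independence), `score` at
#'   the solution, `converged`, `boundary` (TRUE when any fitted logit
#'   exceeds 10 in absolute value, flagging a non-estimable boundary fit)
#'   and `iterations`.
#' @examples
#' cs <- summary(synthetic_chipmunk_history())
#' gee_solve(cs$T, cbind(1, cs$covariates$sex), m = 6)
#' @export
gee_solve <- function(T, X, m,
                      mean_form = c("conditional", "marginal"),
                      corr = c("independence", "exchangeable"),
                      weights = NULL, tol = 1e-8, maxit = 100L,
                      start = NULL) {
  mean_form <- match.arg(mean_form)
  corr <- match.arg(corr)
  X <- as.matrix(X)
  stopifnot(length(T) == nrow(X), all(T >= 1), all(T <= m), m >= 2)
  if (is.null(weights)) weights <- rep(1, nrow(X))
  p_dim <- ncol(X)
  beta <- if (is.null(start)) numeric(p_dim) else start

  score_parts <- function(beta) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    if (mean_form == "conditional") {
      pi_ <- prob_ever_captured(p, m)
      g <- p / pi_
      dg <- (pi_ - p * dpi_dp(p, m)) / pi_^2      # dg/dp
      cc <- dg * p * (1 - p)                      # dmu/deta
      v <- g * (1 - g)
    } else {
      g <- p
      cc <- p * (1 - p)
      v <- cc
    }
    v <- pmax(v, 1e-12)
    list(eta = eta, p = p, g = g, cc = cc, v = v,
         U = colSums(X * (weights * cc / v * (T - m * g))),
         J = crossprod(X * sqrt(weights * m * cc^2 / v)))
  }

  sp <- score_parts(beta)
  converged <- FALSE
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    step <- tryCatch(solve(sp$J, sp$U), error = function(e)
      stop("singular information matrix: collinear model terms (",
           paste(colnames(X), collapse = ", "), ")", call. = FALSE))
    # step-halving on the estimating-function norm
    lam <- 1
    for (h in 1:25) {
      cand <- beta + lam * step
      sp_new <- score_parts(cand)
      if (sum(sp_new$U^2) <= sum(sp$U^2) || lam < 1e-6) break
      lam <- lam / 2
    }
    delta <- max(abs(cand - beta))
    beta <- cand
    sp <- sp_new
    if (delta < tol || sqrt(sum(sp$U^2)) < tol) {
      converged <- TRUE
      break
    }
  }

  boundary <- any(abs(sp$eta) > 10)
  # exchangeable correlation: moment estimator from within-individual
  # Pearson-residual cross-products, expressed through T alone
  cross <- ((T^2 - T) / 2 - (m - 1) * T * sp$g + choose(m, 2) * sp$g^2) / sp$v
  alpha_hat <- sum(weights * cross) / (sum(weights) * choose(m, 2))
  alpha_hat <- max(min(alpha_hat, 0.999), -1 / (m - 1) + 1e-6)
  kfac <- if (corr == "exchangeable") 1 / (1 + (m - 1) * alpha_hat) else 1

  Jw <- kfac * sp$J
  vcov <- solve(Jw)
  resid_score <- weights * sp$cc / sp$v * (T - m * sp$g) * kfac
  meat <- crossprod(X * resid_score)
  vcov_sandwich <- vcov %*% meat %*% vcov
  dimnames(vcov) <- dimnames(vcov_sandwich) <- list(colnames(X), colnames(X))

  list(beta = stats::setNames(beta, colnames(X)),
       vcov = vcov, vcov_sandwich = vcov_sandwich,
       alpha = if (corr == "exchangeable") alpha_hat else 0,
       score = sp$U, converged = converged, boundary = boundary,
       iterations = it, mean_form = mean_form, corr = corr)
}

#' Closed-form equal-catchability solutions
#'
#' For the intercept-only (equal capture probability) model, the marginal
#' moment equation has the closed form `p_hat = total_captures / (n * m)`.
#' The conditional equation `m p / pi(p) = total_captures / n` has a unique
#' root in (0, 1) because its left side is strictly increasing in `p`;
#' [solve_conditional_group()] finds it by bracketed root-finding.  Both are
#' also used group-by-group for a saturated categorical covariate.
#'
#' @param n,count number of captured individuals (overall, or in the group).
#' @param m number of occasions.
#' @param total_captures total number of captures.
#' @return `p_hat`, with attribute `boundary = TRUE` when the solution lies
#'   on the boundary of (0, 1) (all individuals caught on every occasion, or
#'   every individual caught exactly once).
#' @export
solve_m0_marginal <- function(n, m, total_captures) {
  stopifnot(n >= 1, m >= 2, total_captures >= n, total_captures <= n * m)
  p <- total_captures / (n * m)
  structure(p, boundary = (p >= 1) || (p <= 0))
}

#' @rdname solve_m0_marginal
#' @export
solve_conditional_group <- function(count, m, total_captures) {
  stopifnot(count >= 1, m >= 2, total_captures >= count,
            total_captures <= count * m)
  mean_cap <- total_captures / count
  if (mean_cap <= 1) {
    # every individual caught exactly once: conditional mean -> 1 as p -> 0
    return(structure(0, boundary = TRUE))
  }
  if (mean_cap >= m) {
    return(structure(1, boundary = TRUE))
  }
  fn <- function(p) m * p / prob_ever_captured(p, m) - mean_cap
  root <- stats::uniroot(fn, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  structure(root, boundary = FALSE)
}

#' Moment estimator of the exchangeable working correlation
#'
#' Averages within-individual cross-products of Pearson residuals over all
#' pairs of occasions.  Near zero for occasion-independent data; approaches 1
#' when occasion outcomes are duplicated; positive when a shared random
#' effect induces within-individual dependence.
#'
#' @param residuals n x m matrix of Pearson residuals.
#' @return estimated exchangeable correlation `alpha`.
#' @export
estimate_alpha_exchangeable <- function(residuals) {
  r <- as.matrix(residuals)
  m <- ncol(r)
  stopifnot(m >= 2)
  s <- rowSums(r)
  cross <- (s^2 - rowSums(r^2)) / 2
  phi <- mean(r^2)
  mean(cross) / (choose(m, 2) * phi)
}
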