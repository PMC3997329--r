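test_that("partial-likelihood records enumerate recaptures after first capture", {
  cs <- list(T = c(1L, 3L), t_first = c(6L, 2L), m = 6L, n = 2L)
  class(cs) <- "capture_summary"
  pl <- build_pl_data(cs, matrix(1, 2, 1))
  expect_equal(pl$successes, c(0L, 2L))
  expect_equal(pl$trials, c(0L, 4L))

  fx <- sim_fixture("high", N = 150, seed = 13)
  pl2 <- build_pl_data(fx$cs, fx$X)
  expect_equal(sum(pl2$successes), sum(fx$cs$T - 1L))
  expect_true(all(pl2$successes >= 0 & pl2$successes <= pl2$trials))
})

test_that("PL-GLM equals a grid-search likelihood oracle on 1-parameter fits", {
  for (seed in c(2, 14, 27)) {
    fx <- sim_fixture("medium", N = 120, seed = seed)
    pl <- build_pl_data(fx$cs, fx$X[, 1, drop = FALSE])
    fit <- fit_pl_glm(pl)
    act <- pl$trials > 0
    oracle <- pl_grid_oracle(pl$successes[act], pl$trials[act])
    expect_equal(unname(fit$beta), oracle, tolerance = 1e-6)
  }
})

test_that("PL-GLM flags degenerate and symmetric inputs correctly", {
  # all successes equal trials: p_hat at the boundary
  cs <- list(T = rep(4L, 10), t_first = rep(3L, 10), m = 6L, n = 10L)
  class(cs) <- "capture_summary"
  fit <- fit_pl_glm(build_pl_data(cs, matrix(1, 10, 1)))
  expect_true(fit$boundary)

  # all first caught on the final occasion: nothing to fit
  cs2 <- list(T = rep(1L, 5), t_first = rep(6L, 5), m = 6L, n = 5L)
  class(cs2) <- "capture_summary"
  expect_error(fit_pl_glm(build_pl_data(cs2, matrix(1, 5, 1))),
               "no recapture")

  # two groups with identical recapture rates: slope ~ 0
  cs3 <- list(T = rep(c(3L, 3L), each = 8), t_first = rep(2L, 16),
              m = 6L, n = 16L)
  class(cs3) <- "capture_summary"
  X <- cbind(1, rep(c(0, 1), each = 8))
  fit3 <- fit_pl_glm(build_pl_data(cs3, X))
  expect_equal(unname(fit3$beta[2]), 0, tolerance = 1e-8)
})

test_that("GLMM with sigma_b = 0 reproduces the GLM fit", {
  sc <- scenario("high", N = 400, m = 6)
  sc$sigma_b <- 0
  sim <- simulate_capture(sc, seed = 5)
  cs <- summary(sim$observed)
  X <- cbind(1, cs$covariates$sex, cs$covariates$weight)
  pl <- build_pl_data(cs, X)
  glm_fit <- fit_pl_glm(pl)
  glmm_fix <- fit_pl_glmm(pl, sigma_b = 0)
  expect_equal(glmm_fix$deviance, glm_fit$deviance, tolerance = 1e-6)
  expect_equal(unname(glmm_fix$beta), unname(glm_fit$beta), tolerance = 1e-6)
  # and the estimated variance collapses to zero on homogeneous data
  glmm_est <- fit_pl_glmm(pl)
  expect_lt(glmm_est$sigma_b, 0.1)
  expect_equal(unname(glmm_est$beta), unname(glm_fit$beta), tolerance = 0.05)
})

test_that("PQL detects heterogeneity but attenuates the variance component", {
  # strong unexplained heterogeneity: sigma_b estimated well above zero,
  # below the generating value (the documented PQL attenuation for
  # few-trial binomial data under capture-conditioned sampling)
  sc <- scenario(NULL, N = 1000, m = 6, beta0 = -3.5, beta1 = 0.1,
                 beta2 = 0.2, sigma_b = 1)
  sig <- vapply(1:5, function(r) {
    sim <- simulate_capture(sc, seed = 100 + r)
    cs <- summary(sim$observed)
    X <- cbind(1, cs$covariates$sex, cs$covariates$weight)
    fit_pl_glmm(build_pl_data(cs, X))$sigma_b
  }, numeric(1))
  expect_true(all(sig > 0.4))
  expect_true(all(sig < 1))
})

test_that("eta variance weights match their closed form and are nonnegative", {
  # pi^-2 * m * p * (1 - pi) recomputed directly for random (p, m)
  set.seed(8)
  p <- runif(50, 0.01, 0.99)
  m <- sample(2:12, 50, replace = TRUE)
  pi_ <- 1 - (1 - p)^m
  expect_equal(eta_weight(p, m), pi_^(-2) * m * p * (1 - pi_),
               tolerance = 1e-12)
  expect_true(all(eta_weight(p, m) >= 0))
  expect_equal(eta_weight(0.5, 1), 1)  # 0.5^-2 * 1 * 0.5 * (1 - 0.5)
})

test_that("penalized-information variance shrinks penalized directions", {
  fx <- sim_fixture("medium", N = 150, seed = 19)
  pl <- build_pl_data(fx$cs, fx$X)
  fit <- fit_pl_glmm(pl)
  lams <- c(1, 100, 1e8)
  vb <- sapply(lams, function(l) {
    V <- glmm_variance(fit, pl, lambda = l)
    zidx <- grep("^z_", rownames(V))
    mean(diag(V)[zidx])
  })
  expect_true(all(diff(vb) < 0))
  expect_lt(vb[3], 1e-6)
})

test_that("GCV selects a finite positive penalty and breaks ties downward", {
  fx <- sim_fixture("medium", N = 200, seed = 29)
  pl <- build_pl_data(fx$cs, fx$X)
  lam <- select_lambda_gcv(pl)
  expect_true(is.finite(lam) && lam > 0)
  path <- attr(lam, "path")
  expect_equal(nrow(path), 25L)
  # ties (or a flat score) resolve to the smallest candidate
  expect_equal(as.numeric(select_lambda_gcv(pl, grid = c(5, 5, 5))), 5)
})
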