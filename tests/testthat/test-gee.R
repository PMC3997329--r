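test_that("closed-form equal-catchability solutions are exact", {
  expect_equal(as.numeric(solve_m0_marginal(45, 6, 88)), 88 / 270)
  expect_equal(round(qlogis(as.numeric(solve_m0_marginal(45, 6, 88))), 2),
               -0.73)
  expect_equal(as.numeric(solve_m0_marginal(10, 5, 10)), 0.2)
  expect_true(attr(solve_m0_marginal(10, 5, 50), "boundary"))

  # conditional group equations solved by bracketed root-finding
  p_m <- as.numeric(solve_conditional_group(22, 6, 41))
  p_f <- as.numeric(solve_conditional_group(23, 6, 47))
  expect_equal(p_m, 0.2593, tolerance = 5e-4)
  expect_equal(p_f, 0.3008, tolerance = 5e-4)
  # each root satisfies its defining moment equation
  expect_equal(6 * p_m / prob_ever_captured(p_m, 6), 41 / 22,
               tolerance = 1e-10)
  expect_equal(6 * p_f / prob_ever_captured(p_f, 6), 47 / 23,
               tolerance = 1e-10)
  expect_equal(round(qlogis(p_f), 2), -0.84)

  # boundary cases: all caught every time; every individual caught once
  expect_true(attr(solve_conditional_group(10, 6, 60), "boundary"))
  expect_true(attr(solve_conditional_group(10, 6, 10), "boundary"))
})

test_that("gee_solve reproduces the closed-form group solutions", {
  ch <- synthetic_chipmunk_history()
  cs <- summary(ch)
  X <- cbind("(Intercept)" = 1, sex = ch$covariates$sex)
  sol <- gee_solve(cs$T, X, 6, mean_form = "conditional")
  p_f <- as.numeric(solve_conditional_group(23, 6, 47))
  p_m <- as.numeric(solve_conditional_group(22, 6, 41))
  expect_equal(unname(sol$beta),
               c(qlogis(p_f), qlogis(p_m) - qlogis(p_f)), tolerance = 1e-8)
  expect_true(sol$converged)
  expect_lte(sqrt(sum(sol$score^2)), 1e-6)

  sol0 <- gee_solve(cs$T, X[, 1, drop = FALSE], 6, mean_form = "marginal")
  expect_equal(unname(sol0$beta), qlogis(88 / 270), tolerance = 1e-8)
})

test_that("marginal-form GEE with independence equals the Bernoulli GLM root", {
  fx <- sim_fixture("high", N = 150, seed = 17)
  sol <- gee_solve(fx$cs$T, fx$X, fx$cs$m, mean_form = "marginal")
  glm_fit <- glm.fit(fx$X[rep(seq_len(fx$cs$n), fx$cs$m), ],
                     as.vector(fx$sim$observed$y),
                     family = binomial())
  expect_equal(unname(sol$beta), unname(glm_fit$coefficients),
               tolerance = 1e-8)
})

test_that("exchangeable working correlation leaves the root unchanged and
           inflates the model-based variance when alpha > 0", {
  fx <- sim_fixture("medium", N = 200, seed = 23)
  ind <- gee_solve(fx$cs$T, fx$X, fx$cs$m)
  exch <- gee_solve(fx$cs$T, fx$X, fx$cs$m, corr = "exchangeable")
  expect_equal(unname(ind$beta), unname(exch$beta), tolerance = 1e-10)
  if (exch$alpha > 0) {
    expect_true(all(diag(exch$vcov) >= diag(ind$vcov)))
  }
})

test_that("exchangeable alpha moment estimator behaves at its anchors", {
  set.seed(101)
  # occasion-independent residuals: alpha near 0
  r <- matrix(rnorm(800 * 6), 800, 6)
  expect_lt(abs(estimate_alpha_exchangeable(r)), 0.05)
  # duplicated occasion columns: alpha = 1
  rd <- matrix(rnorm(400), 400, 6)[, rep(1, 6)]
  expect_equal(estimate_alpha_exchangeable(rd), 1, tolerance = 1e-10)
  # a shared random effect induces positive alpha in binary residuals
  sim <- simulate_capture(scenario(NULL, N = 2000, m = 6, beta0 = -1,
                                   beta1 = 0, beta2 = 0, sigma_b = 1.5),
                          seed = 7)
  p0 <- mean(sim$full_y)
  rb <- (sim$full_y - p0) / sqrt(p0 * (1 - p0))
  expect_gt(estimate_alpha_exchangeable(rb), 0.1)
})

test_that("degenerate and pathological inputs are flagged, not returned silently", {
  # every individual caught on every occasion: boundary fit
  Tall <- rep(6L, 20)
  X <- matrix(1, 20, 1, dimnames = list(NULL, "(Intercept)"))
  sol <- gee_solve(Tall, X, 6, mean_form = "marginal", maxit = 50)
  expect_true(sol$boundary)
  # collinear design columns are reported by name
  Xc <- cbind("(Intercept)" = 1, a = rep(1, 20), b = rep(2, 20))
  expect_error(gee_solve(rep(2L, 20), Xc, 6), "collinear")
})

test_that("the estimating-function norm at the solution is below tolerance", {
  for (seed in 1:5) {
    fx <- sim_fixture(c("high", "medium", "low")[1 + seed %% 3],
                      N = 120, seed = seed)
    sol <- gee_solve(fx$cs$T, fx$X, fx$cs$m, tol = 1e-8)
    expect_true(sol$converged)
    expect_lte(sqrt(sum(sol$score^2)), 1e-6)
  }
})
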