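# Small deterministic fixtures used across test files.

# capture history with known summaries: T = (1, 2), t_first = (1, 1)
tiny_history <- function() {
  capture_history(rbind(c(1, 0, 0), c(1, 1, 0)), data.frame(sex = c(1, 0)))
}

# simulated dataset under a scenario, returned with its summary and design
sim_fixture <- function(preset = "high", N = 300, m = 6, seed = 42) {
  sim <- simulate_capture(scenario(preset, N = N, m = m), seed = seed)
  cs <- summary(sim$observed)
  X <- cbind("(Intercept)" = 1, sex = cs$covariates$sex,
             weight = cs$covariates$weight)
  list(sim = sim, cs = cs, X = X)
}

# independent grid-search maximizer of the 1-parameter partial likelihood
# (intercept-only binomial logit), used as an oracle for fit_pl_glm
pl_grid_oracle <- function(successes, trials, lo = -6, hi = 4) {
  loglik <- function(b) {
    p <- plogis(b)
    sum(successes * log(p) + (trials - successes) * log1p(-p))
  }
  grid <- seq(lo, hi, by = 1e-4)
  b <- grid[which.max(vapply(grid, loglik, numeric(1)))]
  # one refinement pass around the coarse optimum
  grid2 <- seq(b - 2e-4, b + 2e-4, by = 1e-7)
  grid2[which.max(vapply(grid2, loglik, numeric(1)))]
}
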