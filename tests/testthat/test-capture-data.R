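test_that("constructor enforces the capture-history invariants", {
  expect_error(capture_history(rbind(c(1, 2, 0), c(1, 0, 0))), "non-binary")
  expect_error(capture_history(rbind(c(1, 0, 0), c(0, 0, 0))), "all-zero")
  expect_error(capture_history(rbind(c(1, 0), c(0, 1)),
                               data.frame(sex = 1)), "one row per individual")
  ch <- tiny_history()
  expect_s3_class(ch, "capture_history")
  expect_equal(ch$n, 2L)
  expect_equal(ch$m, 3L)
})

test_that("summarize produces consistent sufficient statistics", {
  cs <- summary(tiny_history())
  expect_equal(cs$T, c(1L, 2L))
  expect_equal(cs$t_first, c(1L, 1L))
  expect_equal(cs$f, c(1L, 1L, 0L))

  # conservation identity on simulated data, and permutation equivariance
  fx <- sim_fixture("high", N = 200, seed = 11)
  cs <- fx$cs
  expect_equal(sum(seq_len(cs$m) * cs$f), cs$total_captures)
  expect_equal(sum(cs$f), cs$n)
  expect_equal(sum(cs$n_per_occasion), cs$total_captures)
  expect_true(all(cs$t_first >= 1 & cs$t_first <= cs$m))

  perm <- sample(fx$sim$observed$n)
  cs_p <- summary(capture_history(fx$sim$observed$y[perm, ],
                                  fx$sim$observed$covariates[perm, ,
                                                             drop = FALSE]))
  expect_equal(sort(cs_p$T), sort(cs$T))
  expect_equal(cs_p$f, cs$f)
  expect_equal(cs_p$n_per_occasion, cs$n_per_occasion)
})

test_that("CSV round-trip is the identity and malformed files are rejected", {
  fx <- sim_fixture("medium", N = 80, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_capture_csv(fx$sim$observed, path)
  back <- read_capture_csv(path)
  expect_equal(back$y, fx$sim$observed$y)
  expect_equal(back$covariates$sex, fx$sim$observed$covariates$sex)
  expect_equal(back$covariates$weight, fx$sim$observed$covariates$weight,
               tolerance = 1e-12)

  # 45 x 6 chipmunk-like file round-trips with its sex covariate
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_capture_csv(synthetic_chipmunk_history(), path2)
  ch2 <- read_capture_csv(path2, covariate_names = "sex")
  expect_equal(ch2$n, 45L)
  expect_equal(ch2$m, 6L)

  bad <- data.frame(occ_1 = c(1, 2), occ_2 = c(0, 1))
  path3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad, path3, row.names = FALSE)
  expect_error(read_capture_csv(path3), "non-binary")

  zero <- data.frame(occ_1 = c(1, 0), occ_2 = c(0, 0))
  path4 <- withr::local_tempfile(fileext = ".csv")
  write.csv(zero, path4, row.names = FALSE)
  expect_error(read_capture_csv(path4), "all-zero")
  expect_error(read_capture_csv(path, covariate_names = "age"),
               "missing covariate")
})

test_that("MARK INP round-trip is the identity and parse errors are caught", {
  txt <- write_mark_inp(tiny_history())
  expect_length(txt, 2L)
  expect_match(txt[1], "^100 1;$")
  back <- read_mark_inp(txt, covariate_names = "sex")
  expect_equal(back$y, tiny_history()$y)
  expect_equal(back$covariates$sex, c(1, 0))

  fx <- sim_fixture("low", N = 60, seed = 9)
  back2 <- read_mark_inp(write_mark_inp(fx$sim$observed),
                         covariate_names = c("sex", "weight"))
  expect_equal(back2$y, fx$sim$observed$y)

  expect_error(read_mark_inp(c("101 1;", "10 1;")), "differ in length")
  expect_error(read_mark_inp(c("1x1 1;")), "malformed")
})

test_that("chipmunk grouped summary matches the published totals", {
  gs <- chipmunk_summary()
  expect_equal(gs$count, c(23L, 22L))
  expect_equal(gs$captures, c(47L, 41L))
  expect_equal(gs$total_captures, 88L)
  expect_equal(round(41 / 22, 2), 1.86)
  expect_equal(round(47 / 23, 2), 2.04)
  # group totals sum to the overall totals
  expect_equal(sum(gs$count), gs$n)
  expect_equal(sum(gs$captures), gs$total_captures)
  expect_equal(sum(attr(gs, "n_per_occasion")), 88L)
  expect_equal(sum(seq_len(6) * attr(gs, "f")), 88L)

  # the synthetic individual-level reconstruction reproduces every margin
  cs <- summary(synthetic_chipmunk_history())
  expect_equal(cs$total_captures, 88L)
  expect_equal(cs$f, attr(gs, "f"))
  expect_equal(cs$n_per_occasion, attr(gs, "n_per_occasion"))
  sex <- synthetic_chipmunk_history()$covariates$sex
  expect_equal(sum(sex), 22L)
  expect_equal(sum(cs$T[sex == 1]), 41L)
})
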