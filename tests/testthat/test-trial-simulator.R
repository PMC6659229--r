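test_that("simulate_trial reproduces the profile means and rejects bad input", {
  d <- simulate_trial(linear_profile, n = 200, seed = 1)
  expect_s3_class(d, "trial_data")
  expect_equal(sum(d$arm == 1), 100)

  # per-(arm, timepoint) sample means within 3 SE of the profile means
  se <- sqrt(12^2 + 7^2) / sqrt(100)
  for (j in 1:4) {
    expect_lt(abs(mean(d[d$arm == 1, paste0("Y", j)]) -
                    linear_profile$mu_A[j]), 3 * se)
    expect_lt(abs(mean(d[d$arm == 0, paste0("Y", j)]) -
                    linear_profile$mu_B[j]), 3 * se)
  }

  expect_error(simulate_trial(linear_profile, n = 201), "even")
  expect_error(simulate_trial(linear_profile, n = 2), "even|>= 4")
  expect_error(variance_components(sigma_eps = 0), "positive")
})

test_that("noise-free limit returns the profile means exactly", {
  v <- variance_components(sigma_b = 0, sigma_eps = 1e-9)
  d <- simulate_trial(response_profile("nonlinear"), n = 10, var = v,
                      seed = 2)
  mu <- response_profile("nonlinear")
  for (j in 1:4) {
    expect_equal(d[d$arm == 1, paste0("Y", j)], rep(mu$mu_A[j], 5),
                 tolerance = 1e-6)
    expect_equal(d[d$arm == 0, paste0("Y", j)], rep(mu$mu_B[j], 5),
                 tolerance = 1e-6)
  }
})

test_that("change scores have variance 2*sigma_eps^2, free of sigma_b", {
  # within arm (pooling arms would add the between-arm mean-change
  # spread); 10^4 change scores per arm
  d <- simulate_trial(linear_profile, n = 20000, seed = 3)
  for (a in 0:1) {
    v <- var((d$Y4 - d$Y1)[d$arm == a])
    expect_lt(abs(v - 98) / 98, 0.05)
  }
  # same with a much larger random intercept: b_i cancels
  d2 <- simulate_trial(linear_profile, n = 20000,
                       var = variance_components(sigma_b = 40), seed = 4)
  expect_lt(abs(var((d2$Y4 - d2$Y1)[d2$arm == 1]) - 98) / 98, 0.05)
})

test_that("simulation is bitwise reproducible for a fixed seed", {
  d1 <- simulate_trial(linear_profile, n = 50, seed = 42)
  d2 <- simulate_trial(linear_profile, n = 50, seed = 42)
  expect_identical(d1, d2)
  expect_identical(generate_cv(d1, seed = 9), generate_cv(d2, seed = 9))
  expect_identical(generate_ae(d1, seed = 9), generate_ae(d2, seed = 9))
})

test_that("generate_cv hits the target correlation, mean and SD", {
  d <- simulate_trial(linear_profile, n = 10000, seed = 5)
  d <- generate_cv(d, rho = 0.3, mean = 38.0, sd = 62.7, seed = 6)
  expect_lt(abs(cor(d$CV, d$Y4) - 0.3), 0.03)
  expect_lt(abs(mean(d$CV) - 38.0), 3 * 62.7 / sqrt(10000))
  expect_lt(abs(sd(d$CV) - 62.7) / 62.7, 0.05)

  # independence case
  d0 <- generate_cv(simulate_trial(linear_profile, 10000, seed = 7),
                    rho = 0, seed = 8)
  expect_lt(abs(cor(d0$CV, d0$Y4)), 3 / sqrt(10000))

  # near-degenerate case: CV is almost an affine transform of Y4. A null
  # profile keeps the arm means equal, so the marginal and within-arm
  # correlations coincide (the construction standardizes Y4 per arm).
  d9 <- generate_cv(simulate_trial(response_profile("null1"), 2000,
                                   seed = 9),
                    rho = 0.999, seed = 10)
  expect_gt(cor(d9$CV, d9$Y4), 0.99)

  expect_error(generate_cv(d, rho = 1), "rho")
})

test_that("adverse-event process matches its conditional table", {
  d <- simulate_trial(linear_profile, n = 20000, seed = 11)
  d <- generate_ae(d, seed = 12)
  expect_true(all(d$AE1 == 0))

  emp <- function(sel_num, sel_den) mean(sel_num) / mean(sel_den)
  # P(AE3 = 1 | AE2 = 1, arm A) = 0.8
  selA2 <- d$arm == 1 & d$AE2 == 1
  p <- mean(d$AE3[selA2])
  expect_lt(abs(p - 0.8), 3 * sqrt(0.8 * 0.2 / sum(selA2)))
  # P(AE4 = 1 | AE3 = 0, arm B) = 0.2
  selB3 <- d$arm == 0 & d$AE3 == 0
  p <- mean(d$AE4[selB3])
  expect_lt(abs(p - 0.2), 3 * sqrt(0.2 * 0.8 / sum(selB3)))
  # initial rates
  expect_lt(abs(mean(d$AE2[d$arm == 1]) - 0.3), 0.02)
  expect_lt(abs(mean(d$AE2[d$arm == 0]) - 0.5), 0.02)

  # all-zero table gives no AEs anywhere
  tab0 <- default_ae_table(); tab0$prob <- 0
  d0 <- generate_ae(simulate_trial(linear_profile, 100, seed = 13),
                    ae_model(0, 0, tab0), seed = 14)
  expect_true(all(d0$AE2 == 0 & d0$AE3 == 0 & d0$AE4 == 0))

  # incomplete table rejected
  expect_error(ae_model(conditional_table = default_ae_table()[-1, ]),
               "cells")
})

test_that("responder classification is inclusive at the boundary and
           explicit about undetermined subjects", {
  d <- manual_trial(data.frame(
    arm = c(1, 1, 0, 0),
    Y1 = c(65, 65, 65, 65), Y2 = 65, Y3 = 65,
    Y4 = c(77.4, 65, NA, 90)))
  r <- classify_responders(d, responder_rule(12.4))
  expect_identical(r, c(1L, 0L, NA_integer_, 1L))
})

test_that("analytic true response rate matches a Monte Carlo oracle", {
  rule <- responder_rule(12.4)
  for (name in c("linear", "nonlinear", "null1", "null2")) {
    prof <- response_profile(name)
    for (arm in c(0L, 1L)) {
      mu <- if (arm == 1L) prof$mu_A else prof$mu_B
      delta <- mu[4] - mu[1]
      set.seed(1000 + arm)
      mc <- mean(rnorm(1e6, delta, sqrt(2 * 7^2)) >= 12.4)
      expect_lt(abs(true_response_rate(prof, rule, default_var, arm) - mc),
                0.002)
    }
  }
  # frozen closed-form values for the linear profile
  expect_equal(true_response_rate(linear_profile, rule, default_var, 1L),
               0.2589786, tolerance = 1e-6)
  expect_equal(true_response_rate(linear_profile, rule, default_var, 0L),
               0.1051776, tolerance = 1e-6)
  # threshold -> -Inf classifies everyone as responder
  expect_equal(true_response_rate(linear_profile, responder_rule(-1e9),
                                  default_var, 1L), 1.0)
})

test_that("null profiles give equal true rates in both arms", {
  for (name in c("null1", "null2")) {
    prof <- response_profile(name)
    expect_equal(true_response_rate(prof, arm = 1L),
                 true_response_rate(prof, arm = 0L))
  }
})

test_that("wide CSV round-trips with empty cells for missing values", {
  tr <- make_masked_trial(n = 40, seed = 21, pilot = 20)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_trial_csv(tr$masked, path)
  back <- read_trial_csv(path)
  expect_equal(back$Y4, tr$masked$Y4)
  expect_equal(back$arm, tr$masked$arm)
  expect_true(anyNA(back$Y4))
})
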