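test_that("NRI equals the observed classification when nothing is missing,
           and zeroes out fully missing endpoints", {
  d <- make_complete_trial(n = 100, seed = 51)
  expect_identical(nri_impute(d), classify_responders(d))

  d2 <- d
  d2$Y4 <- NA_real_
  r <- nri_impute(d2)
  expect_true(all(r == 0L))
  expect_equal(diff_proportions(r, d2$arm)$p_A, 0)
})

test_that("NRI arm proportions never exceed the full-data proportions", {
  for (s in 1:20) {
    tr <- make_masked_trial(n = 100, seed = 60 + s, pilot = 20)
    full <- classify_responders(tr$complete)
    nri <- nri_impute(tr$masked)
    for (a in 0:1) {
      expect_lte(mean(nri[tr$complete$arm == a]),
                 mean(full[tr$complete$arm == a]))
    }
  }
})

test_that("the starting fill is the identity on complete data and exact on
           noise-free relations", {
  d <- make_complete_trial(n = 50, seed = 71)
  spec <- imputation_spec("IBD", M = 2)
  D <- fill_in_start(d, spec)
  expect_equal(D[, "Y4"], d$Y4)
  expect_equal(D[, "Y2"], d$Y2)

  # exact linear relation: missing Y4 filled by the fitted regression
  # (complete predictors vary, so the design is full rank and the fitted
  # prediction is exact)
  d2 <- manual_trial(data.frame(
    arm = rep(c(1, 0), 10),
    Y1 = (1:20)^2 / 10, Y2 = sqrt(1:20), Y3 = seq(1, 20),
    Y4 = 2 * seq(1, 20) + 5 * rep(c(1, 0), 10)))
  d2$Y4[c(3, 8)] <- NA
  D2 <- fill_in_start(d2, spec)
  expect_equal(unname(D2[3, "Y4"]), 2 * 3 + 5 * 1, tolerance = 1e-8)
  expect_equal(unname(D2[8, "Y4"]), 2 * 8 + 5 * 0, tolerance = 1e-8)
})

test_that("continuous posterior draws concentrate on a noise-free relation
           and match the closed-form intercept-only posterior", {
  set.seed(81)
  x <- matrix(rnorm(2000), ncol = 1)
  y <- 2 * x[, 1]
  y[1:50] <- NA
  dr <- impute_continuous_draw(y, x, seed = 82)
  expect_lt(max(abs(dr$values - 2 * x[1:50, 1])), 0.01)

  # intercept-only: draws ~ N(ybar, s^2) for large n
  y2 <- c(rep(NA, 500), rnorm(5000, mean = 10, sd = 3))
  dr2 <- impute_continuous_draw(y2, matrix(numeric(0), 5500, 0), seed = 83)
  expect_lt(abs(mean(dr2$values) - 10), 0.5)
  expect_lt(abs(sd(dr2$values) - 3) / 3, 0.1)

  # reproducibility
  dr3 <- impute_continuous_draw(y2, matrix(numeric(0), 5500, 0), seed = 83)
  expect_identical(dr2$values, dr3$values)
})

test_that("binary posterior draws follow a separating rule, recover the
           prevalence with no predictors, and are reproducible", {
  set.seed(91)
  x <- matrix(c(rnorm(1000, -3), rnorm(1000, 3)), ncol = 1)
  y <- as.numeric(x[, 1] > 0)
  miss <- sort(sample(2000, 200))
  y[miss] <- NA
  dr <- impute_binary_draw(y, x, seed = 92)
  truth <- as.numeric(x[miss, 1] > 0)
  expect_gt(mean(dr$values == truth), 0.97)

  # intercept-only: imputations near the observed prevalence
  y2 <- c(rep(NA, 300), rbinom(3000, 1, 0.25))
  dr2 <- impute_binary_draw(y2, matrix(numeric(0), 3300, 0), seed = 93)
  expect_lt(abs(mean(dr2$values) - 0.25), 0.08)

  dr3 <- impute_binary_draw(y2, matrix(numeric(0), 3300, 0), seed = 93)
  expect_identical(dr2$values, dr3$values)

  # degenerate single-class data: fills are that class
  y4 <- c(NA, NA, rep(1, 30))
  dr4 <- impute_binary_draw(y4, matrix(rnorm(32), ncol = 1), seed = 94)
  expect_identical(dr4$values, c(1L, 1L))
  expect_true(dr4$fallback)
})

test_that("FCS with nothing missing is the identity for any M", {
  d <- make_complete_trial(n = 60, seed = 95)
  for (strat in c("IBD", "DTI")) {
    spec <- imputation_spec(strat, M = 3, include_cv = TRUE)
    completed <- fcs_impute(d, spec, seed = 96)
    expect_length(completed, 3)
    for (m in 1:3) {
      expect_equal(completed[[m]][, "Y4"], d$Y4)
      expect_equal(completed[[m]][, "Y2"], d$Y2)
    }
    # and run_strategy gives identical estimates across strategies
  }
  rI <- run_strategy(d, imputation_spec("IBD", M = 3), seed = 97)
  rD <- run_strategy(d, imputation_spec("DTI", M = 3), seed = 97)
  expect_equal(rI$estimates$estimate, rD$estimates$estimate)
  expect_equal(rI$estimates$estimate,
               rep(diff_proportions(classify_responders(d), d$arm)$diff, 3))
})

test_that("observed values are never altered by any strategy", {
  tr <- make_masked_trial(n = 100, seed = 101, model_id = 6, pilot = 20)
  md <- tr$masked
  obsY <- !is.na(md$Y4)
  for (strat in c("IBD", "DTI")) {
    spec <- imputation_spec(strat, M = 3, include_ae = TRUE)
    completed <- fcs_impute(md, spec, seed = 102)
    for (m in seq_along(completed)) {
      D <- completed[[m]]
      for (v in c("Y2", "Y3", "Y4", "AE2", "AE3", "AE4")) {
        obs <- !is.na(md[[v]])
        expect_equal(D[obs, v], as.numeric(md[[v]][obs]))
      }
      expect_false(anyNA(D))
    }
  }
  # NRI leaves determined statuses untouched
  r <- nri_impute(md)
  det <- !is.na(classify_responders(md))
  expect_identical(r[det], classify_responders(md)[det])
})

test_that("fcs_impute is bitwise reproducible and seed-sensitive", {
  tr <- make_masked_trial(n = 100, seed = 103, pilot = 20)
  spec <- imputation_spec("DTI", M = 2)
  c1 <- fcs_impute(tr$masked, spec, seed = 104)
  c2 <- fcs_impute(tr$masked, spec, seed = 104)
  expect_identical(c1, c2)
  c3 <- fcs_impute(tr$masked, spec, seed = 105)
  expect_false(identical(c1, c3))
})

test_that("run_strategy validates inputs and labels NRI results", {
  tr <- make_masked_trial(n = 60, seed = 106, pilot = 20)
  res <- run_strategy(tr$masked, imputation_spec("NRI"))
  expect_equal(nrow(res$estimates), 1)
  expect_equal(res$M, 1L)
  expect_error(imputation_spec("IBD", M = 1), "M >= 2")
  # a dataset without CV rejects include_cv
  d_nocv <- simulate_trial(linear_profile, 40, seed = 109)
  d_nocv$Y4[1:10] <- NA
  expect_error(run_strategy(d_nocv,
                            imputation_spec("IBD", include_cv = TRUE,
                                            M = 2)),
               "CV")
})

test_that("both MI strategies recover the truth under MCAR", {
  # MCAR on the endpoint only: consistency of MI (pooled proportion close
  # to the full-data proportion on average)
  n_rep <- 100
  gapI <- numeric(n_rep); gapD <- numeric(n_rep)
  for (s in seq_len(n_rep)) {
    d <- simulate_trial(linear_profile, n = 200, seed = 2000 + s)
    set.seed(3000 + s)
    miss <- sample(200, 60)  # 30% MCAR at the endpoint
    Z <- matrix(1L, 200, 4); Z[miss, 4] <- 0L
    mask <- structure(list(Z = Z,
                           dropout_time = replace(rep(NA_integer_, 200),
                                                  miss, 4L),
                           achieved_rate = 0.3, cutoff = NA_real_,
                           model_id = NA_integer_),
                      class = "dropout_mask")
    md <- apply_mask(d, mask)
    full_pA <- diff_proportions(classify_responders(d), d$arm)$p_A
    rI <- run_strategy(md, imputation_spec("IBD", M = 10), seed = 4000 + s)
    rD <- run_strategy(md, imputation_spec("DTI", M = 10), seed = 5000 + s)
    gapI[s] <- mean(rI$estimates$p_A) - full_pA
    gapD[s] <- mean(rD$estimates$p_A) - full_pA
  }
  expect_lt(abs(mean(gapI)), 0.02)
  expect_lt(abs(mean(gapD)), 0.02)
})

test_that("stacked export has one block per imputation", {
  tr <- make_masked_trial(n = 40, seed = 107, pilot = 20)
  completed <- fcs_impute(tr$masked, imputation_spec("IBD", M = 3),
                          seed = 108)
  st <- stack_imputations(completed)
  expect_equal(nrow(st), 3 * 40)
  expect_equal(unique(st$.imp), 1:3)
})
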