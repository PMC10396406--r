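test_that("Wald ratio follows the first-order delta rule", {
  h <- h_table(bx = 0.1, by = 0.05, se_y = 0.01)
  f <- wald_ratio(h)
  expect_equal(f$estimate, 0.5)
  expect_equal(f$se, 0.1)

  # zero outcome beta: estimate 0, two-sided p of z = 0 is 1
  fit0 <- mr_fit(h_table(0.1, 0, 0.01), method = "wald")
  expect_equal(fit0$estimate, 0)
  expect_equal(fit0$pvalue, 1)

  expect_error(wald_ratio(h_table(0, 0.05, 0.01)), "zero")
  expect_error(wald_ratio(h_table(-0.1, 0.05, 0.01)),
               "orient_to_trait_increasing")
  expect_error(mr_fit(h_table(c(0.1, 0.2), c(0.01, 0.02), 0.01),
                      method = "wald"), "exactly one")
})

test_that("IVW reproduces the hand-computed weighted regression through the origin", {
  h <- h_table(bx = c(0.1, 0.2, 0.1), by = c(0.02, 0.03, 0.01),
               se_y = c(0.01, 0.01, 0.01))
  f <- mr_fit(h, "ivw")
  expect_equal(f$estimate, 0.15, tolerance = 1e-12)
  expect_equal(f$fe_se, sqrt(1 / 600), tolerance = 1e-10)   # 0.040825
  expect_equal(f$Q, 0.5, tolerance = 1e-10)
  expect_equal(f$re_scale_phi, 1)        # sqrt(Q/(J-1)) < 1, truncated
  expect_equal(f$se, f$fe_se)
  expect_equal(f$I2, 0)                  # Q below its degrees of freedom

  het <- heterogeneity(h, f$estimate)
  expect_equal(het$Q, 0.5, tolerance = 1e-10)
  expect_equal(het$I2, 0)

  expect_error(mr_fit(h[1, ], "ivw"), "wald_ratio")
})

test_that("IVW equals the precision-weighted mean of Wald ratios", {
  set.seed(12)
  for (rep in 1:20) {
    J <- sample(3:30, 1)
    h <- h_table(bx = runif(J, 0.02, 0.3), by = rnorm(J, 0.02, 0.05),
                 se_y = runif(J, 0.005, 0.05))
    f <- mr_fit(h, "ivw")
    ratios <- h$beta_outcome / h$beta_exposure
    w <- h$beta_exposure^2 / h$se_outcome^2
    expect_equal(f$estimate, sum(w * ratios) / sum(w), tolerance = 1e-10)
  }
})

test_that("IVW and Egger agree with weighted least squares fitted independently", {
  set.seed(13)
  for (rep in 1:10) {
    J <- sample(5:40, 1)
    bx <- runif(J, 0.02, 0.3)
    # generous pleiotropy so the multiplicative scale exceeds 1 and the
    # lm() residual-variance SEs coincide with the RE-scaled ones
    by <- 0.01 + 0.4 * bx + rnorm(J, 0, 0.05)
    se_y <- runif(J, 0.005, 0.02)
    h <- h_table(bx, by, se_y)
    w <- 1 / se_y^2

    ivw <- mr_fit(h, "ivw")
    ref0 <- oracle_wls_origin(bx, by, w)
    expect_equal(ivw$estimate, ref0$estimate, tolerance = 1e-8)
    if (ivw$re_scale_phi > 1) {
      expect_equal(ivw$se, ref0$se, tolerance = 1e-8)
    }

    egg <- mr_fit(h, "egger")
    ref1 <- oracle_wls_intercept(bx, by, w)
    expect_equal(egg$estimate, ref1$slope, tolerance = 1e-8)
    expect_equal(egg$intercept, ref1$intercept, tolerance = 1e-8)
    if (egg$re_scale_phi > 1) {
      expect_equal(egg$se, ref1$slope_se, tolerance = 1e-8)
      expect_equal(egg$intercept_se, ref1$intercept_se, tolerance = 1e-8)
    }
  }
})

test_that("IVW fixed-effect core matches a standard meta-analysis fit", {
  set.seed(14)
  J <- 25L
  h <- h_table(bx = runif(J, 0.05, 0.3), by = rnorm(J, 0.03, 0.02),
               se_y = runif(J, 0.005, 0.03))
  f <- mr_fit(h, "ivw")
  ref <- metafor::rma(yi = h$beta_outcome / h$beta_exposure,
                      sei = h$se_outcome / abs(h$beta_exposure),
                      method = "FE")
  expect_equal(f$estimate, as.numeric(ref$beta), tolerance = 1e-8)
  expect_equal(f$fe_se, as.numeric(ref$se), tolerance = 1e-8)
})

test_that("zero-heterogeneity identities hold", {
  # all ratios equal c: IVW estimate c with Q = 0
  h <- h_table(bx = c(0.1, 0.2, 0.3), by = 0.3 * c(0.1, 0.2, 0.3),
               se_y = c(0.01, 0.02, 0.015))
  f <- mr_fit(h, "ivw")
  expect_equal(f$estimate, 0.3, tolerance = 1e-12)
  expect_equal(f$Q, 0, tolerance = 1e-20)
  expect_equal(f$I2, 0)

  # exact-fit Egger recovers its generating intercept and slope
  bx <- seq(0.05, 0.3, length.out = 6)
  h2 <- h_table(bx, by = 0.01 + 0.5 * bx, se_y = 0.01)
  e <- mr_fit(h2, "egger")
  expect_equal(e$intercept, 0.01, tolerance = 1e-10)
  expect_equal(e$estimate, 0.5, tolerance = 1e-10)
  expect_equal(e$Q, 0, tolerance = 1e-16)
})

test_that("I2GX matches a direct two-pass weighted-variance computation", {
  set.seed(15)
  J <- 20L
  h <- h_table(bx = runif(J, 0.02, 0.25), by = rnorm(J, 0.02, 0.02),
               se_y = 0.01, se_x = runif(J, 0.002, 0.02))
  v <- 1 / h$se_exposure^2
  mu <- sum(v * h$beta_exposure) / sum(v)
  qgx <- sum(v * (h$beta_exposure - mu)^2)
  expect_equal(igx2(h), max(0, (qgx - (J - 1)) / qgx), tolerance = 1e-12)

  # identical exposure betas: no spread, statistic 0
  same <- h_table(bx = rep(0.1, 5), by = rnorm(5, 0.02, 0.01), se_y = 0.01)
  expect_equal(igx2(same), 0)

  # widely separated betas with tiny SEs: approaches 1
  wide <- h_table(bx = seq(0.1, 1, length.out = 10),
                  by = rnorm(10), se_y = 0.01, se_x = rep(1e-4, 10))
  expect_gt(igx2(wide), 0.999)

  h$se_exposure[1] <- NA
  expect_error(igx2(h), "se_exposure")
})

test_that("weighted median interpolates the ratio at half the weight", {
  # equal weights, ratios {0.1, 0.2, 0.4}: s_2 = 0.5 exactly
  h <- h_table(bx = c(0.1, 0.1, 0.1), by = c(0.01, 0.02, 0.04),
               se_y = c(0.01, 0.01, 0.01))
  f <- mr_fit(h, "wme", seed = 2)
  expect_equal(f$estimate, 0.2, tolerance = 1e-12)

  # all ratios equal: estimate is that constant, bootstrap SE small
  hc <- h_table(bx = c(0.1, 0.2, 0.4), by = 0.25 * c(0.1, 0.2, 0.4),
                se_y = rep(0.001, 3), se_x = rep(1e-4, 3))
  fc <- mr_fit(hc, "wme", seed = 2)
  expect_equal(fc$estimate, 0.25, tolerance = 1e-12)
  expect_lt(fc$se, 0.02)

  # random instances against the hand cumulative-weight oracle
  set.seed(16)
  for (rep in 1:20) {
    J <- sample(3:25, 1)
    hr <- h_table(bx = runif(J, 0.05, 0.3), by = rnorm(J, 0.03, 0.05),
                  se_y = runif(J, 0.005, 0.05))
    f <- mr_fit(hr, "wme", seed = 5)
    want <- oracle_weighted_median(
      hr$beta_outcome / hr$beta_exposure,
      (hr$beta_exposure / hr$se_outcome)^2)
    expect_equal(f$estimate, want, tolerance = 1e-10)
  }

  expect_error(mr_fit(h[1:2, ], "wme"), "at least 3")
})

test_that("estimators are invariant to instrument ordering", {
  set.seed(17)
  J <- 15L
  h <- h_table(bx = runif(J, 0.05, 0.3), by = rnorm(J, 0.03, 0.03),
               se_y = runif(J, 0.005, 0.03))
  perm <- sample(J)
  for (m in c("ivw", "egger", "wme")) {
    a <- mr_fit(h, m, seed = 9)
    b <- mr_fit(h[perm, ], m, seed = 9)
    expect_equal(a$estimate, b$estimate, tolerance = 1e-12)
    expect_equal(a$se, b$se, tolerance = 1e-12)  # bootstrap sorts by id
  }
})

test_that("estimates are scale-equivariant", {
  set.seed(18)
  J <- 12L
  h <- h_table(bx = runif(J, 0.05, 0.3), by = rnorm(J, 0.03, 0.03),
               se_y = runif(J, 0.005, 0.03))
  c_out <- 3.7
  c_exp <- 2.5
  h_out <- h; h_out$beta_outcome <- c_out * h$beta_outcome
  h_out$se_outcome <- c_out * h$se_outcome
  h_exp <- h; h_exp$beta_exposure <- c_exp * h$beta_exposure
  h_exp$se_exposure <- c_exp * h$se_exposure
  for (m in c("ivw", "egger")) {
    f <- mr_fit(h, m)
    fo <- mr_fit(h_out, m)
    fe <- mr_fit(h_exp, m)
    expect_equal(fo$estimate, c_out * f$estimate, tolerance = 1e-10)
    expect_equal(fo$se, c_out * f$se, tolerance = 1e-10)
    expect_equal(fe$estimate, f$estimate / c_exp, tolerance = 1e-10)
    expect_equal(fe$se, f$se / c_exp, tolerance = 1e-10)
  }
})

test_that("fit objects expose the standard modelling methods", {
  h <- h_table(bx = c(0.1, 0.2, 0.1, 0.15), by = c(0.02, 0.05, 0.01, 0.03),
               se_y = 0.01)
  f <- mr_fit(h, "egger")
  expect_named(coef(f), c("causal_effect", "pleiotropy_intercept"))
  ci <- confint(f)
  expect_equal(ci["causal_effect", 1], f$ci_low, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_length(residuals(f), 4L)
  expect_output(print(f), "Egger intercept")
  expect_output(print(summary(f)), "Coefficients")
  expect_s3_class(as.data.frame(f), "data.frame")
  expect_true(f$ci_low <= f$estimate && f$estimate <= f$ci_high)
})
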