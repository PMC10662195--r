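test_that("Wald ratio follows the delta method and respects signs", {
  h <- make_hset(beta_exp = 0.5, se_exp = 0.01, beta_out = 0.05,
                 se_out = 0.01)
  est <- mr_wald_ratio(h[1, ])
  expect_equal(est$b, 0.1)
  expect_equal(est$se, 0.02)

  h0 <- make_hset(beta_exp = 0.5, se_exp = 0.01, beta_out = 0,
                  se_out = 0.01)
  est0 <- mr_wald_ratio(h0[1, ])
  expect_equal(est0$b, 0)
  expect_equal(est0$pval, 1)

  hneg <- make_hset(beta_exp = -0.5, se_exp = 0.01, beta_out = -0.05,
                    se_out = 0.01)
  expect_equal(mr_wald_ratio(hneg[1, ])$b, 0.1)

  hz <- make_hset(beta_exp = 1, se_exp = 0.01, beta_out = 0.1,
                  se_out = 0.01)
  hz$beta_exp <- 0
  expect_error(mr_wald_ratio(hz[1, ]), "degenerate")
})

test_that("IVW reduces to the Wald ratio for one SNP and is exact under homogeneity", {
  h1 <- make_hset(beta_exp = 0.3, se_exp = 0.01, beta_out = 0.045,
                  se_out = 0.006)
  ivw <- mr_ivw(h1)
  wald <- mr_wald_ratio(h1[1, ])
  expect_equal(ivw$b, wald$b)
  expect_equal(ivw$se, wald$se)
  expect_warning(mr_ivw(h1, "random"), "single instrument")

  # three instruments with identical ratios 0.2: estimate 0.2, Q = 0
  bx <- c(0.1, 0.2, 0.3)
  h3 <- make_hset(bx, 0.01, beta_out = 0.2 * bx, se_out = 0.005)
  est <- mr_ivw(h3, "auto")
  expect_equal(est$b, 0.2)
  expect_equal(est$effects_model, "fixed")
  expect_equal(cochran_q(h3, "ivw")$q_stat, 0, tolerance = 1e-20)

  expect_error(mr_ivw(make_hset(numeric(0), numeric(0), numeric(0),
                                numeric(0))),
               "empty")
})

test_that("IVW meta-analytic form equals weighted regression through the origin", {
  set.seed(101)
  for (i in 1:100) {
    h <- random_hset(sample(3:30, 1))
    est <- mr_ivw(h, "fixed")
    fit <- lm(beta_out ~ 0 + beta_exp, data = as.data.frame(h),
              weights = 1 / h$se_out^2)
    expect_equal(est$b, unname(coef(fit)), tolerance = 1e-10)
    # fixed-effect SE is the regression SE with residual scale divided out
    s <- summary(fit)
    expect_equal(est$se, unname(s$coefficients[1, 2] / s$sigma),
                 tolerance = 1e-10)
  }
})

test_that("IVW is invariant to reordering and per-SNP joint sign flips", {
  set.seed(55)
  h <- random_hset(12)
  base <- mr_ivw(h, "auto")
  perm <- mrpipe:::replace_instruments(h, as.data.frame(h)[sample(12), ])
  expect_equal(mr_ivw(perm, "auto")$b, base$b)
  expect_equal(mr_ivw(perm, "auto")$se, base$se)

  flip <- as.data.frame(h)
  idx <- sample(12, 5)
  flip$beta_exp[idx] <- -flip$beta_exp[idx]
  flip$beta_out[idx] <- -flip$beta_out[idx]
  flip$wald_ratio <- flip$beta_out / flip$beta_exp
  flipped <- mrpipe:::replace_instruments(h, flip)
  expect_equal(mr_ivw(flipped, "auto")$b, base$b)
})

test_that("random-effects IVW never undercuts the fixed-effect SE; auto switches on heterogeneity", {
  set.seed(77)
  # heterogeneous ratios: large spread relative to se_out
  bx <- runif(10, 0.1, 0.3)
  h <- make_hset(bx, 0.01, beta_out = bx * runif(10, -0.3, 0.5),
                 se_out = 0.004)
  fixed <- mr_ivw(h, "fixed")
  rand <- mr_ivw(h, "random")
  expect_gte(rand$se, fixed$se)
  q <- cochran_q(h, "ivw")
  auto <- mr_ivw(h, "auto")
  expect_equal(auto$effects_model, if (q$pval < 0.05) "random" else "fixed")
  expect_equal(rand$se, fixed$se * max(1, sqrt(q$q_stat / 9)))
})

test_that("MR-Egger recovers slope and intercept exactly on noiseless data", {
  bx <- seq(0.1, 0.4, length.out = 8)
  h <- make_hset(bx, 0.01, beta_out = 0.03 + 0.1 * bx, se_out = 0.005)
  fit <- mr_egger(h)
  expect_equal(fit$estimate$b, 0.1, tolerance = 1e-6)
  expect_equal(fit$pleiotropy$intercept, 0.03, tolerance = 1e-6)

  expect_error(mr_egger(make_hset(c(0.1, 0.2), 0.01, c(0.01, 0.02),
                                  0.005)),
               "at least 3")
  expect_error(mr_egger(make_hset(rep(0.2, 5), 0.01, rnorm(5, 0, 0.01),
                                  0.005)),
               "collinear")
})

test_that("MR-Egger matches a weighted lm fit with the dispersion floor", {
  set.seed(31)
  for (i in 1:25) {
    h <- random_hset(sample(5:25, 1))
    fit <- mr_egger(h)
    o <- mrpipe:::orient_positive(as.data.frame(h))
    ref <- lm(beta_out ~ beta_exp, data = o, weights = 1 / o$se_out^2)
    s <- summary(ref)
    expect_equal(fit$estimate$b, unname(coef(ref)[2]), tolerance = 1e-10)
    expect_equal(fit$pleiotropy$intercept, unname(coef(ref)[1]),
                 tolerance = 1e-10)
    # lm SEs include the residual scale; the floor divides it out when < 1
    expect_equal(fit$estimate$se,
                 unname(s$coefficients[2, 2]) / min(1, s$sigma),
                 tolerance = 1e-10)
    expect_equal(fit$pleiotropy$se,
                 unname(s$coefficients[1, 2]) / min(1, s$sigma),
                 tolerance = 1e-10)
    df <- nrow(h) - 2
    expect_equal(fit$estimate$pval,
                 2 * pt(-abs(fit$estimate$b / fit$estimate$se), df))
  }
})

test_that("weighted median equals the sample median for equal weights (odd J) and the interpolation oracle on small cases", {
  expect_equal(mrpipe:::weighted_median_estimate(c(0.1, 0.2, 0.9),
                                                 rep(1, 3)), 0.2)
  # frozen hand-worked case: weights (.4,.1,.1,.4), ratios 0..3 -> 1.5
  expect_equal(mrpipe:::weighted_median_estimate(0:3,
                                                 c(0.4, 0.1, 0.1, 0.4)),
               1.5)
  set.seed(13)
  for (J in 3:6) {
    for (rep in 1:25) {
      theta <- sort(rnorm(J))
      w <- runif(J, 0.1, 1)
      expect_equal(mrpipe:::weighted_median_estimate(theta, w),
                   brute_force_weighted_median(theta, w),
                   tolerance = 1e-9)
    }
    # equal weights, odd J: unweighted median
    if (J %% 2 == 1) {
      theta <- rnorm(J)
      expect_equal(mrpipe:::weighted_median_estimate(theta, rep(1, J)),
                   median(theta))
    }
  }
})

test_that("weighted-median bootstrap SE is reproducible bit-for-bit given a seed", {
  set.seed(99)
  h <- random_hset(10)
  a <- mr_weighted_median(h, n_boot = 200, seed = 7)
  b <- mr_weighted_median(h, n_boot = 200, seed = 7)
  expect_identical(a, b)
  c <- mr_weighted_median(h, n_boot = 200, seed = 8)
  expect_false(identical(a$se, c$se))
  expect_equal(a$b, c$b)  # the point estimate does not involve the RNG
  expect_error(mr_weighted_median(h, n_boot = 200), "seed")
  expect_error(mr_weighted_median(random_hset(2), seed = 1), "at least 3")
})

test_that("odds-ratio presentation is the elementwise exponential and monotone", {
  h <- make_hset(c(0.2, 0.25, 0.3), 0.01, beta_out = c(0.02, 0.025, 0.03),
                 se_out = 0.004)
  est <- mr_ivw(h)
  expect_equal(est$or, exp(est$b))
  expect_equal(est$or_lci, exp(est$ci_low))
  expect_equal(est$or_uci, exp(est$ci_high))
  expect_true(est$ci_low < est$b && est$b < est$ci_high)
  expect_equal(est$ci_high - est$b, qnorm(0.975) * est$se)

  zero <- make_hset(0.2, 0.01, 0, 0.004)
  expect_equal(mr_ivw(zero)$or, 1)
})

test_that("IVW recovers the causal effect with nominal coverage under valid instruments", {
  # 1000 simulated studies, J = 50, theta = 0.1, no pleiotropy
  n_rep <- 1000
  est <- numeric(n_rep)
  cover <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    sim <- simulate_two_sample(sim_config(n_snp = 50, theta = 0.1,
                                          frac_flipped = 0, seed = 5000 + r))
    h <- quietly(harmonize(sim$exposure, sim$outcome))
    fit <- mr_ivw(h, "auto")
    est[r] <- fit$b
    cover[r] <- fit$ci_low <= 0.1 && 0.1 <= fit$ci_high
  }
  expect_lt(abs(mean(est) - 0.1), 0.01)
  expect_gte(mean(cover), 0.93)
  expect_lte(mean(cover), 0.97)
})

test_that("under directional pleiotropy with InSIDE, Egger is unbiased where IVW is not", {
  n_rep <- 500
  egger_b <- ivw_b <- intercepts <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    sim <- simulate_two_sample(sim_config(n_snp = 50, theta = 0.1,
                                          pleio_mean = 0.05,
                                          pleio_sd = 0.02,
                                          frac_flipped = 0,
                                          seed = 90000 + r))
    h <- quietly(harmonize(sim$exposure, sim$outcome))
    fit <- mr_egger(h)
    egger_b[r] <- fit$estimate$b
    intercepts[r] <- fit$pleiotropy$intercept
    ivw_b[r] <- mr_ivw(h, "fixed")$b
  }
  expect_lt(abs(mean(intercepts) - 0.05), 0.01)
  expect_lt(abs(mean(egger_b) - 0.1), 0.02)
  expect_gt(abs(mean(ivw_b) - 0.1), abs(mean(egger_b) - 0.1))
})

test_that("the Egger intercept test holds its size under no pleiotropy", {
  n_rep <- 500
  reject <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    sim <- simulate_two_sample(sim_config(n_snp = 50, theta = 0.1,
                                          frac_flipped = 0,
                                          seed = 40000 + r))
    h <- quietly(harmonize(sim$exposure, sim$outcome))
    reject[r] <- mr_egger(h)$pleiotropy$pval < 0.05
  }
  expect_gte(mean(reject), 0.025)
  expect_lte(mean(reject), 0.075)
})
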