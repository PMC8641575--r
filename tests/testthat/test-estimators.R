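test_that("Wald ratio arithmetic and error cases", {
  wr <- wald_ratio(0.1, 0.01, 0.05, 0.02)
  expect_equal(wr$estimate, 0.5)
  expect_equal(wr$se, 0.2)
  expect_equal(wald_ratio(0.1, 0.01, 0, 0.02)$estimate, 0)
  expect_error(wald_ratio(0, 0.01, 0.05, 0.02), "beta_x")
})

test_that("second-order Wald SE matches the Monte-Carlo ratio SD", {
  bx <- 0.1; sx <- 0.01; by <- 0.05; sy <- 0.02
  analytic <- wald_ratio(bx, sx, by, sy, second_order = TRUE)$se
  withr::local_seed(123)
  n <- 1e6
  mc <- sd(rnorm(n, by, sy) / rnorm(n, bx, sx))
  expect_lt(abs(analytic - mc) / mc, 0.02)
  # and the first-order SE understates it
  expect_lt(wald_ratio(bx, sx, by, sy)$se, analytic)
})

test_that("IVW reproduces the hand-computed weighted mean and Q", {
  # ratios 0.5 (se 0.1) and 0.3 (se 0.2): w = {100, 25}
  # theta = (100*0.5 + 25*0.3)/125 = 0.46; se_fixed = 125^-0.5; Q = 0.8
  set <- make_hset(beta_x = c(1, 1), se_x = c(1e-6, 1e-6),
                   beta_y = c(0.5, 0.3), se_y = c(0.1, 0.2))
  res <- mr_ivw(set, effects = "fixed")
  expect_equal(res$estimate, 0.46)
  expect_equal(res$se, 125^-0.5)
  expect_equal(res$q, 0.8)
  # random-effects floor: Q/(J-1) = 0.8 < 1, so se is not deflated
  expect_equal(mr_ivw(set, effects = "random")$se, 125^-0.5)
})

test_that("IVW reduces to the Wald ratio for a single SNP", {
  set <- make_hset(0.1, 0.01, 0.05, 0.02)
  res <- mr_ivw(set)
  expect_equal(res$estimate, 0.5)
  expect_equal(res$se, 0.2)
  expect_equal(res$n_snp, 1L)
})

test_that("identical ratios give Q = 0 and random se = fixed se", {
  set <- make_hset(beta_x = c(0.1, 0.2, 0.4), se_x = rep(1e-6, 3),
                   beta_y = c(0.05, 0.10, 0.20), se_y = c(0.02, 0.03, 0.05))
  res <- mr_ivw(set)
  expect_equal(res$estimate, 0.5)
  expect_equal(res$q, 0, tolerance = 1e-20)
  expect_equal(res$se, mr_ivw(set, effects = "fixed")$se)
  expect_equal(res$i2, 0)
})

test_that("Cochran arithmetic: I2 from Q, floored at zero", {
  # Q = 10 with J = 6 gives I2 = 50%
  expect_equal(max(0, (10 - 5) / 10) * 100, 50)
  set <- make_hset(beta_x = rep(0.1, 6), se_x = rep(1e-6, 6),
                   beta_y = 0.1 * c(0.3, 0.34, 0.28, 0.31, 0.30, 0.32),
                   se_y = rep(0.05, 6))
  cq <- cochran_q(set)
  expect_gte(cq$q, 0)
  expect_equal(cq$i2, max(0, (cq$q - 5) / cq$q) * 100)
  expect_false(cq$heterogeneous)  # tiny spread: Q below its df
  expect_equal(cq$i2, 0)          # floored
  expect_error(cochran_q(make_hset(0.1, 0.01, 0.05, 0.02)), "at least 2")
})

test_that("Q's null rejection rate is calibrated", {
  reps <- 2000
  rej <- vapply(seq_len(reps), function(r) {
    s <- simulate_two_sample(sim_config(n_snps = 50, theta = 0.1, seed = r))
    cochran_q(harmonize(s$exposure, s$outcome))$q_pval < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.035)
  expect_lte(mean(rej), 0.065)
})

test_that("Egger recovers an exact line and orients beta_x first", {
  set <- make_hset(beta_x = c(0.05, -0.1, 0.15, 0.2),
                   se_x = rep(0.01, 4),
                   beta_y = 0.3 * c(0.05, -0.1, 0.15, 0.2),
                   se_y = c(0.02, 0.03, 0.02, 0.04))
  res <- mr_egger(set)
  expect_equal(res$estimate, 0.3, tolerance = 1e-10)
  expect_equal(res$egger_intercept, 0, tolerance = 1e-12)
  # negative-beta_x pair was flipped, not dropped
  expect_equal(res$n_snp, 4L)
  expect_error(mr_egger(make_hset(0.1, 0.01, 0.05, 0.02)), "at least 3")
  expect_error(mr_egger(make_hset(rep(0.1, 3), rep(0.01, 3),
                                  c(0.03, 0.04, 0.05), rep(0.02, 3))),
               "zero variance")
})

test_that("Egger constrained through the origin equals fixed-effect IVW", {
  sim <- simulate_two_sample(sim_config(n_snps = 40, theta = 0.15, seed = 21))
  h <- harmonize(sim$exposure, sim$outcome)
  s <- ifelse(h$beta_x < 0, -1, 1)
  slope0 <- coef(lm(I(s * h$beta_y) ~ 0 + I(s * h$beta_x),
                    weights = 1 / h$se_y^2))[[1]]
  expect_equal(slope0, mr_ivw(h, effects = "fixed")$estimate,
               tolerance = 1e-12)
})

test_that("balanced pleiotropy keeps the intercept test at its nominal level", {
  reps <- 300
  rej <- vapply(seq_len(reps), function(r) {
    s <- simulate_two_sample(sim_config(n_snps = 50, theta = 0.1,
                                        invalid_fraction = 1,
                                        pleiotropy_mean = 0,
                                        pleiotropy_sd = 0.003, seed = r))
    mr_egger(harmonize(s$exposure, s$outcome))$intercept_pval < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.035)
})

test_that("weighted median: symmetry, degeneracy, and seed stability", {
  set <- make_hset(beta_x = c(1, 1, 1), se_x = rep(1e-6, 3),
                   beta_y = c(0.4, 0.5, 0.6), se_y = rep(0.1, 3))
  res <- mr_weighted_median(set, n_boot = 200, seed = 1)
  expect_equal(res$estimate, 0.5)

  const <- make_hset(beta_x = c(0.1, 0.2, 0.3), se_x = rep(1e-6, 3),
                     beta_y = 0.7 * c(0.1, 0.2, 0.3),
                     se_y = 0.001 * c(1, 2, 3))
  r1 <- mr_weighted_median(const, n_boot = 300, seed = 1)
  r2 <- mr_weighted_median(const, n_boot = 300, seed = 2)
  expect_equal(r1$estimate, 0.7)
  expect_lt(r1$se, 0.05)
  expect_lt(abs(r1$se - r2$se) / r1$se, 0.5)  # MC error only
  r1b <- mr_weighted_median(const, n_boot = 300, seed = 1)
  expect_identical(r1, r1b)
})

test_that("maximum likelihood matches Wald at J=1 and IVW on homogeneous data", {
  one <- make_hset(0.1, 0.01, 0.05, 0.02)
  expect_equal(mr_max_likelihood(one)$estimate, 0.5, tolerance = 1e-6)

  # small-noise regime: se_x negligible, where ML and first-order IVW agree
  sim <- simulate_two_sample(sim_config(n_snps = 60, theta = 0.3,
                                        n_exposure = 1e7, seed = 31))
  h <- harmonize(sim$exposure, sim$outcome)
  ml <- mr_max_likelihood(h)
  ivw <- mr_ivw(h, effects = "fixed")
  expect_lt(abs(ml$estimate - ivw$estimate), 1e-3)
})

test_that("maximum likelihood recovers theta = 0.3 on average", {
  reps <- 300
  est <- vapply(seq_len(reps), function(r) {
    s <- simulate_two_sample(sim_config(n_snps = 30, theta = 0.3, seed = r))
    mr_max_likelihood(harmonize(s$exposure, s$outcome))$estimate
  }, numeric(1))
  mc_se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - 0.3), 2 * mc_se)
})

test_that("leave-one-out: cardinality, degeneracy, outlier localization", {
  set <- make_hset(beta_x = rep(0.1, 3), se_x = rep(1e-6, 3),
                   beta_y = c(0.03, 0.0300001, 0.0299999),
                   se_y = rep(0.02, 3))
  loo <- leave_one_out(set)
  expect_equal(nrow(loo), 3L)
  expect_equal(diff(range(loo$estimate)), 0, tolerance = 1e-4)

  sim <- simulate_two_sample(sim_config(n_snps = 20, theta = 0.1, seed = 41))
  h <- harmonize(sim$exposure, sim$outcome)
  h$beta_y[7] <- h$beta_y[7] + 12 * h$se_y[7]
  loo2 <- leave_one_out(h)
  full <- attr(loo2, "full")$estimate
  expect_equal(which.max(abs(loo2$estimate - full)), 7L)
  expect_error(leave_one_out(make_hset(0.1, 0.01, 0.05, 0.02)), "at least 3")
})

test_that("estimators respect sign and scale equivariance", {
  sim <- simulate_two_sample(sim_config(n_snps = 25, theta = 0.2, seed = 51))
  h <- harmonize(sim$exposure, sim$outcome)
  neg <- h; neg$beta_y <- -neg$beta_y
  scl <- h; scl$beta_x <- 2 * scl$beta_x; scl$se_x <- 2 * scl$se_x
  cases <- list(list(fn = mr_ivw, exact_se = TRUE),
                list(fn = mr_egger, exact_se = TRUE),
                list(fn = function(s) mr_weighted_median(s, n_boot = 200,
                                                         seed = 3),
                     exact_se = FALSE),  # bootstrap SE is only MC-symmetric
                list(fn = mr_max_likelihood, exact_se = TRUE))
  for (case in cases) {
    base <- case$fn(h)
    flipped <- case$fn(neg)
    expect_equal(flipped$estimate, -base$estimate, tolerance = 1e-6)
    if (case$exact_se) {
      expect_equal(flipped$se, base$se, tolerance = 1e-6)
    } else {
      expect_lt(abs(flipped$se - base$se) / base$se, 0.5)
    }
    scaled <- case$fn(scl)
    expect_equal(scaled$estimate, base$estimate / 2, tolerance = 1e-5)
  }
})

test_that("or_scale exponentiates the interval consistently", {
  res <- mr_ivw(make_hset(c(0.1, 0.2), c(0.01, 0.01), c(0.03, 0.05),
                          c(0.02, 0.02)))
  os <- or_scale(res)
  expect_equal(unname(os), exp(c(res$estimate, res$ci_low, res$ci_high)))
  expect_true(res$ci_low <= res$estimate && res$estimate <= res$ci_high)
})
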