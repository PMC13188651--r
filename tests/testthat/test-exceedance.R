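paper_summary <- function() {
  log_sample_summary(xbar = log(2.18), s = sigma_from_cv(0.197), n = 46)
}

test_that("plug-in exceedance is the log-normal upper tail", {
  s <- log_sample_summary(log(5), 0.3, 10)
  expect_equal(plug_in_exceedance(s, 5), 0.5)
  s2 <- log_sample_summary(0, 1, 10)
  expect_equal(plug_in_exceedance(s2, exp(1)), pnorm(1, lower.tail = FALSE))
  s3 <- log_sample_summary(0.7793, 0.19513, 46)
  expect_equal(plug_in_exceedance(s3, 5), 1.048608e-5, tolerance = 1e-5)
  expect_error(plug_in_exceedance(s3, 0), "> 0")
  expect_error(log_sample_summary(1, 0, 46), "s must be")
  expect_error(log_sample_summary(1, 0.2, 1), "n must be")
})

test_that("GPQ limit is deterministic given the seed and valid by construction", {
  s <- paper_summary()
  a <- gpq_exceedance_upper(s, 5, replications = 50000L, seed = 7)
  b <- gpq_exceedance_upper(s, 5, replications = 50000L, seed = 7)
  expect_identical(a$upper_limit, b$upper_limit)
  expect_identical(a$mc_se, b$mc_se)
  expect_true(a$point_estimate <= a$upper_limit)
  expect_gt(a$mc_se, 0)
  expect_error(gpq_exceedance_upper(s, 5, replications = 500L), ">= 10000")
})

test_that("GPQ limit is monotone in level and in the tolerance limit", {
  s <- paper_summary()
  u95 <- gpq_exceedance_upper(s, 5, level = 0.95, replications = 1e5, seed = 3)
  u90 <- gpq_exceedance_upper(s, 5, level = 0.90, replications = 1e5, seed = 3)
  expect_gt(u95$upper_limit, u90$upper_limit)
  u4 <- gpq_exceedance_upper(s, 4, level = 0.95, replications = 1e5, seed = 3)
  expect_gt(u4$upper_limit, u95$upper_limit)
})

test_that("the pivotal distribution collapses to the plug-in value as n grows", {
  s <- log_sample_summary(0, 1, 1e6)
  est <- gpq_exceedance_upper(s, exp(1), replications = 1e5, seed = 5)
  expect_lt(abs(est$upper_limit - est$point_estimate) / est$point_estimate, 0.01)
})

test_that("GPQ agrees with the exact noncentral-t construction", {
  s <- log_sample_summary(1, 0.5, 20)
  nct <- exceedance_upper_noncentral_t(s, exp(2), level = 0.95)
  gpq <- gpq_exceedance_upper(s, exp(2), level = 0.95, replications = 5e5,
                              seed = 11)
  expect_lt(abs(gpq$upper_limit - nct$upper_limit), 3 * gpq$mc_se)
  expect_true(is.na(nct$mc_se))
})

test_that("the noncentral-t bound behaves like a one-sided tolerance limit", {
  s <- log_sample_summary(1, 0.5, 20)
  u95 <- exceedance_upper_noncentral_t(s, exp(2), level = 0.95)$upper_limit
  u90 <- exceedance_upper_noncentral_t(s, exp(2), level = 0.90)$upper_limit
  expect_gt(u95, u90)
  # at the observed median (k-hat = 0) the upper bound exceeds 0.5
  s0 <- log_sample_summary(log(5), 0.4, 15)
  expect_gt(exceedance_upper_noncentral_t(s0, 5, 0.95)$upper_limit, 0.5)
})

test_that("Monte Carlo standard error shrinks like 1/sqrt(R)", {
  s <- paper_summary()
  Rs <- c(1e4, 1e5, 1e6)
  ses <- vapply(Rs, function(R) {
    gpq_exceedance_upper(s, 5, replications = R, seed = 13)$mc_se
  }, numeric(1))
  slope <- coef(lm(log(ses) ~ log(Rs)))[2]
  expect_gt(slope, -0.6)
  expect_lt(slope, -0.4)
})

test_that("Clopper-Pearson upper limits match closed forms and a tail oracle", {
  expect_equal(clopper_pearson_upper(0, 46, 0.05), 1 - 0.05^(1 / 46))
  expect_equal(round(100 * clopper_pearson_upper(0, 46, 0.05), 1), 6.3)
  expect_equal(clopper_pearson_upper(0, 1, 0.05), 0.95)
  expect_equal(clopper_pearson_upper(10, 10, 0.05), 1)
  # brute-force inversion of the binomial tail for x = 1, n = 10
  expect_equal(clopper_pearson_upper(1, 10, 0.05), 0.394163302437,
               tolerance = 1e-9)
  expect_error(clopper_pearson_upper(-1, 10), "0 <= x <= n")
  expect_error(clopper_pearson_upper(1, 10, 1.5), "alpha")
})

test_that("zero-event bound matches its closed form and the uniform-prior Bayesian limit", {
  for (n in c(1, 10, 46, 200)) {
    # exact closed form of the zero-event Clopper-Pearson limit
    expect_equal(clopper_pearson_upper(0, n, 0.05), 1 - 0.05^(1 / n),
                 tolerance = 1e-12)
    # uniform-prior posterior at x = 0 is Beta(1, n+1): its upper credible
    # limit is exactly the Clopper-Pearson limit with one extra trial
    bayes <- qbeta(0.95, 1, n + 1)
    expect_equal(bayes, clopper_pearson_upper(0, n + 1, 0.05),
                 tolerance = 1e-12)
  }
  # at the study size the frequentist and Bayesian limits nearly coincide
  expect_lt(abs(qbeta(0.95, 1, 47) - clopper_pearson_upper(0, 46, 0.05)),
            0.0015)
})

test_that("exceedance counting honours the comparator at the boundary", {
  expect_equal(count_exceedances(c(3.55, 2.0), 3.55, ">="), list(x = 1L, n = 2L))
  expect_equal(count_exceedances(c(3.55, 2.0), 3.55, ">"), list(x = 0L, n = 2L))
  expect_equal(count_exceedances(c(1, 2, 3), 0, ">"), list(x = 3L, n = 3L))
  expect_error(count_exceedances(numeric(0), 5), "empty")
})

test_that("coverage simulation is calibrated at the median level and at boundaries", {
  cov50 <- coverage_simulation(0.78, 0.2, n = 46, tolerance_L = 5, level = 0.5,
                               n_cohorts = 300, R_per_cohort = 2e4, seed = 17)
  expect_lt(abs(cov50$coverage - 0.5), 3 * sqrt(0.5 * 0.5 / 300))
  # tiny sigma, L far above the median: limits always cover
  cov1 <- coverage_simulation(0.78, 0.01, n = 46, tolerance_L = 5, level = 0.95,
                              n_cohorts = 200, R_per_cohort = 2e4, seed = 19)
  expect_gte(cov1$coverage, 0.95)
  expect_error(coverage_simulation(0.78, 0.2, 46, 5, n_cohorts = 50), ">= 200")
})
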