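test_that("log-normal fit equals normal moments of the logs", {
  p <- fit_lognormal(c(1, exp(2)))
  expect_equal(p$mu, 1)
  expect_equal(p$sigma, sqrt(2))
  expect_error(fit_lognormal(rep(exp(1), 3)), "degenerate")
  expect_error(fit_lognormal(c(1, -1)), "positive")
  expect_error(fit_lognormal(2), "n >= 2")

  set.seed(5)
  x <- rlnorm(200, 0.3, 0.7)
  p <- fit_lognormal(x)
  expect_equal(p$mu, mean(log(x)))
  expect_equal(p$sigma, sd(log(x)))
  expect_equal(lognormal_median(p), exp(p$mu))
  expect_equal(lognormal_cv(p), sqrt(exp(p$sigma^2) - 1))
})

test_that("log-normal parameters are recovered within 3 standard errors", {
  set.seed(6)
  x <- rlnorm(1e5, 0.7793, 0.195)
  p <- fit_lognormal(x)
  expect_lt(abs(p$mu - 0.7793), 3 * 0.195 / sqrt(1e5))
  expect_lt(abs(p$sigma - 0.195), 3 * 0.195 / sqrt(2e5))
})

test_that("Weibull MLE recovers parameters and is scale equivariant", {
  set.seed(7)
  x <- rweibull(1e5, shape = 2, scale = 3)
  p <- fit_weibull(x)
  expect_lt(abs(p$shape / 2 - 1), 0.02)
  expect_lt(abs(p$scale / 3 - 1), 0.02)

  p10 <- fit_weibull(10 * x[1:500])
  p1 <- fit_weibull(x[1:500])
  expect_equal(p10$shape, p1$shape, tolerance = 1e-8)
  expect_equal(p10$scale, 10 * p1$scale, tolerance = 1e-8)

  # exponential data: shape within 3 SE of 1 (asymptotic SE ~ 0.78/sqrt(n))
  set.seed(8)
  e <- rexp(1e5)
  expect_lt(abs(fit_weibull(e)$shape - 1), 3 * 0.78 / sqrt(1e5))

  expect_error(fit_weibull(rep(2, 10)), "equal")
})

test_that("Weibull MLE matches an independent optimizer", {
  skip_if_not_installed("MASS")
  set.seed(9)
  x <- rweibull(500, 1.6, 2.2)
  mine <- fit_weibull(x)
  ref <- suppressWarnings(MASS::fitdistr(x, "weibull")$estimate)
  expect_equal(mine$shape, unname(ref["shape"]), tolerance = 1e-4)
  expect_equal(mine$scale, unname(ref["scale"]), tolerance = 1e-4)
})

test_that("chi-square bins are equal probability with documented df", {
  set.seed(10)
  x <- rlnorm(46, 0.78, 0.2)
  r <- pearson_chisq_gof(x, "lognormal")
  edges <- attr(r, "bin_edges")
  expect_equal(length(edges) - 1, 9)          # floor(46/5) = 9 bins
  expect_equal(r$df, 9 - 1 - 2)
  # equal-probability construction: expected count n/k in every bin
  p <- fit_lognormal(x)
  probs <- diff(plnorm(edges, p$mu, p$sigma))
  expect_equal(probs, rep(1 / 9, 9), tolerance = 1e-10)

  expect_error(pearson_chisq_gof(x[1:10], "lognormal"), "n >= 20")
  expect_error(pearson_chisq_gof(x, "lognormal", n_bins = 60), "fewer bins")
})

test_that("chi-square type-I error is at or below nominal with re-fitted parameters", {
  set.seed(12)
  rej <- vapply(1:400, function(i) {
    x <- rlnorm(46, 0.78, 0.2)
    pearson_chisq_gof(x, "lognormal")$p_value < 0.05
  }, logical(1))
  # conservative because parameters are estimated; allow 3 binomial SEs
  expect_lt(mean(rej), 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("probability-plot coordinates are exact and robust to ties", {
  mu <- 0.5; sigma <- 0.3
  pp <- (1:46 - 0.375) / 46.25
  x <- qlnorm(pp, mu, sigma)
  co <- probability_plot_coords(x, "lognormal",
                                params = structure(list(mu = mu, sigma = sigma),
                                                   class = "lognormal_params"))
  expect_equal(co$theoretical, co$ordered, tolerance = 1e-12)
  expect_equal(cor(co$theoretical, co$ordered), 1, tolerance = 1e-12)

  tied <- c(1, 2, 2, 2, 3, 4)
  co2 <- probability_plot_coords(tied, "normal")
  expect_equal(nrow(co2), 6)
})

test_that("log-normal data plot straighter under log-normal than normal coordinates", {
  wins <- vapply(1:50, function(s) {
    set.seed(400 + s)
    x <- rlnorm(46, 0.78, 0.5)
    r2 <- function(d) cor(d$theoretical, d$ordered)^2
    r2(probability_plot_coords(x, "lognormal")) >
      r2(probability_plot_coords(x, "normal"))
  }, logical(1))
  expect_gt(mean(wins), 0.5)
})

test_that("Shapiro-Wilk power simulation is calibrated and consistent", {
  null_gen <- function(n) rnorm(n)
  p0 <- shapiro_power_sim(null_gen, n = 30, alpha = 0.10, n_sims = 400, seed = 1)
  expect_lt(abs(p0$power - 0.10), 3 * sqrt(0.10 * 0.90 / 400))

  alt <- function(n) rlnorm(n, 0, 0.5)
  p20 <- shapiro_power_sim(alt, n = 20, alpha = 0.10, n_sims = 300, seed = 2)
  p50 <- shapiro_power_sim(alt, n = 50, alpha = 0.10, n_sims = 300, seed = 2)
  expect_gt(p50$power, p20$power)
  p200 <- shapiro_power_sim(alt, n = 200, alpha = 0.10, n_sims = 300, seed = 2)
  expect_gt(p200$power, 0.95)
})

test_that("the fit report compares candidates and names a winner", {
  set.seed(13)
  x <- rlnorm(200, 0.78, 0.6)
  rep <- fit_report(x)
  expect_setequal(names(rep$entries), c("lognormal", "normal", "weibull"))
  expect_equal(rep$winner, "lognormal")
  expect_equal(rep$entries$lognormal$tests$shapiro_wilk$transform, "log")
  expect_equal(rep$entries$normal$tests$shapiro_wilk$transform, "identity")
  expect_null(rep$entries$weibull$tests$shapiro_wilk)
})
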