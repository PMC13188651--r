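#' Fit a two-parameter log-normal distribution
#'
#' mu is the mean of log-times and sigma their sd with n-1 denominator
#' (matching the pivotal inference, which uses the same sufficient
#' statistics). Median and CV accessors expose the natural-scale
#' parameterisation: median = exp(mu), CV = sqrt(exp(sigma^2) - 1).
#'
#' @param times positive numeric vector, n >= 2.
#' @return An object of class \code{lognormal_params}: list(mu, sigma, n).
#' @export
fit_lognormal <- function(times) {
  times <- as.numeric(times)
  if (length(times) < 2) stop("fit_lognormal: need n >= 2", call. = FALSE)
  if (any(is.na(times)) || any(times <= 0)) {
    stop("fit_lognormal: all times must be positive", call. = FALSE)
  }
  lt <- log(times)
  sigma <- stats::sd(lt)
  if (sigma <= 0) stop("fit_lognormal: degenerate sample (sigma = 0)", call. = FALSE)
  structure(list(mu = mean(lt), sigma = sigma, n = length(times)),
            class = "lognormal_params")
}

#' Median of a fitted log-normal
#' @param params a [fit_lognormal()] object.
#' @return exp(mu), minutes.
#' @export
lognormal_median <- function(params) exp(params$mu)

#' Coefficient of variation of a fitted log-normal
#' @param params a [fit_lognormal()] object.
#' @return sqrt(exp(sigma^2) - 1), dimensionless.
#' @export
lognormal_cv <- function(params) sqrt(exp(params$sigma^2) - 1)

#' @export
print.lognormal_params <- function(x, ...) {
  cat(sprintf("log-normal: mu = %.4g, sigma = %.4g (median %.4g, CV %.1f%%), n = %d\n",
              x$mu, x$sigma, lognormal_median(x), 100 * lognormal_cv(x), x$n))
  invisible(x)
}

#' Fit a Weibull distribution by maximum likelihood
#'
#' The shape is found by one-dimensional root-finding on the profile
#' score g(k) = sum(x^k log x)/sum(x^k) - 1/k - mean(log x); given the
#' shape, the scale is (mean(x^k))^(1/k) in closed form. Convergence
#' tolerance 1e-10 on the shape.
#'
#' @param times positive numeric vector, n >= 2, not all equal.
#' @param max_expand maximum bracket-expansion steps before giving up.
#' @return An object of class \code{weibull_params}: list(shape, scale, n).
#' @export
fit_weibull <- function(times, max_expand = 60L) {
  x <- as.numeric(times)
  if (length(x) < 2) stop("fit_weibull: need n >= 2", call. = FALSE)
  if (any(is.na(x)) || any(x <= 0)) {
    stop("fit_weibull: all times must be positive", call. = FALSE)
  }
  lx <- log(x)
  if (stats::sd(lx) == 0) stop("fit_weibull: all values equal", call. = FALSE)
  mean_lx <- mean(lx)
  # centre on the geometric mean for numerical stability of x^k at large k
  lxc <- lx - mean_lx
  score <- function(k) {
    w <- exp(k * lxc)
    sum(w * lx) / sum(w) - 1 / k - mean_lx
  }
  # method-of-moments style start: sd(log X) = (pi/sqrt(6))/shape;
  # the profile score is increasing in k (-> -Inf as k -> 0+, -> max(lx)
  # - mean(lx) > 0 as k -> Inf)
  k0 <- max(1e-3, (pi / sqrt(6)) / stats::sd(lx))
  lo <- k0 / 2
  hi <- k0 * 2
  for (i in seq_len(max_expand)) {
    if (score(lo) < 0) break
    lo <- lo / 2
  }
  for (i in seq_len(max_expand)) {
    if (score(hi) > 0) break
    hi <- hi * 2
  }
  if (score(lo) >= 0 || score(hi) <= 0) {
    stop("fit_weibull: profile score root not bracketed after ", max_expand,
         " expansions (lo = ", lo, ", hi = ", hi, ")", call. = FALSE)
  }
  shape <- stats::uniroot(score, c(lo, hi), tol = 1e-10)$root
  scale <- exp(mean_lx) * mean(exp(shape * lxc))^(1 / shape)
  structure(list(shape = shape, scale = scale, n = length(x)),
            class = "weibull_params")
}

#' @export
print.weibull_params <- function(x, ...) {
  cat(sprintf("Weibull: shape = %.4g, scale = %.4g, n = %d\n",
              x$shape, x$scale, x$n))
  invisible(x)
}

# quantile function of a fitted candidate distribution
dist_quantile <- function(p, distribution, params) {
  switch(distribution,
    lognormal = stats::qlnorm(p, meanlog = params$mu, sdlog = params$sigma),
    normal = stats::qnorm(p, mean = params$mean, sd = params$sd),
    weibull = stats::qweibull(p, shape = params$shape, scale = params$scale),
    stop("unknown distribution: ", distribution, call. = FALSE))
}

fit_params <- function(times, distribution) {
  switch(distribution,
    lognormal = fit_lognormal(times),
    normal = {
      structure(list(mean = mean(times), sd = stats::sd(times),
                     n = length(times)), class = "normal_params")
    },
    weibull = fit_weibull(times),
    stop("unknown distribution: ", distribution, call. = FALSE))
}

n_fitted_params <- function(distribution) 2L

#' Pearson chi-square goodness-of-fit test with equal-probability bins
#'
#' Bins are equal-probability under the fitted distribution, so every
#' bin's expected count is exactly n / n_bins. The default binning is
#' n_bins = max(4, min(10, floor(n/5))); degrees of freedom are
#' n_bins - 1 - (number of fitted parameters).
#'
#' @param values positive numeric vector.
#' @param distribution \code{"lognormal"}, \code{"normal"} or
#'   \code{"weibull"}.
#' @param params fitted parameters (from [fit_lognormal()],
#'   [fit_weibull()], or a list(mean, sd) for normal); fitted on the same
#'   data by default if NULL.
#' @param n_bins \code{"auto"} or an integer >= 3.
#' @return A \code{fit_test_result} with the statistic, df, p-value and a
#'   \code{bin_edges} attribute.
#' @export
pearson_chisq_gof <- function(values, distribution, params = NULL,
                              n_bins = "auto") {
  x <- as.numeric(values)
  n <- length(x)
  if (identical(n_bins, "auto")) {
    if (n < 20) stop("pearson_chisq_gof: need n >= 20 for auto binning",
                     call. = FALSE)
    n_bins <- max(4, min(10, floor(n / 5)))
  }
  n_bins <- as.integer(n_bins)
  if (n_bins < 3) stop("pearson_chisq_gof: need at least 3 bins", call. = FALSE)
  expected <- n / n_bins
  if (expected < 1) {
    stop("pearson_chisq_gof: expected count below 1; use fewer bins",
         call. = FALSE)
  }
  if (is.null(params)) params <- fit_params(x, distribution)
  inner <- dist_quantile(seq_len(n_bins - 1) / n_bins, distribution, params)
  edges <- c(-Inf, inner, Inf)
  observed <- as.vector(table(cut(x, breaks = edges)))
  stat <- sum((observed - expected)^2 / expected)
  df <- n_bins - 1L - n_fitted_params(distribution)
  if (df < 1) stop("pearson_chisq_gof: non-positive degrees of freedom",
                   call. = FALSE)
  res <- fit_test_result("pearson_chisq", statistic = stat, df = df,
                         p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                         transform = "identity", n = n)
  attr(res, "bin_edges") <- edges
  attr(res, "distribution") <- distribution
  res
}

#' Probability-plot coordinates for a fitted distribution
#'
#' Ordered data against fitted-distribution quantiles at Blom plotting
#' positions (i - 0.375)/(n + 0.25). A straight plot indicates good fit;
#' rendering is left to the caller.
#'
#' @param values numeric vector, n >= 3.
#' @inheritParams pearson_chisq_gof
#' @return data frame with columns \code{theoretical} and \code{ordered}.
#' @export
probability_plot_coords <- function(values, distribution, params = NULL) {
  x <- sort(as.numeric(values))
  n <- length(x)
  if (n < 3) stop("probability_plot_coords: need n >= 3", call. = FALSE)
  if (is.null(params)) params <- fit_params(x, distribution)
  pp <- (seq_len(n) - 0.375) / (n + 0.25)
  data.frame(theoretical = dist_quantile(pp, distribution, params),
             ordered = x)
}

#' Monte Carlo power of the Shapiro-Wilk test
#'
#' Simulates samples from an alternative-generating function and returns
#' the proportion rejected at \code{alpha}, with its binomial standard
#' error.
#'
#' @param alternative function(n) returning one sample of size n.
#' @param n sample size per simulation, >= 3.
#' @param alpha rejection level.
#' @param n_sims number of simulations, >= 100.
#' @param seed integer seed.
#' @param transform passed to [shapiro_wilk()].
#' @return list(power, se, n_sims).
#' @export
shapiro_power_sim <- function(alternative, n, alpha = 0.05, n_sims = 1000L,
                              seed = 1L, transform = "identity") {
  stopifnot(is.function(alternative), n >= 3, n_sims >= 100)
  set.seed(as.integer(seed))
  rej <- vapply(seq_len(n_sims), function(i) {
    shapiro_wilk(alternative(n), transform = transform)$p_value < alpha
  }, logical(1))
  p <- mean(rej)
  list(power = p, se = sqrt(p * (1 - p) / n_sims), n_sims = n_sims)
}

#' Compare candidate time distributions on one sample
#'
#' Fits each requested distribution, runs the Shapiro-Wilk test on the
#' matching transform (log scale for log-normal, raw scale for normal;
#' Shapiro-Wilk does not apply to the Weibull) and the equal-probability
#' Pearson chi-square test for every candidate. The reported winner is
#' the distribution with the highest Shapiro-Wilk p-value on its matching
#' transform, with the chi-square p as tiebreaker; it is a reporting
#' convenience, not a formal selection rule.
#'
#' @param times positive numeric vector.
#' @param distributions subset of c("lognormal", "normal", "weibull").
#' @param n_bins passed to [pearson_chisq_gof()].
#' @return An object of class \code{fit_report}.
#' @export
fit_report <- function(times,
                       distributions = c("lognormal", "normal", "weibull"),
                       n_bins = "auto") {
  distributions <- match.arg(distributions, several.ok = TRUE)
  entries <- lapply(distributions, function(d) {
    params <- fit_params(times, d)
    tests <- list()
    if (d == "lognormal") tests$shapiro_wilk <- shapiro_wilk(times, "log")
    if (d == "normal") tests$shapiro_wilk <- shapiro_wilk(times, "identity")
    tests$pearson_chisq <- pearson_chisq_gof(times, d, params, n_bins)
    list(distribution = d, params = params, tests = tests)
  })
  names(entries) <- distributions
  sw_p <- vapply(entries, function(e) {
    if (is.null(e$tests$shapiro_wilk)) -Inf else e$tests$shapiro_wilk$p_value
  }, numeric(1))
  chi_p <- vapply(entries, function(e) e$tests$pearson_chisq$p_value, numeric(1))
  winner <- distributions[order(-sw_p, -chi_p)][1]
  structure(list(entries = entries, n = length(times), winner = winner),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("Distribution fit report (n = %d), winner: %s\n", x$n, x$winner))
  for (e in x$entries) {
    cat(" -", e$distribution, "\n")
    for (t in e$tests) {
      cat("    ")
      print(t)
    }
  }
  invisible(x)
}
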