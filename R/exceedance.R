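#' Sufficient statistics of log-times
#'
#' All pivotal inference for log-normal exceedance probabilities operates
#' on (xbar, s, n): the mean and sd (n-1 denominator) of the logged times.
#'
#' @param xbar mean of log-times (log-minutes).
#' @param s sd of log-times, n-1 denominator, > 0.
#' @param n sample size, >= 2.
#' @return An object of class \code{log_sample_summary}.
#' @export
log_sample_summary <- function(xbar, s, n) {
  if (!is.finite(xbar) || !is.finite(s) || s <= 0) {
    stop("log_sample_summary: s must be finite and > 0", call. = FALSE)
  }
  n <- as.integer(n)
  if (n < 2) stop("log_sample_summary: n must be >= 2", call. = FALSE)
  structure(list(xbar = xbar, s = s, n = n), class = "log_sample_summary")
}

#' Log-sample summary of observed times
#'
#' @param times positive numeric vector, n >= 2.
#' @return A [log_sample_summary()].
#' @export
log_summary_of <- function(times) {
  fit <- fit_lognormal(times)
  log_sample_summary(fit$mu, fit$sigma, fit$n)
}

as_log_summary <- function(x) {
  if (inherits(x, "log_sample_summary")) return(x)
  if (inherits(x, "lognormal_params")) {
    return(log_sample_summary(x$mu, x$sigma, x$n))
  }
  stop("expected a log_sample_summary or lognormal_params object", call. = FALSE)
}

#' Plug-in exceedance probability under a log-normal model
#'
#' P(T > L) = 1 - Phi((log L - mu) / sigma) for the fitted (mu, sigma).
#'
#' @param params a [fit_lognormal()] or [log_sample_summary()] object.
#' @param tolerance_L tolerance limit in minutes, > 0.
#' @return probability in (0, 1).
#' @export
plug_in_exceedance <- function(params, tolerance_L) {
  if (tolerance_L <= 0) stop("tolerance_L must be > 0", call. = FALSE)
  s <- as_log_summary(params)
  stats::pnorm((log(tolerance_L) - s$xbar) / s$s, lower.tail = FALSE)
}

exceedance_estimate <- function(point_estimate, upper_limit, mc_se, method,
                                tolerance_L, level, n, replications = NA_integer_,
                                seed = NA_integer_) {
  structure(list(point_estimate = point_estimate, upper_limit = upper_limit,
                 mc_se = mc_se, method = method, tolerance_L = tolerance_L,
                 level = level, n = n, replications = replications,
                 seed = seed),
            class = "exceedance_estimate")
}

#' @export
print.exceedance_estimate <- function(x, ...) {
  se_txt <- if (is.na(x$mc_se)) "" else sprintf(" (MC se %.3g%%)", 100 * x$mc_se)
  cat(sprintf(
    "P(time > %g min): point %.4g%%, %g%% upper limit %.4g%%%s [%s, n = %d]\n",
    x$tolerance_L, 100 * x$point_estimate, 100 * x$level,
    100 * x$upper_limit, se_txt, x$method, x$n))
  invisible(x)
}

#' Generalized-pivotal upper confidence limit on an exceedance probability
#'
#' For r = 1..R, draws U_r ~ chi-square(n-1) and Z_r ~ N(0,1), forms the
#' pivotal sigma_r = s * sqrt((n-1)/U_r) and mu_r = xbar - Z_r * sigma_r /
#' sqrt(n), and evaluates p_r = 1 - Phi((log L - mu_r)/sigma_r). The upper
#' limit is the ceil(level * R)-th order statistic of the p_r. The Monte
#' Carlo standard error is the sd of the same quantile over B consecutive
#' equal batches, divided by sqrt(B). Deterministic given \code{seed}.
#'
#' @param summary a [log_sample_summary()] (or [fit_lognormal()] fit).
#' @param tolerance_L tolerance limit in minutes, > 0.
#' @param level one-sided confidence level in (0, 1), default 0.95.
#' @param replications number of pivotal replicates R, >= 10000.
#' @param seed integer seed.
#' @param batches number of batches B for the standard error.
#' @return An \code{exceedance_estimate} with \code{method = "gpq"}.
#' @export
gpq_exceedance_upper <- function(summary, tolerance_L, level = 0.95,
                                 replications = 2999999L, seed = 1L,
                                 batches = 100L) {
  smry <- as_log_summary(summary)
  if (tolerance_L <= 0) stop("tolerance_L must be > 0", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  R <- as.integer(replications)
  if (R < 10000) stop("replications must be >= 10000 for a reported limit",
                      call. = FALSE)
  B <- as.integer(batches)
  set.seed(as.integer(seed))
  U <- stats::rchisq(R, df = smry$n - 1)
  Z <- stats::rnorm(R)
  sigma_r <- smry$s * sqrt((smry$n - 1) / U)
  mu_r <- smry$xbar - Z * sigma_r / sqrt(smry$n)
  p_r <- stats::pnorm((log(tolerance_L) - mu_r) / sigma_r, lower.tail = FALSE)

  upper <- sort(p_r)[ceiling(level * R)]

  bs <- R %/% B
  bq <- vapply(seq_len(B), function(b) {
    block <- p_r[((b - 1) * bs + 1):(b * bs)]
    sort(block)[ceiling(level * bs)]
  }, numeric(1))
  mc_se <- stats::sd(bq) / sqrt(B)

  exceedance_estimate(point_estimate = plug_in_exceedance(smry, tolerance_L),
                      upper_limit = upper, mc_se = mc_se, method = "gpq",
                      tolerance_L = tolerance_L, level = level, n = smry$n,
                      replications = R, seed = as.integer(seed))
}

#' Exact noncentral-t upper confidence limit on an exceedance probability
#'
#' The classical one-sided tolerance construction: with k-hat =
#' (log L - xbar)/s, the limit solves
#' CDF_noncentral-t(sqrt(n) k-hat; df = n-1, ncp = sqrt(n) k_L) = level
#' for k_L by bracketed root-finding (tolerance 1e-10), and the upper
#' limit on P(T > L) is 1 - Phi(k_L). No Monte Carlo error; serves as the
#' validation oracle for [gpq_exceedance_upper()].
#'
#' @inheritParams gpq_exceedance_upper
#' @param max_expand maximum bracket-expansion steps.
#' @return An \code{exceedance_estimate} with \code{method = "noncentral_t"}.
#' @export
exceedance_upper_noncentral_t <- function(summary, tolerance_L, level = 0.95,
                                          max_expand = 60L) {
  smry <- as_log_summary(summary)
  if (tolerance_L <= 0) stop("tolerance_L must be > 0", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  khat <- (log(tolerance_L) - smry$xbar) / smry$s
  tstat <- sqrt(smry$n) * khat
  f <- function(kL) {
    suppressWarnings(
      stats::pt(tstat, df = smry$n - 1, ncp = sqrt(smry$n) * kL)) - level
  }
  # f is decreasing in kL; expand the bracket around khat
  lo <- khat - 1
  hi <- khat + 1
  for (i in seq_len(max_expand)) {
    if (f(lo) > 0) break
    lo <- lo - 2^(i / 4)
  }
  for (i in seq_len(max_expand)) {
    if (f(hi) < 0) break
    hi <- hi + 2^(i / 4)
  }
  if (f(lo) <= 0 || f(hi) >= 0) {
    stop("exceedance_upper_noncentral_t: root not bracketed after ",
         max_expand, " expansions", call. = FALSE)
  }
  kL <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  exceedance_estimate(point_estimate = plug_in_exceedance(smry, tolerance_L),
                      upper_limit = stats::pnorm(kL, lower.tail = FALSE),
                      mc_se = NA_real_, method = "noncentral_t",
                      tolerance_L = tolerance_L, level = level, n = smry$n)
}

#' Clopper-Pearson exact upper confidence limit for a binomial proportion
#'
#' The one-sided 1-alpha upper limit in the Beta-quantile formulation:
#' qbeta(1 - alpha, x + 1, n - x); 1 - alpha^(1/n) for x = 0 and 1 for
#' x = n. Exact for zero observed events, and identical to the Bayesian
#' upper credible limit under a uniform prior when x = 0.
#'
#' @param x event count, 0 <= x <= n.
#' @param n trial count, >= 1.
#' @param alpha one minus the confidence level, in (0, 1).
#' @return upper limit in (0, 1].
#' @export
clopper_pearson_upper <- function(x, n, alpha = 0.05) {
  if (n < 1 || x < 0 || x > n) stop("need 0 <= x <= n, n >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (x == n) return(1)
  stats::qbeta(1 - alpha, x + 1, n - x)
}

#' Count tolerance-limit exceedances
#'
#' @param times numeric vector of observed times, non-empty.
#' @param tolerance_L tolerance limit in minutes.
#' @param comparator \code{">="} (count times at or above L, the default
#'   for binomial counting) or \code{">"}.
#' @return list(x = exceedance count, n = total).
#' @export
count_exceedances <- function(times, tolerance_L, comparator = c(">=", ">")) {
  comparator <- match.arg(comparator)
  times <- as.numeric(times)
  if (length(times) == 0) stop("count_exceedances: empty times", call. = FALSE)
  x <- if (comparator == ">=") sum(times >= tolerance_L) else sum(times > tolerance_L)
  list(x = as.integer(x), n = length(times))
}

#' Coverage simulation for the GPQ upper limit
#'
#' Simulates cohorts from a true log-normal, computes the GPQ upper limit
#' for each, and returns the fraction of cohorts whose limit is at or
#' above the true exceedance probability, with its binomial standard
#' error. Validates the frequentist calibration of the method.
#'
#' @param mu_log,sigma_log true log-scale parameters.
#' @param n cohort size per simulation.
#' @param tolerance_L tolerance limit in minutes.
#' @param level nominal one-sided confidence level.
#' @param n_cohorts number of simulated cohorts, >= 200.
#' @param R_per_cohort pivotal replicates per cohort.
#' @param seed integer seed.
#' @return list(coverage, se, true_exceedance, n_cohorts).
#' @export
coverage_simulation <- function(mu_log, sigma_log, n, tolerance_L,
                                level = 0.95, n_cohorts = 2000L,
                                R_per_cohort = 20000L, seed = 1L) {
  if (n_cohorts < 200) stop("coverage_simulation: need n_cohorts >= 200",
                            call. = FALSE)
  true_p <- stats::pnorm((log(tolerance_L) - mu_log) / sigma_log,
                         lower.tail = FALSE)
  covered <- vapply(seq_len(n_cohorts), function(i) {
    set.seed(sub_seed(seed, 100 + i))
    lt <- stats::rnorm(n, mu_log, sigma_log)
    smry <- log_sample_summary(mean(lt), stats::sd(lt), n)
    est <- gpq_exceedance_upper(smry, tolerance_L, level = level,
                                replications = R_per_cohort,
                                seed = sub_seed(seed, 7000000 + i))
    est$upper_limit >= true_p
  }, logical(1))
  cov <- mean(covered)
  list(coverage = cov, se = sqrt(cov * (1 - cov) / n_cohorts),
       true_exceedance = true_p, n_cohorts = n_cohorts)
}
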