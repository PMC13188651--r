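#' Shapiro-Wilk normality test (Royston's AS R94 approximation)
#'
#' Computes the W statistic and its p-value from Royston's 1995
#' approximation (algorithm AS R94), valid for sample sizes 3 to 5000.
#' For the log-normal hypothesis apply it to log-times
#' (\code{transform = "log"}); for the normal hypothesis to raw times.
#'
#' @param values numeric vector, 3 <= n <= 5000.
#' @param transform \code{"identity"} or \code{"log"}; with \code{"log"}
#'   the test is applied to \code{log(values)} (all values must be > 0).
#' @return An object of class \code{fit_test_result}: list with
#'   \code{test_name = "shapiro_wilk"}, \code{statistic} (W),
#'   \code{p_value}, \code{df = NA}, \code{transform}, \code{n}.
#' @export
shapiro_wilk <- function(values, transform = c("identity", "log")) {
  transform <- match.arg(transform)
  x <- as.numeric(values)
  if (any(is.na(x))) stop("shapiro_wilk: missing values", call. = FALSE)
  if (transform == "log") {
    if (any(x <= 0)) stop("shapiro_wilk: log transform needs positive values",
                          call. = FALSE)
    x <- log(x)
  }
  n <- length(x)
  if (n < 3 || n > 5000) {
    stop("shapiro_wilk: sample size must be between 3 and 5000", call. = FALSE)
  }
  x <- sort(x)
  if (x[n] - x[1] <= 0) stop("shapiro_wilk: all values identical", call. = FALSE)

  # expected normal order statistics (Blom) and the AS R94 weights
  m <- stats::qnorm((seq_len(n) - 0.375) / (n + 0.25))
  ssq_m <- sum(m^2)
  a <- numeric(n)
  if (n == 3) {
    a[1] <- -sqrt(0.5)
    a[3] <- sqrt(0.5)
  } else {
    u <- 1 / sqrt(n)
    cn <- m[n] / sqrt(ssq_m)
    a_n <- cn + u * (0.221157 + u * (-0.147981 + u * (-2.071190 +
             u * (4.434685 + u * (-2.706056)))))
    if (n > 5) {
      cn1 <- m[n - 1] / sqrt(ssq_m)
      a_n1 <- cn1 + u * (0.042981 + u * (-0.293762 + u * (-1.752461 +
                u * (5.682633 + u * (-3.582633)))))
      phi <- (ssq_m - 2 * m[n]^2 - 2 * m[n - 1]^2) /
             (1 - 2 * a_n^2 - 2 * a_n1^2)
      a[3:(n - 2)] <- m[3:(n - 2)] / sqrt(phi)
      a[n - 1] <- a_n1
      a[2] <- -a_n1
    } else {
      phi <- (ssq_m - 2 * m[n]^2) / (1 - 2 * a_n^2)
      if (n > 3) a[2:(n - 1)] <- m[2:(n - 1)] / sqrt(phi)
    }
    a[n] <- a_n
    a[1] <- -a_n
  }

  W <- sum(a * x)^2 / sum((x - mean(x))^2)
  W <- min(W, 1)

  # p-value per Royston (1995)
  if (n == 3) {
    pw <- (6 / pi) * (asin(sqrt(W)) - asin(sqrt(0.75)))
    pw <- min(max(pw, 0), 1)
  } else if (n <= 11) {
    g <- -2.273 + 0.459 * n
    y <- log(1 - W)
    if (y >= g) {
      pw <- 0
    } else {
      y <- -log(g - y)
      mu <- 0.5440 + n * (-0.39978 + n * (0.025054 + n * (-0.0006714)))
      sg <- exp(1.3822 + n * (-0.77857 + n * (0.062767 + n * (-0.0020322))))
      pw <- stats::pnorm((y - mu) / sg, lower.tail = FALSE)
    }
  } else {
    ln <- log(n)
    y <- log(1 - W)
    mu <- -1.5861 + ln * (-0.31082 + ln * (-0.083751 + ln * 0.0038915))
    sg <- exp(-0.4803 + ln * (-0.082676 + ln * 0.0030302))
    pw <- stats::pnorm((y - mu) / sg, lower.tail = FALSE)
  }

  fit_test_result("shapiro_wilk", statistic = W, df = NA_real_,
                  p_value = pw, transform = transform, n = n)
}

fit_test_result <- function(test_name, statistic, df, p_value, transform, n) {
  structure(list(test_name = test_name, statistic = statistic, df = df,
                 p_value = p_value, transform = transform, n = n),
            class = "fit_test_result")
}

#' @export
print.fit_test_result <- function(x, ...) {
  df_txt <- if (is.na(x$df)) "" else sprintf(", df = %g", x$df)
  cat(sprintf("%s (%s scale): statistic = %.4g%s, p = %.4g, n = %d\n",
              x$test_name, x$transform, x$statistic, df_txt, x$p_value, x$n))
  invisible(x)
}
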