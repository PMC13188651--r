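#' Rolling experience-threshold scan
#'
#' Evaluates candidate prior-year endotracheal-intubation thresholds in
#' descending order (every distinct observed count, plus 0). At each
#' candidate with at least \code{min_subset} retained completers, the
#' Shapiro-Wilk test is run on the log-times of the retained subset;
#' a threshold passes when its p-value is at least \code{alpha_fit}.
#' The selected threshold is the smallest passing candidate such that
#' every larger evaluated candidate also passes (a contiguous run from
#' the top), so an isolated pass below a failing threshold is never
#' selected.
#'
#' @param cohort a [as_cohort()] object with completed times.
#' @param alpha_fit pass level for the Shapiro-Wilk p-value (default 0.05).
#' @param min_subset smallest subset size evaluated (default 20; guards
#'   against vacuous passes at small n where the test has little power).
#' @return An object of class \code{threshold_scan_result}: list with
#'   \code{rows} (data frame: threshold, n_retained, shapiro_W, shapiro_p,
#'   passes; descending threshold), \code{selected_threshold} (NA if no
#'   contiguous passing run), \code{alpha_fit}, \code{min_subset}.
#' @export
scan_thresholds <- function(cohort, alpha_fit = 0.05, min_subset = 20L) {
  stopifnot(inherits(cohort, "cohort"))
  done <- cohort[cohort$completed, , drop = FALSE]
  if (nrow(done) == 0) stop("scan_thresholds: no completed records", call. = FALSE)
  candidates <- sort(unique(c(0L, done$eti_prior_year)), decreasing = TRUE)
  rows <- lapply(candidates, function(th) {
    times <- done$time_minutes[done$eti_prior_year >= th]
    if (length(times) < min_subset) return(NULL)
    sw <- shapiro_wilk(times, transform = "log")
    data.frame(threshold = th, n_retained = length(times),
               shapiro_W = sw$statistic, shapiro_p = sw$p_value,
               passes = sw$p_value >= alpha_fit)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0) {
    warning("scan_thresholds: no candidate threshold retains min_subset = ",
            min_subset, " records")
    rows <- data.frame(threshold = integer(0), n_retained = integer(0),
                       shapiro_W = numeric(0), shapiro_p = numeric(0),
                       passes = logical(0))
    selected <- NA_integer_
  } else {
    run <- cumprod(rows$passes) == 1   # contiguous passing run from the top
    selected <- if (any(run)) rows$threshold[max(which(run))] else NA_integer_
  }
  structure(list(rows = rows, selected_threshold = selected,
                 alpha_fit = alpha_fit, min_subset = as.integer(min_subset)),
            class = "threshold_scan_result")
}

#' @export
print.threshold_scan_result <- function(x, ...) {
  cat(sprintf("Experience-threshold scan (alpha_fit = %g, min_subset = %d)\n",
              x$alpha_fit, x$min_subset))
  print(x$rows, row.names = FALSE)
  if (is.na(x$selected_threshold)) {
    cat("selected threshold: none (no contiguous passing run)\n")
  } else {
    cat("selected threshold:", x$selected_threshold, "\n")
  }
  invisible(x)
}

#' Log-normal fit diagnostics at one experience threshold
#'
#' Single-row evaluation at a stated threshold, by the same rule as
#' [scan_thresholds()].
#'
#' @inheritParams scan_thresholds
#' @param threshold prior-year eti count threshold.
#' @return one-row data frame (threshold, n_retained, shapiro_W,
#'   shapiro_p, passes).
#' @export
subset_fit_at <- function(cohort, threshold, alpha_fit = 0.05) {
  stopifnot(inherits(cohort, "cohort"))
  done <- cohort[cohort$completed, , drop = FALSE]
  times <- done$time_minutes[done$eti_prior_year >= threshold]
  if (length(times) < 3) {
    stop("subset_fit_at: fewer than 3 records at threshold ", threshold,
         call. = FALSE)
  }
  sw <- shapiro_wilk(times, transform = "log")
  data.frame(threshold = threshold, n_retained = length(times),
             shapiro_W = sw$statistic, shapiro_p = sw$p_value,
             passes = sw$p_value >= alpha_fit)
}
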