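#' Participant cohorts
#'
#' A cohort is a data frame with one row per participant and columns
#' \code{participant_id} (unique character label), \code{time_minutes}
#' (positive decimal minutes from tube insertion to confirmed selective
#' lobar ventilation), \code{eti_prior_year} and \code{dlt_prior_year}
#' (self-reported counts of endotracheal and double-lumen intubations in
#' the previous calendar year), and \code{completed} (logical). A
#' \code{provenance} attribute records where the cohort came from (a file
#' path or a generator seed description).
#'
#' @param records data frame with the five cohort columns.
#' @param provenance free-text origin label.
#' @return An object of class \code{cohort} (a data frame).
#' @export
as_cohort <- function(records, provenance = "unspecified") {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  validate_cohort(records)
  records$participant_id <- as.character(records$participant_id)
  records$time_minutes <- as.numeric(records$time_minutes)
  records$eti_prior_year <- as.integer(records$eti_prior_year)
  records$dlt_prior_year <- as.integer(records$dlt_prior_year)
  records$completed <- as.logical(records$completed)
  structure(records,
            provenance = as.character(provenance)[1],
            class = c("cohort", "data.frame"))
}

cohort_columns <- c("participant_id", "time_minutes", "eti_prior_year",
                    "dlt_prior_year", "completed")

validate_cohort <- function(df) {
  missing_cols <- setdiff(cohort_columns, names(df))
  if (length(missing_cols) > 0) {
    stop("cohort schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) {
    stop("cohort is empty: no participant rows", call. = FALSE)
  }
  if (anyDuplicated(df$participant_id)) {
    dup <- unique(df$participant_id[duplicated(df$participant_id)])
    stop("cohort validation error: duplicate participant_id ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  cnt <- c(df$eti_prior_year, df$dlt_prior_year)
  if (any(is.na(cnt)) || any(cnt < 0) || any(cnt != round(cnt))) {
    stop("cohort validation error: experience counts must be non-negative integers",
         call. = FALSE)
  }
  done <- as.logical(df$completed)
  tm <- as.numeric(df$time_minutes)
  if (any(done & (is.na(tm) | tm <= 0))) {
    stop("cohort validation error: completed records need time_minutes > 0",
         call. = FALSE)
  }
  invisible(df)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d participants (%d completed) [%s]\n",
              nrow(x), sum(x$completed), attr(x, "provenance")))
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6))
  invisible(x)
}

#' Parse procedure times given as "m:ss" or decimal minutes
#'
#' Ingestion helper: values like \code{"2:30"} are converted to decimal
#' minutes (2.5); plain numbers pass through. Used by [read_cohort()].
#'
#' @param x character vector of times.
#' @return numeric vector of decimal minutes (NA where unparseable).
#' @export
parse_time_minutes <- function(x) {
  x <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(x))
  colon <- grepl("^[0-9]+:[0-5]?[0-9](\\.[0-9]+)?$", x)
  if (any(colon)) {
    parts <- strsplit(x[colon], ":", fixed = TRUE)
    out[colon] <- vapply(parts, function(p) {
      as.numeric(p[1]) + as.numeric(p[2]) / 60
    }, numeric(1))
  }
  out
}

#' Read a cohort from CSV
#'
#' Expects a UTF-8 CSV with header
#' \code{participant_id,time_minutes,eti_prior_year,dlt_prior_year,completed}
#' and "." as decimal mark. Times may be decimal minutes or "m:ss".
#'
#' @param path CSV file path.
#' @return A [as_cohort()] object; row order preserved.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         strip.white = TRUE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(cohort_columns, names(raw))
  if (length(missing_cols) > 0) {
    stop("cohort schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) stop("cohort file has no data rows: ", path, call. = FALSE)
  tm <- parse_time_minutes(raw$time_minutes)
  bad <- which(is.na(tm) & nzchar(raw$time_minutes))
  if (length(bad) > 0) {
    stop("parse error: non-numeric time_minutes at data row ", bad[1],
         " ('", raw$time_minutes[bad[1]], "')", call. = FALSE)
  }
  completed <- tolower(raw$completed) %in% c("true", "t", "1", "yes")
  as_cohort(data.frame(participant_id = raw$participant_id,
                       time_minutes = tm,
                       eti_prior_year = as.integer(raw$eti_prior_year),
                       dlt_prior_year = as.integer(raw$dlt_prior_year),
                       completed = completed,
                       stringsAsFactors = FALSE),
            provenance = path)
}

#' Write a cohort to CSV
#'
#' Times are written at full precision so that a read/write round trip
#' preserves every field.
#'
#' @param cohort a [as_cohort()] object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  df <- as.data.frame(cohort)
  df$time_minutes <- format(df$time_minutes, digits = 17, trim = TRUE,
                            scientific = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Filter a cohort by prior endotracheal-intubation experience
#'
#' Retains the records with \code{eti_prior_year >= min_eti}, order
#' preserved. An empty result is permitted and flagged in the provenance.
#'
#' @param cohort a [as_cohort()] object.
#' @param min_eti non-negative integer threshold.
#' @return filtered cohort.
#' @export
filter_by_experience <- function(cohort, min_eti) {
  stopifnot(inherits(cohort, "cohort"), min_eti >= 0)
  keep <- cohort$eti_prior_year >= min_eti
  out <- as.data.frame(cohort)[keep, , drop = FALSE]
  rownames(out) <- NULL
  prov <- sprintf("%s | eti >= %d (%d/%d retained)",
                  attr(cohort, "provenance"), as.integer(min_eti),
                  sum(keep), nrow(cohort))
  structure(out, provenance = prov, class = c("cohort", "data.frame"))
}

#' Completed procedure times of a cohort
#'
#' Incomplete records are excluded from all time analyses.
#'
#' @param cohort a [as_cohort()] object.
#' @return numeric vector of times in minutes.
#' @export
completed_times <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  cohort$time_minutes[cohort$completed]
}

#' Summary statistics for a sample of procedure times
#'
#' Returns n, mean, sd (n-1 denominator), coefficient of variation
#' (sd/mean), quartiles and range. Quantiles use linear interpolation
#' between order statistics at p(k) = (k-1)/(n-1) (R's default type 7).
#'
#' @param times positive numeric vector, length >= 1.
#' @return An object of class \code{summary_stats} (named list).
#' @export
summarize_times <- function(times) {
  times <- as.numeric(times)
  if (length(times) == 0) stop("summarize_times: empty input", call. = FALSE)
  if (any(is.na(times)) || any(times <= 0)) {
    stop("summarize_times: times must be positive and non-missing", call. = FALSE)
  }
  n <- length(times)
  m <- mean(times)
  s <- if (n > 1) stats::sd(times) else 0
  q <- stats::quantile(times, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(list(n = n, mean = m, sd = s, cv = s / m,
                 q25 = q[1], median = q[2], q75 = q[3],
                 min = min(times), max = max(times)),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf(
    "n = %d  mean = %.4g (sd %.4g, cv %.1f%%)\n  quartiles %.4g / %.4g / %.4g  range [%.4g, %.4g]\n",
    x$n, x$mean, x$sd, 100 * x$cv, x$q25, x$median, x$q75, x$min, x$max))
  invisible(x)
}
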