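#' Configuration for a full analysis run
#'
#' Either \code{input} (a cohort CSV path) or \code{generator} (a
#' [generator_config()]) must be supplied. Every downstream stage
#' receives exactly the values echoed into the report header.
#'
#' @param input path to a cohort CSV, or NULL.
#' @param generator a [generator_config()], or NULL.
#' @param tolerances tolerance limits in minutes (default c(5, 4)).
#' @param level one-sided confidence level for exceedance limits.
#' @param replications GPQ pivotal replicates.
#' @param seed master seed; per-stage seeds are derived from it so adding
#'   a stage never perturbs another stage's draws.
#' @param alpha_fit,min_subset passed to [scan_thresholds()].
#' @param permutations Monte Carlo permutations for association p-values.
#' @param threshold optional fixed experience threshold; NULL selects the
#'   scan's threshold.
#' @param count_comparator comparator for binomial exceedance counting.
#' @return An object of class \code{analysis_config}.
#' @export
analysis_config <- function(input = NULL, generator = NULL,
                            tolerances = c(5, 4), level = 0.95,
                            replications = 2999999L, seed = 1L,
                            alpha_fit = 0.05, min_subset = 20L,
                            permutations = 50000L, threshold = NULL,
                            count_comparator = ">=") {
  if (is.null(input) && is.null(generator)) {
    stop("analysis_config: supply input path or generator config", call. = FALSE)
  }
  structure(list(input = input, generator = generator,
                 tolerances = as.numeric(tolerances), level = level,
                 replications = as.integer(replications),
                 seed = as.integer(seed), alpha_fit = alpha_fit,
                 min_subset = as.integer(min_subset),
                 permutations = as.integer(permutations),
                 threshold = threshold, count_comparator = count_comparator),
            class = "analysis_config")
}

stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  sub_seed(seed, 5000L + h)
}

summary_as_list <- function(s) unclass(s)

#' Run the full procedure-time analysis
#'
#' Ingest (or generate) a cohort, scan experience thresholds, filter at
#' the selected (or configured) threshold, summarize, compare candidate
#' distributions, compute exceedance limits (GPQ, noncentral-t, and
#' Clopper-Pearson binomial) per tolerance, and test experience-time
#' associations on the full completed cohort.
#'
#' @param config an [analysis_config()].
#' @param verbose logical; log stage progress to standard error.
#' @return An object of class \code{analysis_report} (nested list,
#'   serializable with [write_report()]).
#' @export
run_analysis <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "analysis_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("analysis stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    say("stage %-12s %.2fs", name, proc.time()[["elapsed"]] - t0)
    out
  }

  cohort <- stage("ingest", {
    if (!is.null(config$input)) read_cohort(config$input)
    else generate_cohort(config$generator)
  })
  done <- cohort[cohort$completed, , drop = FALSE]
  full_summary <- stage("summarize", summarize_times(done$time_minutes))

  scan <- stage("scan", scan_thresholds(cohort, alpha_fit = config$alpha_fit,
                                        min_subset = config$min_subset))
  threshold <- if (!is.null(config$threshold)) config$threshold
               else scan$selected_threshold
  if (is.na(threshold)) {
    stop("analysis stage 'filter' failed: no threshold selected and none configured",
         call. = FALSE)
  }
  filtered <- stage("filter", filter_by_experience(cohort, threshold))
  times <- completed_times(filtered)
  filtered_summary <- stage("summarize_f", summarize_times(times))

  fits <- stage("fit", fit_report(times))
  smry <- log_summary_of(times)

  exceedance <- stage("exceedance", lapply(config$tolerances, function(L) {
    counts <- count_exceedances(times, L, comparator = config$count_comparator)
    list(tolerance = L,
         gpq = gpq_exceedance_upper(smry, L, level = config$level,
                                    replications = config$replications,
                                    seed = stage_seed(config$seed,
                                                      paste0("gpq_", L))),
         noncentral_t = exceedance_upper_noncentral_t(smry, L,
                                                      level = config$level),
         counts = counts,
         clopper_pearson = list(
           upper_limit = clopper_pearson_upper(counts$x, counts$n,
                                               alpha = 1 - config$level),
           x = counts$x, n = counts$n, method = "clopper_pearson"))
  }))

  assoc <- stage("associate", {
    lapply(c(eti = "eti_prior_year", dlt = "dlt_prior_year"), function(col) {
      list(tau_b = kendall_tau_b(done[[col]], done$time_minutes),
           spearman = permutation_pvalue(
             done[[col]], done$time_minutes, statistic = spearman_rho,
             M = config$permutations, method = "monte_carlo",
             seed = stage_seed(config$seed, paste0("perm_", col))))
    })
  })

  structure(list(
    config = unclass(config),
    provenance = attr(cohort, "provenance"),
    n_total = nrow(cohort), n_completed = nrow(done),
    full_summary = summary_as_list(full_summary),
    scan = list(rows = scan$rows, selected_threshold = scan$selected_threshold),
    threshold_used = threshold,
    n_filtered = nrow(filtered),
    filtered_summary = summary_as_list(filtered_summary),
    fit = fits,
    exceedance = exceedance,
    association = assoc,
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "analysis_report")
}

#' Serialize an analysis report
#'
#' Writes \code{report.json} (machine surface) and \code{report.txt}
#' (human-readable, in the order of the analysis chain) into a directory.
#' Identical config and seed give byte-identical JSON apart from the
#' timestamp field.
#'
#' @param report an [run_analysis()] result.
#' @param dir output directory (created if needed).
#' @return paths of the written files, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  txt_path <- file.path(dir, "report.txt")
  clean <- rapply(unclass(report), function(x) x, how = "replace")
  jsonlite::write_json(clean, json_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  txt <- utils::capture.output(print(report))
  writeLines(txt, txt_path)
  invisible(c(json = json_path, txt = txt_path))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("Analysis report [%s]\n", x$provenance))
  cat(sprintf("Cohort: %d participants, %d completed\n", x$n_total,
              x$n_completed))
  cat("Full-cohort times: ")
  print(structure(x$full_summary, class = "summary_stats"))
  cat(sprintf("Experience threshold: %d (scan selected %s), retained n = %d\n",
              x$threshold_used, as.character(x$scan$selected_threshold),
              x$n_filtered))
  cat("Filtered times: ")
  print(structure(x$filtered_summary, class = "summary_stats"))
  print(x$fit)
  for (e in x$exceedance) {
    print(e$gpq)
    print(e$noncentral_t)
    cat(sprintf(
      "  binomial: %d/%d events, Clopper-Pearson %g%% upper limit %.3g%%\n",
      e$counts$x, e$counts$n, 100 * x$config$level,
      100 * e$clopper_pearson$upper_limit))
  }
  for (nm in names(x$association)) {
    a <- x$association[[nm]]
    cat(sprintf("%s counts vs time: tau_b = %.3g; ", nm, a$tau_b))
    print(a$spearman)
  }
  invisible(x)
}
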