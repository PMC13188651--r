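#' Kendall's tau-b rank concordance with tie correction
#'
#' tau_b = (P - Q) / sqrt((n0 - n1)(n0 - n2)) with P/Q the concordant and
#' discordant pair counts, n0 = n(n-1)/2, and n1/n2 the tied-pair counts
#' within x and y. Delegates to \code{stats::cor(method = "kendall")},
#' which implements exactly this estimator.
#'
#' @param x,y numeric vectors of equal length n >= 2.
#' @return tau_b in [-1, 1].
#' @export
kendall_tau_b <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 2) {
    stop("kendall_tau_b: need equal lengths >= 2", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("kendall_tau_b: all-tied input (zero denominator)", call. = FALSE)
  }
  stats::cor(x, y, method = "kendall")
}

#' Spearman rank correlation with midranks for ties
#'
#' Pearson correlation of the midranks (average ranks for ties).
#'
#' @param x,y numeric vectors of equal length n >= 3.
#' @return rho in [-1, 1].
#' @export
spearman_rho <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3) {
    stop("spearman_rho: need equal lengths >= 3", call. = FALSE)
  }
  if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0) {
    stop("spearman_rho: zero rank variance", call. = FALSE)
  }
  stats::cor(x, y, method = "spearman")
}

# all permutations of 1..n (n <= 8), for exhaustive enumeration
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (pos in seq_len(n)) {
    for (r in seq_len(nrow(sub))) {
      perm <- integer(n)
      perm[pos] <- n
      perm[-pos] <- sub[r, ]
      out[row, ] <- perm
      row <- row + 1L
    }
  }
  out
}

#' Permutation p-value for a rank association statistic
#'
#' Monte Carlo: permutes y \code{M} times and returns the add-one
#' estimator p = (1 + #{|T*| >= |T_obs| - 1e-12}) / (M + 1) (two-sided;
#' one-sided variants use the signed statistic). The +1 guarantees a
#' valid p-value with floor 1/(M+1). For n <= 7,
#' \code{method = "exact"} enumerates all n! permutations and returns the
#' exact permutation p-value #{|T*| >= |T_obs| - 1e-12} / n!.
#'
#' @param x,y numeric vectors of equal length.
#' @param statistic function(x, y) returning a scalar, e.g.
#'   [kendall_tau_b()] or [spearman_rho()].
#' @param M number of Monte Carlo permutations, >= 1000 for reported
#'   p-values.
#' @param seed integer seed (Monte Carlo mode).
#' @param sidedness \code{"two_sided"}, \code{"greater"} or \code{"less"}.
#' @param method \code{"auto"} (exact when n <= 7), \code{"monte_carlo"}
#'   or \code{"exact"}.
#' @return An object of class \code{association_result}: list(statistic_name,
#'   estimate, p_value, n_permutations, seed, method).
#' @export
permutation_pvalue <- function(x, y, statistic = kendall_tau_b, M = 50000L,
                               seed = 1L,
                               sidedness = c("two_sided", "greater", "less"),
                               method = c("auto", "monte_carlo", "exact")) {
  sidedness <- match.arg(sidedness)
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  stopifnot(length(y) == n)
  if (method == "auto") method <- if (n <= 7) "exact" else "monte_carlo"
  if (method == "exact" && n > 7) {
    stop("permutation_pvalue: exact enumeration limited to n <= 7", call. = FALSE)
  }
  t_obs <- statistic(x, y)
  eps <- 1e-12
  as_extreme <- function(t_star) {
    switch(sidedness,
           two_sided = abs(t_star) >= abs(t_obs) - eps,
           greater = t_star >= t_obs - eps,
           less = t_star <= t_obs + eps)
  }
  stat_name <- if (identical(statistic, kendall_tau_b)) "kendall_tau_b"
               else if (identical(statistic, spearman_rho)) "spearman_rho"
               else "custom"
  if (method == "exact") {
    perms <- all_permutations(n)
    t_star <- vapply(seq_len(nrow(perms)), function(r) {
      tryCatch(statistic(x, y[perms[r, ]]),
               error = function(e) stop("statistic failed on permutation ", r,
                                        ": ", conditionMessage(e), call. = FALSE))
    }, numeric(1))
    p <- mean(as_extreme(t_star))
    res <- list(statistic_name = stat_name, estimate = t_obs, p_value = p,
                n_permutations = nrow(perms), seed = NA_integer_,
                method = "exact")
  } else {
    M <- as.integer(M)
    if (M < 1000) stop("permutation_pvalue: need M >= 1000", call. = FALSE)
    set.seed(as.integer(seed))
    hits <- 0L
    for (r in seq_len(M)) {
      t_star <- tryCatch(statistic(x, sample(y)),
                         error = function(e) stop("statistic failed on permutation ",
                                                  r, ": ", conditionMessage(e),
                                                  call. = FALSE))
      hits <- hits + as_extreme(t_star)
    }
    res <- list(statistic_name = stat_name, estimate = t_obs,
                p_value = (1 + hits) / (M + 1), n_permutations = M,
                seed = as.integer(seed), method = "monte_carlo")
  }
  structure(res, class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("%s = %.4g, %s permutation p = %.4g (%d permutations)\n",
              x$statistic_name, x$estimate, x$method, x$p_value,
              x$n_permutations))
  invisible(x)
}
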