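#' Mann-Whitney U comparison with a minimum-sample-size exclusion rule
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test on end-range
#' magnitudes. The exact null distribution is used when the combined sample
#' size is at most 20 and there are no ties; otherwise the normal
#' approximation with tie and continuity corrections. Comparisons where
#' either group is smaller than `min_n` (default 7, the minimum group size
#' this analysis accepts for testing) are excluded rather than tested.
#'
#' @param x,y numeric vectors (degrees); magnitudes are compared.
#' @param min_n minimum group size for testing (default 7).
#' @param exact force the exact (`TRUE`) or approximate (`FALSE`) p-value;
#'   default `NULL` applies the size/ties rule above.
#' @return An object of class `"comparison_result"`: list with `test`,
#'   `n1`, `n2`, `statistic` (U), `p`, `exact`, `status`
#'   (`"tested"` or `"excluded-small-n"`).
#' @examples
#' ranksum_compare(1:8, 11:18, min_n = 2)  # exact p = 2/choose(16, 8)
#' @export
ranksum_compare <- function(x, y, min_n = 7, exact = NULL) {
  x <- abs(as.numeric(x)); y <- abs(as.numeric(y))
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  res <- structure(list(test = "Mann-Whitney U", n1 = n1, n2 = n2,
                        statistic = NA_real_, p = NA_real_, exact = NA,
                        status = "excluded-small-n"),
                   class = "comparison_result")
  if (min(n1, n2) < min_n) return(res)
  if (is.null(exact)) exact <- (n1 + n2 <= 20) && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  res$statistic <- unname(wt$statistic)
  res$p <- wt$p.value
  res$exact <- exact
  res$status <- "tested"
  res
}

#' @export
print.comparison_result <- function(x, ...) {
  if (x$status == "tested") {
    cat(sprintf("<comparison_result> %s (n1 = %d, n2 = %d, %s): U = %g, p = %.4g\n",
                x$test, x$n1, x$n2,
                if (isTRUE(x$exact)) "exact" else "approximate",
                x$statistic, x$p))
  } else {
    cat(sprintf("<comparison_result> %s (n1 = %d, n2 = %d): %s\n",
                x$test, x$n1, x$n2, x$status))
  }
  invisible(x)
}

#' Per-level comparison of type C and type S end-ranges
#'
#' For each direction and joint level, compares the end-range magnitudes of
#' type C and type S records with [ranksum_compare()], applying the n >= 7
#' exclusion rule per group.
#'
#' @param records classified records data frame.
#' @param min_n minimum group size (default 7).
#' @return Data frame with `direction`, `level`, `n_C`, `n_S`,
#'   `mean_C`, `mean_S`, `U`, `p`, `status`.
#' @export
compare_type_endrange <- function(records, min_n = 7) {
  .check_records(records, c("end_range", "joint", "direction", "motion_type"))
  rows <- list()
  for (d in intersect(motion_directions(), unique(records$direction))) {
    for (j in joint_levels()) {
      sub <- records[records$direction == d & records$joint == j, ,
                     drop = FALSE]
      xc <- abs(sub$end_range[sub$motion_type == "C"])
      xs <- abs(sub$end_range[sub$motion_type == "S"])
      cr <- ranksum_compare(xc, xs, min_n = min_n)
      rows[[length(rows) + 1L]] <- data.frame(
        direction = d, level = j, n_C = length(xc), n_S = length(xs),
        mean_C = if (length(xc)) mean(xc) else NA_real_,
        mean_S = if (length(xs)) mean(xs) else NA_real_,
        U = cr$statistic, p = cr$p, status = cr$status,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Independent-samples t-test between flexion and extension magnitudes
#'
#' Welch's unequal-variance t-test by default (`var_equal = TRUE` for the
#' pooled-variance version). When both groups are constant with equal means
#' the test statistic is defined as 0 with p = 1.
#'
#' @param flexion_vals,extension_vals numeric vectors (degrees; magnitudes
#'   are compared), each of length >= 2.
#' @param var_equal pool the variances (default FALSE = Welch).
#' @return A `"comparison_result"` with `test`, `n1`, `n2`, `statistic`
#'   (t), `df`, `p`, `status`.
#' @export
ttest_direction <- function(flexion_vals, extension_vals, var_equal = FALSE) {
  x <- abs(as.numeric(flexion_vals)); y <- abs(as.numeric(extension_vals))
  if (length(x) < 2L || length(y) < 2L)
    cervik_stop("cervik_insufficient_data",
                "each group needs at least 2 values")
  res <- structure(list(test = if (var_equal) "t (pooled)" else "t (Welch)",
                        n1 = length(x), n2 = length(y),
                        statistic = NA_real_, df = NA_real_, p = NA_real_,
                        exact = NA, status = "tested"),
                   class = "comparison_result")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) {
      res$statistic <- 0; res$p <- 1
    } else {
      res$statistic <- sign(mean(x) - mean(y)) * Inf; res$p <- 0
    }
    return(res)
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  res$statistic <- unname(tt$statistic)
  res$df <- unname(tt$parameter)
  res$p <- tt$p.value
  res
}

#' Normality checks (Shapiro-Wilk and Lilliefors/Kolmogorov-Smirnov)
#'
#' Both tests' statistics and p-values are returned; they annotate the
#' reports and never gate any downstream computation. The
#' Kolmogorov-Smirnov test uses the Lilliefors correction for estimated
#' mean and variance (as statistical packages report for normality
#' screening); it requires n >= 4 and is returned as NA for n = 3.
#'
#' @param vals numeric vector, n >= 3.
#' @return List with elements `shapiro` and `ks`, each a list holding
#'   `statistic` and `p`.
#' @export
normality_check <- function(vals) {
  x <- as.numeric(vals)
  x <- x[is.finite(x)]
  if (length(x) < 3L)
    cervik_stop("cervik_insufficient_data",
                "normality checks need at least 3 values, got %d", length(x))
  sw <- stats::shapiro.test(x)
  ks <- if (length(x) >= 4L && stats::sd(x) > 0) {
    lt <- nortest::lillie.test(x)
    list(statistic = unname(lt$statistic), p = lt$p.value)
  } else {
    list(statistic = NA_real_, p = NA_real_)
  }
  list(shapiro = list(statistic = unname(sw$statistic), p = sw$p.value),
       ks = ks)
}
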