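#' Cohort analysis of cervical joint motion
#'
#' The package's main entry point: takes per-record joint motion data and
#' produces the full cohort analysis — motion-type classification and
#' proportions, pro-directional surplus statistics by level and region,
#' quartile tables of surplus against end-range, anti-directional tables,
#' per-level maxima, boundary-crossing frequencies, and Mann-Whitney U
#' comparisons of type C versus type S end-ranges with the n >= 7 exclusion
#' rule.
#'
#' @param x one of: a records data frame (as from [summaries_records()]), a
#'   list of [joint_trajectory()] objects, or a [simulate_cohort()] result.
#'   Trajectories are hold-trimmed and summarised first.
#' @param epsilon C/S classification tolerance in degrees (see
#'   [classify_joint()]).
#' @param min_n minimum group size for statistical comparisons (default 7).
#' @param resolution `"epochs"` (default) or `"frames"`: where extremes are
#'   read (see [motion_summary()]).
#' @param n_epochs number of epochs (default 10).
#' @param boundary_window epoch-boundary averaging half-width in frames.
#' @param start_hold,end_hold hold durations trimmed from trajectories, in
#'   seconds (ignored when `x` is already a records data frame).
#' @return An object of class `"cervik"`: a list with `records` (classified
#'   data frame), `tables` (per-direction `type_proportions`,
#'   `surplus_by_level`, `surplus_by_region`, `surplus_all`, `quartiles`,
#'   `anti_directional`, `max_demonstrated`), `frequency`, `comparisons`,
#'   and `params`.
#' @examples
#' co <- simulate_cohort(cohort_spec(n_subjects = 4, noise_sd = 0), seed = 2)
#' fit <- cervik(co)
#' fit
#' @export
cervik <- function(x, epsilon = 0, min_n = 7,
                   resolution = c("epochs", "frames"), n_epochs = 10,
                   boundary_window = 0, start_hold = 2, end_hold = 2) {
  resolution <- match.arg(resolution)
  if (inherits(x, "cervik_cohort")) {
    start_hold <- x$spec$hold
    end_hold <- x$spec$hold
    x <- x$trajectories
  }
  if (is.list(x) && !is.data.frame(x) &&
      all(vapply(x, inherits, logical(1), "joint_trajectory"))) {
    summaries <- lapply(x, function(tr) {
      motion_summary(trim_holds(tr, start_hold, end_hold),
                     resolution = resolution, n_epochs = n_epochs,
                     boundary_window = boundary_window)
    })
    records <- summaries_records(summaries)
  } else if (is.data.frame(x)) {
    records <- x
  } else {
    cervik_stop("cervik_invalid_argument",
                "x must be records, trajectories or a cervik_cohort")
  }
  if (nrow(records) == 0L)
    cervik_stop("cervik_empty_cohort", "no records to analyse")
  records <- classify_records(records, epsilon = epsilon)
  dirs <- intersect(motion_directions(), unique(records$direction))
  tables <- lapply(dirs, function(d) {
    sub <- records[records$direction == d, , drop = FALSE]
    has_s <- any(sub$motion_type == "S")
    list(
      type_proportions = type_proportions(sub),
      surplus_by_level = if (has_s)
        suppressMessages(surplus_statistics(sub, "level")),
      surplus_by_region = if (has_s)
        suppressMessages(surplus_statistics(sub, "region")),
      surplus_all = if (has_s)
        suppressMessages(surplus_statistics(sub, "all")),
      quartiles = if (has_s) quartile_table(records, d),
      anti_directional = anti_directional_table(records, d),
      max_demonstrated = max_demonstrated(records, d))
  })
  names(tables) <- dirs
  structure(list(records = records, tables = tables,
                 frequency = frequency_stats(records),
                 comparisons = compare_type_endrange(records, min_n = min_n),
                 params = list(epsilon = epsilon, min_n = min_n,
                               resolution = resolution, n_epochs = n_epochs,
                               boundary_window = boundary_window,
                               start_hold = start_hold,
                               end_hold = end_hold)),
            class = "cervik")
}

#' @export
print.cervik <- function(x, ...) {
  cat(sprintf("<cervik> cohort analysis: %d records, %d subject(s)\n",
              nrow(x$records), length(unique(x$records$subject))))
  for (d in names(x$tables)) {
    tp <- x$tables[[d]]$type_proportions
    cat(sprintf("  %-9s n = %3d: C %5.1f%%  S %5.1f%%  A %5.1f%%\n", d,
                sum(tp$count), tp$percent[1], tp$percent[2], tp$percent[3]))
  }
  if (!is.na(x$frequency$one_in_n))
    cat(sprintf("  anti-directional end-range: 1 in %d joints\n",
                x$frequency$one_in_n))
  cat(sprintf("  (%s resolution, epsilon %g deg, min n %d)\n",
              x$params$resolution, x$params$epsilon, x$params$min_n))
  invisible(x)
}

#' @export
summary.cervik <- function(object, ...) {
  structure(object, class = c("summary.cervik", "cervik"))
}

#' @export
print.summary.cervik <- function(x, ...) {
  print.cervik(x)
  for (d in names(x$tables)) {
    tb <- x$tables[[d]]
    cat(sprintf("\n== %s ==\n", d))
    cat("-- motion types --\n")
    print(tb$type_proportions, row.names = FALSE)
    if (!is.null(tb$surplus_by_level)) {
      cat("-- pro-directional surplus (type S), by level --\n")
      print(.round_df(tb$surplus_by_level), row.names = FALSE)
    }
    if (!is.null(tb$quartiles)) {
      cat("-- surplus by end-range quartile --\n")
      print(.round_df(tb$quartiles), row.names = FALSE)
    }
    cat("-- anti-directional motion --\n")
    print(.round_df(tb$anti_directional), row.names = FALSE)
    cat("-- maximum demonstrated motion --\n")
    print(.round_df(tb$max_demonstrated), row.names = FALSE)
  }
  cat("\n-- type C vs type S end-range (Mann-Whitney U) --\n")
  print(.round_df(x$comparisons, 4), row.names = FALSE)
  invisible(x)
}

.round_df <- function(df, digits = 2) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  df
}

#' Plot a cohort analysis or a joint trajectory
#'
#' For a `"cervik"` object: stacked per-level motion-type counts, one panel
#' per direction. For a `"joint_trajectory"`: position against time with
#' epoch boundaries, the end-range and the maximum marked.
#'
#' @param x a `"cervik"` or `"joint_trajectory"` object.
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.cervik <- function(x, ...) {
  dirs <- names(x$tables)
  op <- par(mfrow = c(1, length(dirs)), mar = c(7, 4, 3, 1))
  on.exit(par(op))
  cols <- c(C = "grey35", S = "tomato3", A = "steelblue4")
  for (d in dirs) {
    sub <- x$records[x$records$direction == d, ]
    counts <- table(sub$motion_type, factor(sub$joint, joint_levels()))
    barplot(counts, col = cols[rownames(counts)], las = 2, main = d,
            ylab = "joints", border = NA)
    legend("topright", legend = rownames(counts), fill = cols, bty = "n")
  }
  invisible(x)
}

#' @rdname plot.cervik
#' @param n_epochs epochs drawn for a trajectory plot.
#' @export
plot.joint_trajectory <- function(x, n_epochs = 10, ...) {
  plot(x$times, x$position, type = "l", lwd = 1.5,
       xlab = "time (s)", ylab = "position (deg)",
       main = sprintf("%s %s", x$joint, x$direction))
  es <- segment_epochs(x$position, n_epochs = n_epochs)
  abline(v = x$times[es$boundary_indices],
         col = adjustcolor("grey50", 0.5), lty = 3)
  abline(h = 0, col = "grey30")
  points(x$times[es$boundary_indices], x$position[es$boundary_indices],
         pch = 19, cex = 0.6, col = "tomato3")
  invisible(x)
}
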