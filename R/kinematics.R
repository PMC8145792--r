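#' Remove the upright and end-range holds from a trajectory
#'
#' The recording protocol holds the upright posture at the start and the
#' end-range posture at the end of each excursion (2 s each by default).
#' Frames falling inside those windows are dropped; the retained excursion
#' keeps its original times and positions.
#'
#' @param traj a [joint_trajectory()].
#' @param start_hold,end_hold hold durations in seconds (>= 0); their sum
#'   must be smaller than the total recording duration.
#' @return The trimmed [joint_trajectory()].
#' @examples
#' tr <- joint_trajectory("C3/C4", "extension", seq(0, 16, 0.04),
#'                        sin(seq(0, 16, 0.04) / 6))
#' length(trim_holds(tr)$times)  # 301 of 401 frames retained
#' @export
trim_holds <- function(traj, start_hold = 2, end_hold = 2) {
  if (!inherits(traj, "joint_trajectory"))
    cervik_stop("cervik_invalid_argument", "traj must be a joint_trajectory")
  if (start_hold < 0 || end_hold < 0)
    cervik_stop("cervik_invalid_argument", "hold durations must be >= 0")
  total <- diff(range(traj$times))
  if (start_hold + end_hold >= total)
    cervik_stop("cervik_empty_excursion",
                "holds (%g + %g s) leave no excursion in a %g s recording",
                start_hold, end_hold, total)
  keep <- traj$times >= traj$times[1] + start_hold &
    traj$times <= traj$times[length(traj$times)] - end_hold
  if (sum(keep) < 2L)
    cervik_stop("cervik_empty_excursion",
                "fewer than 2 frames remain after hold trimming")
  joint_trajectory(traj$joint, traj$direction, traj$times[keep],
                   traj$position[keep],
                   raw_angle = traj$raw_angle[keep], subject = traj$subject)
}

#' Segment a position sequence into 10% time epochs
#'
#' Divides an excursion of N samples into `n_epochs` equal time epochs.
#' Boundary k (k = 0...n_epochs) sits at sample index
#' `round(k * (N - 1) / n_epochs)` (round-half-to-even); cumulative boundary
#' positions are re-zeroed to boundary 0, and per-epoch displacements are
#' their successive differences, so they telescope exactly to the end-range.
#'
#' @param positions numeric vector of joint positions (degrees), one per
#'   frame of the trimmed excursion; at least `n_epochs + 1` samples.
#' @param n_epochs number of epochs (default 10).
#' @param boundary_window frames averaged on each side of a boundary when
#'   reading its position (default 0 = the single boundary sample). A small
#'   window suppresses per-frame marking noise; windows are clipped at the
#'   excursion ends.
#' @return An object of class `"epoch_series"`: a list with `n_epochs`,
#'   `boundary_indices` (1-based sample indices, length `n_epochs + 1`),
#'   `cumulative` (boundary positions re-zeroed to boundary 0) and
#'   `per_epoch` (signed per-epoch displacements).
#' @examples
#' es <- segment_epochs(seq(0, 10, length.out = 101))
#' es$per_epoch    # all 1.0
#' @export
segment_epochs <- function(positions, n_epochs = 10, boundary_window = 0) {
  positions <- as.numeric(positions)
  n <- length(positions)
  if (n_epochs < 1L)
    cervik_stop("cervik_invalid_argument", "n_epochs must be >= 1")
  if (n < n_epochs + 1L)
    cervik_stop("cervik_insufficient_frames",
                "need at least %d samples for %d epochs, got %d",
                n_epochs + 1L, n_epochs, n)
  idx <- round((0:n_epochs) * (n - 1) / n_epochs) + 1L
  if (boundary_window > 0) {
    vals <- vapply(idx, function(i) {
      lo <- max(1L, i - boundary_window)
      hi <- min(n, i + boundary_window)
      mean(positions[lo:hi])
    }, numeric(1))
  } else {
    vals <- positions[idx]
  }
  cumulative <- vals - vals[1]
  structure(list(n_epochs = as.integer(n_epochs),
                 boundary_indices = as.integer(idx),
                 cumulative = cumulative,
                 per_epoch = diff(cumulative)),
            class = "epoch_series")
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf("<epoch_series> %d epochs, end-range %.3f deg\n",
              x$n_epochs, x$cumulative[length(x$cumulative)]))
  print(round(x$per_epoch, 3))
  invisible(x)
}

#' Pro-/anti-directional decomposition of a position sequence
#'
#' After normalising the sequence so that pro-directional motion is positive
#' (flexion positions are multiplied by -1), the pro-directional sum is the
#' total of positive frame-to-frame increments and the anti-directional sum
#' the magnitude of the negative ones. Their difference is the resultant,
#' i.e. the net displacement from first to last sample.
#'
#' @param positions numeric vector (degrees, signed convention:
#'   extension-positive), length >= 2.
#' @param direction `"flexion"` or `"extension"`: the direction of the
#'   global neck motion.
#' @return List with `pro_sum`, `anti_sum` (both >= 0) and `resultant`
#'   (degrees, pro-positive).
#' @examples
#' directional_decomposition(c(0, 2, 1, 3), "extension")  # pro 4, anti 1
#' @export
directional_decomposition <- function(positions, direction) {
  .assert_direction(direction)
  if (length(positions) < 2L)
    cervik_stop("cervik_insufficient_frames",
                "need at least 2 samples for a decomposition")
  d <- diff(.pro_sign(direction) * as.numeric(positions))
  pro <- sum(d[d > 0])
  anti <- -sum(d[d < 0])
  list(pro_sum = pro, anti_sum = anti, resultant = pro - anti)
}

#' Per-joint motion summary
#'
#' Extracts the quantities the epoch analysis is built on, all in
#' pro-directional degrees (pro-positive): end-range (final position),
#' maximum pro-directional position (`max_pro`, with the start counting as
#' attainable, hence >= 0), the anti-directional extreme (`min_pos` <= 0),
#' pro-directional surplus (`max_pro - end_range`), anti-directional surplus
#' (`|min_pos|`), the epoch in which the maximum is first attained, boundary
#' crossing flags, the pro-/anti-directional sums, and `never_pro` (the
#' joint never passed upright pro-directionally after the start).
#'
#' Extremes are read at the chosen resolution: `"epochs"` (default) uses the
#' 11 epoch-boundary positions, which is robust to single-frame noise;
#' `"frames"` uses every sample.
#'
#' @param traj a trimmed [joint_trajectory()]; trajectories with holds still
#'   attached are accepted (the holds then simply contribute samples).
#' @param resolution `"epochs"` or `"frames"`.
#' @param n_epochs number of epochs (default 10).
#' @param boundary_window see [segment_epochs()].
#' @return An object of class `"joint_motion_summary"` (a list; see Details).
#' @examples
#' tr <- joint_trajectory("C1/C2", "extension", 0:20, c(seq(0, 5, 0.5), rep(4.5, 10)))
#' motion_summary(tr, n_epochs = 10)
#' @export
motion_summary <- function(traj, resolution = c("epochs", "frames"),
                           n_epochs = 10, boundary_window = 0) {
  resolution <- match.arg(resolution)
  if (!inherits(traj, "joint_trajectory"))
    cervik_stop("cervik_invalid_argument", "traj must be a joint_trajectory")
  s <- .pro_sign(traj$direction)
  norm <- s * traj$position
  es <- segment_epochs(norm, n_epochs = n_epochs,
                       boundary_window = boundary_window)
  if (resolution == "epochs") {
    series <- es$cumulative
  } else {
    series <- norm - norm[1]
  }
  end_range <- es$cumulative[n_epochs + 1L]
  if (resolution == "frames") end_range <- series[length(series)]
  max_pro <- max(series)
  min_pos <- min(series)
  i_max <- which.max(series)
  if (resolution == "epochs") {
    epoch_of_max <- max(i_max - 1L, 1L)
  } else {
    frame_of_max <- i_max
    epoch_of_max <- which(es$boundary_indices[-1] >= frame_of_max)[1]
    if (is.na(epoch_of_max)) epoch_of_max <- n_epochs
  }
  dec <- if (resolution == "epochs") {
    d <- diff(series)
    list(pro_sum = sum(d[d > 0]), anti_sum = -sum(d[d < 0]))
  } else {
    directional_decomposition(traj$position, traj$direction)
  }
  structure(list(
    joint = traj$joint, direction = traj$direction, subject = traj$subject,
    resolution = resolution,
    end_range = end_range,
    max_pro = max_pro,
    min_pos = min_pos,
    surplus_pro = max_pro - end_range,
    surplus_anti = -min(min_pos, 0),
    epoch_of_max = as.integer(epoch_of_max),
    passed_endrange_pro = max_pro > end_range,
    passed_upright_anti = min_pos < 0,
    pro_sum = dec$pro_sum,
    anti_sum = dec$anti_sum,
    never_pro = max(series[-1]) <= 0,
    epochs = es),
    class = "joint_motion_summary")
}

#' @export
print.joint_motion_summary <- function(x, ...) {
  cat(sprintf("<joint_motion_summary> %s %s (%s, %s resolution)\n",
              x$joint, x$direction,
              if (is.na(x$subject)) "?" else x$subject, x$resolution))
  cat(sprintf("  end-range %.3f  max %.3f  surplus pro %.3f  surplus anti %.3f  epoch of max %d\n",
              x$end_range, x$max_pro, x$surplus_pro, x$surplus_anti,
              x$epoch_of_max))
  invisible(x)
}

#' Collect joint motion summaries into a records data frame
#'
#' @param summaries a list of `"joint_motion_summary"` objects.
#' @return A data frame with one row per summary and the summary fields as
#'   columns (without the embedded epoch series).
#' @export
summaries_records <- function(summaries) {
  if (inherits(summaries, "joint_motion_summary")) summaries <- list(summaries)
  stopifnot(all(vapply(summaries, inherits, logical(1),
                       "joint_motion_summary")))
  cols <- c("subject", "joint", "direction", "end_range", "max_pro",
            "min_pos", "surplus_pro", "surplus_anti", "epoch_of_max",
            "passed_endrange_pro", "passed_upright_anti", "pro_sum",
            "anti_sum", "never_pro")
  out <- lapply(cols, function(cl)
    unlist(lapply(summaries, function(s) s[[cl]]), use.names = FALSE))
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE)
}
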