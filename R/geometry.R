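## Landmark scheme: the marking points are the 2 anterior and 2 posterior
## external occiput markers (C0), the centers of the anterior and posterior
## arch medullary cavities of the atlas (C1), the 2 inferior corners of the
## axis (C2), the anterior/posterior corners of the superior and inferior
## endplates of C3-C6, and the 2 superior corners of C7 -- 26 named points.
.landmark_map <- local({
  m <- list(
    C0 = list(ant = c("C0_ant_1", "C0_ant_2"),
              post = c("C0_post_1", "C0_post_2")),
    C1 = list(ant = "C1_ant_arc", post = "C1_post_arc"),
    C2 = list(ant = "C2_inf_ant", post = "C2_inf_post"))
  for (v in paste0("C", 3:6)) {
    m[[v]] <- list(ant = paste0(v, c("_ant_sup", "_ant_inf")),
                   post = paste0(v, c("_post_sup", "_post_inf")))
  }
  m$C7 <- list(ant = "C7_sup_ant", post = "C7_sup_post")
  m
})

#' Canonical landmark identifiers
#'
#' The fixed enumeration of the 26 named osseous points used by the
#' landmark-based geometry: four external occiput markers (C0), the anterior
#' and posterior arch centers of the atlas (C1), the two inferior corners of
#' the axis (C2), the four endplate corners of each of C3--C6, and the two
#' superior corners of C7.
#'
#' @param vertebra optionally restrict to one vertebra (`"C0"` ... `"C7"`).
#' @return Character vector of landmark ids.
#' @examples
#' length(landmark_ids())   # 26
#' landmark_ids("C1")
#' @export
landmark_ids <- function(vertebra = NULL) {
  m <- .landmark_map
  if (!is.null(vertebra)) {
    if (!vertebra %in% names(m))
      cervik_stop("cervik_invalid_argument", "unknown vertebra '%s'", vertebra)
    m <- m[vertebra]
  }
  unname(unlist(lapply(m, function(g) c(g$ant, g$post))))
}

.as_point_matrix <- function(points) {
  if (is.list(points) && !is.data.frame(points)) {
    points <- do.call(rbind, points)
  }
  points <- as.matrix(points)
  if (ncol(points) != 2L)
    cervik_stop("cervik_invalid_argument", "points must be n x 2 (x, y)")
  storage.mode(points) <- "double"
  points
}

#' Vertebral midplane angle from landmarks
#'
#' Computes the orientation of one vertebra's midplane: the directed line
#' from the posterior reference midpoint to the anterior reference midpoint
#' (C0: means of the paired external markers; C1: anterior to posterior arch
#' center; C2: inferior corners; C3--C6: means of the anterior and posterior
#' endplate-corner pairs; C7: superior corners). The angle is measured
#' counterclockwise from the horizontal and mapped to the half-open interval
#' (-90, 90] degrees. Data recorded with the subject facing -x are mirrored
#' into the canonical +x frame first.
#'
#' @param points named list or matrix (rownames = landmark ids) of 2D
#'   coordinates containing at least the required ids for `vertebra`.
#' @param vertebra one of `"C0"` ... `"C7"`.
#' @param facing `"+x"` if the subject faces towards positive x, `"-x"`
#'   otherwise.
#' @return Midplane angle in degrees, CCW-positive, in (-90, 90].
#' @examples
#' midplane_angle(list(C1_ant_arc = c(5, 5), C1_post_arc = c(0, 0)), "C1")
#' @export
midplane_angle <- function(points, vertebra, facing = c("+x", "-x")) {
  facing <- match.arg(facing)
  if (!vertebra %in% names(.landmark_map))
    cervik_stop("cervik_invalid_argument", "unknown vertebra '%s'", vertebra)
  pts <- .as_point_matrix(points)
  need <- landmark_ids(vertebra)
  missing_ids <- setdiff(need, rownames(pts))
  if (length(missing_ids))
    cervik_stop("cervik_missing_landmark",
                "vertebra %s: missing landmark(s) %s", vertebra,
                paste(missing_ids, collapse = ", "))
  if (any(!is.finite(pts[need, ])))
    cervik_stop("cervik_invalid_argument",
                "vertebra %s: non-finite landmark coordinates", vertebra)
  if (facing == "-x") pts[, 1] <- -pts[, 1]
  grp <- .landmark_map[[vertebra]]
  ant <- colMeans(pts[grp$ant, , drop = FALSE])
  post <- colMeans(pts[grp$post, , drop = FALSE])
  v <- ant - post
  scale <- max(abs(pts[need, ])) + 1
  if (sqrt(sum(v^2)) < 1e-9 * scale)
    cervik_stop("cervik_degenerate_geometry",
                "vertebra %s: anterior and posterior reference points coincide",
                vertebra)
  .wrap_halfturn(atan2(v[2], v[1]) * 180 / pi)
}

## map an angle in degrees to (-90, 90]: midplane orientation is a line,
## defined modulo 180 degrees
.wrap_halfturn <- function(a) {
  r <- a %% 180
  r[r > 90] <- r[r > 90] - 180
  r
}

#' Midplane angles for every vertebra in a frame
#'
#' @inheritParams midplane_angle
#' @return Named numeric vector, one angle per vertebra C0...C7 present in
#'   `points` (all eight are required).
#' @export
midplane_angles <- function(points, facing = c("+x", "-x")) {
  facing <- match.arg(facing)
  vapply(vertebra_ids(), function(v) midplane_angle(points, v, facing),
         numeric(1))
}

#' Relative joint rotation from two midplane angles
#'
#' The rotation of an intervertebral joint is the difference between the
#' midplane angles of its cranial (upper) and caudal (lower) vertebrae. In
#' the canonical frame a positive value is extension and a negative value
#' flexion.
#'
#' @param theta_upper,theta_lower midplane angles in degrees.
#' @return `theta_upper - theta_lower`, in degrees.
#' @examples
#' joint_rotation(5, 0)   # +5 degrees: extension
#' joint_rotation(-3, 2)  # -5 degrees: flexion
#' @export
joint_rotation <- function(theta_upper, theta_lower) {
  if (any(!is.finite(theta_upper)) || any(!is.finite(theta_lower)))
    cervik_stop("cervik_invalid_angle", "non-finite midplane angle")
  theta_upper - theta_lower
}

#' Construct a landmark sequence
#'
#' A landmark sequence holds one subject-direction recording: strictly
#' increasing frame times and a `frames x 26 x 2` coordinate array with the
#' landmark ids of [landmark_ids()] as its second dimension names.
#'
#' @param subject subject identifier.
#' @param direction `"flexion"` or `"extension"`.
#' @param times numeric vector of frame times in seconds, strictly
#'   increasing, length >= 2.
#' @param coords numeric array `length(times) x 26 x 2`.
#' @param frame_rate frames per second (> 0).
#' @return An object of class `"landmark_sequence"`.
#' @export
landmark_sequence <- function(subject, direction, times, coords,
                              frame_rate = 25) {
  .assert_direction(direction)
  if (length(times) < 2L)
    cervik_stop("cervik_invalid_argument", "need at least 2 frames")
  if (any(diff(times) <= 0))
    cervik_stop("cervik_invalid_argument", "times must be strictly increasing")
  if (!is.numeric(frame_rate) || frame_rate <= 0)
    cervik_stop("cervik_invalid_argument", "frame_rate must be positive")
  coords <- as.array(coords)
  if (length(dim(coords)) != 3L || dim(coords)[1] != length(times) ||
      dim(coords)[3] != 2L)
    cervik_stop("cervik_invalid_argument",
                "coords must be a frames x landmarks x 2 array")
  ids <- dimnames(coords)[[2]]
  if (is.null(ids) || !setequal(ids, landmark_ids()))
    cervik_stop("cervik_invalid_argument",
                "coords landmark names must be the 26 canonical ids")
  coords <- coords[, landmark_ids(), , drop = FALSE]
  if (any(!is.finite(coords)))
    cervik_stop("cervik_invalid_argument", "non-finite landmark coordinates")
  structure(list(subject = as.character(subject), direction = direction,
                 frame_rate = frame_rate, times = as.numeric(times),
                 coords = coords),
            class = "landmark_sequence")
}

#' @export
print.landmark_sequence <- function(x, ...) {
  cat(sprintf("<landmark_sequence> subject %s, %s: %d frames @ %g fps (%.2f-%.2f s)\n",
              x$subject, x$direction, length(x$times), x$frame_rate,
              min(x$times), max(x$times)))
  invisible(x)
}

#' Construct a joint-angle trajectory
#'
#' @param joint joint label, e.g. `"C3/C4"`.
#' @param direction `"flexion"` or `"extension"`.
#' @param times frame times in seconds, strictly increasing.
#' @param position joint position in degrees relative to the upright
#'   reference, extension-positive (canonical signed convention).
#' @param raw_angle optional raw joint rotation before re-referencing.
#' @param subject optional subject identifier.
#' @return An object of class `"joint_trajectory"`.
#' @export
joint_trajectory <- function(joint, direction, times, position,
                             raw_angle = NULL, subject = NA_character_) {
  if (!joint %in% joint_levels())
    cervik_stop("cervik_invalid_argument", "unknown joint '%s'", joint)
  .assert_direction(direction)
  if (length(times) != length(position))
    cervik_stop("cervik_invalid_argument",
                "times and position must have equal length")
  if (any(diff(times) <= 0))
    cervik_stop("cervik_invalid_argument", "times must be strictly increasing")
  structure(list(joint = joint, direction = direction, subject = subject,
                 times = as.numeric(times), position = as.numeric(position),
                 raw_angle = if (!is.null(raw_angle)) as.numeric(raw_angle)),
            class = "joint_trajectory")
}

#' @export
print.joint_trajectory <- function(x, ...) {
  cat(sprintf("<joint_trajectory> %s %s (%s): %d frames, %.2f-%.2f s, end position %.2f deg\n",
              x$joint, x$direction,
              if (is.na(x$subject)) "?" else x$subject,
              length(x$times), min(x$times), max(x$times),
              x$position[length(x$position)]))
  invisible(x)
}

#' Joint-angle trajectories from a landmark sequence
#'
#' Computes, frame by frame, the eight vertebral midplane angles and the
#' seven intervertebral joint rotations, then re-references each joint to
#' its upright position: either the first frame or the mean raw angle over
#' the initial hold window (default, which averages marking noise).
#'
#' @param seq a [landmark_sequence()].
#' @param upright_reference `"initial-hold-mean"` (default) or
#'   `"first-frame"`.
#' @param hold_duration length of the initial upright hold in seconds (used
#'   only for `"initial-hold-mean"`); must be positive and no longer than
#'   the recording.
#' @param facing `"+x"` if the subject faces positive x.
#' @return Named list of seven [joint_trajectory()] objects
#'   (`"C0/C1"` ... `"C6/C7"`).
#' @export
angle_trajectories <- function(seq,
                               upright_reference = c("initial-hold-mean",
                                                     "first-frame"),
                               hold_duration = 2, facing = c("+x", "-x")) {
  upright_reference <- match.arg(upright_reference)
  facing <- match.arg(facing)
  if (!inherits(seq, "landmark_sequence"))
    cervik_stop("cervik_invalid_argument", "seq must be a landmark_sequence")
  n <- length(seq$times)
  theta <- matrix(NA_real_, n, 8, dimnames = list(NULL, vertebra_ids()))
  for (f in seq_len(n)) {
    theta[f, ] <- tryCatch(
      midplane_angles(seq$coords[f, , ], facing = facing),
      cervik_error = function(e) {
        cervik_stop(class(e)[1], "frame %d: %s", f, conditionMessage(e))
      })
  }
  rot <- theta[, 1:7, drop = FALSE] - theta[, 2:8, drop = FALSE]
  colnames(rot) <- joint_levels()
  if (upright_reference == "first-frame") {
    ref <- rot[1, ]
  } else {
    if (!is.numeric(hold_duration) || hold_duration <= 0 ||
        hold_duration > diff(range(seq$times)))
      cervik_stop("cervik_invalid_argument",
                  "hold_duration must be in (0, total duration]")
    win <- seq$times <= seq$times[1] + hold_duration
    ref <- colMeans(rot[win, , drop = FALSE])
  }
  out <- lapply(joint_levels(), function(j) {
    joint_trajectory(j, seq$direction, seq$times,
                     position = rot[, j] - ref[[j]], raw_angle = rot[, j],
                     subject = seq$subject)
  })
  names(out) <- joint_levels()
  out
}
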