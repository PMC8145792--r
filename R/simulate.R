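## synthetic trajectory / cohort generator; every output carries the ground
## truth it was built from, so downstream recovery can be verified exactly

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (!is.numeric(seed) || seed != as.integer(seed))
    cervik_stop("cervik_invalid_argument", "seed must be an integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

## one-sided truncated normal by rejection; clamps to the bound after 200
## failed proposals (only reachable with extreme parameter choices)
.rtrunc_norm <- function(n, mean, sd, lower) {
  out <- stats::rnorm(n, mean, sd)
  for (i in seq_len(200)) {
    bad <- out < lower
    if (!any(bad)) break
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmax(out, lower)
}

## cubic smoothstep: C1, monotone on [0, 1], zero slope at both ends
.smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

## evaluate a knot profile: smoothstep interpolation between successive
## (s, value) control points; plateaus are consecutive equal-value knots
.eval_knots <- function(s, knots) {
  ks <- knots$s; kv <- knots$v
  i <- findInterval(s, ks, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(ks) - 1L)
  u <- (s - ks[i]) / (ks[i + 1L] - ks[i])
  kv[i] + (kv[i + 1L] - kv[i]) * .smoothstep(u)
}

#' Specify one synthetic joint excursion
#'
#' Parameters of a single simulated joint-direction excursion, in
#' pro-normalised degrees. The profile is built from smoothstep segments
#' with short plateaus placed exactly on epoch boundaries, so that the
#' noise-free epoch-boundary analysis recovers `end_range`, `surplus_pro`
#' and `surplus_anti` exactly.
#'
#' @param joint joint label (`"C0/C1"` ... `"C6/C7"`).
#' @param direction `"flexion"` or `"extension"`.
#' @param motion_type `"C"`, `"S"` or `"A"`.
#' @param end_range terminal position, degrees: > 0 for C/S, < 0 for A.
#' @param surplus_pro pro-directional surplus, degrees: 0 for type C, > 0
#'   for type S; for type A it is the height of the pro-directional peak
#'   above the terminal position (`max_pro = end_range + surplus_pro`,
#'   clipped at 0 — a value below `|end_range|` yields a joint that never
#'   passes upright pro-directionally).
#' @param surplus_anti depth of the early anti-directional dip, degrees
#'   (>= 0; ignored for type A, whose anti-directional extreme is its own
#'   terminal position).
#' @param overshoot_epoch epoch (2--9; 3--9 with a dip) in which the
#'   pro-directional maximum is attained for types S and A.
#' @param noise_sd per-frame Gaussian angle noise, degrees.
#' @param duration,frame_rate,hold recording protocol: total seconds,
#'   frames per second, and hold length in seconds at upright and at
#'   end-range.
#' @return An object of class `"synthetic_joint_spec"`.
#' @export
joint_spec <- function(joint, direction, motion_type, end_range,
                       surplus_pro = 0, surplus_anti = 0,
                       overshoot_epoch = 5, noise_sd = 0,
                       duration = 16, frame_rate = 25, hold = 2) {
  if (!joint %in% joint_levels())
    cervik_stop("cervik_invalid_argument", "unknown joint '%s'", joint)
  .assert_direction(direction)
  if (!motion_type %in% c("C", "S", "A"))
    cervik_stop("cervik_spec_validation", "motion_type must be C, S or A")
  if (motion_type %in% c("C", "S") && end_range <= 0)
    cervik_stop("cervik_spec_validation",
                "type %s requires end_range > 0 (pro-normalised)", motion_type)
  if (motion_type == "A" && end_range >= 0)
    cervik_stop("cervik_spec_validation", "type A requires end_range < 0")
  if (motion_type == "C" && surplus_pro != 0)
    cervik_stop("cervik_spec_validation", "type C requires surplus_pro = 0")
  if (motion_type == "S" && surplus_pro <= 0)
    cervik_stop("cervik_spec_validation", "type S requires surplus_pro > 0")
  if (surplus_anti < 0 || noise_sd < 0)
    cervik_stop("cervik_spec_validation",
                "surplus_anti and noise_sd must be >= 0")
  dip <- surplus_anti > 0 && motion_type != "A"
  lo <- if (dip) 3L else 2L
  if (motion_type != "C" &&
      (overshoot_epoch < lo || overshoot_epoch > 9L))
    cervik_stop("cervik_spec_validation",
                "overshoot_epoch must be in %d..9", lo)
  if (hold < 0 || duration <= 2 * hold || frame_rate <= 0)
    cervik_stop("cervik_spec_validation",
                "need duration > 2 * hold and frame_rate > 0")
  structure(list(joint = joint, direction = direction,
                 motion_type = motion_type, end_range = end_range,
                 surplus_pro = surplus_pro, surplus_anti = surplus_anti,
                 overshoot_epoch = as.integer(overshoot_epoch),
                 noise_sd = noise_sd, duration = duration,
                 frame_rate = frame_rate, hold = hold),
            class = "synthetic_joint_spec")
}

## control points of the noise-free pro-normalised profile over the trimmed
## excursion, s in [0, 1]
.profile_knots <- function(spec) {
  E <- spec$end_range
  m <- spec$overshoot_epoch
  s1 <- (m - 0.5) / 10; s2 <- (m + 0.5) / 10
  ks <- 0; kv <- 0
  dip <- spec$surplus_anti > 0 && spec$motion_type != "A"
  if (dip) {
    ks <- c(ks, 0.05, 0.15); kv <- c(kv, -spec$surplus_anti,
                                     -spec$surplus_anti)
  }
  if (spec$motion_type == "C") {
    ks <- c(ks, 1); kv <- c(kv, E)
  } else if (spec$motion_type == "S") {
    P <- E + spec$surplus_pro
    ks <- c(ks, s1, s2, 1); kv <- c(kv, P, P, E)
  } else {  # type A
    P <- E + spec$surplus_pro
    if (P > 0) {
      ks <- c(ks, s1, s2, 1); kv <- c(kv, P, P, E)
    } else {
      ks <- c(ks, 1); kv <- c(kv, E)
    }
  }
  list(s = ks, v = kv)
}

#' Simulate one joint-angle trajectory
#'
#' Builds the full recorded trajectory for one joint and direction: upright
#' hold at 0, a smooth excursion following the [joint_spec()] profile,
#' end-range hold, per-frame Gaussian noise, and the sign convention of the
#' requested direction (flexion negative). The ground-truth quantities are
#' attached as the `"ground_truth"` attribute.
#'
#' @param spec a [joint_spec()].
#' @param seed optional integer seed (the caller's RNG state is restored).
#' @param subject subject identifier stored on the trajectory.
#' @return A [joint_trajectory()] with attribute `ground_truth`: a list
#'   with `motion_type`, `end_range`, `max_pro`, `surplus_pro`,
#'   `surplus_anti`, `epoch_of_max`, `never_pro`.
#' @examples
#' sp <- joint_spec("C1/C2", "extension", "S", end_range = 5,
#'                  surplus_pro = 2, overshoot_epoch = 6)
#' tr <- simulate_trajectory(sp, seed = 1)
#' motion_summary(trim_holds(tr))$surplus_pro  # 2
#' @export
simulate_trajectory <- function(spec, seed = NULL, subject = NA_character_) {
  if (!inherits(spec, "synthetic_joint_spec"))
    cervik_stop("cervik_invalid_argument", "spec must be a joint_spec()")
  .with_seed(seed, {
    times <- seq(0, spec$duration, by = 1 / spec$frame_rate)
    t0 <- spec$hold; t1 <- spec$duration - spec$hold
    s <- (times - t0) / (t1 - t0)
    knots <- .profile_knots(spec)
    pos <- numeric(length(times))
    pos[times < t0] <- 0
    pos[times > t1] <- spec$end_range
    mid <- times >= t0 & times <= t1
    pos[mid] <- .eval_knots(s[mid], knots)
    if (spec$noise_sd > 0)
      pos <- pos + stats::rnorm(length(pos), 0, spec$noise_sd)
    P <- max(knots$v)
    never_pro <- spec$motion_type == "A" &&
      spec$end_range + spec$surplus_pro <= 0
    gt <- list(
      motion_type = spec$motion_type,
      end_range = spec$end_range,
      max_pro = max(P, 0),
      surplus_pro = max(P, 0) - spec$end_range,
      surplus_anti = if (spec$motion_type == "A") abs(spec$end_range)
        else spec$surplus_anti,
      epoch_of_max = if (spec$motion_type == "C") 10L
        else if (never_pro) 1L else spec$overshoot_epoch,
      never_pro = never_pro)
    tr <- joint_trajectory(spec$joint, spec$direction, times,
                           position = .pro_sign(spec$direction) * pos,
                           subject = subject)
    attr(tr, "ground_truth") <- gt
    tr
  })
}

#' Specify a synthetic cohort
#'
#' Study-protocol defaults: 33 subjects, 7 joints, both directions, 16 s
#' excursions at 25 frames/s with 2 s holds at upright and end-range, type
#' mixes and per-level magnitude distributions from
#' [default_cohort_params()], per-frame angle noise of 0.1 degrees
#' (sub-degree marking error). All magnitudes are drawn from one-sided
#' truncated normal distributions (end-ranges >= 0.3, surpluses and dips
#' >= 0.02 degrees).
#'
#' @param n_subjects number of subjects (default 33).
#' @param directions directions simulated per subject.
#' @param type_mix named list (per direction) of C/S/A probabilities.
#' @param params per-level parameter table as in [default_cohort_params()].
#' @param never_pro_frac named vector: fraction of type A joints that never
#'   pass upright pro-directionally.
#' @param noise_sd per-frame angle noise in degrees.
#' @param duration,frame_rate,hold recording protocol.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_subjects = 33,
                        directions = c("flexion", "extension"),
                        type_mix = default_type_mix(),
                        params = default_cohort_params(),
                        never_pro_frac = default_never_pro_frac(),
                        noise_sd = 0.1, duration = 16, frame_rate = 25,
                        hold = 2) {
  stopifnot(n_subjects >= 1, all(directions %in% motion_directions()))
  for (d in directions) {
    p <- type_mix[[d]]
    if (is.null(p) || length(p) != 3L || any(p < 0) ||
        abs(sum(p) - 1) > 1e-6)
      cervik_stop("cervik_spec_validation",
                  "type_mix$%s must be 3 probabilities summing to 1", d)
  }
  need <- c("direction", "joint", "er_C_mean", "er_C_sd", "er_S_mean",
            "er_S_sd", "er_A_mean", "er_A_sd", "surplus_mean", "surplus_sd",
            "dip_prob", "dip_mean", "dip_sd")
  if (!all(need %in% names(params)))
    cervik_stop("cervik_spec_validation", "params table lacks columns")
  if (any(params[grep("_sd$", names(params))] < 0))
    cervik_stop("cervik_spec_validation", "all SDs must be >= 0")
  if (noise_sd < 0)
    cervik_stop("cervik_spec_validation", "noise_sd must be >= 0")
  structure(list(n_subjects = as.integer(n_subjects),
                 directions = directions, type_mix = type_mix,
                 params = params, never_pro_frac = never_pro_frac,
                 noise_sd = noise_sd, duration = duration,
                 frame_rate = frame_rate, hold = hold),
            class = "cohort_spec")
}

#' Simulate a cohort of joint excursions with ground truth
#'
#' Draws, for every subject x joint x direction, a motion type from the
#' direction's mix and magnitudes from the per-level distributions, then
#' simulates the full trajectory (holds and noise included). The manifest
#' lists every ground-truth quantity; identical spec + seed reproduce the
#' cohort exactly.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @return An object of class `"cervik_cohort"`: list with `trajectories`
#'   (one [joint_trajectory()] per record, ground truth attached),
#'   `manifest` (data frame of ground truth), and `spec`.
#' @examples
#' co <- simulate_cohort(cohort_spec(n_subjects = 2, noise_sd = 0), seed = 7)
#' nrow(co$manifest)  # 2 subjects x 7 joints x 2 directions
#' @export
simulate_cohort <- function(spec, seed = NULL) {
  if (!inherits(spec, "cohort_spec"))
    cervik_stop("cervik_invalid_argument", "spec must be a cohort_spec()")
  .with_seed(seed, {
    trajectories <- list()
    rows <- list()
    for (subj in seq_len(spec$n_subjects)) {
      sid <- sprintf("S%03d", subj)
      for (d in spec$directions) {
        for (j in joint_levels()) {
          pr <- spec$params[spec$params$direction == d &
                              spec$params$joint == j, ]
          ty <- sample(c("C", "S", "A"), 1, prob = spec$type_mix[[d]])
          dip <- ty != "A" && stats::runif(1) < pr$dip_prob
          sa <- if (dip) .rtrunc_norm(1, pr$dip_mean, pr$dip_sd, 0.02) else 0
          m <- sample(3:9, 1)
          if (ty == "C") {
            er <- .rtrunc_norm(1, pr$er_C_mean, pr$er_C_sd, 0.3)
            sp <- 0
          } else if (ty == "S") {
            er <- .rtrunc_norm(1, pr$er_S_mean, pr$er_S_sd, 0.3)
            sp <- .rtrunc_norm(1, pr$surplus_mean, pr$surplus_sd, 0.02)
          } else {
            er <- -.rtrunc_norm(1, pr$er_A_mean, pr$er_A_sd, 0.3)
            never <- stats::runif(1) < spec$never_pro_frac[[d]]
            sp <- if (never) 0 else
              abs(er) + .rtrunc_norm(1, pr$surplus_mean, pr$surplus_sd, 0.02)
          }
          js <- joint_spec(j, d, ty, end_range = er, surplus_pro = sp,
                           surplus_anti = sa, overshoot_epoch = m,
                           noise_sd = spec$noise_sd,
                           duration = spec$duration,
                           frame_rate = spec$frame_rate, hold = spec$hold)
          tr <- simulate_trajectory(js, subject = sid)
          gt <- attr(tr, "ground_truth")
          trajectories[[length(trajectories) + 1L]] <- tr
          rows[[length(rows) + 1L]] <- data.frame(
            subject = sid, joint = j, direction = d,
            motion_type = gt$motion_type, end_range = gt$end_range,
            max_pro = gt$max_pro, surplus_pro = gt$surplus_pro,
            surplus_anti = gt$surplus_anti,
            epoch_of_max = gt$epoch_of_max, never_pro = gt$never_pro,
            stringsAsFactors = FALSE)
        }
      }
    }
    structure(list(trajectories = trajectories,
                   manifest = do.call(rbind, rows), spec = spec),
              class = "cervik_cohort")
  })
}

#' @export
print.cervik_cohort <- function(x, ...) {
  cat(sprintf("<cervik_cohort> %d subjects, %d records (%s), noise sd %g deg\n",
              x$spec$n_subjects, nrow(x$manifest),
              paste(x$spec$directions, collapse = " + "),
              x$spec$noise_sd))
  print(table(x$manifest$direction, x$manifest$motion_type))
  invisible(x)
}

#' Canonical vertebra landmark template
#'
#' A neutral-posture sagittal layout of the 26 canonical landmarks
#' (millimetre-scale, x anterior, y superior) in which every vertebral
#' midplane is horizontal, so that rotating a vertebra's points about their
#' centroid by an angle theta gives it midplane angle exactly theta.
#'
#' @return A 26 x 2 matrix with landmark ids as row names.
#' @export
vertebra_template <- function() {
  yc <- c(C7 = 0, C6 = 18, C5 = 36, C4 = 54, C3 = 72)
  pts <- rbind(
    C0_ant_1 = c(25, 126), C0_ant_2 = c(25, 134),
    C0_post_1 = c(-5, 126), C0_post_2 = c(-5, 134),
    C1_ant_arc = c(18, 108), C1_post_arc = c(-2, 108),
    C2_inf_ant = c(16, 84), C2_inf_post = c(0, 84),
    C7_sup_ant = c(16, 8), C7_sup_post = c(0, 8))
  for (v in paste0("C", 3:6)) {
    y <- yc[[v]]
    pts <- rbind(pts,
                 matrix(c(16, y + 7, 16, y - 7, 0, y + 7, 0, y - 7),
                        ncol = 2, byrow = TRUE,
                        dimnames = list(paste0(v, c("_ant_sup", "_ant_inf",
                                                    "_post_sup", "_post_inf")),
                                        NULL)))
  }
  pts[landmark_ids(), ]
}

#' Landmark sequence from joint-angle series
#'
#' Inverse of the landmark geometry: given per-frame signed joint rotations
#' (extension-positive) for all seven joints, stacks the vertebra template
#' and rotates each vertebra about its own centroid so that successive
#' midplane-angle differences reproduce the requested joint angles exactly
#' (C7 is held fixed). Optional Gaussian jitter emulates marking error.
#'
#' @param angles numeric matrix, frames x 7, columns in the order of
#'   [joint_levels()] (a single frame may be passed as a vector).
#' @param direction `"flexion"` or `"extension"` (metadata only).
#' @param times frame times in seconds; default a uniform grid at
#'   `frame_rate`.
#' @param frame_rate frames per second.
#' @param template landmark template, see [vertebra_template()].
#' @param jitter_sd per-coordinate Gaussian jitter SD (same units as the
#'   template).
#' @param subject subject identifier.
#' @param seed optional integer seed for the jitter.
#' @return A [landmark_sequence()].
#' @export
landmarks_from_angles <- function(angles, direction, times = NULL,
                                  frame_rate = 25,
                                  template = vertebra_template(),
                                  jitter_sd = 0, subject = "synthetic",
                                  seed = NULL) {
  if (is.null(dim(angles))) angles <- matrix(angles, nrow = 1)
  angles <- as.matrix(angles)
  if (ncol(angles) != 7L)
    cervik_stop("cervik_invalid_argument",
                "angles must have 7 columns (one per joint)")
  if (!setequal(rownames(template), landmark_ids()))
    cervik_stop("cervik_template_error",
                "template must contain all 26 canonical landmark ids")
  n <- nrow(angles)
  if (is.null(times)) times <- (seq_len(n) - 1) / frame_rate
  # vertebra orientations: theta_v = sum of joint angles below vertebra v
  theta <- cbind(t(apply(angles, 1, function(a) rev(cumsum(rev(a))))),
                 rep(0, n))
  colnames(theta) <- vertebra_ids()
  coords <- array(NA_real_, dim = c(n, 26, 2),
                  dimnames = list(NULL, landmark_ids(), c("x", "y")))
  centroids <- lapply(vertebra_ids(), function(v)
    colMeans(template[landmark_ids(v), , drop = FALSE]))
  names(centroids) <- vertebra_ids()
  for (f in seq_len(n)) {
    for (v in vertebra_ids()) {
      ids <- landmark_ids(v)
      a <- theta[f, v] * pi / 180
      R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
      ctr <- centroids[[v]]
      rel <- sweep(template[ids, , drop = FALSE], 2, ctr)
      coords[f, ids, ] <- sweep(rel %*% t(R), 2, ctr, "+")
    }
  }
  if (jitter_sd > 0)
    coords <- .with_seed(seed,
                         coords + stats::rnorm(length(coords), 0, jitter_sd))
  landmark_sequence(subject, direction, times, coords,
                    frame_rate = frame_rate)
}

#' Landmark sequences for a simulated cohort
#'
#' Stacks each subject-direction's seven simulated joint trajectories into
#' a full landmark sequence via [landmarks_from_angles()].
#'
#' @param cohort a [simulate_cohort()] result.
#' @param jitter_sd per-coordinate marking jitter SD.
#' @param seed optional integer seed for the jitter.
#' @return List of [landmark_sequence()] objects, one per subject x
#'   direction.
#' @export
cohort_landmarks <- function(cohort, jitter_sd = 0, seed = NULL) {
  if (!inherits(cohort, "cervik_cohort"))
    cervik_stop("cervik_invalid_argument", "cohort must be a cervik_cohort")
  key <- vapply(cohort$trajectories,
                function(tr) paste(tr$subject, tr$direction), character(1))
  .with_seed(seed, {
    out <- lapply(unique(key), function(k) {
      trs <- cohort$trajectories[key == k]
      names(trs) <- vapply(trs, `[[`, character(1), "joint")
      trs <- trs[joint_levels()]
      angles <- do.call(cbind, lapply(trs, `[[`, "position"))
      landmarks_from_angles(angles, trs[[1]]$direction,
                            times = trs[[1]]$times,
                            frame_rate = cohort$spec$frame_rate,
                            jitter_sd = jitter_sd,
                            subject = trs[[1]]$subject)
    })
    names(out) <- unique(key)
    out
  })
}
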