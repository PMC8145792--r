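#' Classify a joint-direction record into motion type C, S or A
#'
#' Three motion types, all defined from the end-range (terminal) position
#' relative to upright:
#' \describe{
#'   \item{C (Classic)}{maximum motion equals the terminal position: the
#'     joint never exceeds its end-range.}
#'   \item{S (Surplus)}{maximum motion exceeds the terminal position: the
#'     joint passes its end-range pro-directionally before returning.}
#'   \item{A (Anti-directional)}{the terminal position lies on the opposite
#'     side of upright (strictly negative in pro-normalised degrees).}
#' }
#' Ties (`max_pro <= end_range + epsilon`) classify as C, as does an
#' end-range of exactly zero (type A is defined strictly). `epsilon`
#' defaults to 0, appropriate for epoch-boundary resolution on clean data;
#' for noisy data see [recommended_epsilon()].
#'
#' @param summary a [motion_summary()] result.
#' @param epsilon non-negative tolerance in degrees for the C/S tie rule.
#' @return `"C"`, `"S"` or `"A"`.
#' @examples
#' tr <- joint_trajectory("C2/C3", "extension", 0:12,
#'                        c(0, 0.5, 1, 1.5, 2, 2.5, 3, 2.9, 2.7, 2.5, 2.3, 2.1, 2))
#' classify_joint(motion_summary(tr))
#' @export
classify_joint <- function(summary, epsilon = 0) {
  if (!inherits(summary, "joint_motion_summary"))
    cervik_stop("cervik_invalid_argument",
                "summary must be a joint_motion_summary")
  if (epsilon < 0)
    cervik_stop("cervik_invalid_argument", "epsilon must be >= 0")
  .classify(summary$end_range, summary$max_pro, epsilon)
}

.classify <- function(end_range, max_pro, epsilon = 0) {
  ifelse(end_range < 0, "A",
         ifelse(max_pro > end_range + epsilon, "S", "C"))
}

#' Boundary-crossing flags for a motion summary
#'
#' Whether the joint passed its end-range position pro-directionally
#' (`max_pro > end_range`; true for every type S and, since `max_pro >= 0`,
#' for every type A joint), whether it passed upright anti-directionally
#' (`min_pos < 0`), and their conjunction.
#'
#' @inheritParams classify_joint
#' @return List with logical `passed_endrange_pro`, `passed_upright_anti`,
#'   `passed_both`.
#' @export
boundary_crossings <- function(summary) {
  if (!inherits(summary, "joint_motion_summary"))
    cervik_stop("cervik_invalid_argument",
                "summary must be a joint_motion_summary")
  list(passed_endrange_pro = summary$passed_endrange_pro,
       passed_upright_anti = summary$passed_upright_anti,
       passed_both = summary$passed_endrange_pro && summary$passed_upright_anti)
}

#' Classify a records data frame
#'
#' Adds a `motion_type` column (C/S/A) to a records data frame produced by
#' [summaries_records()]; the crossing flags and `never_pro` are already
#' columns of the records.
#'
#' @param records data frame with at least `end_range` and `max_pro`
#'   columns (pro-normalised degrees).
#' @param epsilon tolerance passed to the C/S tie rule, degrees.
#' @return `records` with a `motion_type` factor column (levels C, S, A).
#' @export
classify_records <- function(records, epsilon = 0) {
  stopifnot(is.data.frame(records),
            all(c("end_range", "max_pro") %in% names(records)))
  if (epsilon < 0)
    cervik_stop("cervik_invalid_argument", "epsilon must be >= 0")
  records$motion_type <- factor(
    .classify(records$end_range, records$max_pro, epsilon),
    levels = c("C", "S", "A"))
  records
}

#' Classification tolerance recommended for noisy recordings
#'
#' With per-frame marking noise of standard deviation `noise_sd` degrees and
#' epoch boundaries read as means over `2 * window + 1` frames, the
#' difference between two boundary readings carries noise with standard
#' deviation `sqrt(2) * noise_sd / sqrt(2 * window + 1)`. A three-sigma
#' tolerance on that difference keeps spurious C-to-S flips rare without
#' swallowing genuinely small surpluses.
#'
#' @param noise_sd per-frame landmark/angle noise, degrees.
#' @param window boundary averaging half-width in frames (see
#'   [segment_epochs()]).
#' @return Tolerance in degrees: `3 * sqrt(2) * noise_sd / sqrt(2 * window + 1)`.
#' @export
recommended_epsilon <- function(noise_sd, window = 0) {
  stopifnot(noise_sd >= 0, window >= 0)
  3 * sqrt(2) * noise_sd / sqrt(2 * window + 1)
}
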