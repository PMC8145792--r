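## landmark CSV interface: columns subject_id, direction, frame, time_s,
## landmark_id, x, y; one row per point per frame; header required; UTF-8,
## period decimal

.landmark_csv_cols <- c("subject_id", "direction", "frame", "time_s",
                        "landmark_id", "x", "y")

#' Read landmark trajectories from CSV
#'
#' Parses a tidy landmark file (one row per landmark per frame) into one
#' [landmark_sequence()] per subject x direction. Row order in the file is
#' irrelevant; frames are ordered by frame index. Validation errors (wrong
#' header, unknown landmark id, duplicated landmark within a frame,
#' incomplete frames, non-increasing times) name the offending rows.
#'
#' @param path path to a CSV file with columns `subject_id`, `direction`,
#'   `frame`, `time_s`, `landmark_id`, `x`, `y`.
#' @param frame_rate frames per second recorded in the returned sequences.
#' @return Named list of [landmark_sequence()] objects
#'   (`"<subject>.<direction>"`).
#' @export
read_landmarks <- function(path, frame_rate = 25) {
  if (!file.exists(path))
    cervik_stop("cervik_parse_error", "file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.landmark_csv_cols, names(df))
  if (length(miss))
    cervik_stop("cervik_parse_error", "%s: missing column(s) %s", path,
                paste(miss, collapse = ", "))
  if (nrow(df) == 0L)
    cervik_stop("cervik_parse_error", "%s: no data rows", path)
  bad_id <- which(!df$landmark_id %in% landmark_ids())
  if (length(bad_id))
    cervik_stop("cervik_parse_error",
                "%s: unknown landmark id '%s' (data row %d%s)", path,
                df$landmark_id[bad_id[1]], bad_id[1],
                if (length(bad_id) > 1)
                  sprintf(" and %d more", length(bad_id) - 1) else "")
  bad_dir <- which(!df$direction %in% motion_directions())
  if (length(bad_dir))
    cervik_stop("cervik_parse_error",
                "%s: invalid direction '%s' (data row %d)", path,
                df$direction[bad_dir[1]], bad_dir[1])
  if (any(!is.finite(df$x)) || any(!is.finite(df$y)))
    cervik_stop("cervik_parse_error", "%s: non-finite coordinates (data row %d)",
                path, which(!is.finite(df$x) | !is.finite(df$y))[1])
  key <- paste(df$subject_id, df$direction, sep = ".")
  out <- lapply(split(seq_len(nrow(df)), key), function(rows) {
    sub <- df[rows, , drop = FALSE]
    dup <- duplicated(sub[c("frame", "landmark_id")])
    if (any(dup))
      cervik_stop("cervik_parse_error",
                  "%s: duplicated landmark '%s' in frame %d (data row %d)",
                  path, sub$landmark_id[dup][1], sub$frame[dup][1],
                  rows[dup][1])
    frames <- sort(unique(sub$frame))
    times <- vapply(frames,
                    function(f) sub$time_s[sub$frame == f][1], numeric(1))
    if (any(diff(times) <= 0))
      cervik_stop("cervik_parse_error",
                  "%s: non-increasing time_s across frames for %s", path,
                  paste(sub$subject_id[1], sub$direction[1]))
    coords <- array(NA_real_, dim = c(length(frames), 26, 2),
                    dimnames = list(NULL, landmark_ids(), c("x", "y")))
    for (i in seq_along(frames)) {
      fr <- sub[sub$frame == frames[i], , drop = FALSE]
      if (!setequal(fr$landmark_id, landmark_ids()))
        cervik_stop("cervik_parse_error",
                    "%s: frame %d of %s has %d of 26 landmarks", path,
                    frames[i], paste(fr$subject_id[1], fr$direction[1]),
                    nrow(fr))
      coords[i, fr$landmark_id, ] <- cbind(fr$x, fr$y)
    }
    landmark_sequence(sub$subject_id[1], sub$direction[1], times, coords,
                      frame_rate = frame_rate)
  })
  out
}

#' Write landmark sequences to the standard CSV layout
#'
#' @param seqs a [landmark_sequence()] or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(seqs, path) {
  if (inherits(seqs, "landmark_sequence")) seqs <- list(seqs)
  rows <- lapply(seqs, function(s) {
    n <- length(s$times)
    data.frame(subject_id = s$subject, direction = s$direction,
               frame = rep(seq_len(n) - 1L, each = 26),
               time_s = rep(s$times, each = 26),
               landmark_id = rep(landmark_ids(), n),
               x = as.vector(t(s$coords[, , 1])),
               y = as.vector(t(s$coords[, , 2])),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
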