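#' Pipeline configuration
#'
#' A validated, serialisable set of analysis parameters. Round-trips
#' through YAML ([yaml::as.yaml()] / [read_pipeline_config()]).
#'
#' @param epochs number of time epochs (default 10).
#' @param start_hold,end_hold hold durations trimmed from each recording,
#'   seconds (default 2 each, matching the recording protocol).
#' @param upright_reference `"initial-hold-mean"` or `"first-frame"`.
#' @param hold_duration upright-reference averaging window, seconds.
#' @param resolution `"epochs"` or `"frames"`.
#' @param boundary_window epoch-boundary averaging half-width, frames.
#' @param epsilon C/S classification tolerance, degrees.
#' @param facing `"+x"` or `"-x"`.
#' @param min_n minimum group size for statistical tests.
#' @param frame_rate frames per second of the recordings.
#' @param seed integer seed recorded with every report.
#' @return An object of class `"pipeline_config"` (a named list).
#' @export
pipeline_config <- function(epochs = 10, start_hold = 2, end_hold = 2,
                            upright_reference = "initial-hold-mean",
                            hold_duration = 2,
                            resolution = "epochs", boundary_window = 0,
                            epsilon = 0, facing = "+x", min_n = 7,
                            frame_rate = 25, seed = 1L) {
  cfg <- list(epochs = as.integer(epochs), start_hold = start_hold,
              end_hold = end_hold, upright_reference = upright_reference,
              hold_duration = hold_duration, resolution = resolution,
              boundary_window = as.integer(boundary_window),
              epsilon = epsilon, facing = facing, min_n = as.integer(min_n),
              frame_rate = frame_rate, seed = as.integer(seed))
  if (cfg$epochs < 1 || cfg$start_hold < 0 || cfg$end_hold < 0 ||
      cfg$hold_duration <= 0 || cfg$boundary_window < 0 ||
      cfg$epsilon < 0 || cfg$min_n < 1 || cfg$frame_rate <= 0)
    cervik_stop("cervik_invalid_argument", "invalid pipeline configuration")
  if (!cfg$upright_reference %in% c("initial-hold-mean", "first-frame") ||
      !cfg$resolution %in% c("epochs", "frames") ||
      !cfg$facing %in% c("+x", "-x"))
    cervik_stop("cervik_invalid_argument", "invalid pipeline configuration")
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file holding a subset of the configuration fields.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals[intersect(names(vals),
                                          names(formals(pipeline_config)))])
}

#' Run the full landmark-to-report pipeline
#'
#' Reads landmark trajectories (or accepts simulated inputs), computes
#' joint-angle trajectories, trims the holds, summarises and classifies
#' every joint-direction record, aggregates the cohort tables and
#' comparisons, and writes the report bundle to `out_dir`: `records.csv`,
#' one CSV per summary table, `report.json` (which embeds the resolved
#' configuration), and `run_log.txt`. Output CSVs report flexion magnitudes
#' with a negative sign (`end_range_signed`) alongside the pro-normalised
#' values.
#'
#' @param input a landmark CSV path, a list of [landmark_sequence()]
#'   objects, or a [simulate_cohort()] result.
#' @param out_dir output directory (created if missing); `NULL` to skip
#'   writing.
#' @param config a [pipeline_config()].
#' @return The fitted [cervik()] object, invisibly.
#' @export
run_pipeline <- function(input, out_dir = NULL, config = pipeline_config()) {
  if (!inherits(config, "pipeline_config"))
    cervik_stop("cervik_invalid_argument", "config must be a pipeline_config")
  stage <- function(name, expr) {
    tryCatch(expr, cervik_error = function(e) {
      cervik_stop("cervik_pipeline_error", "stage '%s': %s", name,
                  conditionMessage(e))
    })
  }
  if (is.character(input)) {
    if (dir.exists(input)) {
      files <- list.files(input, pattern = "\\.csv$", full.names = TRUE)
      if (!length(files))
        cervik_stop("cervik_empty_cohort",
                    "no landmark CSV files in %s", input)
      input <- stage("read", unlist(lapply(files, read_landmarks,
                                           frame_rate = config$frame_rate),
                                    recursive = FALSE))
    } else {
      input <- stage("read", read_landmarks(input,
                                            frame_rate = config$frame_rate))
    }
  }
  if (inherits(input, "cervik_cohort")) {
    trajectories <- input$trajectories
  } else if (is.list(input) &&
             all(vapply(input, inherits, logical(1), "landmark_sequence"))) {
    trajectories <- stage("geometry", unlist(lapply(input, function(s) {
      angle_trajectories(s, upright_reference = config$upright_reference,
                         hold_duration = config$hold_duration,
                         facing = config$facing)
    }), recursive = FALSE))
  } else if (is.list(input) &&
             all(vapply(input, inherits, logical(1), "joint_trajectory"))) {
    trajectories <- input
  } else {
    cervik_stop("cervik_invalid_argument",
                "input must be a CSV path/directory, landmark sequences, trajectories or a cervik_cohort")
  }
  fit <- stage("analysis",
               cervik(trajectories, epsilon = config$epsilon,
                      min_n = config$min_n, resolution = config$resolution,
                      n_epochs = config$epochs,
                      boundary_window = config$boundary_window,
                      start_hold = config$start_hold,
                      end_hold = config$end_hold))
  fit$config <- config
  if (!is.null(out_dir)) stage("write", write_report(fit, out_dir))
  invisible(fit)
}

#' Write the report bundle of a cohort analysis
#'
#' @param fit a [cervik()] object.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(fit, out_dir) {
  if (!inherits(fit, "cervik"))
    cervik_stop("cervik_invalid_argument", "fit must be a cervik object")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rec <- fit$records
  sgn <- ifelse(rec$direction == "flexion", -1, 1)
  rec$end_range_signed <- sgn * rec$end_range
  rec$max_pro_signed <- sgn * rec$max_pro
  utils::write.csv(rec, file.path(out_dir, "records.csv"), row.names = FALSE)
  for (d in names(fit$tables)) {
    tb <- fit$tables[[d]]
    for (nm in names(tb)) {
      if (is.null(tb[[nm]])) next
      utils::write.csv(tb[[nm]],
                       file.path(out_dir, sprintf("%s_%s.csv", d, nm)),
                       row.names = FALSE)
    }
  }
  utils::write.csv(fit$comparisons, file.path(out_dir, "comparisons.csv"),
                   row.names = FALSE)
  report <- list(config = if (!is.null(fit$config))
                   unclass(fit$config) else fit$params,
                 params = fit$params,
                 n_records = nrow(rec),
                 frequency = fit$frequency,
                 tables = lapply(fit$tables, function(tb)
                   Filter(Negate(is.null), tb)),
                 comparisons = fit$comparisons,
                 r_version = as.character(getRversion()),
                 package_version =
                   as.character(utils::packageVersion("cervik")))
  tmp <- file.path(out_dir, ".report.json.tmp")
  jsonlite::write_json(report, tmp, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  file.rename(tmp, file.path(out_dir, "report.json"))
  writeLines(c(sprintf("cervik %s / R %s",
                       as.character(utils::packageVersion("cervik")),
                       getRversion()),
               sprintf("records: %d", nrow(rec)),
               sprintf("written: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
               yaml::as.yaml(if (!is.null(fit$config))
                 unclass(fit$config) else fit$params)),
             file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
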