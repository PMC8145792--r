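## cohort-level summaries: per-level, per-region and quartile tables over a
## records data frame (one row per subject x joint x direction)

.check_records <- function(records, need = character()) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    cervik_stop("cervik_empty_cohort", "no records to aggregate")
  miss <- setdiff(need, names(records))
  if (length(miss))
    cervik_stop("cervik_invalid_argument",
                "records lack column(s): %s", paste(miss, collapse = ", "))
  invisible(records)
}

.round1 <- function(x) round(x, 1)

#' Motion-type counts and proportions
#'
#' Counts of type C, S and A records and their percentages of the total,
#' reported to one decimal. Either a classified records data frame or a
#' named count vector can be supplied (the latter lets printed counts from a
#' published table be fed through the same arithmetic).
#'
#' @param records classified records data frame (column `motion_type`), or
#'   `NULL` when `counts` is given.
#' @param counts optional named integer vector with names `C`, `S`, `A`.
#' @return Data frame with columns `type`, `count`, `percent` (1 decimal)
#'   and `percent_raw` (unrounded).
#' @examples
#' type_proportions(counts = c(C = 106, S = 113, A = 12))
#' @export
type_proportions <- function(records = NULL, counts = NULL) {
  if (is.null(counts)) {
    .check_records(records, "motion_type")
    counts <- table(factor(records$motion_type, levels = c("C", "S", "A")))
    counts <- stats::setNames(as.integer(counts), c("C", "S", "A"))
  } else {
    if (!all(c("C", "S", "A") %in% names(counts)))
      cervik_stop("cervik_invalid_argument",
                  "counts must be named with C, S and A")
    counts <- counts[c("C", "S", "A")]
  }
  total <- sum(counts)
  if (total == 0L) cervik_stop("cervik_empty_cohort", "no records to aggregate")
  pct <- 100 * counts / total
  data.frame(type = c("C", "S", "A"), count = as.integer(counts),
             percent = .round1(as.numeric(pct)),
             percent_raw = as.numeric(pct),
             row.names = NULL, stringsAsFactors = FALSE)
}

.group_of <- function(records, grouping) {
  switch(grouping,
         all = rep("all", nrow(records)),
         level = records$joint,
         region = as.character(joint_region(records$joint)),
         cervik_stop("cervik_invalid_argument",
                     "grouping must be 'all', 'level' or 'region'"))
}

#' Pro-directional surplus statistics for type S joints
#'
#' Arithmetic mean, sample standard deviation (n - 1 denominator) and range
#' of the pro-directional surplus, per grouping. Groups of one record report
#' an SD of 0 together with an `n1` flag so tables keep their shape; empty
#' groups are omitted with a message.
#'
#' @param records classified records; rows with `motion_type != "S"` are
#'   dropped (the secondary analysis stage excludes joints with
#'   anti-directional end-range and surplus is zero for type C).
#' @param grouping `"all"`, `"level"` or `"region"`.
#' @param direction optional: restrict to one motion direction.
#' @return Data frame with `group`, `n`, `mean`, `sd`, `min`, `max`,
#'   `n1` (TRUE when the SD is a single-record placeholder).
#' @export
surplus_statistics <- function(records, grouping = c("all", "level", "region"),
                               direction = NULL) {
  grouping <- match.arg(grouping)
  .check_records(records, c("surplus_pro", "joint", "direction"))
  if (!is.null(direction)) {
    .assert_direction(direction)
    records <- records[records$direction == direction, , drop = FALSE]
  }
  if ("motion_type" %in% names(records))
    records <- records[records$motion_type == "S", , drop = FALSE]
  if (nrow(records) == 0L)
    cervik_stop("cervik_empty_cohort", "no type S records")
  grp <- .group_of(records, grouping)
  lv <- if (grouping == "level") joint_levels() else
    if (grouping == "region") c("upper", "lower") else "all"
  present <- intersect(lv, unique(grp))
  if (length(dropped <- setdiff(lv, present)))
    message("surplus_statistics: empty group(s) omitted: ",
            paste(dropped, collapse = ", "))
  rows <- lapply(present, function(g) {
    x <- records$surplus_pro[grp == g]
    data.frame(group = g, n = length(x), mean = mean(x),
               sd = if (length(x) > 1L) stats::sd(x) else 0,
               min = min(x), max = max(x), n1 = length(x) == 1L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## quartile of 1-based rank r among n, remainders filling the low quartiles
## so the smallest end-ranges always populate quartile 1
.quartile_of_rank <- function(r, n) floor(4 * (r - 1) / n) + 1L

.quartile_rows <- function(sub, label) {
  ord <- order(abs(sub$end_range))
  sub <- sub[ord, , drop = FALSE]
  n <- nrow(sub)
  q <- .quartile_of_rank(seq_len(n), n)
  lapply(1:4, function(k) {
    x <- sub[q == k, , drop = FALSE]
    if (nrow(x) == 0L)
      return(data.frame(level = label, quartile = k, n = 0L,
                        mean_surplus_deg = NA_real_,
                        mean_surplus_pct = NA_real_, n_pct_excluded = 0L,
                        stringsAsFactors = FALSE))
    er <- abs(x$end_range)
    ok <- er > 0
    pct <- 100 * x$surplus_pro[ok] / er[ok]
    data.frame(level = label, quartile = k, n = nrow(x),
               mean_surplus_deg = mean(x$surplus_pro),
               mean_surplus_pct = if (any(ok)) mean(pct) else NA_real_,
               n_pct_excluded = sum(!ok), stringsAsFactors = FALSE)
  })
}

#' Quartile table of surplus motion by end-range
#'
#' Type S records of one direction are ranked per joint level by the
#' magnitude of their end-range and split into quartiles (smallest
#' end-ranges in quartile 1; with n not divisible by 4 the remainders fill
#' the lower quartiles). Each quartile reports the mean pro-directional
#' surplus in degrees and the mean of the per-joint surplus expressed as a
#' percentage of its own end-range. Region rows (`upper`, `lower`) pool the
#' region's records and re-rank within the pool. Records with a zero
#' end-range are excluded from the percentage mean (counted in
#' `n_pct_excluded`).
#'
#' @param records classified records data frame.
#' @param direction `"flexion"` or `"extension"`.
#' @param regions also emit pooled upper/lower region rows (default TRUE).
#' @return Data frame with columns `level`, `quartile`, `n`,
#'   `mean_surplus_deg`, `mean_surplus_pct`, `n_pct_excluded`.
#' @export
quartile_table <- function(records, direction, regions = TRUE) {
  .assert_direction(direction)
  .check_records(records, c("surplus_pro", "end_range", "joint", "direction",
                            "motion_type"))
  rec <- records[records$direction == direction &
                   records$motion_type == "S", , drop = FALSE]
  if (nrow(rec) == 0L)
    cervik_stop("cervik_empty_cohort", "no type S records for %s", direction)
  out <- list()
  for (j in joint_levels()) {
    sub <- rec[rec$joint == j, , drop = FALSE]
    if (nrow(sub) > 0L) out <- c(out, .quartile_rows(sub, j))
  }
  if (regions) {
    reg <- joint_region(rec$joint)
    for (g in c("upper", "lower")) {
      sub <- rec[reg == g, , drop = FALSE]
      if (nrow(sub) > 0L) out <- c(out, .quartile_rows(sub, g))
    }
  }
  do.call(rbind, out)
}

#' Anti-directional motion table
#'
#' Two panels per direction and joint level: anti-directional end-range
#' (type A joints only; magnitudes reported positive) and anti-directional
#' surplus (every record that passed upright anti-directionally, i.e.
#' `surplus_anti > 0`).
#'
#' @param records classified records data frame.
#' @param direction `"flexion"` or `"extension"`.
#' @return Data frame with one row per joint level: `level`, `n_endrange`,
#'   `endrange_mean`, `endrange_sd`, `n_surplus`, `surplus_mean`,
#'   `surplus_sd`. Empty panels report n = 0 and NA statistics.
#' @export
anti_directional_table <- function(records, direction) {
  .assert_direction(direction)
  .check_records(records, c("end_range", "surplus_anti", "joint", "direction",
                            "motion_type"))
  rec <- records[records$direction == direction, , drop = FALSE]
  rows <- lapply(joint_levels(), function(j) {
    sub <- rec[rec$joint == j, , drop = FALSE]
    a <- abs(sub$end_range[sub$motion_type == "A"])
    s <- sub$surplus_anti[sub$surplus_anti > 0]
    data.frame(
      level = j,
      n_endrange = length(a),
      endrange_mean = if (length(a)) mean(a) else NA_real_,
      endrange_sd = if (length(a) > 1L) stats::sd(a) else
        if (length(a) == 1L) 0 else NA_real_,
      n_surplus = length(s),
      surplus_mean = if (length(s)) mean(s) else NA_real_,
      surplus_sd = if (length(s) > 1L) stats::sd(s) else
        if (length(s) == 1L) 0 else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Maximum demonstrated joint motion per level
#'
#' The largest pro-directional position attained by any record of the
#' cohort, per joint level and direction.
#'
#' @param records records data frame.
#' @param direction `"flexion"` or `"extension"`.
#' @return Data frame with `level` and `max_deg`.
#' @export
max_demonstrated <- function(records, direction) {
  .assert_direction(direction)
  .check_records(records, c("max_pro", "joint", "direction"))
  rec <- records[records$direction == direction, , drop = FALSE]
  if (nrow(rec) == 0L)
    cervik_stop("cervik_empty_cohort", "no records for %s", direction)
  rows <- lapply(joint_levels(), function(j) {
    x <- rec$max_pro[rec$joint == j]
    data.frame(level = j,
               max_deg = if (length(x)) max(abs(x)) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Boundary-crossing frequencies and the type A rate
#'
#' Percentages of records (per direction, to one decimal) that passed the
#' end-range position pro-directionally, passed upright anti-directionally,
#' or both; plus the pooled anti-directional end-range rate expressed as
#' "1 in N" joints (`N = round(total / count of type A)`, NA when no type A
#' record exists).
#'
#' @param records classified records data frame (column `motion_type`;
#'   crossing-flag columns are optional, percentages are NA without them).
#' @return List with `by_direction` (data frame), `n`, `n_type_A`,
#'   `one_in_n`.
#' @export
frequency_stats <- function(records) {
  .check_records(records, "motion_type")
  has_flags <- all(c("passed_endrange_pro", "passed_upright_anti") %in%
                     names(records))
  dirs <- if ("direction" %in% names(records))
    intersect(motion_directions(), unique(records$direction)) else "all"
  by_dir <- do.call(rbind, lapply(dirs, function(d) {
    sub <- if (identical(d, "all")) records else
      records[records$direction == d, , drop = FALSE]
    data.frame(
      direction = d, n = nrow(sub),
      pct_passed_endrange_pro = if (has_flags)
        .round1(100 * mean(sub$passed_endrange_pro)) else NA_real_,
      pct_passed_upright_anti = if (has_flags)
        .round1(100 * mean(sub$passed_upright_anti)) else NA_real_,
      pct_passed_both = if (has_flags)
        .round1(100 * mean(sub$passed_endrange_pro &
                             sub$passed_upright_anti)) else NA_real_,
      stringsAsFactors = FALSE)
  }))
  n <- nrow(records)
  n_a <- sum(records$motion_type == "A")
  list(by_direction = by_dir, n = n, n_type_A = n_a,
       one_in_n = if (n_a > 0) round(n / n_a) else NA_integer_)
}
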