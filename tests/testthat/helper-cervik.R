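# shared fixtures and independent oracles, built in code at test time

# rotate 2D points (rows) about the origin by `deg` degrees CCW
rotate_points <- function(p, deg) {
  a <- deg * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  out <- p %*% t(R)
  rownames(out) <- rownames(p)
  out
}

# trajectory whose samples are exactly the epoch boundaries: with n_epochs =
# length(vals) - 1, every sample is a boundary, so motion_summary reads the
# given normalised boundary positions verbatim
traj_from_boundaries <- function(vals, direction = "extension",
                                 joint = "C0/C1") {
  sgn <- if (direction == "flexion") -1 else 1
  joint_trajectory(joint, direction, seq_along(vals) - 1, sgn * vals)
}

summary_from_boundaries <- function(vals, direction = "extension",
                                    joint = "C0/C1") {
  motion_summary(traj_from_boundaries(vals, direction, joint),
                 n_epochs = length(vals) - 1)
}

# random-walk trajectory for conservation / telescoping properties
random_walk_traj <- function(n = 30, direction = "extension", sd = 1) {
  joint_trajectory("C3/C4", direction, seq_len(n) - 1,
                   cumsum(stats::rnorm(n, sd = sd)))
}

# brute-force exact two-sided Mann-Whitney p by enumerating all label
# assignments (tie-free inputs only)
mw_exact_oracle <- function(x, y) {
  n1 <- length(x)
  all_v <- c(x, y)
  r <- rank(all_v)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(all_v), n1)
  us <- apply(combs, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# minimal records data frame for cohort-level functions
make_records <- function(joint, direction, motion_type, end_range,
                         surplus_pro = 0, surplus_anti = 0,
                         max_pro = NULL, subject = NULL) {
  n <- max(length(joint), length(direction), length(motion_type),
           length(end_range), length(surplus_pro), length(surplus_anti))
  df <- data.frame(
    subject = if (is.null(subject)) sprintf("S%03d", seq_len(n)) else subject,
    joint = rep_len(joint, n), direction = rep_len(direction, n),
    end_range = rep_len(end_range, n),
    surplus_pro = rep_len(surplus_pro, n),
    surplus_anti = rep_len(surplus_anti, n),
    motion_type = factor(rep_len(motion_type, n), levels = c("C", "S", "A")),
    stringsAsFactors = FALSE)
  df$max_pro <- if (is.null(max_pro)) pmax(df$end_range, 0) + df$surplus_pro
    else rep_len(max_pro, n)
  df$min_pos <- -df$surplus_anti
  df$passed_endrange_pro <- df$max_pro > df$end_range
  df$passed_upright_anti <- df$min_pos < 0
  df
}
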