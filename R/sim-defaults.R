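## Default per-level simulation parameters (degrees). End-range means/SDs
## for type C and S come from the cohort's published per-level comparisons;
## type A end-range magnitudes and anti-directional surplus (dip) statistics
## from the anti-directional motion table; pro-directional surplus from the
## surplus table; dip probabilities from the per-level counts out of 33
## subjects. Levels that the source cohort could not estimate (too few
## joints of a type) carry synthetic stand-in values chosen from reported
## whole-level averages and neighbouring levels; these are marked below and
## discussed in the methods vignette.

.sim_param_table <- local({
  jl <- c("C0/C1", "C1/C2", "C2/C3", "C3/C4", "C4/C5", "C5/C6", "C6/C7")
  flex <- data.frame(
    direction = "flexion", joint = jl,
    er_C_mean = c(4.2, 4.6, 5.1, 9.5, 11.0, 11.9, 10.0),  # C1/C2, C6/C7 stand-ins
    er_C_sd   = c(4.0, 2.5, 1.7, 2.4, 4.0, 3.9, 4.0),
    er_S_mean = c(2.8, 3.5, 4.9, 5.4, 6.7, 9.3, 9.0),
    er_S_sd   = c(2.1, 2.5, 3.6, 3.0, 4.1, 4.6, 4.5),
    er_A_mean = c(2.93, 5.97, 2.16, 2.0, 2.0, 2.0, 0.32),
    er_A_sd   = c(1.53, 2.68, 1.0, 1.0, 1.0, 1.0, 1.0),
    surplus_mean = c(2.36, 3.92, 2.71, 1.82, 1.47, 1.40, 1.48),
    surplus_sd   = c(3.20, 2.37, 1.65, 1.03, 1.18, 1.35, 2.00),
    dip_prob = c(13, 14, 14, 13, 9, 16, 18) / 33,
    dip_mean = c(2.18, 3.11, 2.08, 1.26, 1.20, 1.27, 2.04),
    dip_sd   = c(1.93, 4.67, 1.71, 0.92, 1.07, 1.03, 1.75),
    stringsAsFactors = FALSE)
  ext <- data.frame(
    direction = "extension", joint = jl,
    er_C_mean = c(11.9, 10.6, 6.2, 10.1, 11.1, 8.6, 7.8),  # C0/C1 stand-in
    er_C_sd   = c(3.5, 3.2, 3.2, 3.9, 4.1, 3.9, 4.8),
    er_S_mean = c(8.0, 6.4, 5.4, 6.08, 9.3, 8.4, 3.5),
    er_S_sd   = c(4.0, 4.3, 3.5, 3.7, 4.6, 5.0, 2.0),
    er_A_mean = c(2.72, 3.72, 1.84, 0.3, 2.0, 2.0, 2.0),
    er_A_sd   = c(1.0, 0.98, 1.48, 1.0, 1.0, 1.0, 1.0),
    surplus_mean = c(1.99, 3.38, 2.57, 1.45, 1.08, 1.78, 1.34),
    surplus_sd   = c(1.42, 1.95, 1.97, 1.18, 1.15, 1.70, 0.96),
    dip_prob = c(12, 8, 15, 14, 10, 15, 21) / 33,
    dip_mean = c(2.15, 2.47, 2.83, 1.78, 1.65, 1.23, 1.80),
    dip_sd   = c(1.42, 1.73, 1.82, 1.30, 1.23, 0.87, 1.38),
    stringsAsFactors = FALSE)
  rbind(flex, ext)
})

#' Default simulation parameters
#'
#' `default_cohort_params()` returns the per-level, per-direction parameter
#' table the cohort generator draws from (end-range mean/SD by motion type,
#' pro-directional surplus mean/SD, anti-directional dip probability and
#' magnitude, all in degrees). `default_type_mix()` returns the motion-type
#' probabilities per direction and `default_never_pro_frac()` the fraction
#' of type A joints that never pass upright pro-directionally.
#'
#' @return `default_cohort_params()`: a data frame (14 rows = 7 levels x 2
#'   directions). `default_type_mix()`: a named list of length-3 probability
#'   vectors. `default_never_pro_frac()`: a named numeric vector.
#' @export
default_cohort_params <- function() .sim_param_table

#' @rdname default_cohort_params
#' @export
default_type_mix <- function() {
  list(flexion = c(C = 0.459, S = 0.489, A = 0.052) /
         sum(c(0.459, 0.489, 0.052)),
       extension = c(C = 0.468, S = 0.472, A = 0.061) /
         sum(c(0.468, 0.472, 0.061)))
}

#' @rdname default_cohort_params
#' @export
default_never_pro_frac <- function() {
  c(flexion = 0.9 / 5.2, extension = 2.2 / 6.1)
}
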