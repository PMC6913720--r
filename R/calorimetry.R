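# Indirect-calorimetry processing: cumulative calorie records -> net
# (above-basal) walking expenditure rates.

#' Construct a calorimetry series
#'
#' @param times_s Strictly increasing sample times, seconds.
#' @param cumulative_kcal Nondecreasing cumulative energy, kcal.
#' @return Object of class `gp_calorimetry_series`.
#' @export
calorimetry_series <- function(times_s, cumulative_kcal) {
  if (length(times_s) != length(cumulative_kcal) || length(times_s) < 2)
    stop("need >= 2 paired samples", call. = FALSE)
  if (any(diff(times_s) <= 0))
    stop("times_s must be strictly increasing", call. = FALSE)
  if (any(diff(cumulative_kcal) < -1e-9))
    stop("cumulative_kcal must be nondecreasing", call. = FALSE)
  structure(list(times_s = as.numeric(times_s),
                 cumulative_kcal = as.numeric(cumulative_kcal)),
            class = "gp_calorimetry_series")
}

#' Gross expenditure rate from a cumulative-calorie series
#'
#' Ordinary least-squares slope of cumulative energy against time over the
#' trimmed window. A slope (rather than an endpoint difference) is used
#' because it is robust to sample-level noise; the leading trim discards
#' the ramp-in before consumption stabilises to a linear rate.
#'
#' @param series A [calorimetry_series()].
#' @param trim_head_s,trim_tail_s Seconds discarded at the start / end
#'   (defaults 50 and 10).
#' @return Gross expenditure rate, kcal/s.
#' @export
gross_rate <- function(series, trim_head_s = 50, trim_tail_s = 10) {
  stopifnot(inherits(series, "gp_calorimetry_series"))
  t <- series$times_s
  keep <- t >= t[1] + trim_head_s & t <= t[length(t)] - trim_tail_s
  if (sum(keep) < 2)
    stop("trimmed calorimetry window contains fewer than 2 samples",
         call. = FALSE)
  tt <- t[keep]; yy <- series$cumulative_kcal[keep]
  unname(stats::coef(stats::lm(yy ~ tt))[2])
}

#' Basal metabolic rate model
#'
#' @param formula_id "harris_benedict_revised" (default) or "constant".
#' @param constant_kcal_per_s Required when `formula_id = "constant"`.
#' @return Object of class `gp_basal_model`.
#' @export
basal_model <- function(formula_id = c("harris_benedict_revised", "constant"),
                        constant_kcal_per_s = NULL) {
  formula_id <- match.arg(formula_id)
  if (formula_id == "constant" &&
      (is.null(constant_kcal_per_s) || !is.finite(constant_kcal_per_s)))
    stop("constant basal model requires constant_kcal_per_s", call. = FALSE)
  structure(list(formula_id = formula_id,
                 constant_kcal_per_s = constant_kcal_per_s),
            class = "gp_basal_model")
}

#' Basal metabolic rate of a subject
#'
#' The default is the revised Harris-Benedict equation (daily kcal
#' converted to kcal/s): for women
#' 447.593 + 9.247 M + 3.098 h_cm - 4.330 age, for men
#' 88.362 + 13.397 M + 4.799 h_cm - 5.677 age.
#'
#' @param subj A [subject()] (or list with sex, mass_kg, height_m, age_yr).
#' @param model A [basal_model()].
#' @return Basal rate, kcal/s.
#' @export
basal_rate <- function(subj, model = basal_model()) {
  stopifnot(inherits(model, "gp_basal_model"))
  if (model$formula_id == "constant") return(model$constant_kcal_per_s)
  subj <- as_gp_subject(subj)
  h_cm <- subj$height_m * 100
  daily <- if (subj$sex == "female")
    447.593 + 9.247 * subj$mass_kg + 3.098 * h_cm - 4.330 * subj$age_yr
  else
    88.362 + 13.397 * subj$mass_kg + 4.799 * h_cm - 5.677 * subj$age_yr
  daily / 86400
}

#' Net (above-basal) walking expenditure rate
#'
#' @inheritParams gross_rate
#' @param subj Subject whose basal rate is subtracted.
#' @param model A [basal_model()].
#' @param clamp_negative If TRUE, negative net rates are clamped to zero;
#'   by default they are returned as-is with a warning.
#' @return Net walking rate, kcal/s.
#' @export
net_walking_rate <- function(series, subj, model = basal_model(),
                             trim_head_s = 50, trim_tail_s = 10,
                             clamp_negative = FALSE) {
  net <- gross_rate(series, trim_head_s, trim_tail_s) - basal_rate(subj, model)
  if (net < 0) {
    warning("net walking rate is negative (basal exceeds gross)",
            call. = FALSE)
    if (clamp_negative) net <- 0
  }
  net
}

#' Write a calorimetry series as CSV
#'
#' Columns `time_s,cumulative_kcal`.
#'
#' @param series A [calorimetry_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calorimetry <- function(series, path) {
  stopifnot(inherits(series, "gp_calorimetry_series"))
  data.table::fwrite(data.frame(time_s = series$times_s,
                                cumulative_kcal = series$cumulative_kcal),
                     path)
  invisible(path)
}

#' Read a calorimetry CSV
#'
#' Irregular sampling is tolerated; times must still increase.
#'
#' @param path CSV path with header `time_s,cumulative_kcal`.
#' @return A [calorimetry_series()].
#' @export
read_calorimetry <- function(path) {
  if (!file.exists(path))
    stop("calorimetry file not found: ", path, call. = FALSE)
  df <- data.table::fread(path, data.table = FALSE)
  if (!all(c("time_s", "cumulative_kcal") %in% names(df)))
    stop("calorimetry CSV ", path,
         " must have columns time_s,cumulative_kcal", call. = FALSE)
  calorimetry_series(df$time_s, df$cumulative_kcal)
}
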