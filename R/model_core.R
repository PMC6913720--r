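# Physical constants and the piecewise walking-power model.
#
# Internally all mechanical powers are computed in watts and converted to
# kcal/s only at the model boundary (1 kcal = 4184 J), so the fitted
# coefficients gamma, b0, b1 are dimensionless and unit-system invariant.

#' Physical constants used by the walking-power model
#'
#' Returns the fixed constants of the model: standard gravity, the
#' joule content of one kilocalorie, and the leg-to-body mass ratios
#' (`alpha`) for adult women and men taken from anatomical reference data.
#'
#' @return Named list with elements `g` (m/s^2), `kcal_joules` (J/kcal),
#'   `alpha_female` and `alpha_male` (dimensionless leg-mass fractions).
#' @export
#' @examples
#' walking_constants()$g
walking_constants <- function() {
  list(g = 9.80665, kcal_joules = 4184,
       alpha_female = 0.185, alpha_male = 0.165)
}

#' Leg-to-body mass ratio for a given sex
#'
#' @param sex "female" or "male".
#' @return The dimensionless ratio alpha of single-leg mass to body mass.
#' @export
leg_mass_fraction <- function(sex) {
  sex <- match.arg(sex, c("female", "male"))
  k <- walking_constants()
  if (sex == "female") k$alpha_female else k$alpha_male
}

#' Construct a subject record
#'
#' @param sex "female" or "male".
#' @param mass_kg Body mass in kilograms (> 0).
#' @param height_m Standing height in metres (0.5, 2.5).
#' @param age_yr Age in years (>= 0).
#' @return An object of class `gp_subject`.
#' @export
#' @examples
#' subject("female", 57, 1.61, 43.6)
subject <- function(sex, mass_kg, height_m, age_yr) {
  sex <- match.arg(sex, c("female", "male"))
  if (!is.finite(mass_kg) || mass_kg <= 0)
    stop("mass_kg must be a positive number", call. = FALSE)
  if (!is.finite(height_m) || height_m <= 0.5 || height_m >= 2.5)
    stop("height_m must lie strictly between 0.5 and 2.5 m", call. = FALSE)
  if (!is.finite(age_yr) || age_yr < 0)
    stop("age_yr must be nonnegative", call. = FALSE)
  structure(list(sex = sex, mass_kg = mass_kg, height_m = height_m,
                 age_yr = age_yr),
            class = "gp_subject")
}

#' Construct a walking condition
#'
#' Incline angles are accepted in degrees everywhere (positive uphill).
#' The model was calibrated on gradients between -14 and +14 degrees; a
#' warning is emitted for conditions outside that range.
#'
#' @param speed_mps Treadmill/walking speed, m/s (>= 0).
#' @param incline_deg Surface gradient in degrees; positive is uphill.
#' @param step_freq_hz Per-foot stride frequency, Hz (>= 0).
#' @return An object of class `gp_condition`.
#' @export
walk_condition <- function(speed_mps, incline_deg, step_freq_hz) {
  if (!is.finite(speed_mps) || speed_mps < 0)
    stop("speed_mps must be nonnegative", call. = FALSE)
  if (!is.finite(incline_deg) || abs(incline_deg) > 90)
    stop("incline_deg must be finite with |incline_deg| <= 90", call. = FALSE)
  if (!is.finite(step_freq_hz) || step_freq_hz < 0)
    stop("step_freq_hz must be nonnegative", call. = FALSE)
  if (abs(incline_deg) > 14)
    warning("incline_deg outside the calibrated range of +/-14 degrees",
            call. = FALSE)
  structure(list(speed_mps = speed_mps, incline_deg = incline_deg,
                 step_freq_hz = step_freq_hz),
            class = "gp_condition")
}

#' Construct a model coefficient set
#'
#' The four coefficients of the piecewise model: `gamma` scales kinetic
#' power, `b0` scales potential power (its inverse is the efficiency of
#' converting metabolic to potential energy), `b1` is the dimensionless
#' quadratic downhill coefficient (in units of `p0`), and `p0` is the
#' constant power offset in kcal/s.
#'
#' @param gamma,b0,b1 Dimensionless coefficients.
#' @param p0 Constant offset, kcal/s (> 0).
#' @param sex Optional label "female"/"male" recording which calibration
#'   the set belongs to.
#' @return Object of class `gp_coefficients`.
#' @export
coefficient_set <- function(gamma, b0, b1, p0, sex = NA_character_) {
  vals <- c(gamma = gamma, b0 = b0, b1 = b1, p0 = p0)
  if (!all(is.finite(vals)))
    stop("all coefficients must be finite", call. = FALSE)
  if (p0 <= 0)
    stop("p0 must be positive (kcal/s)", call. = FALSE)
  if (any(vals[c("gamma", "b0", "b1")] < 0))
    warning("negative coefficient(s): ",
            paste(names(which(vals[1:3] < 0)), collapse = ", "),
            call. = FALSE)
  structure(list(gamma = gamma, b0 = b0, b1 = b1, p0 = p0,
                 sex = if (is.null(sex)) NA_character_ else sex),
            class = "gp_coefficients")
}

#' Reference coefficient sets from the treadmill calibration study
#'
#' Per-sex coefficient values obtained by two-stage regression on a
#' 73-participant treadmill cohort walking at gradients between -14 and
#' +14 degrees, with indirect calorimetry as the criterion measure.
#'
#' @param sex "female" or "male".
#' @return A [coefficient_set()].
#' @export
#' @examples
#' reference_coefficients("male")
reference_coefficients <- function(sex) {
  sex <- match.arg(sex, c("female", "male"))
  if (sex == "female")
    coefficient_set(gamma = 0.662, b0 = 1.591, b1 = 0.575, p0 = 0.042,
                    sex = "female")
  else
    coefficient_set(gamma = 0.517, b0 = 1.694, b1 = 1.086, p0 = 0.058,
                    sex = "male")
}

#' Kinetic power regressor
#'
#' Rate of kinetic-energy turnover of the swinging legs: each leg is
#' accelerated and decelerated once per stride, giving work per cycle
#' proportional to M v^2 and hence power P_K = 2 M v^2 f. Leg mass and
#' peak leg speed are absorbed into the fitted coefficient gamma.
#'
#' @param mass_kg Body mass, kg.
#' @param speed_mps Walking speed, m/s.
#' @param step_freq_hz Per-foot stride frequency, Hz.
#' @return P_K in watts. Vectorised.
#' @export
#' @examples
#' kinetic_power(70, 1.5, 1.0)  # 315 W
kinetic_power <- function(mass_kg, speed_mps, step_freq_hz) {
  if (any(!is.finite(mass_kg)) || any(mass_kg < 0) ||
      any(!is.finite(speed_mps)) || any(speed_mps < 0) ||
      any(!is.finite(step_freq_hz)) || any(step_freq_hz < 0))
    stop("kinetic_power: all arguments must be finite and nonnegative",
         call. = FALSE)
  2 * mass_kg * speed_mps^2 * step_freq_hz
}

#' Potential power regressor
#'
#' Rate of change of gravitational potential energy while walking at
#' speed v parallel to a surface inclined theta degrees from horizontal:
#' P_U = M g v sin(theta). Negative downhill.
#'
#' @inheritParams kinetic_power
#' @param incline_deg Gradient in degrees, positive uphill.
#' @return P_U in watts (sign matches the sign of the incline). Vectorised.
#' @export
#' @examples
#' potential_power(70, 1.5, 4)
potential_power <- function(mass_kg, speed_mps, incline_deg) {
  if (any(!is.finite(mass_kg)) || any(mass_kg <= 0))
    stop("potential_power: mass_kg must be positive", call. = FALSE)
  if (any(!is.finite(speed_mps)) || any(speed_mps < 0))
    stop("potential_power: speed_mps must be nonnegative", call. = FALSE)
  if (any(!is.finite(incline_deg)) || any(abs(incline_deg) > 90))
    stop("potential_power: |incline_deg| must be <= 90", call. = FALSE)
  walking_constants()$g * mass_kg * speed_mps * sin(incline_deg * pi / 180)
}

# Piecewise model evaluated directly on power regressors already expressed
# in kcal/s. The downhill branch is selected by the sign of the incline,
# not of p_u, so theta = 0 always takes the linear branch (both branches
# coincide there since p_u = 0).
model_predict <- function(coeffs, p_k_kcal_s, p_u_kcal_s, incline_deg) {
  stopifnot(inherits(coeffs, "gp_coefficients"))
  down <- incline_deg < 0
  if (any(down) && coeffs$p0 <= 0)
    stop("downhill branch requires p0 > 0 (division by p0)", call. = FALSE)
  coeffs$gamma * p_k_kcal_s + coeffs$b0 * p_u_kcal_s + coeffs$p0 +
    ifelse(down, coeffs$b1 * p_u_kcal_s^2 / coeffs$p0, 0)
}

#' Predict net walking energy-expenditure rate
#'
#' Evaluates the piecewise model
#' \deqn{P = \gamma P_K + b_0 P_U + P_0 \quad (\theta \ge 0)}
#' \deqn{P = \gamma P_K + b_0 P_U + b_1 P_U^2/P_0 + P_0 \quad (\theta < 0)}
#' with \eqn{P_K = 2 M v^2 f} and \eqn{P_U = M g v \sin\theta}, all powers
#' in kcal/s. The result is the net (above-basal) expenditure rate.
#' The two branches agree at \eqn{\theta = 0} since \eqn{P_U(0) = 0}.
#'
#' @param coeffs A [coefficient_set()].
#' @param subj A [subject()] (only `mass_kg` is used here).
#' @param cond A [walk_condition()].
#' @return Net expenditure rate in kcal/s.
#' @seealso [predict_net_kcal_min()] for the kcal/min convenience scale.
#' @export
#' @examples
#' s <- subject("female", 57, 1.61, 43.6)
#' predict_net_power(reference_coefficients("female"),
#'                   s, walk_condition(1.4, 0, 1.0857))
predict_net_power <- function(coeffs, subj, cond) {
  stopifnot(inherits(coeffs, "gp_coefficients"),
            inherits(subj, "gp_subject"),
            inherits(cond, "gp_condition"))
  kj <- walking_constants()$kcal_joules
  pk <- kinetic_power(subj$mass_kg, cond$speed_mps, cond$step_freq_hz) / kj
  pu <- potential_power(subj$mass_kg, cond$speed_mps, cond$incline_deg) / kj
  model_predict(coeffs, pk, pu, cond$incline_deg)
}

#' Predicted expenditure rate in kcal/min
#'
#' @inheritParams predict_net_power
#' @return 60 times [predict_net_power()], kcal/min.
#' @export
predict_net_kcal_min <- function(coeffs, subj, cond) {
  60 * predict_net_power(coeffs, subj, cond)
}

#' Peak-leg-speed to walking-speed ratio from fitted coefficients
#'
#' Decomposes the fitted kinetic coefficient as gamma = alpha beta^2 / eta
#' with eta the metabolic-to-mechanical conversion efficiency; assuming the
#' kinetic and potential efficiencies are equal (eta = 1/b0) gives
#' beta = sqrt(gamma / (alpha b0)), the ratio of the peak speed of the leg
#' centre of mass to the average walking speed.
#'
#' @param gamma Fitted kinetic coefficient (> 0).
#' @param alpha Leg-to-body mass ratio (> 0), see [leg_mass_fraction()].
#' @param b0 Fitted potential coefficient (> 0).
#' @return The dimensionless ratio beta.
#' @export
#' @examples
#' beta_from_coefficients(0.517, 0.165, 1.694)  # ~1.36
beta_from_coefficients <- function(gamma, alpha, b0) {
  if (any(!is.finite(c(gamma, alpha, b0))) || any(c(gamma, alpha, b0) <= 0))
    stop("beta_from_coefficients: all inputs must be positive", call. = FALSE)
  sqrt(gamma / (alpha * b0))
}

#' Write a coefficient set to a flat key-value file
#'
#' The on-disk format is flat YAML with keys `gamma`, `b0`, `b1`,
#' `p0_kcal_per_s` and `sex`.
#'
#' @param coeffs A [coefficient_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_coefficients <- function(coeffs, path) {
  stopifnot(inherits(coeffs, "gp_coefficients"))
  yaml::write_yaml(list(gamma = coeffs$gamma, b0 = coeffs$b0,
                        b1 = coeffs$b1, p0_kcal_per_s = coeffs$p0,
                        sex = coeffs$sex),
                   path)
  invisible(path)
}

#' Read a coefficient set from a flat key-value file
#'
#' @param path File written by [write_coefficients()] (or hand-authored
#'   with the same keys). Missing keys are rejected.
#' @return A [coefficient_set()].
#' @export
read_coefficients <- function(path) {
  if (!file.exists(path))
    stop("coefficient file not found: ", path, call. = FALSE)
  x <- yaml::read_yaml(path)
  need <- c("gamma", "b0", "b1", "p0_kcal_per_s", "sex")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("coefficient file ", path, " is missing key(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  coefficient_set(as.numeric(x$gamma), as.numeric(x$b0), as.numeric(x$b1),
                  as.numeric(x$p0_kcal_per_s),
                  sex = if (is.null(x$sex)) NA_character_ else as.character(x$sex))
}

#' @export
print.gp_coefficients <- function(x, ...) {
  cat(sprintf("Walking-power coefficients (%s):\n",
              ifelse(is.na(x$sex), "unlabelled", x$sex)))
  cat(sprintf("  gamma = %.4g  b0 = %.4g  b1 = %.4g  p0 = %.4g kcal/s\n",
              x$gamma, x$b0, x$b1, x$p0))
  invisible(x)
}

#' @export
print.gp_subject <- function(x, ...) {
  cat(sprintf("Subject: %s, %.1f kg, %.2f m, %.1f yr\n",
              x$sex, x$mass_kg, x$height_m, x$age_yr))
  invisible(x)
}
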