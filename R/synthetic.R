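# Synthetic study generator.
#
# Generates cohorts, trials, insole pressure traces and calorimetry series
# with exactly the statistical structure the model and its processing
# pipeline assume, providing ground truth for every other module: a failed
# end-to-end recovery therefore localises a bug to the processing code,
# not the data.

#' Study design for a synthetic validation experiment
#'
#' Defaults mirror the treadmill protocol the model was calibrated on:
#' gradients 0, +/-4, +/-9, +/-14 degrees, roughly 5-minute sessions, and
#' trial-level observation noise at the calibration residual scale
#' (0.016 kcal/s). The walking-speed set brackets normal walking speeds.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param incline_set_deg Gradient set, degrees.
#' @param speed_set_mps Speed set, m/s.
#' @param session_duration_s Session length, seconds (> 60).
#' @param noise_sd_kcal_s SD of trial-level observation noise, kcal/s.
#' @param seed Integer RNG seed making the whole study deterministic.
#' @return Object of class `gp_study_design`.
#' @export
study_design <- function(n_subjects,
                         incline_set_deg = c(-14, -9, -4, 0, 4, 9, 14),
                         speed_set_mps = c(0.8, 1.1, 1.4, 1.7, 2.0),
                         session_duration_s = 300,
                         noise_sd_kcal_s = 0.016,
                         seed = 1L) {
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  if (session_duration_s <= 60)
    stop("session_duration_s must exceed 60 s", call. = FALSE)
  if (noise_sd_kcal_s < 0) stop("noise must be nonnegative", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects),
                 incline_set_deg = incline_set_deg,
                 speed_set_mps = speed_set_mps,
                 session_duration_s = session_duration_s,
                 noise_sd_kcal_s = noise_sd_kcal_s,
                 seed = as.integer(seed)),
            class = "gp_study_design")
}

#' Gait profile for the pressure-trace simulator
#'
#' @param stride_freq_hz Per-foot stride frequency, Hz (> 0).
#' @param stance_fraction Fraction of the cycle with the foot on the
#'   ground, strictly in (0, 1); 0.62 is typical of walking.
#' @param faulty_sensor Optional `list(index =, value =)`: sensor
#'   1..16 (L1..L8 then R1..R8) stuck at `value` (1 or 2) even during
#'   swing, emulating residual pressure or a fault.
#' @return Object of class `gp_gait_profile`.
#' @export
gait_profile <- function(stride_freq_hz, stance_fraction = 0.62,
                         faulty_sensor = NULL) {
  if (!is.finite(stride_freq_hz) || stride_freq_hz <= 0)
    stop("stride_freq_hz must be positive", call. = FALSE)
  if (stance_fraction <= 0 || stance_fraction >= 1)
    stop("stance_fraction must lie strictly in (0, 1)", call. = FALSE)
  if (!is.null(faulty_sensor)) {
    if (is.null(faulty_sensor$index) || is.null(faulty_sensor$value) ||
        faulty_sensor$index < 1 || faulty_sensor$index > 16 ||
        !faulty_sensor$value %in% 1:2)
      stop("faulty_sensor must be list(index = 1..16, value = 1 or 2)",
           call. = FALSE)
  }
  structure(list(stride_freq_hz = stride_freq_hz,
                 stance_fraction = stance_fraction,
                 faulty_sensor = faulty_sensor),
            class = "gp_gait_profile")
}

#' Sample a synthetic cohort
#'
#' Per-sex truncated-normal anthropometrics chosen so the pooled cohort
#' moments approximate the calibration cohort (pooled mean height about
#' 168.3 cm, mean mass about 68.1 kg, ages 20-60 centred on 43.6 years).
#' The per-sex distributions themselves are synthetic conventions, not
#' estimates of the original cohort.
#'
#' @param n Number of subjects.
#' @param seed Optional seed (restores the caller's RNG state).
#' @param p_female Probability a subject is female (default 0.5).
#' @return data.frame `subject_id, sex, mass_kg, height_m, age_yr`.
#' @export
sample_subjects <- function(n, seed = NULL, p_female = 0.5) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  with_seed(seed, {
    sex <- ifelse(stats::runif(n) < p_female, "female", "male")
    fem <- sex == "female"
    height <- rnorm_trunc(n, ifelse(fem, 1.61, 1.75), 0.06, 1.40, 2.05)
    mass <- rnorm_trunc(n, ifelse(fem, 61, 74), 10, 35, 130)
    age <- rnorm_trunc(n, 43.6, 15, 20, 60)
    data.frame(subject_id = sprintf("P%04d", seq_len(n)), sex = sex,
               mass_kg = mass, height_m = height, age_yr = age,
               stringsAsFactors = FALSE)
  })
}

#' Step frequency implied by walking speed and height
#'
#' Inverts the empirical cadence line fh = 0.52 v + 1.02 (m/s):
#' f = (0.52 v + 1.02)/h, optionally with Gaussian noise on f, floored at
#' 0.1 Hz.
#'
#' @param speed_mps Walking speed, m/s (> 0).
#' @param height_m Height, m (> 0).
#' @param noise_sd SD of Gaussian noise added to f, Hz.
#' @param seed Optional seed.
#' @param slope,intercept Cadence-line parameters (defaults 0.52 and
#'   1.02 m/s).
#' @return Step frequency, Hz. Vectorised over speed and height.
#' @export
#' @examples
#' cadence_from_speed(1.5, 1.70)  # ~1.059 Hz
cadence_from_speed <- function(speed_mps, height_m, noise_sd = 0,
                               seed = NULL, slope = 0.52, intercept = 1.02) {
  if (any(!is.finite(height_m)) || any(height_m <= 0))
    stop("height_m must be positive", call. = FALSE)
  if (any(!is.finite(speed_mps)) || any(speed_mps <= 0))
    stop("speed_mps must be positive", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  with_seed(seed, {
    n <- max(length(speed_mps), length(height_m))
    f <- (slope * speed_mps + intercept) / height_m
    if (noise_sd > 0) f <- f + stats::rnorm(n, 0, noise_sd)
    pmax(f, 0.1)
  })
}

#' Synthetic cadence-line records
#'
#' Draws speeds and heights uniformly and sets the product f h on the
#' cadence line plus Gaussian noise (noise applied to f h, in m/s) — the
#' sampling scheme used to exercise [cadence_regression()].
#'
#' @param n Number of records.
#' @param seed Optional seed.
#' @param speed_range,height_range Uniform sampling ranges.
#' @param noise_sd_fh SD of the noise on the product f h, m/s.
#' @param slope,intercept Generating line.
#' @return data.frame `speed_mps, height_m, step_freq_hz`.
#' @export
sample_cadence_records <- function(n, seed = NULL,
                                   speed_range = c(0.8, 2.0),
                                   height_range = c(1.5, 1.9),
                                   noise_sd_fh = 0.1,
                                   slope = 0.52, intercept = 1.02) {
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  with_seed(seed, {
    v <- stats::runif(n, speed_range[1], speed_range[2])
    h <- stats::runif(n, height_range[1], height_range[2])
    fh <- slope * v + intercept + stats::rnorm(n, 0, noise_sd_fh)
    data.frame(speed_mps = v, height_m = h,
               step_freq_hz = pmax(fh / h, 0.1))
  })
}

#' Simulate one trial record
#'
#' Draws the step frequency from the cadence line (unless overridden),
#' evaluates the piecewise model, and adds Gaussian observation noise.
#'
#' @param subj A [subject()] (or one-row cohort entry).
#' @param speed_mps,incline_deg Walking condition.
#' @param coeffs Generating [coefficient_set()].
#' @param noise_sd_kcal_s Observation noise SD, kcal/s.
#' @param seed Optional seed.
#' @param cadence_noise_sd SD of the cadence noise, Hz (default 0.05).
#' @param step_freq_hz Optional override of the step frequency (e.g. 0
#'   for a standing measurement).
#' @return One-row data.frame with the trial fields, the power
#'   regressors, `p_measured_kcal_s` and the noiseless
#'   `true_net_rate_kcal_s`.
#' @export
simulate_trial <- function(subj, speed_mps, incline_deg, coeffs,
                           noise_sd_kcal_s = 0.016, seed = NULL,
                           cadence_noise_sd = 0.05, step_freq_hz = NULL) {
  subj <- as_gp_subject(subj)
  stopifnot(inherits(coeffs, "gp_coefficients"))
  with_seed(seed, {
    f <- if (!is.null(step_freq_hz)) step_freq_hz
         else if (speed_mps == 0) 0
         else cadence_from_speed(speed_mps, subj$height_m, cadence_noise_sd)
    kj <- walking_constants()$kcal_joules
    pk <- kinetic_power(subj$mass_kg, speed_mps, f) / kj
    pu <- potential_power(subj$mass_kg, speed_mps, incline_deg) / kj
    p_true <- model_predict(coeffs, pk, pu, incline_deg)
    p_meas <- p_true + if (noise_sd_kcal_s > 0)
      stats::rnorm(1, 0, noise_sd_kcal_s) else 0
    data.frame(sex = subj$sex, mass_kg = subj$mass_kg,
               height_m = subj$height_m, age_yr = subj$age_yr,
               speed_mps = speed_mps, incline_deg = incline_deg,
               step_freq_hz = f, p_k_kcal_s = pk, p_u_kcal_s = pu,
               p_measured_kcal_s = p_meas, true_net_rate_kcal_s = p_true)
  })
}

#' Simulate a table of model trials for one sex
#'
#' Vectorised trial factory used for parameter-recovery studies: each
#' trial draws a fresh subject, a speed and gradient uniformly from the
#' design sets, a cadence from the cadence line, and an observed power
#' equal to the model prediction plus Gaussian noise.
#'
#' @param n_trials Number of trials.
#' @param coeffs Generating [coefficient_set()].
#' @param sex "female" or "male".
#' @param seed Optional seed.
#' @param incline_set_deg,speed_set_mps Condition sets.
#' @param noise_sd_kcal_s Observation noise SD, kcal/s.
#' @param cadence_noise_sd Cadence noise SD, Hz.
#' @return data.frame of trial records (one per row) including the power
#'   regressors and `true_net_rate_kcal_s`.
#' @export
simulate_model_trials <- function(n_trials, coeffs, sex, seed = NULL,
                                  incline_set_deg = c(-14, -9, -4, 0, 4, 9, 14),
                                  speed_set_mps = c(0.8, 1.1, 1.4, 1.7, 2.0),
                                  noise_sd_kcal_s = 0.016,
                                  cadence_noise_sd = 0.05) {
  sex <- match.arg(sex, c("female", "male"))
  stopifnot(inherits(coeffs, "gp_coefficients"))
  if (n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  with_seed(seed, {
    cohort <- sample_subjects(n_trials,
                              p_female = if (sex == "female") 1 else 0)
    v <- sample(speed_set_mps, n_trials, replace = TRUE)
    th <- sample(incline_set_deg, n_trials, replace = TRUE)
    f <- cadence_from_speed(v, cohort$height_m, cadence_noise_sd)
    kj <- walking_constants()$kcal_joules
    pk <- kinetic_power(cohort$mass_kg, v, f) / kj
    pu <- potential_power(cohort$mass_kg, v, th) / kj
    p_true <- model_predict(coeffs, pk, pu, th)
    p_meas <- p_true + stats::rnorm(n_trials, 0, noise_sd_kcal_s)
    data.frame(subject_id = cohort$subject_id, sex = sex,
               mass_kg = cohort$mass_kg, height_m = cohort$height_m,
               speed_mps = v, incline_deg = th, step_freq_hz = f,
               p_k_kcal_s = pk, p_u_kcal_s = pu,
               p_measured_kcal_s = p_meas, true_net_rate_kcal_s = p_true)
  })
}

#' Simulate an insole pressure trace
#'
#' Generates a 10 Hz, 16-channel trace from a phase model of the stride:
#' each foot cycles through stance (heel sensors loading first, then
#' midfoot, then toe, with the mid-stance sum well above the upper
#' detection threshold) and swing (all sensors 0, or the stuck value for
#' a configured faulty sensor); the right foot runs half a cycle out of
#' phase with the left.
#'
#' @param profile A [gait_profile()].
#' @param duration_s Trace length, seconds (>= 10).
#' @param seed Optional seed; when given, the initial stride phase is
#'   randomised, otherwise both feet start at phase 0 / 0.5.
#' @param dt_s Sampling interval (default 0.1 s).
#' @return List with `trace` (a [pressure_trace()]) and `true_steps`
#'   (named integer vector of per-foot stance-to-swing transitions).
#' @export
simulate_pressure_trace <- function(profile, duration_s, seed = NULL,
                                    dt_s = 0.1) {
  stopifnot(inherits(profile, "gp_gait_profile"))
  if (duration_s < 10) stop("duration_s must be >= 10 s", call. = FALSE)
  with_seed(seed, {
    phase0 <- if (is.null(seed)) 0 else stats::runif(1)
    n <- round(duration_s / dt_s)
    t <- (seq_len(n) - 1) * dt_s
    sf <- profile$stance_fraction
    foot <- function(offset) {
      phase <- (t * profile$stride_freq_hz + phase0 + offset) %% 1
      stance <- phase < sf
      s <- phase / sf                       # position within stance, [0,1)
      m <- matrix(0L, n, 8)
      m[, 1:3] <- 2L * (stance & s < 0.65)  # heel
      m[, 4:5] <- 1L * (stance & s > 0.15 & s < 0.85)
      m[, 6:8] <- 2L * (stance & s > 0.35)  # toe
      list(m = m, steps = sum(stance[-n] & !stance[-1]))
    }
    L <- foot(0); R <- foot(0.5)
    if (!is.null(profile$faulty_sensor)) {
      i <- profile$faulty_sensor$index
      v <- as.integer(profile$faulty_sensor$value)
      if (i <= 8) L$m[, i] <- pmax(L$m[, i], v)
      else R$m[, i - 8] <- pmax(R$m[, i - 8], v)
    }
    list(trace = pressure_trace(L$m, R$m, start_time_s = 0, dt_s = dt_s),
         true_steps = c(left = L$steps, right = R$steps))
  })
}

#' Simulate a cumulative-calorie series
#'
#' Emulates a portable gas analyzer: the expenditure rate ramps linearly
#' from zero to (net + basal) over `ramp_s` seconds (consumption takes
#' about 30 s to stabilise), then stays constant; cumulative energy is
#' its integral plus independent Gaussian noise on each increment,
#' clamped so the series never decreases.
#'
#' @param net_rate_kcal_s True net walking rate, kcal/s (>= 0).
#' @param basal_rate_kcal_s Basal rate, kcal/s (>= 0).
#' @param duration_s Series length, seconds.
#' @param noise_sd_kcal SD of per-sample increment noise, kcal.
#' @param seed Optional seed.
#' @param ramp_s Ramp-in duration, seconds (default 30).
#' @param dt_s Sampling interval, seconds (default 1).
#' @return A [calorimetry_series()].
#' @export
simulate_calorimetry <- function(net_rate_kcal_s, basal_rate_kcal_s,
                                 duration_s, noise_sd_kcal = 0.005,
                                 seed = NULL, ramp_s = 30, dt_s = 1) {
  if (net_rate_kcal_s < 0 || basal_rate_kcal_s < 0)
    stop("rates must be nonnegative", call. = FALSE)
  if (duration_s <= 0) stop("duration_s must be positive", call. = FALSE)
  with_seed(seed, {
    t <- seq(0, duration_s, by = dt_s)
    full <- net_rate_kcal_s + basal_rate_kcal_s
    cum <- ifelse(t < ramp_s, full * t^2 / (2 * ramp_s),
                  full * (t - ramp_s / 2))
    inc <- diff(cum)
    if (noise_sd_kcal > 0)
      inc <- pmax(inc + stats::rnorm(length(inc), 0, noise_sd_kcal), 0)
    calorimetry_series(t, c(0, cumsum(inc)))
  })
}

#' Materialise a full synthetic study on disk
#'
#' For every subject x gradient x speed session, writes the insole
#' pressure CSV and calorimetry CSV in the formats the processing modules
#' read, plus a session manifest, a ground-truth sidecar and the
#' generating per-sex coefficient files. Fully deterministic under
#' `design$seed`.
#'
#' @param design A [study_design()].
#' @param coeffs_by_sex Named list `list(female =, male =)` of generating
#'   [coefficient_set()]s (default: the reference calibration).
#' @param out_dir Output directory (created if needed).
#' @param basal A [basal_model()] used to generate gross calorimetry.
#' @param cadence_noise_sd Cadence noise SD, Hz.
#' @return List with `manifest` (data.frame), `truth` (data.frame),
#'   `manifest_path`, `truth_path`, `out_dir`.
#' @export
make_study <- function(design,
                       coeffs_by_sex = list(
                         female = reference_coefficients("female"),
                         male = reference_coefficients("male")),
                       out_dir, basal = basal_model(),
                       cadence_noise_sd = 0.05) {
  stopifnot(inherits(design, "gp_study_design"))
  dir.create(file.path(out_dir, "traces"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "calorimetry"), showWarnings = FALSE)
  with_seed(design$seed, {
    cohort <- sample_subjects(design$n_subjects)
    grid <- expand.grid(subject = seq_len(design$n_subjects),
                        incline_deg = design$incline_set_deg,
                        speed_mps = design$speed_set_mps,
                        KEEP.OUT.ATTRS = FALSE)
    grid <- grid[order(grid$subject, grid$incline_deg, grid$speed_mps), ]
    kj <- walking_constants()$kcal_joules
    rows <- vector("list", nrow(grid))
    for (k in seq_len(nrow(grid))) {
      su <- cohort[grid$subject[k], ]
      v <- grid$speed_mps[k]; th <- grid$incline_deg[k]
      id <- sprintf("S%04d_%s", k, su$subject_id)
      f <- cadence_from_speed(v, su$height_m, cadence_noise_sd)
      coeffs <- coeffs_by_sex[[su$sex]]
      pk <- kinetic_power(su$mass_kg, v, f) / kj
      pu <- potential_power(su$mass_kg, v, th) / kj
      p_net <- model_predict(coeffs, pk, pu, th) +
        stats::rnorm(1, 0, design$noise_sd_kcal_s)
      p_net <- max(p_net, 1e-4)  # generator precondition: rate >= 0
      b <- basal_rate(su, basal)
      tr <- simulate_pressure_trace(gait_profile(f),
                                    design$session_duration_s)
      cal <- simulate_calorimetry(p_net, b, design$session_duration_s,
                                  seed = NULL)
      trace_file <- file.path("traces", paste0(id, ".csv"))
      cal_file <- file.path("calorimetry", paste0(id, ".csv"))
      write_pressure_trace(tr$trace, file.path(out_dir, trace_file))
      write_calorimetry(cal, file.path(out_dir, cal_file))
      rows[[k]] <- data.frame(session_id = id, subject_id = su$subject_id,
                              sex = su$sex, mass_kg = su$mass_kg,
                              height_m = su$height_m, age_yr = su$age_yr,
                              speed_mps = v, incline_deg = th,
                              pressure_file = trace_file,
                              calorimetry_file = cal_file,
                              true_step_freq_hz = f,
                              true_net_rate_kcal_s = p_net)
    }
    all <- do.call(rbind, rows)
    manifest <- all[, c("session_id", "subject_id", "sex", "mass_kg",
                        "height_m", "age_yr", "speed_mps", "incline_deg",
                        "pressure_file", "calorimetry_file")]
    truth <- all[, c("session_id", "true_step_freq_hz",
                     "true_net_rate_kcal_s")]
    manifest_path <- file.path(out_dir, "manifest.csv")
    truth_path <- file.path(out_dir, "ground_truth.csv")
    data.table::fwrite(manifest, manifest_path)
    data.table::fwrite(truth, truth_path)
    for (s in names(coeffs_by_sex))
      write_coefficients(coeffs_by_sex[[s]],
                         file.path(out_dir, paste0("coefficients_", s, ".yml")))
    list(manifest = manifest, truth = truth,
         manifest_path = manifest_path, truth_path = truth_path,
         out_dir = out_dir)
  })
}
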