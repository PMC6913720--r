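# Two-stage calibration of the piecewise model and evaluation metrics.
#
# Stage 1: ordinary least squares of measured net power on (P_K, P_U) over
# flat and uphill trials (theta >= 0) gives gamma, b0 and the intercept P0.
# Stage 2: with those three frozen, the downhill quadratic coefficient b1
# is the closed-form least-squares slope of the stage-1 residual on
# u = P_U^2 / P0 over flat and downhill trials (theta <= 0); flat trials
# have u = 0 and carry no weight.

# Add the mechanical power regressors (kcal/s) to a trial table.
compute_trial_powers <- function(df) {
  need <- c("mass_kg", "speed_mps", "incline_deg", "step_freq_hz")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trial table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  kj <- walking_constants()$kcal_joules
  df$p_k_kcal_s <- kinetic_power(df$mass_kg, df$speed_mps, df$step_freq_hz) / kj
  df$p_u_kcal_s <- potential_power(df$mass_kg, df$speed_mps, df$incline_deg) / kj
  df
}

#' Read a trials table from CSV
#'
#' Expects columns `subject_id,sex,mass_kg,height_m,speed_mps,incline_deg,
#' step_freq_hz,p_measured_kcal_s`; the kinetic and potential power
#' regressors are computed internally.
#'
#' @param path CSV path.
#' @return data.frame with the input columns plus `p_k_kcal_s`,
#'   `p_u_kcal_s`.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("trials file not found: ", path, call. = FALSE)
  df <- data.table::fread(path, data.table = FALSE)
  need <- c("subject_id", "sex", "mass_kg", "height_m", "speed_mps",
            "incline_deg", "step_freq_hz", "p_measured_kcal_s")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trials CSV ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  compute_trial_powers(df)
}

#' Stage-1 fit: flat and uphill multiple regression
#'
#' OLS of measured power on kinetic and potential power with intercept,
#' restricted to trials with `incline_deg >= 0`.
#'
#' @param trials data.frame with columns `p_measured_kcal_s`,
#'   `p_k_kcal_s`, `p_u_kcal_s`, `incline_deg` (see
#'   [compute_trial_powers()] / [read_trials()]).
#' @return List with `gamma`, `b0`, `p0`, `adj_r2`, `n`.
#' @export
stage1_fit <- function(trials) {
  d <- trials[trials$incline_deg >= 0, , drop = FALSE]
  if (nrow(d) < 3)
    stop("stage 1 needs at least 3 flat/uphill trials", call. = FALSE)
  X <- cbind(1, d$p_k_kcal_s, d$p_u_kcal_s)
  if (qr(X)$rank < 3)
    stop("stage-1 design is rank-deficient (collinear regressors)",
         call. = FALSE)
  fit <- stats::lm(p_measured_kcal_s ~ p_k_kcal_s + p_u_kcal_s, data = d)
  cf <- stats::coef(fit)
  list(gamma = unname(cf["p_k_kcal_s"]), b0 = unname(cf["p_u_kcal_s"]),
       p0 = unname(cf["(Intercept)"]),
       adj_r2 = adjusted_r2(d$p_measured_kcal_s, stats::fitted(fit), 2),
       n = nrow(d))
}

#' Stage-2 fit: downhill quadratic coefficient
#'
#' With `gamma`, `b0`, `p0` frozen at their stage-1 values, fits the
#' single coefficient of the quadratic downhill term by closed-form least
#' squares of the residual r = P - gamma P_K - b0 P_U - P0 on
#' u = P_U^2 / P0 over trials with `incline_deg <= 0`:
#' b1 = sum(r u) / sum(u^2). Flat trials have u = 0 and contribute
#' nothing.
#'
#' @param trials Trial table (see [stage1_fit()]).
#' @param gamma,b0,p0 Frozen stage-1 coefficients (`p0 > 0`).
#' @return The scalar b1.
#' @export
stage2_fit <- function(trials, gamma, b0, p0) {
  if (!is.finite(p0) || p0 <= 0)
    stop("stage 2 requires p0 > 0", call. = FALSE)
  d <- trials[trials$incline_deg <= 0, , drop = FALSE]
  if (!any(d$incline_deg < 0))
    stop("stage 2 needs at least one strictly downhill trial", call. = FALSE)
  u <- d$p_u_kcal_s^2 / p0
  r <- d$p_measured_kcal_s - gamma * d$p_k_kcal_s - b0 * d$p_u_kcal_s - p0
  su2 <- sum(u^2)
  if (su2 == 0)
    stop("all stage-2 trials are flat (sum u^2 = 0)", call. = FALSE)
  sum(r * u) / su2
}

#' Fit the full model separately for each sex
#'
#' Splits the trial table by sex and runs the two-stage calibration on
#' each group; flat (`incline_deg == 0`) trials enter both stages. The
#' per-sex residual RMSD is computed from the full piecewise model over
#' all of that sex's trials.
#'
#' @param trials Trial table with a `sex` column (see [read_trials()]).
#' @return Named list (one element per sex present) of `gp_fit_result`
#'   objects: `coeffs` ([coefficient_set()]), `adj_r2_stage1`,
#'   `rmsd_kcal_s`, `rmsd_kcal_min`, `n_stage1`, `n_stage2`.
#' @export
fit_by_gender <- function(trials) {
  if (is.null(trials) || nrow(trials) == 0)
    stop("empty trial table", call. = FALSE)
  if (!all(c("p_k_kcal_s", "p_u_kcal_s") %in% names(trials)))
    trials <- compute_trial_powers(trials)
  sexes <- c("female", "male")
  present <- intersect(sexes, unique(trials$sex))
  if (!length(present))
    stop("trial table contains no female or male records", call. = FALSE)
  for (s in setdiff(sexes, present))
    warning("no trials for ", s, "; skipping that fit", call. = FALSE)
  out <- lapply(present, function(s) {
    d <- trials[trials$sex == s, , drop = FALSE]
    s1 <- tryCatch(stage1_fit(d),
                   error = function(e) stop(s, ": ", conditionMessage(e),
                                            call. = FALSE))
    b1 <- tryCatch(stage2_fit(d, s1$gamma, s1$b0, s1$p0),
                   error = function(e) stop(s, ": ", conditionMessage(e),
                                            call. = FALSE))
    if (any(c(s1$gamma, s1$b0, b1) < 0))
      warning(s, ": negative fitted coefficient(s)", call. = FALSE)
    cf <- coefficient_set(s1$gamma, s1$b0, b1, s1$p0, sex = s)
    pred <- model_predict(cf, d$p_k_kcal_s, d$p_u_kcal_s, d$incline_deg)
    r <- rmsd(pred, d$p_measured_kcal_s)
    structure(list(coeffs = cf, adj_r2_stage1 = s1$adj_r2,
                   rmsd_kcal_s = r, rmsd_kcal_min = 60 * r,
                   n_stage1 = s1$n,
                   n_stage2 = sum(d$incline_deg <= 0)),
              class = "gp_fit_result")
  })
  names(out) <- present
  out
}

#' Root-mean-square deviation
#'
#' @param predicted,observed Equal-length nonempty numeric vectors.
#' @return sqrt(mean((predicted - observed)^2)).
#' @export
rmsd <- function(predicted, observed) {
  if (length(predicted) != length(observed) || !length(predicted))
    stop("predicted and observed must be nonempty and of equal length",
         call. = FALSE)
  sqrt(mean((predicted - observed)^2))
}

#' Absolute percent error against a reference measurement
#'
#' @param predicted Model predictions.
#' @param reference Criterion (measured) values; must be nonzero.
#' @return 100 * |predicted - reference| / reference, vectorised.
#' @export
percent_error <- function(predicted, reference) {
  if (length(predicted) != length(reference))
    stop("predicted and reference must have equal length", call. = FALSE)
  if (any(reference == 0))
    stop("percent error undefined for zero reference", call. = FALSE)
  100 * abs(predicted - reference) / reference
}

#' Cadence-speed regression
#'
#' Walking speed equals step frequency times step length, and step length
#' is close to standing height, so f h is approximately linear in v. Fits
#' the OLS line of the product (step frequency x height) on speed.
#'
#' @param records data.frame with columns `speed_mps`, `step_freq_hz`,
#'   `height_m`.
#' @return List with `slope` (dimensionless) and `intercept` (m/s).
#' @export
cadence_regression <- function(records) {
  need <- c("speed_mps", "step_freq_hz", "height_m")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("cadence records missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (length(unique(records$speed_mps)) < 2)
    stop("cadence regression needs at least 2 distinct speeds", call. = FALSE)
  fh <- records$step_freq_hz * records$height_m
  cf <- stats::coef(stats::lm(fh ~ records$speed_mps))
  list(slope = unname(cf[2]), intercept = unname(cf[1]))
}

#' Adjusted coefficient of determination
#'
#' @param observed,fitted Equal-length numeric vectors.
#' @param n_params Number of fitted slope parameters (excluding the
#'   intercept).
#' @return 1 - (1 - R^2)(n - 1)/(n - n_params - 1).
#' @export
adjusted_r2 <- function(observed, fitted, n_params) {
  n <- length(observed)
  if (length(fitted) != n)
    stop("observed and fitted must have equal length", call. = FALSE)
  if (n <= n_params + 1)
    stop("adjusted R^2 requires n > n_params + 1", call. = FALSE)
  r2 <- 1 - sum((observed - fitted)^2) / sum((observed - mean(observed))^2)
  1 - (1 - r2) * (n - 1) / (n - n_params - 1)
}

#' Write a per-sex fit result to disk
#'
#' Writes the coefficient key-value file plus a one-row CSV metrics
#' report (adjusted R^2, RMSD in both units, sample sizes).
#'
#' @param fit A `gp_fit_result` from [fit_by_gender()].
#' @param coeff_path Path for the coefficient file.
#' @param metrics_path Optional path for the metrics CSV.
#' @return `coeff_path`, invisibly.
#' @export
write_fit_result <- function(fit, coeff_path, metrics_path = NULL) {
  stopifnot(inherits(fit, "gp_fit_result"))
  write_coefficients(fit$coeffs, coeff_path)
  if (!is.null(metrics_path))
    data.table::fwrite(data.frame(sex = fit$coeffs$sex,
                                  adj_r2_stage1 = fit$adj_r2_stage1,
                                  rmsd_kcal_s = fit$rmsd_kcal_s,
                                  rmsd_kcal_min = fit$rmsd_kcal_min,
                                  n_stage1 = fit$n_stage1,
                                  n_stage2 = fit$n_stage2),
                       metrics_path)
  invisible(coeff_path)
}

#' @export
print.gp_fit_result <- function(x, ...) {
  print(x$coeffs)
  cat(sprintf("  stage-1 adj R2 = %.3f (n = %d); RMSD = %.4f kcal/s (%.2f kcal/min); stage-2 n = %d\n",
              x$adj_r2_stage1, x$n_stage1, x$rmsd_kcal_s, x$rmsd_kcal_min,
              x$n_stage2))
  invisible(x)
}
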