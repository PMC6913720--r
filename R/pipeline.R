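# Session-level pipeline: manifest -> step frequencies -> net rates ->
# trial table -> fitted coefficients / evaluation.

read_manifest <- function(manifest) {
  if (is.character(manifest)) {
    if (!file.exists(manifest))
      stop("manifest not found: ", manifest, call. = FALSE)
    manifest <- data.table::fread(manifest, data.table = FALSE)
  }
  need <- c("session_id", "subject_id", "sex", "mass_kg", "height_m",
            "age_yr", "speed_mps", "incline_deg", "pressure_file",
            "calorimetry_file")
  miss <- setdiff(need, names(manifest))
  if (length(miss))
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  manifest
}

#' Detect step frequencies for every session in a manifest
#'
#' Sessions whose trace file is missing or unreadable are skipped with a
#' warning; the run continues.
#'
#' @param manifest Manifest data.frame or path to the manifest CSV.
#' @param config A [detector_config()].
#' @param data_dir Directory the manifest's relative file paths are
#'   resolved against (defaults to the manifest's own directory when a
#'   path is given, else the working directory).
#' @return data.frame `session_id, step_freq_hz`.
#' @export
detect_study <- function(manifest, config = detector_config(),
                         data_dir = NULL) {
  if (is.character(manifest) && is.null(data_dir))
    data_dir <- dirname(manifest)
  if (is.null(data_dir)) data_dir <- "."
  m <- read_manifest(manifest)
  f <- rep(NA_real_, nrow(m))
  for (k in seq_len(nrow(m))) {
    f[k] <- tryCatch(
      step_frequency(read_pressure_trace(file.path(data_dir,
                                                   m$pressure_file[k])),
                     config),
      error = function(e) {
        warning("session ", m$session_id[k], " skipped: ",
                conditionMessage(e), call. = FALSE)
        NA_real_
      })
  }
  out <- data.frame(session_id = m$session_id, step_freq_hz = f)
  out[!is.na(out$step_freq_hz), , drop = FALSE]
}

#' Compute net walking rates for every session in a manifest
#'
#' @inheritParams detect_study
#' @param basal A [basal_model()].
#' @param trim_head_s,trim_tail_s Calorimetry trims, seconds.
#' @return data.frame `session_id, gross_rate_kcal_s, basal_rate_kcal_s,
#'   net_rate_kcal_s`.
#' @export
rate_study <- function(manifest, basal = basal_model(), data_dir = NULL,
                       trim_head_s = 50, trim_tail_s = 10) {
  if (is.character(manifest) && is.null(data_dir))
    data_dir <- dirname(manifest)
  if (is.null(data_dir)) data_dir <- "."
  m <- read_manifest(manifest)
  rows <- vector("list", nrow(m))
  for (k in seq_len(nrow(m))) {
    rows[[k]] <- tryCatch({
      ser <- read_calorimetry(file.path(data_dir, m$calorimetry_file[k]))
      g <- gross_rate(ser, trim_head_s, trim_tail_s)
      b <- basal_rate(m[k, ], basal)
      data.frame(session_id = m$session_id[k], gross_rate_kcal_s = g,
                 basal_rate_kcal_s = b, net_rate_kcal_s = g - b)
    }, error = function(e) {
      warning("session ", m$session_id[k], " skipped: ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    data.frame(session_id = character(), gross_rate_kcal_s = numeric(),
               basal_rate_kcal_s = numeric(), net_rate_kcal_s = numeric())
  else out
}

#' Assemble a trial table from manifest, frequencies and rates
#'
#' Joins per-session step frequencies and net rates onto the manifest and
#' computes the power regressors; sessions missing either measurement are
#' dropped.
#'
#' @param manifest Manifest data.frame or CSV path.
#' @param freqs Output of [detect_study()].
#' @param rates Output of [rate_study()].
#' @return Trial table ready for [fit_by_gender()].
#' @export
build_trials <- function(manifest, freqs, rates) {
  m <- read_manifest(manifest)
  d <- merge(merge(m, freqs, by = "session_id"),
             rates[, c("session_id", "net_rate_kcal_s")], by = "session_id")
  d$p_measured_kcal_s <- d$net_rate_kcal_s
  compute_trial_powers(d)
}

#' Evaluate predictions against a reference measurement
#'
#' Computes RMSD (kcal/s and kcal/min) and the median and IQR of the
#' absolute percent error, overall and stratified by sex and by flat
#' versus sloped sessions.
#'
#' @param predicted,reference Equal-length paired vectors, kcal/s.
#' @param sex Optional per-record sex labels for stratification.
#' @param incline_deg Optional per-record gradients for the flat/sloped
#'   strata.
#' @return data.frame with one row per stratum: `stratum, n, rmsd_kcal_s,
#'   rmsd_kcal_min, median_pct_error, iqr_pct_error`.
#' @export
evaluate_predictions <- function(predicted, reference, sex = NULL,
                                 incline_deg = NULL) {
  if (length(predicted) != length(reference) || !length(predicted))
    stop("predicted and reference must be nonempty and paired",
         call. = FALSE)
  if (any(!is.finite(predicted)) || any(!is.finite(reference)))
    stop("unpaired or non-finite rows rejected", call. = FALSE)
  one <- function(name, idx) {
    if (!any(idx)) return(NULL)
    pe <- percent_error(predicted[idx], reference[idx])
    r <- rmsd(predicted[idx], reference[idx])
    data.frame(stratum = name, n = sum(idx), rmsd_kcal_s = r,
               rmsd_kcal_min = 60 * r,
               median_pct_error = stats::median(pe),
               iqr_pct_error = stats::IQR(pe))
  }
  all_idx <- rep(TRUE, length(predicted))
  out <- list(one("all", all_idx))
  if (!is.null(sex))
    for (s in unique(sex)) out <- c(out, list(one(s, sex == s)))
  if (!is.null(incline_deg)) {
    out <- c(out, list(one("flat", incline_deg == 0),
                       one("sloped", incline_deg != 0)))
  }
  do.call(rbind, out)
}
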