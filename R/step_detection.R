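# Foot-contact detection from insole pressure traces.
#
# The insole reports 8 coarse pressure sensors per foot at 10 Hz, each
# quantised to 0/1/2. Foot contact is classified from the per-foot pressure
# sum with a dual-threshold (hysteresis) state machine: a frame leaves the
# ground only when the sum drops strictly below the lower threshold and
# re-enters contact only when it rises strictly above the upper threshold.
# Hysteresis makes the classification robust to a sensor stuck at a small
# positive value (residual pressure or a fault), which would defeat a
# single zero threshold.

#' Detector configuration
#'
#' @param lower_threshold Pressure sum strictly below this leaves the
#'   ground (default 2).
#' @param upper_threshold Pressure sum strictly above this re-enters
#'   ground contact (default 5).
#' @param trim_head_s Seconds discarded at the start of a session before
#'   counting steps (default 50; covers the metabolic/gait run-in).
#' @param trim_tail_s Seconds discarded at the end (default 10).
#' @return Object of class `gp_detector_config`.
#' @export
detector_config <- function(lower_threshold = 2L, upper_threshold = 5L,
                            trim_head_s = 50, trim_tail_s = 10) {
  if (lower_threshold < 0 || upper_threshold > 16 ||
      lower_threshold > upper_threshold)
    stop("need 0 <= lower_threshold <= upper_threshold <= 16", call. = FALSE)
  if (trim_head_s < 0 || trim_tail_s < 0)
    stop("trims must be nonnegative", call. = FALSE)
  structure(list(lower_threshold = as.integer(lower_threshold),
                 upper_threshold = as.integer(upper_threshold),
                 trim_head_s = trim_head_s, trim_tail_s = trim_tail_s),
            class = "gp_detector_config")
}

#' Construct a pressure trace
#'
#' @param left,right Integer matrices with 8 columns (one per sensor,
#'   heel to toe) and one row per 0.1 s frame; values must be 0, 1 or 2.
#' @param start_time_s Time of the first frame, seconds.
#' @param dt_s Sampling interval, seconds (default 0.1 = 10 Hz).
#' @return Object of class `gp_pressure_trace`: list with `time_s`,
#'   `left`, `right`, `dt_s`.
#' @export
pressure_trace <- function(left, right, start_time_s = 0, dt_s = 0.1) {
  left <- as.matrix(left); right <- as.matrix(right)
  if (ncol(left) != 8 || ncol(right) != 8 || nrow(left) != nrow(right) ||
      nrow(left) < 1)
    stop("left and right must be n x 8 matrices with n >= 1", call. = FALSE)
  if (!all(left %in% 0:2) || !all(right %in% 0:2))
    stop("sensor values must be 0, 1 or 2", call. = FALSE)
  if (dt_s <= 0) stop("dt_s must be positive", call. = FALSE)
  structure(list(time_s = start_time_s + (seq_len(nrow(left)) - 1) * dt_s,
                 left = left, right = right, dt_s = dt_s),
            class = "gp_pressure_trace")
}

#' Per-frame pressure sum of one foot
#'
#' @param trace A [pressure_trace()].
#' @param side "left" or "right".
#' @return Integer vector of per-frame sums, each in 0..16.
#' @export
foot_pressure_sum <- function(trace, side = c("left", "right")) {
  stopifnot(inherits(trace, "gp_pressure_trace"))
  side <- match.arg(side)
  as.integer(rowSums(trace[[side]]))
}

#' Classify foot-contact states from a pressure-sum sequence
#'
#' The first frame is defined to be on the ground. Each following frame:
#' from on-ground, the state flips to off-ground only when the sum is
#' strictly below `lower_threshold`; from off-ground, it flips back only
#' when the sum is strictly above `upper_threshold`; sums in between leave
#' the state unchanged.
#'
#' @param sums Integer vector of per-frame pressure sums (0..16).
#' @param config A [detector_config()].
#' @param side Optional side label carried on the result.
#' @return Object of class `gp_contact_series`: list with `statuses`
#'   (factor with levels on_ground/off_ground) and `side`.
#' @export
contact_states <- function(sums, config = detector_config(), side = NA_character_) {
  stopifnot(inherits(config, "gp_detector_config"))
  if (length(sums) < 1) stop("sums must be nonempty", call. = FALSE)
  if (any(!is.finite(sums)) || any(sums < 0) || any(sums > 16))
    stop("pressure sums must lie in [0, 16]", call. = FALSE)
  # Equivalent vectorised form of the sequential rules: a frame forces
  # on (+1) above the upper threshold, forces off (-1) below the lower
  # threshold, and holds (0) in between; the state at any frame is the
  # most recent forced state (the first frame is forced on).
  forced <- integer(length(sums))
  forced[sums > config$upper_threshold] <- 1L
  forced[sums < config$lower_threshold] <- -1L
  forced[1] <- 1L
  last <- cummax(seq_along(forced) * (forced != 0L))
  st <- forced[last]
  structure(list(statuses = factor(ifelse(st == 1L, "on_ground", "off_ground"),
                                   levels = c("on_ground", "off_ground")),
                 side = side),
            class = "gp_contact_series")
}

#' Count steps in a contact series
#'
#' A step is one on-ground to off-ground transition (toe-off). A final
#' unterminated off-ground episode still contributes its transition.
#'
#' @param states A [contact_states()] result.
#' @return Integer step count.
#' @export
step_count <- function(states) {
  stopifnot(inherits(states, "gp_contact_series"))
  s <- states$statuses
  n <- length(s)
  if (n < 2) return(0L)
  sum(s[-n] == "on_ground" & s[-1] == "off_ground")
}

#' Gait events (toe-off / heel-strike) with timestamps
#'
#' A toe-off event is stamped at the first off-ground frame of each swing
#' episode, a heel-strike at the first on-ground frame after a swing.
#'
#' @param trace A [pressure_trace()].
#' @param config A [detector_config()] (trims are not applied here).
#' @return data.frame with columns `time_s`, `side`, `event`.
#' @export
step_events <- function(trace, config = detector_config()) {
  stopifnot(inherits(trace, "gp_pressure_trace"))
  one <- function(side) {
    st <- contact_states(foot_pressure_sum(trace, side), config, side)$statuses
    n <- length(st)
    if (n < 2) return(NULL)
    off <- which(st[-n] == "on_ground" & st[-1] == "off_ground") + 1L
    on  <- which(st[-n] == "off_ground" & st[-1] == "on_ground") + 1L
    rbind(
      if (length(off)) data.frame(time_s = trace$time_s[off], side = side,
                                  event = "toe_off"),
      if (length(on))  data.frame(time_s = trace$time_s[on], side = side,
                                  event = "heel_strike"))
  }
  out <- rbind(one("left"), one("right"))
  if (is.null(out))
    return(data.frame(time_s = numeric(), side = character(),
                      event = character()))
  out[order(out$time_s, out$side), , drop = FALSE]
}

# Indices of frames kept after trimming; errors if the trace is too short.
trim_window <- function(n, dt_s, config) {
  head_n <- round(config$trim_head_s / dt_s)
  tail_n <- round(config$trim_tail_s / dt_s)
  if (n * dt_s <= config$trim_head_s + config$trim_tail_s)
    stop("trace too short for the configured trims (",
         config$trim_head_s, " + ", config$trim_tail_s, " s)", call. = FALSE)
  (head_n + 1L):(n - tail_n)
}

#' Average step frequency of a trace
#'
#' Runs the contact classifier on each foot over the full trace, counts
#' toe-off transitions whose off-ground frame falls inside the trimmed
#' analysis window, divides by the window duration, and averages the two
#' feet.
#'
#' @param trace A [pressure_trace()].
#' @param config A [detector_config()] (thresholds and trims).
#' @param per_foot If TRUE, also return the per-foot frequencies.
#' @return Step frequency in Hz (strides per second per foot); with
#'   `per_foot = TRUE`, a named vector `c(mean, left, right)`.
#' @export
step_frequency <- function(trace, config = detector_config(),
                           per_foot = FALSE) {
  stopifnot(inherits(trace, "gp_pressure_trace"))
  n <- length(trace$time_s)
  keep <- trim_window(n, trace$dt_s, config)
  dur <- length(keep) * trace$dt_s
  freq_side <- function(side) {
    st <- contact_states(foot_pressure_sum(trace, side), config, side)$statuses
    idx <- which(st[-n] == "on_ground" & st[-1] == "off_ground") + 1L
    sum(idx >= keep[1] & idx <= keep[length(keep)]) / dur
  }
  fl <- freq_side("left"); fr <- freq_side("right")
  if (per_foot) c(mean = (fl + fr) / 2, left = fl, right = fr)
  else (fl + fr) / 2
}

#' Write a pressure trace as CSV
#'
#' Columns `time_s,L1,...,L8,R1,...,R8`, one row per 0.1 s frame.
#'
#' @param trace A [pressure_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pressure_trace <- function(trace, path) {
  stopifnot(inherits(trace, "gp_pressure_trace"))
  df <- data.frame(time_s = trace$time_s, trace$left, trace$right)
  names(df) <- c("time_s", paste0("L", 1:8), paste0("R", 1:8))
  data.table::fwrite(df, path)
  invisible(path)
}

#' Read a pressure trace CSV
#'
#' Expects the header `time_s,L1,...,L8,R1,...,R8`, integer sensor cells
#' in 0..2, and strict 0.1 s sampling (checked to 1e-6 s).
#'
#' @param path CSV path.
#' @param dt_s Expected sampling interval (default 0.1 s).
#' @return A [pressure_trace()].
#' @export
read_pressure_trace <- function(path, dt_s = 0.1) {
  if (!file.exists(path))
    stop("pressure trace file not found: ", path, call. = FALSE)
  df <- data.table::fread(path, data.table = FALSE)
  need <- c("time_s", paste0("L", 1:8), paste0("R", 1:8))
  if (!identical(names(df), need))
    stop("pressure CSV ", path, " must have header ",
         paste(need, collapse = ","), call. = FALSE)
  if (nrow(df) < 2)
    stop("pressure CSV ", path, " has fewer than 2 frames", call. = FALSE)
  if (any(abs(diff(df$time_s) - dt_s) > 1e-6))
    stop("pressure CSV ", path, " is not uniformly sampled at ", dt_s,
         " s (tolerance 1e-6 s)", call. = FALSE)
  pressure_trace(as.matrix(df[paste0("L", 1:8)]),
                 as.matrix(df[paste0("R", 1:8)]),
                 start_time_s = df$time_s[1], dt_s = dt_s)
}
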