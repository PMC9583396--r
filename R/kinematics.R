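#' Instantaneous angular velocity
#'
#' Differentiates an elbow-angle series with central differences (forward /
#' backward differences at the ends). Central differences are zero-lag and
#' second-order accurate, so the velocity peak of a smooth movement is not
#' shifted in time.
#'
#' @param data Data frame with `time_s` and an angle column in degrees.
#' @param col Name of the angle column (default `"elbow_angle_deg"`).
#' @return Tibble with `time_s` and `velocity_dps` (degrees per second).
#' @export
angular_velocity <- function(data, col = "elbow_angle_deg") {
  col <- value_cols(data, col)
  th <- data[[col]]
  t <- data$time_s
  if (length(th) < 3L) abort("need at least 3 samples to differentiate")
  check_finite(th, col)
  n <- length(th)
  v <- numeric(n)
  v[2:(n - 1)] <- (th[3:n] - th[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  v[1] <- (th[2] - th[1]) / (t[2] - t[1])
  v[n] <- (th[n] - th[n - 1]) / (t[n] - t[n - 1])
  tibble(time_s = t, velocity_dps = v)
}

#' Detect movement onset, offset and peak velocity
#'
#' Segments discrete movements from a (low-pass filtered) angular-velocity
#' series. Candidate movements are excursions where `|velocity|` exceeds
#' `min_peak_velocity`; within each excursion the peak-velocity time is the
#' absolute-velocity maximum, the onset is the last sample before the peak
#' with `|velocity| < threshold`, and the offset is the first sample after
#' the peak below the same threshold. Searching outward from the peak makes
#' the very low 0.01 deg/s threshold usable in practice: the search cannot
#' get stuck on the noise floor far from the movement.
#'
#' @param velocity Data frame with `time_s` and `velocity_dps` (pass the
#'   output of [angular_velocity()] after 6 Hz low-pass filtering).
#' @param threshold Velocity threshold in deg/s defining onset/offset
#'   (default 0.01).
#' @param min_peak_velocity Minimum absolute peak velocity in deg/s for an
#'   excursion to count as a movement rather than tremor/noise (default 5).
#' @param direction `"both"` keeps all excursions; `"positive"` keeps only
#'   movements with positive peak velocity (extension when the angle grows
#'   with extension), `"negative"` the converse.
#' @return Tibble with one row per movement: `movement`, `onset_s`,
#'   `peak_velocity_s`, `offset_s`, `peak_velocity_dps`, `duration_s`.
#'   Zero rows when no excursion exceeds `min_peak_velocity`.
#' @export
detect_movement_bounds <- function(velocity, threshold = 0.01, min_peak_velocity = 5,
                                   direction = c("both", "positive", "negative")) {
  direction <- match.arg(direction)
  if (!all(c("time_s", "velocity_dps") %in% names(velocity))) {
    abort("`velocity` must have columns time_s and velocity_dps")
  }
  v <- velocity$velocity_dps
  t <- velocity$time_s
  check_finite(v, "velocity_dps")
  if (threshold <= 0) abort("`threshold` must be positive")
  av <- abs(v)
  hot <- av >= min_peak_velocity
  if (!any(hot)) {
    return(tibble(movement = integer(), onset_s = double(), peak_velocity_s = double(),
                  offset_s = double(), peak_velocity_dps = double(), duration_s = double()))
  }
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  # sub-sample refinement: linear interpolation of |v| to the threshold
  # crossing between the bracketing samples (|v| changes by O(peak) per
  # sample near the boundary, so the raw sample index alone is coarse)
  interp_cross <- function(i_below, i_above) {
    if (i_above < 1 || i_above > length(av) || av[i_above] <= av[i_below]) {
      return(t[i_below])
    }
    frac <- (threshold - av[i_below]) / (av[i_above] - av[i_below])
    t[i_below] + frac * (t[i_above] - t[i_below])
  }
  out <- purrr::map(runs, function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    pk <- i0 + which.max(av[i0:i1]) - 1L
    below_pre <- which(av[seq_len(pk - 1L)] < threshold)
    onset <- if (length(below_pre)) max(below_pre) else 1L
    below_post <- which(av[seq(pk + 1L, length(av))] < threshold)
    offset <- if (length(below_post)) pk + min(below_post) else length(av)
    tibble(onset_s = interp_cross(onset, onset + 1L),
           peak_velocity_s = t[pk],
           offset_s = if (offset > pk) interp_cross(offset, offset - 1L) else t[offset],
           peak_velocity_dps = v[pk])
  })
  out <- bind_rows(out)
  if (direction == "positive") out <- filter(out, .data$peak_velocity_dps > 0)
  if (direction == "negative") out <- filter(out, .data$peak_velocity_dps < 0)
  out <- arrange(out, .data$onset_s)
  # excursions in one movement (velocity dip) can share onset/offset; merge
  out <- out[!duplicated(out[, c("onset_s", "offset_s")]), ]
  mutate(out, movement = dplyr::row_number(),
         duration_s = .data$offset_s - .data$onset_s,
         .before = 1)
}
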