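# Antagonist co-contraction: flexor RMS during extension normalized to the
# maximal-voluntary-contraction reference.

#' Root-mean-square amplitude
#'
#' @param data Data frame with `time_s` and one signal column, or a numeric
#'   vector.
#' @param window Optional time interval `c(t0, t1)` in seconds restricting
#'   the computation.
#' @param col Signal column when `data` has several.
#' @return RMS in the signal's units (volts for EMG).
#' @export
emg_rms <- function(data, window = NULL, col = NULL) {
  if (is.data.frame(data)) {
    cl <- value_cols(data, col)
    if (length(cl) != 1L) abort("pass `col` to choose among several signal columns")
    x <- data[[cl]]
    if (!is.null(window)) {
      sel <- data$time_s >= window[1] - 1e-9 & data$time_s <= window[2] + 1e-9
      if (!any(sel)) abort("`window` selects no samples")
      x <- x[sel]
    }
  } else {
    x <- data
    if (!length(x)) abort("empty input")
  }
  check_finite(x, "signal")
  sqrt(mean(x^2))
}

#' Maximal-voluntary-contraction reference
#'
#' Selects, among the MVC trials, the one whose mean torque over the
#' central plateau is maximal, and computes each flexor's reference RMS on
#' that trial's plateau. MVC trials are nominally 5 s; the central
#' `plateau` seconds (default 3) exclude the ramp-up and ramp-down.
#'
#' @param mvc Nested tibble with columns `trial` and `data`, each `data` a
#'   tibble with `time_s`, the muscle columns and `torque_nm` (as returned
#'   by [simulate_session()] or [read_mvc()]).
#' @param muscles Character vector of muscle columns (default BB and BR).
#' @param plateau Plateau duration centred in the trial, s.
#' @return Object of class `mvc_reference`: `rms` (named per-muscle RMS,
#'   volts), `selected_trial`, `max_torque_nm`.
#' @export
mvc_reference <- function(mvc, muscles = c("emg_bb_v", "emg_br_v"), plateau = 3) {
  if (!all(c("trial", "data") %in% names(mvc)) || nrow(mvc) < 1) {
    abort("`mvc` must be a nested tibble with columns trial and data")
  }
  plateau_window <- function(d) {
    t0 <- (min(d$time_s) + max(d$time_s)) / 2 - plateau / 2
    c(t0, t0 + plateau)
  }
  torque <- purrr::map_dbl(mvc$data, function(d) {
    if (!"torque_nm" %in% names(d)) abort("MVC trial is missing a torque_nm column")
    w <- plateau_window(d)
    mean(d$torque_nm[d$time_s >= w[1] & d$time_s <= w[2]])
  })
  if (all(torque <= 0)) abort("no valid MVC: torque is zero in every trial")
  sel <- which.max(torque)
  d <- mvc$data[[sel]]
  missing <- setdiff(muscles, names(d))
  if (length(missing)) abort(sprintf("MVC trial lacks muscle column(s): %s",
                                     paste(missing, collapse = ", ")))
  w <- plateau_window(d)
  rms <- vapply(muscles, function(m) emg_rms(d[, c("time_s", m)], window = w), numeric(1))
  names(rms) <- muscles
  if (any(rms <= 0)) abort("MVC reference RMS must be positive")
  structure(list(rms = rms, selected_trial = mvc$trial[sel], max_torque_nm = torque[sel],
                 plateau_s = plateau),
            class = "mvc_reference")
}

#' @export
print.mvc_reference <- function(x, ...) {
  cat(sprintf("<mvc_reference> trial %s (%.1f N.m): %s\n", x$selected_trial,
              x$max_torque_nm,
              paste(sprintf("%s = %.4g V", names(x$rms), x$rms), collapse = ", ")))
  invisible(x)
}

#' Antagonist co-contraction index
#'
#' For each movement, each flexor's EMG RMS over `[onset, offset]` is
#' divided by that muscle's MVC reference RMS; the per-movement index is
#' the mean of the per-muscle ratios, and the session index the mean over
#' movements, expressed in percent of MVC. Ratio-before-averaging makes
#' the index invariant to per-channel amplifier gains.
#'
#' @param trials Trial table from [extract_trials()] (EMG already
#'   preprocessed as for the coherence analysis; RMS is sign-invariant so
#'   rectification would not change it).
#' @param ref [mvc_reference()] for the same muscles.
#' @param muscles Flexor EMG columns (default BB and BR).
#' @return Object of class `cocontraction_index` with the session `value`
#'   (percent of MVC), and per-movement / per-muscle components.
#' @export
antagonist_cocontraction <- function(trials, ref, muscles = c("emg_bb_v", "emg_br_v")) {
  if (!inherits(ref, "mvc_reference")) abort("`ref` must be an mvc_reference")
  missing <- setdiff(muscles, names(ref$rms))
  if (length(missing)) abort(sprintf("MVC reference lacks muscle(s): %s",
                                     paste(missing, collapse = ", ")))
  per_movement <- purrr::pmap(list(trials$emg, trials$onset_s, trials$offset_s,
                                   trials$movement),
                              function(e, on, off, mv) {
    missing <- setdiff(muscles, names(e))
    if (length(missing)) abort(sprintf("trial lacks flexor channel(s): %s",
                                       paste(missing, collapse = ", ")))
    ratios <- vapply(muscles, function(m) {
      emg_rms(e[, c("time_s", m)], window = c(on, off)) / ref$rms[[m]]
    }, numeric(1))
    tibble(movement = mv, muscle = muscles, ratio = unname(ratios))
  })
  per_movement <- bind_rows(per_movement)
  per_mv <- summarise(group_by(per_movement, .data$movement),
                      ratio = mean(.data$ratio), .groups = "drop")
  structure(list(value = 100 * mean(per_mv$ratio),
                 per_movement = mutate(per_mv, percent = 100 * .data$ratio),
                 per_muscle = summarise(group_by(per_movement, .data$muscle),
                                        percent = 100 * mean(.data$ratio),
                                        .groups = "drop"),
                 n_movements = nrow(per_mv)),
            class = "cocontraction_index")
}

#' @export
print.cocontraction_index <- function(x, ...) {
  cat(sprintf("<cocontraction_index> %.1f%% of MVC over %d movements\n",
              x$value, x$n_movements))
  invisible(x)
}

#' @export
tidy.cocontraction_index <- function(x, ...) x$per_movement

#' @export
glance.cocontraction_index <- function(x, ...) {
  tibble(cocontraction_pct = x$value, n_movements = x$n_movements)
}
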