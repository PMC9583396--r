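#' Multichannel EMG + kinematics recording
#'
#' Container for one limb/session: surface EMG of the long head of triceps
#' brachii (TB, extensor), biceps brachii (BB) and brachioradialis (BR,
#' flexors) sampled at `fs_emg`, and the elbow angle sampled at `fs_kin`,
#' sharing the same time origin. EMG and kinematics keep their native
#' clocks; they are never resampled, only event times are mapped between
#' clocks.
#'
#' @param emg Tibble with `time_s`, `emg_tb_v`, `emg_bb_v`, `emg_br_v`
#'   (volts).
#' @param kin Tibble with `time_s`, `elbow_angle_deg`.
#' @param subject,group,limb,age Session metadata. `group` is typically
#'   `"stroke"` or `"control"`; `limb` one of `"paretic"`, `"non_paretic"`,
#'   `"dominant"`.
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(emg, kin, subject = "S1", group = "control",
                          limb = "dominant", age = NA_real_) {
  need_emg <- c("time_s", "emg_tb_v", "emg_bb_v", "emg_br_v")
  miss <- setdiff(need_emg, names(emg))
  if (length(miss)) abort(sprintf("emg table is missing column(s): %s", paste(miss, collapse = ", ")))
  miss <- setdiff(c("time_s", "elbow_angle_deg"), names(kin))
  if (length(miss)) abort(sprintf("kin table is missing column(s): %s", paste(miss, collapse = ", ")))
  structure(
    list(emg = as_tibble(emg), kin = as_tibble(kin),
         meta = list(subject = subject, group = group, limb = limb, age = age,
                     fs_emg = ts_fs(emg$time_s), fs_kin = ts_fs(kin$time_s))),
    class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<emg_recording> subject %s (%s, %s limb, age %s)\n",
              m$subject, m$group, m$limb, format(m$age)))
  cat(sprintf("  EMG: %d samples @ %.5g Hz (%s)\n", nrow(x$emg), m$fs_emg,
              paste(setdiff(names(x$emg), "time_s"), collapse = ", ")))
  cat(sprintf("  kinematics: %d samples @ %.5g Hz\n", nrow(x$kin), m$fs_kin))
  invisible(x)
}

#' @export
tidy.emg_recording <- function(x, ...) {
  bind_rows(
    tidyr::pivot_longer(x$emg, -"time_s", names_to = "channel", values_to = "value"),
    tidyr::pivot_longer(x$kin, -"time_s", names_to = "channel", values_to = "value"))
}

#' Cut padded per-movement trials
#'
#' Extracts one trial per detected movement: the EMG of each muscle over
#' `[onset - pad, offset + pad]` together with the kinematic segment. The
#' pads (3 s by default) are kept so that wavelet edge effects fall outside
#' the movement and can be cropped after the transform. Kinematic event
#' times are mapped onto the EMG clock by nearest-sample conversion (the
#' two streams share `t0`); signals themselves are never resampled.
#'
#' Movements whose padded window does not fit inside the recording are
#' dropped with a warning.
#'
#' @param recording An [emg_recording()].
#' @param bounds Movement table from [detect_movement_bounds()].
#' @param pad Pad duration in seconds on each side (default 3).
#' @return Nested tibble with one row per kept movement: bound times, the
#'   padded `emg` segment and the `kin` segment (list columns), and `pad_s`.
#' @export
extract_trials <- function(recording, bounds, pad = 3) {
  if (!inherits(recording, "emg_recording")) abort("`recording` must be an emg_recording")
  if (nrow(bounds) == 0L) abort("`bounds` has no movements")
  emg_t <- recording$emg$time_s
  kin_t <- recording$kin$time_s
  keep <- bounds$onset_s - pad >= emg_t[1] - 1e-9 &
    bounds$offset_s + pad <= emg_t[length(emg_t)] + 1e-9
  if (any(!keep)) {
    warn(sprintf("dropping %d movement(s) whose %g s pads fall outside the recording",
                 sum(!keep), pad))
  }
  b <- bounds[keep, , drop = FALSE]
  if (nrow(b) == 0L) abort("no movement leaves room for the requested pads")
  segs <- purrr::pmap(list(b$onset_s, b$offset_s), function(on, off) {
    ei <- nearest_index(on - pad, emg_t):nearest_index(off + pad, emg_t)
    ki <- nearest_index(on - pad, kin_t):nearest_index(off + pad, kin_t)
    list(emg = recording$emg[ei, , drop = FALSE],
         kin = recording$kin[ki, , drop = FALSE])
  })
  tibble(movement = seq_len(nrow(b)),
         onset_s = b$onset_s, offset_s = b$offset_s,
         peak_velocity_s = b$peak_velocity_s,
         pad_s = pad,
         emg = purrr::map(segs, "emg"),
         kin = purrr::map(segs, "kin"))
}
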