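# Delimited-table I/O: one kinematics file (time_s, elbow_angle_deg), one
# EMG file (time_s, emg_tb_v, emg_bb_v, emg_br_v), one MVC file (time_s,
# emg_bb_v, emg_br_v, torque_nm) per limb/session, plus a manifest table
# (subject, group, limb, age, file paths).

read_table_checked <- function(path, need, what, time_by = NULL) {
  if (!file.exists(path)) abort(sprintf("%s file not found: %s", what, path))
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    abort(sprintf("%s file %s is missing column(s): %s", what, path,
                  paste(miss, collapse = ", ")))
  }
  groups <- if (is.null(time_by)) list(d$time_s) else split(d$time_s, d[[time_by]])
  for (g in groups) {
    if (is.unsorted(g, strictly = TRUE)) {
      abort(sprintf("%s file %s: column time_s must be strictly increasing", what, path))
    }
  }
  d
}

check_rate <- function(time_s, fs_declared, what, path, tol = 0.01) {
  fs <- ts_fs(time_s)
  if (abs(fs - fs_declared) / fs_declared > tol) {
    abort(sprintf("%s file %s: sampling rate %.6g Hz does not match declared %g Hz",
                  what, path, fs, fs_declared))
  }
  invisible(fs)
}

#' Read one recording from delimited files
#'
#' @param emg_path,kin_path CSV paths for the EMG and kinematics tables.
#' @param subject,group,limb,age Session metadata (typically a manifest
#'   row).
#' @param fs_emg,fs_kin Declared sampling rates, Hz; a mismatch beyond 1%
#'   with the file's time column is an error.
#' @return An [emg_recording()].
#' @export
read_recording <- function(emg_path, kin_path, subject = "S1", group = "control",
                           limb = "dominant", age = NA_real_,
                           fs_emg = 1000, fs_kin = 125) {
  emg <- read_table_checked(emg_path, c("time_s", "emg_tb_v", "emg_bb_v", "emg_br_v"),
                            "EMG")
  kin <- read_table_checked(kin_path, c("time_s", "elbow_angle_deg"), "kinematics")
  check_rate(emg$time_s, fs_emg, "EMG", emg_path)
  check_rate(kin$time_s, fs_kin, "kinematics", kin_path)
  emg_recording(emg, kin, subject = subject, group = group, limb = limb, age = age)
}

#' Read MVC trials from a delimited file
#'
#' The file stacks the MVC contractions with a `trial` column and columns
#' `time_s`, `emg_bb_v`, `emg_br_v`, `torque_nm`.
#'
#' @param path CSV path.
#' @return Nested tibble (`trial`, `data`) as consumed by
#'   [mvc_reference()].
#' @export
read_mvc <- function(path) {
  d <- read_table_checked(path, c("trial", "time_s", "emg_bb_v", "emg_br_v", "torque_nm"),
                          "MVC", time_by = "trial")
  tidyr::nest(d, data = -"trial")
}

#' Write a session (recording + MVC trials) to delimited files
#'
#' @param recording An [emg_recording()].
#' @param mvc Nested MVC tibble (`trial`, `data`).
#' @param dir Output directory (created if needed).
#' @param stem File stem; writes `<stem>_emg.csv`, `<stem>_kin.csv`,
#'   `<stem>_mvc.csv`.
#' @return Invisibly, a named list of the three paths.
#' @export
write_session <- function(recording, mvc, dir, stem = recording$meta$subject) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(emg = file.path(dir, paste0(stem, "_emg.csv")),
                kin = file.path(dir, paste0(stem, "_kin.csv")),
                mvc = file.path(dir, paste0(stem, "_mvc.csv")))
  readr::write_csv(recording$emg, paths$emg, progress = FALSE)
  readr::write_csv(recording$kin, paths$kin, progress = FALSE)
  readr::write_csv(tidyr::unnest(mvc, "data"), paths$mvc, progress = FALSE)
  invisible(paths)
}

#' Write a time-frequency map as a delimited matrix with axis headers
#'
#' First column is frequency (Hz), remaining columns one per time sample
#' with the time (s, relative to peak velocity) in the header.
#'
#' @param map A `tf_map` (real-valued).
#' @param path Output CSV path.
#' @export
write_tf_map <- function(map, path) {
  v <- map$values
  if (is.complex(v)) v <- Mod(v)^2
  d <- as.data.frame(v)
  names(d) <- sprintf("t_%.4f", map$time_s)
  d <- cbind(freq_hz = map$freq_hz, d)
  readr::write_csv(as_tibble(d), path, progress = FALSE)
  invisible(path)
}
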