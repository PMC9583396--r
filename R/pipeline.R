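# Orchestration: configuration, per-session processing, and the full
# simulate -> preprocess -> coherence -> metrics -> stats chain.

pipeline_defaults <- function() {
  list(
    fs_emg = 1000, fs_kin = 125,
    kin_lowpass_hz = 6,
    emg_line_band = c(49, 51), emg_band = c(3, 100),
    velocity_threshold_dps = 0.01, min_peak_velocity_dps = 5,
    pad_s = 3,
    nvoice = 7, J1 = 50, wavenumber = 10, alpha = 0.05,
    f_max = 79.97, freq_range = NULL,
    beta_band = c(13, 31), window_s = c(-0.2, 0),
    significance = "analytic", n_surrogates = 100,
    ancova_alpha = 0.017,
    seed = 1L)
}

#' Pipeline configuration
#'
#' Collects every analysis constant: filter settings, the movement
#' threshold, pad length, wavelet parameters, the beta band and the
#' 200 ms pre-peak-velocity quantification window, significance levels and
#' the seed. Unknown keys are rejected. The returned object carries a hash
#' that changes iff any parameter changes, and is stamped on all outputs.
#'
#' @param ... Named overrides of the defaults (see
#'   `imcoh:::pipeline_defaults()`).
#' @return List of class `pipeline_config` with attribute `hash`.
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(names(over) == ""))) {
    abort("all configuration overrides must be named")
  }
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    abort(sprintf("unknown configuration key(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg[names(over)] <- over
  for (key in c("emg_line_band", "emg_band", "beta_band", "window_s")) {
    v <- cfg[[key]]
    if (length(v) != 2 || v[1] >= v[2]) {
      abort(sprintf("config key %s must be an increasing length-2 interval", key))
    }
  }
  if (cfg$kin_lowpass_hz <= 0 || cfg$kin_lowpass_hz >= cfg$fs_kin / 2) {
    abort("kin_lowpass_hz must lie inside (0, fs_kin/2)")
  }
  if (cfg$pad_s < 0) abort("pad_s must be >= 0")
  if (!cfg$significance %in% c("analytic", "surrogate")) {
    abort('significance must be "analytic" or "surrogate"')
  }
  structure(cfg, class = "pipeline_config", hash = rlang::hash(cfg))
}

#' Read / write a pipeline configuration as YAML
#'
#' The file holds a flat key-value mapping of [pipeline_config()] fields;
#' unknown keys are rejected on read.
#'
#' @param path YAML file path.
#' @return [read_pipeline_config()] returns a validated
#'   [pipeline_config()]; `write_pipeline_config()` returns `path`
#'   invisibly.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals %||% list())
}

#' @rdname read_pipeline_config
#' @param config A [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>", attr(x, "hash"), "\n")
  utils::str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' Process one session to per-pair metrics
#'
#' Runs the single-session chain: low-pass the kinematics, differentiate,
#' detect extension movements (positive-velocity excursions), preprocess
#' the EMG, cut padded trials, compute the MVC-referenced antagonist
#' co-contraction, and for each muscle pair (BB-BR, TB-BR) the
#' trial-averaged wavelet coherence and its significant beta-band volume
#' in the pre-peak-velocity window.
#'
#' @param recording An [emg_recording()].
#' @param mvc Nested MVC tibble (`trial`, `data`).
#' @param config A [pipeline_config()].
#' @return List with `metrics` (tibble, one row per muscle pair),
#'   `cocontraction`, `coherence` (named list of `imc_coherence`),
#'   `bounds`, and a `log` tibble of stage counts.
#' @export
process_session <- function(recording, mvc, config = pipeline_config()) {
  stopifnot(inherits(recording, "emg_recording"))
  meta <- recording$meta
  step <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage %s failed for subject %s (%s limb): %s",
                    what, meta$subject, meta$limb, conditionMessage(e)))
    })
  }
  kin <- step("kinematics", {
    k <- zero_lag_butterworth(recording$kin, "elbow_angle_deg", "low",
                              config$kin_lowpass_hz)
    k
  })
  vel <- step("velocity", angular_velocity(kin))
  bounds <- step("movement detection", detect_movement_bounds(
    vel, threshold = config$velocity_threshold_dps,
    min_peak_velocity = config$min_peak_velocity_dps, direction = "positive"))
  if (nrow(bounds) == 0) {
    abort(sprintf("stage movement detection: no extension movements found for subject %s",
                  meta$subject))
  }
  emg <- step("EMG preprocessing", preprocess_emg(
    recording$emg, line_band = config$emg_line_band, band = config$emg_band))
  filtered <- emg_recording(emg, kin, meta$subject, meta$group, meta$limb, meta$age)
  trials <- step("trial extraction", extract_trials(filtered, bounds, pad = config$pad_s))
  # MVC EMG gets the same conditioning as the movement EMG so that the
  # RMS ratio is not biased by the filters' passband shrinkage
  mvc_f <- mutate(mvc, data = purrr::map(.data$data, function(d) {
    preprocess_emg(d, cols = intersect(c("emg_tb_v", "emg_bb_v", "emg_br_v"), names(d)),
                   line_band = config$emg_line_band, band = config$emg_band)
  }))
  ref <- step("MVC reference", mvc_reference(mvc_f))
  cci <- step("co-contraction", antagonist_cocontraction(trials, ref))

  params <- wavelet_params(config$nvoice, config$J1, config$wavenumber, config$alpha)
  grid <- build_frequency_grid(params, meta$fs_emg, config$f_max,
                               range = config$freq_range)
  pairs <- list(bb_br = c("emg_bb_v", "emg_br_v"), tb_br = c("emg_tb_v", "emg_br_v"))
  coh <- purrr::imap(pairs, function(ch, nm) {
    step(paste0("coherence ", nm), wavelet_coherence(
      trials, channels = ch, pair = nm, params = params, grid = grid,
      significance = config$significance, n_surrogates = config$n_surrogates))
  })
  metrics <- bind_rows(purrr::map(coh, ~ imc_volume(
    .x, trials, band = config$beta_band, window = config$window_s)))
  metrics <- mutate(metrics,
                    subject = meta$subject, group = meta$group, limb = meta$limb,
                    age = meta$age, cocontraction_pct = cci$value,
                    config_hash = attr(config, "hash"), .before = 1)
  log <- tibble(subject = meta$subject, limb = meta$limb,
                movements_detected = nrow(bounds), trials_kept = nrow(trials),
                mvc_trial = ref$selected_trial,
                frac_significant_bb_br = mean(coh$bb_br$mask$values),
                frac_significant_tb_br = mean(coh$tb_br$mask$values))
  list(metrics = metrics, cocontraction = cci, coherence = coh, bounds = bounds,
       log = log)
}

#' Simulate a two-group dataset
#'
#' Builds a stroke-vs-control study in memory: `n_per_group` paretic-limb
#' stroke sessions and dominant-limb control sessions. Stroke subjects get
#' a stronger and more variable common drive and more variable planted
#' co-contraction; within the stroke group the planted co-contraction
#' decreases linearly with the subject's coupling gain, planting a
#' negative volume-co-contraction association whose sign the inference
#' layer should recover.
#'
#' @param n_per_group Subjects per group.
#' @param base_config [synth_config()] shared by all subjects.
#' @param seed Master seed; subject-level seeds and ages derive from it.
#' @param control_gain,stroke_gain_range Flexor coupling gain of controls,
#'   and the range across stroke subjects.
#' @param control_ratio,stroke_ratio_range Planted co-contraction ratios.
#' @return List of sessions, each a [simulate_session()] result plus
#'   subject metadata.
#' @export
simulate_dataset <- function(n_per_group = 8, base_config = synth_config(),
                             seed = 1L, control_gain = 0.5,
                             stroke_gain_range = c(0.7, 1.4),
                             control_ratio = 0.20,
                             stroke_ratio_range = c(0.25, 0.45)) {
  draws <- withr::with_seed(as.integer(seed) + 77L, {
    list(age = round(stats::runif(2 * n_per_group, 40, 75)),
         u = stats::runif(n_per_group),
         # inter-subject movement variability (speed and range of motion)
         dur = stats::runif(2 * n_per_group, 1.0, 1.6),
         amp = stats::runif(2 * n_per_group, 150, 170))
  })
  make <- function(i, group) {
    stroke <- group == "stroke"
    u <- if (stroke) draws$u[i] else NA
    gain <- if (stroke) stroke_gain_range[1] + u * diff(stroke_gain_range) else control_gain
    # co-contraction decreases with coupling gain within the stroke group
    ratio <- if (stroke) stroke_ratio_range[2] - u * diff(stroke_ratio_range) else control_ratio
    cfg <- base_config
    cfg$coupling_gains[c("bb", "br")] <- gain
    cfg$coupling_gains["tb"] <- 0.8 * gain
    cfg$cocontraction_ratio <- ratio
    cfg$seed <- as.integer(seed) + i + (if (stroke) 1000L else 2000L)
    idx <- i + (if (stroke) 0L else n_per_group)
    cfg$movement_duration <- draws$dur[idx]
    cfg$angle_end <- draws$amp[idx]
    ses <- simulate_session(cfg,
                            subject = sprintf("%s%02d", if (stroke) "P" else "C", i),
                            group = if (stroke) "stroke" else "control",
                            limb = if (stroke) "paretic" else "dominant")
    ses$recording$meta$age <- draws$age[idx]
    ses
  }
  c(purrr::map(seq_len(n_per_group), make, group = "stroke"),
    purrr::map(seq_len(n_per_group), make, group = "control"))
}

#' Run the full analysis chain
#'
#' Processes every session to the long metrics table and fits the group
#' inference layer: the pooled t-test on antagonist co-contraction
#' (paretic vs dominant), a 2x2 limb-by-pair ANCOVA per available limb
#' contrast, and the partial Spearman correlation between the paretic
#' BB-BR coherence volume and co-contraction (covariates: window angle and
#' velocity, age). Deterministic given the configuration.
#'
#' @param sessions List of sessions: each either a [simulate_session()]
#'   result or a list with `recording` and `mvc`.
#' @param config A [pipeline_config()].
#' @return Object of class `imc_pipeline_result`: `metrics`, `stats`
#'   (named list), `log`, and the config hash.
#' @export
run_pipeline <- function(sessions, config = pipeline_config()) {
  res <- purrr::map(sessions, ~ process_session(.x$recording, .x$mvc, config))
  metrics <- bind_rows(purrr::map(res, "metrics"))
  log <- bind_rows(purrr::map(res, "log"))
  stats_out <- list()

  limbs <- unique(metrics$limb)
  if (all(c("paretic", "dominant") %in% limbs)) {
    cc <- dplyr::distinct(metrics[metrics$limb %in% c("paretic", "dominant"),
                                  c("subject", "limb", "cocontraction_pct")])
    cc$limb <- factor(cc$limb, levels = c("paretic", "dominant"))
    stats_out$cocontraction_t <- two_sample_t(cc, "cocontraction_pct", "limb")
  }
  contrasts <- list(c("paretic", "dominant"), c("paretic", "non_paretic"),
                    c("non_paretic", "dominant"))
  for (ct in contrasts) {
    if (all(ct %in% limbs)) {
      nm <- paste0("ancova_", ct[1], "_vs_", ct[2])
      stats_out[[nm]] <- ancova_imc(metrics, ct, alpha = config$ancova_alpha)
    }
  }
  par <- metrics[metrics$limb == "paretic" & metrics$pair == "bb_br", , drop = FALSE]
  if (nrow(par) > 6) {
    stats_out$volume_cocontraction_rho <- partial_spearman(
      par, "imc_volume", "cocontraction_pct",
      covariates = c("mean_velocity_dps", "mean_angle_deg", "age"))
  }
  structure(list(metrics = metrics, stats = stats_out, log = log,
                 config_hash = attr(config, "hash")),
            class = "imc_pipeline_result")
}

#' @export
print.imc_pipeline_result <- function(x, ...) {
  cat(sprintf("<imc_pipeline_result> %d sessions, %d metric rows (config %s)\n",
              nrow(x$log), nrow(x$metrics), x$config_hash))
  for (nm in names(x$stats)) {
    cat("--", nm, "--\n")
    print(x$stats[[nm]])
  }
  invisible(x)
}
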