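# ggplot2 displays for time-frequency results.

#' @export
autoplot.tf_map <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$time_s, .data$freq_hz, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = object$kind) +
    ggplot2::labs(x = "time re peak velocity (s)", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot significant intermuscular coherence
#'
#' Raster of the coherence map with non-significant cells blanked, the
#' usual display for trial-averaged wavelet coherence. Optionally rescales
#' the time axis to percent of the common movement window (display only;
#' the underlying maps stay in absolute time).
#'
#' @param object An `imc_coherence` object.
#' @param masked Blank non-significant cells (default `TRUE`).
#' @param percent_time Show time as percent of the aligned window.
#' @param ... Unused.
#' @export
autoplot.imc_coherence <- function(object, masked = TRUE, percent_time = FALSE, ...) {
  d <- tidy(object)
  if (masked) d$msc[!d$significant] <- NA_real_
  if (percent_time) {
    rng <- range(d$time_s)
    d$time_s <- 100 * (d$time_s - rng[1]) / diff(rng)
  }
  ggplot2::ggplot(d, ggplot2::aes(.data$time_s, .data$freq_hz, fill = .data$msc)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "coherence", na.value = "white",
                                  limits = c(0, 1)) +
    ggplot2::labs(x = if (percent_time) "movement time (%)" else "time re peak velocity (s)",
                  y = "frequency (Hz)",
                  title = sprintf("%s (K = %d, threshold %.3f)", object$pair,
                                  object$K, object$threshold)) +
    ggplot2::theme_minimal()
}

#' Per-movement co-contraction plot
#'
#' @param object A `cocontraction_index`.
#' @param ... Unused.
#' @export
autoplot.cocontraction_index <- function(object, ...) {
  ggplot2::ggplot(object$per_movement,
                  ggplot2::aes(.data$movement, .data$percent)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_hline(yintercept = object$value, linetype = 2, colour = "red") +
    ggplot2::labs(x = "movement", y = "co-contraction (% MVC)") +
    ggplot2::theme_minimal()
}
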