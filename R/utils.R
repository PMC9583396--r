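#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join across all_of
#' @importFrom purrr map map_dbl map2 pmap
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# Sampling rate of a regular time column, Hz.
ts_fs <- function(time_s) {
  if (length(time_s) < 2L) abort("need at least two samples to infer a sampling rate")
  dt <- diff(time_s)
  if (any(!is.finite(dt)) || any(dt <= 0)) abort("time column must be finite and strictly increasing")
  1 / stats::median(dt)
}

check_finite <- function(x, what = "values") {
  if (any(!is.finite(x))) abort(sprintf("%s must be finite (no NA/NaN/Inf)", what))
  invisible(x)
}

# value columns of a signal tibble (everything but time_s)
value_cols <- function(data, cols = NULL) {
  if (!is.data.frame(data) || !"time_s" %in% names(data)) {
    abort("expected a data frame with a `time_s` column")
  }
  if (is.null(cols)) cols <- setdiff(names(data), "time_s")
  missing <- setdiff(cols, names(data))
  if (length(missing)) abort(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  cols
}

# nearest sample index of time `t` on clock `time_s` (regular grid)
nearest_index <- function(t, time_s) {
  fs <- ts_fs(time_s)
  i <- round((t - time_s[1]) * fs) + 1
  pmin(pmax(as.integer(i), 1L), length(time_s))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
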