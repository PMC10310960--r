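#' Uniformly sampled signal
#'
#' The elementary carrier for every signal handled by cvrtime: ROI-mean BOLD
#' time courses (arbitrary units), respiratory CO2 traces (mmHg), end-tidal
#' envelopes and model regressors. A `sampled_series` stores the sample
#' values, the sampling interval `tr` (seconds) and the time of the first
#' sample `t0` (seconds); sample `k` (0-based) sits at time `t0 + k * tr`.
#'
#' @param values Numeric vector of sample values. `NA` is allowed only where
#'   a sample has been explicitly flagged as missing (e.g. censored volumes);
#'   infinite values are rejected.
#' @param tr Sampling interval in seconds; must be positive.
#' @param t0 Time of the first sample in seconds (default 0).
#'
#' @return An object of class `sampled_series`.
#' @examples
#' s <- sampled_series(rnorm(100), tr = 1.55)
#' series_times(s)[1:3]
#' @export
sampled_series <- function(values, tr, t0 = 0) {
  values <- as.numeric(values)
  if (length(values) < 1L) {
    stop("a sampled_series needs at least one sample", call. = FALSE)
  }
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0) {
    stop("`tr` must be a single positive number (seconds)", call. = FALSE)
  }
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0)) {
    stop("`t0` must be a single finite number (seconds)", call. = FALSE)
  }
  if (any(is.infinite(values))) {
    stop("series values must be finite (NA allowed for flagged samples)",
         call. = FALSE)
  }
  structure(list(values = values, tr = tr, t0 = t0),
            class = "sampled_series")
}

#' @export
length.sampled_series <- function(x) length(x$values)

#' Sample times of a series
#'
#' @param series A [sampled_series()].
#' @return Numeric vector of sample times in seconds.
#' @export
series_times <- function(series) {
  stopifnot(inherits(series, "sampled_series"))
  series$t0 + (seq_along(series$values) - 1) * series$tr
}

#' @export
print.sampled_series <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf("<sampled_series> %d samples, tr = %g s, t0 = %g s, span [%g, %g) s\n",
              n, x$tr, x$t0, x$t0, x$t0 + n * x$tr))
  cat(sprintf("  values: mean %.4g, sd %.4g, %d NA\n",
              mean(x$values, na.rm = TRUE),
              stats::sd(x$values, na.rm = TRUE),
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
as.numeric.sampled_series <- function(x, ...) x$values
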