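#' End-tidal CO2 extraction and the hypercapnic step
#'
#' The CO2 trace from a gas analyzer oscillates with each breath; its
#' breath-wise maxima approximate the end-tidal partial pressure (PETCO2),
#' the standard non-invasive proxy for arterial CO2. CVR normalization
#' requires the hypercapnic step `delta = plateau_mean - baseline_mean`
#' in mmHg.
#'
#' @name capnometry
NULL

#' Extract the end-tidal (peak) envelope of a CO2 trace
#'
#' Detects breath-wise local maxima with a minimum peak separation and
#' resamples the resulting envelope onto a target grid by previous-peak
#' hold (PETCO2 is a breath-wise quantity, so no interpolation between
#' breaths is performed; samples before the first peak hold its value).
#'
#' @param co2_trace A [sampled_series()] in mmHg, sampled at 4 Hz or
#'   faster.
#' @param min_breath_period_s Minimum separation between detected peaks in
#'   seconds (default 2, i.e. a maximum plausible breathing rate of 30
#'   breaths/min). Must be at least 1.
#' @param out_tr Sampling interval of the output envelope in seconds
#'   (typically the BOLD TR). Defaults to the trace's own interval.
#' @param out_n Number of output samples. Defaults to spanning the trace.
#' @param out_t0 Time of the first output sample (default 0).
#' @return A [sampled_series()] of PETCO2 values (mmHg) on the requested
#'   grid.
#' @export
extract_petco2 <- function(co2_trace, min_breath_period_s = 2,
                           out_tr = NULL, out_n = NULL, out_t0 = 0) {
  stopifnot(inherits(co2_trace, "sampled_series"))
  fs <- 1 / co2_trace$tr
  if (fs < 4) {
    stop(sprintf("CO2 trace sampled at %.3g Hz; need >= 4 Hz", fs),
         call. = FALSE)
  }
  if (min_breath_period_s < 1) {
    stop("`min_breath_period_s` must be >= 1 s", call. = FALSE)
  }
  min_dist <- max(1L, as.integer(round(min_breath_period_s / co2_trace$tr)))
  pk <- pracma::findpeaks(co2_trace$values, minpeakdistance = min_dist,
                          zero = "0")
  if (is.null(pk) || nrow(pk) == 0L) {
    stop("no breath peaks found in the CO2 trace", call. = FALSE)
  }
  ord <- order(pk[, 2])
  peak_t <- series_times(co2_trace)[pk[ord, 2]]
  peak_v <- pk[ord, 1]
  if (is.null(out_tr)) out_tr <- co2_trace$tr
  if (is.null(out_n)) {
    span <- length(co2_trace) * co2_trace$tr
    out_n <- max(1L, floor((span - (out_t0 - co2_trace$t0)) / out_tr))
  }
  t_out <- out_t0 + (seq_len(out_n) - 1) * out_tr
  idx <- findInterval(t_out, peak_t)
  idx[idx < 1L] <- 1L  # hold the first peak backwards in time
  sampled_series(peak_v[idx], tr = out_tr, t0 = out_t0)
}

#' Summarize the hypercapnic PETCO2 step for one challenge
#'
#' `baseline_mean` is the mean PETCO2 over the challenge's baseline window;
#' `plateau_mean` is the mean over the second half of the dilation window,
#' which excludes the dilatory ramp so the value reflects the steady
#' hypercapnic level; `delta = plateau_mean - baseline_mean` must be
#' positive for a hypercapnia challenge.
#'
#' @param petco2 A [sampled_series()] of PETCO2 values (mmHg) on the
#'   post-discard axis.
#' @param windows An [windows_for_design()] object.
#' @param challenge_index 1 or 2.
#' @return An object of class `petco2_summary`: list with `baseline_mean`,
#'   `plateau_mean`, `delta` (mmHg) and `challenge_index`.
#' @export
petco2_delta <- function(petco2, windows, challenge_index) {
  stopifnot(inherits(petco2, "sampled_series"),
            inherits(windows, "analysis_windows"))
  if (!challenge_index %in% c(1L, 2L)) {
    stop("`challenge_index` must be 1 or 2", call. = FALSE)
  }
  bwin <- windows[[paste0("baseline", challenge_index)]]
  cwin <- windows[[paste0("cvr", challenge_index)]]
  plateau_win <- time_window((cwin$start_s + cwin$end_s) / 2, cwin$end_s)
  baseline_mean <- mean(slice_window(petco2, bwin)$values, na.rm = TRUE)
  plateau_mean <- mean(slice_window(petco2, plateau_win)$values, na.rm = TRUE)
  delta <- plateau_mean - baseline_mean
  if (!is.finite(delta) || delta <= 0) {
    stop(sprintf("non-hypercapnic PETCO2 change (delta = %.3g mmHg)", delta),
         call. = FALSE)
  }
  structure(list(baseline_mean = baseline_mean, plateau_mean = plateau_mean,
                 delta = delta, challenge_index = as.integer(challenge_index)),
            class = "petco2_summary")
}

#' @export
print.petco2_summary <- function(x, ...) {
  cat(sprintf("<petco2_summary> challenge %d: baseline %.2f mmHg, plateau %.2f mmHg, delta %.2f mmHg\n",
              x$challenge_index, x$baseline_mean, x$plateau_mean, x$delta))
  invisible(x)
}
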