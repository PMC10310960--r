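#' Non-parametric CVR and transition-rate metrics
#'
#' The core estimators. The per-challenge CVR metric is built from the
#' Theil-Sen slope of the BOLD signal across the dilation window:
#'
#' \deqn{\mathrm{Sen's\ slope} = \mathrm{median}\Big(\frac{x_j - x_i}{j - i}\Big),\ j > i}
#'
#' over all n(n-1)/2 sample pairs, with indices in samples, followed by
#'
#' \deqn{\%\Delta \mathrm{BOLD} = \frac{\mathrm{slope} \cdot n}{\bar{x}_{\mathrm{baseline}}} \cdot 100,
#' \qquad \mathrm{CVR} = \frac{\%\Delta \mathrm{BOLD}}{\Delta \mathrm{PETCO_2}}}
#'
#' Multiplying the per-sample slope by the number of samples in the window
#' converts it to a total signal change over the window; the sampling
#' interval cancels, so the percent change is unit-less and CVR is in
#' %/mmHg. Being a median of pairwise slopes, the estimator tolerates a
#' substantial fraction of outlying samples (breakdown point about 29%)
#' without assuming any response shape.
#'
#' The hypercapnia-to-normocapnia transition is summarized by the ordinary
#' least-squares slope of the BOLD signal on time (seconds) over the
#' transition window, normalized by the same PETCO2 step.
#'
#' @name cvr-metrics
NULL

#' Theil-Sen slope of a series
#'
#' Median of all pairwise slopes `(x[j] - x[i]) / (j - i)`, `j > i`, with
#' indices counted in samples; an even number of pairs yields the mean of
#' the two central order statistics. `NA` samples are dropped first (their
#' index positions are preserved, so gaps widen the denominators).
#'
#' @param x A numeric vector or [sampled_series()] with at least 3
#'   non-missing samples.
#' @return The slope in signal units per sample.
#' @examples
#' sens_slope(c(1, 2, 4, 3, 5))  # 1
#' @export
sens_slope <- function(x) {
  v <- if (inherits(x, "sampled_series")) x$values else as.numeric(x)
  idx <- which(!is.na(v))
  if (length(idx) < 3L) {
    stop("need at least 3 non-missing samples for a Sen's slope",
         call. = FALSE)
  }
  v <- v[idx]
  dv <- outer(v, v, "-")
  di <- outer(idx, idx, "-")
  lt <- lower.tri(dv)
  stats::median(dv[lt] / di[lt])
}

#' Theil-Sen intercept
#'
#' The standard companion estimator `median(x[k] - slope * k)` with k a
#' 0-based sample index; used to form residuals of the Sen line.
#'
#' @inheritParams sens_slope
#' @param slope Optional precomputed [sens_slope()].
#' @return Intercept in signal units (value of the Sen line at the first
#'   sample).
#' @export
sen_intercept <- function(x, slope = NULL) {
  v <- if (inherits(x, "sampled_series")) x$values else as.numeric(x)
  if (is.null(slope)) slope <- sens_slope(v)
  k <- seq_along(v) - 1
  stats::median(v - slope * k, na.rm = TRUE)
}

#' BOLD percent signal change from a Sen's slope
#'
#' @param sens_slope Slope in signal units per sample.
#' @param n_points Number of samples in the dilation window (>= 3).
#' @param baseline_mean Mean baseline BOLD signal prior to the challenge;
#'   must be positive.
#' @return Percent signal change (unit-less, in %).
#' @examples
#' pct_bold_change(0.5, 20, 100)  # 10
#' @export
pct_bold_change <- function(sens_slope, n_points, baseline_mean) {
  if (!is.numeric(n_points) || n_points < 3) {
    stop("`n_points` must be at least 3", call. = FALSE)
  }
  if (!is.numeric(baseline_mean) || baseline_mean <= 0) {
    stop("`baseline_mean` must be positive", call. = FALSE)
  }
  sens_slope * n_points / baseline_mean * 100
}

#' CVR from percent signal change and the PETCO2 step
#'
#' @param pct_bold Percent BOLD signal change.
#' @param delta_petco2 Hypercapnic PETCO2 step in mmHg; must be positive.
#' @return CVR in % per mmHg.
#' @examples
#' cvr(10, 10)  # 1
#' @export
cvr <- function(pct_bold, delta_petco2) {
  if (!is.numeric(delta_petco2) || delta_petco2 <= 0) {
    stop("`delta_petco2` must be positive (non-hypercapnic change)",
         call. = FALSE)
  }
  pct_bold / delta_petco2
}

#' Per-challenge non-parametric CVR estimate
#'
#' Slices the challenge's dilation window from the (post-discard) BOLD
#' series, computes the Theil-Sen slope with `n_points` equal to the number
#' of retained samples, takes the mean baseline signal over the preceding
#' baseline window, and applies the percent-change and PETCO2
#' normalizations.
#'
#' @param series A [sampled_series()] BOLD ROI-mean series on the
#'   post-discard axis.
#' @param windows An [windows_for_design()] object.
#' @param challenge_index 1 or 2.
#' @param delta_petco2 Either a positive scalar (mmHg) or a
#'   [petco2_delta()] summary.
#' @return An object of class `cvr_estimate`: list with `sens_slope`
#'   (a.u./sample), `n_points`, `baseline_mean` (a.u.), `pct_bold` (%),
#'   `delta_petco2` (mmHg), `cvr` (%/mmHg), `window`, `challenge_index`.
#' @export
cvr_for_challenge <- function(series, windows, challenge_index,
                              delta_petco2) {
  stopifnot(inherits(series, "sampled_series"),
            inherits(windows, "analysis_windows"))
  if (!challenge_index %in% c(1L, 2L)) {
    stop("`challenge_index` must be 1 or 2", call. = FALSE)
  }
  if (inherits(delta_petco2, "petco2_summary")) {
    delta_petco2 <- delta_petco2$delta
  }
  cwin <- windows[[paste0("cvr", challenge_index)]]
  bwin <- windows[[paste0("baseline", challenge_index)]]
  excerpt <- slice_window(series, cwin)
  n_points <- sum(!is.na(excerpt$values))
  slope <- sens_slope(excerpt)
  baseline_mean <- mean(slice_window(series, bwin)$values, na.rm = TRUE)
  pct <- pct_bold_change(slope, n_points, baseline_mean)
  structure(list(sens_slope = slope, n_points = n_points,
                 baseline_mean = baseline_mean, pct_bold = pct,
                 delta_petco2 = delta_petco2,
                 cvr = cvr(pct, delta_petco2),
                 window = cwin,
                 challenge_index = as.integer(challenge_index)),
            class = "cvr_estimate")
}

#' @export
print.cvr_estimate <- function(x, ...) {
  cat(sprintf(
    "<cvr_estimate> challenge %d [%g, %g) s: slope %.4g a.u./sample (n = %d), baseline %.4g, %%dBOLD %.3f, dPETCO2 %.2f mmHg, CVR %.4f %%/mmHg\n",
    x$challenge_index, x$window$start_s, x$window$end_s, x$sens_slope,
    x$n_points, x$baseline_mean, x$pct_bold, x$delta_petco2, x$cvr))
  invisible(x)
}

#' Linear transition fit for a hypercapnia-to-normocapnia period
#'
#' Ordinary least-squares regression of the BOLD signal on time in seconds
#' (absolute post-discard time), fitted with [stats::lm()]. The slope `tau`
#' (a.u./s) normalized by the PETCO2 step gives the transition rate
#' (a.u./s/mmHg); for a recovering signal both are negative.
#'
#' @param excerpt A [sampled_series()] covering one transition window
#'   (at least 3 samples).
#' @param delta_petco2 Positive scalar (mmHg) or [petco2_delta()] summary.
#' @return An object of class `transition_fit`: list with `tau`,
#'   `intercept`, `transition_rate`, `r_squared`, `n`, `window`
#'   (the time span fitted).
#' @export
transition_fit <- function(excerpt, delta_petco2) {
  stopifnot(inherits(excerpt, "sampled_series"))
  if (inherits(delta_petco2, "petco2_summary")) {
    delta_petco2 <- delta_petco2$delta
  }
  if (!is.numeric(delta_petco2) || delta_petco2 <= 0) {
    stop("`delta_petco2` must be positive", call. = FALSE)
  }
  ok <- !is.na(excerpt$values)
  if (sum(ok) < 3L) stop("need at least 3 samples", call. = FALSE)
  t <- series_times(excerpt)[ok]
  y <- excerpt$values[ok]
  if (stats::sd(t) == 0) stop("degenerate time axis", call. = FALSE)
  fit <- stats::lm(y ~ t)
  tau <- unname(stats::coef(fit)[2])
  # direct R^2 (summary.lm warns on noise-free, exactly linear excerpts)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) NA_real_ else 1 - sum(stats::residuals(fit)^2) / tss
  structure(list(tau = tau, intercept = unname(stats::coef(fit)[1]),
                 transition_rate = tau / delta_petco2,
                 r_squared = r2, n = sum(ok),
                 window = time_window(t[1], t[length(t)] + excerpt$tr)),
            class = "transition_fit")
}

#' Transition fit for one of a design's transition windows
#'
#' @inheritParams cvr_for_challenge
#' @param period 1 or 2, selecting `transition1`/`transition2`.
#' @return A [transition_fit()] object.
#' @export
transition_for_period <- function(series, windows, period, delta_petco2) {
  stopifnot(inherits(windows, "analysis_windows"))
  if (!period %in% c(1L, 2L)) stop("`period` must be 1 or 2", call. = FALSE)
  win <- windows[[paste0("transition", period)]]
  transition_fit(slice_window(series, win), delta_petco2)
}

#' @export
print.transition_fit <- function(x, ...) {
  cat(sprintf(
    "<transition_fit> [%g, %g) s: tau %.4g a.u./s, rate %.4g a.u./s/mmHg, R^2 %.3f (n = %d)\n",
    x$window$start_s, x$window$end_s, x$tau, x$transition_rate,
    x$r_squared, x$n))
  invisible(x)
}

#' Temporal signal-to-noise ratio
#'
#' Mean of the baseline excerpt divided by its sample standard deviation
#' (n - 1 denominator).
#'
#' @param baseline_excerpt A numeric vector or [sampled_series()] with at
#'   least 2 samples and non-zero variability.
#' @return The tSNR (dimensionless).
#' @examples
#' tsnr(c(98, 100, 102))  # 50
#' @export
tsnr <- function(baseline_excerpt) {
  v <- if (inherits(baseline_excerpt, "sampled_series"))
    baseline_excerpt$values else as.numeric(baseline_excerpt)
  v <- v[!is.na(v)]
  if (length(v) < 2L) stop("need at least 2 samples", call. = FALSE)
  s <- stats::sd(v)
  if (s == 0) stop("zero temporal standard deviation", call. = FALSE)
  mean(v) / s
}

#' Full per-subject metric set for a two-challenge paradigm
#'
#' Convenience wrapper running both per-challenge CVR estimates and both
#' transition fits on one series.
#'
#' @inheritParams cvr_for_challenge
#' @param delta_petco2 Scalar mmHg or [petco2_delta()] summaries (a list of
#'   two, one per challenge, is also accepted).
#' @return A list with `cvr1`, `cvr2` ([cvr_for_challenge()] results) and
#'   `transition1`, `transition2` ([transition_fit()] results).
#' @export
subject_metrics <- function(series, windows, delta_petco2) {
  deltas <- if (is.list(delta_petco2) && !inherits(delta_petco2, "petco2_summary")) {
    delta_petco2
  } else list(delta_petco2, delta_petco2)
  list(cvr1 = cvr_for_challenge(series, windows, 1L, deltas[[1]]),
       cvr2 = cvr_for_challenge(series, windows, 2L, deltas[[2]]),
       transition1 = transition_for_period(series, windows, 1L, deltas[[1]]),
       transition2 = transition_for_period(series, windows, 2L, deltas[[2]]))
}
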