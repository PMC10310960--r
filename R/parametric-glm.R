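#' Conventional gamma-HRF GLM comparator and AIC model comparison
#'
#' The standard fMRI analysis models the BOLD response as the experimental
#' paradigm convolved with a hemodynamic response function (HRF) and reads
#' the fitted regression coefficient (the COPE, contrast of parameter
#' estimates) as the response amplitude. These routines provide that
#' comparator for ROI-mean series, plus Akaike Information Criterion
#' computations that put the parametric (HRF-regressor) fit and the
#' non-parametric (Sen line) fit on the same residual scale.
#'
#' @name parametric-glm
NULL

#' Single-gamma hemodynamic response function kernel
#'
#' Gamma density parameterized by its mean lag and standard deviation
#' (shape `= mean^2/sd^2`, scale `= sd^2/mean`), sampled at the BOLD TR,
#' truncated at `length_s` and renormalized to unit sum so convolution
#' preserves the regressor's plateau amplitude.
#'
#' @param tr Sampling interval in seconds.
#' @param mean_lag_s Mean lag of the response in seconds (default 6).
#' @param sd_s Dispersion in seconds (default 3).
#' @param length_s Kernel support in seconds (default 30).
#' @return An object of class `hrf_kernel`: list with `weights` (unit sum),
#'   `tr`, `mean_lag_s`, `sd_s`.
#' @export
gamma_hrf <- function(tr, mean_lag_s = 6, sd_s = 3, length_s = 30) {
  if (!is.numeric(tr) || tr <= 0) stop("`tr` must be positive", call. = FALSE)
  if (mean_lag_s <= 0 || sd_s <= 0 || length_s <= 0) {
    stop("HRF parameters must be positive", call. = FALSE)
  }
  shape <- mean_lag_s^2 / sd_s^2
  scale <- sd_s^2 / mean_lag_s
  t <- seq(0, length_s, by = tr)
  w <- stats::dgamma(t, shape = shape, scale = scale)
  if (sum(w) <= 0) stop("degenerate HRF kernel", call. = FALSE)
  w <- w / sum(w)
  structure(list(weights = w, tr = tr, mean_lag_s = mean_lag_s, sd_s = sd_s,
                 shape = shape, scale = scale),
            class = "hrf_kernel")
}

#' Convolve a boxcar regressor with an HRF kernel
#'
#' Causal convolution: the output at sample k is the HRF-weighted sum of
#' the boxcar at samples `k, k-1, ...` (zero-padded before the start).
#'
#' @param boxcar A [sampled_series()] of 0/1 paradigm values.
#' @param hrf An [gamma_hrf()] kernel on the same TR.
#' @return A [sampled_series()] of the convolved regressor.
#' @export
convolve_regressor <- function(boxcar, hrf) {
  stopifnot(inherits(boxcar, "sampled_series"), inherits(hrf, "hrf_kernel"))
  if (abs(boxcar$tr - hrf$tr) > 1e-9) {
    stop("boxcar and HRF kernel are on different sampling grids",
         call. = FALSE)
  }
  x <- boxcar$values
  h <- hrf$weights
  n <- length(x)
  padded <- c(rep(0, length(h) - 1), x)
  out <- stats::filter(padded, rev(h), method = "convolution", sides = 1)
  out <- as.numeric(out)[length(h):(length(h) + n - 1)]
  sampled_series(out, tr = boxcar$tr, t0 = boxcar$t0)
}

#' GLM fit of a series on an HRF-convolved boxcar regressor
#'
#' Ordinary least squares of the series on an intercept and the convolved
#' regressor; the regressor coefficient is the COPE. When a PETCO2 step and
#' a baseline level are supplied the COPE is additionally expressed as a
#' percent-per-mmHg equivalent (`cope / baseline * 100 / delta`); the
#' normalization convention for COPE-based CVR varies between pipelines, so
#' the raw COPE is always reported.
#'
#' @param series A [sampled_series()] BOLD series.
#' @param boxcar A [sampled_series()] 0/1 paradigm regressor, same length.
#' @param hrf An [gamma_hrf()] kernel; `NULL` fits the raw boxcar.
#' @param delta_petco2,baseline_mean Optional normalizers for
#'   `pct_equivalent`.
#' @return An object of class `glm_result`: list with `cope`, `intercept`,
#'   `residuals`, `fitted`, `regressor`, `pct_equivalent` (or `NA`).
#' @export
glm_cope <- function(series, boxcar, hrf = NULL, delta_petco2 = NULL,
                     baseline_mean = NULL) {
  stopifnot(inherits(series, "sampled_series"))
  reg <- if (is.null(hrf)) boxcar else convolve_regressor(boxcar, hrf)
  if (length(reg) != length(series)) {
    stop(sprintf("series (%d) and regressor (%d) lengths differ",
                 length(series), length(reg)), call. = FALSE)
  }
  r <- reg$values
  if (stats::sd(r) == 0) {
    stop("constant regressor: paradigm has no CO2 variation over the series",
         call. = FALSE)
  }
  y <- series$values
  ok <- !is.na(y)
  fit <- stats::lm.fit(cbind(intercept = 1, regressor = r[ok]), y[ok])
  cope <- unname(fit$coefficients["regressor"])
  res <- rep(NA_real_, length(y))
  res[ok] <- fit$residuals
  pct <- NA_real_
  if (!is.null(delta_petco2) && !is.null(baseline_mean)) {
    if (delta_petco2 <= 0 || baseline_mean <= 0) {
      stop("normalizers must be positive", call. = FALSE)
    }
    pct <- cope / baseline_mean * 100 / delta_petco2
  }
  structure(list(cope = cope,
                 intercept = unname(fit$coefficients["intercept"]),
                 residuals = res, fitted = y - res,
                 regressor = reg, pct_equivalent = pct),
            class = "glm_result")
}

#' Akaike Information Criterion for a Gaussian OLS fit
#'
#' `n * log(RSS / n) + 2 * k`, dropping the additive Gaussian constant
#' (the same convention must be used for every model being compared; AIC
#' differences are convention-free).
#'
#' @param residuals Numeric residual vector (`NA` dropped).
#' @param k_params Number of fitted parameters.
#' @return The AIC value.
#' @export
aic_ols <- function(residuals, k_params) {
  r <- residuals[!is.na(residuals)]
  n <- length(r)
  if (n <= k_params) stop("need more residuals than parameters", call. = FALSE)
  rss <- sum(r^2)
  if (rss == 0) stop("degenerate fit: zero residual sum of squares",
                     call. = FALSE)
  n * log(rss / n) + 2 * k_params
}

#' AIC of the Theil-Sen line fit
#'
#' Residuals are taken about the Sen line (slope from [sens_slope()],
#' intercept from [sen_intercept()]) and scored with the same Gaussian
#' pseudo-likelihood as [aic_ols()], with k = 2 (slope and intercept), so
#' parametric and non-parametric fits are comparable on a common residual
#' scale.
#'
#' @param excerpt A numeric vector or [sampled_series()] (>= 3 samples).
#' @return The AIC value.
#' @export
aic_sen <- function(excerpt) {
  v <- if (inherits(excerpt, "sampled_series")) excerpt$values
       else as.numeric(excerpt)
  slope <- sens_slope(v)
  b0 <- sen_intercept(v, slope)
  k <- seq_along(v) - 1
  aic_ols(v - (b0 + slope * k), k_params = 2)
}

#' Compare parametric and non-parametric fits on a simulated epoch
#'
#' Fits both models to the same normocapnia-to-hypercapnia epoch: the
#' parametric model regresses the series on the gamma-HRF-convolved onset
#' boxcar; the non-parametric model is the Theil-Sen line. Both are scored
#' with the shared AIC convention (k = 2 each); a zero-residual fit is
#' reported as `-Inf`. The realized tSNR of the pre-onset baseline segment
#' is attached.
#'
#' @param simulated A [simulate_epoch()] result (or any list with elements
#'   `series`, a [sampled_series()], and `onset_s`).
#' @param hrf Optional [gamma_hrf()] kernel; default `gamma_hrf(tr)`.
#' @return An object of class `model_fit_comparison`: list with
#'   `aic_parametric`, `aic_nonparametric`, `tsnr`, `shape` (if present on
#'   the input), `n`.
#' @export
compare_models <- function(simulated, hrf = NULL) {
  series <- simulated$series
  stopifnot(inherits(series, "sampled_series"))
  onset <- simulated$onset_s
  if (is.null(onset)) stop("`simulated` must carry `onset_s`", call. = FALSE)
  t <- series_times(series)
  if (!any(t < onset) || !any(t >= onset)) {
    stop("epoch must span both a baseline and a hypercapnia segment",
         call. = FALSE)
  }
  if (is.null(hrf)) hrf <- gamma_hrf(series$tr)
  box <- sampled_series(as.numeric(t >= onset), tr = series$tr, t0 = series$t0)
  safe_aic <- function(expr) tryCatch(expr, error = function(e) -Inf)
  g <- glm_cope(series, box, hrf)
  aic_par <- safe_aic(aic_ols(g$residuals, k_params = 2))
  aic_sen_val <- safe_aic(aic_sen(series))
  base_seg <- series$values[t < onset]
  structure(list(aic_parametric = aic_par, aic_nonparametric = aic_sen_val,
                 tsnr = tsnr(base_seg),
                 shape = simulated$shape %||% NA_character_,
                 n = length(series)),
            class = "model_fit_comparison")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
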