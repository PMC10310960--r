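#' Synthetic hypercapnic responses, epochs, subjects and cohorts
#'
#' Two idealized single-challenge response shapes are simulated: a *fast*
#' response, a sigmoidal BOLD rise completing within tens of seconds of the
#' gas switch, and a *slow* response, a linear ramp spanning the whole
#' dilation period. White Gaussian noise is added in increments to sweep
#' the temporal SNR. Full two-challenge subjects and cohorts with a planted
#' dependence of the second-challenge amplitude on the recovery rate make
#' every downstream stage testable without access to scanner data.
#'
#' @name simulator
NULL

# evaluate `expr` under a temporary RNG state seeded with `seed`
with_rng <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

infer_tr <- function(t) {
  if (length(t) < 2L) stop("time axis needs >= 2 points", call. = FALSE)
  dt <- diff(t)
  tr <- stats::median(dt)
  if (tr <= 0 || any(abs(dt - tr) > 1e-6 * tr)) {
    stop("time axis must be uniformly spaced", call. = FALSE)
  }
  tr
}

#' Noise-free fast (sigmoidal) hypercapnic response
#'
#' `baseline * (1 + (a/100) * logistic((t - onset - rise/2) * 8 / rise))`:
#' the response is centred halfway through the rise time and the steepness
#' factor 8 carries it from 2% to 98% of the plateau within one
#' `rise_time_s`.
#'
#' @param t Uniform time axis in seconds.
#' @param amplitude_pct Plateau amplitude as percent of baseline.
#' @param baseline_level Baseline signal level (a.u.), positive.
#' @param onset_s Gas-switch time in seconds.
#' @param rise_time_s Rise time in seconds (default 20), positive.
#' @return A noise-free [sampled_series()].
#' @export
simulate_fast <- function(t, amplitude_pct, baseline_level = 1000,
                          onset_s, rise_time_s = 20) {
  if (baseline_level <= 0) stop("baseline must be positive", call. = FALSE)
  if (rise_time_s <= 0) stop("rise time must be positive", call. = FALSE)
  tr <- infer_tr(t)
  v <- baseline_level *
    (1 + (amplitude_pct / 100) *
       stats::plogis((t - onset_s - rise_time_s / 2) * (8 / rise_time_s)))
  sampled_series(v, tr = tr, t0 = t[1])
}

#' Noise-free slow (ramp) hypercapnic response
#'
#' Linear rise from baseline at `onset_s` to the plateau at
#' `onset_s + ramp_duration_s`, flat on both sides.
#'
#' @inheritParams simulate_fast
#' @param ramp_duration_s Ramp duration in seconds (default 180, a full
#'   dilation block), positive.
#' @return A noise-free [sampled_series()].
#' @export
simulate_slow <- function(t, amplitude_pct, baseline_level = 1000,
                          onset_s, ramp_duration_s = 180) {
  if (baseline_level <= 0) stop("baseline must be positive", call. = FALSE)
  if (ramp_duration_s <= 0) stop("ramp duration must be positive",
                                 call. = FALSE)
  tr <- infer_tr(t)
  frac <- pmin(pmax((t - onset_s) / ramp_duration_s, 0), 1)
  v <- baseline_level * (1 + (amplitude_pct / 100) * frac)
  sampled_series(v, tr = tr, t0 = t[1])
}

#' Add white Gaussian noise to a series
#'
#' @param series A [sampled_series()].
#' @param noise_sd Noise standard deviation (a.u.), non-negative.
#' @param seed Optional integer seed; when supplied the global RNG state is
#'   left untouched and the same seed reproduces the same output exactly.
#' @return A [sampled_series()].
#' @export
add_noise <- function(series, noise_sd, seed = NULL) {
  stopifnot(inherits(series, "sampled_series"))
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be non-negative", call. = FALSE)
  }
  if (noise_sd == 0) return(series)
  n <- length(series)
  eps <- with_rng(seed, stats::rnorm(n, 0, noise_sd))
  sampled_series(series$values + eps, tr = series$tr, t0 = series$t0)
}

#' Simulate one normocapnia-to-hypercapnia epoch
#'
#' One room-air baseline segment followed by one CO2 segment, with the
#' chosen response shape and added noise — the unit of the fast/slow
#' simulation study.
#'
#' @param shape `"fast"` or `"slow"`.
#' @param noise_sd Noise standard deviation (a.u.).
#' @param seed Optional integer seed for the noise.
#' @param baseline_s Baseline segment duration (default 120 s).
#' @param challenge_s CO2 segment duration (default 180 s).
#' @param tr Sampling interval (default 1.55 s).
#' @param baseline_level Baseline signal level (default 1000 a.u.).
#' @param amplitude_pct Response amplitude (default 2%).
#' @param rise_time_s Fast-response rise time (default 20 s); the slow ramp
#'   always spans `challenge_s`.
#' @return An object of class `simulated_response`: list with `series`,
#'   `onset_s`, `shape`, `amplitude_pct`, `baseline_level`, `noise_sd`,
#'   `seed` and `true_slope_per_sample` (the noise-free ramp slope of the
#'   rising segment, a.u. per sample).
#' @export
simulate_epoch <- function(shape = c("fast", "slow"), noise_sd = 0,
                           seed = NULL, baseline_s = 120, challenge_s = 180,
                           tr = 1.55, baseline_level = 1000,
                           amplitude_pct = 2, rise_time_s = 20) {
  shape <- match.arg(shape)
  t <- seq(0, baseline_s + challenge_s - tr / 2, by = tr)
  clean <- if (shape == "fast") {
    simulate_fast(t, amplitude_pct, baseline_level, onset_s = baseline_s,
                  rise_time_s = rise_time_s)
  } else {
    simulate_slow(t, amplitude_pct, baseline_level, onset_s = baseline_s,
                  ramp_duration_s = challenge_s)
  }
  rise_au <- baseline_level * amplitude_pct / 100
  slope <- if (shape == "fast") rise_au / (rise_time_s / tr)
           else rise_au / (challenge_s / tr)
  structure(list(series = add_noise(clean, noise_sd, seed),
                 clean = clean, onset_s = baseline_s, shape = shape,
                 amplitude_pct = amplitude_pct,
                 baseline_level = baseline_level,
                 noise_sd = noise_sd, seed = seed,
                 true_slope_per_sample = slope),
            class = "simulated_response")
}

#' Run the fast/slow AIC simulation grid
#'
#' For every combination of response shape and temporal-SNR level,
#' simulates `reps` epochs, fits the parametric (gamma-HRF GLM) and
#' non-parametric (Theil-Sen line) models to each, and records both AIC
#' values and the realized baseline tSNR. The default grid — 2 shapes x 20
#' noise levels x 100 replicates = 4000 epochs — spans nominal tSNR 5 to
#' 100.
#'
#' @param shapes Character vector of shapes (default both).
#' @param tsnr_levels Nominal tSNR levels; noise SD is
#'   `baseline_level / tsnr` (default 20 levels, 5 to 100).
#' @param reps Replicates per cell (default 100).
#' @param base_seed Integer seed governing all noise draws.
#' @param ... Passed to [simulate_epoch()] (e.g. `tr`, `amplitude_pct`).
#' @param baseline_level Baseline signal level (default 1000 a.u.).
#' @return A data.frame with one row per epoch: `shape`, `tsnr_nominal`,
#'   `noise_sd`, `rep`, `tsnr`, `aic_parametric`, `aic_nonparametric`.
#' @export
run_simulation_grid <- function(shapes = c("fast", "slow"),
                                tsnr_levels = seq(5, 100, length.out = 20),
                                reps = 100, base_seed = 1,
                                baseline_level = 1000, ...) {
  stopifnot(all(shapes %in% c("fast", "slow")), reps >= 1,
            all(tsnr_levels > 0))
  cells <- expand.grid(rep = seq_len(reps), tsnr_nominal = tsnr_levels,
                       shape = shapes, stringsAsFactors = FALSE)
  seeds <- with_rng(base_seed,
                    sample.int(.Machine$integer.max - 1L, nrow(cells)))
  hrf <- NULL
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sd_i <- baseline_level / cells$tsnr_nominal[i]
    sim <- simulate_epoch(shape = cells$shape[i], noise_sd = sd_i,
                          seed = seeds[i], baseline_level = baseline_level,
                          ...)
    if (is.null(hrf)) hrf <- gamma_hrf(sim$series$tr)
    cmp <- compare_models(sim, hrf = hrf)
    out[[i]] <- data.frame(shape = cells$shape[i],
                           tsnr_nominal = cells$tsnr_nominal[i],
                           noise_sd = sd_i, rep = cells$rep[i],
                           tsnr = cmp$tsnr,
                           aic_parametric = cmp$aic_parametric,
                           aic_nonparametric = cmp$aic_nonparametric)
  }
  do.call(rbind, out)
}

#' Synthesize a full two-challenge subject
#'
#' Builds a paradigm-length BOLD series on the post-discard axis of the
#' requested design as baseline plus one response "bump" per challenge.
#' Each bump rises across the challenge's dilation window to its plateau
#' amplitude (`a1`/`a2` percent of baseline; a ramp spanning the window by
#' default, the slow-dilation regime the window-wide Sen's-slope read-out
#' is designed for, or a fast sigmoid via `response`), then declines
#' linearly at the recovery rate `tau` (a.u./s, negative) across the whole
#' following transition window — the linear-recovery regime the
#' transition-rate model reads out; a steep `tau` may mildly undershoot
#' the baseline, as post-stimulus BOLD signals do — and resettles at
#' baseline when the transition window ends. A breath-modulated PETCO2
#' trace whose end-tidal level follows the dilation/recovery timing is
#' generated alongside unless `with_petco2_trace = FALSE` (the scalar
#' `delta_petco2` is always carried).
#'
#' @param id Subject identifier.
#' @param design `"A"` or `"B"`.
#' @param a1_pct,a2_pct Challenge amplitudes in percent of baseline.
#' @param tau True recovery slope in a.u. per second (negative).
#' @param delta_petco2 Hypercapnic PETCO2 step in mmHg.
#' @param group `"cognitive"` or `"sleep_apnea"`.
#' @param age,sex Demographics (`sex` 0/1 coded, 1 = male).
#' @param baseline_level Baseline signal (default 1000 a.u.).
#' @param tsnr_target Nominal tSNR; noise SD is `baseline_level /
#'   tsnr_target` (default 200).
#' @param response `"ramp"` or `"sigmoid"` dilation shape.
#' @param rise_time_s Sigmoid rise time (default 20 s).
#' @param seed Integer seed for the noise.
#' @param with_petco2_trace Generate the raw CO2 trace (default TRUE).
#' @return An object of class `synthetic_subject`: list carrying the
#'   demographics, the ground-truth parameters, `bold_series`,
#'   `petco2_trace` (or `NULL`), `windows` and `noise_sd`.
#' @export
synthesize_subject <- function(id, design, a1_pct = 2, a2_pct = 2,
                               tau = -0.18, delta_petco2 = 10,
                               group = "cognitive", age = 65, sex = 0,
                               baseline_level = 1000, tsnr_target = 200,
                               response = c("ramp", "sigmoid"),
                               rise_time_s = 20, seed = NULL,
                               with_petco2_trace = TRUE) {
  response <- match.arg(response)
  paradigm <- design_paradigm(design)
  if (delta_petco2 <= 0) stop("`delta_petco2` must be positive", call. = FALSE)
  n_acq <- switch(paradigm$design_label, A = 478L, B = 255L)
  n_ret <- n_acq - default_discard_volumes(design)
  tr <- paradigm$tr
  t <- (seq_len(n_ret) - 1) * tr
  windows <- windows_for_design(design)
  v <- rep(baseline_level, n_ret)
  amps <- c(a1_pct, a2_pct)
  for (j in 1:2) {
    cwin <- windows[[paste0("cvr", j)]]
    twin <- windows[[paste0("transition", j)]]
    amp_au <- baseline_level * amps[j] / 100
    in_cvr <- t >= cwin$start_s & t < cwin$end_s
    if (response == "ramp") {
      frac <- (t[in_cvr] - cwin$start_s) / (cwin$end_s - cwin$start_s)
      v[in_cvr] <- v[in_cvr] + amp_au * frac
    } else {
      v[in_cvr] <- v[in_cvr] + amp_au *
        stats::plogis((t[in_cvr] - cwin$start_s - rise_time_s / 2) *
                        (8 / rise_time_s))
    }
    in_tr <- t >= twin$start_s & t < twin$end_s
    v[in_tr] <- v[in_tr] + amp_au + tau * (t[in_tr] - twin$start_s)
  }
  noise_sd <- baseline_level / tsnr_target
  bold <- add_noise(sampled_series(v, tr = tr, t0 = 0), noise_sd, seed)
  petco2 <- if (with_petco2_trace) {
    synth_petco2_trace(t_end = n_ret * tr, windows = windows,
                       delta = delta_petco2)
  } else NULL
  structure(list(id = id, design = paradigm$design_label, group = group,
                 age = age, sex = sex, a1_pct = a1_pct, a2_pct = a2_pct,
                 tau = tau, delta_petco2 = delta_petco2,
                 baseline_level = baseline_level, noise_sd = noise_sd,
                 seed = seed, bold_series = bold, petco2_trace = petco2,
                 windows = windows),
            class = "synthetic_subject")
}

# breath-modulated CO2 trace whose end-tidal envelope follows the gas
# timing: rises over the first half of each CVR window, plateaus over the
# second half, then washes out over a few breaths once the gas switches
# back — end-tidal CO2 is the stimulus, so unlike the BOLD recovery it
# returns to baseline quickly rather than spanning the transition window
synth_petco2_trace <- function(t_end, windows, delta, baseline_mmHg = 40,
                               fs = 10, breath_hz = 0.25, depth_mmHg = 8,
                               washout_s = 20) {
  t <- seq(0, t_end - 1 / fs, by = 1 / fs)
  level <- rep(baseline_mmHg, length(t))
  for (j in 1:2) {
    cwin <- windows[[paste0("cvr", j)]]
    twin <- windows[[paste0("transition", j)]]
    mid <- (cwin$start_s + cwin$end_s) / 2
    up <- t >= cwin$start_s & t < mid
    level[up] <- baseline_mmHg +
      delta * (t[up] - cwin$start_s) / (mid - cwin$start_s)
    hold <- t >= mid & t < twin$start_s
    level[hold] <- baseline_mmHg + delta
    w_s <- min(washout_s, twin$end_s - twin$start_s)
    down <- t >= twin$start_s & t < twin$start_s + w_s
    level[down] <- baseline_mmHg +
      delta * (1 - (t[down] - twin$start_s) / w_s)
  }
  breath <- depth_mmHg * 0.5 * (1 + cos(2 * pi * breath_hz * t))
  sampled_series(level - breath, tr = 1 / fs, t0 = 0)
}

#' Synthesize a cohort with a planted transition-rate effect
#'
#' The planted physiology lives on the PETCO2-normalized scale, the scale
#' on which subjects are comparable: each subject gets a true
#' first-challenge CVR `c1` (%/mmHg), a true per-mmHg recovery rate `r`
#' (a.u./s/mmHg, negative), and a true second-challenge CVR
#' `c2 = alpha + beta * r + eps`, so a negative `beta` plants the
#' hypothesized dependence of the second response on the preceding
#' recovery rate (steeper recovery predicting a larger second response;
#' `beta = 0` gives a true null). Signal-scale quantities then follow the
#' subject's own hypercapnic step `delta`: challenge amplitudes
#' `a_j = c_j * delta` percent, recovery slope `tau = r * delta` a.u./s —
#' BOLD responses scale with the CO2 stimulus, which is exactly why the
#' CVR and transition-rate metrics divide it back out. Demographic
#' covariates (age, sex) and the design/group structure carry no planted
#' effect. The default composition mirrors a two-site
#' memory-clinic/sleep-clinic cohort: 54 subjects, 40 on Design A (20
#' cognitive, 20 sleep apnea) and 14 on Design B (all cognitive; targeted
#' 10 mmHg step, while Design A steps are drawn from 7-10 mmHg).
#'
#' @param n_subjects Cohort size (>= 10, default 54).
#' @param beta Planted effect of the true per-mmHg recovery rate on the
#'   second-challenge CVR; default -7 (the strong-effect preset), 0 for a
#'   null cohort.
#' @param alpha Intercept of the `c2` rule in %/mmHg (default 0.1).
#' @param rate_range Uniform range for true per-mmHg recovery rates,
#'   a.u./s/mmHg (default c(-0.028, -0.014): recoveries slow enough to
#'   span the transition window, the regime the transition-rate metric
#'   measures).
#' @param c1_mean,c1_sd First-challenge true CVR distribution in %/mmHg.
#' @param c2_noise_sd SD of the subject-level residual `eps` in %/mmHg.
#' @param design_mix Named counts or weights for designs A and B.
#' @param tsnr_target Nominal per-subject tSNR (default 200).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param with_petco2_trace Generate raw CO2 traces per subject (default
#'   FALSE; the scalar PETCO2 step is always carried).
#' @return An object of class `synthetic_cohort`: list of
#'   [synthesize_subject()]s with the generating parameters attached as
#'   attributes.
#' @export
synthesize_cohort <- function(n_subjects = 54, beta = -7, alpha = 0.1,
                              rate_range = c(-0.028, -0.014),
                              c1_mean = 0.2, c1_sd = 0.04,
                              c2_noise_sd = 0.015,
                              design_mix = c(A = 40, B = 14),
                              tsnr_target = 200, seed = 1,
                              with_petco2_trace = FALSE) {
  if (n_subjects < 10) stop("need at least 10 subjects", call. = FALSE)
  params <- with_rng(seed, {
    n_b <- round(n_subjects * design_mix[["B"]] / sum(design_mix))
    design <- c(rep("A", n_subjects - n_b), rep("B", n_b))
    # Design B subjects are all 'cognitive'; Design A splits evenly
    group <- ifelse(design == "B", "cognitive",
                    rep_len(c("cognitive", "sleep_apnea"), n_subjects))
    r <- stats::runif(n_subjects, rate_range[1], rate_range[2])
    c1 <- pmax(0.05, stats::rnorm(n_subjects, c1_mean, c1_sd))
    c2 <- pmax(0.05, alpha + beta * r +
                 stats::rnorm(n_subjects, 0, c2_noise_sd))
    delta <- ifelse(design == "B", 10, stats::runif(n_subjects, 7, 10))
    age <- round(pmin(95, pmax(40, stats::rnorm(n_subjects, 67, 11))))
    sex <- stats::rbinom(n_subjects, 1, 25 / 54)
    sub_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
    list(design = design, group = group, r = r, c1 = c1, c2 = c2,
         delta = delta, age = age, sex = sex, sub_seeds = sub_seeds)
  })
  subjects <- lapply(seq_len(n_subjects), function(i) {
    synthesize_subject(
      id = sprintf("sub-%03d", i), design = params$design[i],
      a1_pct = params$c1[i] * params$delta[i],
      a2_pct = params$c2[i] * params$delta[i],
      tau = params$r[i] * params$delta[i],
      delta_petco2 = params$delta[i], group = params$group[i],
      age = params$age[i], sex = params$sex[i],
      tsnr_target = tsnr_target, seed = params$sub_seeds[i],
      with_petco2_trace = with_petco2_trace)
  })
  structure(subjects, class = "synthetic_cohort",
            beta = beta, alpha = alpha, seed = seed,
            tsnr_target = tsnr_target)
}

#' Run the measurement pipeline over a cohort
#'
#' Applies the window/Sen's-slope/normalization pipeline and the
#' transition fits to every subject's BOLD series and returns the flat
#' subject table consumed by the group-level models. The gamma-HRF GLM
#' COPE estimate (normalized to %/mmHg) is included as `cope_cvr`.
#'
#' @param cohort A [synthesize_cohort()] result (or list of
#'   [synthesize_subject()]s).
#' @param roi Label stored in the `roi` column (default `"simulated"`).
#' @return A data.frame with one row per subject: demographics, design,
#'   measured `cvr1`, `cvr2` (%/mmHg), `transition_rate_1`,
#'   `transition_rate_2` (a.u./s/mmHg), `cope_cvr`, and the ground-truth
#'   columns `true_a1`, `true_a2`, `true_tau`.
#' @export
cohort_table <- function(cohort, roi = "simulated") {
  hrf_by_tr <- list()
  rows <- lapply(cohort, function(s) {
    m <- subject_metrics(s$bold_series, s$windows, s$delta_petco2)
    tr_key <- sprintf("%.6f", s$bold_series$tr)
    if (is.null(hrf_by_tr[[tr_key]])) {
      hrf_by_tr[[tr_key]] <<- gamma_hrf(s$bold_series$tr)
    }
    paradigm <- design_paradigm(s$design)
    box <- build_boxcar(paradigm, n_samples = length(s$bold_series),
                        discard_s = default_discard_volumes(s$design) *
                          paradigm$tr)
    g <- glm_cope(s$bold_series, box, hrf_by_tr[[tr_key]],
                  delta_petco2 = s$delta_petco2,
                  baseline_mean = m$cvr1$baseline_mean)
    data.frame(id = s$id, age = s$age, sex = s$sex, group = s$group,
               design = s$design, roi = roi,
               cvr1 = m$cvr1$cvr, cvr2 = m$cvr2$cvr,
               transition_rate_1 = m$transition1$transition_rate,
               transition_rate_2 = m$transition2$transition_rate,
               cope_cvr = g$pct_equivalent,
               true_a1 = s$a1_pct, true_a2 = s$a2_pct, true_tau = s$tau,
               true_cvr1 = s$a1_pct / s$delta_petco2,
               true_cvr2 = s$a2_pct / s$delta_petco2,
               true_rate = s$tau / s$delta_petco2,
               delta_petco2 = s$delta_petco2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a cohort to per-subject CSV files plus a manifest
#'
#' @param cohort A [synthesize_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- do.call(rbind, lapply(cohort, function(s) {
    f <- file.path(dir, paste0(s$id, "_bold.csv"))
    write_series_csv(s$bold_series, f)
    if (!is.null(s$petco2_trace)) {
      write_series_csv(s$petco2_trace,
                       file.path(dir, paste0(s$id, "_co2.csv")))
    }
    data.frame(id = s$id, design = s$design, group = s$group, age = s$age,
               sex = s$sex, delta_petco2 = s$delta_petco2,
               true_a1 = s$a1_pct, true_a2 = s$a2_pct, true_tau = s$tau,
               noise_sd = s$noise_sd, bold_file = basename(f),
               stringsAsFactors = FALSE)
  }))
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}
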