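test_that("fast response passes its midpoint and reaches the plateau", {
  t <- seq(0, 299, by = 1)
  s <- simulate_fast(t, amplitude_pct = 2, baseline_level = 1000,
                     onset_s = 120, rise_time_s = 20)
  # half the rise at onset + rise/2
  expect_equal(s$values[t == 130], 1010, tolerance = 1e-6)
  # plateau within 2% of full amplitude one rise-time past onset
  expect_gt(s$values[t == 140], 1000 + 0.98 * 20)
  # essentially flat long before the onset
  expect_lt(s$values[t == 60], 1000 + 0.001 * 20)
  expect_true(all(diff(s$values) >= 0))
  expect_error(simulate_fast(t, 2, baseline_level = -1, onset_s = 10),
               "positive")
})

test_that("slow response ramps linearly across the challenge", {
  t <- seq(0, 299, by = 1)
  s <- simulate_slow(t, amplitude_pct = 2, baseline_level = 1000,
                     onset_s = 120, ramp_duration_s = 180)
  expect_equal(s$values[t <= 120], rep(1000, 121))
  expect_equal(s$values[t == 299], 1000 + 20 * (179 / 180), tolerance = 1e-9)
  ramp <- s$values[t >= 120]
  # Sen's slope of the ramp equals the analytic rise per sample
  expect_equal(sens_slope(ramp), 20 / 180, tolerance = 1e-9)
})

test_that("add_noise is deterministic under a seed and inert at sd 0", {
  s <- sampled_series(rep(100, 500), tr = 1.55)
  expect_identical(add_noise(s, 0), s)
  a <- add_noise(s, 3, seed = 12)
  b <- add_noise(s, 3, seed = 12)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, add_noise(s, 3, seed = 13)$values))
  # a seeded call leaves the global RNG stream untouched
  set.seed(99); x1 <- rnorm(1)
  set.seed(99); invisible(add_noise(s, 3, seed = 12)); x2 <- rnorm(1)
  expect_identical(x1, x2)
  expect_error(add_noise(s, -1), "non-negative")
})

test_that("realized tSNR tracks the nominal level", {
  base <- sampled_series(rep(1000, 2000), tr = 1)
  for (nominal in c(20, 50, 200)) {
    noisy <- add_noise(base, 1000 / nominal, seed = nominal)
    expect_lt(abs(tsnr(noisy$values) - nominal) / nominal, 0.15)
  }
})

test_that("simulate_epoch assembles the documented timing", {
  e <- simulate_epoch("fast", noise_sd = 0)
  expect_equal(e$onset_s, 120)
  expect_equal(e$series$tr, 1.55)
  expect_equal(length(e$series), length(seq(0, 300 - 1.55 / 2, by = 1.55)))
  expect_equal(e$true_slope_per_sample, 20 / (20 / 1.55))
  e2 <- simulate_epoch("slow", noise_sd = 0)
  expect_equal(e2$true_slope_per_sample, 20 / (180 / 1.55))
  expect_error(simulate_epoch("medium"), "arg")
})

test_that("run_simulation_grid returns one row per epoch, reproducibly", {
  g <- run_simulation_grid(shapes = "fast", tsnr_levels = c(20, 80),
                           reps = 3, base_seed = 7)
  expect_equal(nrow(g), 6)
  expect_setequal(g$tsnr_nominal, c(20, 80))
  expect_true(all(is.finite(g$aic_parametric)))
  g2 <- run_simulation_grid(shapes = "fast", tsnr_levels = c(20, 80),
                            reps = 3, base_seed = 7)
  expect_identical(g, g2)
})

test_that("a noise-free synthetic subject returns its planted parameters", {
  s <- synthesize_subject("t", "B", a1_pct = 1.5, a2_pct = 2.5, tau = -0.2,
                          delta_petco2 = 10, tsnr_target = Inf)
  m <- subject_metrics(s$bold_series, s$windows, 10)
  expect_lt(abs(m$cvr1$cvr - 0.15) / 0.15, 0.05)
  expect_lt(abs(m$cvr2$cvr - 0.25) / 0.25, 0.05)
  # recovery slope tau is read back by the transition fit
  expect_lt(abs(m$transition1$tau - (-0.2)) / 0.2, 0.05)
  expect_equal(m$transition1$transition_rate, m$transition1$tau / 10)
  expect_equal(length(s$bold_series), 250)

  sA <- synthesize_subject("tA", "A", tsnr_target = Inf)
  expect_equal(length(sA$bold_series), 453)
  expect_equal(sA$bold_series$tr, 1.55)
})

test_that("the synthetic PETCO2 trace round-trips through capnometry", {
  s <- synthesize_subject("p", "B", delta_petco2 = 10, tsnr_target = Inf,
                          with_petco2_trace = TRUE)
  pet <- extract_petco2(s$petco2_trace, out_tr = s$bold_series$tr,
                        out_n = length(s$bold_series))
  d <- petco2_delta(pet, s$windows, 1)
  expect_lt(abs(d$delta - 10), 0.5)
  d2 <- petco2_delta(pet, s$windows, 2)
  expect_lt(abs(d2$delta - 10), 0.5)
})

test_that("cohorts are reproducible from the seed and carry the composition", {
  c1 <- synthesize_cohort(n_subjects = 12, seed = 31,
                          design_mix = c(A = 8, B = 4))
  c2 <- synthesize_cohort(n_subjects = 12, seed = 31,
                          design_mix = c(A = 8, B = 4))
  expect_identical(cohort_table(c1), cohort_table(c2))
  tab <- cohort_table(c1)
  expect_equal(nrow(tab), 12)
  expect_equal(sum(tab$design == "B"), 4)
  expect_true(all(tab$group[tab$design == "B"] == "cognitive"))
  expect_true(all(tab$delta_petco2[tab$design == "B"] == 10))
  expect_true(all(tab$delta_petco2 >= 7 & tab$delta_petco2 <= 10))
  expect_true(all(tab$true_tau < 0))
  expect_error(synthesize_cohort(n_subjects = 5), "at least 10")
})

test_that("measured metrics track the planted truths across a cohort", {
  tab <- cohort_table(synthesize_cohort(n_subjects = 60, seed = 88,
                                        design_mix = c(A = 44, B = 16)))
  expect_gt(cor(tab$cvr1, tab$true_cvr1), 0.75)
  expect_gt(cor(tab$cvr2, tab$true_cvr2), 0.75)
  expect_gt(cor(tab$transition_rate_1, tab$true_rate), 0.5)
  # the GLM COPE estimate co-varies with the non-parametric CVR within a
  # design; its scale factor depends on the paradigm timing (how much of
  # the response falls under the convolved boxcar), so it is compared
  # within Design A only rather than pooled across designs
  a <- tab[tab$design == "A", ]
  expect_gt(cor(a$cope_cvr, (a$cvr1 + a$cvr2) / 2), 0.3)
})

test_that("write_cohort emits per-subject series plus a manifest", {
  dir <- tempfile("cohort")
  coh <- synthesize_cohort(n_subjects = 10, seed = 3,
                           design_mix = c(A = 7, B = 3))
  mpath <- write_cohort(coh, dir)
  man <- read.csv(mpath)
  expect_equal(nrow(man), 10)
  s1 <- read_series_csv(file.path(dir, man$bold_file[1]))
  expect_equal(s1$values, coh[[1]]$bold_series$values, tolerance = 1e-9)
  expect_equal(s1$tr, coh[[1]]$bold_series$tr)
})
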