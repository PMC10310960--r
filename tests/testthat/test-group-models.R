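make_records <- function(n = 40, seed = 15, beta_rate = -0.6) {
  withr::with_seed(seed, {
    rate <- rnorm(n, -0.02, 0.004)
    cvr1 <- rnorm(n, 0.2, 0.04)
    data.frame(
      id = sprintf("s%02d", seq_len(n)),
      roi = "simulated",
      cvr1 = cvr1,
      transition_rate_1 = rate,
      cvr2 = 0.2 + beta_rate * scale(rate)[, 1] * 0.04 + rnorm(n, 0, 0.02),
      cope_cvr = cvr1 + rnorm(n, 0, 0.02),
      age = round(runif(n, 45, 90)),
      sex = rbinom(n, 1, 0.5),
      group = sample(c("cognitive", "sleep_apnea"), n, replace = TRUE),
      design = sample(c("A", "B"), n, replace = TRUE),
      stringsAsFactors = FALSE)
  })
}

test_that("standardize centers, scales and is idempotent", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  z <- standardize(rnorm(50, 10, 3))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(standardize(z), z, tolerance = 1e-12)
  expect_error(standardize(rep(4, 10)), "constant")
})

test_that("orthogonalize removes all linear dependence", {
  withr::with_seed(6, {
    b <- rnorm(60)
    a <- 2 + 3 * b + rnorm(60, 0, 0.5)
    r <- orthogonalize(a, b)
    expect_lt(abs(cor(r, b)), 1e-10)
    expect_equal(mean(r), 0, tolerance = 1e-12)
    # already-orthogonal input passes through up to centering
    expect_equal(orthogonalize(r, b), r, tolerance = 1e-10)
  })
  expect_error(orthogonalize(rnorm(5), rep(1, 5)), "constant")
})

test_that("fit_model1 matches the normal-equations oracle", {
  rec <- make_records()
  f <- fit_model1(rec, roi = "simulated")
  expect_s3_class(f, "cvr_model_fit")
  expect_equal(f$n, 40)
  expect_setequal(f$terms$term,
                  c("transition_rate", "age", "sex_male", "group_apnea",
                    "design_b"))

  X <- cbind(1,
             standardize(rec$transition_rate_1),
             standardize(rec$age),
             rec$sex,
             as.numeric(rec$group == "sleep_apnea"),
             as.numeric(rec$design == "B"))
  beta <- normal_equations(X, standardize(rec$cvr2))
  got <- f$terms$std_pe[match(c("transition_rate", "age", "sex_male",
                                "group_apnea", "design_b"), f$terms$term)]
  expect_equal(got, unname(beta[-1]), tolerance = 1e-8)

  # the planted negative rate effect is detected
  pe <- f$terms$std_pe[f$terms$term == "transition_rate"]
  expect_lt(pe, 0)
  expect_true(bonferroni_flag(f$terms$p[f$terms$term == "transition_rate"]))
})

test_that("standardized PEs are invariant to affine rescaling of inputs", {
  rec <- make_records(seed = 44)
  f1 <- fit_model1(rec)
  rec2 <- rec
  rec2$cvr2 <- 100 * rec$cvr2 - 3          # units change
  rec2$transition_rate_1 <- rec$transition_rate_1 / 60 + 0.5
  rec2$age <- rec$age * 12                 # months instead of years
  f2 <- fit_model1(rec2)
  expect_equal(f1$terms$std_pe, f2$terms$std_pe, tolerance = 1e-8)
  expect_equal(f1$terms$p, f2$terms$p, tolerance = 1e-8)
})

test_that("fit_model2 residualizes the transition rate against CVR-1", {
  rec <- make_records(seed = 29)
  f <- fit_model2(rec)
  expect_setequal(f$terms$term,
                  c("cvr1", "adj_transition_rate", "age", "sex_male",
                    "group_apnea", "design_b"))
  # reproduce the orthogonalized regressor and the full fit by hand
  orth <- orthogonalize(rec$transition_rate_1, rec$cvr1)
  X <- cbind(1,
             standardize(rec$cvr1),
             standardize(orth),
             standardize(rec$age),
             rec$sex,
             as.numeric(rec$group == "sleep_apnea"),
             as.numeric(rec$design == "B"))
  beta <- normal_equations(X, standardize(rec$cvr2))
  got <- f$terms$std_pe[match(c("cvr1", "adj_transition_rate", "age",
                                "sex_male", "group_apnea", "design_b"),
                              f$terms$term)]
  expect_equal(got, unname(beta[-1]), tolerance = 1e-8)

  # selectable target
  f2 <- fit_model2(rec, orth_target = "cvr2")
  expect_false(isTRUE(all.equal(f$terms$std_pe, f2$terms$std_pe)))
})

test_that("prepare_records handles coding, missingness and degeneracy", {
  rec <- make_records(seed = 9)
  rec$cvr2[3] <- NA
  expect_message(f <- fit_model1(rec), "1 row\\(s\\) dropped")
  expect_equal(f$n, 39)

  tiny <- make_records(n = 12, seed = 9)
  tiny$cvr2[1:5] <- NA
  expect_error(suppressMessages(fit_model1(tiny)), "at least 10")

  bad <- make_records(seed = 9)
  bad$sex <- 2
  expect_error(fit_model1(bad), "0/1")

  # F/M coding equals 0/1 coding
  fm <- make_records(seed = 9)
  fm$sex <- ifelse(fm$sex == 1, "M", "F")
  expect_equal(fit_model1(fm)$terms$std_pe,
               fit_model1(make_records(seed = 9))$terms$std_pe,
               tolerance = 1e-12)

  # a collinear duplicate predictor is refused with a clear message
  dup <- make_records(seed = 9)
  dup$design <- dup$sex   # design indicator identical to sex
  expect_error(fit_model1(dup), "collinear")
})

test_that("bonferroni_flag applies the alpha/m threshold inclusively", {
  expect_equal(bonferroni_flag(c(0.01, 0.0125, 0.013, 0.5)),
               c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(bonferroni_flag(0.011, alpha = 0.05, m = 5), FALSE)
  expect_equal(bonferroni_flag(0.009, alpha = 0.05, m = 5), TRUE)
  expect_error(bonferroni_flag(1.2), "\\[0, 1\\]")
  expect_true(is.na(bonferroni_flag(NA)))
})

test_that("correlation_matrix reports Pearson r and r^2", {
  rec <- make_records(seed = 50)
  cm <- correlation_matrix(rec)
  expect_equal(dim(cm$r), c(4, 4))
  expect_equal(diag(cm$r), rep(1, 4), ignore_attr = TRUE)
  expect_equal(cm$r, t(cm$r))
  expect_equal(cm$r2, cm$r^2)
  expect_equal(cm$r["cvr1", "cope_cvr"],
               cor(rec$cvr1, rec$cope_cvr))
  # constant column -> NA with warning
  rec$cope_cvr <- 1
  expect_warning(cm2 <- correlation_matrix(rec), "constant")
  expect_true(is.na(cm2$r["cvr1", "cope_cvr"]))
})

test_that("model_results_table flattens fits with significance flags", {
  rec <- make_records(seed = 61)
  tab <- model_results_table(fit_model1(rec), fit_model2(rec))
  expect_equal(sort(unique(tab$model)), c("model1", "model2"))
  expect_equal(nrow(tab), 5 + 6)
  expect_equal(tab$significant, bonferroni_flag(tab$p))
})
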