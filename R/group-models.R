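#' Group-level CVR regression models
#'
#' Two linear models per region of interest test whether the rate of BOLD
#' recovery after the first hypercapnia challenge predicts the response to
#' the second challenge:
#'
#' * **Model 1** — `CVR-2 ~ transition rate + age + sex + group + design`
#' * **Model 2** — `CVR-2 ~ CVR-1 + orthogonalized transition rate + age +
#'   sex + group + design`, where the transition rate is first
#'   residualized so that only its variance not shared with the
#'   co-regressor enters the model.
#'
#' Continuous variables (outcome and predictors) are standardized so the
#' reported parameter estimates are standardized PEs; sex, group and
#' design enter as 0/1 indicators. Significance across the four regions of
#' interest is controlled with a Bonferroni threshold (`alpha / m`, 0.0125
#' at the defaults).
#'
#' @name group-models
NULL

#' Standardize a column to zero mean and unit variance
#'
#' @param x Numeric vector with positive standard deviation (n - 1
#'   denominator); `NA` preserved.
#' @return The standardized vector.
#' @export
standardize <- function(x) {
  x <- as.numeric(x)
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) {
    stop("cannot standardize a constant column", call. = FALSE)
  }
  (x - mean(x, na.rm = TRUE)) / s
}

#' Orthogonalize one column with respect to another
#'
#' Residual of the OLS regression of `a` on an intercept and `b`; the
#' result is exactly uncorrelated with `b` and mean-zero.
#'
#' @param a Numeric vector to orthogonalize.
#' @param b Non-constant numeric vector of the same length.
#' @return Residual vector.
#' @export
orthogonalize <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) == length(b))
  if (stats::sd(b, na.rm = TRUE) == 0) {
    stop("cannot orthogonalize against a constant column", call. = FALSE)
  }
  stats::residuals(stats::lm(a ~ b, na.action = stats::na.exclude))
}

# common front end: subset to the ROI, code covariates, drop incomplete rows
prepare_records <- function(records, roi, needed) {
  stopifnot(is.data.frame(records))
  if (!is.null(roi) && "roi" %in% names(records)) {
    records <- records[records$roi == roi, , drop = FALSE]
    if (nrow(records) == 0L) stop("no rows for roi '", roi, "'", call. = FALSE)
  }
  miss <- setdiff(needed, names(records))
  if (length(miss)) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  keep <- stats::complete.cases(records[, needed])
  dropped <- sum(!keep)
  if (dropped > 0) {
    message(dropped, " row(s) dropped for missing values")
  }
  records <- records[keep, , drop = FALSE]
  if (nrow(records) < 10L) {
    stop("need at least 10 complete rows; have ", nrow(records),
         call. = FALSE)
  }
  records$sex_male <- code_binary(records$sex, c("F", "M"))
  records$group_apnea <- code_binary(records$group,
                                     c("cognitive", "sleep_apnea"))
  records$design_b <- code_binary(records$design, c("A", "B"))
  records
}

code_binary <- function(x, levels_01) {
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) stop("numeric indicator must be 0/1",
                                   call. = FALSE)
    return(as.numeric(x))
  }
  if (!all(x %in% levels_01)) {
    stop("values must be in {", paste(levels_01, collapse = ", "), "}",
         call. = FALSE)
  }
  as.numeric(x == levels_01[2])
}

fit_cvr_lm <- function(df, terms, model_id, roi) {
  X <- as.matrix(df[, terms, drop = FALSE])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    bad <- c("(intercept)", terms)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("rank-deficient design; collinear term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fml <- stats::as.formula(paste("outcome ~", paste(terms, collapse = " + ")))
  fit <- stats::lm(fml, data = df)
  sm <- summary(fit)
  co <- sm$coefficients
  res <- data.frame(term = rownames(co)[-1],
                    std_pe = unname(co[-1, "Estimate"]),
                    p = unname(co[-1, "Pr(>|t|)"]),
                    stringsAsFactors = FALSE)
  structure(list(model_id = model_id, roi = roi, n = nrow(df),
                 adj_r2 = sm$adj.r.squared, r2 = sm$r.squared,
                 terms = res, fit = fit),
            class = "cvr_model_fit")
}

#' @export
print.cvr_model_fit <- function(x, ...) {
  cat(sprintf("<cvr_model_fit> %s%s: n = %d, R^2 = %.3f, adj R^2 = %.3f\n",
              x$model_id,
              if (is.null(x$roi)) "" else paste0(" [", x$roi, "]"),
              x$n, x$r2, x$adj_r2))
  print(format(x$terms, digits = 3), row.names = FALSE)
  invisible(x)
}

#' CVR Model 1: transition rate predicting the second CVR response
#'
#' Linear model `CVR-2 ~ transition_rate_1 + age + sex + group + design`
#' with all continuous columns standardized, fitted by OLS after listwise
#' deletion. The transition-rate predictor is the recovery rate of the
#' hypercapnia-to-normocapnia period preceding the second challenge.
#'
#' @param records Subject table: columns `cvr2`, `transition_rate_1`,
#'   `age`, `sex` (0/1 or F/M), `group` (`cognitive`/`sleep_apnea` or 0/1),
#'   `design` (`A`/`B` or 0/1) and optionally `roi`.
#' @param roi Optional ROI label to subset on.
#' @return A `cvr_model_fit`: standardized PEs with p-values, adjusted R2,
#'   n used.
#' @export
fit_model1 <- function(records, roi = NULL) {
  needed <- c("cvr2", "transition_rate_1", "age", "sex", "group", "design")
  df <- prepare_records(records, roi, needed)
  d <- data.frame(outcome = standardize(df$cvr2),
                  transition_rate = standardize(df$transition_rate_1),
                  age = standardize(df$age),
                  sex_male = df$sex_male,
                  group_apnea = df$group_apnea,
                  design_b = df$design_b)
  fit_cvr_lm(d, c("transition_rate", "age", "sex_male", "group_apnea",
                  "design_b"),
             model_id = "model1", roi = roi)
}

#' CVR Model 2: first response plus the orthogonalized transition rate
#'
#' Linear model `CVR-2 ~ CVR-1 + orthogonalized transition rate + age +
#' sex + group + design`. The transition rate is residualized against the
#' co-regressor before entering the model, so its PE reflects only
#' recovery-rate variance not shared with the co-regressor; by default the
#' orthogonalization target is CVR-1 (residualizing a predictor against
#' the outcome itself would distort inference — see the package vignette).
#'
#' @inheritParams fit_model1
#' @param orth_target `"cvr1"` (default) or `"cvr2"`: the column the
#'   transition rate is residualized against.
#' @return A `cvr_model_fit`.
#' @export
fit_model2 <- function(records, roi = NULL, orth_target = c("cvr1", "cvr2")) {
  orth_target <- match.arg(orth_target)
  needed <- c("cvr1", "cvr2", "transition_rate_1", "age", "sex", "group",
              "design")
  df <- prepare_records(records, roi, needed)
  orth <- orthogonalize(df$transition_rate_1, df[[orth_target]])
  d <- data.frame(outcome = standardize(df$cvr2),
                  cvr1 = standardize(df$cvr1),
                  adj_transition_rate = standardize(orth),
                  age = standardize(df$age),
                  sex_male = df$sex_male,
                  group_apnea = df$group_apnea,
                  design_b = df$design_b)
  fit_cvr_lm(d, c("cvr1", "adj_transition_rate", "age", "sex_male",
                  "group_apnea", "design_b"),
             model_id = "model2", roi = roi)
}

#' Bonferroni significance flags
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param alpha Family-wise error rate (default 0.05).
#' @param m Number of comparisons (default 4, one per ROI).
#' @return Logical vector: `p <= alpha / m` (threshold 0.0125 at the
#'   defaults).
#' @export
bonferroni_flag <- function(p_values, alpha = 0.05, m = 4) {
  p <- as.numeric(p_values)
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p <= alpha / m
}

#' Pearson correlation matrix of CVR temporal features
#'
#' Pairwise Pearson correlations (complete observations per pair) between
#' the requested metric columns, with the squared correlations attached.
#' A constant column yields `NA` entries with a warning.
#'
#' @param records Subject table.
#' @param roi Optional ROI label to subset on.
#' @param columns Metric columns to correlate (default the four temporal
#'   features: transition rate, both non-parametric CVR estimates and the
#'   GLM COPE-based estimate).
#' @return A list with `r` (correlation matrix, unit diagonal) and `r2`.
#' @export
correlation_matrix <- function(records, roi = NULL,
                               columns = c("transition_rate_1", "cvr1",
                                           "cvr2", "cope_cvr")) {
  stopifnot(is.data.frame(records))
  if (!is.null(roi) && "roi" %in% names(records)) {
    records <- records[records$roi == roi, , drop = FALSE]
  }
  miss <- setdiff(columns, names(records))
  if (length(miss)) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(records[, columns, drop = FALSE])
  if (nrow(x) < 3L) stop("need at least 3 rows per pair", call. = FALSE)
  const <- apply(x, 2, function(col) stats::sd(col, na.rm = TRUE) == 0)
  if (any(const)) {
    warning("constant column(s): ", paste(columns[const], collapse = ", "),
            "; correlations set to NA", call. = FALSE)
  }
  r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs",
                                   method = "pearson"))
  diag(r) <- ifelse(const, NA_real_, 1)
  list(r = r, r2 = r^2)
}

#' Tidy table of one or more fitted models
#'
#' @param ... `cvr_model_fit` objects.
#' @param alpha,m Passed to [bonferroni_flag()].
#' @return A data.frame with columns `roi`, `model`, `term`, `std_pe`,
#'   `p`, `significant`, `adj_r2`, `n`.
#' @export
model_results_table <- function(..., alpha = 0.05, m = 4) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1]]) &&
      !inherits(fits[[1]], "cvr_model_fit")) {
    fits <- fits[[1]]
  }
  do.call(rbind, lapply(fits, function(f) {
    stopifnot(inherits(f, "cvr_model_fit"))
    data.frame(roi = if (is.null(f$roi)) NA_character_ else f$roi,
               model = f$model_id, term = f$terms$term,
               std_pe = f$terms$std_pe, p = f$terms$p,
               significant = bonferroni_flag(f$terms$p, alpha, m),
               adj_r2 = f$adj_r2, n = f$n,
               stringsAsFactors = FALSE)
  }))
}
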