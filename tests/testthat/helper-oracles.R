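# Independent oracles used to cross-check the package's estimators.

# Brute-force Theil-Sen: enumerate every index pair explicitly.
brute_force_sen <- function(x) {
  n <- length(x)
  pairs <- utils::combn(n, 2)
  slopes <- (x[pairs[2, ]] - x[pairs[1, ]]) / (pairs[2, ] - pairs[1, ])
  median(sort(slopes))
}

# Textbook normal-equations OLS solve.
normal_equations <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# Closed-form simple-regression slope.
ols_slope <- function(t, y) {
  sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
}

# Full-constant Gaussian AIC (keeps the 1 + log(2*pi) term).
aic_full_constant <- function(residuals, k) {
  n <- length(residuals)
  rss <- sum(residuals^2)
  n * (log(2 * pi) + log(rss / n) + 1) + 2 * k
}

# Tiny 4D NIfTI fixture written to a temp file; returns the paths and array.
make_nifti_fixture <- function(dim3 = c(4, 4, 3), n_vol = 10, tr = 2,
                               seed = 99) {
  arr <- withr::with_seed(seed,
    array(rnorm(prod(dim3) * n_vol, 100, 5), dim = c(dim3, n_vol)))
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, c(1, 1, 1, tr))
  bold_path <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, bold_path)
  list(bold = bold_path, arr = arr, tr = tr, dim3 = dim3, n_vol = n_vol)
}

write_mask <- function(mask_arr) {
  path <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(mask_arr), path)
  path
}
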