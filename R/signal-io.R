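#' Extract an ROI-mean BOLD time series from a 4D NIfTI image
#'
#' Computes, for each volume, the unweighted mean over the voxels selected
#' by the mask. Masks resampled from anatomical space typically carry
#' fractional values; voxels with mask value > `mask_threshold` are
#' included. Voxels that are `NA` in a given volume (e.g. masked out after
#' registration) are excluded from that volume's mean; a series in which
#' more than 10% of volumes contain `NA` voxels beyond repair is rejected.
#'
#' The BOLD image and mask must already be on the same voxel grid —
#' registration and resampling are upstream concerns.
#'
#' @param bold_4d Path to a 4D BOLD NIfTI-1 file (`.nii`/`.nii.gz`).
#' @param mask Path to a 3D mask NIfTI-1 file on the same grid.
#' @param tr_override Optional repetition time in seconds, used instead of
#'   the NIfTI header value (required when the header TR is missing/zero).
#' @param mask_threshold Inclusion threshold for (possibly fractional)
#'   mask values; default 0.5.
#' @return A [sampled_series()] of per-volume ROI means, `t0 = 0`.
#' @export
read_bold_roi_series <- function(bold_4d, mask, tr_override = NULL,
                                 mask_threshold = 0.5) {
  img <- RNifti::readNifti(bold_4d)
  msk <- RNifti::readNifti(mask)
  dim_img <- dim(img)
  if (length(dim_img) < 4L) {
    # accept 3D-with-singleton or true 4D only
    stop("BOLD image must be 4D; got dims ",
         paste(dim_img, collapse = "x"), call. = FALSE)
  }
  grid_img <- dim_img[1:3]
  dim_msk <- dim(msk)
  grid_msk <- dim_msk[seq_len(min(3L, length(dim_msk)))]
  if (!identical(as.integer(grid_img), as.integer(grid_msk))) {
    stop(sprintf("grid mismatch: BOLD %s vs mask %s",
                 paste(grid_img, collapse = "x"),
                 paste(grid_msk, collapse = "x")), call. = FALSE)
  }
  sel <- which(as.array(msk) > mask_threshold)
  if (length(sel) == 0L) {
    stop("mask selects no voxels at threshold ", mask_threshold, call. = FALSE)
  }
  tr <- tr_override
  if (is.null(tr)) {
    tr <- RNifti::pixdim(img)[4]
    if (!is.finite(tr) || tr <= 0) {
      stop("TR missing or zero in the NIfTI header; supply `tr_override`",
           call. = FALSE)
    }
  }
  n_vol <- dim_img[4]
  arr <- as.array(img)
  dim(arr) <- c(prod(grid_img), n_vol)
  roi <- arr[sel, , drop = FALSE]
  vals <- colMeans(roi, na.rm = TRUE)
  if (mean(colSums(is.na(roi)) > 0) > 0.10) {
    stop("more than 10% of volumes contain NA voxels inside the ROI",
         call. = FALSE)
  }
  sampled_series(vals, tr = tr, t0 = 0)
}

#' Discard initial equilibration volumes
#'
#' Drops the first `n_discard` samples. The retained series is re-indexed so
#' that its first sample sits at time 0: all analytical windows are defined
#' on this post-discard axis.
#'
#' @param series A [sampled_series()].
#' @param n_discard Number of leading samples to drop (`0 <= n_discard <
#'   length`).
#' @return A [sampled_series()] with `t0 = 0`.
#' @export
discard_initial_volumes <- function(series, n_discard) {
  stopifnot(inherits(series, "sampled_series"))
  n <- length(series$values)
  if (!is.numeric(n_discard) || n_discard < 0 || n_discard != round(n_discard)) {
    stop("`n_discard` must be a non-negative integer", call. = FALSE)
  }
  if (n_discard >= n) {
    stop(sprintf("cannot discard %d of %d volumes", n_discard, n),
         call. = FALSE)
  }
  if (n_discard == 0) return(series)
  sampled_series(series$values[-seq_len(n_discard)], tr = series$tr, t0 = 0)
}

#' High-pass detrending by Gaussian-weighted running-line subtraction
#'
#' Removes signal components slower than `cutoff_hz` by fitting, at each
#' time point, a locally weighted straight line (Gaussian weights with
#' standard deviation of half the cutoff period) and subtracting it. The
#' series mean is re-added afterwards, so baseline normalization of percent
#' signal change remains meaningful.
#'
#' @param series A [sampled_series()].
#' @param cutoff_hz Cutoff frequency in Hz; must lie strictly between 0 and
#'   the Nyquist frequency `1/(2*tr)`. Typical values: 3.18e-4 Hz (500 s
#'   period) for long paradigms, 1.60e-3 Hz (300 s) for shorter ones.
#' @return Detrended [sampled_series()] with the original mean.
#' @export
highpass_detrend <- function(series, cutoff_hz) {
  stopifnot(inherits(series, "sampled_series"))
  nyq <- 1 / (2 * series$tr)
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= nyq) {
    stop(sprintf("cutoff must be in (0, %g) Hz (Nyquist)", nyq), call. = FALSE)
  }
  y <- series$values
  t <- series_times(series)
  sigma_s <- (1 / cutoff_hz) / 2
  n <- length(y)
  trend <- numeric(n)
  for (i in seq_len(n)) {
    w <- exp(-0.5 * ((t - t[i]) / sigma_s)^2)
    ok <- !is.na(y)
    w <- w * ok
    sw <- sum(w)
    tc <- t - t[i]
    wt <- sum(w * tc) / sw
    wy <- sum(w * y, na.rm = TRUE) / sw
    stt <- sum(w * (tc - wt)^2)
    sty <- sum(w * (tc - wt) * (ifelse(ok, y, 0) - wy))
    slope <- if (stt > 0) sty / stt else 0
    trend[i] <- wy + slope * (0 - wt)
  }
  out <- y - trend + mean(y, na.rm = TRUE)
  sampled_series(out, tr = series$tr, t0 = series$t0)
}

#' Read a sampled series from a delimited text file
#'
#' Accepts either a two-column layout (time in seconds, value) with
#' uniform spacing, or a single value column plus an explicit `tr`.
#' Non-uniform time spacing beyond 1% of the median interval is an error.
#'
#' @param path CSV/TSV file path (delimiter sniffed from the first line).
#' @param time_col,value_col Column names or 1-based indices; defaults:
#'   first column is time, second is value when `tr` is `NULL`, otherwise
#'   the first column is the value.
#' @param tr Optional sampling interval in seconds; when supplied, no time
#'   column is required and `t0` defaults to 0.
#' @return A [sampled_series()].
#' @export
read_series_csv <- function(path, time_col = NULL, value_col = NULL,
                            tr = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (nrow(df) < 2L) stop("need at least 2 rows", call. = FALSE)
  pick <- function(col, default_idx) {
    if (is.null(col)) {
      if (ncol(df) < default_idx) stop("missing column", call. = FALSE)
      df[[default_idx]]
    } else if (is.character(col)) {
      if (!col %in% names(df)) stop("missing column '", col, "'", call. = FALSE)
      df[[col]]
    } else df[[col]]
  }
  if (is.null(tr)) {
    t <- pick(time_col, 1L)
    v <- pick(value_col, 2L)
    if (!is.numeric(t) || !is.numeric(v)) {
      stop("time and value columns must be numeric", call. = FALSE)
    }
    dt <- diff(t)
    tr_est <- stats::median(dt)
    if (tr_est <= 0 || any(abs(dt - tr_est) > 0.01 * tr_est)) {
      stop("time column is not uniformly spaced (tolerance 1%)",
           call. = FALSE)
    }
    sampled_series(v, tr = tr_est, t0 = t[1])
  } else {
    v <- pick(value_col, 1L)
    if (!is.numeric(v)) stop("value column must be numeric", call. = FALSE)
    sampled_series(v, tr = tr, t0 = 0)
  }
}

#' Write a sampled series to CSV
#'
#' Two columns, `t_s` and `value`, one row per sample.
#'
#' @param series A [sampled_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  stopifnot(inherits(series, "sampled_series"))
  df <- data.frame(t_s = series_times(series), value = series$values)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
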