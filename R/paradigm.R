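#' Boxcar gas-challenge paradigms and analytical time windows
#'
#' A hypercapnia CVR experiment interleaves room-air ("baseline") periods
#' with CO2-enriched air in a boxcar breathing paradigm. Two built-in
#' experimental designs are provided:
#'
#' * **Design A** — 2 min room air, 3 min 6% CO2, 2 min room air,
#'   3 min 6% CO2, 2 min room air (720 s total, TR 1.55 s).
#' * **Design B** — 45 s rest, 45 s CO2, 90 s rest, 120 s CO2,
#'   180 s rest (480 s total, TR 2.0 s; computer-controlled targeting of a
#'   10 mmHg end-tidal CO2 step).
#'
#' Analysis operates on fixed per-design time windows that isolate the
#' physiologically distinct phases: the two dilation (CVR) windows covering
#' the responses to the first and second CO2 administration, and the two
#' hypercapnia-to-normocapnia transition windows covering the signal
#' recovery (the first half of each rest period). All window times are on
#' the post-discard axis, i.e. time 0 is the first retained BOLD volume
#' after dropping the initial equilibration volumes.
#'
#' @name paradigm
NULL

#' Construct a block paradigm
#'
#' @param states Character vector of gas states, each `"room_air"` or
#'   `"co2"`.
#' @param durations_s Numeric vector of block durations in seconds, same
#'   length as `states`; all strictly positive.
#' @param tr Repetition time (sampling interval of the BOLD acquisition) in
#'   seconds.
#' @param design_label Optional design label (`"A"`, `"B"`, or `NA` for a
#'   custom paradigm).
#'
#' @return An object of class `block_paradigm` with elements `blocks`
#'   (data.frame of `state`, `duration_s`, `onset_s`), `tr`, `design_label`
#'   and `total_s`.
#' @export
block_paradigm <- function(states, durations_s, tr, design_label = NA_character_) {
  states <- as.character(states)
  if (!all(states %in% c("room_air", "co2"))) {
    stop("gas states must be 'room_air' or 'co2'", call. = FALSE)
  }
  durations_s <- as.numeric(durations_s)
  if (length(durations_s) != length(states) || length(states) == 0L) {
    stop("`states` and `durations_s` must be non-empty and the same length",
         call. = FALSE)
  }
  if (any(!is.finite(durations_s)) || any(durations_s <= 0)) {
    stop("block durations must be strictly positive", call. = FALSE)
  }
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0) {
    stop("`tr` must be a single positive number (seconds)", call. = FALSE)
  }
  blocks <- data.frame(state = states, duration_s = durations_s,
                       onset_s = cumsum(c(0, durations_s[-length(durations_s)])))
  structure(list(blocks = blocks, tr = tr,
                 design_label = design_label,
                 total_s = sum(durations_s)),
            class = "block_paradigm")
}

#' Built-in experimental designs
#'
#' @param design_label `"A"` or `"B"`.
#' @return A [block_paradigm()] with the design's block schedule and TR.
#' @examples
#' design_paradigm("A")$total_s  # 720
#' @export
design_paradigm <- function(design_label) {
  switch(match_design(design_label),
    A = block_paradigm(
      states = c("room_air", "co2", "room_air", "co2", "room_air"),
      durations_s = c(120, 180, 120, 180, 120),
      tr = 1.55, design_label = "A"),
    B = block_paradigm(
      states = c("room_air", "co2", "room_air", "co2", "room_air"),
      durations_s = c(45, 45, 90, 120, 180),
      tr = 2.0, design_label = "B"))
}

match_design <- function(design_label) {
  if (length(design_label) != 1L || !design_label %in% c("A", "B")) {
    stop("unknown design label '", paste(design_label, collapse = ","),
         "'; valid labels are 'A' and 'B'", call. = FALSE)
  }
  design_label
}

#' Number of volumes conventionally discarded for a design
#'
#' Initial BOLD volumes are dropped to allow the signal to reach
#' equilibrium: 25 volumes for Design A acquisitions, 5 for Design B.
#'
#' @param design_label `"A"` or `"B"`.
#' @return Integer count of volumes.
#' @export
default_discard_volumes <- function(design_label) {
  switch(match_design(design_label), A = 25L, B = 5L)
}

#' Closed-open time window
#'
#' @param start_s,end_s Window bounds in seconds on the post-discard axis;
#'   samples at times `start_s <= t < end_s` belong to the window.
#' @return An object of class `time_window`.
#' @export
time_window <- function(start_s, end_s) {
  if (!is.finite(start_s) || !is.finite(end_s) || start_s < 0 ||
      end_s <= start_s) {
    stop("need end_s > start_s >= 0", call. = FALSE)
  }
  structure(list(start_s = as.numeric(start_s), end_s = as.numeric(end_s)),
            class = "time_window")
}

#' @export
print.time_window <- function(x, ...) {
  cat(sprintf("[%g, %g) s\n", x$start_s, x$end_s)); invisible(x)
}

#' Analytical time windows for a design
#'
#' Returns the fixed per-design windows that isolate each phase of the
#' two-challenge paradigm: `cvr1`/`cvr2` (dilation windows, response to the
#' first/second CO2 administration), `transition1`/`transition2`
#' (hypercapnia-to-normocapnia recovery, the first half of the following
#' rest period), and `baseline1`/`baseline2` (late-rest reference windows
#' used for the mean baseline BOLD signal, by default the `baseline_s`
#' seconds immediately preceding each dilation window, truncated at 0).
#'
#' All windows are closed-open intervals on the post-discard time axis.
#'
#' @param design_label `"A"` or `"B"`.
#' @param baseline_s Length of the baseline windows in seconds (default 30).
#' @return An object of class `analysis_windows`: a named list of
#'   [time_window()]s with elements `cvr1`, `cvr2`, `transition1`,
#'   `transition2`, `baseline1`, `baseline2`, plus the `design_label`.
#' @examples
#' w <- windows_for_design("A")
#' w$cvr1        # [40, 280) s
#' w$transition1 # [280, 360) s
#' @export
windows_for_design <- function(design_label, baseline_s = 30) {
  design_label <- match_design(design_label)
  stopifnot(is.numeric(baseline_s), baseline_s > 0)
  win <- switch(design_label,
    A = list(cvr1 = c(40, 280), cvr2 = c(360, 580),
             transition1 = c(280, 360), transition2 = c(580, 660)),
    B = list(cvr1 = c(10, 80), cvr2 = c(135, 280),
             transition1 = c(80, 135), transition2 = c(280, 390)))
  b1 <- c(max(0, win$cvr1[1] - baseline_s), win$cvr1[1])
  b2 <- c(max(0, win$cvr2[1] - baseline_s), win$cvr2[1])
  out <- list(
    cvr1 = time_window(win$cvr1[1], win$cvr1[2]),
    cvr2 = time_window(win$cvr2[1], win$cvr2[2]),
    transition1 = time_window(win$transition1[1], win$transition1[2]),
    transition2 = time_window(win$transition2[1], win$transition2[2]),
    baseline1 = time_window(b1[1], b1[2]),
    baseline2 = time_window(b2[1], b2[2]),
    design_label = design_label)
  class(out) <- "analysis_windows"
  out
}

#' @export
print.analysis_windows <- function(x, ...) {
  cat(sprintf("<analysis_windows> design %s\n", x$design_label))
  for (nm in c("baseline1", "cvr1", "transition1",
               "baseline2", "cvr2", "transition2")) {
    cat(sprintf("  %-12s [%g, %g) s\n", nm, x[[nm]]$start_s, x[[nm]]$end_s))
  }
  invisible(x)
}

#' Boxcar regressor for a paradigm
#'
#' Samples the paradigm's gas state on the BOLD sampling grid: value 1
#' during CO2 blocks, 0 during room air. The series is expressed on the
#' post-discard axis, i.e. sample `k` at time `k * tr` corresponds to
#' paradigm time `k * tr + discard_s`.
#'
#' @param paradigm A [block_paradigm()].
#' @param n_samples Number of retained BOLD volumes (must be positive).
#' @param discard_s Duration in seconds removed from the start of the
#'   paradigm clock (discarded volumes times TR).
#' @return A [sampled_series()] of 0/1 values at spacing `tr`, `t0 = 0`.
#' @examples
#' b <- build_boxcar(design_paradigm("A"), n_samples = 453,
#'                   discard_s = 25 * 1.55)
#' @export
build_boxcar <- function(paradigm, n_samples, discard_s = 0) {
  stopifnot(inherits(paradigm, "block_paradigm"))
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 1) {
    stop("`n_samples` must be a positive count", call. = FALSE)
  }
  if (!is.numeric(discard_s) || discard_s < 0) {
    stop("`discard_s` must be non-negative", call. = FALSE)
  }
  if (discard_s >= paradigm$total_s) {
    stop(sprintf("discard (%g s) consumes the whole paradigm (%g s)",
                 discard_s, paradigm$total_s), call. = FALSE)
  }
  t_paradigm <- (seq_len(n_samples) - 1) * paradigm$tr + discard_s
  ends <- cumsum(paradigm$blocks$duration_s)
  idx <- findInterval(t_paradigm, c(0, ends), rightmost.closed = FALSE)
  idx <- pmin(idx, nrow(paradigm$blocks))  # samples past the paradigm end
  on <- as.numeric(paradigm$blocks$state[idx] == "co2" &
                     t_paradigm < paradigm$total_s)
  sampled_series(on, tr = paradigm$tr, t0 = 0)
}

#' Extract the samples of a series falling in a time window
#'
#' Keeps samples whose times satisfy `start_s <= t < end_s`. If the window
#' extends past the sampled span the overlap is used and a warning is
#' emitted; an empty overlap is an error.
#'
#' @param series A [sampled_series()].
#' @param window A [time_window()].
#' @return A [sampled_series()] whose `t0` is the time of the first retained
#'   sample, with attribute `"n_retained"` recording the sample count.
#' @export
slice_window <- function(series, window) {
  stopifnot(inherits(series, "sampled_series"), inherits(window, "time_window"))
  t <- series_times(series)
  keep <- which(t >= window$start_s & t < window$end_s)
  if (length(keep) == 0L) {
    stop(sprintf("window [%g, %g) s does not overlap the series span [%g, %g) s",
                 window$start_s, window$end_s, t[1],
                 t[length(t)] + series$tr), call. = FALSE)
  }
  span_end <- t[length(t)] + series$tr
  if (window$start_s < series$t0 || window$end_s > span_end) {
    warning(sprintf(
      "window [%g, %g) s truncated to the sampled span [%g, %g) s",
      window$start_s, window$end_s, series$t0, span_end), call. = FALSE)
  }
  out <- sampled_series(series$values[keep], tr = series$tr, t0 = t[keep[1]])
  attr(out, "n_retained") <- length(keep)
  out
}

#' Read a paradigm description from a YAML or JSON config file
#'
#' The config either names a built-in preset (`preset: designA` or
#' `designB`) or lists the blocks explicitly:
#' ```yaml
#' tr_s: 1.55
#' discard_volumes: 25
#' design: A
#' blocks:
#'   - {state: room_air, duration_s: 120}
#'   - {state: co2, duration_s: 180}
#' ```
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return A list with elements `paradigm` (a [block_paradigm()]) and
#'   `discard_volumes`.
#' @export
paradigm_from_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(cfg$preset)) {
    label <- toupper(sub("^design", "", cfg$preset, ignore.case = TRUE))
    par <- design_paradigm(label)
    discard <- if (is.null(cfg$discard_volumes))
      default_discard_volumes(label) else as.integer(cfg$discard_volumes)
    return(list(paradigm = par, discard_volumes = discard))
  }
  if (is.null(cfg$blocks) || is.null(cfg$tr_s)) {
    stop("config needs either `preset` or both `blocks` and `tr_s`",
         call. = FALSE)
  }
  blocks <- cfg$blocks
  if (is.data.frame(blocks)) {
    states <- blocks$state; durs <- blocks$duration_s
  } else {
    states <- vapply(blocks, function(b) b$state, character(1))
    durs <- vapply(blocks, function(b) as.numeric(b$duration_s), numeric(1))
  }
  par <- block_paradigm(states, durs, tr = as.numeric(cfg$tr_s),
                        design_label = if (is.null(cfg$design))
                          NA_character_ else as.character(cfg$design))
  discard <- if (is.null(cfg$discard_volumes)) 0L
             else as.integer(cfg$discard_volumes)
  list(paradigm = par, discard_volumes = discard)
}
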