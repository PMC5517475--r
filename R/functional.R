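#' Resting baseline of a fluorescence trace
#'
#' Mean fluorescence (or reconstructed strength) over the resting window.
#'
#' @param F_trace Numeric fluorescence series.
#' @param t Frame times, s (same length).
#' @param rest_window `c(start, end)` in seconds; must be non-empty and is
#'   expected to precede the stimulus.
#' @return Baseline `F0` (> 0).
#' @examples
#' compute_f0(rep(100, 10), t = 0:9, rest_window = c(0, 5))   # 100
#' @export
compute_f0 <- function(F_trace, t, rest_window) {
  idx <- t >= rest_window[1] & t <= rest_window[2]
  if (!any(idx)) stop("rest window contains no frames", call. = FALSE)
  F0 <- mean(F_trace[idx])
  if (!is.finite(F0) || F0 <= 0) {
    stop("baseline F0 <= 0: trace unusable for dF/F0", call. = FALSE)
  }
  F0
}

#' Fractional fluorescence change
#'
#' \eqn{\Delta F/F_0 = (F - F_0)/F_0}, elementwise.  Negative values are
#' meaningful (suppressed activity).
#'
#' @param F_trace Numeric fluorescence series.
#' @param F0 Baseline (> 0).
#' @return \eqn{\Delta F/F_0} series.
#' @examples
#' delta_f_over_f(c(150, 80, 100), 100)   # 0.5 -0.2 0
#' @export
delta_f_over_f <- function(F_trace, F0) {
  if (F0 <= 0) stop("`F0` must be > 0", call. = FALSE)
  (F_trace - F0) / F0
}

# default resting window: recording start to 0.5 s before the stimulus
default_rest_window <- function(stim_onset, guard = 0.5) {
  c(0, max(stim_onset - guard, 0))
}

#' Per-ROI fluorescence traces from an acquired movie
#'
#' Averages the reconstructed strength movie over each ROI's member pixels
#' (the generator's ground-truth ROI map; no segmentation), computes the
#' resting baseline and \eqn{\Delta F/F_0}.  Because \eqn{\Delta F/F_0} is a
#' ratio, the unknown global scale of the reconstruction cancels exactly.
#'
#' @param movie A `movie_record` from [scan_movie()], or a numeric array
#'   `[row, col, frame]` of linear strength estimates.
#' @param roi_ids Integer ROI map (taken from the movie record if present).
#' @param t Frame times (taken from the movie record if present).
#' @param stim_onset Stimulus time, s (ditto).
#' @param rest_guard Gap between the end of the resting window and the
#'   stimulus, s.
#' @return Tibble with `roi_id`, `t`, `F`, `F0`, `dff`, and the windows as
#'   attributes `rest_window` / `stim_onset`.
#' @export
roi_traces <- function(movie, roi_ids = NULL, t = NULL, stim_onset = NULL,
                       rest_guard = 0.5) {
  if (inherits(movie, "movie_record")) {
    if (is.null(roi_ids)) roi_ids <- movie$roi_ids
    if (is.null(t)) t <- movie$t
    if (is.null(stim_onset)) stim_onset <- movie$stim_onset
    X <- movie$X_rel
  } else {
    X <- movie
  }
  stopifnot(is.array(X), length(dim(X)) == 3, !is.null(roi_ids),
            !is.null(t), !is.null(stim_onset))
  rest <- default_rest_window(stim_onset, rest_guard)
  ids <- sort(unique(roi_ids[roi_ids > 0]))
  purrr::map_dfr(ids, function(k) {
    m <- roi_ids == k
    F_tr <- apply(X, 3, function(fr) mean(fr[m]))
    f0 <- compute_f0(F_tr, t, rest)
    dff <- delta_f_over_f(F_tr, f0)
    tibble::tibble(roi_id = k, t = t, F = F_tr, F0 = f0, dff = dff)
  }) |>
    structure(rest_window = rest, stim_onset = stim_onset)
}

#' Pixelwise activity map
#'
#' Mean \eqn{\Delta F/F_0} per pixel over the response window (default: the
#' 5 s following stimulus onset).  Pixels whose resting baseline is not
#' positive are masked `NA`.
#'
#' @param movie A `movie_record` or strength array `[row, col, frame]`.
#' @param stim_onset Stimulus time, s.
#' @param window_s Response-window length after `stim_onset`, s.
#' @param t Frame times (taken from the movie record if present).
#' @param rest_guard Gap before the stimulus excluded from the baseline, s.
#' @return Matrix of mean \eqn{\Delta F/F_0}, class `activity_map`.
#' @export
activity_map <- function(movie, stim_onset = NULL, window_s = 5, t = NULL,
                         rest_guard = 0.5) {
  if (inherits(movie, "movie_record")) {
    if (is.null(t)) t <- movie$t
    if (is.null(stim_onset)) stim_onset <- movie$stim_onset
    X <- movie$X_rel
  } else {
    X <- movie
  }
  stopifnot(is.array(X), length(dim(X)) == 3, !is.null(t),
            !is.null(stim_onset))
  if (stim_onset + window_s > max(t) + 1e-9) {
    stop("response window extends past the recording", call. = FALSE)
  }
  rest <- default_rest_window(stim_onset, rest_guard)
  ridx <- t >= rest[1] & t <= rest[2]
  widx <- t >= stim_onset & t <= stim_onset + window_s
  F0 <- apply(X[, , ridx, drop = FALSE], c(1, 2), mean)
  Fw <- apply(X[, , widx, drop = FALSE], c(1, 2), mean)
  out <- (Fw - F0) / F0
  out[!is.finite(out) | F0 <= 0] <- NA_real_
  structure(out, class = c("activity_map", "matrix"))
}

#' Pixels clipped at any time during an image sequence
#'
#' @param movie A `movie_record`, or a logical clip array, or an integer
#'   `S_hat` array (clipping judged against `cfg`).
#' @param cfg Needed only when `movie` is a raw code array.
#' @return Logical matrix: `TRUE` where the pixel reached the maximum code in
#'   at least one frame.
#' @export
clip_mask <- function(movie, cfg = NULL) {
  arr <- if (inherits(movie, "movie_record")) {
    movie$clip
  } else if (is.logical(movie)) {
    movie
  } else {
    if (is.null(cfg)) stop("`cfg` required for a raw code array", call. = FALSE)
    movie >= cfg$S_max_code
  }
  if (length(dim(arr)) == 3) apply(arr, c(1, 2), any) else arr
}

#' Response statistics per ROI
#'
#' For each ROI: the peak \eqn{\Delta F/F_0} in the response window, taken as
#' the signed extremum of largest magnitude so suppressed cells get negative
#' peaks; the resting noise (SD of \eqn{\Delta F/F_0} in the resting window);
#' and the response SNR, peak \eqn{\Delta F/F_0} divided by the resting SD.
#'
#' @param traces Tibble from [roi_traces()].
#' @param response_window `c(start, end)` in s; default stimulus onset plus
#'   5 s.
#' @param rest_window `c(start, end)` in s; default as in [roi_traces()].
#' @return Tibble with one row per ROI: `roi_id`, `peak_dff`, `rest_sd`,
#'   `snr`, `sign` (`"increase"`/`"decrease"`), and `snr_infinite` flagging
#'   zero resting noise.
#' @examples
#' # peak 0.5 over rest SD 0.05 gives SNR 10
#' @export
response_stats <- function(traces, response_window = NULL,
                           rest_window = NULL) {
  stim <- attr(traces, "stim_onset")
  if (is.null(response_window)) {
    if (is.null(stim)) stop("supply `response_window`", call. = FALSE)
    response_window <- c(stim, stim + 5)
  }
  if (is.null(rest_window)) {
    rest_window <- attr(traces, "rest_window")
    if (is.null(rest_window)) stop("supply `rest_window`", call. = FALSE)
  }
  traces |>
    dplyr::group_by(.data$roi_id) |>
    dplyr::summarise(
      peak_dff = {
        w <- .data$dff[.data$t >= response_window[1] &
                         .data$t <= response_window[2]]
        w[which.max(abs(w))]
      },
      rest_sd = stats::sd(.data$dff[.data$t >= rest_window[1] &
                                      .data$t <= rest_window[2]]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      snr_infinite = .data$rest_sd == 0,
      snr = ifelse(.data$snr_infinite, Inf, .data$peak_dff / .data$rest_sd),
      sign = ifelse(.data$peak_dff >= 0, "increase", "decrease")
    )
}

#' Cohort summary of response statistics
#'
#' @param stats Tibble from [response_stats()].
#' @return One-row tibble: number of ROIs, median resting SD, median |SNR|,
#'   and counts of increasing / decreasing responses.
#' @export
cohort_summary <- function(stats) {
  tibble::tibble(
    n_roi = nrow(stats),
    median_rest_sd = stats::median(stats$rest_sd),
    median_abs_snr = stats::median(abs(stats$snr[is.finite(stats$snr)])),
    n_increase = sum(stats$sign == "increase"),
    n_decrease = sum(stats$sign == "decrease")
  )
}
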