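#' Post-hoc linear reconstruction of sample strength
#'
#' Inverts the log encoding with the simple relation
#' \eqn{X \propto 2^{\hat{\hat L}_X / (G_L G_M)}}.  Constant offsets (the
#' additive constant `C` and the power-code normalization) contribute only a
#' global scale factor, which is deliberately carried as metadata rather than
#' silently normalized away: ratios between pixels — and therefore
#' \eqn{\Delta F/F_0} — are exact, absolute emissivity is not claimed.
#'
#' @param L_dd Re-digitized log map (integer codes or any nonnegative
#'   values).
#' @param G_L Log scale gain (> 0).
#' @param G_M Re-digitization gain (> 0).
#' @return A `recon_image`: `X` (relative linear strength), `log2X`
#'   (`X = 2^log2X` exactly), and `scale_note` flagging the unknown global
#'   factor.
#' @examples
#' reconstruct_linear(0, 630.15, 0.12)$X   # 1 (relative)
#' @export
reconstruct_linear <- function(L_dd, G_L, G_M) {
  if (G_L <= 0 || G_M <= 0) stop("gains must be > 0", call. = FALSE)
  log2X <- L_dd / (G_L * G_M)
  structure(
    list(X = 2^log2X, log2X = log2X,
         scale_note = "values proportional to sample strength (unknown global factor)"),
    class = "recon_image"
  )
}

#' Reconstruct a scanned AI frame
#'
#' Convenience wrapper: encode (if needed) and linearize a frame in one step.
#'
#' @param frame A `frame_record` (AI) or `encoded_frame`.
#' @param cfg An [acquisition_config()].
#' @return A `recon_image`.
#' @export
reconstruct_frame <- function(frame, cfg) {
  enc <- if (inherits(frame, "encoded_frame")) frame else encode_frame(frame, cfg)
  reconstruct_linear(enc$L_dd, cfg$G_L, enc$G_M_used)
}

#' @export
print.recon_image <- function(x, ...) {
  cat(sprintf("<recon_image> %s, log2 range [%.2f, %.2f] (%s)\n",
              paste(dim(as.matrix(x$X)), collapse = " x "),
              min(x$log2X), max(x$log2X), x$scale_note))
  invisible(x)
}

#' Occupied dynamic range of an image, in bits
#'
#' Histograms the log2 of the positive values in 0.5-bit bins and reports the
#' span between the lowest and highest bin holding at least `min_count`
#' pixels.  The count threshold (default 10) suppresses single-pixel noise
#' tails, making the reading the operational equivalent of judging the span
#' of a log histogram by eye.
#'
#' @param image A matrix of linear values, a `recon_image`, or — with
#'   `log_domain = TRUE` — a matrix already in log2 units.
#' @param min_count Minimum pixels for a bin to count as occupied.
#' @param bin_width Histogram bin width in bits.
#' @param log_domain Set `TRUE` if `image` is already log2-encoded.
#' @return Span in bits (>= 0; 0 when all occupied values fall in one bin).
#' @examples
#' occupied_bits(matrix(c(rep(1, 50), rep(2^20, 50)), 10), min_count = 10)
#' @export
occupied_bits <- function(image, min_count = 10, bin_width = 0.5,
                          log_domain = FALSE) {
  v <- if (inherits(image, "recon_image")) image$log2X else image
  v <- as.vector(v)
  if (!log_domain && !inherits(image, "recon_image")) {
    v <- v[is.finite(v) & v > 0]
    if (length(v) == 0) stop("image has no positive values", call. = FALSE)
    v <- log2(v)
  } else {
    v <- v[is.finite(v)]
    if (length(v) == 0) stop("image has no finite values", call. = FALSE)
  }
  lo <- floor(min(v) / bin_width) * bin_width
  hi <- ceiling(max(v) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  counts <- graphics::hist(v, breaks = breaks, plot = FALSE)$counts
  centers <- breaks[-length(breaks)] + bin_width / 2
  occ <- which(counts >= min_count)
  if (length(occ) == 0) return(0)
  centers[max(occ)] - centers[min(occ)]
}

#' Compare AI and conventional linear histograms
#'
#' Checks the consistency claim that fluorescence levels acquired with and
#' without active illumination agree over the strengths both can see: the AI
#' reconstruction (known only up to a global factor) is scaled onto the
#' conventional image by the median per-pixel ratio over valid pixels, then
#' both are histogrammed in log-spaced bins over the overlap range —
#' conventional pixels that are clipped or below a noise floor are excluded —
#' and per-bin relative deviations are reported.
#'
#' @param ai_image `recon_image` or matrix of relative linear AI strengths.
#' @param conventional_image Matrix of linear conventional strengths
#'   (same scene, co-registered).
#' @param conventional_clip Optional logical matrix of clipped pixels to
#'   exclude.
#' @param noise_floor Conventional values at or below this are considered
#'   noise-dominated and excluded.
#' @param n_bins Number of log-spaced bins over the overlap range.
#' @return A `hist_comparison`: tibble of bins with counts and relative
#'   deviation, the overlap range, the scale factor used, the mean relative
#'   deviation over occupied bins, and a `no_overlap` flag.
#' @export
compare_histograms <- function(ai_image, conventional_image,
                               conventional_clip = NULL, noise_floor = 0,
                               n_bins = 32) {
  ai <- if (inherits(ai_image, "recon_image")) ai_image$X else ai_image
  conv <- conventional_image
  stopifnot(all(dim(ai) == dim(conv)))
  valid <- is.finite(conv) & conv > noise_floor & is.finite(ai) & ai > 0
  if (!is.null(conventional_clip)) valid <- valid & !conventional_clip
  if (!any(valid)) {
    return(structure(
      list(bins = tibble::tibble(), overlap = c(NA_real_, NA_real_),
           scale = NA_real_, mean_rel_dev = NA_real_, no_overlap = TRUE),
      class = "hist_comparison"
    ))
  }
  scale <- stats::median(conv[valid] / ai[valid])
  ai_s <- ai * scale
  lo <- max(min(conv[valid]), min(ai_s[valid]))
  hi <- min(max(conv[valid]), max(ai_s[valid]))
  if (!(hi > lo)) {
    return(structure(
      list(bins = tibble::tibble(), overlap = c(lo, hi), scale = scale,
           mean_rel_dev = NA_real_, no_overlap = TRUE),
      class = "hist_comparison"
    ))
  }
  breaks <- 2^seq(log2(lo), log2(hi), length.out = n_bins + 1)
  cut_counts <- function(x) {
    x <- x[x >= lo & x <= hi]
    graphics::hist(x, breaks = breaks, plot = FALSE)$counts
  }
  n_ai <- cut_counts(ai_s[valid])
  n_conv <- cut_counts(conv[valid])
  rel_dev <- ifelse(pmax(n_ai, n_conv) > 0,
                    abs(n_ai - n_conv) / pmax(n_ai, n_conv), 0)
  bins <- tibble::tibble(
    lower = breaks[-length(breaks)], upper = breaks[-1],
    n_ai = n_ai, n_conventional = n_conv, rel_dev = rel_dev
  )
  occupied <- n_ai + n_conv > 0
  structure(
    list(bins = bins, overlap = c(lo, hi), scale = scale,
         mean_rel_dev = mean(rel_dev[occupied]), no_overlap = FALSE),
    class = "hist_comparison"
  )
}

#' @export
print.hist_comparison <- function(x, ...) {
  if (isTRUE(x$no_overlap)) {
    cat("<hist_comparison> no overlap between the two images\n")
  } else {
    cat(sprintf(
      "<hist_comparison> overlap [%.3g, %.3g], scale %.3g, mean relative deviation %.3f\n",
      x$overlap[1], x$overlap[2], x$scale, x$mean_rel_dev))
  }
  invisible(x)
}
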