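#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

raster_df <- function(m, value = "value") {
  tibble::tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    !!value := as.vector(m)
  )
}

#' Plot a synthetic scene on a log brightness scale
#'
#' @param object A `scene_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot scene_map
#' @export
autoplot.scene_map <- function(object, ...) {
  df <- raster_df(object$strength, "strength")
  df$log2X <- ifelse(df$strength > 0, log2(df$strength), NA)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$log2X)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "black",
                                  name = expression(log[2] ~ X)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "Synthetic scene (log scale)",
                  x = NULL, y = NULL)
}

#' Plot a reconstructed image on its log2 scale
#'
#' @param object A `recon_image`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot recon_image
#' @export
autoplot.recon_image <- function(object, ...) {
  df <- raster_df(as.matrix(object$log2X), "log2X")
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$log2X)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = expression(log[2] ~ hat(X))) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "Reconstructed sample strength (relative)",
                  x = NULL, y = NULL)
}

#' Plot SNR versus sample strength
#'
#' Log-log traces for conventional acquisition and the two AI branches, with
#' vertical guides at the landmark strengths.
#'
#' @param object An [snr_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot snr_curve
#' @export
autoplot.snr_curve <- function(object, ...) {
  lm <- attr(object, "landmarks")
  long <- tidy(object)
  marks <- tibble::tibble(
    X = c(lm$X_sat, lm$X_t, lm$X_r),
    label = c("X[sat]", "X[t]", "X[r]")
  )
  marks <- marks[is.finite(marks$X), ]
  ggplot2::ggplot(long, ggplot2::aes(.data$X, .data$snr,
                                     colour = .data$trace,
                                     linetype = .data$trace)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_vline(data = marks, ggplot2::aes(xintercept = .data$X),
                        linetype = "dotted", colour = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "sample strength X", y = "SNR",
                  title = "SNR versus sample strength")
}

#' Plot an activity map
#'
#' Diverging colour scale centred at zero so increases and decreases in
#' activity read symmetrically; `NA` (masked) pixels are black.
#'
#' @param object An [activity_map()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot activity_map
#' @export
autoplot.activity_map <- function(object, ...) {
  df <- raster_df(unclass(object), "dff")
  lim <- max(abs(df$dff), na.rm = TRUE)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$dff)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(limits = c(-lim, lim), na.value = "black",
                                  name = expression(Delta * F / F[0])) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "Mean ΔF/F0 over the response window",
                  x = NULL, y = NULL)
}

#' Cumulative response-SNR histogram
#'
#' The standard cohort comparison: empirical CDFs of |response SNR| for one
#' or more acquisitions; a rightward shift means higher-SNR responses.
#'
#' @param ... Named tibbles from [response_stats()], e.g.
#'   `plot_snr_cdf(ai = stats_ai, conventional = stats_conv)`.
#' @return A ggplot.
#' @export
plot_snr_cdf <- function(...) {
  groups <- list(...)
  stopifnot(length(groups) >= 1, !is.null(names(groups)))
  df <- purrr::imap_dfr(groups, function(s, nm) {
    tibble::tibble(acquisition = nm, snr = abs(s$snr[is.finite(s$snr)]))
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$snr, colour = .data$acquisition)) +
    ggplot2::stat_ecdf() +
    ggplot2::labs(x = "|response SNR|", y = "cumulative fraction of ROIs",
                  title = "Cumulative response-SNR histogram")
}
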