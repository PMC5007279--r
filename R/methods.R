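#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-slice fits of a segmentation result
#'
#' @param x a `segmentation_result`.
#' @param ... unused.
#' @return The per-slice fit tibble (slice, segment, canal and cord
#'   parameters, votes, status).
#' @method tidy segmentation_result
#' @export
tidy.segmentation_result <- function(x, ...) x$fits

#' One-row summary of a segmentation result
#'
#' @param x a `segmentation_result`.
#' @param ... unused.
#' @return Tibble: slice counts, fit success rate, per-segment volumes.
#' @method glance segmentation_result
#' @export
glance.segmentation_result <- function(x, ...) {
  v <- x$volumes
  tibble::tibble(
    n_slices = nrow(x$fits),
    n_fitted = sum(x$fits$status == "ok"),
    fit_rate = mean(x$fits$status == "ok"),
    cervical_canal_ml = v$canal_volume_ml[v$segment == "cervical"],
    cervical_cord_ml = v$cord_volume_ml[v$segment == "cervical"],
    dorsal_canal_ml = v$canal_volume_ml[v$segment == "dorsal"],
    dorsal_cord_ml = v$cord_volume_ml[v$segment == "dorsal"])
}

#' Tidy an uptake report
#'
#' @param x an `uptake_report`.
#' @param ... unused.
#' @return The per-segment NSUV/volume tibble.
#' @method tidy uptake_report
#' @export
tidy.uptake_report <- function(x, ...) x$table

#' One-row summary of an uptake report
#'
#' @param x an `uptake_report`.
#' @param ... unused.
#' @return Tibble with the liver SUV and whole-cord NSUV.
#' @method glance uptake_report
#' @export
glance.uptake_report <- function(x, ...) {
  tibble::tibble(subject_id = x$subject_id, liver_suv = x$liver_suv,
                 sc_nsuv = x$sc_nsuv,
                 cervical_nsuv = x$table$cord_nsuv[x$table$segment == "cervical"],
                 dorsal_nsuv = x$table$cord_nsuv[x$table$segment == "dorsal"])
}

#' Plot fitted curve parameters along the cord
#'
#' Line plot of the fitted canal (a, b) and cord semi-axes per slice,
#' colored by segment -- the quickest visual check of fit stability
#' along the cranio-caudal axis.
#'
#' @param object a `segmentation_result`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot segmentation_result
#' @export
autoplot.segmentation_result <- function(object, ...) {
  f <- object$fits[object$fits$status == "ok", ]
  long <- rbind(
    data.frame(slice = f$slice, segment = f$segment,
               parameter = "canal a", value = f$canal_a),
    data.frame(slice = f$slice, segment = f$segment,
               parameter = "canal b", value = f$canal_b),
    data.frame(slice = f$slice, segment = f$segment,
               parameter = "cord semi-axis a", value = f$cord_a),
    data.frame(slice = f$slice, segment = f$segment,
               parameter = "cord semi-axis b", value = f$cord_b))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$slice, y = .data$value,
                               color = .data$segment)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "axial slice (cranial to caudal)",
                  y = "working units") +
    ggplot2::theme_minimal()
}

#' Plot per-segment NSUVs of an uptake report
#'
#' @param object an `uptake_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot uptake_report
#' @export
autoplot.uptake_report <- function(object, ...) {
  tab <- object$table
  long <- rbind(
    data.frame(segment = tab$segment, region = "canal",
               nsuv = tab$canal_nsuv),
    data.frame(segment = tab$segment, region = "cord",
               nsuv = tab$cord_nsuv))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$segment, y = .data$nsuv,
                                     fill = .data$region)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = object$sc_nsuv, linetype = 2) +
    ggplot2::labs(y = "liver-normalized SUV",
                  caption = sprintf("dashed: whole-cord NSUV %.3f",
                                    object$sc_nsuv)) +
    ggplot2::theme_minimal()
}

#' Overlay fitted curves on a CT slice
#'
#' Raster of the slice with the fitted canal and cord boundaries, the
#' standard visual check of a single-slice fit.
#'
#' @param ct_slice HU matrix.
#' @param fit result of [segment_slice()].
#' @param frame_scale_px working-frame scale in pixels used for the fit.
#' @return A ggplot object.
#' @export
plot_slice_fit <- function(ct_slice, fit, frame_scale_px) {
  frame <- working_frame(fit$center, frame_scale_px)
  canal_px <- frame_to_pixel(frame, sample_curve(fit$canal, 360L))
  cord_px <- frame_to_pixel(frame, sample_curve(fit$cord, 360L))
  df <- data.frame(x = rep(seq_len(nrow(ct_slice)), times = ncol(ct_slice)),
                   y = rep(seq_len(ncol(ct_slice)), each = nrow(ct_slice)),
                   hu = as.vector(ct_slice))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$hu)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::annotate("path", x = canal_px[, 1], y = canal_px[, 2],
                      color = "dodgerblue") +
    ggplot2::annotate("path", x = cord_px[, 1], y = cord_px[, 2],
                      color = "green3") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
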