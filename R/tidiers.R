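#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy and glance methods for fitted objects
#'
#' `tidy()` returns the per-step/per-row records; `glance()` a one-row
#' summary.
#'
#' @param x Fitted object.
#' @param ... Unused.
#' @return A tibble.
#' @name echosynth-tidiers
NULL

#' @rdname echosynth-tidiers
#' @export
tidy.sdm_fit <- function(x, ...) x$history

#' @rdname echosynth-tidiers
#' @export
glance.sdm_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(steps = nrow(h),
                 simple_first100 = mean(head(h$simple_term, 100)),
                 simple_last100 = mean(tail(h$simple_term, 100)),
                 kl_last100 = mean(tail(h$kl_term, 100)),
                 kl_weight = x$loss_config$kl_weight)
}

#' @rdname echosynth-tidiers
#' @export
tidy.seg_fit <- function(x, ...) x$history

#' @rdname echosynth-tidiers
#' @export
glance.seg_fit <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$history),
                 best_epoch = x$best_epoch,
                 best_val_loss = min(x$history$val_loss),
                 train_manifest_hash = x$train_manifest_hash)
}

#' @rdname echosynth-tidiers
#' @export
tidy.dice_report <- function(x, ...) x$rows

#' @rdname echosynth-tidiers
#' @export
glance.dice_report <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary[, c("label_name", "mean_dice")],
                             names_from = "label_name",
                             values_from = "mean_dice")
  dplyr::mutate(wide, overall_mean = mean(x$summary$mean_dice),
                n_cases = length(unique(x$rows$case_id)))
}

#' @rdname echosynth-tidiers
#' @export
tidy.noise_schedule <- function(x, ...) tibble::as_tibble(unclass(x))

raster_df <- function(m) {
  tibble::tibble(row = rep(seq_len(nrow(m)), times = ncol(m)),
                 col = rep(seq_len(ncol(m)), each = nrow(m)),
                 value = as.vector(m))
}

#' Plot methods
#'
#' `autoplot()` for schedules (cumulative signal curve), training histories
#' (loss terms over steps/epochs), Dice reports (per-label score spread),
#' label maps and echo images (rasters).
#'
#' @param object Object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @name echosynth-plots
NULL

#' @rdname echosynth-plots
#' @export
autoplot.noise_schedule <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$alpha_bar)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "timestep t", y = expression(bar(alpha)[t]),
                  title = "Cumulative signal retention") +
    ggplot2::theme_minimal()
}

#' @rdname echosynth-plots
#' @export
autoplot.sdm_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("simple_term", "kl_term"),
                            names_to = "term", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$value,
                                   colour = .data$term)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "step", y = "loss term", title = "Diffusion training") +
    ggplot2::theme_minimal()
}

#' @rdname echosynth-plots
#' @export
autoplot.dice_report <- function(object, ...) {
  ggplot2::ggplot(object$rows, ggplot2::aes(x = .data$label_name, y = .data$dice)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Dice", title = "Per-label Dice scores") +
    ggplot2::theme_minimal()
}

#' @rdname echosynth-plots
#' @export
autoplot.label_map <- function(object, ...) {
  df <- raster_df(unclass(object))
  df$class <- factor(class_name_of(df$value), levels = names(echo_classes()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "Semantic label map") +
    ggplot2::theme_void()
}

#' @rdname echosynth-plots
#' @export
autoplot.echo_image <- function(object, ...) {
  df <- raster_df(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
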