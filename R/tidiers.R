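# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @export
tidy.cnn_fit <- function(x, ...) {
  x$log
}

#' @export
glance.cnn_fit <- function(x, ...) {
  tibble(epochs = nrow(x$log), best_epoch = x$best_epoch,
         final_train_loss = x$log$train_loss[nrow(x$log)],
         best_val_loss = if (all(is.na(x$log$val_loss))) NA_real_
                         else min(x$log$val_loss, na.rm = TRUE),
         dropout = x$config$dropout_rate, lr0 = x$schedule$lr0)
}

#' @export
tidy.lr_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble(term = c("(Intercept)", x$feature), estimate = s[, 1],
         std.error = s[, 2], statistic = s[, 3], p.value = s[, 4])
}

#' @export
glance.lr_fit <- function(x, ...) {
  s <- summary(x$model)
  tibble(r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
         sigma = s$sigma, nobs = length(x$fitted))
}

#' @export
tidy.eval_report <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.eval_report <- function(x, ...) {
  x %>% filter(.data$stratum %in% c("all", "cross-season")) %>%
    group_by(.data$trait) %>%
    summarise(best_model = .data$model[which.max(.data$r2)],
              best_r2 = max(.data$r2), .groups = "drop")
}

#' Predicted-vs-actual scatter with the 1:1 line
#'
#' @param object An `eval_report`.
#' @param models Optional subset of model labels to plot.
#' @param ... Unused.
#' @return A ggplot object, faceted by trait (columns) and model (rows),
#'   with the dashed identity line.
#' @export
autoplot.eval_report <- function(object, models = NULL, ...) {
  pred <- report_predictions(object)
  if (is.null(pred)) abort("Report carries no prediction pairs.")
  if (!is.null(models)) pred <- pred %>% filter(.data$model %in% models)
  ggplot2::ggplot(pred, ggplot2::aes(x = .data$actual, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(colour = if ("cultivar" %in% names(pred))
      .data$cultivar else NULL), alpha = 0.7, size = 1.2) +
    ggplot2::facet_grid(model ~ trait, scales = "free") +
    ggplot2::labs(x = "Actual", y = "Estimated", colour = "Cultivar") +
    ggplot2::theme_bw()
}

#' Training-loss curves of a fitted convolutional regressor
#'
#' @param object A `cnn_fit`.
#' @param ... Unused.
#' @return A ggplot object with train and validation loss per epoch (log
#'   scale).
#' @export
autoplot.cnn_fit <- function(object, ...) {
  d <- object$log %>%
    tidyr::pivot_longer(c("train_loss", "val_loss"), names_to = "set",
                        values_to = "loss") %>%
    filter(is.finite(.data$loss))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Epoch", y = "MSE (standardized targets)", colour = NULL) +
    ggplot2::theme_bw()
}

#' Show a rendered plant sample
#'
#' @param object A `plant_sample` from [render_plant()].
#' @param what `"rgb"`, `"depth"` or `"mask"`.
#' @param ... Unused.
#' @return A ggplot raster plot.
#' @export
autoplot.plant_sample <- function(object, what = c("rgb", "depth", "mask"), ...) {
  what <- match.arg(what)
  img <- switch(what,
    rgb = object$rgb,
    depth = {
      d <- object$depth
      n <- (d - min(d)) / max(diff(range(d)), 1)
      array(rep(n, 3), c(dim(d), 3))
    },
    mask = array(rep(as.numeric(object$mask), 3), c(dim(object$mask), 3))
  )
  rast <- grDevices::as.raster(img)
  ggplot2::ggplot() +
    ggplot2::annotation_raster(rast, 0, ncol(img), 0, -nrow(img)) +
    ggplot2::xlim(0, ncol(img)) + ggplot2::ylim(-nrow(img), 0) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::ggtitle(sprintf("%s (stage %d, %s)", object$cultivar,
                             object$stage, what))
}
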