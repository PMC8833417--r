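#' Plot a fitted detection function over the distance histogram
#'
#' @param object A `detection_fit`.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot: scaled distance histogram with one detection curve per
#'   covariate level (the curve for the baseline level when no covariates).
#' @method autoplot detection_fit
#' @export
autoplot.detection_fit <- function(object, bins = 15, ...) {
  obs <- object$data
  lev <- if (length(object$covariates) > 0) {
    distinct(as_tibble(obs)[, object$covariates, drop = FALSE])
  } else {
    tibble(.rows = 1)
  }
  xg <- seq(0, object$w, length.out = 200)
  curves <- purrr::map_dfr(seq_len(nrow(lev)), function(i) {
    sig <- fit_sigma(object, lev[i, , drop = FALSE])
    tibble(x = xg,
           g = g_eval(xg, sig, object$key, object$shape, object$w,
                      object$adjustment, object$orders, object$adj_coefs),
           level = if (ncol(lev) > 0)
             paste(unlist(lev[i, ]), collapse = "/") else "all")
  })
  ggplot2::ggplot() +
    ggplot2::geom_histogram(
      data = as_tibble(obs),
      ggplot2::aes(x = .data$distance_m, y = ggplot2::after_stat(.data$ncount)),
      bins = bins, fill = "grey80", color = "grey50") +
    ggplot2::geom_line(
      data = curves,
      ggplot2::aes(x = .data$x, y = .data$g, color = .data$level)) +
    ggplot2::labs(x = "perpendicular distance (m)",
                  y = "detection probability g(x)",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Quantile-quantile plot of a density surface model
#'
#' @param object A `dsm_fit`.
#' @param ... Unused.
#' @return A ggplot of sorted deviance residuals against standard normal
#'   quantiles.
#' @method autoplot dsm_fit
#' @export
autoplot.dsm_fit <- function(object, ...) {
  r <- sort(stats::residuals(object$gam, type = "deviance"))
  df <- tibble(theoretical = stats::qnorm(stats::ppoints(length(r))),
               residual = r)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$theoretical,
                                   y = .data$residual)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "grey60") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "theoretical quantiles", y = "deviance residuals",
                  title = paste("QQ,", object$family)) +
    ggplot2::theme_minimal()
}

#' Map predicted abundance (or any cell quantity)
#'
#' @param cells Prediction-cell tibble with `x`, `y`.
#' @param fill Column to map (default `abundance`).
#' @param mask_invalid Grey out cells with `valid == FALSE`.
#' @return A ggplot tile map.
#' @export
plot_prediction_map <- function(cells, fill = "abundance",
                                mask_invalid = TRUE) {
  p <- ggplot2::ggplot(as_tibble(cells),
                       ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data[[fill]])) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "easting (m)", y = "northing (m)") +
    ggplot2::theme_minimal()
  if (mask_invalid && "valid" %in% names(cells) && any(!cells$valid)) {
    p <- p + ggplot2::geom_tile(data = filter(as_tibble(cells), !.data$valid),
                                fill = "grey70")
  }
  p
}

#' Boxplots of predicted density along the climate x landscape gradient
#'
#' @param cells Prediction cells with `quadrant_id`, `abundance`, `valid`.
#' @param quadrant_classes Tibble with `quadrant_id`, `climate`, `landscape`.
#' @return A ggplot of per-class density distributions.
#' @export
plot_gradient <- function(cells, quadrant_classes) {
  df <- as_tibble(cells) %>%
    filter(.data$valid) %>%
    left_join(distinct(quadrant_classes, .data$quadrant_id, .data$climate,
                       .data$landscape), by = "quadrant_id") %>%
    filter(!is.na(.data$climate))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$climate),
                                   y = .data$abundance)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~landscape) +
    ggplot2::labs(x = "climate class (cool to warm)",
                  y = "predicted pellet groups per cell") +
    ggplot2::theme_minimal()
}
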