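#' Predict pellet-group abundance on a regular grid
#'
#' Evaluates the fitted density surface on prediction cells, returning the
#' expected abundance per cell `N = area * exp(eta)` and the standard error
#' of the linear predictor from the coefficient covariance.
#'
#' @param fit A `dsm_fit`.
#' @param grid_covariates Tibble of prediction cells with every retained
#'   model covariate (and optionally `x`, `y`, `cell_id`).
#' @param cell_area_m2 Cell area in square meters (default 1 km^2).
#' @return A tibble of prediction cells: `cell_id`, coordinates if supplied,
#'   covariates, `abundance`, `se_link`.
#' @export
predict_grid <- function(fit, grid_covariates, cell_area_m2 = 1e6) {
  nd <- as_tibble(grid_covariates)
  miss <- setdiff(fit$covariates, names(nd))
  if (length(miss) > 0) {
    abort(paste0("prediction grid lacks model covariate(s): ",
                 paste(miss, collapse = ", ")))
  }
  nd$area_m2 <- cell_area_m2
  pr <- predict(fit$gam, newdata = nd, type = "link", se.fit = TRUE)
  nd$abundance <- as.numeric(exp(pr$fit))
  nd$se_link <- as.numeric(pr$se.fit)
  if (!"cell_id" %in% names(nd)) {
    nd$cell_id <- sprintf("C%05d", seq_len(nrow(nd)))
  }
  select(nd, "cell_id", everything())
}

#' Combine detection-stage and model-stage CVs by the delta method
#'
#' Independent relative errors add in quadrature:
#' `cv_total = sqrt(cv_detection^2 + cv_gam^2)`.
#'
#' @param cv_detection,cv_gam Non-negative CVs (vectorized).
#' @return Combined CV(s).
#' @export
combine_cv <- function(cv_detection, cv_gam) {
  if (any(cv_detection < 0) || any(cv_gam < 0)) {
    abort("CVs must be non-negative.")
  }
  sqrt(cv_detection^2 + cv_gam^2)
}

#' Per-cell coefficient of variation of predicted abundance
#'
#' The model-stage CV of each cell is the delta-method CV of a lognormal
#' mean, which for small errors is the standard error of the linear
#' predictor; it is combined with the (spatially constant) detection-stage CV
#' in quadrature.
#'
#' @param fit A `dsm_fit`.
#' @param cells Prediction cells from [predict_grid()] (must carry
#'   `se_link`).
#' @param cv_detection Detection-function CV (scalar, default 0).
#' @return `cells` with appended `cv_gam` and `cv_total`.
#' @export
cell_cv <- function(fit, cells, cv_detection = 0) {
  if (!"se_link" %in% names(cells)) {
    abort("`cells` must come from predict_grid() (no `se_link` column).")
  }
  cells$cv_gam <- cells$se_link
  cells$cv_total <- combine_cv(cv_detection, cells$cv_gam)
  cells
}
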