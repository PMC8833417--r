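#' Tidy a detection-function fit
#'
#' @param x A `detection_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `std.error` (scale coefficients on the log-sigma scale, the hazard
#'   shape on its natural scale, adjustment coefficients as fitted).
#' @method tidy detection_fit
#' @export
tidy.detection_fit <- function(x, ...) {
  se <- if (all(is.finite(x$vcov))) sqrt(pmax(diag(x$vcov), 0)) else
    rep(NA_real_, x$npar)
  terms <- paste0("log_sigma:", names(x$beta))
  est <- unname(x$beta)
  if (x$key == "hazard_rate") {
    terms <- c(terms, "shape")
    est <- c(est, x$shape)
    # delta method from log(b - 1) to b
    i <- length(x$beta) + 1
    se[i] <- se[i] * (x$shape - 1)
  }
  if (length(x$adj_coefs) > 0) {
    terms <- c(terms, paste0("adj_", x$adjustment, "_", x$orders))
    est <- c(est, x$adj_coefs)
  }
  tibble(term = terms, estimate = est, std.error = se[seq_along(est)])
}

#' Glance at a detection-function fit
#'
#' @param x A `detection_fit`.
#' @param ... Unused.
#' @return One-row tibble: key, adjustment, covariates, n, parameters,
#'   log-likelihood, AIC, truncation distance, average detection
#'   probability and its CV, convergence flag.
#' @method glance detection_fit
#' @export
glance.detection_fit <- function(x, ...) {
  tibble(key = x$key, adjustment = x$adjustment,
         covariates = paste(x$covariates, collapse = "+"),
         n = x$n, npar = x$npar, logLik = x$loglik, AIC = x$aic,
         w = x$w, p_bar = x$p_bar %||% NA_real_,
         cv_p = x$cv_p %||% NA_real_, converged = isTRUE(x$converged))
}

#' Tidy a density surface model
#'
#' @param x A `dsm_fit`.
#' @param ... Unused.
#' @return Smooth-term table: `term`, `covariate`, `edf`, `ref_df`,
#'   `statistic`, `p_value`.
#' @method tidy dsm_fit
#' @export
tidy.dsm_fit <- function(x, ...) {
  smooth_table(x)
}

#' Glance at a density surface model
#'
#' @param x A `dsm_fit`.
#' @param ... Unused.
#' @return One-row tibble: family, dispersion (tweedie power or NB theta),
#'   n segments, AIC, log-likelihood, percent deviance explained, terms
#'   removed by backward selection.
#' @method glance dsm_fit
#' @export
glance.dsm_fit <- function(x, ...) {
  tibble(family = x$family, dispersion = x$dispersion,
         season = x$season %||% NA_character_,
         n = nrow(x$data), AIC = x$aic, logLik = x$loglik,
         deviance_expl = x$deviance_expl,
         n_smooths = length(x$covariates),
         removed = paste(x$removed, collapse = "+"))
}
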