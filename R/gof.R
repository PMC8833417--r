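# Fitted distance CDF F(x | z) per observation, via a fine cumulative
# trapezoid grid per unique scale (adequate well below CvM resolution).
det_cdf <- function(fit, x, newdata = fit$data, n_grid = 2001L) {
  sigma <- fit_sigma(fit, newdata)
  usig <- unique(sigma)
  xg <- seq(0, fit$w, length.out = n_grid)
  out <- numeric(length(x))
  for (s in usig) {
    gg <- g_eval(xg, s, fit$key, fit$shape, fit$w, fit$adjustment,
                 fit$orders, fit$adj_coefs)
    cs <- c(0, cumsum((gg[-1] + gg[-n_grid]) / 2 * diff(xg)))
    cs <- cs / cs[n_grid]
    sel <- sigma == s
    out[sel] <- stats::approx(xg, cs, xout = pmin(x[sel], fit$w),
                              rule = 2)$y
  }
  out
}

# Sample distances from the fitted model by CDF inversion, one per row of
# newdata.
det_rdist <- function(fit, newdata = fit$data, n_grid = 2001L) {
  sigma <- fit_sigma(fit, newdata)
  usig <- unique(sigma)
  xg <- seq(0, fit$w, length.out = n_grid)
  u <- runif(length(sigma))
  out <- numeric(length(sigma))
  for (s in usig) {
    gg <- g_eval(xg, s, fit$key, fit$shape, fit$w, fit$adjustment,
                 fit$orders, fit$adj_coefs)
    cs <- c(0, cumsum((gg[-1] + gg[-n_grid]) / 2 * diff(xg)))
    cs <- cs / cs[n_grid]
    sel <- sigma == s
    out[sel] <- stats::approx(cs, xg, xout = u[sel], ties = "ordered",
                              rule = 2)$y
  }
  out
}

# W^2 from probability-integral-transformed values u.
cvm_statistic <- function(u) {
  n <- length(u)
  u <- sort(u)
  1 / (12 * n) + sum((u - (2 * seq_len(n) - 1) / (2 * n))^2)
}

#' Cramér–von Mises goodness of fit for a detection function
#'
#' Transforms the observed distances through the fitted conditional CDF and
#' computes `W^2 = 1/(12n) + sum_i (u_(i) - (2i-1)/(2n))^2`. The p-value is
#' obtained by parametric bootstrap: distances are resampled from the fitted
#' model (keeping each observation's covariates), the model is refitted, and
#' the statistic recomputed under the null.
#'
#' @param fit A converged `detection_fit`.
#' @param obs Observations to test; defaults to the fitting data.
#' @param n_boot Number of bootstrap resamples (default 499; the p-value is
#'   `(1 + #\{W*^2 >= W^2\}) / (n_boot + 1)`).
#' @param seed Optional seed for the bootstrap.
#' @return One-row tibble `statistic` (W^2), `p_value`, `n`, `n_boot`.
#' @export
cvm_goodness_of_fit <- function(fit, obs = fit$data, n_boot = 499,
                                seed = NULL) {
  if (!isTRUE(fit$converged)) abort("fit has not converged.")
  if (!is.null(seed)) set.seed(as.integer(seed))
  u <- det_cdf(fit, obs$distance_m, obs)
  w2 <- cvm_statistic(u)
  n <- nrow(obs)
  if (n < 5) {
    warn("fewer than 5 observations; bootstrap p-value omitted.")
    return(tibble(statistic = w2, p_value = NA_real_, n = n, n_boot = 0L))
  }
  w2_boot <- vapply(seq_len(n_boot), function(b) {
    sim <- obs
    sim$distance_m <- det_rdist(fit, obs)
    ref <- tryCatch(
      fit_detection_function(sim, key = fit$key, adjustment = fit$adjustment,
                             orders = fit$orders, covariates = fit$covariates,
                             w = fit$w, start = fit$par),
      error = function(e) NULL)
    if (is.null(ref) || !isTRUE(ref$converged)) return(NA_real_)
    cvm_statistic(det_cdf(ref, sim$distance_m, sim))
  }, numeric(1))
  w2_boot <- w2_boot[is.finite(w2_boot)]
  p <- (1 + sum(w2_boot >= w2)) / (length(w2_boot) + 1)
  tibble(statistic = w2, p_value = p, n = n, n_boot = length(w2_boot))
}
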