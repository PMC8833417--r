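#' Truncate perpendicular distances
#'
#' Right-truncates an observation table at distance `w`, the standard first
#' step of a distance-sampling analysis (the field default of 1.5 m discards
#' roughly the farthest 5% of pellet-group detections).
#'
#' @param obs Observation tibble with a `distance_m` column.
#' @param w Truncation distance in meters (> 0).
#' @return The retained rows, with attributes `truncation_m`, `n_recorded`
#'   and `n_discarded`.
#' @export
truncate_distances <- function(obs, w = 1.5) {
  if (!is.numeric(w) || w <= 0) abort("`w` must be > 0.")
  if (nrow(obs) == 0) {
    warn("empty observation table; nothing to truncate.")
    out <- obs
  } else {
    out <- filter(obs, .data$distance_m <= w)
  }
  attr(out, "truncation_m") <- w
  attr(out, "n_recorded") <- nrow(obs)
  attr(out, "n_discarded") <- nrow(obs) - nrow(out)
  out
}

#' Post-stratify observers into detection groups
#'
#' Individual observers rarely have enough detections to support their own
#' detection function, so they are pooled: observers are ordered by
#' descending survey effort and greedily accumulated into groups until each
#' group holds at least `min_detections` detections; a trailing group below
#' the minimum is merged into its predecessor. The grouping is deterministic
#' given the effort table.
#'
#' @param obs Observation tibble with an `observer` column.
#' @param effort_per_observer Named numeric vector (or tibble with columns
#'   `observer`, `effort_m`) of total transect effort per observer.
#' @param min_detections Minimum detections per group (default 70).
#' @return `obs` with an `observer_group` column (`"G1"`, `"G2"`, ...).
#' @export
assign_observer_groups <- function(obs, effort_per_observer,
                                   min_detections = 70) {
  if (is.data.frame(effort_per_observer)) {
    eff <- setNames(effort_per_observer$effort_m,
                    effort_per_observer$observer)
  } else {
    eff <- effort_per_observer
  }
  missing_eff <- setdiff(unique(obs$observer), names(eff))
  if (length(missing_eff) > 0) {
    abort(paste0("no effort given for observer(s): ",
                 paste(missing_eff, collapse = ", ")))
  }
  ord <- names(sort(eff, decreasing = TRUE))
  dets <- table(factor(obs$observer, levels = ord))
  if (nrow(obs) < min_detections) {
    warn("fewer total detections than `min_detections`; using a single group.")
    obs$observer_group <- "G1"
    return(obs)
  }
  grp <- integer(length(ord)); g <- 1L; acc <- 0L
  for (i in seq_along(ord)) {
    grp[i] <- g
    acc <- acc + dets[[i]]
    if (acc >= min_detections && i < length(ord)) {
      g <- g + 1L; acc <- 0L
    }
  }
  if (acc < min_detections && g > 1L) grp[grp == g] <- g - 1L  # merge trailing
  labels <- paste0("G", match(grp, sort(unique(grp))))
  obs$observer_group <- labels[match(obs$observer, ord)]
  obs
}

# ---- detection-function internals -----------------------------------------

# Probabilists' Hermite polynomial He_j(x).
hermite_poly <- function(x, j) {
  h0 <- rep(1, length(x)); h1 <- x
  if (j == 0) return(h0)
  if (j == 1) return(h1)
  for (k in 2:j) {
    h2 <- x * h1 - (k - 1) * h0
    h0 <- h1; h1 <- h2
  }
  h1
}

# Adjustment series value 1 + sum_j a_j h_j(x / w); distances scaled by w.
adj_series <- function(x, w, adjustment, orders, a) {
  if (adjustment == "none" || length(a) == 0) return(rep(1, length(x)))
  xs <- x / w
  s <- rep(1, length(x))
  for (k in seq_along(orders)) {
    h <- switch(adjustment,
                cosine = cos(orders[k] * pi * xs),
                hermite = hermite_poly(xs, orders[k]),
                simple_polynomial = xs^orders[k],
                abort("unknown adjustment series."))
    s <- s + a[k] * h
  }
  s
}

# Detection function with key, optional adjustments, standardized to g(0)=1.
g_eval <- function(x, sigma, key, shape, w,
                   adjustment = "none", orders = integer(), a = numeric()) {
  gk <- det_g(x, sigma, key, shape)
  if (adjustment == "none" || length(a) == 0) return(gk)
  s0 <- adj_series(0, w, adjustment, orders, a)
  gk * adj_series(x, w, adjustment, orders, a) / s0
}

# Effective strip half-width mu(z) = integral of g over [0, w]; closed form
# for plain half-normal, adaptive quadrature (abs.tol 1e-8) otherwise.
mu_integral <- function(sigma, key, shape, w,
                        adjustment = "none", orders = integer(),
                        a = numeric()) {
  vapply(sigma, function(s) {
    if (key == "half_normal" && (adjustment == "none" || length(a) == 0)) {
      s * sqrt(2 * pi) * (pnorm(w / s) - 0.5)
    } else {
      integrate(g_eval, 0, w, sigma = s, key = key, shape = shape, w = w,
                adjustment = adjustment, orders = orders, a = a,
                abs.tol = 1e-8, subdivisions = 200L)$value
    }
  }, numeric(1))
}

# Unpack a parameter vector for a given model structure.
unpack_par <- function(par, n_beta, key, n_adj) {
  i <- n_beta
  shape <- NULL
  if (key == "hazard_rate") {
    shape <- 1 + exp(par[i + 1])
    i <- i + 1
  }
  a <- if (n_adj > 0) par[i + seq_len(n_adj)] else numeric()
  list(beta = par[seq_len(n_beta)], shape = shape, a = a)
}

# Negative conditional log-likelihood of the MCDS model.
det_negloglik <- function(par, x, Z, key, w, adjustment, orders) {
  p <- unpack_par(par, ncol(Z), key, length(orders))
  if (!all(is.finite(par))) return(1e10)
  sigma <- exp(as.vector(Z %*% p$beta))
  if (any(!is.finite(sigma)) || any(sigma <= 0)) return(1e10)
  g <- g_eval(x, sigma, key, p$shape, w, adjustment, orders, p$a)
  if (any(!is.finite(g)) || any(g <= 0)) return(1e10)
  usig <- unique(sigma)
  mu_u <- tryCatch(
    mu_integral(usig, key, p$shape, w, adjustment, orders, p$a),
    error = function(e) NULL)
  if (is.null(mu_u) || any(!is.finite(mu_u)) || any(mu_u <= 0)) return(1e10)
  mu <- mu_u[match(sigma, usig)]
  -(sum(log(g)) - sum(log(mu)))
}

#' Fit a multiple-covariate distance-sampling detection function
#'
#' Maximizes the conditional likelihood `prod g(x_i; z_i) / mu(z_i)` with
#' `mu(z) = integral of g over [0, w]`, where the scale is log-linear in the
#' covariates, `sigma(z) = exp(b0 + sum_k b_k z_k)`. Keys are half-normal and
#' hazard-rate (shape constrained > 1). Adjustment series (cosine, Hermite,
#' simple polynomial; distances scaled by `w`) are allowed only without scale
#' covariates, and an adjusted fit whose detection function is non-monotonic
#' or negative on a 100-point check grid is flagged as not converged.
#' Optimization is quasi-Newton from multiple scale starts
#' (`sigma0 = w/4, w/2, w`).
#'
#' @param obs Truncated observation tibble (see [truncate_distances()]); the
#'   truncation distance is taken from its attribute unless `w` is given.
#' @param key `"half_normal"` or `"hazard_rate"`.
#' @param adjustment `"none"`, `"cosine"`, `"hermite"` or
#'   `"simple_polynomial"`.
#' @param orders Integer orders of the adjustment terms (defaults: cosine
#'   `2`, hermite `4`, simple polynomial `4`).
#' @param covariates Character vector of observation columns entering the
#'   scale model (e.g. `"observer_group"`, `"ground_cover"`).
#' @param w Truncation distance in meters.
#' @param start Optional full start vector (used internally for bootstrap
#'   refits; suppresses the multi-start).
#' @return An object of class `detection_fit`: parameter estimates,
#'   log-likelihood, AIC (`-2 loglik + 2 npar`), variance matrix from the
#'   observed information, average detection probability `p_bar` with its
#'   delta-method CV, and the data needed for prediction.
#' @export
fit_detection_function <- function(obs,
                                   key = c("half_normal", "hazard_rate"),
                                   adjustment = c("none", "cosine", "hermite",
                                                  "simple_polynomial"),
                                   orders = NULL,
                                   covariates = character(),
                                   w = attr(obs, "truncation_m"),
                                   start = NULL) {
  key <- arg_match(key)
  adjustment <- arg_match(adjustment)
  if (is.null(w)) abort("`w` is not given and `obs` carries no truncation attribute.")
  x <- obs$distance_m
  if (any(x > w + 1e-9)) abort("observations exceed the truncation distance; truncate first.")
  if (length(unique(x)) < 2) abort("need at least 2 distinct distances.")
  if (adjustment != "none" && length(covariates) > 0) {
    abort("adjustment terms are only allowed without scale covariates.")
  }
  if (adjustment != "none" && is.null(orders)) {
    orders <- switch(adjustment, cosine = 2L, hermite = 4L,
                     simple_polynomial = 4L)
  }
  orders <- as.integer(orders %||% integer())

  dat <- as_tibble(obs)[, covariates, drop = FALSE]
  dat[] <- lapply(dat, function(col) factor(col))
  fml <- if (length(covariates) == 0) ~1 else
    stats::reformulate(covariates)
  Z <- stats::model.matrix(fml, data = dat)
  xlev <- lapply(dat, levels)

  n_adj <- length(orders)
  make_start <- function(sig0) {
    c(log(sig0), rep(0, ncol(Z) - 1),
      if (key == "hazard_rate") log(1.5),
      rep(0, n_adj))
  }
  starts <- if (!is.null(start)) list(start) else
    lapply(c(w / 4, w / 2, w), make_start)

  best <- NULL
  for (s0 in starts) {
    opt <- tryCatch(
      optim(s0, det_negloglik, x = x, Z = Z, key = key, w = w,
            adjustment = adjustment, orders = orders,
            method = "BFGS",
            control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e9) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }

  converged <- !is.null(best) && best$convergence == 0
  reason <- if (is.null(best)) "optimization failed" else NULL
  par <- if (!is.null(best)) best$par else make_start(w / 2)
  up <- unpack_par(par, ncol(Z), key, n_adj)
  loglik <- if (!is.null(best)) -best$value else NA_real_
  npar <- length(par)

  if (converged && adjustment != "none") {
    xx <- seq(0, w, length.out = 100)
    gg <- g_eval(xx, exp(up$beta[1]), key, up$shape, w, adjustment, orders,
                 up$a)
    if (any(gg < 0) || any(diff(gg) > 1e-8)) {
      converged <- FALSE
      reason <- "adjusted detection function non-monotonic or negative"
    }
  }

  vcov_par <- matrix(NA_real_, npar, npar)
  if (converged) {
    H <- tryCatch(
      optimHess(par, det_negloglik, x = x, Z = Z, key = key, w = w,
                adjustment = adjustment, orders = orders),
      error = function(e) NULL)
    if (!is.null(H)) {
      vcov_par <- tryCatch(solve(H), error = function(e) vcov_par)
    }
  }

  fit <- structure(
    list(key = key, adjustment = adjustment, orders = orders,
         covariates = covariates, w = w,
         par = par, beta = setNames(up$beta, colnames(Z)),
         shape = up$shape, adj_coefs = up$a,
         loglik = loglik, npar = npar,
         aic = -2 * loglik + 2 * npar,
         vcov = vcov_par, converged = converged, reason = reason,
         n = length(x), data = obs, formula = fml, xlevels = xlev),
    class = "detection_fit")
  if (converged) {
    pb <- average_detection_probability(fit)
    fit$p_bar <- pb$p_bar
    fit$cv_p <- pb$cv_p
  }
  fit
}

# Scale sigma(z) for rows of newdata under a fitted scale model.
fit_sigma <- function(fit, newdata) {
  dat <- as_tibble(newdata)[, fit$covariates, drop = FALSE]
  for (nm in names(fit$xlevels)) {
    dat[[nm]] <- factor(dat[[nm]], levels = fit$xlevels[[nm]])
  }
  Z <- stats::model.matrix(fit$formula, data = dat)
  exp(as.vector(Z %*% fit$beta))
}

#' Per-observation detection probability under a fitted model
#'
#' `p(z) = mu(z) / w`, the probability of detecting an object uniformly
#' distributed in the strip given its covariates.
#'
#' @param fit A `detection_fit`.
#' @param newdata Observation rows carrying the fit's covariates; defaults to
#'   the fitting data.
#' @return Numeric vector of detection probabilities.
#' @export
detection_probability <- function(fit, newdata = fit$data) {
  sigma <- fit_sigma(fit, newdata)
  usig <- unique(sigma)
  mu <- mu_integral(usig, fit$key, fit$shape, fit$w, fit$adjustment,
                    fit$orders, fit$adj_coefs)
  mu[match(sigma, usig)] / fit$w
}

# p_bar as a function of the raw parameter vector, for delta-method CV.
p_bar_of_par <- function(par, fit, newdata) {
  tmp <- fit
  up <- unpack_par(par, length(fit$beta), fit$key, length(fit$orders))
  tmp$beta <- setNames(up$beta, names(fit$beta))
  tmp$shape <- up$shape
  tmp$adj_coefs <- up$a
  p <- detection_probability(tmp, newdata)
  length(p) / sum(1 / p)
}

#' Average detection probability with delta-method CV
#'
#' The Horvitz–Thompson-consistent average `p_bar = n / sum_i 1/p(z_i)`
#' (harmonic weighting over the observed covariates), with a CV obtained by
#' the delta method: numeric gradient of `p_bar` in the fit parameters
#' against the observed-information covariance.
#'
#' @param fit A converged `detection_fit`.
#' @param obs Observation rows; defaults to the fitting data.
#' @return One-row tibble `p_bar`, `cv_p`, `n`.
#' @export
average_detection_probability <- function(fit, obs = fit$data) {
  p <- detection_probability(fit, obs)
  if (any(p <= 0)) abort("non-positive detection probability; the fit failed.")
  p_bar <- nrow(obs) / sum(1 / p)
  cv <- NA_real_
  if (all(is.finite(fit$vcov))) {
    eps <- 1e-5
    grad <- vapply(seq_along(fit$par), function(j) {
      pp <- fit$par; pp[j] <- pp[j] + eps
      pm <- fit$par; pm[j] <- pm[j] - eps
      (p_bar_of_par(pp, fit, obs) - p_bar_of_par(pm, fit, obs)) / (2 * eps)
    }, numeric(1))
    v <- drop(t(grad) %*% fit$vcov %*% grad)
    if (is.finite(v) && v >= 0) cv <- sqrt(v) / p_bar
  }
  tibble(p_bar = p_bar, cv_p = cv, n = nrow(obs))
}

#' Select the best detection function by AIC
#'
#' Non-converged fits are excluded; among the rest the minimum-AIC fit wins,
#' with ties broken in favor of fewer parameters. The full AIC ladder is
#' attached to the returned fit as attribute `"aic_ladder"`.
#'
#' @param fits List of `detection_fit` objects.
#' @return The selected `detection_fit`.
#' @export
select_detection_model <- function(fits) {
  if (length(fits) == 0) abort("no fits supplied.")
  ok <- purrr::keep(fits, ~ isTRUE(.x$converged))
  if (length(ok) == 0) abort("no converged detection fits to select from.")
  ladder <- purrr::map_dfr(fits, function(f) {
    tibble(key = f$key, adjustment = f$adjustment,
           covariates = paste(f$covariates, collapse = "+"),
           npar = f$npar, loglik = f$loglik, aic = f$aic,
           converged = isTRUE(f$converged))
  })
  ladder <- arrange(ladder, !.data$converged, .data$aic, .data$npar)
  ladder$delta_aic <- ladder$aic - min(ladder$aic[ladder$converged])
  ord <- order(vapply(ok, function(f) f$aic, numeric(1)),
               vapply(ok, function(f) f$npar, numeric(1)))
  best <- ok[[ord[1]]]
  attr(best, "aic_ladder") <- ladder
  best
}

#' @export
print.detection_fit <- function(x, ...) {
  cat("Detection function (", x$key,
      if (x$adjustment != "none") paste0(" + ", x$adjustment, " adj"),
      ")\n", sep = "")
  if (length(x$covariates) > 0) {
    cat("  scale covariates:", paste(x$covariates, collapse = ", "), "\n")
  }
  cat(sprintf("  n = %d, w = %.3g m, logLik = %.3f, AIC = %.2f\n",
              x$n, x$w, x$loglik, x$aic))
  if (!is.null(x$p_bar)) {
    cat(sprintf("  average detection probability = %.3f (CV %.3f)\n",
                x$p_bar, x$cv_p))
  }
  if (!isTRUE(x$converged)) cat("  NOT CONVERGED:", x$reason %||% "", "\n")
  invisible(x)
}
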