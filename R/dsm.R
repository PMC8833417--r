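#' Horvitz–Thompson segment abundances
#'
#' Each detection contributes the inverse of its detection probability under
#' the fitted detection function, `1/p(z_i)`, to the abundance of the segment
#' that contains it (matched by transect id and along-transect position).
#' Segments without detections get abundance 0.
#'
#' @param obs Truncated observation tibble with `transect_id` and
#'   `position_m` (and the detection fit's covariates).
#' @param fit A converged `detection_fit` with the same truncation distance.
#' @param segments Segment tibble from [build_segments()].
#' @return `segments` with appended `n` (detections) and `nhat`
#'   (Horvitz–Thompson-corrected abundance).
#' @export
ht_segment_abundance <- function(obs, fit, segments) {
  segments$n <- 0L
  segments$nhat <- 0
  if (nrow(obs) == 0) return(segments)
  p <- detection_probability(fit, obs)
  if (any(p <= 0)) abort("non-positive detection probability.")
  seg_of <- integer(nrow(obs))
  for (i in seq_len(nrow(obs))) {
    cand <- which(segments$transect_id == obs$transect_id[i] &
                    segments$start_m <= obs$position_m[i] &
                    (segments$end_m > obs$position_m[i] |
                       # closed right boundary on the final segment
                       (segments$end_m == obs$position_m[i] &
                          segments$end_m == max(segments$end_m[
                            segments$transect_id == obs$transect_id[i]]))))
    if (length(cand) == 0) {
      abort(paste0("detection at position ", signif(obs$position_m[i], 4),
                   " m on transect ", obs$transect_id[i],
                   " falls in no segment."))
    }
    seg_of[i] <- cand[1]
  }
  agg_n <- tapply(rep(1L, nrow(obs)), seg_of, sum)
  agg_w <- tapply(1 / p, seg_of, sum)
  idx <- as.integer(names(agg_n))
  segments$n[idx] <- as.integer(agg_n)
  segments$nhat[idx] <- as.numeric(agg_w)
  segments
}

#' Fit a density surface model to segment abundances
#'
#' Models the Horvitz–Thompson-corrected abundances as
#' `log E[nhat_j] = log A_j + b0 + sum_k f_k(z_jk)` — a penalized additive
#' model with thin-plate regression spline smooths, the segment strip area as
#' offset, and a tweedie or negative-binomial response. Smoothness is chosen
#' by REML; the tweedie power (in (1, 2)) and the negative-binomial theta are
#' profiled alongside. The negative binomial needs integer counts, so `nhat`
#' is rounded for that family (with a warning when it changes values).
#'
#' @param segments Segment tibble with `nhat`, `area_m2` and covariate
#'   columns (see [ht_segment_abundance()], [extract_buffer_covariates()]).
#' @param covariates Character vector of covariates to smooth over (pass the
#'   collinearity-filtered list).
#' @param family `"tweedie"` or `"negative_binomial"`.
#' @param k Basis dimension per smooth (default 10; capped below the number
#'   of distinct covariate values).
#' @param season Optional season label carried into summaries.
#' @return An object of class `dsm_fit` wrapping the fitted `mgcv::gam`,
#'   with `aic`, `deviance_expl` (percent), the dispersion parameter, and
#'   the data needed for refits.
#' @export
fit_dsm <- function(segments, covariates,
                    family = c("tweedie", "negative_binomial"),
                    k = 10, season = NULL) {
  family <- arg_match(family)
  dat <- as_tibble(segments)
  miss <- setdiff(c("nhat", "area_m2", covariates), names(dat))
  if (length(miss) > 0) {
    abort(paste0("missing columns: ", paste(miss, collapse = ", ")))
  }
  if (any(!complete.cases(dat[, c("nhat", "area_m2", covariates)]))) {
    abort("segments contain missing values in modelled columns.")
  }
  if (family == "negative_binomial" &&
      any(abs(dat$nhat - round(dat$nhat)) > 1e-9)) {
    warn("negative binomial requires integer counts; `nhat` rounded.")
    dat$nhat <- round(dat$nhat)
  }
  terms <- vapply(covariates, function(v) {
    kk <- max(3L, min(k, dplyr::n_distinct(dat[[v]]) - 1L))
    sprintf("s(%s, k = %d)", v, kk)
  }, character(1))
  rhs <- paste(c(terms, "offset(log(area_m2))"), collapse = " + ")
  if (length(terms) == 0) rhs <- "offset(log(area_m2))"
  fml <- stats::as.formula(paste("nhat ~", rhs))
  fam <- if (family == "tweedie") mgcv::tw() else mgcv::nb()
  if (nrow(dat) <= length(covariates) * 3 + 1) {
    abort("fewer segments than model coefficients.")
  }
  g <- mgcv::gam(fml, family = fam, data = dat, method = "REML")
  smry <- summary(g)
  fam_str <- g$family$family
  disp <- if (family == "tweedie") {
    as.numeric(sub(".*p=([0-9.]+).*", "\\1", fam_str))
  } else {
    g$family$getTheta(TRUE)
  }
  structure(
    list(gam = g, family = family, dispersion = disp,
         covariates = covariates, season = season, k = k,
         aic = AIC(g), loglik = as.numeric(logLik(g)),
         deviance_expl = 100 * smry$dev.expl,
         data = dat, removed = character()),
    class = "dsm_fit")
}

# Smooth-term table (term, edf, p-value) of a dsm_fit.
smooth_table <- function(fit) {
  st <- summary(fit$gam)$s.table
  if (is.null(st) || nrow(st) == 0) {
    return(tibble(term = character(), covariate = character(),
                  edf = numeric(), p_value = numeric()))
  }
  tibble(term = rownames(st),
         covariate = sub("^s\\((.*)\\)$", "\\1", rownames(st)),
         edf = st[, "edf"], ref_df = st[, "Ref.df"],
         statistic = st[, ncol(st) - 1], p_value = st[, "p-value"])
}

#' Backward term selection for a density surface model
#'
#' Repeatedly removes the smooth with the largest approximate p-value above
#' `alpha` and refits, until every remaining smooth is significant or only
#' the intercept remains. Ties in p-value are broken by dropping the term
#' with the larger effective degrees of freedom. If a refit fails, the
#' previous model is returned with a warning.
#'
#' @param fit A `dsm_fit`.
#' @param alpha Significance level (default 0.05).
#' @return The reduced `dsm_fit`; removed covariates (in removal order) are
#'   recorded in its `removed` field.
#' @export
backward_select <- function(fit, alpha = 0.05) {
  removed <- fit$removed
  repeat {
    st <- smooth_table(fit)
    if (nrow(st) == 0 || max(st$p_value) <= alpha) break
    worst <- st[st$p_value == max(st$p_value), ]
    worst <- worst[order(-worst$edf), ][1, ]
    new_covs <- setdiff(fit$covariates, worst$covariate)
    nxt <- tryCatch(
      fit_dsm(fit$data, new_covs, family = fit$family, k = fit$k,
              season = fit$season),
      error = function(e) NULL)
    if (is.null(nxt)) {
      warn(paste0("refit without ", worst$covariate,
                  " failed; returning previous model."))
      break
    }
    removed <- c(removed, worst$covariate)
    fit <- nxt
  }
  fit$removed <- removed
  fit
}

#' Compare candidate density surface models
#'
#' Builds the family-comparison table (AIC, delta AIC versus the best model,
#' percent deviance explained) with delta AIC computed within season when a
#' season column/label is present. When `dsm_fit` objects are supplied,
#' quantile-quantile data (sorted deviance residuals against standard normal
#' quantiles) are attached as attribute `"qq"`.
#'
#' @param fits A list of `dsm_fit` objects, or a data frame with columns
#'   `family`, `aic` (and optionally `season`, `formula`, `deviance_expl`)
#'   for comparisons from published values.
#' @return A tibble with `season`, `family`, `formula`, `aic`, `delta_aic`,
#'   `deviance_expl`, and logical `best`.
#' @export
compare_dsm <- function(fits) {
  if (is.data.frame(fits)) {
    tab <- as_tibble(fits)
    if (!"season" %in% names(tab)) tab$season <- NA_character_
    if (!"formula" %in% names(tab)) tab$formula <- NA_character_
    if (!"deviance_expl" %in% names(tab)) tab$deviance_expl <- NA_real_
    qq <- NULL
  } else {
    if (length(fits) == 0) abort("no fits to compare.")
    tab <- purrr::map_dfr(fits, function(f) {
      tibble(season = f$season %||% NA_character_, family = f$family,
             formula = paste(deparse(stats::formula(f$gam)), collapse = ""),
             aic = f$aic, deviance_expl = f$deviance_expl)
    })
    qq <- purrr::map(fits, function(f) {
      r <- sort(stats::residuals(f$gam, type = "deviance"))
      tibble(theoretical = stats::qnorm(stats::ppoints(length(r))),
             residual = r)
    })
  }
  tab <- tab %>%
    group_by(.data$season) %>%
    mutate(delta_aic = .data$aic - min(.data$aic),
           best = .data$delta_aic == 0) %>%
    ungroup() %>%
    select("season", "family", "formula", "aic", "delta_aic",
           "deviance_expl", "best")
  if (!is.null(qq)) attr(tab, "qq") <- qq
  tab
}

#' @export
print.dsm_fit <- function(x, ...) {
  cat("Density surface model (", x$family, ")\n", sep = "")
  if (!is.null(x$season)) cat("  season:", x$season, "\n")
  cat("  smooths:", if (length(x$covariates)) paste(x$covariates, collapse = ", ")
      else "(intercept only)", "\n")
  cat(sprintf("  n = %d segments, AIC = %.2f, %%deviance = %.1f\n",
              nrow(x$data), x$aic, x$deviance_expl))
  if (length(x$removed) > 0) {
    cat("  removed by backward selection:", paste(x$removed, collapse = ", "),
        "\n")
  }
  invisible(x)
}
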