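#' Classify prediction cells by extrapolation type (ExDet)
#'
#' For each target point, the univariate component `UD_j = min(x_j - min_j,
#' max_j - x_j, 0) / (max_j - min_j)` measures how far covariate `j` falls
#' outside the reference range; `NT1 = sum_j UD_j <= 0`. Points inside every
#' univariate range (`NT1 = 0`) get the multivariate novelty ratio
#' `NT2 = D^2(x) / max_ref D^2`, the Mahalanobis distance to the reference
#' mean (reference covariance) scaled by the largest reference distance.
#' Classes: `univariate` (`NT1 < 0`), `combinatorial` (`NT1 = 0`, `NT2 > 1`),
#' `analogue` (`NT1 = 0`, `NT2 <= 1`). The most influential covariate (MIC)
#' is the most negative `UD_j` for univariate points, and the covariate whose
#' removal most reduces `D^2` for combinatorial/analogue points.
#'
#' @param reference Data frame of reference (surveyed) covariates.
#' @param target Data frame of target (prediction) covariates; same columns.
#' @param ridge Ridge factor applied to a computationally singular reference
#'   covariance (with a warning).
#' @return Tibble with one row per target: `nt1`, `nt2`, `class`, `mic`.
#' @export
exdet_classify <- function(reference, target, ridge = 1e-8) {
  covs <- intersect(names(reference), names(target))
  covs <- covs[vapply(reference[covs], is.numeric, logical(1))]
  if (length(covs) == 0) abort("no shared numeric covariates.")
  ref <- as.matrix(as_tibble(reference)[covs])
  tgt <- as.matrix(as_tibble(target)[covs])
  rng_min <- apply(ref, 2, min)
  rng_max <- apply(ref, 2, max)
  rng <- rng_max - rng_min
  if (any(rng <= 0)) {
    abort(paste0("degenerate reference range for: ",
                 paste(covs[rng <= 0], collapse = ", ")))
  }
  ud <- sweep(pmin(sweep(tgt, 2, rng_min), sweep(-tgt, 2, -rng_max), 0),
              2, rng, "/")
  nt1 <- rowSums(ud)

  mu <- colMeans(ref)
  S <- stats::cov(ref)
  Sinv <- tryCatch(solve(S), error = function(e) {
    warn("singular reference covariance; ridge regularization applied.")
    solve(S + diag(ridge * mean(diag(S)), ncol(S)))
  })
  d2_ref_max <- max(stats::mahalanobis(ref, mu, Sinv, inverted = TRUE))
  d2_tgt <- stats::mahalanobis(tgt, mu, Sinv, inverted = TRUE)
  nt2 <- ifelse(nt1 < 0, NA_real_, d2_tgt / d2_ref_max)

  cls <- case_when(nt1 < 0 ~ "univariate",
                   nt2 > 1 ~ "combinatorial",
                   TRUE ~ "analogue")

  mic <- character(nrow(tgt))
  uni <- nt1 < 0
  if (any(uni)) {
    mic[uni] <- covs[apply(ud[uni, , drop = FALSE], 1, which.min)]
  }
  if (any(!uni) && length(covs) == 1) {
    mic[!uni] <- covs
  } else if (any(!uni)) {
    # leave-one-covariate-out reduction in D^2, largest contribution wins
    contrib <- vapply(seq_along(covs), function(j) {
      Sj <- S[-j, -j, drop = FALSE]
      Sjinv <- tryCatch(solve(Sj), error = function(e)
        solve(Sj + diag(ridge * mean(diag(Sj)), ncol(Sj))))
      d2_tgt - stats::mahalanobis(tgt[, -j, drop = FALSE], mu[-j], Sjinv,
                                  inverted = TRUE)
    }, numeric(nrow(tgt)))
    contrib <- matrix(contrib, nrow = nrow(tgt))
    mic[!uni] <- covs[apply(contrib[!uni, , drop = FALSE], 1, which.max)]
  }
  tibble(nt1 = nt1, nt2 = nt2, class = cls, mic = mic)
}

# Gower distances from each row of `a` to each row of `b` given ranges.
gower_cross <- function(a, b, rng) {
  out <- matrix(0, nrow(a), nrow(b))
  for (j in seq_along(rng)) {
    out <- out + abs(outer(a[, j], b[, j], "-")) / rng[j]
  }
  out / length(rng)
}

#' Percentage of reference data nearby (%N)
#'
#' For each target point, the share of reference points within a Gower
#' distance threshold, where the threshold is the mean Gower distance over
#' all pairs of reference points. Gower distance is the mean over covariates
#' of `|x_j - y_j| / range_j` (reference ranges); zero-range covariates are
#' excluded from the sum with a warning. Low values flag predictions with
#' little supporting survey data.
#'
#' @param reference Data frame of reference covariates (>= 2 rows).
#' @param target Data frame of target covariates; same columns.
#' @return Tibble with one row per target: `pct_nearby` in [0, 100] and the
#'   `threshold` used (also stored as an attribute).
#' @export
percent_data_nearby <- function(reference, target) {
  covs <- intersect(names(reference), names(target))
  covs <- covs[vapply(reference[covs], is.numeric, logical(1))]
  ref <- as.matrix(as_tibble(reference)[covs])
  if (nrow(ref) < 2) abort("need at least 2 reference points.")
  tgt <- as.matrix(as_tibble(target)[covs])
  rng <- apply(ref, 2, max) - apply(ref, 2, min)
  if (any(rng <= 0)) {
    warn(paste0("zero-range covariate(s) excluded from Gower distance: ",
                paste(covs[rng <= 0], collapse = ", ")))
    keep <- rng > 0
    ref <- ref[, keep, drop = FALSE]
    tgt <- tgt[, keep, drop = FALSE]
    rng <- rng[keep]
    if (length(rng) == 0) abort("no covariate with positive range.")
  }
  dref <- gower_cross(ref, ref, rng)
  threshold <- mean(dref[upper.tri(dref)])
  dtgt <- gower_cross(tgt, ref, rng)
  pct <- unname(100 * rowMeans(dtgt <= threshold))
  structure(tibble(pct_nearby = pct, threshold = threshold),
            threshold = threshold)
}

#' Mask unreliable predictions
#'
#' Flags prediction cells as valid or not from their extrapolation class and
#' %N support. The default (`rule = "strict"`) keeps only analogue or
#' combinatorial cells with `%N >= nearby_threshold`; the alternative
#' (`rule = "univariate_only"`) discards only univariate cells with low %N.
#'
#' @param cells Tibble with `class` and `pct_nearby` columns.
#' @param nearby_threshold %N below which support is considered insufficient
#'   (default 5).
#' @param rule `"strict"` or `"univariate_only"` (see Details).
#' @return `cells` with a logical `valid` column; attribute
#'   `"class_summary"` holds per-class percentages of all cells.
#' @export
apply_discard_rule <- function(cells, nearby_threshold = 5,
                               rule = c("strict", "univariate_only")) {
  rule <- arg_match(rule)
  stopifnot(all(c("class", "pct_nearby") %in% names(cells)))
  cells$valid <- if (rule == "strict") {
    cells$class %in% c("analogue", "combinatorial") &
      cells$pct_nearby >= nearby_threshold
  } else {
    !(cells$class == "univariate" & cells$pct_nearby < nearby_threshold)
  }
  smry <- cells %>%
    count(class = .data$class) %>%
    mutate(pct = 100 * .data$n / sum(.data$n))
  attr(cells, "class_summary") <- smry
  cells
}
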