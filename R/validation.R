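#' Build a crossed quadrant classification design
#'
#' Study quadrants crossed over climate classes (multi-year mean temperature
#' bins, cool `1` to warm `5`) and dominant-landscape types, with a fixed
#' number of replicates per combination.
#'
#' @param n_climate Number of climate classes (default 5).
#' @param landscapes Landscape type labels.
#' @param replicates Replicate quadrants per climate x landscape class.
#' @return Tibble `quadrant_id`, `climate`, `landscape`, `replicate`.
#' @export
make_quadrant_classes <- function(n_climate = 5,
                                  landscapes = c("near-natural",
                                                 "agricultural", "urban"),
                                  replicates = 4) {
  grid <- tidyr::expand_grid(climate = seq_len(n_climate),
                             landscape = landscapes,
                             replicate = seq_len(replicates))
  grid$quadrant_id <- sprintf("Q%03d", seq_len(nrow(grid)))
  select(grid, "quadrant_id", everything())
}

#' Aggregate valid predictions to management districts
#'
#' Districts are given as seed points (the synthetic analogue of district
#' polygons: each cell belongs to the district of its nearest seed — the
#' Voronoi tessellation, equivalent to cell-center-in-polygon assignment for
#' those polygons). Per district the mean predicted density over valid cells
#' and the valid-area fraction are computed; districts with no valid cells
#' get an undefined mean and fraction 0.
#'
#' @param cells Prediction cells with `x`, `y`, `abundance` and logical
#'   `valid`.
#' @param districts Tibble `district_id`, `x`, `y` (seed coordinates) and
#'   optionally `harvest_density`.
#' @return Tibble per district: `district_id`, `harvest_density` (if given),
#'   `n_cells`, `n_valid`, `mean_density`, `valid_fraction`.
#' @export
aggregate_to_districts <- function(cells, districts) {
  stopifnot(all(c("x", "y", "abundance", "valid") %in% names(cells)),
            all(c("district_id", "x", "y") %in% names(districts)))
  d2 <- outer(cells$x, districts$x, "-")^2 + outer(cells$y, districts$y, "-")^2
  nearest <- districts$district_id[max.col(-d2, ties.method = "first")]
  out <- tibble(district_id = nearest,
                abundance = cells$abundance, valid = cells$valid) %>%
    group_by(.data$district_id) %>%
    summarise(n_cells = dplyr::n(), n_valid = sum(.data$valid),
              mean_density = ifelse(sum(.data$valid) > 0,
                                    mean(.data$abundance[.data$valid]),
                                    NA_real_),
              .groups = "drop") %>%
    mutate(valid_fraction = .data$n_valid / .data$n_cells)
  base <- select(districts, -"x", -"y")
  out <- left_join(base, out, by = "district_id")
  out$n_cells[is.na(out$n_cells)] <- 0L
  out$n_valid[is.na(out$n_valid)] <- 0L
  out$valid_fraction[out$n_cells == 0] <- 0
  out
}

#' Filter districts by valid prediction coverage
#'
#' A district enters the harvest comparison only when at least
#' `min_fraction` of its cells carry valid predictions (boundary inclusive).
#'
#' @param records District tibble from [aggregate_to_districts()].
#' @param min_fraction Minimum valid-area fraction (default 0.5).
#' @return The included subset, with attribute `"counts"` (list with
#'   `included`, `excluded`, `total`).
#' @export
filter_districts <- function(records, min_fraction = 0.5) {
  inc <- records$valid_fraction >= min_fraction
  out <- records[inc, ]
  attr(out, "counts") <- list(included = sum(inc),
                              excluded = sum(!inc),
                              total = length(inc))
  out
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' Rank correlation on average (midrank) ranks, with the p-value from the
#' t-approximation `t = rho sqrt((n-2)/(1-rho^2))` on `n - 2` degrees of
#' freedom — the standard large-sample treatment when ties are present.
#'
#' @param x,y Paired numeric vectors (finite, `n >= 3`).
#' @return One-row tibble `rho`, `p_value`, `n`.
#' @export
spearman_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("need at least 3 paired finite values.")
  if (var(x) < .Machine$double.eps || var(y) < .Machine$double.eps) {
    abort("rank correlation undefined for a constant vector.")
  }
  rho <- cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tval), df = n - 2)
  }
  tibble(rho = rho, p_value = p, n = n)
}

#' Summarize predicted density along the climate x land-use gradient
#'
#' Median and quartiles of valid predicted cell densities per climate class
#' and landscape type (the numbers behind gradient boxplots). Classes with
#' no valid cells appear with `n = 0`.
#'
#' @param cells Prediction cells with `quadrant_id`, `abundance` and logical
#'   `valid`.
#' @param quadrant_classes Tibble from [make_quadrant_classes()] (or with
#'   columns `quadrant_id`, `climate`, `landscape`).
#' @return Tibble per (climate, landscape): `n`, `median`, `q25`, `q75`.
#' @export
gradient_summary <- function(cells, quadrant_classes) {
  stopifnot(all(c("quadrant_id", "abundance", "valid") %in% names(cells)))
  joined <- cells %>%
    filter(.data$valid) %>%
    left_join(distinct(quadrant_classes, .data$quadrant_id, .data$climate,
                       .data$landscape),
              by = "quadrant_id") %>%
    filter(!is.na(.data$climate))
  smry <- joined %>%
    group_by(.data$climate, .data$landscape) %>%
    summarise(n = dplyr::n(),
              median = median(.data$abundance),
              q25 = quantile(.data$abundance, 0.25, names = FALSE),
              q75 = quantile(.data$abundance, 0.75, names = FALSE),
              .groups = "drop")
  frame <- distinct(quadrant_classes, .data$climate, .data$landscape)
  frame %>%
    left_join(smry, by = c("climate", "landscape")) %>%
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n)) %>%
    arrange(.data$climate, .data$landscape)
}
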