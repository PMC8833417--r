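#' Specify a distance-sampling detection process
#'
#' Describes the generating detection function used by
#' [simulate_observations()]: a half-normal `exp(-x^2 / (2 sigma^2))` or
#' hazard-rate `1 - exp(-(x / sigma)^-b)` key, with per-observer
#' multiplicative factors on the scale `sigma` (observer skill), and the strip
#' half-width within which pellet groups are generated.
#'
#' @param key `"half_normal"` or `"hazard_rate"`.
#' @param sigma0 Baseline scale parameter in meters (> 0).
#' @param shape Hazard-rate shape `b` (> 1); ignored for half-normal.
#' @param observer_effects Named numeric vector of multiplicative factors on
#'   `sigma0`, one per observer. Defaults to a single perfect-average observer.
#' @param w_gen Generation strip half-width in meters; must be at least the
#'   analysis truncation distance so that truncation discards real data.
#' @return A list of class `detection_spec`.
#' @export
detection_spec <- function(key = c("half_normal", "hazard_rate"),
                           sigma0 = 0.6, shape = 2.5,
                           observer_effects = c(obs1 = 1),
                           w_gen = 2.5) {
  key <- arg_match(key)
  if (!is.numeric(sigma0) || sigma0 <= 0) abort("`sigma0` must be > 0.")
  if (key == "hazard_rate" && (!is.numeric(shape) || shape <= 1)) {
    abort("hazard-rate `shape` must be > 1.")
  }
  if (is.null(names(observer_effects)) || any(observer_effects <= 0)) {
    abort("`observer_effects` must be a named vector of positive factors.")
  }
  if (w_gen <= 0) abort("`w_gen` must be > 0.")
  structure(list(key = key, sigma0 = sigma0,
                 shape = if (key == "hazard_rate") shape else NULL,
                 observer_effects = observer_effects, w_gen = w_gen),
            class = "detection_spec")
}

# Detection probability g(x); g(0) = 1 for both keys.
det_g <- function(x, sigma, key, shape = NULL) {
  if (key == "half_normal") {
    exp(-x^2 / (2 * sigma^2))
  } else {
    ifelse(x <= 0, 1, 1 - exp(-(x / sigma)^(-shape)))
  }
}

#' Lay out a line-transect survey on a synthetic landscape
#'
#' Two survey modes mirror field practice. The designed mode places
#' fixed-length west-to-east transects with a stratified systematic effort
#' split between the woodland and open strata (default 75% of effort in
#' woodland). The undesigned mode places short transects at study plots: each
#' start point is drawn uniformly within `radius_m` (default 30 m) of the
#' plot center, with a random direction.
#'
#' @param landscape A `pellet_landscape`.
#' @param design A list. For mode `"designed"`: `n_transects`, `length_m`
#'   (default 200), `effort_split` (named, `woodland`/`open`, default
#'   `c(woodland = 0.75, open = 0.25)`), optional `quadrant_id`. For mode
#'   `"undesigned"`: `plot_centers` (tibble with `x`, `y` and optionally
#'   `quadrant_id`), `n_per_plot` (default 1), `length_m` (default 200),
#'   `radius_m` (default 30).
#' @param seed Integer seed.
#' @return A tibble of transects: `transect_id`, `quadrant_id`, `x_start`,
#'   `y_start`, `x_end`, `y_end`, `length_m`, `design`, `stratum`.
#' @export
design_survey <- function(landscape, design, seed) {
  set.seed(as.integer(seed))
  mode <- design$mode %||% "designed"
  len <- design$length_m %||% 200
  if (len <= 0) abort("transect length must be > 0.")
  if (mode == "designed") {
    n_tr <- design$n_transects %||% 20
    split <- design$effort_split %||% c(woodland = 0.75, open = 0.25)
    stopifnot(abs(sum(split) - 1) < 1e-9)
    wood <- woodland_mask(landscape,
                          classes = design$woodland_classes %||%
                            c("coniferous", "deciduous_and_mixed"),
                          threshold = design$woodland_threshold %||% 0.5)
    n_wood <- round(n_tr * split[["woodland"]])
    n_open <- n_tr - n_wood
    margin <- design$margin_m %||% 0
    org0 <- attr(landscape, "origin")
    ext0 <- attr(landscape, "dims") * attr(landscape, "resolution_m")
    interior <- landscape$x >= org0[1] + margin &
      landscape$x <= org0[1] + ext0[1] - margin &
      landscape$y >= org0[2] + margin &
      landscape$y <= org0[2] + ext0[2] - margin
    idx <- list(woodland = which(wood & interior),
                open = which(!wood & interior))
    want <- c(woodland = n_wood, open = n_open)
    for (s in names(want)) {
      if (want[[s]] > 0 && length(idx[[s]]) == 0) {
        abort(paste0("stratum \"", s, "\" has zero area but positive effort share."))
      }
    }
    res <- attr(landscape, "resolution_m")
    org <- attr(landscape, "origin")
    ext <- attr(landscape, "dims")[1] * res
    rows <- purrr::map(names(want), function(s) {
      k <- want[[s]]
      if (k == 0) return(NULL)
      pick <- sample(idx[[s]], k, replace = length(idx[[s]]) < k)
      x0 <- pmin(pmax(landscape$x[pick] - len / 2, org[1]), org[1] + ext - len)
      tibble(quadrant_id = design$quadrant_id %||% "Q1",
             x_start = x0, y_start = landscape$y[pick],
             x_end = x0 + len, y_end = landscape$y[pick],
             length_m = len, design = "designed", stratum = s)
    })
    out <- bind_rows(rows)
  } else if (mode == "undesigned") {
    pc <- as_tibble(design$plot_centers)
    stopifnot(all(c("x", "y") %in% names(pc)))
    n_per <- design$n_per_plot %||% 1
    radius <- design$radius_m %||% 30
    wood <- woodland_mask(landscape)
    out <- purrr::map_dfr(seq_len(nrow(pc)), function(i) {
      purrr::map_dfr(seq_len(n_per), function(j) {
        r <- radius * sqrt(runif(1))
        a <- runif(1, 0, 2 * pi)
        x0 <- pc$x[i] + r * cos(a)
        y0 <- pc$y[i] + r * sin(a)
        th <- runif(1, 0, 2 * pi)
        tibble(quadrant_id = pc$quadrant_id[i] %||% paste0("P", i),
               x_start = x0, y_start = y0,
               x_end = x0 + len * cos(th), y_end = y0 + len * sin(th),
               length_m = len, design = "undesigned",
               stratum = ifelse(wood[cell_index(landscape, x0, y0)],
                                "woodland", "open"))
      })
    })
  } else {
    abort("design mode must be \"designed\" or \"undesigned\".")
  }
  out$transect_id <- sprintf("T%03d", seq_len(nrow(out)))
  select(out, "transect_id", everything())
}

#' Summarize survey effort by stratum
#'
#' @param transects A transect tibble from [design_survey()].
#' @return A tibble with one row per stratum plus a `total` row: effort in
#'   meters and kilometers and percentage of total effort.
#' @export
survey_effort <- function(transects) {
  by <- transects %>%
    group_by(stratum = .data$stratum) %>%
    summarise(n_transects = dplyr::n(), effort_m = sum(.data$length_m),
              .groups = "drop")
  tot <- tibble(stratum = "total", n_transects = nrow(transects),
                effort_m = sum(transects$length_m))
  out <- bind_rows(by, tot)
  out$effort_km <- out$effort_m / 1000
  out$pct_effort <- 100 * out$effort_m / tot$effort_m
  out
}

#' Default mapping from land-cover class to ground-cover class
#'
#' Ground cover along a transect (what the observer wades through) is derived
#' in the synthetic world from the locally dominant land-cover class. This
#' mapping is an assumption of the generator, not an estimate.
#'
#' @return Named character vector, land-cover class to ground-cover class.
#' @export
default_ground_cover_map <- function() {
  c(coniferous = "shrub_gt100", deciduous_and_mixed = "shrub_30_100",
    arable = "bare", grass_and_shrubs = "grass_forb",
    artificial = "bare", water = "bare")
}

# Dominant land-cover class (among the "landcover" compositional family) at
# planar points.
dominant_landcover <- function(landscape, x, y) {
  fams <- attr(landscape, "families")
  lc <- names(fams)[!is.na(fams) & fams == "landcover"]
  if (length(lc) == 0) abort("landscape has no land-cover family.")
  idx <- cell_index(landscape, x, y)
  m <- as.matrix(landscape[idx, lc, drop = FALSE])
  lc[max.col(m, ties.method = "first")]
}

#' Ground-cover transitions along transects
#'
#' Samples the dominant land-cover class every meter under each transect line
#' and records a transition wherever the class changes, mirroring the
#' transitions noted during field surveys. The first row of each transect is
#' at position 0 and carries the starting class.
#'
#' @param transects Transect tibble.
#' @param landscape A `pellet_landscape` with a land-cover family.
#' @param cover_map Named mapping from land-cover class to ground-cover class.
#' @return Tibble `transect_id`, `position_m`, `cover_class`.
#' @export
transect_transitions <- function(transects, landscape,
                                 cover_map = default_ground_cover_map()) {
  purrr::map_dfr(seq_len(nrow(transects)), function(i) {
    tr <- transects[i, ]
    s <- seq(0.5, tr$length_m - 0.5, by = 1)
    ux <- (tr$x_end - tr$x_start) / tr$length_m
    uy <- (tr$y_end - tr$y_start) / tr$length_m
    cls <- dominant_landcover(landscape, tr$x_start + s * ux,
                              tr$y_start + s * uy)
    gc <- unname(cover_map[cls])
    gc[is.na(gc)] <- "grass_forb"
    change <- c(TRUE, gc[-1] != gc[-length(gc)])
    tibble(transect_id = tr$transect_id,
           position_m = ifelse(s[change] == 0.5, 0, s[change] - 0.5),
           cover_class = gc[change])
  })
}

#' Simulate pellet-group detections on strip transects
#'
#' Pellet groups are placed on each transect strip by an inhomogeneous
#' Poisson process with the truth surface's intensity (evaluated at the cell
#' under each along-transect meter), each at a uniform perpendicular distance
#' in `[0, w_gen]`. Each group is then retained with probability
#' `g(distance; sigma0 * observer factor)` — distance-dependent,
#' observer-dependent thinning. True generated counts per transect are
#' returned alongside for recovery tests.
#'
#' @param truth A `pellet_truth` surface.
#' @param transects Transect tibble from [design_survey()].
#' @param det A [detection_spec()].
#' @param seed Integer seed.
#' @param landscape Optional `pellet_landscape` used to attach ground-cover
#'   classes at each detection's along-transect position.
#' @param season Season label stored on each record.
#' @return A list with `observations` (tibble: `transect_id`, `position_m`,
#'   `distance_m`, `observer`, `ground_cover`, `season`) and `true_counts`
#'   (tibble: `transect_id`, `n_true`, `observer`).
#' @export
simulate_observations <- function(truth, transects, det, seed,
                                  landscape = NULL, season = "spring") {
  stopifnot(inherits(det, "detection_spec"))
  set.seed(as.integer(seed))
  obs_names <- names(det$observer_effects)
  observer_of <- rep(obs_names, length.out = nrow(transects))

  rows <- vector("list", nrow(transects))
  n_true <- integer(nrow(transects))
  for (i in seq_len(nrow(transects))) {
    tr <- transects[i, ]
    s <- seq(0.5, tr$length_m - 0.5, by = 1)
    ux <- (tr$x_end - tr$x_start) / tr$length_m
    uy <- (tr$y_end - tr$y_start) / tr$length_m
    lam <- truth$lambda[cell_index(truth, tr$x_start + s * ux,
                                   tr$y_start + s * uy)]
    k <- rpois(length(s), lam * 2 * det$w_gen)  # per 1-m slice of the strip
    n_true[i] <- sum(k)
    if (n_true[i] == 0) next
    along <- rep(s, k) - 0.5 + runif(n_true[i])
    dist <- runif(n_true[i], 0, det$w_gen)
    sig <- det$sigma0 * det$observer_effects[[observer_of[i]]]
    keep <- runif(n_true[i]) < det_g(dist, sig, det$key, det$shape)
    if (!any(keep)) next
    rows[[i]] <- tibble(transect_id = tr$transect_id,
                        position_m = along[keep], distance_m = dist[keep],
                        observer = observer_of[i])
  }
  obs <- bind_rows(rows)
  if (nrow(obs) == 0) {
    obs <- tibble(transect_id = character(), position_m = numeric(),
                  distance_m = numeric(), observer = character())
  }
  obs$ground_cover <- if (!is.null(landscape) && nrow(obs) > 0) {
    tr_idx <- match(obs$transect_id, transects$transect_id)
    ux <- (transects$x_end - transects$x_start) / transects$length_m
    uy <- (transects$y_end - transects$y_start) / transects$length_m
    cls <- dominant_landcover(
      landscape,
      transects$x_start[tr_idx] + obs$position_m * ux[tr_idx],
      transects$y_start[tr_idx] + obs$position_m * uy[tr_idx]
    )
    gc <- unname(default_ground_cover_map()[cls])
    gc[is.na(gc)] <- "grass_forb"
    gc
  } else {
    rep(NA_character_, nrow(obs))
  }
  obs$season <- rep(season, nrow(obs))
  list(
    observations = obs,
    true_counts = tibble(transect_id = transects$transect_id,
                         n_true = n_true, observer = observer_of)
  )
}
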