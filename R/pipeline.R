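#' Assemble a pipeline configuration
#'
#' Collects every tunable constant of the end-to-end synthetic pipeline with
#' the field defaults: 1.5-m truncation, 500-m covariate buffers, at least 70
#' detections per observer group, |r| > 0.7 collinearity screening, p < 0.05
#' term retention, 5% %N support, 50% minimum valid district coverage and
#' 1-km prediction cells. Values can be overridden by arguments or by a YAML
#' file (file values are applied first, then arguments).
#'
#' @param ... Named overrides of the defaults (see Details; unknown names
#'   are rejected).
#' @param file Optional YAML file of overrides.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(..., file = NULL) {
  defaults <- list(
    seed = 1L,
    season = "spring",
    truncation_m = 1.5,
    buffer_radius_m = 500,
    min_group_detections = 70,
    r_threshold = 0.7,
    alpha = 0.05,
    nearby_threshold_pct = 5,
    min_valid_fraction = 0.5,
    grid_cell_km = 1,
    discard_rule = "strict",
    extent_m = 8000,
    resolution_m = 200,
    n_transects = 256,
    effort_split = c(woodland = 0.75, open = 0.25),
    detection_key = "hazard_rate",
    detection_sigma0 = 0.5,
    detection_shape = 2.5,
    observer_effects = c(obs1 = 1, obs2 = 0.75, obs3 = 1.25, obs4 = 1),
    w_gen = 2.5,
    truth_intercept = log(0.008),
    dsm_k = 6,
    gof_n_boot = 49,
    n_districts = 25,
    n_quadrants_side = 4
  )
  cfg <- defaults
  if (!is.null(file)) {
    cfg <- utils::modifyList(cfg, yaml::read_yaml(file))
  }
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad) > 0) {
    abort(paste0("unknown configuration key(s): ", paste(bad, collapse = ", ")))
  }
  cfg <- utils::modifyList(cfg, over)
  stopifnot(cfg$truncation_m > 0, cfg$buffer_radius_m > 0,
            cfg$r_threshold > 0, cfg$alpha > 0, cfg$alpha < 1,
            cfg$nearby_threshold_pct >= 0, cfg$nearby_threshold_pct <= 100,
            cfg$min_valid_fraction >= 0, cfg$min_valid_fraction <= 1,
            cfg$w_gen >= cfg$truncation_m)
  structure(cfg, class = c("pipeline_config", "list"))
}

# Default generating effects of the synthetic truth surface: habitat and
# climate effects of realistic magnitude on the log scale.
default_truth_effects <- function() {
  list(
    coniferous = function(v) 1.2 * (v - 0.5),
    arable = function(v) 0.8 * (v - 0.5),
    win_mean_temp = function(v) -0.5 * v^2 + 0.3 * v
  )
}

#' Run the full synthetic survey-to-validation pipeline
#'
#' Executes, with a single seed, the whole analysis chain: simulate a
#' landscape, truth surface and stratified survey; truncate distances and
#' post-stratify observers; fit and select a detection function and test its
#' fit; segment transects and attach buffered covariates with collinearity
#' screening; estimate segment abundances by Horvitz–Thompson and fit
#' tweedie/negative-binomial density surface models with backward selection;
#' predict on a regular grid with delta-method CVs; evaluate extrapolation
#' (ExDet, %N) and mask unreliable cells; aggregate to Voronoi management
#' districts and correlate with synthetic harvest densities; summarize the
#' climate x landscape gradient.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, the tabular artifacts are
#'   written there as CSV and the configuration as YAML.
#' @return A named list with every intermediate and final artifact.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- as.integer(config$seed)

  spec <- landscape_spec(extent_m = config$extent_m,
                         resolution_m = config$resolution_m)
  landscape <- generate_landscape(spec, seed)
  truth <- generate_truth(landscape, default_truth_effects(),
                          intercept = config$truth_intercept)

  margin <- config$buffer_radius_m + config$resolution_m
  transects <- design_survey(
    landscape,
    list(mode = "designed", n_transects = config$n_transects,
         length_m = 200, effort_split = config$effort_split,
         margin_m = margin),
    seed + 1L)
  transitions <- transect_transitions(transects, landscape)

  det <- detection_spec(key = config$detection_key,
                        sigma0 = config$detection_sigma0,
                        shape = config$detection_shape,
                        observer_effects = config$observer_effects,
                        w_gen = config$w_gen)
  sim <- simulate_observations(truth, transects, det, seed + 2L,
                               landscape = landscape,
                               season = config$season)

  obs <- truncate_distances(sim$observations, config$truncation_m)
  effort <- sim$true_counts %>%
    left_join(select(transects, "transect_id", "length_m"),
              by = "transect_id") %>%
    group_by(observer = .data$observer) %>%
    summarise(effort_m = sum(.data$length_m), .groups = "drop")
  obs <- assign_observer_groups(obs, effort, config$min_group_detections)
  attr(obs, "truncation_m") <- config$truncation_m

  cand <- list(
    fit_detection_function(obs, key = "half_normal", w = config$truncation_m),
    fit_detection_function(obs, key = "hazard_rate", w = config$truncation_m)
  )
  if (dplyr::n_distinct(obs$observer_group) > 1) {
    cand <- c(cand, list(
      fit_detection_function(obs, key = "half_normal",
                             covariates = "observer_group",
                             w = config$truncation_m),
      fit_detection_function(obs, key = "hazard_rate",
                             covariates = "observer_group",
                             w = config$truncation_m)))
  }
  det_fit <- select_detection_model(cand)
  gof <- cvm_goodness_of_fit(det_fit, obs, n_boot = config$gof_n_boot,
                             seed = seed + 3L)

  segments <- build_segments(transects, transitions, w = config$truncation_m)
  segments <- extract_buffer_covariates(segments, landscape,
                                        config$buffer_radius_m)
  priority <- unique(c("win_mean_temp", landscape_covariates(landscape)))
  retained <- filter_collinear(segments, priority, config$r_threshold)
  segments <- ht_segment_abundance(obs, det_fit, segments)

  dsm_fits <- purrr::map(c("tweedie", "negative_binomial"), function(fam) {
    backward_select(
      fit_dsm(segments, as.character(retained), family = fam,
              k = config$dsm_k, season = config$season),
      alpha = config$alpha)
  })
  comparison <- compare_dsm(dsm_fits)
  best_dsm <- dsm_fits[[which(comparison$best)[1]]]

  cell_m <- config$grid_cell_km * 1000
  half <- cell_m / 2
  ctr <- seq(half, config$extent_m - half, by = cell_m)
  cells <- tidyr::expand_grid(x = ctr, y = ctr)
  cells <- extract_buffer_covariates(cells, landscape,
                                     config$buffer_radius_m)
  cells <- predict_grid(best_dsm, cells, cell_area_m2 = cell_m^2)
  cells <- cell_cv(best_dsm, cells, cv_detection = det_fit$cv_p %||% 0)

  ref <- segments[, best_dsm$covariates, drop = FALSE]
  tgt <- cells[, best_dsm$covariates, drop = FALSE]
  ex <- exdet_classify(ref, tgt)
  nb <- percent_data_nearby(ref, tgt)
  cells$class <- ex$class
  cells$nt1 <- ex$nt1
  cells$nt2 <- ex$nt2
  cells$pct_nearby <- nb$pct_nearby
  cells <- apply_discard_rule(cells, config$nearby_threshold_pct,
                              rule = config$discard_rule)

  # quadrant classification of the synthetic world: carve the landscape into
  # a coarse quadrant grid, class each quadrant by its mean winter
  # temperature quintile and dominant landscape type
  qside <- config$n_quadrants_side
  qsize <- config$extent_m / qside
  qx <- pmin(floor(cells$x / qsize), qside - 1)
  qy <- pmin(floor(cells$y / qsize), qside - 1)
  cells$quadrant_id <- sprintf("Q%02d", qy * qside + qx + 1)
  qclass <- cells %>%
    group_by(.data$quadrant_id) %>%
    summarise(temp = mean(.data$win_mean_temp),
              agr = mean(.data$arable + .data$grass_and_shrubs),
              forest = mean(.data$coniferous + .data$deciduous_and_mixed),
              .groups = "drop") %>%
    mutate(climate = as.integer(cut(.data$temp, breaks = quantile(
      .data$temp, probs = seq(0, 1, 0.2)), include.lowest = TRUE,
      labels = FALSE)),
      landscape = ifelse(.data$forest > .data$agr, "near-natural",
                         "agricultural")) %>%
    select("quadrant_id", "climate", "landscape")

  set.seed(seed + 4L)
  districts <- tibble(
    district_id = sprintf("D%03d", seq_len(config$n_districts)),
    x = runif(config$n_districts, 0, config$extent_m),
    y = runif(config$n_districts, 0, config$extent_m))
  truth_cells <- tibble(x = cells$x, y = cells$y,
                        abundance = exp(predict_truth_eta(truth, cells$x,
                                                          cells$y)) * cell_m^2,
                        valid = TRUE)
  truth_by_d <- aggregate_to_districts(truth_cells, districts)
  districts$harvest_density <- 0.002 * truth_by_d$mean_density *
    exp(rnorm(config$n_districts, 0, 0.25))

  district_records <- aggregate_to_districts(cells, districts)
  included <- filter_districts(district_records, config$min_valid_fraction)
  correlation <- if (nrow(included) >= 3) {
    spearman_correlation(included$mean_density, included$harvest_density)
  } else {
    tibble(rho = NA_real_, p_value = NA_real_, n = nrow(included))
  }

  gradient <- gradient_summary(cells, qclass)

  result <- list(config = config, landscape = landscape, truth = truth,
                 transects = transects, effort = survey_effort(transects),
                 observations = obs, true_counts = sim$true_counts,
                 detection = det_fit,
                 aic_ladder = attr(det_fit, "aic_ladder"),
                 gof = gof, segments = segments,
                 retained_covariates = as.character(retained),
                 dsm_fits = dsm_fits, comparison = comparison,
                 dsm = best_dsm, cells = cells,
                 class_summary = attr(cells, "class_summary"),
                 districts = district_records,
                 included_districts = included,
                 district_counts = attr(included, "counts"),
                 correlation = correlation,
                 quadrant_classes = qclass, gradient = gradient)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, nm) utils::write.csv(
      df, file.path(out_dir, paste0(nm, ".csv")), row.names = FALSE)
    wr(as_tibble(transects), "transects")
    wr(as_tibble(obs), "observations")
    wr(as_tibble(segments), "segments")
    wr(comparison, "dsm_comparison")
    wr(as_tibble(cells), "prediction_cells")
    wr(district_records, "districts")
    wr(gradient, "gradient_summary")
    wr(attr(det_fit, "aic_ladder"), "detection_aic_ladder")
    yaml::write_yaml(unclass(config), file.path(out_dir, "config.yml"))
  }
  result
}

# Truth log-intensity at planar points (nearest-cell lookup).
predict_truth_eta <- function(truth, x, y) {
  truth$eta[cell_index(truth, x, y)]
}
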