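#' Cut transects into ground-cover-homogeneous segments
#'
#' Segments partition each transect exactly at its ground-cover transition
#' points; each segment carries the cover class that starts at its left
#' boundary and the strip area `A = 2 w l` that serves as the density-model
#' offset.
#'
#' @param transects Transect tibble.
#' @param transitions Tibble `transect_id`, `position_m`, `cover_class`
#'   (first row of each transect at position 0), e.g. from
#'   [transect_transitions()]; `NULL` gives one segment per transect.
#' @param w Strip half-width in meters used for the area offset.
#' @return Tibble of class segments: `segment_id`, `transect_id`, `start_m`,
#'   `end_m`, `length_m`, `x`, `y` (centroid), `area_m2`, `cover_class`.
#' @export
build_segments <- function(transects, transitions = NULL, w = 1.5) {
  if (w <= 0) abort("`w` must be > 0.")
  purrr::map_dfr(seq_len(nrow(transects)), function(i) {
    tr <- transects[i, ]
    trs <- if (is.null(transitions)) {
      tibble(position_m = 0, cover_class = NA_character_)
    } else {
      filter(transitions, .data$transect_id == tr$transect_id) %>%
        arrange(.data$position_m)
    }
    if (nrow(trs) == 0) {
      trs <- tibble(position_m = 0, cover_class = NA_character_)
    }
    if (any(trs$position_m >= tr$length_m) || any(trs$position_m < 0)) {
      abort(paste0("transition beyond the end of transect ", tr$transect_id))
    }
    if (trs$position_m[1] != 0) {
      trs <- bind_rows(tibble(position_m = 0,
                              cover_class = NA_character_), trs)
    }
    b <- c(trs$position_m, tr$length_m)
    mid <- (head(b, -1) + tail(b, -1)) / 2
    ux <- (tr$x_end - tr$x_start) / tr$length_m
    uy <- (tr$y_end - tr$y_start) / tr$length_m
    tibble(transect_id = tr$transect_id,
           start_m = head(b, -1), end_m = tail(b, -1),
           length_m = diff(b),
           x = tr$x_start + mid * ux, y = tr$y_start + mid * uy,
           area_m2 = segment_area(diff(b), w),
           cover_class = trs$cover_class)
  }) %>%
    mutate(segment_id = sprintf("S%04d", row_number())) %>%
    select("segment_id", everything())
}

#' Strip-segment area offset
#'
#' The covered area of a line-transect segment of length `l` with strip
#' half-width `w` is `A = 2 w l`, the offset of the density surface model.
#'
#' @param length_m Segment length(s) in meters.
#' @param w Strip half-width in meters.
#' @return Area(s) in square meters.
#' @export
segment_area <- function(length_m, w) {
  if (any(w <= 0)) abort("`w` must be > 0.")
  2 * w * length_m
}

#' Attach buffered landscape covariates to segments
#'
#' Around each segment centroid a disk of radius `radius_m` (default 500 m,
#' roughly a monthly roe deer home range treated as a circle) is laid over
#' the covariate grids. A cell belongs to the buffer iff its center falls in
#' the disk. Continuous grids are summarized as the mean cell value; fraction
#' grids as percentage cover in [0, 100].
#'
#' @param segments Tibble with `x`, `y` centroids (segments or prediction
#'   cells).
#' @param landscape A `pellet_landscape`.
#' @param radius_m Buffer radius in meters.
#' @return `segments` with one appended column per landscape covariate.
#' @export
extract_buffer_covariates <- function(segments, landscape, radius_m = 500) {
  res <- attr(landscape, "resolution_m")
  org <- attr(landscape, "origin")
  ext <- attr(landscape, "dims") * res
  kinds <- attr(landscape, "kinds")
  covs <- landscape_covariates(landscape)
  lx <- landscape$x; ly <- landscape$y
  vals <- as.matrix(landscape[covs])
  out <- matrix(NA_real_, nrow(segments), length(covs),
                dimnames = list(NULL, covs))
  id_col <- if ("segment_id" %in% names(segments)) segments[["segment_id"]]
    else if ("cell_id" %in% names(segments)) segments[["cell_id"]]
    else as.character(seq_len(nrow(segments)))
  for (i in seq_len(nrow(segments))) {
    cx <- segments$x[i]; cy <- segments$y[i]
    if (cx - radius_m < org[1] - res / 2 || cx + radius_m > org[1] + ext[1] + res / 2 ||
        cy - radius_m < org[2] - res / 2 || cy + radius_m > org[2] + ext[2] + res / 2) {
      abort(paste0("buffer of segment ", id_col[i], " exceeds the grid extent."))
    }
    inside <- (lx - cx)^2 + (ly - cy)^2 <= radius_m^2
    if (!any(inside)) {
      abort(paste0("buffer of segment ", id_col[i], " contains no cell centers."))
    }
    out[i, ] <- colMeans(vals[inside, , drop = FALSE])
  }
  for (j in seq_along(covs)) {
    scale <- if (identical(kinds[[covs[j]]], "fraction")) 100 else 1
    segments[[covs[j]]] <- out[, j] * scale
  }
  segments
}

#' Reclassify a raw land-use class map into fraction grids
#'
#' Maps fine raw land-use classes (one class per cell) onto a coarser target
#' roster and emits one fraction grid per target class. With one class per
#' cell the fractions are one-hot, so the target grids sum to exactly 1 per
#' cell (compositional closure).
#'
#' @param raw_map Tibble `x`, `y`, `raw_class`.
#' @param mapping Named character vector, raw class -> target class; must
#'   cover every raw class present.
#' @return Tibble `x`, `y` plus one numeric column per target class.
#' @export
reclassify_landcover <- function(raw_map, mapping) {
  unmapped <- setdiff(unique(raw_map$raw_class), names(mapping))
  if (length(unmapped) > 0) {
    abort(paste0("unmapped raw class(es): ", paste(unmapped, collapse = ", ")))
  }
  targets <- unique(unname(mapping))
  out <- tibble(x = raw_map$x, y = raw_map$y)
  tgt <- unname(mapping[raw_map$raw_class])
  for (t in targets) out[[t]] <- as.numeric(tgt == t)
  out
}

#' Drop collinear covariates by ecological priority
#'
#' Screens a segment covariate table for pairwise Pearson correlation above
#' `r_threshold` (default |r| > 0.7). Conflicting pairs are processed in
#' descending |r|; in each pair the covariate that comes later in the
#' priority list (less ecologically relevant) is dropped, and correlations
#' are re-checked after every drop. Zero-variance covariates are dropped with
#' a warning.
#'
#' @param covariate_table Data frame of candidate covariate columns (extra
#'   non-candidate columns are ignored).
#' @param priority Character vector of every candidate covariate, most
#'   ecologically relevant first.
#' @param r_threshold Absolute Pearson correlation above which a pair
#'   conflicts.
#' @return Character vector of retained covariates (in priority order) with
#'   attribute `"drop_log"`: a tibble `dropped`, `kept_instead`, `r`.
#' @export
filter_collinear <- function(covariate_table, priority, r_threshold = 0.7) {
  missing_cols <- setdiff(priority, names(covariate_table))
  if (length(missing_cols) > 0) {
    abort(paste0("priority covariates absent from the table: ",
                 paste(missing_cols, collapse = ", ")))
  }
  tab <- as_tibble(covariate_table)[, priority, drop = FALSE]
  if (nrow(tab) < 2) abort("need at least 2 rows to assess collinearity.")
  log <- tibble(dropped = character(), kept_instead = character(),
                r = numeric())
  keep <- priority
  zv <- keep[vapply(tab[keep], function(v) var(v) < .Machine$double.eps,
                    logical(1))]
  if (length(zv) > 0) {
    warn(paste0("zero-variance covariate(s) dropped: ",
                paste(zv, collapse = ", ")))
    keep <- setdiff(keep, zv)
    log <- bind_rows(log, tibble(dropped = zv, kept_instead = NA_character_,
                                 r = NA_real_))
  }
  repeat {
    if (length(keep) < 2) break
    cm <- cor(tab[keep])
    diag(cm) <- 0
    if (max(abs(cm)) <= r_threshold) break
    ij <- which(abs(cm) == max(abs(cm)), arr.ind = TRUE)[1, ]
    pair <- keep[ij]
    # the pair member later in the priority list loses
    loser <- pair[which.max(match(pair, priority))]
    winner <- setdiff(pair, loser)
    log <- bind_rows(log, tibble(dropped = loser, kept_instead = winner,
                                 r = cm[ij[1], ij[2]]))
    keep <- setdiff(keep, loser)
  }
  structure(keep, drop_log = log)
}
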