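#' Specify a synthetic landscape
#'
#' A landscape specification names the covariate grids to simulate, their
#' kind (`"continuous"` or `"fraction"`), the compositional family a fraction
#' grid belongs to (all members of one family are renormalized to sum to one
#' per cell, e.g. land-cover classes or forest-ownership classes), and the
#' spatial correlation scale of the underlying random field.
#'
#' The default roster is a compact analogue of the covariates used in
#' broad-scale deer density surface models: four land-cover fractions, a
#' forest-ownership fraction, winter climate summaries, spring precipitation
#' and forest-edge proximity.
#'
#' @param extent_m Side length of the square landscape in meters.
#' @param resolution_m Cell edge in meters.
#' @param covariates A data frame with columns `name`, `kind`
#'   (`"continuous"`/`"fraction"`), `family` (`NA` for continuous grids) and
#'   `cor_scale_m` (e-folding distance of spatial autocorrelation in meters).
#' @param origin Planar coordinates (m) of the lower-left corner, length 2.
#' @return A list of class `landscape_spec`.
#' @export
landscape_spec <- function(extent_m = 8000,
                           resolution_m = 200,
                           covariates = default_covariate_roster(),
                           origin = c(0, 0)) {
  if (!is.numeric(extent_m) || extent_m <= 0) {
    abort("`extent_m` must be a positive number.")
  }
  if (!is.numeric(resolution_m) || resolution_m <= 0) {
    abort("`resolution_m` must be a positive number.")
  }
  covariates <- as_tibble(covariates)
  stopifnot(all(c("name", "kind", "family", "cor_scale_m") %in% names(covariates)))
  if (anyDuplicated(covariates$name)) abort("covariate names must be unique.")
  if (!all(covariates$kind %in% c("continuous", "fraction"))) {
    abort("covariate `kind` must be \"continuous\" or \"fraction\".")
  }
  structure(
    list(extent_m = extent_m, resolution_m = resolution_m,
         covariates = covariates, origin = as.numeric(origin)),
    class = "landscape_spec"
  )
}

#' Default synthetic covariate roster
#'
#' @return A tibble describing the default covariate grids of
#'   [landscape_spec()].
#' @export
default_covariate_roster <- function() {
  tibble(
    name = c("coniferous", "deciduous_and_mixed", "arable", "grass_and_shrubs",
             "private_forest", "state_forest",
             "win_mean_temp", "win_temp_range", "spr_acc_precip",
             "edge_proximity"),
    kind = c(rep("fraction", 6), rep("continuous", 4)),
    family = c(rep("landcover", 4), rep("ownership", 2), rep(NA_character_, 4)),
    cor_scale_m = c(rep(1500, 4), rep(2000, 2), 4000, 4000, 3000, 800)
  )
}

# Circular FFT convolution of a matrix with an isotropic Gaussian kernel.
# Kernel sd in cells; the resulting field has autocorrelation ~ exp(-d^2 /
# (2 * (sqrt(2) * sd)^2)), so a correlation e-folding scale L maps to sd = L/2.
gaussian_blur <- function(mat, sd_cells) {
  if (sd_cells <= 0) return(mat)
  nr <- nrow(mat); nc <- ncol(mat)
  dr <- pmin(0:(nr - 1), nr - 0:(nr - 1))
  dc <- pmin(0:(nc - 1), nc - 0:(nc - 1))
  kern <- exp(-outer(dr^2, dc^2, "+") / (2 * sd_cells^2))
  kern <- kern / sum(kern)
  out <- Re(stats::fft(stats::fft(mat) * stats::fft(kern), inverse = TRUE)) /
    (nr * nc)
  out
}

# Standardized smooth Gaussian field on an nr x nc grid.
smooth_field <- function(nr, nc, sd_cells) {
  f <- gaussian_blur(matrix(rnorm(nr * nc), nr, nc), sd_cells)
  s <- sd(f)
  if (s < .Machine$double.eps) f[] <- 0 else f <- (f - mean(f)) / s
  f
}

#' Generate a synthetic covariate landscape
#'
#' Continuous grids are smoothed Gaussian white noise (standardized to mean 0,
#' sd 1) with the requested autocorrelation scale. Fraction grids are built
#' from the same smooth fields: members of one compositional family are
#' passed through a softmax per cell, so the family sums to exactly 1
#' everywhere; a fraction grid without a family is passed through a logistic
#' link, giving values in (0, 1).
#'
#' @param spec A [landscape_spec()].
#' @param seed Integer seed; the same spec and seed give bit-identical grids.
#' @return A tibble of cell centers (`x`, `y`, in meters) with one column per
#'   covariate, of class `pellet_landscape`. Grid geometry is stored in
#'   attributes `resolution_m`, `origin`, `dims` (cells in x, y) and
#'   `kinds`/`families` (named character vectors).
#' @export
generate_landscape <- function(spec, seed) {
  stopifnot(inherits(spec, "landscape_spec"))
  set.seed(as.integer(seed))
  res <- spec$resolution_m
  nx <- max(1L, as.integer(round(spec$extent_m / res)))
  ny <- nx
  ox <- spec$origin[1]; oy <- spec$origin[2]
  cx <- ox + (seq_len(nx) - 0.5) * res
  cy <- oy + (seq_len(ny) - 0.5) * res

  covs <- spec$covariates
  fields <- lapply(seq_len(nrow(covs)), function(i) {
    smooth_field(nx, ny, covs$cor_scale_m[i] / (2 * res))
  })
  names(fields) <- covs$name

  out <- vector("list", nrow(covs))
  names(out) <- covs$name
  for (fam in unique(covs$family[!is.na(covs$family)])) {
    member <- covs$name[!is.na(covs$family) & covs$family == fam]
    ex <- lapply(fields[member], function(f) exp(2 * f))
    tot <- Reduce(`+`, ex)
    for (m in member) out[[m]] <- ex[[m]] / tot
  }
  for (i in seq_len(nrow(covs))) {
    nm <- covs$name[i]
    if (!is.null(out[[nm]])) next
    out[[nm]] <- if (covs$kind[i] == "fraction") {
      stats::plogis(fields[[nm]])
    } else {
      fields[[nm]]
    }
  }

  grid <- expand.grid(x = cx, y = cy, KEEP.OUT.ATTRS = FALSE)
  land <- as_tibble(grid)
  for (nm in covs$name) land[[nm]] <- as.vector(out[[nm]])

  structure(
    land,
    resolution_m = res, origin = c(ox, oy), dims = c(nx, ny),
    kinds = setNames(covs$kind, covs$name),
    families = setNames(covs$family, covs$name),
    class = c("pellet_landscape", class(land))
  )
}

#' Covariate names of a landscape
#' @param landscape A `pellet_landscape`.
#' @return Character vector of covariate column names.
#' @export
landscape_covariates <- function(landscape) {
  setdiff(names(landscape), c("x", "y"))
}

# Row index of the cell containing planar point(s) (x, y); points outside the
# grid are clamped to the nearest edge cell.
cell_index <- function(landscape, x, y) {
  res <- attr(landscape, "resolution_m")
  org <- attr(landscape, "origin")
  dm <- attr(landscape, "dims")
  ix <- pmin(pmax(ceiling((x - org[1]) / res), 1L), dm[1])
  iy <- pmin(pmax(ceiling((y - org[2]) / res), 1L), dm[2])
  (iy - 1L) * dm[1] + ix
}

#' Woodland mask of a landscape
#'
#' A cell is woodland when the summed forest land-cover fraction exceeds the
#' threshold. Used to stratify survey designs into woodland and open strata.
#'
#' @param landscape A `pellet_landscape`.
#' @param classes Land-cover fraction columns counted as forest.
#' @param threshold Summed fraction above which a cell is woodland.
#' @return Logical vector along the landscape rows.
#' @export
woodland_mask <- function(landscape,
                          classes = c("coniferous", "deciduous_and_mixed"),
                          threshold = 0.5) {
  classes <- intersect(classes, names(landscape))
  if (length(classes) == 0) abort("no forest land-cover columns present.")
  rowSums(as.matrix(landscape[classes])) > threshold
}

#' Build a true pellet-group intensity surface
#'
#' The truth surface is the generating analogue of the fitted density model:
#' a log-linear additive combination of covariate effects,
#' `lambda = exp(intercept + sum_k f_k(z_k))`, in pellet groups per square
#' meter. Downstream stages are tested by recovering these effects and the
#' implied total abundance.
#'
#' @param landscape A `pellet_landscape`.
#' @param effects Named list of vectorized functions; names must be landscape
#'   covariates. An effect is evaluated on its covariate column and added to
#'   the log-intensity.
#' @param intercept Log intensity (log pellet groups per m^2) when all
#'   effects are zero. The default corresponds to a few thousand pellet
#'   groups per km^2, the magnitude seen in deer pellet surveys.
#' @return A tibble `x, y, eta, lambda` of class `pellet_truth` with
#'   attributes `expected_total` (sum of `lambda` times cell area),
#'   `cell_area_m2`, and the grid geometry of the landscape.
#' @export
generate_truth <- function(landscape, effects = list(),
                           intercept = log(0.003)) {
  stopifnot(inherits(landscape, "pellet_landscape"))
  bad <- setdiff(names(effects), landscape_covariates(landscape))
  if (length(bad) > 0) {
    abort(paste0("effects reference unknown covariates: ",
                 paste(bad, collapse = ", ")))
  }
  eta <- rep(intercept, nrow(landscape))
  for (nm in names(effects)) {
    eta <- eta + effects[[nm]](landscape[[nm]])
  }
  lambda <- exp(eta)
  if (!all(is.finite(lambda))) abort("non-finite intensity produced.")
  res <- attr(landscape, "resolution_m")
  structure(
    tibble(x = landscape$x, y = landscape$y, eta = eta, lambda = lambda),
    resolution_m = res, origin = attr(landscape, "origin"),
    dims = attr(landscape, "dims"),
    cell_area_m2 = res^2,
    intercept = intercept,
    expected_total = sum(lambda) * res^2,
    class = c("pellet_truth", class(tibble()))
  )
}
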