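# Shared fixtures, generated in code.

# Small landscape for fast tests.
tiny_landscape <- function(seed = 11, extent_m = 4000, resolution_m = 100) {
  generate_landscape(landscape_spec(extent_m = extent_m,
                                    resolution_m = resolution_m), seed)
}

# Distances from a half-normal detection function on [0, w] by rejection.
r_halfnormal_distances <- function(n, sigma, w) {
  x <- numeric(0)
  while (length(x) < n) {
    cand <- runif(2 * n, 0, w)
    x <- c(x, cand[runif(2 * n) < exp(-cand^2 / (2 * sigma^2))])
  }
  x[seq_len(n)]
}

# Distances from a hazard-rate detection function on [0, w] by rejection.
r_hazard_distances <- function(n, sigma, b, w) {
  x <- numeric(0)
  while (length(x) < n) {
    cand <- runif(2 * n, 0, w)
    x <- c(x, cand[runif(2 * n) < 1 - exp(-(cand / sigma)^(-b))])
  }
  x[seq_len(n)]
}

# A single long transect with constant-intensity truth, for thinning checks.
flat_world <- function(lambda, extent_m = 2000, resolution_m = 100) {
  land <- tiny_landscape(5, extent_m, resolution_m)
  truth <- generate_truth(land, intercept = log(lambda))
  transects <- tibble::tibble(
    transect_id = "T001", quadrant_id = "Q1",
    x_start = 100, y_start = extent_m / 2,
    x_end = extent_m - 100, y_end = extent_m / 2,
    length_m = extent_m - 200, design = "designed", stratum = "open")
  list(landscape = land, truth = truth, transects = transects)
}

# Hazard-rate key, written out independently of the package internals.
det_g_oracle <- function(x, sigma, b) 1 - exp(-(x / sigma)^(-b))

# Synthetic segment table with a known smooth effect and thinned counts:
# true counts are Poisson with log-intensity b0 + f(z), detections binomial
# with probability p, and nhat the Horvitz-Thompson correction n/p.
make_segment_data <- function(n, f = function(z) 0, p = 0.5, b0 = log(0.005),
                              area = 600, seed = 1, extra_covs = 0) {
  set.seed(seed)
  dat <- tibble::tibble(
    segment_id = sprintf("S%04d", seq_len(n)),
    area_m2 = area,
    z = runif(n, -2, 2))
  n_true <- rpois(n, area * exp(b0 + f(dat$z)))
  n_det <- rbinom(n, n_true, p)
  dat$n <- n_det
  dat$nhat <- n_det / p
  if (extra_covs > 0) {
    for (j in seq_len(extra_covs)) dat[[paste0("noise", j)]] <- rnorm(n)
  }
  dat
}


# Brute-force ExDet reimplementation, independent of the package path.
exdet_oracle <- function(ref, tgt) {
  ref <- as.matrix(ref); tgt <- as.matrix(tgt)
  mins <- apply(ref, 2, min); maxs <- apply(ref, 2, max)
  mu <- colMeans(ref); S <- cov(ref)
  d2max <- max(apply(ref, 1, function(r) t(r - mu) %*% solve(S) %*% (r - mu)))
  t(apply(tgt, 1, function(x) {
    ud <- pmin(x - mins, maxs - x, 0) / (maxs - mins)
    nt1 <- sum(ud)
    if (nt1 < 0) return(c(nt1 = nt1, nt2 = NA, cls = 3))
    d2 <- drop(t(x - mu) %*% solve(S) %*% (x - mu))
    nt2 <- d2 / d2max
    c(nt1 = 0, nt2 = nt2, cls = if (nt2 > 1) 2 else 1)
  }))
}

# Brute-force %N: mean pairwise Gower threshold, fraction of reference
# points within it.
pctn_oracle <- function(ref, tgt) {
  ref <- as.matrix(ref); tgt <- as.matrix(tgt)
  rng <- apply(ref, 2, max) - apply(ref, 2, min)
  gow <- function(a, b) mean(abs(a - b) / rng)
  n <- nrow(ref)
  pair <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) pair <- c(pair, gow(ref[i, ], ref[j, ]))
  thr <- mean(pair)
  vapply(seq_len(nrow(tgt)), function(t) {
    100 * mean(vapply(seq_len(n), function(i) gow(tgt[t, ], ref[i, ]) <= thr,
                      logical(1)))
  }, numeric(1))
}

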