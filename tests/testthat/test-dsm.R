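test_that("Horvitz-Thompson weights sum inverse detection probabilities", {
  tr <- tibble::tibble(transect_id = "T001", quadrant_id = "Q1",
                       x_start = 0, y_start = 0, x_end = 200, y_end = 0,
                       length_m = 200, design = "designed", stratum = "open")
  seg <- build_segments(
    tr, tibble::tibble(transect_id = "T001", position_m = c(0, 100),
                       cover_class = c("bare", "grass_forb")), w = 1.5)

  # constant p = 0.5 via a wide half-normal evaluated through a stub fit
  obs3 <- tibble::tibble(transect_id = "T001",
                         position_m = c(10, 50, 150), distance_m = 0.2)
  fit <- fit_detection_function(
    tibble::tibble(distance_m = r_halfnormal_distances(100, 0.6, 1.5)),
    key = "half_normal", w = 1.5)
  p <- detection_probability(fit, obs3)
  got <- ht_segment_abundance(obs3, fit, seg)
  expect_equal(sum(got$nhat), sum(1 / p))
  expect_equal(got$n, c(2L, 1L))
  expect_equal(got$nhat, c(1 / p[1] + 1 / p[2], 1 / p[3]))

  # detections outside every segment are an error
  bad <- tibble::tibble(transect_id = "T001", position_m = 999,
                        distance_m = 0.2)
  expect_error(ht_segment_abundance(bad, fit, seg), "no segment")

  # perfect detection: nhat equals n (hand case: p {0.5, 0.25} -> 6)
  expect_equal(sum(1 / c(0.5, 0.25)), 6)
  expect_equal(sum(1 / rep(0.5, 3)), 6)
})

test_that("a single-covariate smooth effect is recovered (r > 0.9)", {
  f_true <- function(z) 0.8 * sin(z)
  dat <- make_segment_data(500, f = f_true, seed = 61)
  fit <- fit_dsm(dat, "z", family = "tweedie")
  expect_equal(fit$family, "tweedie")
  expect_gt(fit$deviance_expl, 0)
  sm <- predict(fit$gam, type = "terms")[, "s(z)"]
  truth <- f_true(dat$z) - mean(f_true(dat$z))
  expect_gt(cor(sm, truth), 0.9)
})

test_that("null data produce flat smooths", {
  dat <- make_segment_data(300, seed = 62)
  fit <- fit_dsm(dat, "z", family = "tweedie")
  st <- tidy(fit)
  expect_lt(st$edf, 1.6)  # effectively linear-or-less wiggliness
  expect_gt(st$p_value, 0.05)
})

test_that("doubling the offset shifts only the intercept by -log 2", {
  dat <- make_segment_data(400, f = function(z) 0.5 * z, seed = 63)
  f1 <- fit_dsm(dat, "z", family = "tweedie")
  dat2 <- dat
  dat2$area_m2 <- 2 * dat2$area_m2
  f2 <- fit_dsm(dat2, "z", family = "tweedie")
  b1 <- coef(f1$gam)[["(Intercept)"]]
  b2 <- coef(f2$gam)[["(Intercept)"]]
  expect_equal(b2 - b1, -log(2), tolerance = 0.02)
  sm1 <- predict(f1$gam, type = "terms")[, "s(z)"]
  sm2 <- predict(f2$gam, type = "terms")[, "s(z)"]
  expect_gt(cor(sm1, sm2), 0.999)
  expect_lt(max(abs(sm1 - sm2)), 0.05)
})

test_that("negative binomial rounds non-integer responses with a warning", {
  dat <- make_segment_data(300, f = function(z) 0.5 * z, p = 0.4, seed = 64)
  expect_warning(fit <- fit_dsm(dat, "z", family = "negative_binomial"),
                 "rounded")
  expect_equal(fit$family, "negative_binomial")
  expect_true(is.finite(fit$aic))
})

test_that("backward selection is a fixed point when all terms are significant", {
  dat <- make_segment_data(500, f = function(z) 0.8 * sin(z), seed = 65)
  fit <- fit_dsm(dat, "z", family = "tweedie")
  sel <- backward_select(fit)
  expect_equal(sel$covariates, fit$covariates)
  expect_equal(sel$removed, character(0))
  expect_true(all(tidy(sel)$p_value <= 0.05))
})

test_that("backward selection drops a pure-noise covariate", {
  dat <- make_segment_data(500, f = function(z) 0.8 * sin(z), seed = 66,
                           extra_covs = 1)
  fit <- fit_dsm(dat, c("z", "noise1"), family = "tweedie")
  sel <- backward_select(fit)
  expect_false("noise1" %in% sel$covariates)
  expect_true("z" %in% sel$covariates)
  expect_true(all(tidy(sel)$p_value <= 0.05))
})

test_that("model comparison reproduces published delta-AIC arithmetic", {
  tab <- tibble::tibble(
    season = c("spring", "spring", "autumn", "autumn"),
    family = rep(c("tweedie", "negative_binomial"), 2),
    aic = c(1046.11, 1064.06, 1177.12, 1248.35))
  cmp <- compare_dsm(tab)
  spring <- cmp[cmp$season == "spring", ]
  autumn <- cmp[cmp$season == "autumn", ]
  expect_equal(spring$delta_aic[spring$family == "negative_binomial"], 17.95)
  expect_equal(autumn$delta_aic[autumn$family == "negative_binomial"], 71.23)
  expect_true(all(cmp$family[cmp$best] == "tweedie"))
  # delta AIC non-negative with exactly one zero per season
  expect_true(all(cmp$delta_aic >= 0))
  expect_equal(sum(spring$delta_aic == 0), 1)
})

test_that("comparing fitted models attaches QQ data and self-delta 0", {
  dat <- make_segment_data(300, f = function(z) 0.5 * z, seed = 67)
  fit <- fit_dsm(dat, "z", family = "tweedie", season = "spring")
  cmp <- compare_dsm(list(fit))
  expect_equal(cmp$delta_aic, 0)
  qq <- attr(cmp, "qq")
  expect_length(qq, 1)
  expect_equal(nrow(qq[[1]]), 300)
  expect_true(all(diff(qq[[1]]$residual) >= 0))
})

test_that("tweedie beats the negative binomial on compound-Poisson data", {
  # family comparison should prefer tweedie for thinned-count noise
  wins <- vapply(1:12, function(r) {
    dat <- make_segment_data(250, f = function(z) 0.6 * z, seed = 600 + r)
    tw <- fit_dsm(dat, "z", family = "tweedie")
    nb <- suppressWarnings(fit_dsm(dat, "z", family = "negative_binomial"))
    cmp <- compare_dsm(list(tw, nb))
    cmp$family[cmp$best][1] == "tweedie"
  }, logical(1))
  expect_gte(mean(wins), 0.7)
})
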