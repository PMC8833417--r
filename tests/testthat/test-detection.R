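test_that("truncation applies the distance rule and reports discards", {
  obs <- tibble::tibble(distance_m = c(0.2, 1.4, 1.6))
  out <- truncate_distances(obs, 1.5)
  expect_equal(out$distance_m, c(0.2, 1.4))
  expect_equal(attr(out, "n_discarded"), 1)

  all_in <- tibble::tibble(distance_m = c(0.1, 0.5))
  expect_equal(truncate_distances(all_in, 1.5)$distance_m, all_in$distance_m)
  expect_warning(truncate_distances(tibble::tibble(distance_m = numeric()),
                                    1.5), "empty")
  expect_error(truncate_distances(obs, -1), "> 0")
})

test_that("observer grouping follows the greedy effort-ordered rule", {
  # one observer with enough detections forms one group
  one <- tibble::tibble(observer = rep("a", 100))
  g1 <- assign_observer_groups(one, c(a = 1000))
  expect_equal(unique(g1$observer_group), "G1")

  # hand-traced greedy accumulation: detections (80, 40, 40, 30) by
  # descending effort -> groups {o1}, {o2, o3, o4} (trailing merge)
  obs <- tibble::tibble(observer = rep(c("o1", "o2", "o3", "o4"),
                                       c(80, 40, 40, 30)))
  eff <- c(o1 = 4000, o2 = 3000, o3 = 2000, o4 = 1000)
  g <- assign_observer_groups(obs, eff, min_detections = 70)
  tab <- table(g$observer, g$observer_group)
  expect_equal(unname(g$observer_group[g$observer == "o1"][1]), "G1")
  expect_true(all(g$observer_group[g$observer %in% c("o2", "o3", "o4")] == "G2"))
  counts <- table(g$observer_group)
  expect_true(all(counts >= 70))

  # too few detections in total: single group with a warning
  few <- tibble::tibble(observer = rep(c("a", "b"), c(10, 5)))
  expect_warning(gg <- assign_observer_groups(few, c(a = 10, b = 5)),
                 "single group")
  expect_equal(unique(gg$observer_group), "G1")
})

test_that("key functions satisfy g(0) = 1 and the flat-detection limit", {
  expect_equal(det_g(0, sigma = 0.3, key = "hazard_rate", shape = 4), 1)
  expect_equal(det_g(0, sigma = 2, key = "half_normal"), 1)
  # sigma >> w: the model's average detection probability approaches 1
  p_flat <- pelletdsm:::mu_integral(50, "half_normal", NULL, 1.5) / 1.5
  expect_gt(p_flat, 0.999)
})

test_that("half-normal scale is recovered from simulated distances", {
  set.seed(31)
  obs <- tibble::tibble(distance_m = r_halfnormal_distances(2000, 0.6, 1.5))
  f <- fit_detection_function(obs, key = "half_normal", w = 1.5)
  expect_true(f$converged)
  sigma_hat <- exp(unname(f$beta[1]))
  expect_lt(abs(sigma_hat - 0.6) / 0.6, 0.10)
  expect_equal(f$aic, -2 * f$loglik + 2 * f$npar)
})

test_that("fitted half-normal p-bar equals its closed form to 1e-6", {
  set.seed(32)
  obs <- tibble::tibble(distance_m = r_halfnormal_distances(500, 0.5, 1.5))
  f <- fit_detection_function(obs, key = "half_normal", w = 1.5)
  s <- exp(unname(f$beta[1]))
  erf <- function(z) 2 * pnorm(z * sqrt(2)) - 1
  closed <- s * sqrt(pi / 2) * erf(1.5 / (s * sqrt(2))) / 1.5
  expect_equal(f$p_bar, closed, tolerance = 1e-6)
})

test_that("average detection probability matches the quadrature oracle", {
  # oracle: (1/w) * integral of exp(-x^2 / (2 sigma^2)) over [0, w]
  oracle <- integrate(function(x) exp(-x^2 / (2 * 0.6^2)), 0, 1.5)$value / 1.5
  expect_equal(oracle, 0.495, tolerance = 0.001)
  set.seed(33)
  obs <- tibble::tibble(distance_m = r_halfnormal_distances(3000, 0.6, 1.5))
  f <- fit_detection_function(obs, key = "half_normal", w = 1.5)
  expect_lt(abs(f$p_bar - oracle), 0.03)
  expect_gt(f$cv_p, 0)
})

test_that("the optimum beats random parameter perturbations", {
  set.seed(34)
  obs <- tibble::tibble(distance_m = r_hazard_distances(400, 0.5, 2.5, 1.5))
  f <- fit_detection_function(obs, key = "hazard_rate", w = 1.5)
  nll_opt <- -f$loglik
  for (i in 1:20) {
    pert <- f$par + rnorm(length(f$par), 0, 0.15)
    nll_pert <- pelletdsm:::det_negloglik(
      pert, obs$distance_m, matrix(1, nrow(obs), 1), "hazard_rate", 1.5,
      "none", integer())
    expect_gte(nll_pert, nll_opt - 1e-6)
  }
})

test_that("scale covariates shift sigma by observer group", {
  set.seed(35)
  x1 <- r_halfnormal_distances(400, 0.4, 1.5)
  x2 <- r_halfnormal_distances(400, 0.8, 1.5)
  obs <- tibble::tibble(distance_m = c(x1, x2),
                        observer_group = rep(c("G1", "G2"), each = 400))
  f <- fit_detection_function(obs, covariates = "observer_group",
                              key = "half_normal", w = 1.5)
  expect_true(f$converged)
  s1 <- exp(unname(f$beta[1]))
  s2 <- exp(unname(f$beta[1] + f$beta[2]))
  expect_lt(abs(s1 - 0.4) / 0.4, 0.15)
  expect_lt(abs(s2 - 0.8) / 0.8, 0.15)
  expect_error(fit_detection_function(obs, covariates = "observer_group",
                                      adjustment = "cosine", w = 1.5),
               "without scale covariates")
})

test_that("model selection takes the AIC argmin, ties to fewer parameters", {
  set.seed(36)
  obs <- tibble::tibble(distance_m = r_halfnormal_distances(400, 0.6, 1.5))
  hn <- fit_detection_function(obs, key = "half_normal", w = 1.5)
  hr <- fit_detection_function(obs, key = "hazard_rate", w = 1.5)
  best <- select_detection_model(list(hn, hr))
  ladder <- attr(best, "aic_ladder")
  expect_equal(best$aic, min(ladder$aic))
  expect_true(all(ladder$delta_aic >= 0))
  expect_equal(sum(ladder$delta_aic == 0), 1)
  # tie-break on parameters
  fake_a <- hn; fake_b <- hr
  fake_b$aic <- fake_a$aic
  picked <- select_detection_model(list(fake_b, fake_a))
  expect_equal(picked$npar, min(fake_a$npar, fake_b$npar))
  expect_error(select_detection_model(list()), "no fits")
})

test_that("the AIC ladder is invariant to observation order", {
  set.seed(37)
  obs <- tibble::tibble(distance_m = r_halfnormal_distances(300, 0.5, 1.5))
  shuffled <- obs[sample(nrow(obs)), , drop = FALSE]
  f1 <- fit_detection_function(obs, key = "half_normal", w = 1.5)
  f2 <- fit_detection_function(shuffled, key = "half_normal", w = 1.5)
  expect_equal(f1$aic, f2$aic, tolerance = 1e-6)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
})

test_that("adjustment-series fits are monotonicity-checked", {
  set.seed(38)
  obs <- tibble::tibble(distance_m = r_halfnormal_distances(500, 0.6, 1.5))
  f <- fit_detection_function(obs, key = "half_normal",
                              adjustment = "cosine", orders = 2, w = 1.5)
  # either a valid monotone adjusted fit or an explicit rejection flag
  if (f$converged) {
    xx <- seq(0, 1.5, length.out = 100)
    gg <- pelletdsm:::g_eval(xx, exp(f$beta[1]), "half_normal", NULL, 1.5,
                             "cosine", f$orders, f$adj_coefs)
    expect_true(all(diff(gg) <= 1e-8))
    expect_true(all(gg >= 0))
  } else {
    expect_match(f$reason, "monotonic")
  }
})
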