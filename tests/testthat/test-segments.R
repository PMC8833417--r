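test_that("segments partition transects exactly at transition points", {
  tr <- tibble::tibble(transect_id = "T001", quadrant_id = "Q1",
                       x_start = 0, y_start = 0, x_end = 200, y_end = 0,
                       length_m = 200, design = "designed",
                       stratum = "woodland")
  # no transitions: a single 200-m segment
  s0 <- build_segments(tr, NULL, w = 1.5)
  expect_equal(nrow(s0), 1)
  expect_equal(s0$length_m, 200)
  expect_equal(s0$area_m2, 600)

  trans <- tibble::tibble(transect_id = "T001",
                          position_m = c(0, 50, 120),
                          cover_class = c("bare", "grass_forb", "shrub_lt30"))
  s <- build_segments(tr, trans, w = 1.5)
  expect_equal(s$length_m, c(50, 70, 80))
  expect_equal(s$cover_class, c("bare", "grass_forb", "shrub_lt30"))
  expect_equal(sum(s$length_m), 200)
  expect_equal(s$x, c(25, 85, 160))

  bad <- tibble::tibble(transect_id = "T001", position_m = c(0, 250),
                        cover_class = c("bare", "bare"))
  expect_error(build_segments(tr, bad), "beyond the end")
})

test_that("segment lengths are conserved over a synthetic survey", {
  land <- tiny_landscape(51)
  tr <- design_survey(land, list(mode = "designed", n_transects = 15,
                                 margin_m = 300), 3)
  trans <- transect_transitions(tr, land)
  seg <- build_segments(tr, trans, w = 1.5)
  expect_equal(sum(seg$length_m), sum(tr$length_m))
  expect_equal(seg$area_m2, 2 * 1.5 * seg$length_m)
  # each transect partitions independently
  by_tr <- tapply(seg$length_m, seg$transect_id, sum)
  expect_true(all(abs(by_tr - 200) < 1e-9))
})

test_that("strip areas follow A = 2 w l", {
  expect_equal(segment_area(200, 1.5), 600)
  expect_equal(segment_area(3, 1.5), 9)
  # a full survey of 512 transects of 200 m covers 307,200 m^2
  expect_equal(sum(segment_area(rep(200, 512), 1.5)), 307200)
  expect_error(segment_area(10, 0), "> 0")
})

test_that("buffer extraction matches brute-force disk enumeration", {
  land <- tiny_landscape(52, 3000, 100)
  pts <- tibble::tibble(x = c(1500, 900, 2100), y = c(1500, 1300, 1800))
  got <- extract_buffer_covariates(pts, land, radius_m = 500)
  kinds <- attr(land, "kinds")
  for (i in seq_len(nrow(pts))) {
    inside <- which(sqrt((land$x - pts$x[i])^2 + (land$y - pts$y[i])^2) <= 500)
    for (cv in landscape_covariates(land)) {
      expected <- mean(land[[cv]][inside]) *
        (if (kinds[[cv]] == "fraction") 100 else 1)
      expect_equal(got[[cv]][i], expected)
    }
  }
  # fraction covariates are percentages
  expect_true(all(got$coniferous >= 0 & got$coniferous <= 100))
  # buffers falling off the grid are an error naming the point
  far <- tibble::tibble(x = 100, y = 100)
  expect_error(extract_buffer_covariates(far, land, 500), "exceeds")
})

test_that("a constant grid gives the constant as buffer mean", {
  land <- tiny_landscape(53, 2000, 100)
  land$edge_proximity <- 7
  pts <- tibble::tibble(x = c(800, 1200), y = c(1000, 900))
  got <- extract_buffer_covariates(pts, land, 500)
  expect_equal(got$edge_proximity, c(7, 7))
})

test_that("land-cover reclassification preserves composition", {
  raw <- tidyr::expand_grid(x = seq(50, 950, 100), y = seq(50, 950, 100))
  set.seed(2)
  raw$raw_class <- sample(c("c311", "c312", "c211", "c231"), nrow(raw),
                          replace = TRUE)
  # identity mapping reproduces one-hot layers
  idmap <- c(c311 = "c311", c312 = "c312", c211 = "c211", c231 = "c231")
  one_hot <- reclassify_landcover(raw, idmap)
  expect_equal(one_hot$c311, as.numeric(raw$raw_class == "c311"))

  # two raw classes onto one target add up
  mapping <- c(c311 = "coniferous", c312 = "coniferous",
               c211 = "arable", c231 = "grass_and_shrubs")
  out <- reclassify_landcover(raw, mapping)
  expect_equal(out$coniferous, one_hot$c311 + one_hot$c312)
  # compositional closure
  sums <- rowSums(as.matrix(out[setdiff(names(out), c("x", "y"))]))
  expect_true(all(sums == 1))
  expect_error(reclassify_landcover(raw, mapping[-1]), "unmapped")
})

test_that("collinearity filter drops the lower-priority of a conflicted pair", {
  set.seed(3)
  n <- 200
  a <- rnorm(n)
  tab <- tibble::tibble(temp = a, elev = a + rnorm(n, 0, 0.1),
                        forest = rnorm(n), precip = rnorm(n))
  keep <- filter_collinear(tab, c("temp", "forest", "precip", "elev"))
  expect_false("elev" %in% keep)  # correlated with higher-priority temp
  expect_setequal(as.character(keep), c("temp", "forest", "precip"))
  log <- attr(keep, "drop_log")
  expect_equal(log$dropped, "elev")
  expect_equal(log$kept_instead, "temp")
  expect_gt(abs(log$r), 0.7)

  # independent noise columns are all retained
  noise <- tibble::tibble(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  expect_equal(as.character(filter_collinear(noise, c("a", "b", "c"))),
               c("a", "b", "c"))

  # exact duplicate: r = 1, lower-priority copy dropped
  dup <- tibble::tibble(u = a, v = a)
  expect_equal(as.character(filter_collinear(dup, c("u", "v"))), "u")

  # zero-variance covariate dropped with a warning
  zv <- tibble::tibble(u = a, w = rep(1, n))
  expect_warning(kz <- filter_collinear(zv, c("u", "w")), "zero-variance")
  expect_equal(as.character(kz), "u")
})

test_that("the filter result is invariant to column order", {
  set.seed(4)
  n <- 150
  a <- rnorm(n)
  tab <- tibble::tibble(p1 = a, p2 = a + rnorm(n, 0, 0.05), p3 = rnorm(n))
  pri <- c("p1", "p2", "p3")
  k1 <- filter_collinear(tab, pri)
  k2 <- filter_collinear(tab[, c("p3", "p2", "p1")], pri)
  expect_equal(as.character(k1), as.character(k2))
})
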