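test_that("focal statistics are exact against brute-force window enumeration", {
  r <- rsf_raster(matrix(0, 9, 9), res = 30)
  r$values[5, 5] <- 1
  # radius of one cell -> the 5-cell discrete plus
  expect_equal(sum(circle_kernel(30, 30)), 5)
  fr <- focal_statistic(r, 30, "fraction", class = 1)
  expect_equal(fr$values[4, 5], 1 / 5)
  expect_equal(fr$values[5, 5], 1 / 5)
  expect_equal(fr$values[5, 6], 1 / 5)
  expect_equal(fr$values[3, 5], 0)

  set.seed(2)
  v <- matrix(rnorm(15 * 15), 15, 15)
  v[4, 7] <- NA
  rr <- rsf_raster(v, res = 30)
  for (rad in c(30, 65, 95)) {
    expect_equal(focal_statistic(rr, rad, "mean")$values,
                 brute_focal(v, 30, rad), tolerance = 1e-8)
  }
  # constants are idempotent
  cr <- rsf_raster(matrix(3.7, 8, 8), res = 30)
  expect_equal(focal_statistic(cr, 100, "mean")$values, cr$values,
               tolerance = 1e-10)
})

test_that("study radii window populations match exhaustive distance counts", {
  for (rad in c(167.9, 439.5, 1451.7)) {
    R <- floor(rad / 30)
    cnt <- 0L
    for (a in -R:R) for (b in -R:R) {
      if (30 * sqrt(a^2 + b^2) <= rad) cnt <- cnt + 1L
    }
    expect_equal(sum(circle_kernel(rad, 30)), cnt)
  }
  expect_error(circle_kernel(10, 30), "at least one cell")
})

test_that("distance covariates are exact, monotone and 1-Lipschitz", {
  gr <- rsf_raster(matrix(0, 5, 5), res = 1)
  # feature point on the center cell's center
  pts <- list(points = cbind(2.5, 2.5))
  d <- distance_covariate(pts, gr, "linear")
  hand <- outer(1:5, 1:5, function(i, j) {
    sqrt((j - 0.5 - 2.5)^2 + ((5 - i + 0.5) - 2.5)^2)
  })
  expect_equal(d$values * 1000, hand, tolerance = 1e-9)
  expect_equal(min(d$values), 0)
  dec <- distance_covariate(pts, gr, "decay", decay_m = 2)
  expect_equal(max(dec$values), 1)
  expect_equal(dec$values, exp(-hand / 2), tolerance = 1e-9)
  # decay decreases with distance
  expect_true(all(diff(dec$values[3, 3:5]) < 0))
  # Lipschitz: neighbouring linear distances differ by at most one cell
  dx <- abs(diff(t(d$values))) * 1000
  expect_true(all(dx <= 1 + 1e-9))
  expect_error(distance_covariate(list(), gr, "linear"), "empty feature")
})

test_that("mask-based distance transform agrees with brute force", {
  set.seed(8)
  m <- matrix(runif(144) < 0.08, 12, 12)
  m[3, 4] <- TRUE
  gr <- rsf_raster(matrix(0, 12, 12), res = 30)
  d <- feature_distance(list(masks = list(m)), gr)
  idx <- which(m, arr.ind = TRUE)
  brute <- matrix(NA_real_, 12, 12)
  for (i in 1:12) for (j in 1:12) {
    brute[i, j] <- 30 * min(sqrt((idx[, 1] - i)^2 + (idx[, 2] - j)^2))
  }
  expect_equal(d$values, brute, tolerance = 1e-6)
})

test_that("TPI excludes the center and matches window means on a ramp", {
  dem <- rsf_raster(outer(1:7, 1:7, function(i, j) 10 * j), res = 30)
  t1 <- tpi(dem, 30)
  # interior: neighbours at -10, +10 horizontally and 0, 0 vertically
  expect_equal(t1$values[4, 4], 0)
  expect_equal(t1$values[4, 1], 10 * 1 - (10 * 1 + 10 * 1 + 10 * 2) / 3)
  flat <- rsf_raster(matrix(5, 6, 6), res = 30)
  expect_true(all(abs(tpi(flat, 60)$values) < 1e-10))
  peak <- rsf_raster(matrix(0, 5, 5), res = 30)
  peak$values[3, 3] <- 100
  tp <- tpi(peak, 30)
  expect_gt(tp$values[3, 3], 0)
  expect_lt(tp$values[3, 4], 0)
})

test_that("Riley roughness: flat zero, exact 3x3 values, shift-invariant", {
  flat <- rsf_raster(matrix(7, 6, 6), res = 30)
  expect_true(all(roughness(flat, 0)$values == 0))
  # parity checkerboard: the four rook neighbours differ by 1, diagonals match
  cb <- rsf_raster(outer(1:8, 1:8, function(i, j) (i + j) %% 2), res = 30)
  tri <- roughness(cb, 0)
  expect_equal(tri$values[4, 4], sqrt(4))
  # an isolated unit peak differs from all eight neighbours
  pk <- rsf_raster(matrix(0, 5, 5), res = 30)
  pk$values[3, 3] <- 1
  expect_equal(roughness(pk, 0)$values[3, 3], sqrt(8))
  shifted <- rsf_raster(cb$values + 123.4, res = 30)
  expect_equal(roughness(shifted, 0)$values, tri$values, tolerance = 1e-9)
})

test_that("land-cover variety and edge counts match exhaustive enumeration", {
  set.seed(5)
  lc <- rsf_raster(matrix(sample(1:3, 49, replace = TRUE), 7, 7), res = 30)
  het <- landcover_heterogeneity(lc, 65)
  R <- 65 / 30
  v <- lc$values
  for (i in c(1, 4, 7)) for (j in c(2, 4, 6)) {
    inwin <- function(a, b) 30 * sqrt((a - i)^2 + (b - j)^2) <= 65 + 1e-9
    seen <- c(); edges <- 0L
    for (a in 1:7) for (b in 1:7) {
      if (inwin(a, b)) {
        seen <- union(seen, v[a, b])
        if (b < 7 && inwin(a, b + 1) && v[a, b] != v[a, b + 1]) edges <- edges + 1L
        if (a < 7 && inwin(a + 1, b) && v[a, b] != v[a + 1, b]) edges <- edges + 1L
      }
    }
    expect_equal(het$variety$values[i, j], length(seen))
    expect_equal(het$edges$values[i, j], edges)
  }
  uni <- rsf_raster(matrix(2, 6, 6), res = 30)
  h2 <- landcover_heterogeneity(uni, 60)
  expect_true(all(h2$variety$values == 1))
  expect_true(all(h2$edges$values == 0))
  # two-class half plane: window straddling the boundary sees both
  hp <- rsf_raster(cbind(matrix(1, 6, 3), matrix(2, 6, 3)), res = 30)
  h3 <- landcover_heterogeneity(hp, 60)
  expect_equal(h3$variety$values[3, 3], 2)
})

test_that("nodata propagates through focal operators without becoming zero", {
  v <- matrix(1:36, 6, 6) * 1.0
  v[3, 3] <- NA
  r <- rsf_raster(v, res = 30)
  fm <- focal_statistic(r, 30, "mean")
  expect_true(is.na(fm$values[3, 3]))
  # neighbour means exclude the nodata cell rather than treating it as 0
  expect_equal(fm$values[2, 3], mean(v[cbind(c(1, 2, 2, 2), c(3, 2, 3, 4))],
                                     na.rm = TRUE))
})

test_that("covariate stack builder dispatches every declared form", {
  L <- tiny_landscape(seed = 12, n = 24)
  specs <- rbind(
    covariate_spec("h_mean", "herbaceous", "focal-mean", 90),
    covariate_spec("sage_frac", "landcover", "focal-fraction", 90,
                   class = L$legend[["sagebrush"]]),
    covariate_spec("spr_km", "springs", "linear-distance"),
    covariate_spec("spr_dec", "springs", "exp-decay-distance", 500),
    covariate_spec("elev_km", "elevation", "elevation-km"),
    covariate_spec("tpi_510", "elevation", "tpi", 510),
    covariate_spec("rough", "elevation", "roughness", 56.4),
    covariate_spec("variety", "landcover", "variety", 90),
    covariate_spec("edges", "landcover", "edge-variety", 90)
  )
  stack <- build_covariates(L, specs)
  expect_named(stack, specs$name)
  expect_true(all(vapply(stack, function(r) identical(dim(r$values), c(24L, 24L)), TRUE)))
  expect_true(all(stack$sage_frac$values >= 0 & stack$sage_frac$values <= 1))
  expect_equal(stack$elev_km$values, L$continuous$elevation$values / 1000)
  expect_error(covariate_spec("x", "y", "focal-mean", scale = -5), "positive")
})
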