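test_that("season assignment matches the calendar windows and is total", {
  expect_equal(assign_season(as.Date("2010-04-01")), "spring")
  expect_equal(assign_season(as.Date("2010-03-16")), "spring")
  expect_equal(assign_season(as.Date("2010-03-15")), "winter")
  expect_equal(assign_season(as.Date("2010-06-30")), "spring")
  expect_equal(assign_season(as.Date("2010-07-01")), "summer_fall")
  expect_equal(assign_season(as.Date("2010-10-15")), "summer_fall")
  expect_equal(assign_season(as.Date("2010-10-16")), "winter")
  expect_equal(assign_season(as.Date("2011-02-14")), "winter")
  days <- seq(as.Date("2012-01-01"), as.Date("2012-12-31"), by = 1)
  lab <- assign_season(days)
  expect_true(all(lab %in% c("spring", "summer_fall", "winter")))
  expect_equal(as.vector(table(lab)[c("spring", "summer_fall")]), c(107, 107))
  # winter season-year: early-winter keeps the year, late-winter the previous
  expect_equal(season_year(as.Date("2011-11-01")), 2011)
  expect_equal(season_year(as.Date("2012-02-01")), 2011)
  expect_equal(season_year(as.Date("2012-05-01")), 2012)
})

test_that("site-season screen applies both thresholds inclusively", {
  counts <- data.frame(site = c("a", "b", "c", "d"), season = "spring",
                       n_birds = c(19, 20, 25, 20),
                       n_locs = c(5000, 100, 99, 100))
  sc <- screen_site_seasons(counts)
  expect_equal(sc$eligible, c(FALSE, TRUE, FALSE, TRUE))
  # the published counts: 53 birds with 62 winter locations is excluded
  pub <- pmu_season_counts()
  pub <- screen_site_seasons(pub[, c("pmu", "season", "n_birds", "n_locs")] |>
                               stats::setNames(c("site", "season", "n_birds", "n_locs")))
  vm <- pub[pub$site == "Virginia Mtns" & pub$season == "winter", ]
  expect_false(vm$eligible)
  expect_true(pub$eligible[pub$site == "Virginia Mtns" & pub$season == "spring"])
})

test_that("buffered MCP obeys the exact convex-dilation area formula", {
  tri <- rbind(c(0, 0), c(1, 0), c(0, 1))
  expect_equal(polygon_area(availability_extent(tri, buffer_m = 0)), 0.5)
  set.seed(3)
  pts <- cbind(runif(200, 0, 5000), runif(200, 0, 3000))
  b <- 1451
  ext <- availability_extent(pts, buffer_m = b)
  hull <- attr(ext, "hull")
  A <- polygon_area(hull)
  P <- sum(sqrt(rowSums((hull[-1, ] - hull[-nrow(hull), ])^2)))
  expect_equal(polygon_area(ext), A + P * b + pi * b^2, tolerance = 0.01)
  # every used point strictly inside the buffered polygon
  expect_true(all(in_polygon(ext, pts)))
  expect_error(availability_extent(rbind(c(0, 0), c(1, 1), c(2, 2))), "hull")
})

test_that("available points are uniform over the extent at the declared ratio", {
  poly <- rbind(c(0, 0), c(4000, 0), c(4000, 4000), c(0, 4000), c(0, 0))
  pts <- sample_available(poly, n_used = 100, ratio = 5, seed = 4)
  expect_equal(nrow(pts), 500)
  expect_true(all(in_polygon(poly, pts)))
  expect_identical(pts, sample_available(poly, 100, 5, seed = 4))
  big <- sample_available(poly, n_used = 10000, ratio = 5, seed = 9)
  cnt <- table(cut(big[, 1], seq(0, 4000, 1000)),
               cut(big[, 2], seq(0, 4000, 1000)))
  expect_gt(stats::chisq.test(as.vector(cnt))$p.value, 0.01)
})

test_that("class weights balance the two response masses exactly", {
  for (ratio in c(1, 5, 10)) {
    tab <- data.frame(used = rep(c(1, 0), c(20, 20 * ratio)))
    tab <- assign_weights(tab, ratio)
    expect_equal(unique(tab$weight[tab$used == 0]), 1 / ratio)
    expect_equal(unique(tab$weight[tab$used == 1]), 1)
    expect_identical(sum(tab$weight[tab$used == 1]),
                     sum(tab$weight[tab$used == 0]))
  }
})

test_that("rare-cover screen drops classes at or below 0.1% strictly", {
  v <- matrix(1, 40, 25)  # exactly 1000 cells
  v[1, 1] <- 2            # exactly 0.1%
  v[2, 1:2] <- 3          # 0.2%
  lc <- rsf_raster(v, res = 30)
  poly <- rbind(c(0, 0), c(750, 0), c(750, 1200), c(0, 1200), c(0, 0))
  sc <- screen_rare_covers(lc, poly, threshold = 0.001)
  expect_equal(sc$fraction[sc$class == 2], 0.001)
  expect_false(sc$admissible[sc$class == 2])
  expect_true(sc$admissible[sc$class == 3])
  expect_false(4 %in% sc$class)
  # hand-counted toy fractions
  expect_equal(sc$fraction[sc$class == 1], 997 / 1000)
})

test_that("bird split is a largest-remainder bird-level partition", {
  sp <- split_by_bird(sprintf("b%02d", 1:10), seed = 1)
  expect_equal(lengths(sp), c(train = 8L, classify = 1L, validate = 1L))
  for (n in c(3, 7, 23, 28, 101)) {
    ids <- sprintf("x%03d", seq_len(n))
    sp <- split_by_bird(ids, seed = n)
    expect_setequal(unlist(sp), ids)
    expect_equal(sum(duplicated(unlist(sp))), 0)
    expect_true(all(abs(lengths(sp) - n * c(0.8, 0.1, 0.1)) <= 1))
  }
  expect_error(split_by_bird(c("a", "b")), "at least")
})

test_that("used-available table has exact 5:1 structure and balanced mass", {
  L <- tiny_landscape(seed = 21, n = 30)
  tr <- tiny_truth(L, beta_vals = c(1, 0))
  tel <- generate_telemetry(L, tr, n_birds = 8, locs_per_bird = 40, seed = 2)
  stack <- build_covariates(L, tr$covariates)
  ext <- availability_extent(cbind(tel$x, tel$y), buffer_m = 300)
  tab <- build_ua_table(tel, ext, stack, ratio = 5, seed = 3)
  expect_equal(sum(tab$used == 0), 5 * sum(tab$used == 1))
  expect_identical(sum(tab$weight[tab$used == 1]),
                   sum(tab$weight[tab$used == 0]))
  # covariates standardized on the availability rows
  av <- tab[tab$used == 0, ]
  expect_equal(mean(av$herb_loc), 0, tolerance = 1e-10)
  expect_equal(sd(av$herb_loc), 1, tolerance = 1e-10)
  expect_true(all(is.finite(as.matrix(tab[, c("herb_loc", "elev_km")]))))
  # available rows inherit their parent's bird label
  expect_setequal(unique(tab$bird[tab$used == 0]), unique(tel$bird_id))
})
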