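test_that("AICc matches the closed form and its limits", {
  expect_equal(aicc(-50, 2, 100), 104 + 12 / 97)
  # correction vanishes as n grows: AICc -> AIC
  expect_equal(aicc(-50, 2, 1e9), 104, tolerance = 1e-6)
  expect_lt(aicc(-50, 2, 1e9), aicc(-50, 2, 50))
  ns <- c(20, 50, 200, 1000)
  expect_true(all(diff(vapply(ns, function(n) aicc(-10, 3, n), 0)) < 0))
  expect_error(aicc(-10, 5, 6), "n > k")
})

test_that("degenerate random effects reduce to the weighted GLM", {
  tab <- sim_glmm_table(n_used = 300, sigma_bird = 0, seed = 3)
  tab$weight <- ifelse(tab$used == 1, 1, 0.2)
  fit <- fit_weighted_glmm(tab, c("x1", "x2"), engine = "auto")
  ref <- suppressWarnings(stats::glm(used ~ x1 + x2, binomial, tab,
                                     weights = tab$weight))
  expect_equal(fit$engine, "glm")  # boundary fallback engaged
  expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-6)
  # parameter count still includes the variance components of the contract
  expect_equal(fit$k, 3 + 2)
})

test_that("intercept is near zero on a balanced 5:1 weighted null table", {
  set.seed(4)
  n <- 600
  tab <- data.frame(used = rep(c(1, 0), c(n, 5 * n)),
                    weight = rep(c(1, 0.2), c(n, 5 * n)),
                    bird = sample(sprintf("b%02d", 1:20), 6 * n, TRUE),
                    year = sample(c("a", "b"), 6 * n, TRUE))
  fit <- fit_weighted_glmm(tab, character(), engine = "auto")
  expect_lt(abs(fit$coef[["(Intercept)"]]), 0.05)
})

test_that("the mixed engine recovers known coefficients with real bird effects", {
  hits <- 0L; total <- 0L
  for (s in 1:12) {
    tab <- sim_glmm_table(n_used = 350, n_birds = 25, sigma_bird = 0.5, seed = s)
    fit <- fit_weighted_glmm(tab, c("x1", "x2"), engine = "glmm")
    expect_true(fit$converged)
    z <- abs(fit$coef[c("x1", "x2")] - c(0.8, -1.2)) / fit$se[c("x1", "x2")]
    hits <- hits + sum(z <= 3); total <- total + 2L
  }
  expect_gte(hits / total, 0.95)
})

test_that("scale selection keeps the best candidate only if it beats the null by 2", {
  set.seed(10)
  n <- 500
  x <- rnorm(6 * n)
  tab <- data.frame(used = rep(c(1, 0), c(n, 5 * n)),
                    weight = rep(c(1, 0.2), c(n, 5 * n)),
                    bird = sample(sprintf("b%02d", 1:20), 6 * n, TRUE),
                    year = "y1",
                    strong = NA, weak = NA, noise = rnorm(6 * n))
  # construct signal: strong covariate separates classes, weak barely
  tab$strong <- x + tab$used * 1.0
  tab$weak <- rnorm(6 * n) + tab$used * 0.12
  null_fit <- fit_weighted_glmm(tab, character(), engine = "glm")
  s <- select_scale(tab, c("strong", "weak"), null_fit, engine = "glm")
  expect_equal(s$chosen, "strong")
  expect_gte(s$delta_null, 2)
  s2 <- select_scale(tab, "noise", null_fit, engine = "glm")
  expect_true(is.na(s2$chosen))
})

test_that("correlation screen resolves collinear sets by dropping higher AICc", {
  set.seed(11)
  n <- 400
  a <- rnorm(n); b <- a + rnorm(n, 0, 0.1); c_ <- a + rnorm(n, 0, 0.2)
  d <- rnorm(n)
  dat <- data.frame(a = a, b = b, c = c_, d = d, dup = a)
  aiccs <- c(a = 100, b = 105, c = 103, d = 99, dup = 101)
  # duplicated column: exactly one survives
  sc <- correlation_screen(dat, c("a", "dup"), aiccs)
  expect_equal(sc$keep, "a")
  # r = 0 pair: both kept
  sc2 <- correlation_screen(dat, c("a", "d"), aiccs)
  expect_setequal(sc2$keep, c("a", "d"))
  # three mutually correlated: greedy oracle keeps only the lowest-AICc member
  sc3 <- correlation_screen(dat, c("a", "b", "c"), aiccs, cutoff = 0.65)
  oracle <- local({
    keep <- c("a", "b", "c")
    repeat {
      C <- abs(cor(dat[, keep, drop = FALSE])); diag(C) <- 0
      if (max(C) < 0.65 || length(keep) < 2) break
      ij <- which(C == max(C), arr.ind = TRUE)[1, ]
      keep <- setdiff(keep, keep[ij][which.max(aiccs[keep[ij]])])
    }
    keep
  })
  expect_equal(sc3$keep, oracle)
  expect_equal(sc3$keep, "a")
})

test_that("pairwise model sets have choose(m, 2) members covering each covariate m-1 times", {
  tab <- sim_glmm_table(n_used = 120, sigma_bird = 0, seed = 5)
  tab$x3 <- rnorm(nrow(tab)); tab$x4 <- rnorm(nrow(tab)); tab$x5 <- rnorm(nrow(tab))
  cols <- c("x1", "x2", "x3", "x4", "x5")
  fits <- pairwise_model_set(tab, cols, engine = "glm")
  expect_length(fits, choose(5, 2))
  appearances <- table(unlist(lapply(fits, function(f) f$covariates)))
  expect_true(all(appearances == 4))
  expect_length(pairwise_model_set(tab, c("x1", "x2"), engine = "glm"), 1L)
})

test_that("model averaging reproduces hand-computed weights and Buckland SEs", {
  # three-model toy: printed (AICc via loglik/k/n, beta, SE) triples
  n <- 1000
  mk <- function(ll, b, s, nm) {
    fit_stub(coef = c("(Intercept)" = 0, x = b), se = c("(Intercept)" = 1, x = s),
             loglik = ll, k = 2, n = n, covariates = "x")
  }
  fits <- list(mk(-100, 0.50, 0.10), mk(-101, 0.70, 0.12), mk(-103, 0.40, 0.20))
  av <- model_average(fits)
  a <- vapply(fits, function(f) aicc(f$loglik, 2, n), 0)
  d <- a - min(a); w <- exp(-d / 2) / sum(exp(-d / 2))
  bbar <- sum(w * c(0.5, 0.7, 0.4))
  seu <- sum(w * sqrt(c(0.1, 0.12, 0.2)^2 + (c(0.5, 0.7, 0.4) - bbar)^2))
  row <- av[av$term == "x", ]
  expect_equal(row$beta, bbar, tolerance = 1e-10)
  expect_equal(row$se_u, seu, tolerance = 1e-10)
  expect_equal(c(row$lo, row$hi), c(bbar - 1.96 * seu, bbar + 1.96 * seu),
               tolerance = 1e-10)
  # equal AICc -> equal weights
  av2 <- model_average(list(mk(-100, 0.5, 0.1), mk(-100, 0.7, 0.1)))
  expect_equal(attr(av2, "models")$weight, c(0.5, 0.5))
  # all models identical -> collapse to (b, s)
  av3 <- model_average(list(mk(-100, 0.5, 0.1), mk(-100, 0.5, 0.1)))
  expect_equal(av3$beta[av3$term == "x"], 0.5)
  expect_equal(av3$se_u[av3$term == "x"], 0.1)
})

test_that("Akaike weights sum to one and ignore AICc shifts; SE_u grows with spread", {
  mk <- function(ll, b, s) fit_stub(c("(Intercept)" = 0, x = b),
                                    c("(Intercept)" = 1, x = s),
                                    loglik = ll, k = 2, n = 500, covariates = "x")
  av1 <- model_average(list(mk(-100, 0.4, 0.1), mk(-102, 0.6, 0.1)))
  av2 <- model_average(list(mk(-90, 0.4, 0.1), mk(-92, 0.6, 0.1)))  # shifted
  expect_equal(sum(attr(av1, "models")$weight), 1)
  expect_equal(attr(av1, "models")$weight, attr(av2, "models")$weight,
               tolerance = 1e-12)
  narrow <- model_average(list(mk(-100, 0.50, 0.1), mk(-100, 0.52, 0.1)))
  wide <- model_average(list(mk(-100, 0.40, 0.1), mk(-100, 0.62, 0.1)))
  expect_gt(wide$se_u[wide$term == "x"], narrow$se_u[narrow$term == "x"])
})

test_that("zero-overlap retention rule keeps and drops the right covariates", {
  av <- data.frame(term = c("(Intercept)", "kept", "dropped"),
                   beta = c(-1, 0.5, 0.1), se_u = c(0.1, 0.1, 0.2))
  av$lo <- av$beta - 1.96 * av$se_u
  av$hi <- av$beta + 1.96 * av$se_u
  fin <- finalize_rsf(av)
  expect_setequal(fin$term, c("(Intercept)", "kept"))
  expect_equal(attr(fin, "excluded"), "dropped")
  all_null <- av[av$term != "kept", ]
  expect_warning(finalize_rsf(all_null), "intercept-only")
})

test_that("rsf() end to end retains the true covariates and drops noise", {
  L <- tiny_landscape(seed = 31, n = 36)
  tr <- tiny_truth(L, beta_vals = c(1.2, -0.8))
  tel <- generate_telemetry(L, tr, n_birds = 15, locs_per_bird = 60, seed = 7)
  stack <- build_covariates(L, tr$covariates)
  ext <- availability_extent(cbind(tel$x, tel$y), buffer_m = 200)
  tab <- build_ua_table(tel, ext, stack, seed = 8)
  set.seed(99)
  tab$noise1 <- rnorm(nrow(tab)); tab$noise2 <- rnorm(nrow(tab))
  f <- rsf(tab, list(herb = "herb_loc", elev = "elev_km",
                     n1 = "noise1", n2 = "noise2"),
           site = "s1", season = "spring", engine = "glm")
  expect_s3_class(f, "rsf")
  expect_true(all(c("herb_loc", "elev_km") %in% f$retained$term))
  expect_false(any(c("noise1", "noise2") %in% f$retained$term))
  # methods
  expect_named(coef(f), c("(Intercept)", f$retained$term))
  expect_output(print(f), "retained")
  pred <- predict(f, stack = stack, type = "hsi")
  expect_true(all(pred$values > 0 & pred$values < 1))
  # prediction on raw newdata equals cellwise raster prediction
  cc <- cell_centers(pred)
  nd <- extract_covariates(stack, cc[1:5, ])
  expect_equal(predict(f, newdata = nd),
               extract_at(predict(f, stack = stack), cc[1:5, ]),
               tolerance = 1e-10)
})
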