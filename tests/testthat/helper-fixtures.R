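# small shared fixtures, all generated in code

tiny_landscape <- function(seed = 42, n = 48, res = 30, n_springs = 6) {
  generate_landscape(seed = seed, n_rows = n, n_cols = n, resolution_m = res,
                     n_springs = n_springs, feature_margin_m = 0)
}

# one-site truth on a small landscape; covariates chosen to be cheap
tiny_truth <- function(landscape, beta_vals = c(1, -1.5),
                       sigma_bird = 0, sigma_year = 0) {
  n <- nrow(landscape$landcover$values)
  ext <- n * landscape$res
  specs <- rbind(
    covariate_spec("herb_loc", "herbaceous", "focal-mean", landscape$res),
    covariate_spec("elev_km", "elevation", "elevation-km")
  )
  sites <- data.frame(site = "s1", subregion = "mesic",
                      xmin = 0, xmax = ext, ymin = 0, ymax = ext)
  b <- stats::setNames(beta_vals, specs$name)
  rsf_truth(list(mesic = list(spring = b, summer_fall = b, winter = b)),
            specs, sites, sigma_bird = sigma_bird, sigma_year = sigma_year)
}

# brute-force focal statistic over a circular window (centers within radius)
brute_focal <- function(vals, res, radius, stat = mean) {
  nr <- nrow(vals); nc <- ncol(vals)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(vals[i, j])) next
    acc <- c()
    for (a in seq_len(nr)) for (b in seq_len(nc)) {
      d <- res * sqrt((a - i)^2 + (b - j)^2)
      if (d <= radius + 1e-9 && !is.na(vals[a, b])) acc <- c(acc, vals[a, b])
    }
    out[i, j] <- stat(acc)
  }
  out
}

# direct Bernoulli GLMM simulation (engine-level check, no landscape)
sim_glmm_table <- function(n_used = 400, ratio = 5, n_birds = 20,
                           beta = c(0.8, -1.2), sigma_bird = 0.5, seed = 1) {
  set.seed(seed)
  n <- n_used * (1 + ratio)
  bird <- sample(sprintf("b%02d", seq_len(n_birds)), n, replace = TRUE)
  b <- stats::setNames(stats::rnorm(n_birds, 0, sigma_bird),
                       sprintf("b%02d", seq_len(n_birds)))
  x1 <- stats::rnorm(n); x2 <- stats::rnorm(n)
  eta <- -1.2 + beta[1] * x1 + beta[2] * x2 + b[bird]
  data.frame(used = stats::rbinom(n, 1, stats::plogis(eta)),
             weight = 1, bird = bird,
             year = sample(c("2011", "2012"), n, replace = TRUE),
             x1 = x1, x2 = x2)
}

# hand-rolled fit stubs for model-averaging oracles
fit_stub <- function(coef, se, loglik, k, n, covariates = names(coef)[-1]) {
  structure(list(coef = coef, se = se, loglik = loglik, k = k, n = n,
                 converged = TRUE, covariates = covariates),
            class = "rsf_glmm")
}
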