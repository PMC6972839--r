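#' True selection model for synthetic telemetry
#'
#' Declares the data-generating habitat-selection truth: per-season fixed
#' effect vectors on standardized covariates for each hydrographic subregion
#' (mesic and xeric), Gaussian random-intercept SDs for bird and year, the
#' covariate definitions the truth acts on, and the per-site availability
#' extents (one rectangle per site; birds never switch sites).
#'
#' @param beta named list `subregion -> season -> named coefficient vector`;
#'   seasons are `spring`, `summer_fall`, `winter`; coefficient names must
#'   match `covariates$name` and share one ordering.
#' @param covariates covariate specification table ([covariate_spec()] rows)
#'   defining the standardized covariates the coefficients act on.
#' @param sites data frame with columns `site`, `subregion`, `xmin`, `xmax`,
#'   `ymin`, `ymax` (metres) giving each site's availability rectangle.
#' @param sigma_bird,sigma_year random-intercept SDs (>= 0).
#' @return an object of class `rsf_truth`.
#' @export
rsf_truth <- function(beta, covariates, sites, sigma_bird = 0.3, sigma_year = 0.2) {
  stopifnot(sigma_bird >= 0, sigma_year >= 0)
  cov_names <- covariates$name
  for (sr in names(beta)) for (ss in names(beta[[sr]])) {
    b <- beta[[sr]][[ss]]
    if (!identical(names(b), cov_names)) {
      stop("coefficient vectors must share the covariate ordering of `covariates`",
           call. = FALSE)
    }
  }
  structure(list(beta = beta, covariates = covariates, sites = sites,
                 sigma_bird = sigma_bird, sigma_year = sigma_year),
            class = "rsf_truth")
}

#' @export
print.rsf_truth <- function(x, ...) {
  cat(sprintf("<rsf_truth> %d sites, sigma_bird = %g, sigma_year = %g\n",
              nrow(x$sites), x$sigma_bird, x$sigma_year))
  for (sr in names(x$beta)) {
    cat(" ", sr, "\n")
    for (ss in names(x$beta[[sr]])) {
      cat(sprintf("    %-12s %s\n", ss,
                  paste(sprintf("%s=%+.2f", names(x$beta[[sr]][[ss]]), x$beta[[sr]][[ss]]),
                        collapse = "  ")))
    }
  }
  invisible(x)
}

# landscape-wide covariate moments, so truth coefficients refer to one fixed
# standardized scale rather than drifting with each site's extent
global_moments <- function(stack) {
  list(mean = vapply(stack, function(r) mean(r$values, na.rm = TRUE), 0),
       sd = vapply(stack, function(r) stats::sd(r$values, na.rm = TRUE), 0))
}

# cells (row/col indices + standardized truth covariates) of one site rectangle
site_cells <- function(stack, grid, site_row, moments) {
  cc <- cell_centers(grid)
  keep <- cc[, 1] >= site_row$xmin & cc[, 1] <= site_row$xmax &
    cc[, 2] >= site_row$ymin & cc[, 2] <= site_row$ymax
  idx <- which(keep)
  X <- vapply(stack, function(r) r$values[idx], numeric(length(idx)))
  X <- as.matrix(X)
  ok <- stats::complete.cases(X)
  idx <- idx[ok]; X <- X[ok, , drop = FALSE]
  if (!length(idx)) stop("site extent contains no valid cells", call. = FALSE)
  X <- sweep(sweep(X, 2, moments$mean[colnames(X)]), 2, moments$sd[colnames(X)], `/`)
  list(idx = idx, X = X, xy = cc[idx, , drop = FALSE])
}

#' Generate synthetic telemetry
#'
#' Each bird is assigned one site and one tracking year; location days are
#' sampled without replacement within the year (one location per bird-day)
#' and dated uniformly. For each location the cell is drawn from the site's
#' availability rectangle with weight `exp(beta_season . x + b_bird + b_year)`
#' evaluated on the standardized truth covariates; used locations snap to
#' cell centers so the sampling distribution is exactly enumerable.
#'
#' @param landscape an `rsf_landscape`.
#' @param truth an [rsf_truth()] object.
#' @param n_birds birds per site (recycled over sites).
#' @param locs_per_bird locations per bird.
#' @param years integer vector of tracking years (e.g. `2011:2012`).
#' @param seed integer seed.
#' @return data frame of telemetry records: `bird_id`, `site`, `subregion`,
#'   `date`, `x`, `y`.
#' @export
generate_telemetry <- function(landscape, truth, n_birds, locs_per_bird,
                               years = 2011:2012, seed = 1) {
  stopifnot(all(n_birds >= 1), all(locs_per_bird >= 1))
  set.seed(seed)
  grid <- grid_of(landscape)
  stack <- build_covariates(landscape, truth$covariates)
  sites <- truth$sites
  n_birds <- rep_len(n_birds, nrow(sites))
  locs_per_bird <- rep_len(locs_per_bird, nrow(sites))
  b_year <- stats::setNames(stats::rnorm(length(years), 0, truth$sigma_year), years)
  moments <- global_moments(stack)
  out <- vector("list", nrow(sites))
  bird_counter <- 0L
  for (i in seq_len(nrow(sites))) {
    srow <- sites[i, ]
    cells <- site_cells(stack, grid, srow, moments)
    betas <- truth$beta[[srow$subregion]]
    eta <- lapply(betas, function(b) drop(cells$X %*% b))
    recs <- vector("list", n_birds[i])
    for (j in seq_len(n_birds[i])) {
      bird_counter <- bird_counter + 1L
      bird <- sprintf("b%04d", bird_counter)
      yr <- sample(years, 1L)
      day0 <- as.Date(sprintf("%d-01-01", yr))
      ndays <- as.integer(as.Date(sprintf("%d-12-31", yr)) - day0) + 1L
      days <- sort(sample.int(ndays, min(locs_per_bird[i], ndays)))
      dates <- day0 + days - 1L
      season <- assign_season(dates)
      bb <- stats::rnorm(1, 0, truth$sigma_bird)
      pick <- integer(length(dates))
      for (ss in unique(season)) {
        sel <- season == ss
        w <- exp(eta[[ss]] + bb + b_year[[as.character(yr)]])
        pick[sel] <- sample.int(length(w), sum(sel), replace = TRUE, prob = w)
      }
      recs[[j]] <- data.frame(
        bird_id = bird, site = srow$site, subregion = srow$subregion,
        date = dates, x = cells$xy[pick, 1], y = cells$xy[pick, 2],
        stringsAsFactors = FALSE
      )
    }
    out[[i]] <- do.call(rbind, recs)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Place synthetic leks in high-quality spring habitat
#'
#' Leks (communal display grounds) are drawn uniformly from the top fraction
#' of cells ranked by true spring selection utility within each subregion's
#' half of the landscape, mimicking their association with good breeding
#' habitat.
#'
#' @inheritParams generate_telemetry
#' @param n_leks number of leks.
#' @param top_frac fraction of best spring-habitat cells eligible.
#' @param boundary_x planar x coordinate splitting mesic (west) from xeric
#'   (east); defaults to the landscape midline.
#' @return two-column matrix of lek coordinates.
#' @export
generate_leks <- function(landscape, truth, n_leks = 24, top_frac = 0.05,
                          boundary_x = NULL, seed = 1) {
  set.seed(seed)
  grid <- grid_of(landscape)
  stack <- build_covariates(landscape, truth$covariates)
  cc <- cell_centers(grid)
  if (is.null(boundary_x)) boundary_x <- grid$xmin + ncol(grid$values) * grid$res / 2
  X <- as.matrix(vapply(stack, function(r) r$values[seq_len(nrow(cc))], numeric(nrow(cc))))
  moments <- global_moments(stack)
  pick_half <- function(subregion, n) {
    in_half <- if (subregion == "mesic") cc[, 1] < boundary_x else cc[, 1] >= boundary_x
    idx <- which(in_half & stats::complete.cases(X))
    Xs <- sweep(sweep(X[idx, , drop = FALSE], 2, moments$mean), 2, moments$sd, `/`)
    eta <- drop(Xs %*% truth$beta[[subregion]]$spring)
    top <- idx[eta >= stats::quantile(eta, 1 - top_frac)]
    top[sample.int(length(top), n, replace = length(top) < n)]
  }
  n1 <- ceiling(n_leks / 2)
  idx <- c(pick_half("mesic", n1), pick_half("xeric", n_leks - n1))
  cc[idx, , drop = FALSE]
}

#' Synthetic abundance and space-use index (AUI)
#'
#' A kernel surface around lek locations, Gaussian-smoothed to a declared
#' range and normalized to [0, 1]. Stands in for the lek-count-derived
#' abundance index consumed by the habitat management index; it is an input
#' raster, not an estimate from count data.
#'
#' @param grid template `rsf_raster`.
#' @param leks two-column matrix of lek coordinates.
#' @param range_m smoothing range in metres.
#' @return an `rsf_raster` with values in [0, 1].
#' @export
generate_aui <- function(grid, leks, range_m = 3000) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  m <- matrix(0, nr, nc)
  rc <- cell_of(grid, leks)
  ok <- !is.na(rc[, 1])
  m[cbind(rc[ok, 1], rc[ok, 2])] <- 1
  s <- range_m / grid$res / (2 * sqrt(log(20)))
  half <- max(1L, ceiling(3 * s))
  g <- stats::dnorm(seq(-half, half), sd = s)
  sm <- focal_conv(m, outer(g, g))
  sm <- pmax(sm, 0)
  raster_like(grid, sm / max(sm))
}
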