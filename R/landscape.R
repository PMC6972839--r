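#' Synthetic sagebrush landscapes
#'
#' Generates aligned raster stacks with the statistical structure the
#' habitat-selection analysis assumes: spatially autocorrelated continuous
#' cover surfaces (percent cover in 0-100 and a DEM), a categorical
#' land-cover layer derived by thresholding a latent field, and point, line
#' and patch features (upland springs, streams, wet meadows, roads, lakes,
#' urban areas). Every layer shares one grid so downstream focal and distance
#' covariates need no resampling.
#'
#' @name synthetic-landscape
NULL

# Gaussian-smoothed white noise on a torus, standardized to mean 0 / sd 1.
# `range_cells` is the practical correlation range: the lag at which the
# field correlation drops to 0.05. Smoothing a white-noise field with a
# Gaussian kernel of sd s yields correlation exp(-d^2 / (4 s^2)), so
# s = range / (2 sqrt(log(20))).
gaussian_field <- function(n_rows, n_cols, range_cells) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  if (range_cells <= 0) return(z)
  s <- range_cells / (2 * sqrt(log(20)))
  half <- max(1L, ceiling(4 * s))
  g <- stats::dnorm(seq(-half, half), sd = s)
  kern <- outer(g, g)
  kern <- kern / sum(kern)
  # circular convolution keeps the field stationary right up to the borders
  K <- matrix(0, n_rows, n_cols)
  idx_r <- ((seq_len(2 * half + 1) - half - 1) %% n_rows) + 1L
  idx_c <- ((seq_len(2 * half + 1) - half - 1) %% n_cols) + 1L
  for (i in seq_along(idx_r)) {
    K[idx_r[i], idx_c] <- K[idx_r[i], idx_c] + kern[i, ]
  }
  sm <- Re(stats::fft(stats::fft(z) * stats::fft(K), inverse = TRUE)) / (n_rows * n_cols)
  (sm - mean(sm)) / stats::sd(sm)
}

default_legend <- function() {
  c(sagebrush = 1L, meadow = 2L, pinyon_juniper = 3L, annual_grass = 4L, bare = 5L)
}

default_field_params <- function() {
  list(
    herbaceous      = list(range_m = 900),
    big_sagebrush   = list(range_m = 1200),
    other_sagebrush = list(range_m = 900),
    pinyon_juniper  = list(range_m = 1500),
    bare_ground     = list(range_m = 700),
    elevation       = list(range_m = 3000),
    landcover       = list(range_m = 800),
    meadow          = list(range_m = 600)
  )
}

#' Generate a synthetic landscape
#'
#' Continuous layers are white noise smoothed to a declared spatial
#' autocorrelation range and rescaled (percent covers through the normal CDF
#' to 0-100; elevation to a plausible Great Basin band around 1,500-2,300 m).
#' Land cover is a latent smoothed field cut at quantile thresholds, with wet
#' meadows overlaid from their own latent field. Features are placed by a
#' seeded point/patch process.
#'
#' @param seed integer seed; the same seed reproduces the landscape bit for bit.
#' @param n_rows,n_cols grid dimensions.
#' @param resolution_m cell size in metres (default 30, the DEM resolution).
#' @param legend named integer vector of land-cover codes.
#' @param field_params named list, one entry per layer, each with `range_m`
#'   (practical autocorrelation range; 0 gives white noise).
#' @param n_springs,n_streams counts of point/line water features.
#' @param feature_margin_m point features are placed over the extent expanded
#'   by this margin on every side, so distance covariates carry no boundary
#'   artifact inside the mapped extent.
#' @return an object of class `rsf_landscape`: continuous layers, the
#'   land-cover raster, the legend, and the feature sets.
#' @export
generate_landscape <- function(seed, n_rows, n_cols, resolution_m = 30,
                               legend = default_legend(),
                               field_params = default_field_params(),
                               n_springs = 40, n_streams = 2,
                               feature_margin_m = 2000) {
  if (n_rows <= 0 || n_cols <= 0 || resolution_m <= 0) {
    stop("grid dimensions and resolution must be positive", call. = FALSE)
  }
  if (is.null(names(legend)) || anyDuplicated(legend)) {
    stop("legend must be a named vector of unique codes", call. = FALSE)
  }
  set.seed(seed)
  res <- resolution_m
  rng_cells <- function(nm) (field_params[[nm]]$range_m %||% 800) / res
  blank <- rsf_raster(matrix(NA_real_, n_rows, n_cols), 0, 0, res)

  pct <- function(nm) raster_like(blank, 100 * stats::pnorm(gaussian_field(n_rows, n_cols, rng_cells(nm))))
  continuous <- list(
    herbaceous      = pct("herbaceous"),
    big_sagebrush   = pct("big_sagebrush"),
    other_sagebrush = pct("other_sagebrush"),
    pinyon_juniper  = pct("pinyon_juniper"),
    bare_ground     = pct("bare_ground"),
    elevation       = raster_like(blank, 1900 + 400 * gaussian_field(n_rows, n_cols, rng_cells("elevation")))
  )

  latent <- gaussian_field(n_rows, n_cols, rng_cells("landcover"))
  props <- c(sagebrush = 0.55, pinyon_juniper = 0.15, annual_grass = 0.18, bare = 0.12)
  props <- props[intersect(names(props), names(legend))]
  props <- props / sum(props)
  cuts <- stats::quantile(latent, cumsum(props)[-length(props)])
  lc <- matrix(legend[[names(props)[1]]], n_rows, n_cols)
  bins <- findInterval(latent, cuts) + 1L
  lc[] <- legend[names(props)][bins]
  meadow_latent <- gaussian_field(n_rows, n_cols, rng_cells("meadow"))
  meadow_mask <- meadow_latent > stats::quantile(meadow_latent, 0.98)
  if ("meadow" %in% names(legend)) lc[meadow_mask] <- legend[["meadow"]]
  landcover <- raster_like(blank, lc)

  width <- n_cols * res; height <- n_rows * res
  fm <- feature_margin_m
  springs <- cbind(x = stats::runif(n_springs, -fm, width + fm),
                   y = stats::runif(n_springs, -fm, height + fm))
  streams <- lapply(seq_len(n_streams), function(i) {
    x0 <- stats::runif(1, 0.15, 0.85) * width
    y <- seq(0, height, by = res * 2)
    cbind(x = x0 + 0.04 * width * sin(y / (height / (2 * pi * stats::runif(1, 1, 3)))) +
            stats::rnorm(1, 0, 0.02 * width),
          y = y)
  })
  road_y <- stats::runif(1, 0.3, 0.7) * height
  roads <- list(cbind(x = c(0, width), y = c(road_y, road_y)))
  disc_mask <- function(center, radius_m) {
    cc <- cell_centers(blank)
    m <- matrix(sqrt((cc[, 1] - center[1])^2 + (cc[, 2] - center[2])^2) <= radius_m,
                n_rows, n_cols)
    m
  }
  lakes <- disc_mask(c(stats::runif(1, 0.1, 0.9) * width, stats::runif(1, 0.1, 0.9) * height), 10 * res)
  urban <- disc_mask(c(stats::runif(1, 0.1, 0.9) * width, stats::runif(1, 0.1, 0.9) * height), 6 * res)

  structure(list(
    continuous = continuous,
    landcover = landcover,
    legend = legend,
    features = list(
      springs = list(points = springs),
      streams = list(lines = streams),
      meadows = list(masks = list(meadow_mask)),
      roads = list(lines = roads),
      lakes = list(masks = list(lakes)),
      urban = list(masks = list(urban))
    ),
    res = res, seed = seed
  ), class = "rsf_landscape")
}

#' @export
print.rsf_landscape <- function(x, ...) {
  d <- dim(x$landcover$values)
  cat(sprintf("<rsf_landscape> %d x %d cells at %g m (seed %d)\n", d[1], d[2], x$res, x$seed))
  cat("  continuous:", paste(names(x$continuous), collapse = ", "), "\n")
  cat("  land cover:", paste(names(x$legend), collapse = ", "), "\n")
  cat("  features:  ", paste(names(x$features), collapse = ", "), "\n")
  invisible(x)
}

#' Template grid of a landscape
#' @param landscape an `rsf_landscape`.
#' @return an `rsf_raster` with the landscape's grid and all-zero values.
#' @export
grid_of <- function(landscape) raster_like(landscape$landcover, matrix(0, nrow(landscape$landcover$values), ncol(landscape$landcover$values)))

#' Write landscape layers as ASCII grids
#'
#' One `.asc` file per continuous layer plus the land-cover layer.
#'
#' @param landscape an `rsf_landscape`.
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
write_landscape <- function(landscape, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  layers <- c(landscape$continuous, list(landcover = landscape$landcover))
  paths <- vapply(names(layers), function(nm) {
    write_ascii_grid(layers[[nm]], file.path(dir, paste0(nm, ".asc")))
  }, "")
  invisible(paths)
}
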