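#' Multi-scale raster covariates
#'
#' Focal (moving-window) statistics over discrete circular windows, distance
#' and exponential-decay covariates to landscape features, topographic
#' position (TPI) and terrain-ruggedness (Riley) indices, and land-cover
#' heterogeneity (variety and edge counts). These are the covariate families
#' evaluated in the habitat-selection models, each computable at any of the
#' three movement-based radii (167.9, 439.5 and 1,451.7 m by default).
#'
#' @name covariates
NULL

# cross-correlation of `mat` with a centered odd-dimension kernel, zero-padded
# linear (non-circular) via FFT; returns a matrix the size of `mat`
focal_conv <- function(mat, kern) {
  kr <- nrow(kern); kc <- ncol(kern)
  stopifnot(kr %% 2L == 1L, kc %% 2L == 1L)
  # convolution with the flipped kernel == cross-correlation with the kernel
  kern <- kern[kr:1, kc:1, drop = FALSE]
  nr <- nrow(mat); nc <- ncol(mat)
  p1 <- stats::nextn(nr + kr - 1L, c(2L, 3L, 5L))
  p2 <- stats::nextn(nc + kc - 1L, c(2L, 3L, 5L))
  A <- matrix(0, p1, p2); A[seq_len(nr), seq_len(nc)] <- mat
  B <- matrix(0, p1, p2); B[seq_len(kr), seq_len(kc)] <- kern
  C <- Re(stats::fft(stats::fft(A) * stats::fft(B), inverse = TRUE)) / (p1 * p2)
  off_r <- (kr - 1L) %/% 2L; off_c <- (kc - 1L) %/% 2L
  C[off_r + seq_len(nr), off_c + seq_len(nc), drop = FALSE]
}

#' Discrete circular window
#'
#' 0/1 kernel of cell offsets whose centers lie within `radius_m` (inclusive)
#' of the focal cell center.
#'
#' @param radius_m window radius in metres.
#' @param res cell size in metres.
#' @return square 0/1 matrix of odd dimension.
#' @export
circle_kernel <- function(radius_m, res) {
  if (radius_m < res) stop("radius must be at least one cell", call. = FALSE)
  R <- floor(radius_m / res + 1e-9)
  d <- seq(-R, R) * res
  dist <- sqrt(outer(d^2, d^2, `+`))
  (dist <= radius_m + 1e-9) * 1
}

# shared focal-sum machinery with nodata exclusion
focal_sums <- function(values, kern) {
  mask <- !is.na(values)
  v0 <- values; v0[!mask] <- 0
  list(sum = focal_conv(v0, kern),
       n = round(focal_conv(mask * 1, kern)),
       mask = mask)
}

#' Focal statistic over a circular window
#'
#' Value at each cell is the statistic over cells whose centers lie within the
#' circular radius. Nodata cells are excluded from both numerator and
#' denominator; cells that are themselves nodata stay nodata.
#'
#' @param r an `rsf_raster`.
#' @param radius_m window radius in metres (at least one cell).
#' @param statistic `"mean"` or `"fraction"` (fraction of cells equal to `class`).
#' @param class land-cover code, required for `statistic = "fraction"`.
#' @return an `rsf_raster` aligned with `r`.
#' @export
focal_statistic <- function(r, radius_m, statistic = c("mean", "fraction"), class = NULL) {
  statistic <- match.arg(statistic)
  kern <- circle_kernel(radius_m, r$res)
  v <- r$values
  if (statistic == "fraction") {
    if (is.null(class)) stop("'class' is required for the fraction statistic", call. = FALSE)
    ind <- (v == class) * 1
    ind[is.na(v)] <- NA_real_
    v <- ind
  }
  fs <- focal_sums(v, kern)
  num <- if (statistic == "fraction") round(fs$sum) else fs$sum
  out <- num / fs$n
  out[fs$n == 0 | !fs$mask] <- NA_real_
  raster_like(r, out)
}

#' Topographic position index
#'
#' Center elevation minus the mean elevation of surrounding cells within the
#' radius; the center cell is excluded from the surrounding mean. Positive on
#' ridges and knolls, negative in drainages and basins.
#'
#' @param dem elevation raster (m).
#' @param radius_m neighbourhood radius in metres (510 and 2,010 m are the
#'   scales used in model development).
#' @return an `rsf_raster` of elevation differences (m).
#' @export
tpi <- function(dem, radius_m) {
  kern <- circle_kernel(radius_m, dem$res)
  fs <- focal_sums(dem$values, kern)
  s <- fs$sum - ifelse(fs$mask, dem$values, 0)
  n <- fs$n - fs$mask
  out <- dem$values - s / n
  out[n == 0 | !fs$mask] <- NA_real_
  raster_like(dem, out)
}

#' Terrain ruggedness (Riley index)
#'
#' Per cell, the square root of the summed squared elevation differences
#' between the cell and its eight neighbours, then averaged over a circular
#' window of about one hectare (radius 56.4 m by default). Invariant to
#' adding a constant to the DEM.
#'
#' @param dem elevation raster (m).
#' @param radius_m averaging radius in metres; the 1-ha default matches a
#'   56.4-m radius circle.
#' @return an `rsf_raster`.
#' @export
roughness <- function(dem, radius_m = 56.4) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  pad <- matrix(NA_real_, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- z
  ss <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- pad[2:(nr + 1L) + dr, 2:(nc + 1L) + dc, drop = FALSE]
    d2 <- (nb - z)^2
    d2[is.na(d2)] <- 0
    ss <- ss + d2
  }
  tri <- sqrt(ss)
  tri[is.na(z)] <- NA_real_
  tri_r <- raster_like(dem, tri)
  if (radius_m >= dem$res) focal_statistic(tri_r, radius_m, "mean") else tri_r
}

#' Land-cover heterogeneity
#'
#' Counts, within each circular window, the number of distinct land-cover
#' codes (variety) and the number of 4-neighbour adjacencies between cells of
#' differing codes where both cells of the pair fall inside the window (edge
#' count).
#'
#' @param landcover categorical raster of integer codes.
#' @param radius_m window radius in metres.
#' @return list with elements `variety` and `edges`, both `rsf_raster`s.
#' @export
landcover_heterogeneity <- function(landcover, radius_m) {
  v <- landcover$values
  kern <- circle_kernel(radius_m, landcover$res)
  classes <- sort(unique(v[!is.na(v)]))
  variety <- matrix(0, nrow(v), ncol(v))
  for (cl in classes) {
    cnt <- round(focal_conv((!is.na(v) & v == cl) * 1, kern))
    variety <- variety + (cnt > 0)
  }
  # pair-in-window kernels: a 4-neighbour pair is counted iff both members lie
  # inside the window; the pair indicator sits at the west/north member
  k <- nrow(kern)
  kh <- kern * cbind(kern[, -1, drop = FALSE], 0)
  kv <- kern * rbind(kern[-1, , drop = FALSE], 0)
  eh <- matrix(0, nrow(v), ncol(v))
  dif <- v[, -ncol(v), drop = FALSE] != v[, -1, drop = FALSE]
  dif[is.na(dif)] <- FALSE
  eh[, -ncol(v)] <- dif
  ev <- matrix(0, nrow(v), ncol(v))
  dif <- v[-nrow(v), , drop = FALSE] != v[-1, , drop = FALSE]
  dif[is.na(dif)] <- FALSE
  ev[-nrow(v), ] <- dif
  edges <- round(focal_conv(eh, kh) + focal_conv(ev, kv))
  variety[is.na(v)] <- NA_real_
  edges[is.na(v)] <- NA_real_
  list(variety = raster_like(landcover, variety),
       edges = raster_like(landcover, edges))
}

# rasterize a feature set (points / polylines / masks) to a logical matrix of
# feature cells on the template grid
rasterize_features <- function(features, template) {
  nr <- nrow(template$values); nc <- ncol(template$values)
  mask <- matrix(FALSE, nr, nc)
  add_xy <- function(xy) {
    rc <- cell_of(template, xy)
    ok <- !is.na(rc[, 1])
    mask[cbind(rc[ok, 1], rc[ok, 2])] <<- TRUE
  }
  if (!is.null(features$points) && nrow(features$points)) add_xy(features$points)
  for (ln in features$lines %||% list()) {
    for (i in seq_len(nrow(ln) - 1L)) {
      a <- ln[i, ]; b <- ln[i + 1L, ]
      len <- sqrt(sum((b - a)^2))
      t <- seq(0, 1, length.out = max(2L, ceiling(len / (template$res / 3)) + 1L))
      add_xy(cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2])))
    }
  }
  for (m in features$masks %||% list()) {
    mm <- if (inherits(m, "rsf_raster")) m$values else m
    mask <- mask | (!is.na(mm) & mm > 0)
  }
  mask
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Distance to the nearest feature cell (metres)
#'
#' Point features are measured exactly from each cell center; line and patch
#' features are rasterized to the grid and measured center-to-center with an
#' exact Euclidean distance transform.
#'
#' @param features list with any of `points` (two-column matrix), `lines`
#'   (list of polyline vertex matrices), `masks` (list of logical matrices or
#'   `rsf_raster`s).
#' @param grid template `rsf_raster`.
#' @return an `rsf_raster` of distances in metres.
#' @export
feature_distance <- function(features, grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  d <- matrix(Inf, nr, nc)
  mask <- rasterize_features(list(lines = features$lines, masks = features$masks), grid)
  if (any(mask)) {
    img <- matrix(1, nr, nc)
    img[mask] <- 0
    d <- pmin(d, EBImage::distmap(img, metric = "euclidean") * grid$res)
  }
  pts <- features$points
  if (!is.null(pts) && nrow(pts)) {
    cc <- cell_centers(grid)
    for (i in seq_len(nrow(pts))) {
      di <- sqrt((cc[, 1] - pts[i, 1])^2 + (cc[, 2] - pts[i, 2])^2)
      d <- pmin(d, matrix(di, nr, nc))
    }
  }
  if (all(is.infinite(d))) stop("empty feature set", call. = FALSE)
  raster_like(grid, d)
}

#' Distance-based covariate
#'
#' Either the linear Euclidean distance in kilometres to the nearest feature,
#' or an exponential-decay proximity `exp(-d / decay_m)` in (0, 1].
#'
#' @inheritParams feature_distance
#' @param form `"linear"` (km) or `"decay"`.
#' @param decay_m decay constant in metres (default 1,000 m).
#' @return an `rsf_raster`.
#' @export
distance_covariate <- function(features, grid, form = c("linear", "decay"), decay_m = 1000) {
  form <- match.arg(form)
  if (form == "decay" && !(is.numeric(decay_m) && decay_m > 0)) {
    stop("decay_m must be positive", call. = FALSE)
  }
  d <- feature_distance(features, grid)
  if (form == "linear") raster_like(grid, d$values / 1000)
  else raster_like(grid, exp(-d$values / decay_m))
}

#' Covariate specification table
#'
#' Declares how one covariate column is derived from a landscape: its source
#' layer (or feature set), the functional form, and the spatial scale.
#'
#' @param name covariate column name.
#' @param layer source layer or feature-set name within the landscape.
#' @param form one of `"focal-mean"`, `"focal-fraction"`, `"linear-distance"`,
#'   `"exp-decay-distance"`, `"elevation-km"`, `"tpi"`, `"roughness"`,
#'   `"variety"`, `"edge-variety"`.
#' @param scale radius in metres for focal/TPI/heterogeneity forms, or the
#'   decay constant in metres for `"exp-decay-distance"`.
#' @param class land-cover code for `"focal-fraction"`.
#' @return one-row data frame; rbind rows to build a specification table.
#' @export
covariate_spec <- function(name, layer, form, scale = NA_real_, class = NA_real_) {
  forms <- c("focal-mean", "focal-fraction", "linear-distance", "exp-decay-distance",
             "elevation-km", "tpi", "roughness", "variety", "edge-variety")
  form <- match.arg(form, forms)
  needs_scale <- !form %in% c("linear-distance", "elevation-km")
  if (needs_scale && !(is.numeric(scale) && is.finite(scale) && scale > 0)) {
    stop(sprintf("form '%s' needs a positive scale parameter", form), call. = FALSE)
  }
  data.frame(name = name, layer = layer, form = form, scale = scale,
             class = class, stringsAsFactors = FALSE)
}

#' Build a covariate stack from a landscape
#'
#' @param landscape an `rsf_landscape` (see [generate_landscape()]).
#' @param specs covariate specification table ([covariate_spec()] rows).
#' @return named list of `rsf_raster`s, one per spec row, with the spec table
#'   attached as attribute `"specs"`.
#' @export
build_covariates <- function(landscape, specs) {
  get_layer <- function(nm) {
    if (!is.null(landscape$continuous[[nm]])) return(landscape$continuous[[nm]])
    if (identical(nm, "landcover")) return(landscape$landcover)
    stop(sprintf("unknown landscape layer '%s'", nm), call. = FALSE)
  }
  get_features <- function(nm) {
    f <- landscape$features[[nm]]
    if (is.null(f)) stop(sprintf("unknown feature set '%s'", nm), call. = FALSE)
    f
  }
  out <- vector("list", nrow(specs))
  names(out) <- specs$name
  het_cache <- list()
  for (i in seq_len(nrow(specs))) {
    s <- specs[i, ]
    out[[i]] <- switch(s$form,
      "focal-mean" = focal_statistic(get_layer(s$layer), s$scale, "mean"),
      "focal-fraction" = focal_statistic(get_layer(s$layer), s$scale, "fraction", class = s$class),
      "linear-distance" = distance_covariate(get_features(s$layer), grid_of(landscape), "linear"),
      "exp-decay-distance" = distance_covariate(get_features(s$layer), grid_of(landscape),
                                                "decay", decay_m = s$scale),
      "elevation-km" = raster_like(get_layer(s$layer), get_layer(s$layer)$values / 1000),
      "tpi" = tpi(get_layer(s$layer), s$scale),
      "roughness" = roughness(get_layer(s$layer), s$scale),
      "variety" = ,
      "edge-variety" = {
        key <- sprintf("%s|%g", s$layer, s$scale)
        if (is.null(het_cache[[key]])) {
          het_cache[[key]] <- landcover_heterogeneity(get_layer(s$layer), s$scale)
        }
        het_cache[[key]][[if (s$form == "variety") "variety" else "edges"]]
      })
  }
  attr(out, "specs") <- specs
  out
}

#' Extract a covariate stack at point locations
#'
#' @param stack named list of aligned `rsf_raster`s.
#' @param xy two-column coordinate matrix.
#' @return data frame with one column per stack layer.
#' @export
extract_covariates <- function(stack, xy) {
  as.data.frame(lapply(stack, extract_at, xy = xy))
}
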