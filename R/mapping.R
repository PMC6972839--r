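#' Habitat selection index surfaces and category maps
#'
#' Fitted RSF linear predictors are rescaled to a habitat selection index
#' (HSI) in (0, 1) by the inverse-logit, averaged cellwise across sites,
#' relativized within each hydrographic subregion by its maximum, multiplied
#' across seasons into an annual composite, masked around roads, lakes and
#' urban areas, and binned into four categories from the mean and SD of HSI
#' values at the classification birds' locations.
#'
#' @name hsi-mapping
NULL

#' Inverse-logit HSI transform
#'
#' @param linpred `rsf_raster` of linear-predictor values.
#' @param method `"logistic"` (default) or `"minmax"` (linear stretch of the
#'   linear predictor to [0, 1]).
#' @return `rsf_raster` with values in (0, 1).
#' @export
hsi_transform <- function(linpred, method = c("logistic", "minmax")) {
  method <- match.arg(method)
  v <- linpred$values
  out <- if (method == "logistic") {
    stats::plogis(v)
  } else {
    rng <- range(v, na.rm = TRUE)
    if (diff(rng) == 0) v * 0 + 0.5 else (v - rng[1]) / diff(rng)
  }
  raster_like(linpred, out)
}

#' Average site HSIs and relativize by subregion
#'
#' Cellwise mean over the site surfaces covering each cell, then division by
#' the maximum averaged value within each subregion, so each subregion's
#' maximum is exactly 1. Cells covered by no site stay nodata.
#'
#' @param surfaces list of aligned `rsf_raster` HSI surfaces (NA outside each
#'   site's coverage when not extrapolating).
#' @param subregions `rsf_raster` of subregion codes (1 = mesic, 2 = xeric).
#' @return `rsf_raster` of relativized HSI in [0, 1].
#' @export
average_and_relativize <- function(surfaces, subregions) {
  stopifnot(length(surfaces) >= 1)
  do.call(stop_unless_aligned, c(surfaces, list(subregions)))
  template <- surfaces[[1]]
  s <- matrix(0, nrow(template$values), ncol(template$values))
  n <- s
  for (r in surfaces) {
    ok <- !is.na(r$values)
    s[ok] <- s[ok] + r$values[ok]
    n <- n + ok
  }
  avg <- s / n
  avg[n == 0] <- NA_real_
  for (code in unique(subregions$values[!is.na(subregions$values)])) {
    cells <- !is.na(subregions$values) & subregions$values == code
    mx <- suppressWarnings(max(avg[cells], na.rm = TRUE))
    if (is.finite(mx) && mx > 0) avg[cells] <- avg[cells] / mx
  }
  raster_like(template, avg)
}

#' Annual composite of the three seasonal surfaces
#'
#' Cellwise product of the relativized spring, summer/fall and winter maps;
#' a zero in any season zeroes the composite, and the composite never
#' exceeds any single season.
#'
#' @param spring,summer_fall,winter aligned relativized `rsf_raster`s.
#' @return `rsf_raster` in [0, 1].
#' @export
seasonal_composite <- function(spring, summer_fall, winter) {
  stop_unless_aligned(spring, summer_fall, winter)
  raster_like(spring, spring$values * summer_fall$values * winter$values)
}

#' Mask cells near roads, lakes and urban areas
#'
#' Cells whose centers lie within `buffer_m` of any feature become nodata,
#' eliminating nonhabitat from the maps.
#'
#' @param r surface to mask.
#' @param features feature list (as in [feature_distance()]); `NULL` or empty
#'   leaves `r` unchanged.
#' @param buffer_m mask radius in metres (default 50).
#' @return list: `raster` (masked surface) and `mask` (logical matrix of
#'   masked cells).
#' @export
mask_features <- function(r, features, buffer_m = 50) {
  empty <- is.null(features) ||
    ((is.null(features$points) || nrow(features$points) == 0) &&
       length(features$lines %||% list()) == 0 &&
       length(features$masks %||% list()) == 0)
  if (empty) {
    return(list(raster = r, mask = matrix(FALSE, nrow(r$values), ncol(r$values))))
  }
  d <- feature_distance(features, r)
  mask <- d$values <= buffer_m
  v <- r$values
  v[mask] <- NA_real_
  list(raster = raster_like(r, v), mask = mask)
}

CATEGORY_CODES <- c(nonhabitat = 0L, low = 1L, moderate = 2L, high = 3L)
MASK_CODE <- 255L

#' Bin an HSI surface into habitat categories
#'
#' Thresholds come from the mean and SD of surface values at the
#' classification birds' locations, separately per subregion: high from
#' mean - 0.5 SD up to 1; moderate from mean - 1 SD; low from mean - 1.5 SD;
#' nonhabitat below. Intervals are lower-closed (`[lower, upper)`), high
#' closed at 1.
#'
#' @param surface relativized HSI `rsf_raster`.
#' @param class_values named list `subregion code -> numeric vector` of
#'   surface values at the classification locations (>= 2 values each), or a
#'   single numeric vector applied everywhere.
#' @param subregions `rsf_raster` of subregion codes matching the list names
#'   (ignored for a single vector).
#' @param sd_mult the three SD multipliers (default 0.5, 1, 1.5).
#' @return list: `raster` (integer codes, 3 high .. 0 nonhabitat, NA where the
#'   surface is nodata) and `thresholds` (per-subregion cut points).
#' @export
categorize <- function(surface, class_values, subregions = NULL,
                       sd_mult = c(0.5, 1, 1.5)) {
  if (!is.list(class_values)) class_values <- list(all = class_values)
  thr <- lapply(class_values, function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2) stop("need at least 2 classification values per subregion",
                            call. = FALSE)
    m <- mean(v); s <- stats::sd(v)
    c(low = m - sd_mult[3] * s, moderate = m - sd_mult[2] * s,
      high = m - sd_mult[1] * s)
  })
  v <- surface$values
  out <- matrix(NA_integer_, nrow(v), ncol(v))
  zone_of <- function(nm) {
    if (identical(nm, "all") || is.null(subregions)) !is.na(v)
    else !is.na(v) & !is.na(subregions$values) &
      subregions$values == as.numeric(nm)
  }
  for (nm in names(thr)) {
    cells <- zone_of(nm)
    t <- thr[[nm]]
    cat_v <- ifelse(v >= t[["high"]], 3L,
                    ifelse(v >= t[["moderate"]], 2L,
                           ifelse(v >= t[["low"]], 1L, 0L)))
    out[cells] <- cat_v[cells]
  }
  list(raster = raster_like(surface, out + 0), thresholds = thr)
}

#' Areal shares of the habitat categories
#'
#' Unmasked-cell fractions per category, optionally restricted to an extent
#' polygon.
#'
#' @param category `rsf_raster` of category codes.
#' @param extent optional closed polygon; only cells whose centers fall
#'   inside are counted.
#' @return named numeric vector over nonhabitat/low/moderate/high, summing
#'   to 1.
#' @export
expected_shares <- function(category, extent = NULL) {
  v <- category$values
  if (!is.null(extent)) {
    cc <- cell_centers(category)
    v[!in_polygon(extent, cc)] <- NA_real_
  }
  v <- v[!is.na(v) & v != MASK_CODE]
  shares <- vapply(CATEGORY_CODES, function(code) mean(v == code), 0)
  names(shares) <- names(CATEGORY_CODES)
  shares
}
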