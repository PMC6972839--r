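#' Seasons, screening and the used-available design
#'
#' The three biological seasons tile the calendar year: spring (16 Mar-30
#' Jun, breeding and nesting), summer/fall (1 Jul-15 Oct, brood rearing) and
#' winter (16 Oct-15 Mar, nonbreeding; spans the year boundary). Site-season
#' samples are screened (>= 20 marked birds and >= 100 locations), birds are
#' split 80/10/10 into training / category-classification / validation
#' subsets, availability is a buffered minimum convex polygon, and available
#' points are drawn 5:1 and down-weighted so both response classes carry
#' equal weight.
#'
#' @name ua-design
NULL

#' Assign the biological season of a date
#'
#' @param date a `Date` vector (or something coercible).
#' @return character vector: `"spring"`, `"summer_fall"` or `"winter"`.
#' @export
assign_season <- function(date) {
  date <- as.Date(date)
  md <- as.integer(format(date, "%m")) * 100L + as.integer(format(date, "%d"))
  out <- rep("winter", length(md))
  out[md >= 316L & md <= 630L] <- "spring"
  out[md >= 701L & md <= 1015L] <- "summer_fall"
  out
}

#' Season-year label for random effects
#'
#' Winter spans the calendar boundary, so its locations from 16 Oct-31 Dec
#' keep the starting calendar year and those from 1 Jan-15 Mar are labelled
#' with the previous year, keeping one winter contiguous. Other seasons use
#' the calendar year.
#'
#' @inheritParams assign_season
#' @return integer vector of season-year labels.
#' @export
season_year <- function(date) {
  date <- as.Date(date)
  yr <- as.integer(format(date, "%Y"))
  md <- as.integer(format(date, "%m")) * 100L + as.integer(format(date, "%d"))
  yr - (md <= 315L)
}

#' Screen site-season samples for modelling
#'
#' A site-season enters RSF modelling only with at least `min_birds` marked
#' birds and at least `min_locs` telemetry locations.
#'
#' @param counts data frame with columns `site`, `season`, `n_birds`, `n_locs`.
#' @param min_birds,min_locs inclusion thresholds (both inclusive).
#' @return `counts` with a logical `eligible` column.
#' @export
screen_site_seasons <- function(counts, min_birds = 20, min_locs = 100) {
  stopifnot(all(c("site", "season", "n_birds", "n_locs") %in% names(counts)))
  counts$eligible <- counts$n_birds >= min_birds & counts$n_locs >= min_locs
  counts
}

#' Availability extent: buffered minimum convex polygon
#'
#' The convex hull of a site's locations dilated by the average maximum daily
#' movement (1,451 m). The dilation of a convex polygon is approximated by
#' the hull of dense circles around the vertices; with `arc_segments` points
#' per circle the area error is bounded by the circular-segment sagitta.
#'
#' @param xy two-column matrix of used locations (>= 3 non-collinear points).
#' @param buffer_m buffer distance in metres.
#' @param arc_segments circle discretization (points per full circle).
#' @return closed polygon matrix (first vertex repeated last) with attributes
#'   `hull` (the unbuffered MCP) and `buffer_m`.
#' @export
availability_extent <- function(xy, buffer_m = 1451, arc_segments = 96) {
  xy <- unique(as.matrix(xy))
  if (nrow(xy) < 3L) stop("need at least 3 distinct points", call. = FALSE)
  h <- grDevices::chull(xy)
  hull <- xy[h, , drop = FALSE]
  if (abs(polygon_area(rbind(hull, hull[1, ]))) <= 0) {
    stop("degenerate (collinear) hull", call. = FALSE)
  }
  if (buffer_m > 0) {
    th <- seq(0, 2 * pi, length.out = arc_segments + 1L)[-1L]
    ring <- cbind(cos(th), sin(th)) * buffer_m
    pts <- do.call(rbind, lapply(seq_len(nrow(hull)), function(i) {
      cbind(hull[i, 1] + ring[, 1], hull[i, 2] + ring[, 2])
    }))
    b <- grDevices::chull(pts)
    poly <- pts[b, , drop = FALSE]
  } else {
    poly <- hull
  }
  poly <- rbind(poly, poly[1, ])
  colnames(poly) <- c("x", "y")
  hull_closed <- rbind(hull, hull[1, ])
  colnames(hull_closed) <- c("x", "y")
  structure(poly, hull = hull_closed, buffer_m = buffer_m)
}

#' Shoelace polygon area
#' @param poly closed polygon matrix (first row repeated last).
#' @return area (positive regardless of orientation).
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

#' Points inside a polygon
#' @param poly closed polygon matrix.
#' @param xy two-column point matrix.
#' @return logical vector.
#' @export
in_polygon <- function(poly, xy) {
  mgcv::in.out(as.matrix(poly), as.matrix(xy))
}

#' Sample available locations uniformly within an extent
#'
#' Rejection sampling from the bounding box; points landing on nodata cells
#' of `grid` (when given) are rejected as well.
#'
#' @param extent closed polygon ([availability_extent()]).
#' @param n_used number of used locations.
#' @param ratio available points per used point (default 5).
#' @param grid optional `rsf_raster` whose `NA` cells are excluded.
#' @param seed optional integer seed.
#' @return two-column matrix of `ratio * n_used` points.
#' @export
sample_available <- function(extent, n_used, ratio = 5, grid = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_used * ratio
  xr <- range(extent[, 1]); yr <- range(extent[, 2])
  out <- matrix(NA_real_, 0L, 2L)
  tries <- 0L
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 1000L)
    cand <- cbind(stats::runif(m, xr[1], xr[2]), stats::runif(m, yr[1], yr[2]))
    keep <- in_polygon(extent, cand)
    if (!is.null(grid)) keep <- keep & !is.na(extract_at(grid, cand))
    out <- rbind(out, cand[keep, , drop = FALSE])
    tries <- tries + 1L
    if (tries > 1000L) stop("availability extent appears fully masked", call. = FALSE)
  }
  out <- out[seq_len(n), , drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}

#' Down-weight available points
#'
#' Used rows get weight 1.0 and available rows `1/ratio`, so the summed
#' weight of the two response classes is equal for any ratio.
#'
#' @param table data frame with a 0/1 `used` column.
#' @param ratio available:used ratio (>= 1).
#' @return `table` with a `weight` column.
#' @export
assign_weights <- function(table, ratio = 5) {
  stopifnot(ratio >= 1)
  table$weight <- ifelse(table$used == 1, 1, 1 / ratio)
  table
}

#' Screen rare land-cover classes
#'
#' Classes must account for more than `threshold` (strictly) of the
#' unbuffered MCP's cells to enter modelling.
#'
#' @param landcover categorical `rsf_raster`.
#' @param mcp closed polygon (the unbuffered hull).
#' @param threshold minimum areal fraction (default 0.001 = 0.1%).
#' @return data frame with `class`, `fraction`, `admissible`.
#' @export
screen_rare_covers <- function(landcover, mcp, threshold = 0.001) {
  cc <- cell_centers(landcover)
  inside <- in_polygon(mcp, cc)
  vals <- landcover$values[inside]
  vals <- vals[!is.na(vals)]
  tab <- table(vals)
  frac <- as.numeric(tab) / length(vals)
  data.frame(class = as.numeric(names(tab)), fraction = frac,
             admissible = frac > threshold)
}

#' Split birds into training / classification / validation subsets
#'
#' A bird-level partition (all of a bird's locations inherit its subset) with
#' largest-remainder rounding, so subset sizes are within one bird of the
#' target fractions.
#'
#' @param bird_ids character vector of unique bird ids.
#' @param fractions three fractions summing to 1 (default 0.8/0.1/0.1).
#' @param seed integer seed for the shuffle.
#' @return named list of id vectors: `train`, `classify`, `validate`.
#' @export
split_by_bird <- function(bird_ids, fractions = c(0.8, 0.1, 0.1), seed = 1) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, length(fractions) == 3L)
  ids <- unique(bird_ids)
  n <- length(ids)
  if (n < 3L) stop("need at least as many birds as subsets", call. = FALSE)
  target <- fractions * n
  sizes <- floor(target)
  rem <- target - sizes
  short <- n - sum(sizes)
  if (short > 0) {
    order_rem <- order(rem, decreasing = TRUE)
    sizes[order_rem[seq_len(short)]] <- sizes[order_rem[seq_len(short)]] + 1L
  }
  set.seed(seed)
  ids <- sample(ids)
  grp <- rep(c("train", "classify", "validate"), times = sizes)
  out <- split(ids, factor(grp, levels = c("train", "classify", "validate")))
  lapply(out, as.character)
}

#' Build the used-available modelling table for one site-season
#'
#' Stacks used telemetry rows with `ratio` uniformly sampled available rows
#' per used row (available rows inherit the bird and season-year of their
#' parent used location), extracts the covariate stack at every point,
#' z-scores each covariate on the availability rows, and assigns the class
#' weights.
#'
#' @param telemetry data frame of used locations (`bird_id`, `date`, `x`, `y`).
#' @param extent availability polygon ([availability_extent()]).
#' @param stack named list of covariate `rsf_raster`s.
#' @param ratio available:used ratio (default 5).
#' @param seed integer seed for the available sample.
#' @return data frame with `used`, `weight`, `bird`, `year`, `season` and one
#'   standardized column per covariate; attributes `scaling` (availability
#'   means/sds) and `n_used`.
#' @export
build_ua_table <- function(telemetry, extent, stack, ratio = 5, seed = 1) {
  n_used <- nrow(telemetry)
  stopifnot(n_used > 0)
  used_xy <- cbind(telemetry$x, telemetry$y)
  avail_xy <- sample_available(extent, n_used, ratio = ratio,
                               grid = stack[[1]], seed = seed)
  parent <- rep(seq_len(n_used), each = ratio)
  tab <- data.frame(
    used = rep(c(1, 0), c(n_used, n_used * ratio)),
    bird = c(telemetry$bird_id, telemetry$bird_id[parent]),
    year = c(season_year(telemetry$date), season_year(telemetry$date)[parent]),
    season = assign_season(c(telemetry$date, telemetry$date[parent])),
    x = c(used_xy[, 1], avail_xy[, 1]),
    y = c(used_xy[, 2], avail_xy[, 2]),
    stringsAsFactors = FALSE
  )
  covs <- extract_covariates(stack, cbind(tab$x, tab$y))
  av <- tab$used == 0
  mu <- vapply(covs[av, , drop = FALSE], mean, 0, na.rm = TRUE)
  sd_ <- vapply(covs[av, , drop = FALSE], stats::sd, 0, na.rm = TRUE)
  sd_[sd_ == 0 | is.na(sd_)] <- 1
  covs <- as.data.frame(Map(function(v, m, s) (v - m) / s, covs, mu, sd_))
  tab <- cbind(tab, covs)
  tab <- tab[stats::complete.cases(covs), , drop = FALSE]
  tab <- assign_weights(tab, ratio)
  attr(tab, "scaling") <- list(mean = mu, sd = sd_)
  attr(tab, "n_used") <- sum(tab$used == 1)
  attr(tab, "ratio") <- ratio
  tab
}
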