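#' Validation of habitat category maps
#'
#' Held-out telemetry is scored per bird: each bird contributes its own
#' proportions of locations per category and the validation statistic is the
#' across-bird mean per category, so birds with many locations do not
#' dominate. Observed shares are compared to the categories' areal fractions
#' through a chance-corrected agreement coefficient
#' `kappa = (p - e) / (1 - e)`, with > 0.75 good, 0.40-0.75 acceptable and
#' < 0.40 poor. Lek locations (points, no bird grouping) validate the spring
#' and annual maps.
#'
#' @name map-validation
NULL

#' Per-bird averaged category shares
#'
#' @param birds bird id per location.
#' @param categories category code per location (`NA` or mask code dropped
#'   with a message).
#' @return named shares over nonhabitat/low/moderate/high (mean over birds of
#'   each bird's within-category proportions; sums to 1).
#' @export
observed_shares <- function(birds, categories) {
  drop <- is.na(categories) | categories == MASK_CODE
  if (any(drop)) {
    message(sprintf("dropping %d location(s) on masked or nodata cells", sum(drop)))
    birds <- birds[!drop]; categories <- categories[!drop]
  }
  if (!length(birds)) stop("no usable validation locations", call. = FALSE)
  per_bird <- do.call(rbind, lapply(split(categories, birds), function(v) {
    vapply(CATEGORY_CODES, function(code) mean(v == code), 0)
  }))
  shares <- colMeans(per_bird)
  names(shares) <- names(CATEGORY_CODES)
  shares
}

#' Chance-corrected category agreement
#'
#' `kappa = (p - e) / (1 - e)` clipped to [-1, 1]: the excess use of a
#' category over its areal expectation, rescaled by the maximum achievable
#' excess.
#'
#' @param p observed share in [0, 1].
#' @param e expected (areal) share in [0, 1).
#' @return kappa value(s).
#' @export
kappa_chance <- function(p, e) {
  stopifnot(all(p >= 0 & p <= 1), all(e >= 0))
  if (any(e >= 1)) stop("expected share must be < 1", call. = FALSE)
  pmin(1, pmax(-1, (p - e) / (1 - e)))
}

#' Agreement label from kappa
#' @param kappa kappa value(s).
#' @return `"good"` (> 0.75), `"acceptable"` (0.40-0.75) or `"poor"` (< 0.40).
#' @export
kappa_label <- function(kappa) {
  ifelse(kappa > 0.75, "good", ifelse(kappa >= 0.40, "acceptable", "poor"))
}

#' Score a category map against held-out locations
#'
#' @param category `rsf_raster` of category codes.
#' @param xy two-column matrix of validation locations.
#' @param birds bird ids (one per location); `NULL` treats locations as
#'   ungrouped points (the lek convention).
#' @param extent optional polygon restricting the expected-share computation.
#' @param dataset label stored on the report (e.g. `"within-RSF"`,
#'   `"outside-RSF"`, `"lek"`).
#' @return `data.frame` of class `rsf_validation`: per category the expected
#'   and observed shares, kappa and its label.
#' @export
validate_map <- function(category, xy, birds = NULL, extent = NULL,
                         dataset = "within-RSF") {
  cats <- extract_at(category, xy)
  obs <- if (is.null(birds)) {
    keep <- !is.na(cats) & cats != MASK_CODE
    if (!any(keep)) stop("no usable validation locations", call. = FALSE)
    vapply(CATEGORY_CODES, function(code) mean(cats[keep] == code), 0)
  } else {
    observed_shares(birds, cats)
  }
  exp_ <- expected_shares(category, extent)
  k <- kappa_chance(obs, exp_)
  structure(data.frame(
    dataset = dataset,
    category = names(CATEGORY_CODES),
    expected = as.numeric(exp_),
    observed = as.numeric(obs),
    kappa = as.numeric(k),
    agreement = kappa_label(as.numeric(k))
  ), class = c("rsf_validation", "data.frame"))
}

#' Lek-based validation of the spring and annual maps
#'
#' @param leks two-column matrix of active lek coordinates.
#' @param spring_category,composite_category category rasters.
#' @return `rsf_validation` report rows for both maps.
#' @export
lek_validation <- function(leks, spring_category, composite_category) {
  stopifnot(nrow(leks) > 0)
  rbind(
    cbind(map = "spring", validate_map(spring_category, leks, dataset = "lek")),
    cbind(map = "composite", validate_map(composite_category, leks, dataset = "lek"))
  )
}
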