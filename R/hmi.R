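#' Habitat management index and management categories
#'
#' The continuous habitat management index (HMI) is the cellwise product of
#' the composite HSI and an abundance and space-use index (AUI) in [0, 1].
#' The categorical management map crosses the HSI habitat category with a
#' high/low AUI band: core (high or moderate habitat with high AUI),
#' priority (good habitat with low AUI, or low habitat with high AUI),
#' general (low habitat, low AUI) and nonhabitat. The crossing rule and the
#' AUI band threshold are configurable; the default is illustrative of the
#' four named classes.
#'
#' @name hmi
NULL

#' Continuous habitat management index
#'
#' @param hsi composite HSI `rsf_raster` in [0, 1].
#' @param aui AUI `rsf_raster` in [0, 1].
#' @return `rsf_raster`, cellwise `hsi * aui`.
#' @export
compute_hmi <- function(hsi, aui) {
  stop_unless_aligned(hsi, aui)
  rng <- range(aui$values, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) stop("AUI must lie in [0, 1]", call. = FALSE)
  raster_like(hsi, hsi$values * aui$values)
}

MANAGEMENT_CODES <- c(nonhabitat = 0L, general = 1L, priority = 2L, core = 3L)

default_management_rule <- function() {
  # rows: HSI category; cols: AUI band
  matrix(c(
    # low AUI        high AUI
    "nonhabitat", "nonhabitat",  # nonhabitat HSI
    "general",    "priority",    # low HSI
    "priority",   "core",        # moderate HSI
    "priority",   "core"         # high HSI
  ), nrow = 4, byrow = TRUE,
  dimnames = list(c("nonhabitat", "low", "moderate", "high"), c("low_aui", "high_aui")))
}

#' Categorical habitat management map
#'
#' @param category HSI category `rsf_raster` (codes 0-3).
#' @param aui AUI `rsf_raster` in [0, 1].
#' @param aui_threshold AUI value at or above which a cell is in the high-AUI
#'   band (default 0.25).
#' @param rule 4 x 2 character matrix mapping HSI category (rows: nonhabitat,
#'   low, moderate, high) x AUI band (columns: low, high) to a management
#'   class name; must be total over the cross product.
#' @return list: `raster` (codes 3 core, 2 priority, 1 general, 0 nonhabitat,
#'   NA masked/nodata), `rule`, `aui_threshold`.
#' @export
management_categories <- function(category, aui, aui_threshold = 0.25,
                                  rule = default_management_rule()) {
  stop_unless_aligned(category, aui)
  if (!all(rule %in% names(MANAGEMENT_CODES))) {
    stop("rule must map every HSI category x AUI band to a management class",
         call. = FALSE)
  }
  cat_v <- category$values
  hi <- aui$values >= aui_threshold
  out <- matrix(NA_real_, nrow(cat_v), ncol(cat_v))
  ok <- !is.na(cat_v) & cat_v != MASK_CODE & !is.na(hi)
  cat_name <- names(CATEGORY_CODES)[match(cat_v[ok], CATEGORY_CODES)]
  band <- ifelse(hi[ok], "high_aui", "low_aui")
  out[ok] <- MANAGEMENT_CODES[rule[cbind(cat_name, band)]]
  list(raster = raster_like(category, out), rule = rule,
       aui_threshold = aui_threshold)
}

#' Areal shares of the management classes
#'
#' @param management `rsf_raster` of management codes.
#' @return named fractions over nonhabitat/general/priority/core (unmasked
#'   cells; sums to 1).
#' @export
management_shares <- function(management) {
  v <- management$values
  v <- v[!is.na(v)]
  shares <- vapply(MANAGEMENT_CODES, function(code) mean(v == code), 0)
  names(shares) <- names(MANAGEMENT_CODES)
  shares
}
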