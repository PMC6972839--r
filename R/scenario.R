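#' Pipeline configuration
#'
#' One structured object holding every tunable of the analysis chain, with
#' the study's constants as defaults: the three movement-based radii, the
#' 5:1 availability ratio with 1.0/0.2 weights, the 20-bird/100-location
#' site-season screen, the 0.1% rare-cover threshold, the |r| >= 0.65
#' collinearity cutoff, the 2.0 AICc-versus-null margin, the 1,451-m MCP
#' buffer, the 0.5/1/1.5 SD category multipliers and the 50-m feature mask.
#'
#' @param seed global integer seed.
#' @param radii candidate focal radii in metres, sorted ascending.
#' @param decay_m exponential-decay constant in metres.
#' @param ratio available points per used point.
#' @param min_birds,min_locs site-season screening thresholds.
#' @param rare_threshold minimum land-cover areal fraction of the MCP.
#' @param cutoff collinearity cutoff.
#' @param margin AICc-versus-null margin.
#' @param ci_level CI level for covariate retention and meta-analysis.
#' @param sd_mult category SD multipliers.
#' @param mask_buffer feature mask radius in metres.
#' @param buffer_m MCP buffer in metres.
#' @param split train/classification/validation bird fractions.
#' @param aui_threshold AUI band threshold for the management rule.
#' @param engine GLMM engine passed to [rsf()].
#' @param hsi_method HSI transform (`"logistic"` or `"minmax"`).
#' @param extrapolate apply site coefficients region-wide (the region-wide
#'   map convention) rather than only within buffered MCPs.
#' @return a list of class `rsf_config`.
#' @export
rsf_config <- function(seed = 1,
                       radii = c(167.9, 439.5, 1451.7),
                       decay_m = 1000, ratio = 5,
                       min_birds = 20, min_locs = 100,
                       rare_threshold = 0.001,
                       cutoff = 0.65, margin = 2, ci_level = 0.95,
                       sd_mult = c(0.5, 1, 1.5),
                       mask_buffer = 50, buffer_m = 1451,
                       split = c(0.8, 0.1, 0.1),
                       aui_threshold = 0.25,
                       engine = "auto", hsi_method = "logistic",
                       extrapolate = TRUE) {
  stopifnot(!is.unsorted(radii), all(radii > 0), ratio >= 1,
            min_birds > 0, min_locs > 0, rare_threshold > 0,
            cutoff > 0, margin > 0, mask_buffer > 0, buffer_m > 0,
            all(sd_mult > 0), abs(sum(split) - 1) < 1e-8)
  structure(as.list(environment()), class = "rsf_config")
}

#' Default synthetic study scenario
#'
#' Twelve rectangular sites on one 440 x 334-cell, 30-m landscape: ten
#' modelled sites (28 birds x 75 locations each, about 2,000 locations per
#' site) split five per hydrographic subregion (mesic west, xeric east), and
#' two small sites (8 birds x 25 locations) that fail the site-season screen
#' and serve as the outside-RSF validation set. The true selection model
#' acts on four standardized covariates - herbaceous cover and pinyon-juniper
#' cover at the 439.5-m radius, exponential-decay proximity to springs, and
#' elevation - with season-specific coefficients per subregion. Herbaceous
#' selection flips sign between subregions (+0.5 mesic, -0.5 xeric) so the
#' subregion grouping carries real signal, and pinyon-juniper avoidance is
#' stronger in the xeric subregion, mirroring the spring-avoidance contrast
#' seen in the field.
#'
#' @param n_birds,locs_per_bird per-site sample sizes for modelled sites.
#' @param config an [rsf_config()].
#' @return list of class `rsf_scenario`: `config`, `landscape_args`, `sites`,
#'   `truth`, `specs` (covariate spec table), `candidates` (per-family
#'   candidate columns), `families` (column -> family lookup).
#' @export
rsf_scenario <- function(n_birds = 28, locs_per_bird = 75, config = rsf_config()) {
  res <- 90; side <- 200L; margin <- 22L
  n_cols <- 4L * side + 5L * margin  # 910
  n_rows <- 3L * side + 4L * margin  # 688
  slot <- function(i, j) {
    c0 <- margin + (j - 1L) * (side + margin)
    r0 <- margin + (i - 1L) * (side + margin)
    c(xmin = c0 * res, xmax = (c0 + side) * res,
      ymin = r0 * res, ymax = (r0 + side) * res)
  }
  rows <- list()
  for (i in 1:3) for (j in 1:4) {
    sub <- if (j <= 2) "mesic" else "xeric"
    small <- (i == 3 && j %in% c(2, 3))
    rows[[length(rows) + 1L]] <- data.frame(
      site = sprintf("%s_%d%d", substr(sub, 1, 1), i, j), subregion = sub,
      t(slot(i, j)), modeled_target = !small,
      n_birds = if (small) 8L else n_birds,
      locs_per_bird = if (small) 25L else locs_per_bird
    )
  }
  sites <- do.call(rbind, rows)

  r <- config$radii
  specs <- rbind(
    covariate_spec("herb_168", "herbaceous", "focal-mean", r[1]),
    covariate_spec("herb_439", "herbaceous", "focal-mean", r[2]),
    covariate_spec("herb_1452", "herbaceous", "focal-mean", r[3]),
    covariate_spec("pj_168", "pinyon_juniper", "focal-mean", r[1]),
    covariate_spec("pj_439", "pinyon_juniper", "focal-mean", r[2]),
    covariate_spec("pj_1452", "pinyon_juniper", "focal-mean", r[3]),
    covariate_spec("spring_decay", "springs", "exp-decay-distance", config$decay_m),
    covariate_spec("spring_km", "springs", "linear-distance"),
    covariate_spec("elev_km", "elevation", "elevation-km")
  )
  truth_specs <- specs[specs$name %in%
                         c("herb_439", "pj_439", "spring_decay", "elev_km"), ]
  bvec <- function(h, p, s, e) {
    stats::setNames(c(h, p, s, e), truth_specs$name)
  }
  beta <- list(
    mesic = list(spring      = bvec(+0.5, -0.4, +0.2, +0.1),
                 summer_fall = bvec(+0.5, -0.4, +0.3, +0.4),
                 winter      = bvec(+0.5, -0.4, +0.1, -0.3)),
    xeric = list(spring      = bvec(-0.5, -0.9, +0.5, +0.1),
                 summer_fall = bvec(-0.5, -0.9, +0.8, +0.4),
                 winter      = bvec(-0.5, -0.9, +0.3, -0.3))
  )
  truth <- rsf_truth(beta, truth_specs, sites, sigma_bird = 0.3, sigma_year = 0.2)

  candidates <- list(
    herbaceous = c("herb_168", "herb_439", "herb_1452"),
    pinyon_juniper = c("pj_168", "pj_439", "pj_1452"),
    spring = c("spring_decay", "spring_km"),
    elevation = "elev_km"
  )
  families <- stats::setNames(
    rep(names(candidates), lengths(candidates)), unlist(candidates))

  field_params <- utils::modifyList(default_field_params(), list(
    herbaceous = list(range_m = 300), pinyon_juniper = list(range_m = 350),
    other_sagebrush = list(range_m = 400), bare_ground = list(range_m = 350),
    big_sagebrush = list(range_m = 450), elevation = list(range_m = 700),
    landcover = list(range_m = 600), meadow = list(range_m = 400)
  ))
  structure(list(
    config = config,
    landscape_args = list(n_rows = n_rows, n_cols = n_cols, resolution_m = res,
                          field_params = field_params, n_springs = 700),
    sites = sites, truth = truth, specs = specs,
    candidates = candidates, families = families,
    years = 2011:2012, n_leks = 24, aui_range_m = 3000,
    boundary_x = n_cols / 2 * res
  ), class = "rsf_scenario")
}

#' Majority-vote subregion label for a site
#'
#' A site straddling the hydrographic boundary is classified to the
#' subregion holding most of its telemetry locations.
#'
#' @param x planar x coordinates of the site's locations.
#' @param boundary_x boundary coordinate (mesic west of it, xeric east).
#' @return `"mesic"` or `"xeric"`.
#' @export
site_subregion <- function(x, boundary_x) {
  if (mean(x < boundary_x) >= 0.5) "mesic" else "xeric"
}
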