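#' Run the full seasonal habitat-mapping pipeline
#'
#' Executes every stage on a synthetic scenario: landscape and telemetry
#' generation, covariate stack, site-season screening and the bird-level
#' 80/10/10 split, buffered-MCP used-available tables, the two-step AICc RSF
#' fit per eligible site-season, cross-site meta-analysis by subregion,
#' seasonal HSI surfaces with subregion relativization and the annual
#' composite, 50-m feature masking, SD-threshold categorization from the
#' classification birds, three-way validation (held-out birds within RSF
#' sites, all locations from non-RSF sites, leks), and the AUI-joined HMI
#' with management categories.
#'
#' @param scenario an [rsf_scenario()].
#' @param seed integer seed driving every random stage.
#' @param out_dir optional directory; when given, coefficient tables, the
#'   meta-analysis, validation reports, key rasters (ASCII grid) and a JSON
#'   run manifest are written there.
#' @param quiet suppress stage messages.
#' @return an object of class `rsf_run` containing all stage outputs.
#' @export
run_rsf_pipeline <- function(scenario = rsf_scenario(), seed = 1,
                             out_dir = NULL, quiet = FALSE) {
  cfg <- scenario$config
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()

  say("[simulate] landscape %d x %d", scenario$landscape_args$n_rows,
      scenario$landscape_args$n_cols)
  landscape <- do.call(generate_landscape,
                       c(list(seed = seed), scenario$landscape_args))
  telemetry <- generate_telemetry(landscape, scenario$truth,
                                  n_birds = scenario$sites$n_birds,
                                  locs_per_bird = scenario$sites$locs_per_bird,
                                  years = scenario$years, seed = seed + 1)
  leks <- generate_leks(landscape, scenario$truth, n_leks = scenario$n_leks,
                        boundary_x = scenario$boundary_x, seed = seed + 2)
  telemetry$season <- assign_season(telemetry$date)

  say("[covariates] %d bands", nrow(scenario$specs))
  stack <- build_covariates(landscape, scenario$specs)
  grid <- grid_of(landscape)
  subregions <- raster_like(grid, {
    cc <- cell_centers(grid)
    matrix(ifelse(cc[, 1] < scenario$boundary_x, 1, 2),
           nrow(grid$values), ncol(grid$values))
  })

  say("[design] screening and splits")
  sites <- scenario$sites
  sites$subregion_assigned <- vapply(seq_len(nrow(sites)), function(i) {
    site_subregion(telemetry$x[telemetry$site == sites$site[i]],
                   scenario$boundary_x)
  }, "")
  counts <- do.call(rbind, lapply(split(telemetry, telemetry[c("season", "site")]),
    function(d) data.frame(site = d$site[1], season = d$season[1],
                           n_birds = length(unique(d$bird_id)), n_locs = nrow(d))))
  counts <- screen_site_seasons(counts, cfg$min_birds, cfg$min_locs)

  splits <- list(); extents <- list(); rare <- list()
  eligible_sites <- unique(counts$site[counts$eligible])
  for (i in seq_along(eligible_sites)) {
    st <- eligible_sites[i]
    d <- telemetry[telemetry$site == st, ]
    splits[[st]] <- split_by_bird(d$bird_id, cfg$split, seed = seed + 100 + i)
    extents[[st]] <- availability_extent(cbind(d$x, d$y), cfg$buffer_m)
    rare[[st]] <- screen_rare_covers(landscape$landcover,
                                     attr(extents[[st]], "hull"),
                                     cfg$rare_threshold)
  }

  say("[fit] weighted GLMMs with AICc selection")
  fits <- list(); ua_meta <- list()
  k <- 0L
  for (st in eligible_sites) {
    d <- telemetry[telemetry$site == st, ]
    train <- d[d$bird_id %in% splits[[st]]$train, ]
    for (ss in c("spring", "summer_fall", "winter")) {
      row <- counts[counts$site == st & counts$season == ss, ]
      if (!nrow(row) || !row$eligible) next
      k <- k + 1L
      tr <- train[train$season == ss, ]
      if (!nrow(tr)) next
      tab <- build_ua_table(tr, extents[[st]], stack, ratio = cfg$ratio,
                            seed = seed + 500 + k)
      fit <- rsf(tab, scenario$candidates, site = st, season = ss,
                 cutoff = cfg$cutoff, margin = cfg$margin, engine = cfg$engine)
      fits[[paste(st, ss, sep = ".")]] <- fit
      ua_meta[[paste(st, ss, sep = ".")]] <-
        data.frame(site = st, season = ss, n_used = fit$n_used, n = fit$n)
    }
    say("  %s done", st)
  }

  coef_table <- do.call(rbind, lapply(fits, function(f) {
    if (!nrow(f$retained)) return(NULL)
    data.frame(site = f$site, season = f$season,
               column = f$retained$term,
               covariate = unname(scenario$families[f$retained$term]),
               beta = f$retained$beta, se = f$retained$se_u,
               subregion = sites$subregion_assigned[match(f$site, sites$site)])
  }))
  rownames(coef_table) <- NULL

  say("[meta] pooling %d site-level coefficients", nrow(coef_table))
  meta <- group_meta(coef_table, level = cfg$ci_level)

  say("[map] HSI surfaces")
  seasons <- c("spring", "summer_fall", "winter")
  mask_feats <- list(
    lines = landscape$features$roads$lines,
    masks = c(landscape$features$lakes$masks, landscape$features$urban$masks)
  )
  seasonal <- list(); relativized <- list(); masks <- NULL
  for (ss in seasons) {
    ss_fits <- Filter(function(f) f$season == ss, fits)
    surfaces <- lapply(ss_fits, function(f) {
      s <- predict(f, stack = stack, type = "hsi")
      if (!cfg$extrapolate) {
        cc <- cell_centers(s)
        inside <- in_polygon(extents[[f$site]], cc)
        s$values[!matrix(inside, nrow(s$values), ncol(s$values))] <- NA_real_
      }
      s
    })
    rel <- average_and_relativize(surfaces, subregions)
    relativized[[ss]] <- rel
    mk <- mask_features(rel, mask_feats, cfg$mask_buffer)
    seasonal[[ss]] <- mk$raster
    masks <- mk$mask
  }
  composite <- seasonal_composite(seasonal$spring, seasonal$summer_fall,
                                  seasonal$winter)

  say("[categorize] SD thresholds from classification birds")
  classify_locs <- do.call(rbind, lapply(eligible_sites, function(st) {
    d <- telemetry[telemetry$site == st, ]
    d[d$bird_id %in% splits[[st]]$classify, ]
  }))
  class_values <- function(surface, locs) {
    vals <- extract_at(surface, cbind(locs$x, locs$y))
    sub <- ifelse(locs$x < scenario$boundary_x, 1, 2)
    keep <- is.finite(vals)
    split(vals[keep], sub[keep])
  }
  categories <- list(); thresholds <- list()
  for (ss in seasons) {
    locs <- classify_locs[classify_locs$season == ss, ]
    cz <- categorize(seasonal[[ss]], class_values(seasonal[[ss]], locs), subregions,
                     sd_mult = cfg$sd_mult)
    categories[[ss]] <- cz$raster
    thresholds[[ss]] <- cz$thresholds
  }
  cz <- categorize(composite, class_values(composite, classify_locs), subregions,
                   sd_mult = cfg$sd_mult)
  categories$composite <- cz$raster
  thresholds$composite <- cz$thresholds

  say("[validate] three datasets")
  validate_locs <- do.call(rbind, lapply(eligible_sites, function(st) {
    d <- telemetry[telemetry$site == st, ]
    d[d$bird_id %in% splits[[st]]$validate, ]
  }))
  outside_locs <- telemetry[!telemetry$site %in% eligible_sites, ]
  reports <- list()
  for (ss in seasons) {
    v <- validate_locs[validate_locs$season == ss, ]
    reports[[length(reports) + 1L]] <- cbind(
      map = ss, validate_map(categories[[ss]], cbind(v$x, v$y), v$bird_id,
                             dataset = "within-RSF"))
    o <- outside_locs[outside_locs$season == ss, ]
    if (nrow(o)) {
      reports[[length(reports) + 1L]] <- cbind(
        map = ss, validate_map(categories[[ss]], cbind(o$x, o$y), o$bird_id,
                               dataset = "outside-RSF"))
    }
  }
  reports[[length(reports) + 1L]] <- cbind(
    map = "composite", validate_map(categories$composite,
                                    cbind(validate_locs$x, validate_locs$y),
                                    validate_locs$bird_id, dataset = "within-RSF"))
  reports[[length(reports) + 1L]] <- cbind(
    map = "composite", validate_map(categories$composite,
                                    cbind(outside_locs$x, outside_locs$y),
                                    outside_locs$bird_id, dataset = "outside-RSF"))
  reports[[length(reports) + 1L]] <-
    lek_validation(leks, categories$spring, categories$composite)
  validation <- do.call(rbind, reports)

  say("[hmi] joint index")
  aui <- generate_aui(grid, leks, scenario$aui_range_m)
  hmi <- compute_hmi(composite, aui)
  mgmt <- management_categories(categories$composite, aui, cfg$aui_threshold)

  run <- structure(list(
    seed = seed, config = cfg, scenario = scenario,
    landscape = landscape, telemetry = telemetry, leks = leks,
    stack_names = names(stack), subregions = subregions,
    counts = counts, splits = splits, extents = extents, rare_covers = rare,
    fits = fits, coef_table = coef_table, meta = meta,
    seasonal = seasonal, relativized = relativized,
    composite = composite, mask = masks,
    categories = categories, thresholds = thresholds,
    validation = validation, aui = aui, hmi = hmi,
    management = mgmt$raster, management_rule = mgmt$rule,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "rsf_run")

  if (!is.null(out_dir)) write_run(run, out_dir)
  say("[done] %.1f s", run$elapsed_s)
  run
}

#' @export
print.rsf_run <- function(x, ...) {
  cat(sprintf("<rsf_run> seed %d: %d site-season RSFs, %d pooled effects, %.0f s\n",
              x$seed, length(x$fits), nrow(x$meta), x$elapsed_s))
  cat(sprintf("  telemetry: %d locations, %d birds, %d sites\n",
              nrow(x$telemetry), length(unique(x$telemetry$bird_id)),
              length(unique(x$telemetry$site))))
  cat(sprintf("  management shares: %s\n",
              paste(sprintf("%s %.1f%%", names(management_shares(x$management)),
                            100 * management_shares(x$management)), collapse = ", ")))
  invisible(x)
}

#' Write pipeline artifacts
#'
#' Coefficient, meta-analysis and validation tables as CSV; the composite
#' HSI, its categories, the HMI and the management map as ASCII grids; and a
#' machine-readable JSON manifest (seed, configuration, sample sizes,
#' package version).
#'
#' @param run an `rsf_run`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, `out_dir`.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$coef_table, file.path(out_dir, "site_coefficients.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(run$meta), file.path(out_dir, "meta_analysis.csv"),
                   row.names = FALSE)
  utils::write.csv(run$validation, file.path(out_dir, "validation.csv"),
                   row.names = FALSE)
  utils::write.csv(run$counts, file.path(out_dir, "site_season_counts.csv"),
                   row.names = FALSE)
  write_ascii_grid(run$composite, file.path(out_dir, "composite_hsi.asc"))
  cat_out <- run$categories$composite
  cat_out$values[is.na(cat_out$values) & run$mask] <- MASK_CODE
  write_ascii_grid(cat_out, file.path(out_dir, "composite_category.asc"))
  write_ascii_grid(run$hmi, file.path(out_dir, "hmi.asc"))
  write_ascii_grid(run$management, file.path(out_dir, "management.asc"))
  manifest <- list(
    seed = run$seed,
    package_version = as.character(utils::packageVersion("rsfmap")),
    config = run$config[!vapply(run$config, is.function, TRUE)],
    n_locations = nrow(run$telemetry),
    n_birds = length(unique(run$telemetry$bird_id)),
    n_fits = length(run$fits),
    management_shares = as.list(management_shares(run$management))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
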