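#' Cross-site meta-analysis of selection coefficients
#'
#' Site-level seasonal coefficients for a covariate are pooled by
#' inverse-variance weighting, within each hydrographic subregion (mesic,
#' xeric) and across all sites combined. Heterogeneity is quantified by
#' Cochran's Q, the I-squared percentage (binned low < 25%, moderate 25-75%,
#' high > 75%) and the DerSimonian-Laird tau-squared; random-effects pooling
#' adds tau-squared to each site variance. Selection or avoidance is called
#' consistent within a group when the CI excludes zero.
#'
#' @name meta-analysis
NULL

#' Fixed-effect inverse-variance pooling
#'
#' @param beta site-level estimates.
#' @param v site-level sampling variances (squared SEs), all > 0.
#' @return list with `beta` (pooled) and `se`.
#' @export
pool_fixed <- function(beta, v) {
  stopifnot(length(beta) >= 1, length(beta) == length(v), all(v > 0))
  w <- 1 / v
  list(beta = sum(w * beta) / sum(w), se = sqrt(1 / sum(w)))
}

#' Heterogeneity statistics
#'
#' Cochran's `Q = sum w_i (beta_i - beta_fixed)^2`, `I2 = max(0, (Q - df)/Q)`
#' in percent, and the DerSimonian-Laird
#' `tau2 = max(0, (Q - df) / (sum w - sum w^2 / sum w))` with `w = 1/v`.
#' A single site has no heterogeneity information: Q and I2 are reported as 0
#' with `df = 0`.
#'
#' @inheritParams pool_fixed
#' @return list with `Q`, `df`, `I2` (percent), `tau2`.
#' @export
heterogeneity <- function(beta, v) {
  k <- length(beta)
  if (k < 2) return(list(Q = 0, df = 0L, I2 = 0, tau2 = 0))
  w <- 1 / v
  bf <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - bf)^2)
  df <- k - 1L
  I2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  tau2 <- max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  list(Q = Q, df = df, I2 = I2, tau2 = tau2)
}

#' I-squared inconsistency label
#' @param I2 percentage in [0, 100].
#' @return `"low"` (< 25), `"moderate"` (25-75) or `"high"` (> 75).
#' @export
i2_label <- function(I2) {
  ifelse(I2 < 25, "low", ifelse(I2 > 75, "high", "moderate"))
}

#' Random-effects pooling (DerSimonian-Laird)
#'
#' @inheritParams pool_fixed
#' @param tau2 between-site variance; computed by [heterogeneity()] if missing.
#' @return list with `beta`, `se`, `tau2`.
#' @export
pool_random <- function(beta, v, tau2 = NULL) {
  if (is.null(tau2)) tau2 <- heterogeneity(beta, v)$tau2
  w <- 1 / (v + tau2)
  list(beta = sum(w * beta) / sum(w), se = sqrt(1 / sum(w)), tau2 = tau2)
}

#' Pool site-level coefficients by covariate, season and group
#'
#' @param coefs data frame of site-level results with columns `site`,
#'   `season`, `covariate` (the covariate family name), `beta`, `se`,
#'   `subregion` (`"mesic"` or `"xeric"`).
#' @param level CI level for the consistency call (default 0.95).
#' @param alt_level additional CI level emitted for forest plots (default
#'   0.85).
#' @return an `rsf_meta` data frame: one row per covariate x season x group
#'   (mesic, xeric, combined) with fixed- and random-effects estimates, SEs,
#'   CIs at both levels, Q, df, I2 (+ label), tau2 and the consistency flag.
#' @export
group_meta <- function(coefs, level = 0.95, alt_level = 0.85) {
  stopifnot(all(c("site", "season", "covariate", "beta", "se", "subregion") %in% names(coefs)))
  stopifnot(all(coefs$subregion %in% c("mesic", "xeric")))
  z <- stats::qnorm(1 - (1 - level) / 2)
  z_alt <- stats::qnorm(1 - (1 - alt_level) / 2)
  out <- list()
  for (ss in unique(coefs$season)) for (cv in unique(coefs$covariate)) {
    sub <- coefs[coefs$season == ss & coefs$covariate == cv, ]
    if (!nrow(sub)) next
    for (grp in c("mesic", "xeric", "combined")) {
      g <- if (grp == "combined") sub else sub[sub$subregion == grp, ]
      if (!nrow(g)) next
      v <- g$se^2
      het <- heterogeneity(g$beta, v)
      fx <- pool_fixed(g$beta, v)
      rd <- pool_random(g$beta, v, het$tau2)
      out[[length(out) + 1L]] <- data.frame(
        covariate = cv, season = ss, group = grp, k_sites = nrow(g),
        beta_fixed = fx$beta, se_fixed = fx$se,
        beta_random = rd$beta, se_random = rd$se,
        ci_lo = rd$beta - z * rd$se, ci_hi = rd$beta + z * rd$se,
        ci85_lo = rd$beta - z_alt * rd$se, ci85_hi = rd$beta + z_alt * rd$se,
        Q = het$Q, df = het$df, I2 = het$I2, i2_class = i2_label(het$I2),
        tau2 = het$tau2,
        consistent = (rd$beta - z * rd$se) > 0 | (rd$beta + z * rd$se) < 0
      )
    }
  }
  structure(do.call(rbind, out), class = c("rsf_meta", "data.frame"),
            level = level, alt_level = alt_level)
}

#' @export
print.rsf_meta <- function(x, ...) {
  cat(sprintf("<rsf_meta> %d pooled covariate x season x group results (CI %g%%)\n",
              nrow(x), 100 * attr(x, "level")))
  print.data.frame(
    x[, c("covariate", "season", "group", "k_sites", "beta_random",
          "ci_lo", "ci_hi", "I2", "i2_class", "consistent")],
    row.names = FALSE, digits = 3)
  invisible(x)
}

#' Forest plot of one covariate's pooled effects
#'
#' Site-level estimates with pooled (random-effects) diamonds per group,
#' 85% limits as in the seasonal forest displays.
#'
#' @param x an `rsf_meta` object.
#' @param covariate covariate name to plot.
#' @param coefs the site-level coefficient table used to build `x`
#'   (for the per-site rows); optional.
#' @param ... passed to [graphics::plot()].
#' @export
plot.rsf_meta <- function(x, covariate = x$covariate[1], coefs = NULL, ...) {
  m <- x[x$covariate == covariate, ]
  seasons <- unique(m$season)
  y <- 0; ys <- c(); labs <- c(); est <- c(); lo <- c(); hi <- c(); pch <- c()
  for (ss in seasons) {
    for (grp in c("combined", "mesic", "xeric")) {
      r <- m[m$season == ss & m$group == grp, ]
      if (!nrow(r)) next
      y <- y + 1
      ys <- c(ys, y); labs <- c(labs, paste(ss, grp))
      est <- c(est, r$beta_random); lo <- c(lo, r$ci85_lo); hi <- c(hi, r$ci85_hi)
      pch <- c(pch, c(combined = 16, mesic = 15, xeric = 17)[[grp]])
    }
    y <- y + 0.5
  }
  graphics::plot(est, ys, xlim = range(c(lo, hi, 0)), pch = pch, yaxt = "n",
                 xlab = "standardized coefficient (85% CI)", ylab = "",
                 main = covariate, ...)
  graphics::segments(lo, ys, hi, ys)
  graphics::abline(v = 0, lty = 2)
  graphics::axis(2, at = ys, labels = labs, las = 1, cex.axis = 0.7)
  invisible(x)
}
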