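#' Weighted used-available logistic mixed model
#'
#' Fits the weighted Bernoulli likelihood with a logit link, Gaussian random
#' intercepts for bird and year (crossed), and the used-available class
#' weights, by Laplace-approximate maximum likelihood (glmmTMB backend).
#' When the variance components collapse to the zero boundary, or the mixed
#' fit fails to converge, the model is refit as a weighted logistic GLM with
#' bird-clustered robust standard errors (sandwich estimator), which is the
#' same maximized likelihood restricted to the boundary.
#'
#' @param data used-available table with columns `used`, `weight`, the random
#'   effect grouping columns, and the covariate columns.
#' @param covariates character vector of fixed-effect column names (may be
#'   empty for a null, random-effects-only model).
#' @param random_effects grouping column names (default bird and year).
#' @param engine `"auto"` (mixed fit with boundary fallback), `"glmm"`
#'   (mixed fit only) or `"glm"` (fixed-effects fit with clustered SEs).
#' @return object of class `rsf_glmm`: coefficients, SEs, vcov, maximized
#'   log-likelihood, parameter count `k` (fixed effects + variance
#'   components), `n`, convergence and boundary flags, engine used, and the
#'   random-intercept SDs.
#' @export
fit_weighted_glmm <- function(data, covariates = character(),
                              random_effects = c("bird", "year"),
                              engine = c("auto", "glmm", "glm")) {
  engine <- match.arg(engine)
  stopifnot(all(data$used %in% c(0, 1)), all(data$weight > 0))
  rhs_fix <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  n <- nrow(data)
  k_re <- length(random_effects)

  glm_fit <- function() {
    f <- stats::as.formula(paste("used ~", rhs_fix))
    m <- suppressWarnings(stats::glm(f, family = stats::binomial(), data = data,
                                     weights = data$weight))
    p <- stats::fitted(m)
    ll <- sum(data$weight * (data$used * log(p) + (1 - data$used) * log1p(-p)))
    V <- if (k_re >= 1 && "bird" %in% random_effects) {
      sandwich::vcovCL(m, cluster = data[["bird"]])
    } else {
      stats::vcov(m)
    }
    sep <- any(p > 1 - 1e-8) || any(p < 1e-8)
    list(coef = stats::coef(m), se = sqrt(diag(V)), vcov = V, loglik = ll,
         converged = m$converged, boundary = TRUE, separation = sep,
         engine = "glm", varcomp = stats::setNames(rep(0, k_re), random_effects))
  }

  glmm_fit <- function() {
    f <- stats::as.formula(paste(
      "used ~", rhs_fix,
      if (k_re) paste("+", paste(sprintf("(1 | %s)", random_effects), collapse = " + ")) else ""
    ))
    m <- tryCatch(
      suppressWarnings(glmmTMB::glmmTMB(f, data = data, family = stats::binomial(),
                                        weights = data$weight)),
      error = function(e) NULL
    )
    if (is.null(m)) return(NULL)
    conv <- isTRUE(m$fit$convergence == 0) && isTRUE(m$sdr$pdHess)
    vc <- glmmTMB::VarCorr(m)$cond
    sds <- vapply(random_effects, function(g) {
      if (is.null(vc[[g]])) 0 else attr(vc[[g]], "stddev")[[1]]
    }, 0)
    V <- tryCatch(stats::vcov(m)$cond, error = function(e) NULL)
    if (is.null(V)) return(NULL)
    b <- glmmTMB::fixef(m)$cond
    list(coef = b, se = sqrt(diag(V)), vcov = V, loglik = as.numeric(stats::logLik(m)),
         converged = conv, boundary = all(sds < 1e-4), separation = FALSE,
         engine = "glmm", varcomp = sds)
  }

  fit <- NULL
  if (engine %in% c("auto", "glmm") && k_re > 0) {
    fit <- glmm_fit()
    if (engine == "auto" && (is.null(fit) || !fit$converged || fit$boundary)) fit <- NULL
    if (engine == "glmm" && is.null(fit)) {
      return(structure(list(converged = FALSE, n = n, k = length(covariates) + 1L + k_re),
                       class = "rsf_glmm"))
    }
  }
  if (is.null(fit)) fit <- glm_fit()

  fit$n <- n
  fit$k <- length(fit$coef) + k_re
  fit$covariates <- covariates
  structure(fit, class = "rsf_glmm")
}

#' @export
print.rsf_glmm <- function(x, ...) {
  cat(sprintf("<rsf_glmm> %s fit, n = %d, k = %d, logLik = %.3f%s\n",
              x$engine, x$n, x$k, x$loglik,
              if (isTRUE(x$boundary)) " (variance at boundary)" else ""))
  print(round(cbind(estimate = x$coef, se = x$se), 4))
  invisible(x)
}

#' Small-sample corrected AIC
#'
#' `-2 logLik + 2k + 2k(k+1)/(n - k - 1)`; reduces to AIC as `n` grows.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters (fixed effects, intercept and
#'   variance components).
#' @param n sample size.
#' @return the AICc score.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc requires n > k + 1", call. = FALSE)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

aicc_of <- function(fit) aicc(fit$loglik, fit$k, fit$n)

#' Choose a covariate's scale by AICc against the null model
#'
#' Fits one single-covariate model per candidate scale/form and carries
#' forward the lowest-AICc candidate, provided it beats the random-effects
#' null by at least `margin` AICc units; otherwise the covariate is dropped.
#' Ties go to the first candidate in the supplied order (candidates are
#' conventionally ordered smallest radius first).
#'
#' @param data used-available table.
#' @param candidates character vector of candidate column names.
#' @param null_fit fitted null model ([fit_weighted_glmm()] with no covariates).
#' @param margin required AICc improvement over the null (default 2).
#' @inheritParams fit_weighted_glmm
#' @return list: `chosen` (column name or `NA` if dropped), `aicc`,
#'   `aicc_null`, `delta_null`, and the per-candidate AICc table.
#' @export
select_scale <- function(data, candidates, null_fit,
                         random_effects = c("bird", "year"), margin = 2,
                         engine = "auto") {
  stopifnot(length(candidates) >= 1)
  fits <- lapply(candidates, function(cn) {
    fit_weighted_glmm(data, cn, random_effects, engine)
  })
  ok <- vapply(fits, function(f) isTRUE(f$converged), TRUE)
  if (!any(ok)) stop("all candidate fits failed", call. = FALSE)
  scores <- rep(Inf, length(fits))
  scores[ok] <- vapply(fits[ok], aicc_of, 0)
  best <- which.min(scores)  # first minimum wins ties
  a_null <- aicc_of(null_fit)
  chosen <- if (scores[best] <= a_null - margin) candidates[best] else NA_character_
  list(chosen = chosen, aicc = scores[best], aicc_null = a_null,
       delta_null = a_null - scores[best], fit = fits[[best]],
       table = data.frame(candidate = candidates, aicc = scores))
}

#' Drop collinear covariates
#'
#' Pearson correlations over the design rows; while any pair reaches the
#' cutoff, the currently most-correlated pair is resolved by dropping its
#' higher-AICc member (from the univariate scale-selection fits).
#'
#' @param data used-available table.
#' @param cols covariate columns carried forward.
#' @param aicc_values named vector of univariate AICc per column.
#' @param cutoff absolute-correlation cutoff (default 0.65, inclusive).
#' @return list: `keep` (surviving columns), `dropped` (data frame of drops).
#' @export
correlation_screen <- function(data, cols, aicc_values, cutoff = 0.65) {
  stopifnot(length(cols) >= 1, all(cols %in% names(aicc_values)))
  keep <- cols
  dropped <- data.frame(column = character(), against = character(), r = numeric())
  while (length(keep) >= 2) {
    C <- abs(stats::cor(data[, keep, drop = FALSE]))
    diag(C) <- 0
    m <- max(C)
    if (m < cutoff) break
    ij <- which(C == m, arr.ind = TRUE)[1, ]
    pair <- keep[ij]
    loser <- pair[which.max(aicc_values[pair])]
    dropped <- rbind(dropped, data.frame(column = loser,
                                         against = setdiff(pair, loser)[1], r = m))
    keep <- setdiff(keep, loser)
  }
  list(keep = keep, dropped = dropped)
}

#' Fit the two-covariate model set
#'
#' All `choose(m, 2)` additive two-covariate models over the retained
#' covariates; with a single retained covariate the set is its univariate
#' model.
#'
#' @param data used-available table.
#' @param cols retained covariate columns.
#' @inheritParams fit_weighted_glmm
#' @return list of `rsf_glmm` fits.
#' @export
pairwise_model_set <- function(data, cols, random_effects = c("bird", "year"),
                               engine = "auto") {
  if (length(cols) < 1) stop("no covariates to combine", call. = FALSE)
  sets <- if (length(cols) == 1L) list(cols) else
    utils::combn(cols, 2L, simplify = FALSE)
  lapply(sets, function(cv) fit_weighted_glmm(data, cv, random_effects, engine))
}

#' Model-averaged coefficients with unconditional SEs
#'
#' Akaike weights `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)` over the
#' converged models; each term is averaged over the models containing it with
#' renormalized weights (natural averaging), and its unconditional standard
#' error follows Buckland: `SE_u = sum_i w_i sqrt(SE_i^2 + (b_i - b_bar)^2)`.
#' Confidence limits use the 1.96 multiplier.
#'
#' @param fits list of `rsf_glmm` fits (non-converged fits are dropped and
#'   weights renormalized).
#' @param z CI multiplier (default 1.96 for 95%).
#' @return data frame with `term`, `beta`, `se_u`, `lo`, `hi`, `n_models`,
#'   `weight`; the per-model AICc/weight ledger is attached as attribute
#'   `"models"`.
#' @export
model_average <- function(fits, z = 1.96) {
  ok <- vapply(fits, function(f) isTRUE(f$converged), TRUE)
  if (!any(ok)) stop("no converged models to average", call. = FALSE)
  if (!all(ok)) warning(sprintf("%d non-converged model(s) omitted from averaging",
                                sum(!ok)))
  fits <- fits[ok]
  a <- vapply(fits, aicc_of, 0)
  d <- a - min(a)
  w <- exp(-d / 2); w <- w / sum(w)
  terms <- unique(unlist(lapply(fits, function(f) names(f$coef))))
  rows <- lapply(terms, function(tm) {
    has <- vapply(fits, function(f) tm %in% names(f$coef), TRUE)
    wi <- w[has] / sum(w[has])
    bi <- vapply(fits[has], function(f) f$coef[[tm]], 0)
    si <- vapply(fits[has], function(f) f$se[[tm]], 0)
    bbar <- sum(wi * bi)
    se_u <- sum(wi * sqrt(si^2 + (bi - bbar)^2))
    data.frame(term = tm, beta = bbar, se_u = se_u,
               lo = bbar - z * se_u, hi = bbar + z * se_u,
               n_models = sum(has), weight = sum(w[has]))
  })
  out <- do.call(rbind, rows)
  attr(out, "models") <- data.frame(
    model = vapply(fits, function(f) paste(f$covariates, collapse = "+"), ""),
    aicc = a, delta = d, weight = w
  )
  out
}

#' Retain covariates whose unconditional CI excludes zero
#'
#' @param averaged output of [model_average()].
#' @return `averaged` restricted to retained covariates (intercept always
#'   kept); attribute `"excluded"` lists the CI-overlapping terms. Warns when
#'   every covariate is excluded (intercept-only RSF).
#' @export
finalize_rsf <- function(averaged) {
  is_int <- averaged$term == "(Intercept)"
  keep <- is_int | averaged$lo > 0 | averaged$hi < 0
  if (all(is_int | !keep)) {
    warning("all covariates excluded by the zero-overlap rule; intercept-only RSF")
  }
  out <- averaged[keep, , drop = FALSE]
  attr(out, "excluded") <- averaged$term[!keep]
  attr(out, "models") <- attr(averaged, "models")
  out
}

#' Fit a seasonal resource selection function
#'
#' The full two-step procedure for one site-season used-available table:
#' (1) per covariate, pick the best scale/form by AICc and require a >= 2
#' AICc improvement over the random-effects null; (2) screen the carried
#' covariates for collinearity (|r| >= 0.65, dropping the higher-AICc
#' member); (3) fit all two-covariate additive models; (4) model-average with
#' Akaike weights and Buckland unconditional SEs; (5) retain covariates whose
#' 95% unconditional CI excludes zero.
#'
#' @param table used-available table from [build_ua_table()].
#' @param candidates named list: covariate name -> ordered character vector of
#'   candidate column names (smallest scale first; order breaks AICc ties).
#' @param site,season labels stored on the fit.
#' @param cutoff collinearity cutoff (default 0.65).
#' @param margin AICc-versus-null margin (default 2).
#' @inheritParams fit_weighted_glmm
#' @return an object of class `rsf` with [print()], [summary()], [coef()] and
#'   [predict()] methods.
#' @export
rsf <- function(table, candidates, site = NA_character_, season = NA_character_,
                random_effects = c("bird", "year"), cutoff = 0.65, margin = 2,
                engine = c("auto", "glmm", "glm")) {
  engine <- match.arg(engine)
  null_fit <- fit_weighted_glmm(table, character(), random_effects, engine)

  selection <- lapply(names(candidates), function(nm) {
    s <- select_scale(table, candidates[[nm]], null_fit, random_effects,
                      margin = margin, engine = engine)
    s$covariate <- nm
    s
  })
  names(selection) <- names(candidates)
  carried <- vapply(selection, function(s) s$chosen, "")
  carried <- carried[!is.na(carried)]
  sel_aicc <- stats::setNames(
    vapply(selection, function(s) s$aicc, 0)[names(carried)], carried)

  screen <- if (length(carried)) {
    correlation_screen(table, unname(carried), sel_aicc, cutoff)
  } else {
    list(keep = character(), dropped = data.frame())
  }

  if (length(screen$keep)) {
    fits <- pairwise_model_set(table, screen$keep, random_effects, engine)
    averaged <- model_average(fits)
    final <- finalize_rsf(averaged)
  } else {
    warning(sprintf("no covariate beat the null for %s/%s; intercept-only RSF",
                    site, season))
    final <- data.frame(term = "(Intercept)",
                        beta = null_fit$coef[["(Intercept)"]],
                        se_u = null_fit$se[["(Intercept)"]],
                        lo = NA_real_, hi = NA_real_, n_models = 1L, weight = 1)
    averaged <- final
  }

  structure(list(
    site = site, season = season,
    candidates = candidates,
    selection = data.frame(
      covariate = names(selection),
      chosen = vapply(selection, function(s) s$chosen, ""),
      aicc = vapply(selection, function(s) s$aicc, 0),
      delta_null = vapply(selection, function(s) s$delta_null, 0)
    ),
    screen = screen,
    averaged = averaged,
    retained = final[final$term != "(Intercept)", , drop = FALSE],
    intercept = final$beta[final$term == "(Intercept)"],
    scaling = attr(table, "scaling"),
    n_used = attr(table, "n_used") %||% sum(table$used == 1),
    n = nrow(table),
    null_aicc = aicc_of(null_fit)
  ), class = "rsf")
}

#' @export
print.rsf <- function(x, ...) {
  cat(sprintf("<rsf> site %s, season %s: %d used / %d rows\n",
              x$site, x$season, x$n_used, x$n))
  if (nrow(x$retained)) {
    cat("  retained (model-averaged, 95% unconditional CI):\n")
    r <- x$retained
    for (i in seq_len(nrow(r))) {
      cat(sprintf("    %-24s %+0.3f  [%+0.3f, %+0.3f]\n",
                  r$term[i], r$beta[i], r$lo[i], r$hi[i]))
    }
  } else {
    cat("  intercept-only RSF (no covariate retained)\n")
  }
  invisible(x)
}

#' @export
summary.rsf <- function(object, ...) {
  cat(sprintf("Seasonal RSF - site %s, season %s\n", object$site, object$season))
  cat(sprintf("n used = %d, design rows = %d, null AICc = %.2f\n\n",
              object$n_used, object$n, object$null_aicc))
  cat("Scale selection (AICc vs random-effects null):\n")
  print(object$selection, row.names = FALSE, digits = 5)
  if (nrow(object$screen$dropped)) {
    cat("\nDropped by |r| >= 0.65 screen:\n")
    print(object$screen$dropped, row.names = FALSE)
  }
  cat("\nModel-averaged coefficients:\n")
  print(object$averaged, row.names = FALSE, digits = 4)
  invisible(object)
}

#' @export
coef.rsf <- function(object, ...) {
  stats::setNames(c(object$intercept, object$retained$beta),
                  c("(Intercept)", object$retained$term))
}

#' Predict from a fitted RSF
#'
#' Evaluates the model-averaged linear predictor (random effects at zero)
#' either on new rows of covariate values or cellwise over a covariate raster
#' stack, standardizing with the training moments.
#'
#' @param object an `rsf` fit.
#' @param newdata data frame of raw covariate columns (optional).
#' @param stack named list of covariate `rsf_raster`s (optional).
#' @param type `"link"` for the linear predictor or `"hsi"` for its
#'   inverse-logit.
#' @param ... unused.
#' @return numeric vector (for `newdata`) or `rsf_raster` (for `stack`).
#' @export
predict.rsf <- function(object, newdata = NULL, stack = NULL,
                        type = c("link", "hsi"), ...) {
  type <- match.arg(type)
  terms <- object$retained$term
  beta <- object$retained$beta
  sc <- object$scaling
  if (!is.null(stack)) {
    missing <- setdiff(terms, names(stack))
    if (length(missing)) {
      stop("stack lacks covariate band(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    template <- stack[[1]]
    eta <- matrix(object$intercept, nrow(template$values), ncol(template$values))
    for (i in seq_along(terms)) {
      z <- (stack[[terms[i]]]$values - sc$mean[[terms[i]]]) / sc$sd[[terms[i]]]
      eta <- eta + beta[i] * z
    }
    na <- Reduce(`|`, lapply(stack[terms], function(r) is.na(r$values)),
                 matrix(FALSE, nrow(eta), ncol(eta)))
    eta[na] <- NA_real_
    out <- raster_like(template, if (type == "hsi") stats::plogis(eta) else eta)
    return(out)
  }
  stopifnot(!is.null(newdata))
  eta <- rep(object$intercept, nrow(newdata))
  for (i in seq_along(terms)) {
    z <- (newdata[[terms[i]]] - sc$mean[[terms[i]]]) / sc$sd[[terms[i]]]
    eta <- eta + beta[i] * z
  }
  if (type == "hsi") stats::plogis(eta) else eta
}
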