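## Candidate scaling families.  Each is an OLS fit in a transformed space:
##   linear       y ~ x
##   loglinear    y ~ log(x)
##   power        log(y) ~ log(x)
##   exponential  log(y) ~ x
## BICs of log-y and raw-y fits are made comparable on the original y scale
## by adding the log-Jacobian of the response transform (sum(log y)) to the
## negative log-likelihood, i.e. BIC_adj = BIC + 2 * sum(log(y)).
ontogeny_families <- c("linear", "loglinear", "power", "exponential")

family_spec <- function(family) {
  switch(family,
    linear      = list(logy = FALSE, logx = FALSE, eq = "y = %.4g + %.4g * x"),
    loglinear   = list(logy = FALSE, logx = TRUE,  eq = "y = %.4g + %.4g * log(x)"),
    power       = list(logy = TRUE,  logx = TRUE,  eq = "y = %.4g * x^%.4g"),
    exponential = list(logy = TRUE,  logx = FALSE, eq = "y = %.4g * exp(%.4g * x)"),
    stop_invalid("unknown family '", family, "'"))
}

fit_one_family <- function(x, y, family) {
  sp <- family_spec(family)
  xt <- if (sp$logx) log(x) else x
  yt <- if (sp$logy) log(y) else y
  fit <- stats::lm(yt ~ xt)
  ## exact relations trip summary.lm's perfect-fit warning; they are a
  ## legitimate input here (noise-free synthetic checks)
  sm <- suppressWarnings(summary(fit))
  bic <- stats::BIC(fit) + if (sp$logy) 2 * sum(log(y)) else 0
  co <- stats::coef(fit)
  eq <- if (sp$logy) sprintf(sp$eq, exp(co[1]), co[2]) else sprintf(sp$eq, co[1], co[2])
  structure(list(family = family, coefficients = unname(co),
                 intercept = unname(co[1]), slope = unname(co[2]),
                 r_squared = sm$r.squared,
                 p_value = unname(sm$coefficients[2, 4]),
                 df = unname(fit$df.residual), bic = bic,
                 log_y = sp$logy, log_x = sp$logx, equation = eq,
                 n = length(y), lm = fit),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> %s: %s  (R2 = %.3f, p = %.3g, df = %d, BIC = %.2f)\n",
              x$family, x$equation, x$r_squared, x$p_value, x$df, x$bic))
  invisible(x)
}

#' Normality check for trait distributions
#'
#' Shapiro-Wilk test of a sample together with the transform decision used
#' throughout the scaling analyses: log-transform when the raw sample fails
#' normality at the 5% level and the logged sample passes it or at least
#' improves the W statistic.
#'
#' @param x numeric sample, 3 <= n <= 5000, non-constant.
#' @param alpha significance level for the decision (default 0.05).
#' @return list with `W`, `p`, and -- when `x` is positive -- `W_log`,
#'   `p_log` and the logical `log_recommended`.
#' @export
check_normality <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 3L || length(x) > 5000L)
    stop_invalid("Shapiro-Wilk needs 3 <= n <= 5000")
  if (stats::sd(x) == 0) stop_invalid("constant sample: normality undefined")
  sw <- stats::shapiro.test(x)
  out <- list(W = unname(sw$statistic), p = sw$p.value)
  if (all(x > 0)) {
    swl <- stats::shapiro.test(log(x))
    out$W_log <- unname(swl$statistic)
    out$p_log <- swl$p.value
    out$log_recommended <- out$p < alpha && (swl$p.value >= alpha || swl$statistic > sw$statistic)
  } else {
    out$log_recommended <- FALSE
  }
  out
}

#' Fit candidate scaling models of a trait against bell diameter
#'
#' Least-squares fits of up to four monotone families (linear, log-linear,
#' power and exponential) with BIC-based selection.  BICs are compared on
#' the original response scale (log-Jacobian correction for log-response
#' families), so families with different response transforms compete
#' fairly.  Log families are skipped with a warning when the response has
#' non-positive values.
#'
#' @param x bell diameters (cm), positive.
#' @param y trait values.
#' @param families subset of `c("linear", "loglinear", "power",
#'   "exponential")`.
#' @return An object of class `"ontogeny_fits"`: list with `fits` (one
#'   `model_fit` per family), `best` (the minimum-BIC fit), and `table`
#'   (family, equation, R2, p, df, BIC).
#' @export
fit_models <- function(x, y, families = ontogeny_families) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4L) stop_invalid("need at least 4 complete observations")
  if (any(x <= 0)) stop_invalid("diameters must be positive")
  families <- match.arg(families, ontogeny_families, several.ok = TRUE)
  if (any(y <= 0)) {
    bad <- intersect(families, c("power", "exponential"))
    if (length(bad)) {
      warning("non-positive trait values: skipping families ",
              paste(bad, collapse = ", "))
      families <- setdiff(families, bad)
    }
  }
  if (!length(families)) stop_invalid("no applicable model family")
  fits <- lapply(families, function(fm) fit_one_family(x, y, fm))
  names(fits) <- families
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  best <- fits[[which.min(bics)]]
  tab <- data.frame(family = families,
                    equation = vapply(fits, `[[`, character(1), "equation"),
                    r_squared = vapply(fits, `[[`, numeric(1), "r_squared"),
                    p_value = vapply(fits, `[[`, numeric(1), "p_value"),
                    df = vapply(fits, `[[`, numeric(1), "df"),
                    bic = bics, row.names = NULL)
  structure(list(fits = fits, best = best, table = tab), class = "ontogeny_fits")
}

#' @export
print.ontogeny_fits <- function(x, ...) {
  cat("<ontogeny_fits> best family:", x$best$family, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Group-wise scaling regressions with confidence bands
#'
#' Independent BIC-selected fits per taxonomic co-factor level (order or
#' family), each with a 95% confidence band on the mean response over a
#' diameter grid (bands from the transformed-space fit, back-transformed
#' for log-response families).  Groups with fewer than `min_n` points are
#' omitted with a warning.
#'
#' @param data data.frame.
#' @param x,y,group column names for diameter, trait and co-factor.
#' @param families candidate families, as in [fit_models()].
#' @param min_n minimum observations per group (default 4).
#' @param grid_length points in the prediction grid.
#' @param level confidence level (default 0.95).
#' @return named list per group: `fit` (an `"ontogeny_fits"`) and `band`
#'   (data.frame `x`, `fit`, `lwr`, `upr`).
#' @export
regress_by_group <- function(data, x, y, group, families = ontogeny_families,
                             min_n = 4, grid_length = 50, level = 0.95) {
  out <- list()
  for (g in unique(data[[group]])) {
    d <- data[data[[group]] == g & stats::complete.cases(data[[x]], data[[y]]), ]
    if (nrow(d) < min_n) {
      warning("group '", g, "' has fewer than ", min_n, " points; omitted")
      next
    }
    fits <- fit_models(d[[x]], d[[y]], families)
    best <- fits$best
    grid <- seq(min(d[[x]]), max(d[[x]]), length.out = grid_length)
    newx <- if (best$log_x) log(grid) else grid
    pr <- stats::predict(best$lm, newdata = data.frame(xt = newx),
                         interval = "confidence", level = level)
    if (best$log_y) pr <- exp(pr)
    out[[as.character(g)]] <- list(fit = fits,
                                   band = data.frame(x = grid, fit = pr[, "fit"],
                                                     lwr = pr[, "lwr"], upr = pr[, "upr"]))
  }
  out
}

#' Size-normalized species trait values (allometric correction)
#'
#' Removes the ontogenetic size dependence of a trait by fitting the
#' BIC-selected scaling model to the *pooled* data (all species together)
#' and averaging the residuals per species in the fitted model's
#' transformed space.  When the pooled regression slope is not significant
#' (p > `alpha`) there is no size trend to remove and the residuals reduce
#' to centered trait values (intercept-only regression in the same
#' transformed space).
#'
#' @param data data.frame.
#' @param trait,diameter,species column names.
#' @param families candidate families, as in [fit_models()].
#' @param alpha significance threshold for the pooled slope (default 0.05).
#' @return data.frame `species`, `residual_mean`, `n`, with attributes
#'   `"fit"` (the pooled `"ontogeny_fits"`) and `"size_dependent"`.
#' @export
allometric_normalize <- function(data, trait, diameter = "diameter_cm",
                                 species = "species",
                                 families = ontogeny_families, alpha = 0.05) {
  keep <- stats::complete.cases(data[[diameter]], data[[trait]])
  d <- data[keep, ]
  if (!nrow(d)) stop_invalid("no complete observations for trait '", trait, "'")
  fits <- fit_models(d[[diameter]], d[[trait]], families)
  best <- fits$best
  yt <- if (best$log_y) log(d[[trait]]) else d[[trait]]
  size_dependent <- is.finite(best$p_value) && best$p_value <= alpha
  res <- if (size_dependent) stats::residuals(best$lm) else yt - mean(yt)
  agg <- stats::aggregate(res, by = list(species = d[[species]]), FUN = mean)
  n <- stats::aggregate(res, by = list(species = d[[species]]), FUN = length)
  out <- data.frame(species = agg$species, residual_mean = agg$x, n = n$x)
  attr(out, "fit") <- fits
  attr(out, "size_dependent") <- size_dependent
  out
}

#' Species-level size-normalized trait table
#'
#' Applies [allometric_normalize()] to each trait column and assembles the
#' species x trait matrix of residual means consumed by the correlation,
#' ordination and phylogenetic-signal stages.
#'
#' @param data data.frame with one row per analyzed sequence.
#' @param traits character vector of trait column names.
#' @param diameter,species column names.
#' @param families,alpha passed to [allometric_normalize()].
#' @return data.frame with rownames = species and one column per trait;
#'   attribute `"fits"` holds the pooled fits per trait.
#' @export
species_trait_table <- function(data, traits, diameter = "diameter_cm",
                                species = "species",
                                families = ontogeny_families, alpha = 0.05) {
  sp <- sort(unique(data[[species]]))
  out <- data.frame(row.names = sp)
  fits <- list()
  for (tr in traits) {
    norm <- allometric_normalize(data, tr, diameter, species, families, alpha)
    out[[tr]] <- norm$residual_mean[match(sp, norm$species)]
    fits[[tr]] <- attr(norm, "fit")
  }
  attr(out, "fits") <- fits
  out
}
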