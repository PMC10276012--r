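test_that("normality check calibrates on normal and log-normal samples", {
  hits_normal <- sum(vapply(1:200, function(s) {
    x <- with_seed_local(s, rnorm(100))
    check_normality(x)$p > 0.05
  }, logical(1)))
  expect_gte(hits_normal, 180)  # ~95% expected at the 5% level

  hits_lognormal <- sum(vapply(1:200, function(s) {
    x <- with_seed_local(1000 + s, exp(rnorm(100, sd = 1)))
    res <- check_normality(x)
    res$p < 0.05 && res$log_recommended
  }, logical(1)))
  expect_gte(hits_lognormal, 180)

  expect_error(check_normality(c(1, 2)), "3 <= n")
  expect_error(check_normality(rep(2, 10)), "constant")
})

test_that("exact relations pick their family with the right coefficients", {
  x <- seq(0.5, 8, length.out = 30)
  f <- fit_models(x, 2 * x)
  expect_identical(f$best$family, "linear")
  expect_equal(f$best$slope, 2, tolerance = 1e-9)
  expect_equal(f$best$r_squared, 1, tolerance = 1e-9)
  fp <- fit_models(x, 3 * x^0.8)
  expect_identical(fp$best$family, "power")
  expect_equal(fp$best$slope, 0.8, tolerance = 1e-9)
  expect_equal(exp(fp$best$intercept), 3, tolerance = 1e-9)
  expect_error(fit_models(x[1:3], (2 * x)[1:3]), "at least 4")
  expect_warning(fit_models(x, x - 1), "skipping")
})

test_that("BIC selection recovers a noisy power law and its exponent", {
  wins <- 0; exps <- numeric(0)
  for (s in 1:40) {
    d <- generate_ontogenetic_dataset(
      list(A = list(y = c(a = 3, b = 0.8, sd = 0.1))),
      diameters = exp(seq(log(0.2), log(9), length.out = 200)),
      seed = 5000 + s)
    f <- fit_models(d$diameter_cm, d$y)
    wins <- wins + (f$best$family == "power")
    exps <- c(exps, f$best$slope)
  }
  expect_gte(wins, 36)  # >= 90%
  expect_lt(max(abs(exps - 0.8)), 0.05)
})

test_that("BIC selection gets more reliable as n grows", {
  rate <- function(n) {
    mean(vapply(1:30, function(s) {
      d <- generate_ontogenetic_dataset(
        list(A = list(y = c(a = 2, b = 0.6, sd = 0.25))),
        diameters = exp(with_seed_local(7000 + s, runif(n, log(0.3), log(8)))),
        seed = 8000 + s)
      fit_models(d$diameter_cm, d$y)$best$family == "power"
    }, logical(1)))
  }
  expect_gte(rate(500), rate(50))
})

test_that("group-wise regressions recover group differences; single group reduces to fit_models", {
  d1 <- generate_ontogenetic_dataset(
    list(A = list(y = c(a = 2, b = 0.5, sd = 0.08))),
    diameters = exp(seq(log(0.3), log(8), length.out = 80)), seed = 21)
  d2 <- generate_ontogenetic_dataset(
    list(B = list(y = c(a = 2, b = 1.1, sd = 0.08))),
    diameters = exp(seq(log(0.3), log(8), length.out = 80)), seed = 22)
  d <- rbind(d1, d2)
  res <- regress_by_group(d, "diameter_cm", "y", "species")
  expect_named(res, c("A", "B"))
  expect_lt(res$A$fit$best$slope, res$B$fit$best$slope)
  single <- regress_by_group(d1, "diameter_cm", "y", "species")
  direct <- fit_models(d1$diameter_cm, d1$y)
  expect_equal(single$A$fit$best$coefficients, direct$best$coefficients,
               tolerance = 1e-12)
  expect_true(all(c("fit", "lwr", "upr") %in% names(single$A$band)))
  expect_true(all(single$A$band$lwr <= single$A$band$upr))
  expect_warning(
    regress_by_group(d1[1:6, ], "diameter_cm", "y", "species", min_n = 10),
    "omitted")
})

test_that("allometric residuals are zero on-trend and recover species offsets", {
  D <- exp(seq(log(0.3), log(8), length.out = 60))
  on_trend <- data.frame(species = rep(c("A", "B"), each = 60),
                         diameter_cm = c(D, D), y = c(2 * D^0.7, 2 * D^0.7))
  norm <- allometric_normalize(on_trend, "y")
  expect_equal(norm$residual_mean, c(0, 0), tolerance = 1e-9)

  ## one species offset by +delta in log space under a power-law truth:
  ## expected residual means computed by an independent OLS fit
  delta <- 0.4
  off <- on_trend
  off$y[off$species == "B"] <- off$y[off$species == "B"] * exp(delta)
  fit <- lm(log(y) ~ log(diameter_cm), data = off)
  expected <- tapply(residuals(fit), off$species, mean)
  got <- allometric_normalize(off, "y")
  expect_equal(got$residual_mean, as.numeric(expected[got$species]), tolerance = 1e-9)
  expect_equal(got$residual_mean[got$species == "B"], delta / 2, tolerance = 1e-9)

  single <- allometric_normalize(on_trend[on_trend$species == "A", ], "y")
  expect_equal(single$residual_mean, 0, tolerance = 1e-9)
})

test_that("non-significant pooled slopes reduce to centered trait values", {
  set.seed(33)
  d <- data.frame(species = rep(c("A", "B"), each = 20),
                  diameter_cm = rep(exp(seq(log(0.5), log(5), length.out = 20)), 2),
                  y = exp(rnorm(40, sd = 0.2)))  # no size trend
  norm <- allometric_normalize(d, "y")
  expect_false(attr(norm, "size_dependent"))
  yt <- log(d$y)
  expected <- tapply(yt - mean(yt), d$species, mean)
  expect_equal(norm$residual_mean, as.numeric(expected[norm$species]), tolerance = 1e-9)
})

test_that("residual means are size-independent and average to zero", {
  for (s in 1:20) {
    d <- generate_ontogenetic_dataset(
      list(A = list(y = c(a = 1.5, b = 0.9, sd = 0.15)),
           B = list(y = c(a = 2.5, b = 0.9, sd = 0.15))),
      diameters = exp(seq(log(0.3), log(7), length.out = 50)),
      seed = 9000 + s)
    fits <- fit_models(d$diameter_cm, d$y)
    res <- residuals(fits$best$lm)
    ## grand mean of residuals is 0 (OLS with intercept) and regressing them
    ## on the transformed predictor gives a numerically null slope
    expect_lt(abs(mean(res)), 1e-10)
    xt <- if (fits$best$log_x) log(d$diameter_cm) else d$diameter_cm
    expect_lt(abs(coef(lm(res ~ xt))[2]), 1e-10)
  }
})

test_that("species trait table assembles residual means per trait", {
  d <- generate_ontogenetic_dataset(
    list(A = list(u = c(a = 1, b = 0.6, sd = 0.1), f = c(a = 0.5, b = 0, sd = 0.05)),
         B = list(u = c(a = 1.6, b = 0.6, sd = 0.1), f = c(a = 0.7, b = 0, sd = 0.05))),
    diameters = exp(seq(log(0.4), log(6), length.out = 30)), seed = 77)
  tab <- species_trait_table(d, c("u", "f"))
  expect_identical(rownames(tab), c("A", "B"))
  expect_identical(colnames(tab), c("u", "f"))
  ## weighted (equal n) means of residuals vanish per trait
  expect_equal(colMeans(tab), c(u = 0, f = 0), tolerance = 1e-9)
  ## the faster species sits above the pooled trend
  expect_gt(tab["B", "u"], tab["A", "u"])
})
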