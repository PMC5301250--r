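test_that("an exact power law is fitted exactly", {
  a <- c(12, 40, 120, 650, 2200)
  e <- 10 * a^2
  fit <- fit_loglog(a, e)
  expect_equal(unname(coef(fit)), c(1, 2), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_lt(max(abs(residuals(fit, "raw"))), 1e-10)
  expect_equal(unname(residuals(fit, "studentised")), rep(0, 5))
  rep <- classify_outliers(fit)
  expect_equal(rep$high_stats$n, 0)
  expect_equal(rep$low_stats$n, 0)
})

test_that("coefficients match the closed-form normal equations", {
  a <- c(15, 80, 210, 900, 4000)
  e <- c(3e3, 9e3, 1.1e5, 2.4e5, 3.3e6)
  fit <- fit_loglog(a, e)
  x <- log10(a); y <- log10(e)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  r2 <- 1 - sum((y - intercept - slope * x)^2) / sum((y - mean(y))^2)
  expect_equal(unname(coef(fit)), c(intercept, slope))
  expect_equal(fit$r_squared, r2)
  # order invariance
  perm <- c(3, 1, 5, 2, 4)
  fit2 <- fit_loglog(a[perm], e[perm], ids = as.character(perm))
  expect_equal(coef(fit2), coef(fit))
  expect_equal(unname(residuals(fit2)[order(perm)]), unname(residuals(fit)))
})

test_that("studentised residuals match the textbook formula on a 6-point
           fixture", {
  a <- c(10, 25, 60, 150, 400, 1000)
  e <- c(220, 300, 2400, 3100, 2.1e4, 9.8e4)
  fit <- fit_loglog(a, e)
  x <- log10(a); y <- log10(e); n <- 6
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  res <- y - (mean(y) - slope * mean(x)) - slope * x
  h <- 1 / n + (x - mean(x))^2 / sxx
  s2 <- sum(res^2) / (n - 2)
  expect_equal(unname(residuals(fit, "studentised")),
               res / sqrt(s2 * (1 - h)))
})

test_that("residuals of data symmetric about the line come in +/- pairs", {
  # duplicated predictor values give every point the same leverage, so
  # symmetric deviations give exactly opposite studentised residuals
  x <- c(1, 1, 3, 3)
  dev <- c(0.3, -0.3, 0.3, -0.3)     # orthogonal to x, mean zero
  fit <- fit_loglog(10^x, 10^(2 + x + dev))
  r <- unname(residuals(fit, "studentised"))
  expect_equal(r[1], -r[2])
  expect_equal(r[3], -r[4])
  expect_equal(r[1], r[3])
})

test_that("the fit is scale-equivariant in the emissions unit", {
  set.seed(10)
  a <- 10^runif(30, 1, 4)
  e <- 10^(0.5 + 1.1 * log10(a) + rnorm(30, 0, 0.3))
  f1 <- fit_loglog(a, e)
  f10 <- fit_loglog(a, e * 10)       # annual vs decade totals etc.
  expect_equal(coef(f10)["slope"], coef(f1)["slope"])
  expect_equal(unname(coef(f10)["intercept"] - coef(f1)["intercept"]), 1)
  expect_equal(f10$r_squared, f1$r_squared)
  expect_equal(residuals(f10), residuals(f1))
})

test_that("zero-emission PAs are excluded from the fit but kept in the
           report denominators", {
  a <- c(10, 20, 40, 80, 160)
  e <- c(100, 0, 400, 900, 0)
  fit <- fit_loglog(a, e, ids = letters[1:5])
  expect_equal(fit$n, 3)
  expect_equal(fit$excluded$id, c("b", "e"))
  rep <- classify_outliers(fit)
  expect_equal(rep$n_total, 5)
  expect_error(fit_loglog(c(10, 20), c(1, 2)), "at least 3")
  expect_error(fit_loglog(rep(5, 10), 1:10), "degenerate")
})

test_that("outlier classification uses a strict threshold and coherent
           shares", {
  set.seed(4)
  a <- 10^runif(40, 1, 4)
  e <- 10^(1 + log10(a) + rnorm(40, 0, 0.2))
  fit <- fit_loglog(a, e)
  r <- residuals(fit, "studentised")
  rep <- classify_outliers(fit, threshold = max(abs(r)))  # boundary: not flagged
  expect_equal(rep$high_stats$n + rep$low_stats$n, 0)
  rep2 <- classify_outliers(fit, threshold = 1)
  expect_setequal(rep2$high$id, names(r)[r > 1])
  expect_setequal(rep2$low$id, names(r)[r < -1])
  inlier_em <- sum(e) - sum(rep2$high$emissions) - sum(rep2$low$emissions)
  expect_equal(rep2$high_stats$emission_share + rep2$low_stats$emission_share +
                 inlier_em / sum(e), 1)
  # all residuals inside the band: both sets empty
  rep3 <- classify_outliers(fit, threshold = 10)
  expect_equal(rep3$high_stats$n, 0)
  expect_equal(rep3$low_stats$n, 0)
})

test_that("with Gaussian residual noise the false-flag rate sits near the
           nominal 2-sigma tail", {
  set.seed(77)
  a <- 10^runif(2000, 1, 4)
  e <- 10^(0.2 + 0.9 * log10(a) + rnorm(2000, 0, 0.25))
  rep <- classify_outliers(fit_loglog(a, e))
  expect_gt(rep$high_stats$n / 2000, 0.005)
  expect_lt(rep$high_stats$n / 2000, 0.05)
  expect_gt(rep$low_stats$n / 2000, 0.005)
  expect_lt(rep$low_stats$n / 2000, 0.05)
})

test_that("concentration finds the minimal prefix reaching the target", {
  c1 <- concentration(c(80, 10, 5, 5), 0.8)
  expect_equal(c1$n_pas, 1)
  expect_equal(c1$fraction, 0.25)
  c2 <- concentration(rep(4, 10), 0.8)
  expect_equal(c2$n_pas, 8)          # ceiling(0.8 n) under equal emissions
  set.seed(12)
  for (i in 1:20) {
    e <- rexp(sample(5:60, 1))
    target <- runif(1, 0.1, 1)
    got <- concentration(e, target)
    sorted <- sort(e, decreasing = TRUE)
    want <- min(which(cumsum(sorted) / sum(sorted) >= target - 1e-12))
    expect_equal(got$n_pas, want)
  }
  full <- concentration(c(5, 0, 3, 2), 1)
  expect_equal(full$n_pas, 3)        # every non-zero PA
  expect_equal(max(full$cumulative_share), 1)
  expect_true(all(diff(full$cumulative_share) >= -1e-15))
  expect_error(concentration(c(0, 0)), "all emissions are zero")
  # ties broken by stable original order
  tie <- concentration(c(3, 5, 3, 5), 0.5, ids = c("a", "b", "c", "d"))
  expect_equal(tie$subset_ids, c("b", "d"))
})

test_that("category and country summaries match a groupby recomputation", {
  sim <- small_sim()
  res <- suppressWarnings(pa_pipeline(sim$scene, sim$records))$results
  cs <- suppressWarnings(summarise_categories(res))
  one <- cs$by_category[cs$by_category$n >= 1, ][1, ]
  sub <- res[res$iucn_cat == one$iucn_cat, ]
  expect_equal(one$mean_carbon_density_mg_ha,
               mean(sub$carbon_stock_mg / sub$forest_area_ha))
  expect_equal(one$median_rate_pct_yr,
               unname(quantile(sub$annual_loss_rate_pct_yr, 0.5, type = 7)))
  want_country <- tapply(res$carbon_loss_mg, res$country, sum)
  expect_equal(cs$by_country$carbon_loss_mg,
               as.vector(want_country[cs$by_country$country]))
  want_stock <- tapply(res$carbon_stock_mg, res$country, sum)
  expect_equal(cs$by_country$prop_protected_carbon_lost,
               as.vector(want_country[cs$by_country$country] /
                           want_stock[cs$by_country$country]))
  # a single-category cohort reduces to the cohort mean
  solo <- res; solo$iucn_cat <- "II"
  solo_cs <- suppressWarnings(summarise_categories(solo))
  expect_equal(solo_cs$by_category$mean_rate_pct_yr,
               mean(res$annual_loss_rate_pct_yr))
  # zero-loss country reports zero proportional loss
  z <- res; z$carbon_loss_mg[z$country == z$country[1]] <- 0
  z_cs <- suppressWarnings(summarise_categories(z))
  expect_equal(z_cs$by_country$prop_protected_carbon_lost[
    z_cs$by_country$country == z$country[1]], 0)
})
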