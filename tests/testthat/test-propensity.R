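test_that("LPM equals the explicit normal-equations solution", {
  p <- test_params(n_countries = 3, mothers_per_country = 800)
  d <- collapse_to_deliveries(generate_birth_histories(p))
  f <- twin_lpm(d)
  oracle <- lpm_oracle(d)
  est <- coef(f)
  expect_equal(est[names(oracle)], oracle, tolerance = 1e-10)
  # delivery-weighted mean of fitted probabilities equals the twin fraction
  fitted <- predict(f, d)
  expect_equal(mean(fitted), mean(d$twin), tolerance = 1e-10)
  # reference category coefficient is exactly zero
  expect_identical(unname(f$age_coefficients[f$reference]), 0)
})

test_that("null age effects are recovered as zeros within 3 SE", {
  ae0 <- setNames(rep(0, 7), age_levels("5-year"))
  p <- test_params(n_countries = 2, mothers_per_country = 8000,
                   age_effects = ae0)
  d <- collapse_to_deliveries(generate_birth_histories(p))
  f <- twin_lpm(d)
  z <- f$age_coefficients[-1] / f$se[names(f$age_coefficients)[-1]]
  expect_true(all(abs(z) < 3))
})

test_that("saturated one-country fit reproduces the age-cell means", {
  p <- test_params(n_countries = 1, mothers_per_country = 4000,
                   country_baselines = c(AAA = 0.015))
  d <- collapse_to_deliveries(generate_birth_histories(p))
  f <- twin_lpm(d)
  cell <- tapply(d$twin, d$age_category, mean)
  # with one country the design is saturated in age: intercept = reference
  # cell mean, age coefficient = cell mean difference (exact OLS property)
  expect_equal(unname(f$country_effects[["AAA"]]), unname(cell[["15-19"]]),
               tolerance = 1e-10)
  for (a in names(f$age_coefficients)[-1])
    expect_equal(unname(f$age_coefficients[[a]]),
                 unname(cell[[a]] - cell[["15-19"]]), tolerance = 1e-10)
})

test_that("design degeneracies are handled: empty category, zero variation", {
  d <- deliveries_df(rep(c("AAA", "BBB"), each = 40),
                     age = rep(c(17, 22, 27, 32), 20), twin = 0)
  d$twin[c(1, 7)] <- 1
  expect_warning(f <- twin_lpm(d), "empty age categor")
  expect_true(all(c("20-24", "25-29", "30-34") %in% names(f$age_coefficients)))
  expect_false("35-39" %in% names(f$age_coefficients))
  # a country with zero twin variation (BBB, all singletons) is retained
  expect_true("BBB" %in% names(f$country_effects))
})

test_that("country-rate point estimates are the observed twin fractions", {
  d <- deliveries_df("AAA", age = 25, twin = rep(c(1, 0), c(60, 3940)))
  r <- fit_country_rates(d, n_draws = 50, seed = 2)
  expect_equal(unname(r$point[["AAA"]]), 0.015, tolerance = 1e-12)
  # zero-twin country: point 0, draws degenerate at 0
  d0 <- deliveries_df("CCC", age = 25, twin = rep(0, 100))
  r0 <- fit_country_rates(d0, n_draws = 50, seed = 2)
  expect_identical(unname(r0$point[["CCC"]]), 0)
  expect_true(all(r0$draws == 0))
  # permutation invariance
  p <- test_params(mothers_per_country = 500)
  dd <- collapse_to_deliveries(generate_birth_histories(p))
  r1 <- fit_country_rates(dd, n_draws = 20, seed = 5)
  r2 <- fit_country_rates(dd[sample(nrow(dd)), ], n_draws = 20, seed = 5)
  expect_equal(r1$point, r2$point)
  # points x 1000 reproduce observed twins-per-1000 exactly
  expect_equal(1000 * r1$point, observed_twinning_rates(dd))
})

test_that("posterior draws are seeded, centred and degenerate when exact", {
  p <- test_params(mothers_per_country = 2000)
  d <- collapse_to_deliveries(generate_birth_histories(p))
  f <- twin_lpm(d)
  expect_identical(draw_posterior(f, 200, seed = 7)$draws,
                   draw_posterior(f, 200, seed = 7)$draws)
  big <- draw_posterior(f, 50000, seed = 8)
  mu <- coef(f)
  for (nm in names(mu)) {
    mc_se <- sd(big$draws[, nm]) / sqrt(50000)
    expect_lt(abs(mean(big$draws[, nm]) - mu[[nm]]), 3 * mc_se + 1e-12)
  }
  # zero covariance: every draw equals the point estimate
  f0 <- f
  f0$vcov[] <- 0
  p0 <- draw_posterior(f0, 20, seed = 9)
  expect_true(all(abs(sweep(p0$draws, 2, coef(f0))) < 1e-12))
})

test_that("estimated age profile peaks at 35-39 under the default truth", {
  # an older-weighted fertility schedule keeps the 40+ cells large, and the
  # post-peak decline is made resolvable at this sample size (the default
  # decline of 0.0005-0.002 would need millions of deliveries to separate)
  fs <- setNames(c(0.08, 0.15, 0.2, 0.17, 0.15, 0.15, 0.1),
                 age_levels("5-year"))
  ae <- setNames(c(0, 0.002, 0.0045, 0.007, 0.010, 0.006, 0.004),
                 age_levels("5-year"))
  p <- test_params(n_countries = 2, mothers_per_country = 40000,
                   fertility_schedule = fs, age_effects = ae)
  d <- collapse_to_deliveries(generate_birth_histories(p))
  f <- twin_lpm(d)
  expect_identical(names(which.max(f$age_coefficients)), "35-39")
})

test_that("per-country fits match the pooled fit and identical data", {
  p <- test_params(n_countries = 1, mothers_per_country = 3000,
                   country_baselines = c(AAA = 0.02))
  d <- collapse_to_deliveries(generate_birth_histories(p))
  single <- suppressWarnings(fit_per_country(d))
  pooled <- twin_lpm(d)
  expect_equal(single$estimates["AAA", names(pooled$age_coefficients)],
               pooled$age_coefficients, tolerance = 1e-10,
               ignore_attr = TRUE)
  # two countries with identical data give identical coefficient rows
  d2 <- d; d2$country <- "BBB"; d2$mother_id <- sub("AAA", "BBB", d2$mother_id)
  both <- suppressWarnings(fit_per_country(rbind(d, d2)))
  expect_equal(unname(both$estimates["AAA", ]), unname(both$estimates["BBB", ]))
})

test_that("random-effects pooling matches the hand-computed DL oracle", {
  pc <- structure(list(
    estimates = matrix(c(0, 0, 0, 0.01, 0.02, 0.015), 3, 2,
                       dimnames = list(c("A", "B", "C"), c("15-19", "35-39"))),
    se = matrix(c(NA, NA, NA, 0.002, 0.004, 0.003), 3, 2,
                dimnames = list(c("A", "B", "C"), c("15-19", "35-39"))),
    age_scheme = "5-year", pooled = NULL), class = "twin_meta")
  m <- meta_analyze(pc)
  o <- dl_pool(c(0.01, 0.02, 0.015), c(0.002, 0.004, 0.003))
  row <- m$pooled[m$pooled$age_category == "35-39", ]
  expect_equal(row$pooled, o$est, tolerance = 1e-10)
  expect_equal(row$se, o$se, tolerance = 1e-10)
  expect_equal(row$tau2, o$tau2, tolerance = 1e-10)

  # identical estimates with equal SEs: pooled = common value, tau2 = 0
  pc$estimates[, "35-39"] <- 0.012
  pc$se[, "35-39"] <- 0.002
  m2 <- meta_analyze(pc)
  expect_equal(m2$pooled$pooled[m2$pooled$age_category == "35-39"], 0.012,
               tolerance = 1e-12)
  expect_equal(m2$pooled$tau2[m2$pooled$age_category == "35-39"], 0,
               tolerance = 1e-12)

  # two symmetric estimates 0 and 0.02 with equal SE pool to the midpoint
  pc2 <- pc
  pc2$estimates <- pc$estimates[1:2, ]; pc2$se <- pc$se[1:2, ]
  pc2$estimates[, "35-39"] <- c(0, 0.02); pc2$se[, "35-39"] <- 0.004
  m3 <- meta_analyze(pc2)
  expect_equal(m3$pooled$pooled[m3$pooled$age_category == "35-39"], 0.01,
               tolerance = 1e-10)

  # single-country category is fixed to that estimate and flagged
  pc3 <- pc
  pc3$se[2:3, "35-39"] <- NA
  expect_warning(m4 <- meta_analyze(pc3), "single country")
  expect_true(m4$pooled$single_country[m4$pooled$age_category == "35-39"])
})

test_that("per-country heterogeneous truth is recovered within 3 SE", {
  p <- synth_params(
    country_baselines = c(LOW = 0.008, HIGH = 0.024),
    mothers_per_country = 25000, seed = 31)
  d <- collapse_to_deliveries(generate_birth_histories(p))
  pc <- fit_per_country(d)
  tv <- true_values(p)
  for (cc in c("LOW", "HIGH")) {
    for (a in c("25-29", "35-39")) {
      z <- (pc$estimates[cc, a] - tv$age_effects[[a]]) / pc$se[cc, a]
      expect_lt(abs(z), 3)
    }
  }
})
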