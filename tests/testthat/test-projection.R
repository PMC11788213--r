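uniform_shares <- function() setNames(rep(1 / 7, 7), age_levels("5-year"))

# minimal posterior/rates pair with controllable draws
fake_posterior <- function(draws_mat, countries, reference = "15-19") {
  structure(list(draws = draws_mat, point = colMeans(draws_mat),
                 countries = countries,
                 age_levels = age_levels("5-year"), reference = reference,
                 seed = 0L, n_draws = nrow(draws_mat)),
            class = "age_posterior")
}
fake_rates <- function(tr_draws, country = "AAA") {
  draws <- matrix(tr_draws, ncol = 1, dimnames = list(NULL, country))
  structure(list(point = setNames(mean(tr_draws), country),
                 se = setNames(sd(tr_draws), country),
                 n = setNames(1000L, country), draws = draws,
                 n_draws = length(tr_draws), seed = 0L),
            class = "country_rates")
}
toy_posterior <- function(n_draws, gamma = 0.01, beta3539 = 0.01,
                          country = "AAA") {
  lev <- age_levels("5-year")
  cols <- c(country, lev[-1])
  m <- matrix(0, n_draws, length(cols), dimnames = list(NULL, cols))
  m[, country] <- gamma
  m[, "35-39"] <- beta3539
  fake_posterior(m, country)
}

test_that("births convert to deliveries by b/(1+tr) and back", {
  expect_equal(deliveries_from_births(1000, 0), 1000)
  expect_equal(deliveries_from_births(1015, 0.015), 1000)
  d <- deliveries_from_births(123456, 0.0187)
  expect_equal(d + d * 0.0187, 123456, tolerance = 1e-12)
  expect_error(deliveries_from_births(100, 1), "\\[0, 1\\)")
  expect_error(deliveries_from_births(-1, 0.1), "nonnegative")
})

test_that("partitioning deliveries preserves the total", {
  s <- uniform_shares()
  expect_equal(unname(partition_deliveries(700, s)), rep(100, 7))
  one <- setNames(c(1, rep(0, 6)), age_levels("5-year"))
  expect_equal(unname(partition_deliveries(500, one)),
               c(500, rep(0, 6)))
  wpp_like <- setNames(c(0.1, 0.24, 0.27, 0.2, 0.12, 0.05, 0.02),
                       age_levels("5-year"))
  expect_equal(partition_deliveries(10000, wpp_like), 10000 * wpp_like)
  expect_equal(sum(partition_deliveries(987.65, wpp_like)), 987.65)
  expect_error(partition_deliveries(10, c(uniform_shares()[-1], x = -1/7)),
               "negative")
})

test_that("age probabilities add country and age draws, with closure", {
  post <- toy_posterior(5)
  p_raw <- age_probabilities(post, "AAA", mode = "raw")
  expect_equal(unname(p_raw[1, "35-39"]), 0.020)
  expect_equal(unname(p_raw[1, "15-19"]), 0.010)
  # all age draws zero: profile flat at the country effect
  post0 <- toy_posterior(3, gamma = 0.013, beta3539 = 0)
  expect_true(all(age_probabilities(post0, "AAA", mode = "raw") == 0.013))
  # recentered: implied baseline rate equals tr draw by draw
  s <- uniform_shares()
  tr <- c(0.011, 0.013, 0.017, 0.02, 0.005)
  p_rc <- age_probabilities(post, "AAA", mode = "recentered",
                            baseline_shares = s, tr_draws = tr)
  expect_equal(as.numeric(p_rc %*% s), tr, tolerance = 1e-12)
  expect_error(age_probabilities(post, "ZZZ", mode = "raw"), "ZZZ")
})

test_that("expected twin deliveries follow the mixture identities", {
  d_a <- partition_deliveries(1000, uniform_shares())
  p_flat <- setNames(rep(0.02, 7), age_levels("5-year"))
  r <- expected_twin_deliveries(d_a, p_flat)
  expect_equal(r$implied_tr, 0.02, tolerance = 1e-12) # mixture invariance
  expect_equal(r$dt, 20, tolerance = 1e-12)
  p0 <- setNames(rep(0, 7), age_levels("5-year"))
  expect_equal(expected_twin_deliveries(d_a, p0)$dt, 0)
  # shifting mass toward a higher-probability group raises the implied rate
  p_inc <- setNames(seq(0.005, 0.02, length.out = 7), age_levels("5-year"))
  young <- setNames(c(0.6, 0.4, 0, 0, 0, 0, 0), age_levels("5-year"))
  old <- setNames(c(0.4, 0.6, 0, 0, 0, 0, 0), age_levels("5-year"))
  r_y <- expected_twin_deliveries(partition_deliveries(1000, young), p_inc)
  r_o <- expected_twin_deliveries(partition_deliveries(1000, old), p_inc)
  expect_gt(r_o$implied_tr, r_y$implied_tr)
  expect_error(expected_twin_deliveries(d_a[1:5], p_flat), "match")
})

test_that("percent change is computed per draw, not on summaries", {
  expect_equal(pct_change(55, 50), 10)
  expect_equal(pct_change(50, 50), 0)
  expect_error(pct_change(5, 0), "nonzero")
  # skewed draws: median of per-draw changes != change of medians
  base <- c(1, 1, 10)
  scen <- c(2, 1.1, 10)
  per_draw <- median(pct_change(scen, base))
  of_medians <- pct_change(median(scen), median(base))
  expect_false(isTRUE(all.equal(per_draw, of_medians)))
})

test_that("twin-sibling ratio inverts the share of twin-pair children", {
  expect_equal(twin_sibling_ratio(0.5), 1.5)
  r <- twin_sibling_ratio(0.0069)
  expect_gt(r, 72); expect_lt(r, 74)
  expect_warning(expect_equal(twin_sibling_ratio(0), Inf), "infinite")
  # limit behaviour: decreasing tr increases the ratio
  expect_gt(twin_sibling_ratio(0.001), twin_sibling_ratio(0.002))
})

test_that("identity and scale scenarios behave exactly", {
  lev <- age_levels("5-year")
  shares <- setNames(c(0.1, 0.24, 0.27, 0.2, 0.12, 0.05, 0.02), lev)
  base <- projection_input("AAA", 2010, 1e5, shares)
  set.seed(21)
  post <- toy_posterior(200)
  post$draws[, "35-39"] <- rnorm(200, 0.01, 0.002)
  post$draws[, "AAA"] <- rnorm(200, 0.012, 0.001)
  rates <- fake_rates(rnorm(200, 0.014, 0.001))

  idt <- run_scenario(base, base, rates, post)
  expect_true(all(idt$pct_change_rate == 0))
  expect_true(all(idt$pct_change_count == 0))
  # Eq (3) closure at baseline, recentered mode: b = d + dt per draw
  expect_equal(idt$d + idt$dt, rep(1e5, 200), tolerance = 1e-6 * 1e5)
  # baseline implied rate equals the tr draw (closure by construction)
  expect_equal(idt$implied_tr, pmin(pmax(rates$draws[, "AAA"], 0), 0.999),
               tolerance = 1e-12)

  # doubling births with fixed shares: +100% count, 0% rate, every draw
  double <- projection_input("AAA", 2050, 2e5, shares)
  sc <- run_scenario(base, double, rates, post)
  expect_equal(sc$pct_change_count, rep(100, 200), tolerance = 1e-9)
  expect_true(all(sc$pct_change_rate == 0))
  # scale equivariance: d and dt double, tr unchanged
  expect_equal(sc$d, 2 * idt$d, tolerance = 1e-12)
  expect_equal(sc$dt, 2 * idt$dt, tolerance = 1e-9)
})

test_that("older-shifted scenarios raise the twinning rate when the
           profile increases with age", {
  lev <- age_levels("5-year")
  young <- setNames(c(0.25, 0.3, 0.2, 0.12, 0.08, 0.04, 0.01), lev)
  old <- shift_schedule(shift_schedule(young, 0.5), 0.5)
  base <- projection_input("AAA", 2010, 1e5, young)
  scen <- projection_input("AAA", 2100, 1e5, old)
  set.seed(22)
  post <- toy_posterior(400)
  for (i in seq(2, 7))
    post$draws[, lev[i]] <- rnorm(400, 0.0018 * (i - 1), 0.0006)
  post$draws[, "AAA"] <- rnorm(400, 0.012, 0.001)
  rates <- fake_rates(rnorm(400, 0.015, 0.001))
  sc <- run_scenario(base, scen, rates, post)
  expect_gte(mean(sc$pct_change_rate > 0), 0.95)
  # monotonicity: with a per-draw nondecreasing age profile (age increments
  # fixed, country level random), first-order older shares never decrease
  # the implied rate
  post_mono <- toy_posterior(100)
  for (i in seq(2, 7)) post_mono$draws[, lev[i]] <- 0.0018 * (i - 1)
  set.seed(23)
  post_mono$draws[, "AAA"] <- rnorm(100, 0.012, 0.001)
  rates_mono <- fake_rates(rnorm(100, 0.015, 0.001))
  for (k in 1:5) {
    s1 <- shift_schedule(young, 0.1 * k)
    s2 <- shift_schedule(young, 0.1 * k + 0.05)
    sc1 <- run_scenario(base, projection_input("AAA", 2100, 1e5, s1),
                        rates_mono, post_mono)
    sc2 <- run_scenario(base, projection_input("AAA", 2100, 1e5, s2),
                        rates_mono, post_mono)
    expect_true(all(sc2$implied_tr - sc1$implied_tr > -1e-12))
  }
})

test_that("run_scenario validates its inputs", {
  s <- uniform_shares()
  base <- projection_input("AAA", 2010, 1e5, s)
  other <- projection_input("BBB", 2050, 1e5, s)
  post <- toy_posterior(10)
  rates <- fake_rates(rep(0.015, 10))
  expect_error(run_scenario(base, other, rates, post), "same country")
  rates5 <- fake_rates(rep(0.015, 5))
  expect_error(run_scenario(base, base, rates5, post), "draw")
  expect_error(projection_input("AAA", 2010, 1e5, s * 2), "sum to 1")
  expect_error(projection_input("AAA", 2010, -1, s), "births")
})

test_that("decomposition contributions add up exactly", {
  lev <- age_levels("5-year")
  # two active age groups keep the hand enumeration simple
  W_b <- setNames(c(1000, 800, rep(0, 5)), lev)
  A_b <- setNames(c(0.10, 0.08, rep(0.001, 5)), lev)
  W_s <- setNames(c(900, 1100, rep(0, 5)), lev)
  A_s <- setNames(c(0.09, 0.12, rep(0.001, 5)), lev)
  births_b <- sum(W_b * A_b); births_s <- sum(W_s * A_s)
  mk <- function(yr, b, W, A) projection_input(
    "AAA", yr, b, setNames(W * A / sum(W * A), lev), women = W, asfr = A)
  base <- mk(2010, births_b, W_b, A_b)
  scen <- mk(2100, births_s, W_s, A_s)
  post <- toy_posterior(50)
  set.seed(30)
  post$draws[, "20-24"] <- rnorm(50, 0.004, 0.001)
  rates <- fake_rates(rnorm(50, 0.012, 0.001))
  dc <- decompose_change(base, scen, rates, post)

  for (part in list(dc$rate, dc$count)) {
    expect_equal(rowSums(part$sequential), part$total, tolerance = 1e-12)
    expect_equal(rowSums(part$shapley), part$total, tolerance = 1e-12)
    expect_equal(rowSums(part$main) + part$interaction, part$total,
                 tolerance = 1e-12)
  }

  # hand enumeration of the four rate counterfactuals for draw 1
  p1 <- age_probabilities(post, "AAA", mode = "recentered",
                          baseline_shares = base$shares,
                          tr_draws = pmin(pmax(rates$draws[, "AAA"], 0), 0.999))[1, ]
  v <- function(W, A) sum(p1 * W * A / sum(W * A))
  tot <- v(W_s, A_s) - v(W_b, A_b)
  asfr_first <- v(W_b, A_s) - v(W_b, A_b)
  comp_second <- v(W_s, A_s) - v(W_b, A_s)
  expect_equal(dc$rate$total[1], tot, tolerance = 1e-12)
  expect_equal(unname(dc$rate$sequential[1, "asfr"]), asfr_first,
               tolerance = 1e-12)
  expect_equal(unname(dc$rate$sequential[1, "composition"]), comp_second,
               tolerance = 1e-12)
  sym_asfr <- (asfr_first + (v(W_s, A_s) - v(W_s, A_b))) / 2
  expect_equal(unname(dc$rate$shapley[1, "asfr"]), sym_asfr, tolerance = 1e-12)

  # identity scenario: all contributions zero
  dc0 <- decompose_change(base, base, rates, post)
  expect_true(all(abs(dc0$rate$total) < 1e-15))
  expect_true(all(abs(dc0$count$shapley) < 1e-9))

  # single-factor change: the other contribution is exactly zero
  scen_asfr <- mk(2100, sum(W_b * A_s), W_b, A_s)
  dc1 <- decompose_change(base, scen_asfr, rates, post)
  expect_true(all(abs(dc1$rate$shapley[, "composition"]) < 1e-15))
  expect_equal(dc1$rate$shapley[, "asfr"], dc1$rate$total, tolerance = 1e-12)

  # missing women/ASFR directs the user to share-only scenarios
  no_w <- projection_input("AAA", 2100, births_s,
                           setNames(W_s * A_s / sum(W_s * A_s), lev))
  expect_error(decompose_change(base, no_w, rates, post), "share-only")
})
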