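# Shared fixtures and independent oracles for the test suite.

# quick delivery-table constructor
deliveries_df <- function(country, age, twin, mother_id = NULL,
                          birth_year = 2000L) {
  n <- max(length(country), length(age), length(twin))
  data.frame(
    country = rep_len(country, n),
    mother_id = rep_len(mother_id %||% sprintf("m%04d", seq_len(n)), n),
    birth_year = rep_len(birth_year, n),
    maternal_age_at_birth = rep_len(age, n),
    parity = 1L,
    twin = rep_len(twin, n),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# explicit dummy-matrix least-squares solve of the twinning LPM:
# country indicators (no intercept) + age-category dummies minus reference
lpm_oracle <- function(deliveries, age_scheme = "5-year") {
  y <- as.numeric(deliveries$twin)
  cty <- factor(deliveries$country)
  age <- droplevels(assign_age_category(deliveries$maternal_age_at_birth,
                                        age_scheme))
  X <- cbind(
    sapply(levels(cty), function(l) as.numeric(cty == l)),
    sapply(levels(age)[-1], function(l) as.numeric(age == l))
  )
  colnames(X) <- c(levels(cty), levels(age)[-1])
  beta <- solve(crossprod(X), crossprod(X, y))
  setNames(as.numeric(beta), colnames(X))
}

# explicit dummy-matrix solve of the panel regression (intercept + MAB
# categories minus reference + country and period dummies minus reference)
panel_oracle <- function(cells) {
  y <- cells$period_twinning_rate
  mab <- factor(cells$mab_category, levels = c("<26", "26-26.5", "26.5-27", "27+"))
  mab <- droplevels(mab)
  cty <- factor(cells$country)
  per <- factor(twinprop:::period_group(
    floor((cells$year_start + cells$year_end) / 2)))
  dummies <- function(f) sapply(levels(f)[-1], function(l) as.numeric(f == l))
  X <- cbind(1, dummies(mab), dummies(cty), dummies(per))
  colnames(X) <- c("(intercept)", levels(mab)[-1], levels(cty)[-1],
                   levels(per)[-1])
  beta <- solve(crossprod(X), crossprod(X, y))
  setNames(as.numeric(beta), colnames(X))
}

# DerSimonian-Laird inverse-variance random-effects pooling, by hand
dl_pool <- function(yi, si) {
  wi <- 1 / si^2
  ybar <- sum(wi * yi) / sum(wi)
  Q <- sum(wi * (yi - ybar)^2)
  k <- length(yi)
  cval <- sum(wi) - sum(wi^2) / sum(wi)
  tau2 <- max(0, (Q - (k - 1)) / cval)
  ws <- 1 / (si^2 + tau2)
  list(est = sum(ws * yi) / sum(ws), se = sqrt(1 / sum(ws)), tau2 = tau2)
}

# synthetic panel-cell simulator with known MAB-category effects
simulate_panel_cells <- function(n_countries = 8, n_periods = 8,
                                 mab_effects = c("<26" = 0, "26-26.5" = 0.45,
                                                 "26.5-27" = 1.0, "27+" = 1.8),
                                 sigma = 0.4, seed = 1,
                                 control_effect = 0) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_countries)) {
    cc <- sprintf("P%02d", i)
    gamma <- runif(1, 10, 25)
    for (j in seq_len(n_periods)) {
      y0 <- 1975 + 5 * (j - 1)
      theta <- 0.1 * j
      mab <- runif(1, 25, 28.5)
      cat_m <- as.character(categorize_mab(mab))
      gdp <- runif(1, 500, 5000)
      edu <- runif(1)
      rate <- gamma + theta + mab_effects[[cat_m]] +
        control_effect * edu + rnorm(1, 0, sigma)
      rows[[length(rows) + 1L]] <- data.frame(
        country = cc, year_start = y0, year_end = y0 + 4,
        n_deliveries = 5000L, n_twin_deliveries = round(5 * rate),
        period_twinning_rate = rate, mean_mab = mab,
        mab_category = cat_m, undersized = FALSE,
        gdp_per_capita = gdp, share_primary_education = edu,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# small default generator used across tests
test_params <- function(...) {
  args <- list(...)
  defaults <- list(n_countries = 2, mothers_per_country = 1500, seed = 99)
  do.call(synth_params, utils::modifyList(defaults, args))
}
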