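#' Group birth years into country-period cells
#'
#' Within each country, consecutive birth years are merged greedily from the
#' earliest observed year forward until each group holds at least
#' `min_deliveries` deliveries; a trailing group below the minimum is merged
#' into its predecessor.  The groups partition the observed year span.  A
#' country whose total deliveries fall below the minimum yields a single cell
#' flagged `undersized`.  Each cell carries the delivery and twin-delivery
#' counts, the period twinning rate (twins per 1000 deliveries) and the mean
#' maternal age at birth (MAB).
#'
#' @param deliveries delivery table from [collapse_to_deliveries()].
#' @param min_deliveries minimum deliveries per cell (default 4000; see
#'   [check_min_group_rule()] for the rationale).
#' @return `data.frame` of panel cells: `country`, `year_start`, `year_end`,
#'   `n_deliveries`, `n_twin_deliveries`, `period_twinning_rate`, `mean_mab`,
#'   `mab_category`, `undersized`.
#' @export
group_years <- function(deliveries, min_deliveries = 4000) {
  out <- list()
  for (cc in sort(unique(deliveries$country))) {
    sub <- deliveries[deliveries$country == cc, , drop = FALSE]
    yrs <- seq(min(sub$birth_year), max(sub$birth_year))
    cnt <- tabulate(factor(sub$birth_year, levels = yrs), nbins = length(yrs))
    # greedy forward accumulation over the full observed span
    grp <- integer(length(yrs)); g <- 1L; acc <- 0L
    for (i in seq_along(yrs)) {
      grp[i] <- g
      acc <- acc + cnt[i]
      if (acc >= min_deliveries && i < length(yrs)) { g <- g + 1L; acc <- 0L }
    }
    # trailing group below the minimum merges backward
    if (acc < min_deliveries && g > 1L) grp[grp == g] <- g - 1L
    undersized <- sum(cnt) < min_deliveries
    if (undersized)
      message("country ", cc, " has fewer than ", min_deliveries,
              " deliveries in total; single undersized cell")
    cell_of_year <- setNames(grp, yrs)
    gid <- cell_of_year[as.character(sub$birth_year)]
    for (g2 in sort(unique(grp))) {
      in_g <- gid == g2
      n <- sum(in_g)
      nt <- sum(sub$twin[in_g])
      out[[length(out) + 1L]] <- data.frame(
        country = cc,
        year_start = min(yrs[grp == g2]), year_end = max(yrs[grp == g2]),
        n_deliveries = n, n_twin_deliveries = nt,
        period_twinning_rate = 1000 * nt / n,
        mean_mab = mean(sub$maternal_age_at_birth[in_g]),
        undersized = undersized,
        stringsAsFactors = FALSE)
    }
  }
  cells <- do.call(rbind, out)
  cells$mab_category <- categorize_mab(cells$mean_mab)
  rownames(cells) <- NULL
  cells
}

#' Expected twin count implied by the minimum-group-size rule
#'
#' The minimum of 4000 deliveries per panel cell is chosen so that, at
#' twinning rates of 15-20 per 1000 deliveries, at least 50 twin deliveries
#' are realized by chance alone, enough to estimate a period rate reliably.
#' Returns the expected count `min_deliveries * rate/1000`, the exact
#' binomial probability of observing at least `min_twins`, and optionally a
#' seeded simulation of that probability.
#'
#' @param min_deliveries cell size (e.g. 4000).
#' @param twinning_rate_per_1000 twinning rate in twins per 1000 deliveries,
#'   in (0, 1000) (0 is allowed and yields 0 expected twins).
#' @param min_twins the count whose exceedance probability is evaluated.
#' @param simulate if `TRUE`, also simulate the exceedance probability.
#' @param n_sims,seed simulation size and seed.
#' @return list with `expected`, `prob_at_least` (exact), and
#'   `prob_at_least_sim` (`NA` unless `simulate`).
#' @export
#' @examples
#' check_min_group_rule(4000, 15)$expected # 60
check_min_group_rule <- function(min_deliveries, twinning_rate_per_1000,
                                 min_twins = 50, simulate = FALSE,
                                 n_sims = 10000, seed = 1L) {
  stopifnot_scalar(twinning_rate_per_1000, "twinning_rate_per_1000", 0, 1000)
  p <- twinning_rate_per_1000 / 1000
  expected <- min_deliveries * p
  prob <- if (p == 0) as.numeric(min_twins <= 0) else
    pbinom(min_twins - 1, min_deliveries, p, lower.tail = FALSE)
  sim <- NA_real_
  if (simulate) {
    set.seed(seed)
    sim <- mean(rbinom(n_sims, min_deliveries, p) >= min_twins)
  }
  list(expected = expected, prob_at_least = prob, prob_at_least_sim = sim)
}

#' Remove countries with short observed spans
#'
#' Drops all cells of countries whose covered birth-year span
#' (last year - first year + 1) is below `min_span_years`, to improve the
#' balance of the panel.  Removals are logged by country name.
#'
#' @param cells panel cells from [group_years()].
#' @param min_span_years minimum span in years (default 10).
#' @return filtered cells.
#' @export
filter_short_span <- function(cells, min_span_years = 10) {
  if (nrow(cells) == 0) return(cells)
  span <- tapply(cells$year_end, cells$country, max) -
    tapply(cells$year_start, cells$country, min) + 1
  drop <- names(span)[span < min_span_years]
  if (length(drop))
    message("removed countries with span < ", min_span_years, " years: ",
            paste(drop, collapse = ", "))
  out <- cells[!cells$country %in% drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Categorise mean maternal age at birth
#'
#' Mean MAB is concentrated in a narrow window across country-periods, so it
#' enters the panel regression as categories: below 26, 26 to 26.5, 26.5 to
#' 27, and 27 and above.  Bins are half-open with ties going upward (27.0 is
#' in "27+"), so the bins partition the line.
#'
#' @param mean_mab numeric vector of mean maternal ages, each in \[15, 49\].
#' @return factor with levels `<26`, `26-26.5`, `26.5-27`, `27+`.
#' @export
#' @examples
#' categorize_mab(c(25.99, 26.3, 27))
categorize_mab <- function(mean_mab) {
  if (any(!is.finite(mean_mab) | mean_mab < 15 | mean_mab > 49))
    stop("mean maternal age outside [15, 49]")
  cut(mean_mab, breaks = c(-Inf, 26, 26.5, 27, Inf),
      labels = c("<26", "26-26.5", "26.5-27", "27+"), right = FALSE)
}

## 5-year period-group label for a cell, pooling the tails
period_group <- function(year, pre = 1980, post = 2015) {
  lab <- ifelse(year < pre, sprintf("pre-%d", pre),
         ifelse(year > post, sprintf("post-%d", post),
                sprintf("%d-%d", (year %/% 5) * 5, (year %/% 5) * 5 + 4)))
  lab
}

#' Panel regression of period twinning rates on mean maternal age at birth
#'
#' Fits, by OLS on the country-period cells,
#' \deqn{rate_{c,y} = \alpha + \beta_1 MAB^{cat}_{c,y} + \gamma_c + \theta_y
#'   + \varepsilon_{c,y}}
#' where the outcome is twins per 1000 deliveries, `MAB` enters as the
#' categories of [categorize_mab()] (reference `<26`), \eqn{\gamma_c} are
#' country fixed effects and \eqn{\theta_y} are period fixed effects over
#' 5-year year groups with pooled tails (before 1980, after 2015), smoothing
#' yearly variation given the modest number of cells.  Cells are equally
#' weighted by default; optional controls (GDP per capita, share of women
#' completing primary education) enter linearly.  Classical OLS standard
#' errors are the default presentation; a country-clustered option exists.
#'
#' @param cells panel cells (columns of [group_years()], optionally
#'   `gdp_per_capita` and `share_primary_education`).
#' @param controls character subset of `c("gdp", "education")`.
#' @param weights if `TRUE`, weight cells by delivery counts.
#' @param se_type `"classical"` (default) or `"cluster"` (by country).
#' @param period_tails pooled-tail years, `c(pre, post)`.
#' @return object of class `twin_panel` with `mab_coefficients` (reference
#'   `<26` = 0), `se`, `control_coefficients`, `country_effects`,
#'   `period_effects`, `r_squared`, `n_cells`, and the underlying `lm` fit.
#' @export
fit_panel_fe <- function(cells, controls = character(), weights = FALSE,
                         se_type = c("classical", "cluster"),
                         period_tails = c(1980, 2015)) {
  se_type <- match.arg(se_type)
  if (length(controls))
    controls <- match.arg(controls, c("gdp", "education"), several.ok = TRUE)
  if (length(unique(cells$country)) < 2) stop("need >= 2 countries")
  df <- data.frame(
    rate = cells$period_twinning_rate,
    mab = factor(cells$mab_category, levels = c("<26", "26-26.5", "26.5-27", "27+")),
    country = factor(cells$country),
    period = factor(period_group(floor((cells$year_start + cells$year_end) / 2),
                                 period_tails[1], period_tails[2]))
  )
  if (nlevels(droplevels(df$period)) < 2) stop("need >= 2 period groups")
  terms <- c("mab", "country", "period")
  if ("gdp" %in% controls) { df$gdp <- cells$gdp_per_capita; terms <- c(terms, "gdp") }
  if ("education" %in% controls) {
    df$education <- cells$share_primary_education
    terms <- c(terms, "education")
  }
  drop_mab <- setdiff(levels(df$mab), unique(as.character(df$mab)))
  if (length(drop_mab)) {
    message("MAB categor(ies) never observed, dropped: ",
            paste(drop_mab, collapse = ", "))
    df$mab <- droplevels(df$mab)
  }
  fml <- stats::as.formula(paste("rate ~", paste(terms, collapse = " + ")))
  w <- if (weights) cells$n_deliveries else NULL
  fit <- lm(fml, data = df, weights = w)
  V <- if (se_type == "cluster") vcovCL(fit, cluster = df$country) else vcov(fit)
  cf <- coef(fit)

  mab_lev <- levels(df$mab)
  mab_coefficients <- setNames(numeric(length(mab_lev)), mab_lev)
  est <- paste0("mab", mab_lev[-1])
  mab_coefficients[mab_lev[-1]] <- cf[est]
  se <- setNames(rep(0, length(mab_lev)), mab_lev)
  se[mab_lev[-1]] <- sqrt(diag(V))[est]

  ctrl <- cf[intersect(c("gdp", "education"), names(cf))]
  structure(list(
    mab_coefficients = mab_coefficients, se = se,
    control_coefficients = ctrl,
    country_effects = cf[grep("^country", names(cf))],
    period_effects = cf[grep("^period", names(cf))],
    r_squared = summary(fit)$r.squared,
    n_cells = nrow(df),
    lm = fit, vcov = V, se_type = se_type, weights = weights
  ), class = "twin_panel")
}

#' @export
print.twin_panel <- function(x, ...) {
  cat("Country-period panel regression of twinning rates on mean MAB\n")
  cat("  cells:", x$n_cells, "  R^2:", round(x$r_squared, 3), "\n")
  tab <- data.frame(estimate = x$mab_coefficients, se = x$se)
  print(round(tab, 3))
  if (length(x$control_coefficients)) {
    cat("  controls:\n"); print(round(x$control_coefficients, 4))
  }
  invisible(x)
}

#' @export
coef.twin_panel <- function(object, ...) {
  c(object$mab_coefficients[-1], object$control_coefficients)
}

#' @export
summary.twin_panel <- function(object, ...) {
  est <- object$mab_coefficients[-1]
  tab <- data.frame(estimate = est, se = object$se[names(est)])
  tab$t <- tab$estimate / tab$se
  structure(list(table = tab, fit = object), class = "summary.twin_panel")
}

#' @export
print.summary.twin_panel <- function(x, ...) {
  print(x$fit)
  invisible(x)
}

#' Side-by-side panel regression table
#'
#' Convenience wrapper fitting the no-controls, +GDP, and +GDP+education
#' specifications on the same cells and returning their MAB coefficients in
#' one table (rows: MAB categories and controls; columns: the three models).
#'
#' @param cells panel cells with covariate columns present.
#' @return `data.frame` of coefficients (SEs in attribute `"se"`).
#' @export
panel_regression_table <- function(cells) {
  m1 <- fit_panel_fe(cells)
  m2 <- fit_panel_fe(cells, controls = "gdp")
  m3 <- fit_panel_fe(cells, controls = c("gdp", "education"))
  rows <- c(names(m1$mab_coefficients)[-1], "gdp", "education")
  grab <- function(m) {
    v <- c(m$mab_coefficients[-1], m$control_coefficients)
    out <- setNames(rep(NA_real_, length(rows)), rows)
    out[names(v)] <- v
    out
  }
  tab <- data.frame(no_controls = grab(m1), gdp = grab(m2),
                    gdp_education = grab(m3))
  attr(tab, "r_squared") <- c(m1$r_squared, m2$r_squared, m3$r_squared)
  tab
}
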