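#' Projection input for one country-year
#'
#' Bundles the population-projection quantities for one country and year:
#' total births `b`, the maternal age structure (share of births per 5-year
#' age group, summing to 1), and optionally women counts and age-specific
#' fertility rates (ASFR) per group.  When women and ASFR are both present
#' they must reproduce total births (`sum(women * asfr) == births` within
#' 0.5%).  Births to mothers under 15 or 50 and over are folded into the edge
#' groups before constructing shares.
#'
#' @param country country code.
#' @param year calendar year.
#' @param births total births `b` (>= 0).
#' @param shares named numeric over `age_levels("5-year")`, share of births
#'   per age group, summing to 1 (within 1e-6; renormalised).
#' @param women,asfr optional named numerics over the same groups.
#' @return object of class `projection_input`.
#' @export
projection_input <- function(country, year, births, shares,
                             women = NULL, asfr = NULL) {
  lev <- age_levels("5-year")
  stopifnot_scalar(births, "births", 0)
  if (!all(lev %in% names(shares))) stop("shares must cover groups ",
                                         paste(lev, collapse = ", "))
  shares <- shares[lev]
  if (any(shares < 0)) stop("negative age shares are not allowed")
  if (abs(sum(shares) - 1) > 1e-6)
    stop("age shares must sum to 1 (got ", format(sum(shares)), ")")
  shares <- shares / sum(shares)
  if (!is.null(women) && !is.null(asfr)) {
    women <- women[lev]; asfr <- asfr[lev]
    if (any(women < 0) || any(asfr < 0)) stop("negative counts are not allowed")
    implied <- sum(women * asfr)
    if (births > 0 && abs(implied - births) / births > 0.005)
      stop("women x ASFR does not reproduce total births (",
           format(implied), " vs ", format(births), ")")
  }
  structure(list(country = country, year = as.integer(year),
                 births = births, shares = shares,
                 women = women, asfr = asfr),
            class = "projection_input")
}

#' Extract a projection input from a projection table
#'
#' @param table `data.frame` in the projection CSV schema (`country`, `year`,
#'   `age_group`, `births`, optionally `women`, `asfr`), e.g. from
#'   [generate_projection_tables()].
#' @param country,year the country-year to extract.
#' @return a [projection_input()].
#' @export
as_projection_input <- function(table, country, year) {
  sub <- table[table$country == country & table$year == year, , drop = FALSE]
  if (nrow(sub) == 0) stop("no projection rows for ", country, " ", year)
  lev <- age_levels("5-year")
  sub <- sub[match(lev, sub$age_group), , drop = FALSE]
  if (any(is.na(sub$births))) stop("projection table must cover all age groups")
  b <- sum(sub$births)
  projection_input(country, year, births = b,
                   shares = setNames(sub$births / b, lev),
                   women = if (!is.null(sub$women) && !anyNA(sub$women))
                     setNames(sub$women, lev) else NULL,
                   asfr = if (!is.null(sub$asfr) && !anyNA(sub$asfr))
                     setNames(sub$asfr, lev) else NULL)
}

#' Total deliveries implied by births and a twinning rate
#'
#' Total births `b` equal deliveries plus twin deliveries, `b = d + dt`, and
#' the twinning rate is `tr = dt/d`; solving gives `d = b / (1 + tr)`.
#' The result is kept fractional.
#'
#' @param b total births (>= 0).
#' @param tr twinning rate as a per-delivery fraction in \[0, 1).
#' @return total deliveries `d` (vectorised over `tr`).
#' @export
#' @examples
#' deliveries_from_births(1015, 0.015) # 1000
deliveries_from_births <- function(b, tr) {
  if (any(b < 0)) stop("births must be nonnegative")
  if (any(tr >= 1) || any(tr < 0)) stop("twinning rate must be in [0, 1)")
  b / (1 + tr)
}

#' Partition deliveries across maternal age groups
#'
#' @param d total deliveries.
#' @param age_shares nonnegative shares summing to 1.
#' @return named vector `d * age_shares` (sums to `d` exactly).
#' @export
partition_deliveries <- function(d, age_shares) {
  if (any(age_shares < 0)) stop("negative age shares are not allowed")
  if (abs(sum(age_shares) - 1) > 1e-6) stop("age shares must sum to 1")
  d * age_shares / sum(age_shares)
}

#' Per-draw age-specific twinning probabilities for a country
#'
#' For each posterior draw, the twinning probability in age group `a` is the
#' country effect plus the age-category coefficient, clipped into \[0, 1\]
#' at this consumption point (draws are stored unclipped).  In `"recentered"`
#' mode each draw's profile is shifted by a constant so that its
#' baseline-share-weighted mean equals the same draw's country twinning rate
#' `tr`: the age-free rate model and the age-specific model are fitted
#' separately, and recentering reconciles them so that the identity scenario
#' reproduces the baseline rate exactly, draw by draw.
#'
#' @param posterior an [draw_posterior()] object.
#' @param country country code present in the posterior.
#' @param mode `"recentered"` (default) or `"raw"`.
#' @param baseline_shares baseline-year age shares (required for recentering).
#' @param tr_draws per-draw country twinning rates aligned with the
#'   posterior's draws (required for recentering).
#' @return matrix draws x age groups of twin probabilities.
#' @export
age_probabilities <- function(posterior, country,
                              mode = c("recentered", "raw"),
                              baseline_shares = NULL, tr_draws = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(posterior, "age_posterior"))
  if (!country %in% posterior$countries)
    stop("country not in posterior: ", country)
  lev <- posterior$age_levels
  gamma <- posterior$draws[, country]
  beta <- matrix(0, length(gamma), length(lev), dimnames = list(NULL, lev))
  for (a in setdiff(lev, posterior$reference))
    beta[, a] <- posterior$draws[, a]
  p <- pmin(pmax(gamma + beta, 0), 1)
  if (mode == "recentered") {
    if (is.null(baseline_shares) || is.null(tr_draws))
      stop("recentered mode needs baseline_shares and tr_draws")
    if (length(tr_draws) != nrow(p))
      stop("tr_draws must align with the posterior draws")
    s <- baseline_shares[lev]
    # iterate the shift because clipping into [0, 1] can re-open a gap;
    # converges since tr lies in (0, 1) and the shares sum to 1
    for (it in seq_len(100)) {
      delta <- tr_draws - as.numeric(p %*% s)
      if (max(abs(delta)) < 1e-12) break
      p <- pmin(pmax(p + delta, 0), 1)
    }
  }
  p
}

#' Expected twin deliveries by age group
#'
#' Applies age-specific twin probabilities to age-partitioned deliveries:
#' `dt_a = d_a * p_a`, `dt = sum(dt_a)`, implied rate `tr = dt / d`.
#'
#' @param d_a named deliveries by age group.
#' @param p_a matching named twin probabilities (or a draws x groups matrix).
#' @return list with `dt_by_age`, `dt`, `implied_tr` (vectors over draws when
#'   `p_a` is a matrix).
#' @export
expected_twin_deliveries <- function(d_a, p_a) {
  if (is.matrix(p_a)) {
    if (!identical(colnames(p_a), names(d_a)))
      stop("age groups of deliveries and probabilities do not match")
    dt_by_age <- sweep(p_a, 2, d_a, `*`)
    dt <- rowSums(dt_by_age)
  } else {
    if (!identical(names(p_a), names(d_a)))
      stop("age groups of deliveries and probabilities do not match")
    dt_by_age <- d_a * p_a
    dt <- sum(dt_by_age)
  }
  list(dt_by_age = dt_by_age, dt = dt, implied_tr = dt / sum(d_a))
}

#' Relative change in percent
#'
#' `100 * (scenario - baseline) / baseline`, vectorised; applied per draw
#' before summarising (the median of per-draw changes is reported, not the
#' change of medians).
#'
#' @param scenario_value,baseline_value numeric (draws).
#' @return percent change per element.
#' @export
pct_change <- function(scenario_value, baseline_value) {
  if (any(baseline_value == 0)) stop("baseline value must be nonzero")
  100 * (scenario_value - baseline_value) / baseline_value
}

#' Children per one child with a twin sibling
#'
#' With twinning rate `tr` (per-delivery fraction) and every twin delivery
#' yielding exactly two children, the share of children who are members of a
#' twin pair is `2 tr / (1 + tr)`; its reciprocal `(1 + tr) / (2 tr)` is the
#' "1 out of every N children has a twin sibling" metric.
#'
#' @param tr twinning rate(s) in \[0, 1).
#' @return children per twin-pair child; `Inf` (with a warning) at `tr = 0`.
#' @export
#' @examples
#' twin_sibling_ratio(0.0069) # about 73
twin_sibling_ratio <- function(tr) {
  if (any(tr < 0) || any(tr >= 1)) stop("twinning rate must be in [0, 1)")
  if (any(tr == 0)) warning("twinning rate 0: ratio is infinite")
  (1 + tr) / (2 * tr)
}

#' Project a scenario and compare it with the baseline
#'
#' For every posterior draw `j` (the same draw index is used for the country
#' rate `tr` and the age profile, so parameter uncertainty propagates
#' jointly): the flag-selected total births are converted to deliveries via
#' `d = b / (1 + tr_j)`, partitioned by the flag-selected age shares, and
#' multiplied by the draw's age-specific twin probabilities to give twin
#' deliveries `dt_j` and the implied twinning rate.  The same draw is also
#' evaluated at the baseline inputs, and per-draw percent changes in the rate
#' and the twin-birth count are formed before summarising as median and
#' Q1-Q3.
#'
#' @param baseline,scenario [projection_input()]s for the same country.
#' @param rates a [fit_country_rates()] object (must include the country).
#' @param posterior a [draw_posterior()] object.
#' @param use_scenario_births take `b` from the scenario (`TRUE`) or hold it
#'   at the baseline level (`FALSE`, isolating the age-structure effect).
#' @param use_scenario_shares take age shares from the scenario or baseline.
#' @param mode probability mode, see [age_probabilities()].
#' @return object of class `twin_projection`: per-draw vectors (`d`, `dt`,
#'   `implied_tr`, `pct_change_rate`, `pct_change_count`,
#'   `children_per_twin`), `dt_by_age` draw matrix, and an IQR `summary`
#'   table.
#' @export
run_scenario <- function(baseline, scenario, rates, posterior,
                         use_scenario_births = TRUE,
                         use_scenario_shares = TRUE,
                         mode = c("recentered", "raw")) {
  mode <- match.arg(mode)
  stopifnot(inherits(baseline, "projection_input"),
            inherits(scenario, "projection_input"))
  if (!identical(baseline$country, scenario$country))
    stop("baseline and scenario must refer to the same country")
  cc <- baseline$country
  if (!cc %in% colnames(rates$draws)) stop("country not in rates: ", cc)
  tr <- pmin(pmax(rates$draws[, cc], 0), 0.999)
  if (length(tr) != nrow(posterior$draws))
    stop("rates and posterior must have the same number of draws ",
         "(draw pairing)")
  p <- age_probabilities(posterior, cc, mode = mode,
                         baseline_shares = baseline$shares, tr_draws = tr)

  eval_point <- function(b, shares) {
    d <- deliveries_from_births(b, tr)
    d_a <- outer(d, unname(shares[colnames(p)]))
    colnames(d_a) <- colnames(p)
    dt_by_age <- d_a * p
    dt <- rowSums(dt_by_age)
    list(d = d, dt = dt, dt_by_age = dt_by_age, tr = dt / d)
  }
  base <- eval_point(baseline$births, baseline$shares)
  b_s <- if (use_scenario_births) scenario$births else baseline$births
  s_s <- if (use_scenario_shares) scenario$shares else baseline$shares
  scen <- eval_point(b_s, s_s)

  res <- list(
    country = cc,
    baseline_year = baseline$year, scenario_year = scenario$year,
    use_scenario_births = use_scenario_births,
    use_scenario_shares = use_scenario_shares,
    mode = mode,
    d = scen$d, dt = scen$dt, dt_by_age = scen$dt_by_age,
    implied_tr = scen$tr,
    baseline_d = base$d, baseline_dt = base$dt, baseline_tr = base$tr,
    pct_change_rate = pct_change(scen$tr, base$tr),
    # twin births = 2 * twin deliveries; the factor cancels in the % change
    pct_change_count = pct_change(scen$dt, base$dt),
    children_per_twin = twin_sibling_ratio(pmax(scen$tr, .Machine$double.eps))
  )
  res$summary <- rbind(
    deliveries = iqr_summary(res$d),
    twin_deliveries = iqr_summary(res$dt),
    twinning_rate_per_1000 = iqr_summary(1000 * res$implied_tr),
    pct_change_rate = iqr_summary(res$pct_change_rate),
    pct_change_count = iqr_summary(res$pct_change_count),
    children_per_twin = iqr_summary(res$children_per_twin)
  )
  structure(res, class = "twin_projection")
}

#' @export
print.twin_projection <- function(x, ...) {
  cat("Twin-birth projection for ", x$country, ": ", x$scenario_year,
      " vs baseline ", x$baseline_year, "\n", sep = "")
  cat("  (births from ",
      if (x$use_scenario_births) "scenario" else "baseline",
      ", age shares from ",
      if (x$use_scenario_shares) "scenario" else "baseline",
      ", ", x$mode, " probabilities)\n", sep = "")
  print(round(x$summary, 2))
  invisible(x)
}

## Shapley (symmetrised-over-orders) decomposition of v over named factors.
## v: function(flags named logical) -> per-draw numeric vector.
shapley_contributions <- function(factors, v) {
  n <- length(factors)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  names(subsets) <- factors
  vals <- apply(subsets, 1, function(fl) v(setNames(as.logical(fl), factors)))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
  key <- apply(subsets, 1, function(fl) paste(as.integer(fl), collapse = ""))
  colnames(vals) <- key
  lookup <- function(fl) vals[, paste(as.integer(fl[factors]), collapse = ""),
                              drop = TRUE]
  contrib <- matrix(0, nrow(vals), n, dimnames = list(NULL, factors))
  for (f in factors) {
    others <- setdiff(factors, f)
    for (i in seq_len(nrow(subsets))) {
      fl <- setNames(as.logical(subsets[i, ]), factors)
      if (fl[[f]]) next
      s <- sum(fl[others])
      w <- factorial(s) * factorial(n - s - 1) / factorial(n)
      fl_on <- fl; fl_on[[f]] <- TRUE
      contrib[, f] <- contrib[, f] + w * (lookup(fl_on) - lookup(fl))
    }
  }
  base_flags <- setNames(rep(FALSE, n), factors)
  full_flags <- setNames(rep(TRUE, n), factors)
  mains <- sapply(factors, function(f) {
    fl <- base_flags; fl[[f]] <- TRUE
    lookup(fl) - lookup(base_flags)
  })
  if (is.null(dim(mains))) mains <- matrix(mains, nrow = 1,
                                           dimnames = list(NULL, factors))
  total <- lookup(full_flags) - lookup(base_flags)
  # sequential contributions in the listed factor order
  seqc <- matrix(0, length(total), n, dimnames = list(NULL, factors))
  fl <- base_flags
  prev <- lookup(base_flags)
  for (f in factors) {
    fl[[f]] <- TRUE
    cur <- lookup(fl)
    seqc[, f] <- cur - prev
    prev <- cur
  }
  list(total = total, shapley = contrib, sequential = seqc, main = mains,
       interaction = total - rowSums(mains))
}

#' Decompose the projected change into its demographic sources
#'
#' Counterfactual-substitution decomposition of the change from baseline to
#' scenario.  The twinning-rate change is split into the contribution of
#' changing age-specific fertility rates (ASFR) and of the changing female
#' age composition (women counts), the two routes by which the maternal age
#' structure can shift toward older ages; the twin-birth-count change is
#' additionally split by population scale (total births `b`).  For each
#' subset of substituted factors the implied rate (or count) is evaluated
#' per posterior draw; contributions are reported three ways: sequentially in
#' a fixed substitution order (summing exactly to the total), symmetrised
#' over all substitution orders (Shapley; also summing exactly to the total),
#' and as one-at-a-time main effects with the residual interaction reported
#' separately so that mains + interaction equal the total exactly.
#'
#' @param baseline,scenario [projection_input()]s with `women` and `asfr`.
#' @param rates a [fit_country_rates()] object.
#' @param posterior a [draw_posterior()] object.
#' @param mode probability mode, see [age_probabilities()].
#' @return object of class `twin_decomposition` with elements `rate` and
#'   `count`, each a list of per-draw terms (`total`, `shapley`,
#'   `sequential`, `main`, `interaction`) plus an IQR `summary`.
#' @export
decompose_change <- function(baseline, scenario, rates, posterior,
                             mode = c("recentered", "raw")) {
  mode <- match.arg(mode)
  if (is.null(baseline$women) || is.null(baseline$asfr) ||
      is.null(scenario$women) || is.null(scenario$asfr))
    stop("decomposition needs women and ASFR for both inputs; ",
         "use run_scenario() for share-only scenarios")
  cc <- baseline$country
  tr <- pmin(pmax(rates$draws[, cc], 0), 0.999)
  p <- age_probabilities(posterior, cc, mode = mode,
                         baseline_shares = baseline$shares, tr_draws = tr)
  lev <- colnames(p)

  shares_of <- function(W, A) { x <- W[lev] * A[lev]; x / sum(x) }
  rate_v <- function(flags) {
    W <- if (flags[["composition"]]) scenario$women else baseline$women
    A <- if (flags[["asfr"]]) scenario$asfr else baseline$asfr
    as.numeric(p %*% shares_of(W, A))
  }
  count_v <- function(flags) {
    b <- if (flags[["scale"]]) scenario$births else baseline$births
    W <- if (flags[["composition"]]) scenario$women else baseline$women
    A <- if (flags[["asfr"]]) scenario$asfr else baseline$asfr
    d <- deliveries_from_births(b, tr)
    d * as.numeric(p %*% shares_of(W, A))
  }
  rate <- shapley_contributions(c("asfr", "composition"), rate_v)
  count <- shapley_contributions(c("scale", "composition", "asfr"), count_v)

  summarise <- function(x) {
    rbind(total = iqr_summary(x$total),
          t(apply(x$shapley, 2, iqr_summary)),
          interaction = iqr_summary(x$interaction))
  }
  rate$summary <- summarise(rate)
  count$summary <- summarise(count)
  structure(list(country = cc, baseline_year = baseline$year,
                 scenario_year = scenario$year, mode = mode,
                 rate = rate, count = count),
            class = "twin_decomposition")
}

#' @export
print.twin_decomposition <- function(x, ...) {
  cat("Decomposition of projected change, ", x$country, " ",
      x$scenario_year, " vs ", x$baseline_year, "\n", sep = "")
  cat("Twinning rate (per-delivery fraction), Shapley contributions:\n")
  print(signif(x$rate$summary, 4))
  cat("Twin deliveries, Shapley contributions:\n")
  print(signif(x$count$summary, 4))
  invisible(x)
}
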