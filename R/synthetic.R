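#' Parameters for the synthetic birth-history generator
#'
#' Defines the generative model behind the synthetic data: per-country
#' baseline twin probabilities (country fixed effects on the probability
#' scale), additive maternal-age increments to the twin probability
#' (reference category 15-19 fixed at 0), and a fertility schedule giving the
#' relative intensity of births across maternal age categories.  Defaults
#' emulate low-income-country survey data: country baselines spanning roughly
#' 7 to 26 twin deliveries per 1000 deliveries, an age profile rising to a
#' peak of about +0.01 at 35-39 then declining slightly, and a broad
#' high-fertility age schedule.
#'
#' @param n_countries number of countries to simulate.
#' @param mothers_per_country number of mothers per country.
#' @param year_range inclusive calendar-year interval for interview dates
#'   (length-2 integer vector).
#' @param country_baselines named numeric vector, country code -> baseline
#'   twin probability per delivery (the per-country fixed effect).  Default:
#'   evenly spaced on \[0.0069, 0.0263\].
#' @param age_effects named numeric vector over `age_levels("5-year")`,
#'   additive twin-probability increment per age category; the entry for
#'   15-19 must be 0.
#' @param fertility_schedule named nonnegative vector over the same
#'   categories; normalised internally to sum to 1.  This is the probability
#'   that a delivery falls in each maternal age category.
#' @param recall_years length of the retrospective recall window (years);
#'   all generated births fall within this many years before the interview.
#' @param mean_births expected number of births per mother (>= 1).
#' @param frailty_sd standard deviation (log scale) of an optional
#'   mother-level multiplicative frailty on the twin probability; 0 (the
#'   default) means deliveries are independent within mothers.
#' @param seed integer seed governing all stochastic draws; per-country
#'   sub-streams are derived from it deterministically.
#' @return an object of class `synth_params` (a validated list).
#' @export
#' @examples
#' p <- synth_params(n_countries = 2, mothers_per_country = 500, seed = 1)
#' names(p$country_baselines)
synth_params <- function(n_countries = 3,
                         mothers_per_country = 2000,
                         year_range = c(1995L, 2010L),
                         country_baselines = NULL,
                         age_effects = NULL,
                         fertility_schedule = NULL,
                         recall_years = 10L,
                         mean_births = 3,
                         frailty_sd = 0,
                         seed = 1L) {
  lev <- age_levels("5-year")
  if (is.null(country_baselines)) {
    country_baselines <- setNames(
      seq(0.0069, 0.0263, length.out = n_countries),
      sprintf("C%02d", seq_len(n_countries))
    )
  }
  n_countries <- length(country_baselines)
  if (is.null(age_effects)) {
    age_effects <- setNames(
      c(0, 0.002, 0.0045, 0.007, 0.010, 0.0095, 0.008), lev)
  }
  if (is.null(fertility_schedule)) {
    fertility_schedule <- setNames(
      c(0.12, 0.25, 0.25, 0.18, 0.12, 0.06, 0.02), lev)
  }
  p <- structure(list(
    n_countries = n_countries,
    mothers_per_country = as.integer(mothers_per_country),
    year_range = as.integer(year_range),
    country_baselines = country_baselines,
    age_effects = age_effects,
    fertility_schedule = fertility_schedule / sum(fertility_schedule),
    recall_years = as.integer(recall_years),
    mean_births = mean_births,
    frailty_sd = frailty_sd,
    seed = as.integer(seed)
  ), class = "synth_params")
  validate_synth_params(p)
}

validate_synth_params <- function(p) {
  lev <- age_levels("5-year")
  cb <- p$country_baselines
  ae <- p$age_effects
  if (is.null(names(cb)) || any(names(cb) == ""))
    stop("country_baselines must be a named vector of country codes")
  bad <- names(cb)[cb < 0 | cb > 1]
  if (length(bad))
    stop("baseline twin probability outside [0, 1] for country: ",
         paste(bad, collapse = ", "))
  if (!identical(sort(names(ae)), sort(lev)))
    stop("age_effects must be named over the 5-year categories ",
         paste(lev, collapse = ", "))
  ae <- ae[lev]
  if (ae[["15-19"]] != 0)
    stop("age_effects for reference category 15-19 must be 0")
  badc <- lev[ae < -1 | ae > 1]
  if (length(badc))
    stop("age effect outside [-1, 1] for age category: ",
         paste(badc, collapse = ", "))
  if (max(cb) + max(ae) > 1)
    stop("baseline + maximum age increment exceeds 1 (country ",
         names(cb)[which.max(cb)], ", age category ", lev[which.max(ae)], ")")
  if (any(cb + min(ae) < 0))
    stop("baseline + minimum age increment below 0 for country: ",
         paste(names(cb)[cb + min(ae) < 0], collapse = ", "))
  fs <- p$fertility_schedule
  if (!identical(sort(names(fs)), sort(lev)) || any(fs < 0) || sum(fs) <= 0)
    stop("fertility_schedule must be nonnegative over the 5-year categories")
  if (p$mothers_per_country < 1L || p$n_countries < 1L)
    stop("need at least one country and one mother per country")
  if (p$recall_years < 1L) stop("recall_years must be a positive integer")
  if (p$mean_births < 1) stop("mean_births must be >= 1")
  if (diff(p$year_range) < 0) stop("year_range must be an increasing interval")
  p$age_effects <- ae
  p$fertility_schedule <- fs[lev] / sum(fs)
  p
}

## deterministic per-country sub-seeds so countries stay independent
country_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Generate synthetic retrospective birth histories
#'
#' Simulates DHS-like individual birth-history records.  Each mother has at
#' least one birth; maternal age at each birth is drawn from the fertility
#' schedule (ages within a mother increase with birth order); each delivery is
#' a twin delivery with probability baseline + age increment; twin deliveries
#' emit exactly two child records sharing the mother and birth date, with the
#' multiple-birth flag set.  All births fall within `recall_years` of the
#' interview date.  Identical seeds reproduce identical tables.
#'
#' @param params a [synth_params()] object.
#' @return a `data.frame` of child-level birth records with columns
#'   `country`, `mother_id`, `interview_year`, `interview_month`,
#'   `birth_year`, `birth_month`, `maternal_age_years`, `parity`,
#'   `multiple_flag`, `education`.
#' @export
#' @examples
#' births <- generate_birth_histories(synth_params(2, 200, seed = 7))
#' head(births)
generate_birth_histories <- function(params) {
  params <- validate_synth_params(params)
  seeds <- country_seeds(params$seed, params$n_countries)
  out <- vector("list", params$n_countries)
  for (i in seq_len(params$n_countries)) {
    out[[i]] <- gen_country_histories(
      cc = names(params$country_baselines)[i],
      baseline = params$country_baselines[[i]],
      seed = seeds[i], params = params)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

gen_country_histories <- function(cc, baseline, seed, params) {
  set.seed(seed)
  M <- params$mothers_per_country
  nb <- 1L + rpois(M, params$mean_births - 1)
  iv_year <- sample(seq(params$year_range[1], params$year_range[2]), M,
                    replace = TRUE)
  iv_month <- sample(12L, M, replace = TRUE)
  n_b <- sum(nb)
  idx <- rep(seq_len(M), nb)
  rec12 <- params$recall_years * 12L
  # months before interview, unique within mother so deliveries never share
  # a birth month by accident (a shared month encodes a twin delivery)
  offs <- unlist(lapply(nb, function(k) sample.int(rec12, k) - 1L),
                 use.names = FALSE)
  birth_cm <- cmonth(iv_year, iv_month)[idx] - offs

  f <- params$fertility_schedule
  lev <- names(f)
  cat_idx <- sample.int(length(f), n_b, replace = TRUE, prob = f)
  age <- seq(15L, 45L, 5L)[cat_idx] + sample(0:4, n_b, replace = TRUE)

  # align ages with dates within mother: earliest birth gets the youngest age
  o_date <- order(idx, birth_cm)
  o_age <- order(idx, age)
  birth_cm <- birth_cm[o_date]
  age <- age[o_age]
  parity <- sequence(nb)

  prob <- baseline + unname(params$age_effects[as.character(
    assign_age_category(age, "5-year"))])
  if (params$frailty_sd > 0) {
    fr <- exp(rnorm(M, -params$frailty_sd^2 / 2, params$frailty_sd))
    prob <- pmin(pmax(prob * fr[idx], 0), 1)
  }
  twin <- runif(n_b) < prob
  edu <- sample(0:2, M, replace = TRUE, prob = c(0.4, 0.35, 0.25))

  rec <- data.frame(
    country = cc,
    mother_id = sprintf("%s-%06d", cc, idx),
    interview_year = iv_year[idx],
    interview_month = iv_month[idx],
    birth_year = birth_cm %/% 12L,
    birth_month = birth_cm %% 12L + 1L,
    maternal_age_years = age,
    parity = parity,
    multiple_flag = as.integer(twin),
    education = edu[idx],
    stringsAsFactors = FALSE
  )
  # a twin delivery contributes two children with identical mother/date
  rbind(rec, rec[twin, , drop = FALSE])
}

#' Ground truth implied by synthetic-generator parameters
#'
#' Returns the exact country baselines and age effects used by the generator,
#' together with the analytically expected per-country twinning rate under
#' the generated age mix: the fertility-schedule-weighted mean of
#' baseline + age increment.
#'
#' @param params a [synth_params()] object.
#' @return list with `country_baselines`, `age_effects`, `delivery_shares`
#'   (expected share of deliveries per age category) and `expected_rate`
#'   (named per-country expected twin probability per delivery).
#' @export
true_values <- function(params) {
  params <- validate_synth_params(params)
  f <- params$fertility_schedule
  ae <- params$age_effects[names(f)]
  list(
    country_baselines = params$country_baselines,
    age_effects = params$age_effects,
    delivery_shares = f,
    expected_rate = params$country_baselines + sum(f * ae)
  )
}

#' Shift a fertility schedule toward older maternal ages
#'
#' Moves a fraction `shift` of each age category's mass into the next-older
#' category (the oldest category retains its own shifted mass), preserving
#' the total.  Used to build older-shifted projection scenarios.
#'
#' @param schedule named nonnegative vector over age categories, summing to 1.
#' @param shift fraction in \[0, 1\] of each category's mass moved up.
#' @return shifted schedule, same names, summing to 1.
#' @export
#' @examples
#' f <- synth_params()$fertility_schedule
#' sum(shift_schedule(f, 0.3)) # 1
shift_schedule <- function(schedule, shift = 0.3) {
  stopifnot_scalar(shift, "shift", 0, 1)
  k <- length(schedule)
  g <- (1 - shift) * schedule
  g[2:k] <- g[2:k] + shift * schedule[1:(k - 1)]
  g[k] <- g[k] + shift * schedule[k]
  g
}

#' Generate synthetic population-projection tables
#'
#' Builds WPP-like country x year x 5-year-age-group tables of births, women
#' and age-specific fertility rates (ASFR), mutually consistent by
#' construction (`births = asfr * women`; age shares of births sum to 1).
#' By default every year uses the generator's fertility schedule; supply
#' per-year schedules (e.g. via [shift_schedule()]) and per-year total births
#' to emulate future scenarios.
#'
#' @param params a [synth_params()] object.
#' @param scenario_years integer vector of years (nonempty).
#' @param schedules optional named list, `as.character(year)` -> fertility
#'   schedule for that year; default: the generator's schedule for all years.
#' @param births optional named numeric, `as.character(year)` -> total births
#'   per country for that year (recycled across countries), or a list of
#'   per-country named vectors.  Default: 100000 per country per year.
#' @return a `data.frame` with columns `country`, `year`, `age_group`,
#'   `births`, `women`, `asfr`.
#' @export
generate_projection_tables <- function(params, scenario_years,
                                       schedules = NULL, births = NULL) {
  params <- validate_synth_params(params)
  if (length(scenario_years) == 0) stop("scenario_years must be nonempty")
  lev <- names(params$fertility_schedule)
  countries <- names(params$country_baselines)
  rows <- list()
  for (yr in scenario_years) {
    f <- schedules[[as.character(yr)]] %||% params$fertility_schedule
    f <- f[lev] / sum(f)
    b_yr <- births[[as.character(yr)]] %||% 1e5
    b_by_c <- if (length(b_yr) == length(countries)) b_yr else
      rep(b_yr[[1]], length(countries))
    if (any(b_by_c < 0)) stop("negative birth counts are not allowed")
    # plausible ASFR shape: proportional to the schedule, capped in (0, 0.3]
    asfr <- 0.25 * f / max(f) + 0.02
    for (i in seq_along(countries)) {
      births_a <- b_by_c[i] * f
      rows[[length(rows) + 1L]] <- data.frame(
        country = countries[i], year = as.integer(yr), age_group = lev,
        births = unname(births_a), women = unname(births_a / asfr),
        asfr = unname(asfr), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
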