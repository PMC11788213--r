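#' Linear probability model of twinning on maternal age with country fixed effects
#'
#' Fits, by ordinary least squares, the linear probability model
#' \deqn{twin_{i,c} = \beta_{a(i)} + \gamma_c + \varepsilon_{i,c}}
#' where the outcome is the per-delivery twin indicator, \eqn{\beta_a} are
#' maternal-age-category coefficients (youngest category is the reference,
#' fixed at 0) and \eqn{\gamma_c} are country fixed effects on the
#' probability scale (no global intercept; the country indicators absorb it).
#' An LPM is preferred to logistic regression for very rare binary outcomes
#' because its predicted probabilities track the observed distribution
#' closely.  Because LPM errors are inherently heteroskedastic, the default
#' coefficient covariance is the heteroskedasticity-consistent sandwich (HC1);
#' classical and mother-clustered covariances are available.
#'
#' Optionally period (birth-year) dummies can be added; the default design
#' has no year terms.
#'
#' @param deliveries delivery table from [collapse_to_deliveries()]; needs
#'   columns `country`, `maternal_age_at_birth`, `twin` (and `mother_id` for
#'   clustered covariance, `birth_year` for period dummies).
#' @param age_scheme age categorisation scheme, see [age_levels()].
#' @param vcov_type `"robust"` (HC1 sandwich, default), `"classical"`, or
#'   `"cluster"` (by mother).
#' @param year_effects add period dummies for birth year (default `FALSE`;
#'   the country effects are otherwise static over the observation window).
#' @return object of class `twin_lpm` with components `age_coefficients`
#'   (named, reference included as exact 0), `country_effects`, `vcov`
#'   (covariance of all estimated parameters, countries first), `se`,
#'   `residual_variance`, `n_deliveries`, `age_scheme`, `reference`.
#' @seealso [draw_posterior()], [fit_country_rates()], [fit_per_country()]
#' @export
twin_lpm <- function(deliveries, age_scheme = "5-year",
                     vcov_type = c("robust", "classical", "cluster"),
                     year_effects = FALSE) {
  vcov_type <- match.arg(vcov_type)
  stopifnot(all(c("country", "maternal_age_at_birth", "twin") %in%
                  names(deliveries)))
  df <- data.frame(
    twin = as.numeric(deliveries$twin),
    country = factor(deliveries$country),
    age = assign_age_category(deliveries$maternal_age_at_birth, age_scheme)
  )
  if (any(tapply(rep(1, nrow(df)), df$country, sum, default = 0) == 0))
    stop("every country must have at least one delivery")
  empty <- setdiff(levels(df$age), unique(as.character(df$age)))
  if (length(empty)) {
    warning("empty age categor(ies) dropped from the design: ",
            paste(empty, collapse = ", "))
    df$age <- droplevels(df$age)
  }
  if (nlevels(df$age) < 2) stop("need at least 2 populated age categories")

  one_country <- nlevels(df$country) == 1L
  fml <- if (year_effects) {
    df$period <- factor(deliveries$birth_year)
    if (one_country) twin ~ age + period else twin ~ 0 + country + age + period
  } else if (one_country) twin ~ age else twin ~ 0 + country + age
  fit <- lm(fml, data = df)
  if (anyNA(coef(fit)))
    stop("rank-deficient design: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))

  V <- switch(vcov_type,
    robust = vcovHC(fit, type = "HC1"),
    classical = vcov(fit),
    cluster = vcovCL(fit, cluster = factor(paste(deliveries$country,
                                                 deliveries$mother_id)))
  )
  cf <- coef(fit)
  c_names <- levels(df$country)
  a_lev <- levels(df$age)
  if (one_country) {
    # the intercept is the single country's fixed effect
    names(cf)[names(cf) == "(Intercept)"] <- paste0("country", c_names)
    dimnames(V) <- list(names(cf), names(cf))
  }
  country_effects <- setNames(cf[paste0("country", c_names)], c_names)
  age_coefficients <- setNames(numeric(length(a_lev)), a_lev)
  est_age <- paste0("age", a_lev[-1])
  age_coefficients[a_lev[-1]] <- cf[est_age]

  keep <- c(paste0("country", c_names), est_age)
  V <- V[keep, keep, drop = FALSE]
  dimnames(V) <- list(c(c_names, a_lev[-1]), c(c_names, a_lev[-1]))

  structure(list(
    age_coefficients = age_coefficients,
    country_effects = country_effects,
    vcov = V,
    se = sqrt(diag(V)),
    residual_variance = summary(fit)$sigma^2,
    n_deliveries = nrow(df),
    age_scheme = age_scheme,
    reference = a_lev[1],
    vcov_type = vcov_type,
    year_effects = year_effects
  ), class = "twin_lpm")
}

#' @export
print.twin_lpm <- function(x, ...) {
  cat("Linear probability model of twinning (country fixed effects)\n")
  cat("  deliveries:", x$n_deliveries,
      " countries:", length(x$country_effects),
      " age scheme:", x$age_scheme, "\n")
  cat("  age coefficients (reference", x$reference, "= 0):\n")
  print(round(x$age_coefficients, 5))
  invisible(x)
}

#' @export
coef.twin_lpm <- function(object, ...) {
  c(object$country_effects, object$age_coefficients[-1])
}

#' @export
vcov.twin_lpm <- function(object, ...) object$vcov

#' @export
summary.twin_lpm <- function(object, ...) {
  est <- coef(object)
  tab <- data.frame(estimate = est, se = object$se[names(est)],
                    z = est / object$se[names(est)])
  tab$p <- 2 * pnorm(-abs(tab$z))
  structure(list(table = tab, fit = object), class = "summary.twin_lpm")
}

#' @export
print.summary.twin_lpm <- function(x, ...) {
  print(x$fit)
  cat("\nAll parameters (", x$fit$vcov_type, " SEs):\n", sep = "")
  print(round(x$table, 6))
  invisible(x)
}

#' Fitted twin probability for new deliveries
#'
#' @param object a [twin_lpm()] fit.
#' @param newdata `data.frame` with `country` and either `age_category` or
#'   `maternal_age_at_birth`.
#' @param clip clip fitted values into \[0, 1\] (LPM fits can fall outside;
#'   they are stored unclipped and clipped only when consumed as
#'   probabilities).
#' @param ... unused.
#' @return numeric vector of fitted twin probabilities.
#' @export
predict.twin_lpm <- function(object, newdata, clip = FALSE, ...) {
  age <- if ("age_category" %in% names(newdata)) {
    factor(newdata$age_category, levels = names(object$age_coefficients))
  } else {
    assign_age_category(newdata$maternal_age_at_birth, object$age_scheme)
  }
  p <- object$country_effects[as.character(newdata$country)] +
    object$age_coefficients[as.character(age)]
  p <- unname(p)
  if (clip) p <- pmin(pmax(p, 0), 1)
  p
}

#' Maternal-age profile plot of the twinning probability
#'
#' Plots the estimated age-category increments relative to the youngest
#' category, with pointwise 95% intervals.
#'
#' @param x a [twin_lpm()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.twin_lpm <- function(x, ...) {
  a <- x$age_coefficients
  se <- c(0, x$se[names(a)[-1]])
  at <- seq_along(a)
  graphics::plot(at, a, xaxt = "n", pch = 19,
                 ylim = range(a - 2 * se, a + 2 * se),
                 xlab = "maternal age at birth",
                 ylab = paste("twin probability increment vs", x$reference),
                 ...)
  graphics::axis(1, at = at, labels = names(a), las = 2)
  graphics::segments(at, a - 1.96 * se, at, a + 1.96 * se)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Country baseline twinning rates (age-free model)
#'
#' Fits the twinning model with country fixed effects only, i.e. the average
#' twinning rate for each country over the observed period: the OLS point
#' estimate per country is exactly that country's observed twin fraction.
#' Posterior uncertainty is represented by draws from the flat-prior
#' (= OLS sampling) distribution, independent across countries with variance
#' `p(1-p)/n` (the heteroskedasticity-robust variance of a per-country mean).
#' Draws are stored unclipped; negative draws are truncated at 0 only when
#' consumed as probabilities.
#'
#' @param deliveries delivery table.
#' @param n_draws number of posterior draws.
#' @param seed integer seed for the draws.
#' @return object of class `country_rates`: `point` (named per-delivery twin
#'   fraction), `se`, `n`, `draws` (`n_draws` x countries matrix).
#' @export
fit_country_rates <- function(deliveries, n_draws = 2000, seed = 1L) {
  cc <- factor(deliveries$country)
  n <- tapply(rep(1L, nrow(deliveries)), cc, sum)
  if (any(is.na(n) | n == 0)) {
    warning("countries without deliveries excluded: ",
            paste(levels(cc)[is.na(n) | n == 0], collapse = ", "))
  }
  p <- tapply(as.numeric(deliveries$twin), cc, mean)
  keep <- !is.na(p)
  p <- p[keep]; n <- n[keep]
  se <- sqrt(p * (1 - p) / n)
  set.seed(seed)
  draws <- matrix(rnorm(n_draws * length(p), mean = rep(p, each = n_draws),
                        sd = rep(se, each = n_draws)),
                  nrow = n_draws, dimnames = list(NULL, names(p)))
  structure(list(point = c(p), se = c(se), n = c(n), draws = draws,
                 n_draws = n_draws, seed = seed),
            class = "country_rates")
}

#' @export
print.country_rates <- function(x, ...) {
  cat("Country baseline twinning rates (per 1000 deliveries)\n")
  s <- apply(x$draws, 2, iqr_summary)
  tab <- data.frame(rate = 1000 * x$point, q1 = 1000 * s["q1", ],
                    q3 = 1000 * s["q3", ], n = x$n)
  print(round(tab, 2))
  invisible(x)
}

#' Dot plot of country twinning rates with posterior IQR
#'
#' @param x a [fit_country_rates()] object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.country_rates <- function(x, ...) {
  o <- order(x$point)
  r <- 1000 * x$point[o]
  q <- apply(x$draws[, o, drop = FALSE], 2, iqr_summary) * 1000
  at <- seq_along(r)
  graphics::plot(r, at, pch = 19, yaxt = "n",
                 xlim = range(q), xlab = "twin deliveries per 1000 deliveries",
                 ylab = "", ...)
  graphics::axis(2, at = at, labels = names(r), las = 1)
  graphics::segments(q["q1", ], at, q["q3", ], at)
  invisible(x)
}

#' Joint posterior draws of LPM parameters
#'
#' Draws from the flat-prior posterior of the LPM parameters: a multivariate
#' normal centred at the OLS estimates with the fit's (robust) covariance.
#' With a flat prior the Bayesian LPM posterior coincides with the OLS
#' sampling distribution, so the draws are exactly reproducible without a
#' sampler.  A non-positive-semidefinite covariance (numerically possible for
#' sandwich estimates) is repaired by clipping negative eigenvalues at zero;
#' the largest adjustment is reported.
#'
#' @param fit a [twin_lpm()] object.
#' @param n_draws number of draws.
#' @param seed integer seed.
#' @return object of class `age_posterior`: `draws` (`n_draws` x parameters
#'   matrix, columns = countries then non-reference age categories), `point`,
#'   `countries`, `age_levels`, `reference`, `seed`, `n_draws`.
#' @export
draw_posterior <- function(fit, n_draws = 2000, seed = 1L) {
  stopifnot(inherits(fit, "twin_lpm"))
  mu <- coef(fit)
  V <- fit$vcov
  ev <- eigen(V, symmetric = TRUE)
  if (min(ev$values) < 0) {
    message("covariance repaired to nearest PSD; max eigen-adjustment ",
            format(-min(ev$values), digits = 3))
    V <- ev$vectors %*% diag(pmax(ev$values, 0)) %*% t(ev$vectors)
    dimnames(V) <- dimnames(fit$vcov)
  }
  set.seed(seed)
  draws <- if (all(V == 0)) {
    matrix(rep(mu, each = n_draws), nrow = n_draws,
           dimnames = list(NULL, names(mu)))
  } else {
    d <- MASS::mvrnorm(n_draws, mu = mu, Sigma = V)
    if (n_draws == 1) d <- matrix(d, nrow = 1)
    colnames(d) <- names(mu)
    d
  }
  structure(list(
    draws = draws, point = mu,
    countries = names(fit$country_effects),
    age_levels = names(fit$age_coefficients),
    reference = fit$reference,
    seed = seed, n_draws = n_draws
  ), class = "age_posterior")
}

#' @export
print.age_posterior <- function(x, ...) {
  cat("Posterior draws of twinning-LPM parameters:", x$n_draws, "draws x",
      ncol(x$draws), "parameters\n")
  cat("  countries:", paste(x$countries, collapse = ", "), "\n")
  cat("  age categories (reference ", x$reference, "):\n", sep = "")
  print(round(apply(x$draws[, setdiff(colnames(x$draws), x$countries),
                            drop = FALSE], 2, iqr_summary), 5))
  invisible(x)
}

#' Per-country maternal-age coefficient fits
#'
#' Fits the age-category LPM separately within each country (intercept =
#' country level, coefficients relative to the youngest populated category),
#' as input to [meta_analyze()].  Countries with fewer than two populated age
#' categories are skipped with a warning.
#'
#' @param deliveries delivery table.
#' @param age_scheme age categorisation scheme.
#' @param vcov_type covariance type passed to the per-country fits.
#' @return object of class `twin_meta` with `estimates` and `se` (country x
#'   age-category matrices, reference column = 0 / NA) before pooling.
#' @export
fit_per_country <- function(deliveries, age_scheme = "5-year",
                            vcov_type = "robust") {
  lev <- age_levels(age_scheme)
  countries <- sort(unique(deliveries$country))
  est <- se <- matrix(NA_real_, length(countries), length(lev),
                      dimnames = list(countries, lev))
  skipped <- character()
  for (cc in countries) {
    sub <- deliveries[deliveries$country == cc, , drop = FALSE]
    pop <- unique(as.character(assign_age_category(sub$maternal_age_at_birth,
                                                   age_scheme)))
    if (length(pop) < 2) { skipped <- c(skipped, cc); next }
    f <- suppressWarnings(twin_lpm(sub, age_scheme, vcov_type = vcov_type))
    est[cc, names(f$age_coefficients)] <- f$age_coefficients
    est[cc, f$reference] <- 0
    se[cc, names(f$age_coefficients)[-1]] <-
      f$se[names(f$age_coefficients)[-1]]
  }
  if (length(skipped))
    warning("skipped countries with <2 populated age categories: ",
            paste(skipped, collapse = ", "))
  structure(list(estimates = est, se = se, age_scheme = age_scheme,
                 pooled = NULL),
            class = "twin_meta")
}

#' Random-effects meta-analysis of per-country age coefficients
#'
#' Pools the per-country maternal-age coefficients with inverse-variance
#' random-effects weighting (DerSimonian-Laird method-of-moments
#' heterogeneity variance, via \pkg{metafor}).  A category estimated in only
#' one country is fixed to that estimate and flagged.
#'
#' @param per_country a [fit_per_country()] object.
#' @return the same object with a `pooled` data.frame added: per age category
#'   the pooled estimate, pooled SE, heterogeneity variance `tau2`, the
#'   number of contributing countries and a `single_country` flag.
#' @export
meta_analyze <- function(per_country) {
  stopifnot(inherits(per_country, "twin_meta"))
  lev <- colnames(per_country$estimates)
  ref <- lev[1]
  rows <- lapply(setdiff(lev, ref), function(a) {
    yi <- per_country$estimates[, a]
    si <- per_country$se[, a]
    ok <- !is.na(yi) & !is.na(si) & si > 0
    if (sum(ok) == 0) {
      return(data.frame(age_category = a, pooled = NA_real_, se = NA_real_,
                        tau2 = NA_real_, k = 0L, single_country = FALSE))
    }
    if (sum(ok) == 1) {
      return(data.frame(age_category = a, pooled = yi[ok], se = si[ok],
                        tau2 = 0, k = 1L, single_country = TRUE))
    }
    m <- metafor::rma(yi = yi[ok], sei = si[ok], method = "DL")
    data.frame(age_category = a, pooled = as.numeric(m$beta),
               se = m$se, tau2 = m$tau2, k = sum(ok),
               single_country = FALSE)
  })
  pooled <- do.call(rbind, rows)
  if (any(pooled$single_country))
    warning("categor(ies) pooled from a single country: ",
            paste(pooled$age_category[pooled$single_country], collapse = ", "))
  per_country$pooled <- pooled
  per_country
}

#' @export
print.twin_meta <- function(x, ...) {
  cat("Per-country maternal-age coefficient fits (",
      nrow(x$estimates), " countries)\n", sep = "")
  if (!is.null(x$pooled)) {
    cat("Random-effects pooled age coefficients:\n")
    print(x$pooled, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
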