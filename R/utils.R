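`%||%` <- function(a, b) if (is.null(a)) b else a

#' Maternal age category labels for a categorisation scheme
#'
#' Reproductive ages 15-49 are partitioned into 5-year, 2-year or 1-year
#' intervals.  The first (youngest) category is always the reference level in
#' the twinning regressions.
#'
#' @param scheme one of `"5-year"`, `"2-year"`, `"1-year"`.
#' @return character vector of ordered category labels.
#' @export
#' @examples
#' age_levels("5-year")
age_levels <- function(scheme = c("5-year", "2-year", "1-year")) {
  scheme <- match.arg(scheme)
  switch(scheme,
    "5-year" = sprintf("%d-%d", seq(15, 45, 5), seq(19, 49, 5)),
    "2-year" = {
      lo <- seq(15, 49, 2)
      hi <- pmin(lo + 1L, 49L)
      ifelse(lo == hi, as.character(lo), sprintf("%d-%d", lo, hi))
    },
    "1-year" = as.character(15:49)
  )
}

#' Assign a maternal age category
#'
#' Maps maternal age at birth (integer years) to an age category.  Ages below
#' 15 are clamped into the youngest category and ages above 49 into the oldest
#' one: survey maternal ages at birth can fall below 15 because the 15-49
#' framing reflects interview eligibility, not birth-level truncation.
#'
#' @param age integer vector of maternal ages at birth, each in \[10, 55\].
#' @param scheme categorisation scheme, see [age_levels()].
#' @return factor with levels `age_levels(scheme)`.
#' @export
#' @examples
#' assign_age_category(c(14, 19, 39, 52))
assign_age_category <- function(age, scheme = c("5-year", "2-year", "1-year")) {
  scheme <- match.arg(scheme)
  if (any(!is.finite(age) | age < 10 | age > 55)) {
    bad <- age[!is.finite(age) | age < 10 | age > 55]
    stop("maternal age outside [10, 55]: ", paste(head(bad, 5), collapse = ", "))
  }
  a <- pmin(pmax(as.integer(age), 15L), 49L)
  lev <- age_levels(scheme)
  width <- switch(scheme, "5-year" = 5L, "2-year" = 2L, "1-year" = 1L)
  idx <- pmin((a - 15L) %/% width + 1L, length(lev))
  factor(lev[idx], levels = lev)
}

## century-month encoding (DHS-style): months since January of year 0
cmonth <- function(year, month) year * 12L + (month - 1L)

## interquartile summary used throughout reporting: median and Q1-Q3
iqr_summary <- function(x) {
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, type = 7))
  c(q1 = q[1], median = q[2], q3 = q[3])
}

stopifnot_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    stop(sprintf("'%s' must be a single finite number in [%s, %s]", name, lo, hi))
  invisible(x)
}
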