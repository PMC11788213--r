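birth_history_columns <- c(
  "country", "mother_id", "interview_year", "interview_month",
  "birth_year", "birth_month", "maternal_age_years", "parity",
  "multiple_flag", "education"
)

#' Read a birth-history file
#'
#' Reads the normalized delimited-text birth-history schema (one row per
#' child): `country`, `mother_id`, `interview_year`, `interview_month`,
#' `birth_year`, `birth_month`, `maternal_age_years`, `parity`,
#' `multiple_flag` (0/1), `education` (0/1/2, optional).  Rows violating the
#' record invariants (maternal age outside \[10, 55\], birth after interview,
#' unparseable numbers) are dropped, counted, and reported with their line
#' numbers.
#'
#' @param path path to a CSV file.
#' @return `data.frame` of valid records; the integer vector of rejected
#'   file line numbers is attached as attribute `"rejected_lines"`.
#' @export
read_birth_records <- function(path) {
  if (!file.exists(path)) stop("cannot read birth-history file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  mandatory <- setdiff(birth_history_columns, "education")
  missing <- setdiff(mandatory, names(df))
  if (length(missing))
    stop("birth-history schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  if (!"education" %in% names(df)) df$education <- NA_integer_
  num_cols <- setdiff(mandatory, c("country", "mother_id"))
  for (col in num_cols) df[[col]] <- suppressWarnings(as.numeric(df[[col]]))

  ok <- complete.cases(df[num_cols])
  ok <- ok & df$maternal_age_years >= 10 & df$maternal_age_years <= 55
  ok[is.na(ok)] <- FALSE
  cm_b <- cmonth(df$birth_year, df$birth_month)
  cm_i <- cmonth(df$interview_year, df$interview_month)
  ok <- ok & !is.na(cm_b) & !is.na(cm_i) & cm_b <= cm_i
  ok[is.na(ok)] <- FALSE

  rejected <- which(!ok) + 1L  # +1 for the header line
  if (length(rejected))
    message(length(rejected), " malformed row(s) rejected at line(s): ",
            paste(head(rejected, 10), collapse = ", "),
            if (length(rejected) > 10) ", ..." else "")
  out <- df[ok, birth_history_columns, drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected_lines") <- rejected
  out
}

#' Write birth-history records to the CSV schema
#'
#' @param records `data.frame` of birth records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_birth_histories <- function(records, path) {
  stopifnot(all(setdiff(birth_history_columns, "education") %in% names(records)))
  write.csv(records[intersect(birth_history_columns, names(records))],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Restrict births to a recall window before the interview
#'
#' Retains exactly the births that occurred within `window_years` of the
#' interview date.  Retrospective histories are restricted this way because
#' recall accuracy degrades for distant births; the conventional window is
#' 10 years.
#'
#' @param records birth records (see [read_birth_records()]).
#' @param window_years window length in years; `Inf` keeps everything.
#' @return filtered records.
#' @export
apply_recall_window <- function(records, window_years = 10) {
  if (is.infinite(window_years)) return(records)
  keep <- cmonth(records$interview_year, records$interview_month) -
    cmonth(records$birth_year, records$birth_month) <= window_years * 12
  message("recall window (", window_years, "y): kept ", sum(keep), " of ",
          length(keep), " records")
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply country/period exclusion rules
#'
#' Removes records matching exclusion rules, each a `list(country =, after_year =)`
#' pair: when `after_year` is `NULL` the whole country is removed; otherwise
#' only births with `birth_year > after_year` (so "after 2000" keeps 2000
#' itself).  Removal counts are logged per rule; a rule naming an absent
#' country raises a warning, not an error.
#'
#' @param records birth records.
#' @param rules list of rules, e.g.
#'   `list(list(country = "ZAF"), list(country = "IND", after_year = 2000))`.
#' @return filtered records.
#' @export
apply_exclusions <- function(records, rules = list()) {
  for (rule in rules) {
    cc <- rule$country
    if (!cc %in% records$country) {
      warning("exclusion rule names absent country: ", cc)
      next
    }
    drop <- records$country == cc
    if (!is.null(rule$after_year)) drop <- drop & records$birth_year > rule$after_year
    message("exclusion (", cc,
            if (is.null(rule$after_year)) "" else paste0(", births after ", rule$after_year),
            "): removed ", sum(drop), " records")
    records <- records[!drop, , drop = FALSE]
  }
  rownames(records) <- NULL
  records
}

#' Collapse child-level birth records to deliveries
#'
#' Children sharing (country, mother, birth month) collapse to one delivery.
#' A delivery is a twin delivery when it has two or more children *or* when
#' any of its children carries the multiple-birth flag — a flagged child whose
#' co-twin is unobserved (e.g. died before listing) still marks a twin
#' delivery, because the outcome is the delivery's multiplicity, not the
#' number of listed children.  More than four children at one date is flagged
#' as a data anomaly but still collapsed with `twin = 1`.
#'
#' @param records birth records.
#' @param age_scheme age categorisation scheme, see [assign_age_category()].
#' @return `data.frame` of deliveries: `country`, `mother_id`, `birth_year`,
#'   `maternal_age_at_birth`, `age_category`, `parity`, `twin`.
#' @export
collapse_to_deliveries <- function(records, age_scheme = "5-year") {
  dt <- as.data.table(records)
  del <- dt[, list(
    birth_year = birth_year[1],
    maternal_age_at_birth = as.integer(maternal_age_years[1]),
    parity = as.integer(min(parity)),
    n_children = .N,
    any_flag = any(multiple_flag > 0)
  ), by = list(country, mother_id, .cm = cmonth(birth_year, birth_month))]
  anomalies <- sum(del$n_children > 4)
  if (anomalies > 0)
    warning(anomalies, " delivery(ies) with >4 children at one date; ",
            "collapsed as twin deliveries (data anomaly)")
  del[, twin := as.integer(n_children >= 2L | any_flag)]
  out <- as.data.frame(del[, list(country, mother_id, birth_year,
                                  maternal_age_at_birth, parity, twin)])
  out$age_category <- assign_age_category(out$maternal_age_at_birth, age_scheme)
  out <- out[c("country", "mother_id", "birth_year", "maternal_age_at_birth",
               "age_category", "parity", "twin")]
  rownames(out) <- NULL
  out
}

#' Per-country twinning rate from a delivery table
#'
#' @param deliveries output of [collapse_to_deliveries()].
#' @return named numeric: twin deliveries per 1000 deliveries by country.
#' @export
observed_twinning_rates <- function(deliveries) {
  tab <- tapply(deliveries$twin, deliveries$country, mean)
  1000 * c(tab)
}
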