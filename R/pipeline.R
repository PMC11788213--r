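pipeline_config_defaults <- function() {
  list(
    recall_window_years = 10,
    exclusion_rules = list(),
    age_scheme = "5-year",
    min_group_deliveries = 4000,
    min_span_years = 10,
    n_draws = 2000,
    seed = 1L,
    mab_bin_edges = c(26, 26.5, 27),
    scenario_years = c(2050L, 2100L),
    baseline_year = 2010L,
    probability_mode = "recentered",
    covariance_mode = "robust",
    synth = list()
  )
}

#' Pipeline configuration
#'
#' Builds and validates the configuration governing a full pipeline run.
#' Defaults follow the study conventions: 10-year recall window, minimum
#' 4000 deliveries per panel cell, 5-year age categories, MAB bin edges at
#' 26/26.5/27, minimum 10-year observed span, 2000 posterior draws.
#' Unknown keys are rejected by name.
#'
#' @param ... named overrides of the defaults (see
#'   `twinprop:::pipeline_config_defaults()`); `synth` is a list of
#'   [synth_params()] arguments for the simulate stage.
#' @return validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_config_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot_scalar(cfg$recall_window_years, "recall_window_years", 0)
  stopifnot_scalar(cfg$min_group_deliveries, "min_group_deliveries", 1)
  stopifnot_scalar(cfg$min_span_years, "min_span_years", 0)
  stopifnot_scalar(cfg$n_draws, "n_draws", 1)
  cfg$age_scheme <- match.arg(cfg$age_scheme, c("5-year", "2-year", "1-year"))
  cfg$probability_mode <- match.arg(cfg$probability_mode, c("recentered", "raw"))
  cfg$covariance_mode <- match.arg(cfg$covariance_mode,
                                   c("robust", "classical", "cluster"))
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose top-level keys are [pipeline_config()]
#'   arguments.
#' @return validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Validate a CSV file against a pipeline schema
#'
#' Checks column presence, types and value ranges for the pipeline's file
#' schemas; the first 10 violations are reported with line numbers.
#'
#' @param path CSV file.
#' @param schema one of `"birth_history"`, `"projection"`, `"covariates"`.
#' @return `data.frame` of violations (`line`, `problem`); zero rows when
#'   the file is valid.
#' @export
validate_schemas <- function(path,
                             schema = c("birth_history", "projection",
                                        "covariates")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("cannot read file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  v <- list()
  bad <- function(lines, problem) {
    if (length(lines))
      v[[length(v) + 1L]] <<- data.frame(line = lines + 1L, problem = problem)
  }
  required <- switch(schema,
    birth_history = setdiff(birth_history_columns, "education"),
    projection = c("country", "year", "age_group", "births"),
    covariates = c("country", "year", "gdp_per_capita",
                   "share_primary_education"))
  missing <- setdiff(required, names(df))
  if (length(missing))
    return(data.frame(line = 0L,
                      problem = paste("missing column(s):",
                                      paste(missing, collapse = ", "))))
  if (schema == "birth_history") {
    bad(which(df$maternal_age_years < 10 | df$maternal_age_years > 55),
        "maternal_age_years outside [10, 55]")
    bad(which(cmonth(df$birth_year, df$birth_month) >
                cmonth(df$interview_year, df$interview_month)),
        "birth after interview")
    bad(which(!df$multiple_flag %in% c(0, 1)), "multiple_flag not 0/1")
  } else if (schema == "projection") {
    bad(which(df$births < 0), "negative births")
    if (!is.null(df$women)) bad(which(df$women < 0), "negative women")
    if (!is.null(df$asfr)) bad(which(df$asfr < 0), "negative asfr")
    sums <- tapply(df$births, paste(df$country, df$year), sum)
    shares_bad <- names(sums)[sums <= 0]
    if (length(shares_bad))
      v[[length(v) + 1L]] <- data.frame(
        line = 0L, problem = paste("nonpositive total births for",
                                   paste(shares_bad, collapse = ", ")))
    if (!is.null(df$women) && !is.null(df$asfr)) {
      implied <- tapply(df$women * df$asfr, paste(df$country, df$year), sum)
      rel <- abs(implied - sums) / pmax(sums, 1e-12)
      inc <- names(sums)[rel > 0.005]
      if (length(inc))
        v[[length(v) + 1L]] <- data.frame(
          line = 0L, problem = paste("women x asfr inconsistent with births:",
                                     paste(inc, collapse = ", ")))
    }
  } else {
    bad(which(df$share_primary_education < 0 | df$share_primary_education > 1),
        "share_primary_education outside [0, 1]")
  }
  out <- if (length(v)) do.call(rbind, v) else
    data.frame(line = integer(), problem = character())
  if (nrow(out) > 0)
    message(nrow(out), " schema violation(s); first ",
            min(10, nrow(out)), ":\n",
            paste(utils::capture.output(print(head(out, 10))), collapse = "\n"))
  rownames(out) <- NULL
  out
}

pipeline_stages <- c("simulate", "prep", "fit", "panel", "project", "report")

#' Run the estimation and projection pipeline
#'
#' Executes the stages simulate -> prep -> fit -> panel -> project -> report,
#' writing every output as delimited text under `output_dir`.  Any prefix or
#' contiguous subset of stages can be run; later stages read the cached
#' outputs of earlier ones.  All randomness is derived from `config$seed`, so
#' a full run with a fixed seed is bit-reproducible; the returned manifest
#' lists every output file with its MD5 content hash.  Each filter logs its
#' row counts so sample attrition is auditable.
#'
#' @param config a [pipeline_config()].
#' @param output_dir directory for stage outputs (created if needed).
#' @param stages character subset of
#'   `c("simulate", "prep", "fit", "panel", "project", "report")`.
#' @return `data.frame` manifest (`stage`, `file`, `md5`), invisibly; also
#'   written to `manifest.csv` by the report stage.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir,
                         stages = pipeline_stages) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(output_dir, f)
  manifest <- list()
  note <- function(stage, file) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, file = basename(file),
      md5 = unname(tools::md5sum(file)))
  }

  if ("simulate" %in% stages) {
    message("[simulate]")
    params <- do.call(synth_params, c(config$synth,
                                      if (is.null(config$synth$seed))
                                        list(seed = config$seed)))
    births <- generate_birth_histories(params)
    write_birth_histories(births, pth("births.csv"))
    sched <- setNames(
      lapply(seq_along(config$scenario_years), function(i)
        shift_schedule(params$fertility_schedule, 0.15 * i)),
      as.character(config$scenario_years))
    proj <- generate_projection_tables(
      params, c(config$baseline_year, config$scenario_years),
      schedules = sched)
    write.csv(proj, pth("projection.csv"), row.names = FALSE, quote = FALSE)
    gt <- true_values(params)
    write.csv(data.frame(country = names(gt$expected_rate),
                         baseline = unname(gt$country_baselines),
                         expected_rate = unname(gt$expected_rate)),
              pth("ground_truth.csv"), row.names = FALSE, quote = FALSE)
    note("simulate", pth("births.csv"))
    note("simulate", pth("projection.csv"))
    note("simulate", pth("ground_truth.csv"))
  }

  if ("prep" %in% stages) {
    message("[prep]")
    rec <- read_birth_records(pth("births.csv"))
    rec <- apply_recall_window(rec, config$recall_window_years)
    rec <- apply_exclusions(rec, config$exclusion_rules)
    del <- collapse_to_deliveries(rec, config$age_scheme)
    write.csv(del, pth("deliveries.csv"), row.names = FALSE, quote = FALSE)
    note("prep", pth("deliveries.csv"))
  }

  if ("fit" %in% stages) {
    message("[fit]")
    del <- read.csv(pth("deliveries.csv"), stringsAsFactors = FALSE)
    fit <- twin_lpm(del, config$age_scheme, vcov_type = config$covariance_mode)
    rates <- fit_country_rates(del, n_draws = config$n_draws,
                               seed = config$seed + 1L)
    post <- draw_posterior(fit, n_draws = config$n_draws,
                           seed = config$seed + 2L)
    est <- coef(fit)
    write.csv(data.frame(parameter = names(est), estimate = unname(est),
                         se = unname(fit$se[names(est)])),
              pth("lpm_fit.csv"), row.names = FALSE, quote = FALSE)
    write.csv(data.frame(country = names(rates$point),
                         rate_per_1000 = 1000 * unname(rates$point),
                         se_per_1000 = 1000 * unname(rates$se),
                         n = unname(rates$n)),
              pth("country_rates.csv"), row.names = FALSE, quote = FALSE)
    write.csv(cbind(draw = seq_len(nrow(post$draws)), as.data.frame(post$draws),
                    as.data.frame(rates$draws)[, names(rates$point),
                                               drop = FALSE] |>
                      setNames(paste0("tr_", names(rates$point)))),
              pth("posterior_draws.csv"), row.names = FALSE, quote = FALSE)
    note("fit", pth("lpm_fit.csv"))
    note("fit", pth("country_rates.csv"))
    note("fit", pth("posterior_draws.csv"))
  }

  if ("panel" %in% stages) {
    message("[panel]")
    del <- read.csv(pth("deliveries.csv"), stringsAsFactors = FALSE)
    cells <- group_years(del, config$min_group_deliveries)
    cells <- filter_short_span(cells, config$min_span_years)
    write.csv(cells, pth("panel_cells.csv"), row.names = FALSE, quote = FALSE)
    note("panel", pth("panel_cells.csv"))
    enough <- length(unique(cells$country)) >= 2 &&
      length(unique(period_group(floor((cells$year_start + cells$year_end) / 2)))) >= 2
    if (enough) {
      pf <- fit_panel_fe(cells)
      write.csv(data.frame(term = names(pf$mab_coefficients),
                           estimate = unname(pf$mab_coefficients),
                           se = unname(pf$se)),
                pth("panel_fit.csv"), row.names = FALSE, quote = FALSE)
      note("panel", pth("panel_fit.csv"))
    } else {
      message("  too few countries/periods for the panel fit; skipped")
    }
  }

  if ("project" %in% stages) {
    message("[project]")
    del <- read.csv(pth("deliveries.csv"), stringsAsFactors = FALSE)
    proj <- read.csv(pth("projection.csv"), stringsAsFactors = FALSE)
    fit <- twin_lpm(del, config$age_scheme, vcov_type = config$covariance_mode)
    rates <- fit_country_rates(del, n_draws = config$n_draws,
                               seed = config$seed + 1L)
    post <- draw_posterior(fit, n_draws = config$n_draws,
                           seed = config$seed + 2L)
    rows <- list(); dec_rows <- list()
    for (cc in intersect(unique(proj$country), colnames(rates$draws))) {
      base <- as_projection_input(proj, cc, config$baseline_year)
      for (yr in config$scenario_years) {
        scen <- as_projection_input(proj, cc, yr)
        sc <- run_scenario(base, scen, rates, post,
                           mode = config$probability_mode)
        sm <- sc$summary
        rows[[length(rows) + 1L]] <- data.frame(
          country = cc, scenario_year = yr,
          quantity = rownames(sm), q1 = sm[, "q1"],
          median = sm[, "median"], q3 = sm[, "q3"])
        if (!is.null(base$women) && !is.null(base$asfr) &&
            !is.null(scen$women) && !is.null(scen$asfr)) {
          dc <- decompose_change(base, scen, rates, post,
                                 mode = config$probability_mode)
          for (what in c("rate", "count")) {
            sm2 <- dc[[what]]$summary
            dec_rows[[length(dec_rows) + 1L]] <- data.frame(
              country = cc, scenario_year = yr, outcome = what,
              term = rownames(sm2), q1 = sm2[, "q1"],
              median = sm2[, "median"], q3 = sm2[, "q3"])
          }
        }
      }
    }
    write.csv(do.call(rbind, rows), pth("projections.csv"),
              row.names = FALSE, quote = FALSE)
    note("project", pth("projections.csv"))
    if (length(dec_rows)) {
      write.csv(do.call(rbind, dec_rows), pth("decomposition.csv"),
                row.names = FALSE, quote = FALSE)
      note("project", pth("decomposition.csv"))
    }
  }

  if ("report" %in% stages) {
    message("[report]")
    cfg_flat <- config
    cfg_flat$exclusion_rules <- NULL
    cfg_flat$synth <- NULL
    cfg_lines <- c("# pipeline configuration",
                   paste0(names(cfg_flat), ": ",
                          vapply(cfg_flat, function(x)
                            paste(format(x), collapse = " "), "")))
    writeLines(cfg_lines, pth("run_config.txt"))
    note("report", pth("run_config.txt"))
  }

  man <- do.call(rbind, manifest)
  if ("report" %in% stages) {
    write.csv(man, pth("manifest.csv"), row.names = FALSE, quote = FALSE)
  }
  invisible(man)
}
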