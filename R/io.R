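#' Read diet plans from CSV or JSON
#'
#' The CSV dialect has columns `name`, `kcal`, `carbohydrate_g`,
#' `protein_g`, `fat_g` (the same dialect [generate_diets()],
#' [if_diet_table()] and [nafld_diet_table()] emit).  JSON files hold an
#' array of objects with the same keys.
#'
#' @param path file path (`.csv` or `.json`).
#' @return data.frame of diets; rows are coercible with [as_diet()].
#' @export
read_diets <- function(path) {
  if (!file.exists(path)) stop("diet file not found: ", path)
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  req <- c("carbohydrate_g", "protein_g", "fat_g")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols)) {
    stop("diet table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in req) {
    if (!is.numeric(x[[col]]) || anyNA(x[[col]]) || any(x[[col]] < 0)) {
      stop("diet column '", col, "' must be non-negative numeric")
    }
  }
  if (is.null(x$name)) x$name <- sprintf("diet_%03d", seq_len(nrow(x)))
  if (is.null(x$kcal)) x$kcal <- NA_real_
  x[, c("name", "kcal", req)]
}

#' Write diet plans to CSV
#'
#' @param diets a diet data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_diets <- function(diets, path) {
  utils::write.csv(diets, path, row.names = FALSE)
  invisible(path)
}

#' Exchange tables for a set of diets
#'
#' One row per diet, mirroring the bundled exchange-table layout (O2 in;
#' H2O, CO2, urea, urine, dry feces out), all units in column names.
#'
#' @param diets a diet data.frame (see [read_diets()]).
#' @param profile an [utilization_profile()] applied to every diet.
#' @param db a [thermo_db()].
#' @return data.frame, one row per diet.
#' @export
exchange_report <- function(diets, profile, db = default_thermo_db()) {
  rows <- lapply(seq_len(nrow(diets)),
                 function(i) exchange_table(diets[i, ], profile, db))
  do.call(rbind, rows)
}

#' Write an exchange report to CSV
#'
#' Gram quantities are rounded to one decimal for the file; use
#' [exchange_report()] for full precision.
#'
#' @param report from [exchange_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_exchange_csv <- function(report, path) {
  out <- report
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], round, digits = 1)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Run a lifespan scenario
#'
#' A scenario starts from an accumulated entropic age at a given age and
#' compares a baseline annual rate (optionally divided by a one-year
#' disease survival fraction) against an alternative rate (optionally
#' reduced by an autophagy fraction).  Rates may be given directly or
#' computed from diets via the full pipeline.
#'
#' Scenario fields (list, or YAML/JSON file path):
#' \describe{
#'   \item{age_start}{years at the comparison point.}
#'   \item{accumulated}{kJ/(kg K) at `age_start`; alternatively give
#'     `pre_onset_rate` and it is `pre_onset_rate * age_start`.}
#'   \item{baseline_rate / alternative_rate}{annual rates, kJ/(kg K year).}
#'   \item{survival_fraction}{optional (0, 1]; divides the baseline rate.}
#'   \item{autophagy_reduction}{optional \[0, 1); scales the alternative
#'     rate by `1 - reduction`.}
#'   \item{limit}{lifetime budget; default 11,404 kJ/(kg K).}
#' }
#'
#' @param scenario list or file path.
#' @param db a [thermo_db()].
#' @return list of class `ea_scenario_report` with the resolved rates,
#'   both `ea_lifespan` projections (full precision and rounded) and
#'   `years_gained`.
#' @examples
#' run_lifespan_scenario(list(age_start = 40, pre_onset_rate = 119.9,
#'                            baseline_rate = 119.9, survival_fraction = 0.44,
#'                            alternative_rate = 98.8))
#' @export
run_lifespan_scenario <- function(scenario, db = default_thermo_db()) {
  if (is.character(scenario) && length(scenario) == 1L) {
    scenario <- read_override_file(scenario)
  }
  stopifnot(is.list(scenario))
  if (is.null(scenario$age_start) || scenario$age_start < 0) {
    stop("scenario needs a non-negative age_start")
  }
  limit <- if (is.null(scenario$limit)) {
    db$constants$lifespan_entropy_limit_kJ_per_kgK
  } else {
    scenario$limit
  }
  accumulated <- scenario$accumulated
  if (is.null(accumulated)) {
    if (is.null(scenario$pre_onset_rate)) {
      stop("scenario needs either accumulated or pre_onset_rate")
    }
    accumulated <- accumulate_entropy(scenario$pre_onset_rate,
                                      scenario$age_start)
  }
  if (accumulated > limit) {
    stop("accumulated entropy at onset (", accumulated,
         ") exceeds the lifetime limit (", limit, ")")
  }
  if (is.null(scenario$baseline_rate)) stop("scenario needs baseline_rate")
  base_rate <- scenario$baseline_rate
  if (!is.null(scenario$survival_fraction)) {
    base_rate <- disease_adjusted_rate(base_rate, scenario$survival_fraction)
  }
  alt_rate <- scenario$alternative_rate
  if (is.null(alt_rate)) alt_rate <- base_rate
  if (!is.null(scenario$autophagy_reduction)) {
    alt_rate <- autophagy_adjusted_rate(alt_rate, scenario$autophagy_reduction)
  }
  base_ledger <- entropy_ledger(scenario$age_start, accumulated, base_rate,
                                limit = limit)
  alt_ledger <- entropy_ledger(scenario$age_start, accumulated, alt_rate,
                               limit = limit)
  cmp <- scenario_compare(base_ledger, alt_ledger)
  structure(list(
    age_start = scenario$age_start,
    accumulated = accumulated,
    limit = limit,
    baseline_rate = base_rate,
    alternative_rate = alt_rate,
    baseline = cmp$base,
    alternative = cmp$alternative,
    years_gained = cmp$years_gained,
    years_gained_rounded = cmp$years_gained_rounded
  ), class = "ea_scenario_report")
}

#' @export
print.ea_scenario_report <- function(x, ...) {
  cat(sprintf("<scenario> from age %g with %.0f kJ/(kg K) accumulated (limit %.0f)\n",
              x$age_start, x$accumulated, x$limit))
  cat(sprintf("  baseline    %.1f kJ/(kg K year) -> lifespan %.1f y (%d)\n",
              x$baseline_rate, x$baseline$expected_lifespan,
              x$baseline$expected_lifespan_rounded))
  cat(sprintf("  alternative %.1f kJ/(kg K year) -> lifespan %.1f y (%d)\n",
              x$alternative_rate, x$alternative$expected_lifespan,
              x$alternative$expected_lifespan_rounded))
  cat(sprintf("  years gained: %.1f (%d)\n",
              x$years_gained, x$years_gained_rounded))
  invisible(x)
}

#' Write a scenario report as JSON
#'
#' @param report an `ea_scenario_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scenario_json <- function(report, path) {
  stopifnot(inherits(report, "ea_scenario_report"))
  x <- list(
    age_start = report$age_start,
    accumulated_kJ_per_kgK = report$accumulated,
    limit_kJ_per_kgK = report$limit,
    baseline = list(rate_kJ_per_kgK_year = report$baseline_rate,
                    lifespan_years = report$baseline$expected_lifespan,
                    lifespan_rounded = report$baseline$expected_lifespan_rounded),
    alternative = list(rate_kJ_per_kgK_year = report$alternative_rate,
                       lifespan_years = report$alternative$expected_lifespan,
                       lifespan_rounded = report$alternative$expected_lifespan_rounded),
    years_gained = report$years_gained,
    years_gained_rounded = report$years_gained_rounded
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
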