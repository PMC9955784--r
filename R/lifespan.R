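#' Entropy ledger: accumulated entropic age and future rate segments
#'
#' An organism's entropic age is the specific entropy it has generated
#' since birth, in kJ/(kg K); the projected lifespan is the age at which
#' the accumulated entropy reaches a fixed lifetime budget (11,404
#' kJ/(kg K) by default).  A ledger records the state at `age_start` plus
#' the annual rates expected afterwards as contiguous segments; the final
#' segment is open-ended (`duration = Inf` or `NA`).
#'
#' @param age_start years.
#' @param accumulated kJ/(kg K) already generated at `age_start`; must not
#'   exceed `limit`.
#' @param rates annual rates, kJ/(kg K year), one per segment (> 0).
#' @param durations segment lengths in years; same length as `rates`, with
#'   the last entry `Inf` (or `NA`, treated as `Inf`).  Defaults to a
#'   single open-ended segment.
#' @param limit lifetime budget, kJ/(kg K).
#' @return object of class `ea_ledger`.
#' @examples
#' led <- entropy_ledger(40, 4796, rates = 272.5)
#' project_lifespan(led)
#' @export
entropy_ledger <- function(age_start, accumulated, rates,
                           durations = NULL,
                           limit = 11404) {
  if (is.null(durations)) durations <- c(rep(NA_real_, length(rates) - 1), Inf)
  durations[is.na(durations)] <- Inf
  stopifnot(age_start >= 0, accumulated >= 0, limit > 0,
            length(rates) >= 1, length(durations) == length(rates),
            all(rates > 0), all(durations > 0))
  if (accumulated > limit) {
    stop("accumulated entropy (", accumulated,
         ") already exceeds the lifetime limit (", limit, ")")
  }
  if (any(!is.finite(durations[-length(durations)]))) {
    stop("only the final segment may be open-ended")
  }
  if (!is.infinite(durations[length(durations)])) {
    stop("the final segment must be open-ended (duration Inf)")
  }
  structure(list(age_start = age_start, accumulated = accumulated,
                 rates = rates, durations = durations, limit = limit),
            class = "ea_ledger")
}

#' Entropy accumulated over a period at constant rate
#'
#' @param rate kJ/(kg K year), >= 0.
#' @param years duration, >= 0.
#' @return kJ/(kg K); simply `rate * years`.
#' @examples
#' accumulate_entropy(119.9, 40) # 4796
#' @export
accumulate_entropy <- function(rate, years) {
  stopifnot(rate >= 0, years >= 0)
  rate * years
}

#' Disease-adjusted annual entropy generation rate
#'
#' Converts a healthy annual rate into a disease-state rate by dividing by
#' the one-year survival fraction (Child-Pugh scores A/B/C carry survival
#' fractions 0.95/0.80/0.44): the survivors' average burden rises as the
#' cohort shrinks.
#'
#' @param healthy_rate kJ/(kg K year).
#' @param survival_fraction one-year survival in (0, 1].
#' @return adjusted rate, kJ/(kg K year).
#' @examples
#' disease_adjusted_rate(119.9, 0.95) # 126.2
#' @export
disease_adjusted_rate <- function(healthy_rate, survival_fraction) {
  stopifnot(healthy_rate >= 0)
  if (!is.numeric(survival_fraction) || survival_fraction <= 0 ||
      survival_fraction > 1) {
    stop("survival_fraction must lie in (0, 1]; got ",
         format(survival_fraction))
  }
  healthy_rate / survival_fraction
}

#' Autophagy-adjusted rate
#'
#' Intermittent fasting stimulates autophagy, credited with a 10-25%
#' longevity gain; the annual entropy generation rate is reduced in
#' parallel.
#'
#' @param rate kJ/(kg K year).
#' @param reduction fraction in \[0, 1); typically 0.10-0.25.
#' @return `rate * (1 - reduction)`.
#' @export
autophagy_adjusted_rate <- function(rate, reduction) {
  stopifnot(rate >= 0, reduction >= 0, reduction < 1)
  rate * (1 - reduction)
}

#' Project lifespan from an entropy ledger
#'
#' Walks the ledger's segments, accumulating entropy until the lifetime
#' budget is reached; the age at that point is the expected lifespan.  If
#' the budget is already met at `age_start`, the lifespan is `age_start`.
#'
#' @param ledger an [entropy_ledger()].
#' @return object of class `ea_lifespan`: `expected_lifespan` (years, full
#'   precision), `expected_lifespan_rounded` (nearest integer),
#'   `remaining_years`, `age_start`, `limit`.
#' @export
project_lifespan <- function(ledger) {
  stopifnot(inherits(ledger, "ea_ledger"))
  age <- ledger$age_start
  acc <- ledger$accumulated
  lifespan <- NA_real_
  if (acc >= ledger$limit) {
    lifespan <- age
  } else {
    for (i in seq_along(ledger$rates)) {
      r <- ledger$rates[i]
      dur <- ledger$durations[i]
      if (acc + r * dur >= ledger$limit) {
        lifespan <- age + (ledger$limit - acc) / r
        break
      }
      acc <- acc + r * dur
      age <- age + dur
    }
  }
  if (is.na(lifespan)) {
    # finite segments exhausted the timeline without reaching the limit;
    # cannot happen with a valid (open-ended) ledger
    stop("ledger segments never reach the entropy limit")
  }
  structure(list(expected_lifespan = lifespan,
                 expected_lifespan_rounded = round(lifespan),
                 remaining_years = lifespan - ledger$age_start,
                 age_start = ledger$age_start,
                 limit = ledger$limit),
            class = "ea_lifespan")
}

#' @export
print.ea_lifespan <- function(x, ...) {
  cat(sprintf("<lifespan> %.2f years (%d); %.2f remaining from age %g\n",
              x$expected_lifespan, x$expected_lifespan_rounded,
              x$remaining_years, x$age_start))
  invisible(x)
}

#' Lifespan from a constant power-style entropy rate
#'
#' For a rate expressed in kW/(kg K) (i.e. kJ/(s kg K)), the lifespan from
#' birth is `limit / (rate * seconds_per_year)`.
#'
#' @param rate_kW_per_kgK metabolic entropy generation rate, kW/(kg K).
#' @param limit lifetime budget, kJ/(kg K).
#' @param seconds_per_year defaults to 365 * 24 * 3600.
#' @return years (full precision).
#' @examples
#' constant_rate_lifespan(0.46e-5) # about 79 years
#' @export
constant_rate_lifespan <- function(rate_kW_per_kgK, limit = 11404,
                                   seconds_per_year = 365 * 24 * 3600) {
  stopifnot(rate_kW_per_kgK > 0, limit > 0)
  limit / (rate_kW_per_kgK * seconds_per_year)
}

#' Years gained by switching ledgers
#'
#' Compares the projected lifespans of two ledgers that share the same
#' starting age and accumulated entropy (e.g. continuing the present diet
#' versus changing it at disease onset).
#'
#' @param base,alternative [entropy_ledger()]s with identical `age_start`
#'   and `accumulated`.
#' @return list: `years_gained` (alternative minus base, full precision),
#'   `years_gained_rounded`, and both `ea_lifespan` results.
#' @export
scenario_compare <- function(base, alternative) {
  stopifnot(inherits(base, "ea_ledger"), inherits(alternative, "ea_ledger"))
  if (base$age_start != alternative$age_start ||
      base$accumulated != alternative$accumulated) {
    stop("ledgers must share age_start and accumulated entropy ",
         "(base: age ", base$age_start, ", ", base$accumulated,
         " kJ/kg K; alternative: age ", alternative$age_start, ", ",
         alternative$accumulated, " kJ/kg K)")
  }
  lb <- project_lifespan(base)
  la <- project_lifespan(alternative)
  gained <- la$expected_lifespan - lb$expected_lifespan
  list(years_gained = gained,
       years_gained_rounded = round(gained),
       base = lb, alternative = la)
}
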