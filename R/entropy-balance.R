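#' Entropy carried by the daily material flows
#'
#' Out-term: CO2, metabolic water and urea leaving at 310 K, each mole
#' stream times its absolute entropy `s(310)`.  In-term: fuel moles times
#' `s(298)` plus inhaled O2 times its entropy at 298 K.  Feces carry no
#' assigned thermodynamic properties and are excluded; dietary and urinary
#' water cancel and are likewise excluded.
#'
#' @param fuels an `ea_fuels` vector (mol/day) from [fuel_moles()].
#' @param db a [thermo_db()].
#' @return named numeric, kJ/(K day): `flow_out`, `flow_in`, `net`.
#' @export
flow_entropy <- function(fuels, db = default_thermo_db()) {
  stopifnot(all(fuels >= 0))
  ge <- gas_exchange(fuels, db)
  s_at <- function(name, col) {
    sp <- get_species(db, name)
    v <- sp[[col]]
    if (is.na(v)) stop("species '", name, "' has no ", col,
                       " in the property database")
    v
  }
  # mol -> kmol (1/1000) because entropies are kJ/(kmol K)
  out <- (ge$mol[["co2"]] * s_at("CO2", "s_310") +
            ge$mol[["h2o"]] * s_at("H2O", "s_310") +
            ge$mol[["urea"]] * s_at("urea", "s_310")) / 1000
  inn <- (unname(fuels["glucose"]) * s_at("glucose", "s_298") +
            unname(fuels["palmitate"]) * s_at("palmitate", "s_298") +
            unname(fuels["amino"]) * s_at("amino", "s_298") +
            ge$mol[["o2"]] * s_at("O2", "s_298")) / 1000
  c(flow_out = out, flow_in = inn, net = out - inn)
}

#' Daily and annual specific entropy generation for one diet
#'
#' Closes the open-system entropy balance for the body in quasi-steady
#' state.  Per day,
#' `s_gen = (sum n s)_out - (sum n s)_in + Q/T`,
#' where `Q` is the heat released by metabolism (entered as a positive
#' magnitude: heat export transfers entropy to the surroundings, and with
#' this sign convention `s_gen > 0` for every bundled diet) and `T` is body
#' temperature, 310.15 K.  The annual specific rate divides by the
#' subject's entropy mass basis and multiplies by 365 days.
#'
#' @param d an [diet()] (or coercible).
#' @param subj an [subject()]; supplies the mass basis (kg).
#' @param profile an [utilization_profile()]; defaults to the profile of
#'   the subject's health state.
#' @param db a [thermo_db()].
#' @return object of class `ea_entropy_rate`: list with
#'   `daily_kJ_per_K`, `annual_kJ_per_kgK`, `mass_basis_kg`,
#'   `temperature_K` and `terms` (`flow_out`, `flow_in`, `heat_over_T`,
#'   all kJ/(K day)).
#' @examples
#' db <- default_thermo_db()
#' s <- subject(100, 170, 40)
#' entropy_generation(diet(430, 150, 98), s, db = db)
#' @export
entropy_generation <- function(d, subj, profile = NULL,
                               db = default_thermo_db()) {
  d <- as_diet(d)
  if (is.null(profile)) profile <- utilization_profile(subj$health_state, db)
  fuels <- fuel_moles(oxidized_masses(d, profile), db)
  flow <- flow_entropy(fuels, db)
  heat <- heat_release(fuels, db)
  temperature <- db$constants$body_temperature_K
  heat_over_T <- heat$q_released_kJ_day / temperature
  daily <- unname(flow["net"]) + heat_over_T
  annual <- daily * db$constants$days_per_year / subj$mass_basis_kg
  structure(list(
    diet = d$name,
    daily_kJ_per_K = daily,
    annual_kJ_per_kgK = annual,
    mass_basis_kg = subj$mass_basis_kg,
    temperature_K = temperature,
    terms = c(flow_out = unname(flow["flow_out"]),
              flow_in = unname(flow["flow_in"]),
              heat_over_T = heat_over_T)
  ), class = "ea_entropy_rate")
}

#' @export
print.ea_entropy_rate <- function(x, ...) {
  cat(sprintf(
    "<entropy rate '%s'> %.2f kJ/(K day); %.1f kJ/(kg K year) on %g kg\n",
    x$diet, x$daily_kJ_per_K, x$annual_kJ_per_kgK, x$mass_basis_kg))
  cat(sprintf("  terms kJ/(K day): flow out %.3f, flow in %.3f, Q/T %.3f\n",
              x$terms[["flow_out"]], x$terms[["flow_in"]],
              x$terms[["heat_over_T"]]))
  invisible(x)
}

#' Serialize an entropy-rate result to JSON
#'
#' @param rate an `ea_entropy_rate`.
#' @param path optional output file; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
entropy_rate_json <- function(rate, path = NULL) {
  stopifnot(inherits(rate, "ea_entropy_rate"))
  x <- list(diet = rate$diet,
            daily_kJ_per_K = rate$daily_kJ_per_K,
            annual_kJ_per_kgK = rate$annual_kJ_per_kgK,
            mass_basis_kg = rate$mass_basis_kg,
            temperature_K = rate$temperature_K,
            terms = as.list(rate$terms))
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
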