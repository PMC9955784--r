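#' Reaction enthalpy of one fuel's oxidation
#'
#' Enthalpy of metabolism per mole of fuel, with reactants taken up at
#' 298 K and products leaving the body at 310 K.  Each species' enthalpy is
#' evaluated as `h(T) = h_form(298) + [h_sens(T) - h_sens(298)]` with gases
#' treated as ideal; condensed species carry no sensible correction over
#' the 12 K span (the property table leaves those cells empty).  Oxidations
#' are exothermic, so the result is negative.
#'
#' @param fuel `"glucose"`, `"palmitate"` or `"amino"`.
#' @param db a [thermo_db()].
#' @return list of class `ea_reaction_enthalpy`: `fuel`, `delta_h_kJ_mol`
#'   (per mol fuel), `products_at` (310 K), `reactants_at` (298 K).
#' @export
reaction_enthalpy <- function(fuel, db = default_thermo_db()) {
  rxs <- oxidation_reactions()
  if (!fuel %in% names(rxs)) {
    stop("unknown fuel '", fuel, "'; must be one of ",
         paste(names(rxs), collapse = ", "))
  }
  rx <- rxs[[fuel]]
  dh_kmol <- sum(vapply(names(rx$products), function(sp) {
    rx$products[[sp]] * species_enthalpy(db, sp, temperature = 310)
  }, numeric(1))) -
    sum(vapply(names(rx$reactants), function(sp) {
      rx$reactants[[sp]] * species_enthalpy(db, sp, temperature = 298)
    }, numeric(1)))
  structure(list(fuel = fuel, delta_h_kJ_mol = dh_kmol / 1000,
                 products_at = 310, reactants_at = 298),
            class = "ea_reaction_enthalpy")
}

# enthalpy of one species at 298 or 310 K, kJ/kmol
species_enthalpy <- function(db, name, temperature) {
  sp <- get_species(db, name)
  if (is.na(sp$h_form_298)) {
    stop("species '", name, "' has no h_form_298 in the property database")
  }
  h <- sp$h_form_298
  if (temperature == 310 && sp$phase == "gas") {
    if (is.na(sp$h_sens_310) || is.na(sp$h_sens_298)) {
      stop("species '", name, "' lacks sensible enthalpy (h_sens_298/h_sens_310)")
    }
    h <- h + (sp$h_sens_310 - sp$h_sens_298)
  }
  h
}

#' Reaction enthalpies of all three fuels
#'
#' @param db a [thermo_db()].
#' @return named numeric, kJ per mol fuel (negative).
#' @export
reaction_enthalpies <- function(db = default_thermo_db()) {
  vapply(names(oxidation_reactions()),
         function(f) reaction_enthalpy(f, db)$delta_h_kJ_mol, numeric(1))
}

#' Daily heat released to the surroundings
#'
#' Of each fuel's reaction enthalpy, the metabolic efficiency eta is
#' captured as ATP and the remainder `(1 - eta) |delta_H|` leaves the body
#' as heat (eta: glucose 0.346, palmitate 0.322, amino 0.104; the
#' corresponding ATP yields 32/106/8 mol per mol fuel are carried along for
#' reporting).
#'
#' @param fuels an `ea_fuels` vector (mol/day) from [fuel_moles()].
#' @param db a [thermo_db()].
#' @param efficiency optional named numeric overriding the shipped eta per
#'   fuel.
#' @return list of class `ea_heat`: `q_released_kJ_day` (>= 0),
#'   `per_fuel_kJ_day`, `atp_mol_day`.
#' @export
heat_release <- function(fuels, db = default_thermo_db(), efficiency = NULL) {
  stopifnot(all(fuels >= 0))
  cn <- db$constants
  eta <- cn$efficiency
  if (!is.null(efficiency)) eta[names(efficiency)] <- efficiency
  if (any(eta < 0 | eta > 1)) stop("efficiencies must lie in [0, 1]")
  dh <- reaction_enthalpies(db)
  per_fuel <- vapply(names(oxidation_reactions()), function(f) {
    (1 - eta[[f]]) * abs(dh[[f]]) * unname(fuels[f])
  }, numeric(1))
  structure(list(q_released_kJ_day = sum(per_fuel),
                 per_fuel_kJ_day = per_fuel,
                 atp_mol_day = cn$atp_yield[names(per_fuel)] *
                   unclass(fuels)[names(per_fuel)]),
            class = "ea_heat")
}

#' @export
print.ea_heat <- function(x, ...) {
  cat(sprintf("<heat release> %.1f kJ/day (glucose %.1f, palmitate %.1f, amino %.1f)\n",
              x$q_released_kJ_day, x$per_fuel_kJ_day[["glucose"]],
              x$per_fuel_kJ_day[["palmitate"]], x$per_fuel_kJ_day[["amino"]]))
  invisible(x)
}
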