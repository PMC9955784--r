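#' Daily diet composition
#'
#' @param carbohydrate_g,protein_g,fat_g macronutrient masses, g/day (>= 0).
#' @param kcal stated daily calories (informational; `NA` if unknown).
#' @param name optional plan label.
#' @return object of class `ea_diet`.
#' @export
diet <- function(carbohydrate_g, protein_g, fat_g, kcal = NA_real_,
                 name = "diet") {
  stopifnot(carbohydrate_g >= 0, protein_g >= 0, fat_g >= 0)
  structure(list(name = name, kcal = kcal,
                 carbohydrate_g = carbohydrate_g,
                 protein_g = protein_g, fat_g = fat_g),
            class = "ea_diet")
}

#' @export
print.ea_diet <- function(x, ...) {
  cat(sprintf("<diet '%s'> %s kcal: carbohydrate %g g, protein %g g, fat %g g\n",
              x$name, format(x$kcal), x$carbohydrate_g, x$protein_g, x$fat_g))
  invisible(x)
}

#' Coerce a one-row diet table to a diet object
#'
#' @param x a one-row data.frame with columns `carbohydrate_g`, `protein_g`,
#'   `fat_g`, and optionally `kcal`, `name`.
#' @return an `ea_diet`.
#' @export
as_diet <- function(x) {
  if (inherits(x, "ea_diet")) return(x)
  x <- as.list(x)
  diet(x$carbohydrate_g, x$protein_g, x$fat_g,
       kcal = if (is.null(x$kcal)) NA_real_ else x$kcal,
       name = if (is.null(x$name)) "diet" else x$name)
}

#' Macronutrient utilization profiles
#'
#' In health the fractions are digestibilities (99% of carbohydrate, 92%
#' of protein, 95% of fat absorbed and oxidized).  For fatty liver disease
#' graded by Child-Pugh score, the reduced oxidation fractions replace the
#' healthy digestibilities (A: 88/28/46%, B: 86/31/55%, C: 88/24/59% for
#' carbohydrate/protein/fat).
#'
#' @param state `"healthy"`, `"childpugh_A"`, `"childpugh_B"` or
#'   `"childpugh_C"`; ignored if explicit fractions are given.
#' @param db a [thermo_db()] supplying the shipped fractions.
#' @param carbohydrate,protein,fat explicit fractions in \[0, 1\]; all three
#'   must be given together.
#' @return named numeric vector `c(carbohydrate=, protein=, fat=)` of class
#'   `ea_profile`.
#' @export
utilization_profile <- function(state = "healthy", db = default_thermo_db(),
                                carbohydrate = NULL, protein = NULL,
                                fat = NULL) {
  if (!is.null(carbohydrate) || !is.null(protein) || !is.null(fat)) {
    if (is.null(carbohydrate) || is.null(protein) || is.null(fat)) {
      stop("explicit profiles need all of carbohydrate, protein, fat")
    }
    p <- c(carbohydrate = carbohydrate, protein = protein, fat = fat)
  } else if (state == "healthy") {
    p <- db$constants$digestibility_healthy
  } else if (state %in% names(db$constants$oxidation_fractions)) {
    p <- db$constants$oxidation_fractions[[state]]
  } else {
    stop("unknown utilization state '", state, "'")
  }
  if (any(p < 0 | p > 1)) stop("utilization fractions must lie in [0, 1]")
  structure(p[c("carbohydrate", "protein", "fat")], class = "ea_profile")
}

#' Mass of each macronutrient actually oxidized
#'
#' Component-wise product of the diet with the utilization profile.
#'
#' @param d an [diet()] (or coercible via [as_diet()]).
#' @param profile an [utilization_profile()].
#' @return named numeric, g/day: `carbohydrate`, `protein`, `fat`.
#' @export
oxidized_masses <- function(d, profile) {
  d <- as_diet(d)
  c(carbohydrate = d$carbohydrate_g * unname(profile["carbohydrate"]),
    protein = d$protein_g * unname(profile["protein"]),
    fat = d$fat_g * unname(profile["fat"]))
}

#' Fuel moles from oxidized masses
#'
#' Oxidized carbohydrate, fat and protein are expressed as moles of
#' glucose (180 g/mol), palmitic acid (256 g/mol) and average amino acid
#' (119 g/mol).
#'
#' @param masses named numeric from [oxidized_masses()] (g/day).
#' @param db a [thermo_db()].
#' @return named numeric `c(glucose=, palmitate=, amino=)` mol/day, class
#'   `ea_fuels`.
#' @export
fuel_moles <- function(masses, db = default_thermo_db()) {
  stopifnot(all(masses >= 0))
  structure(
    c(glucose = unname(masses["carbohydrate"]) / get_species(db, "glucose")$molar_mass,
      palmitate = unname(masses["fat"]) / get_species(db, "palmitate")$molar_mass,
      amino = unname(masses["protein"]) / get_species(db, "amino")$molar_mass),
    class = "ea_fuels")
}

#' Respiratory gas exchange and urea production
#'
#' Applies the oxidation stoichiometry to the fuel moles: O2 demand,
#' CO2 and metabolic water production, and urea formed from amino-acid
#' nitrogen.  Grams follow from the shipped molar masses (O2 32, CO2 44,
#' H2O 18, urea 60 g/mol).
#'
#' @param fuels an `ea_fuels` vector from [fuel_moles()].
#' @param db a [thermo_db()].
#' @return list with `mol` and `g` components, each named numeric over
#'   `o2`, `co2`, `h2o`, `urea`.
#' @export
gas_exchange <- function(fuels, db = default_thermo_db()) {
  stopifnot(all(fuels >= 0))
  rxs <- oxidation_reactions()
  mol <- c(o2 = 0, co2 = 0, h2o = 0, urea = 0)
  key <- c(O2 = "o2", CO2 = "co2", H2O = "h2o", urea = "urea")
  for (fuel in names(rxs)) {
    n <- unname(fuels[fuel])
    rx <- rxs[[fuel]]
    mol["o2"] <- mol["o2"] + n * rx$reactants[["O2"]]
    for (sp in names(rx$products)) {
      mol[key[[sp]]] <- mol[key[[sp]]] + n * rx$products[[sp]]
    }
  }
  mm <- c(o2 = get_species(db, "O2")$molar_mass,
          co2 = get_species(db, "CO2")$molar_mass,
          h2o = get_species(db, "H2O")$molar_mass,
          urea = get_species(db, "urea")$molar_mass)
  list(mol = mol, g = mol * mm)
}

#' Urea excretion and urine mass
#'
#' 65% of produced urea is excreted, dissolved at 20 g urea per litre of
#' urine; urine mass assumes 1 g/mL.
#'
#' @param urea_produced_g urea production, g/day.
#' @param db a [thermo_db()].
#' @return named numeric: `urea_excreted_g`, `urine_g` (both per day).
#' @export
urine_mass <- function(urea_produced_g, db = default_thermo_db()) {
  stopifnot(urea_produced_g >= 0)
  cn <- db$constants
  excreted <- cn$urea_excreted_fraction * urea_produced_g
  urine_L <- excreted / cn$urea_urine_conc_g_per_L
  c(urea_excreted_g = excreted, urine_g = urine_L * 1000)
}

#' Dry fecal mass
#'
#' Unabsorbed (non-utilized) dry matter: sum of (1 - fraction) times each
#' macronutrient mass.
#'
#' @inheritParams oxidized_masses
#' @return g/day.
#' @export
feces_mass <- function(d, profile) {
  d <- as_diet(d)
  masses <- c(d$carbohydrate_g, d$protein_g, d$fat_g)
  sum((1 - unname(profile[c("carbohydrate", "protein", "fat")])) * masses)
}

#' Full daily exchange table for one diet
#'
#' Composes [oxidized_masses()], [fuel_moles()], [gas_exchange()],
#' [urine_mass()] and [feces_mass()] into one row mirroring the package's
#' exchange-table layout: inhaled O2 and exhaled CO2/H2O plus excreted
#' urea, urine and dry feces.
#'
#' @inheritParams oxidized_masses
#' @param db a [thermo_db()].
#' @return one-row data.frame with columns `name`, `o2_g`, `h2o_g`,
#'   `co2_g`, `urea_produced_g`, `urea_excreted_g`, `urine_g`,
#'   `dry_feces_g`, `o2_mol`, `co2_mol`, `h2o_mol`, `urea_mol`.
#' @examples
#' db <- default_thermo_db()
#' d <- diet(430, 150, 98, kcal = 3100, name = "healthy obese")
#' exchange_table(d, utilization_profile("healthy", db), db)
#' @export
exchange_table <- function(d, profile, db = default_thermo_db()) {
  d <- as_diet(d)
  ox <- oxidized_masses(d, profile)
  fuels <- fuel_moles(ox, db)
  ge <- gas_exchange(fuels, db)
  ur <- urine_mass(ge$g[["urea"]], db)
  data.frame(
    name = d$name,
    o2_g = ge$g[["o2"]], h2o_g = ge$g[["h2o"]], co2_g = ge$g[["co2"]],
    urea_produced_g = ge$g[["urea"]],
    urea_excreted_g = ur[["urea_excreted_g"]],
    urine_g = ur[["urine_g"]],
    dry_feces_g = feces_mass(d, profile),
    o2_mol = ge$mol[["o2"]], co2_mol = ge$mol[["co2"]],
    h2o_mol = ge$mol[["h2o"]], urea_mol = ge$mol[["urea"]],
    stringsAsFactors = FALSE
  )
}

#' Bundled intermittent-fasting diet plans
#'
#' Six 16:8 intermittent-fasting plans for 80 kg subjects aged 25 and 50:
#' weight-maintaining, weight-gain and weight-loss variants.  Results
#' downstream are keyed to composition, not to plan label.
#'
#' @return data.frame with columns `name`, `age`, `kind`, `kcal`,
#'   `carbohydrate_g`, `protein_g`, `fat_g`.
#' @export
if_diet_table <- function() {
  data.frame(
    name = c("maintain_25", "maintain_50", "gain_25", "gain_50",
             "loss_25", "loss_50"),
    age = c(25, 50, 25, 50, 25, 50),
    kind = rep(c("weight_maintaining", "weight_gain", "weight_loss"), each = 2),
    kcal = c(2210, 2010, 1912, 1711, 1663, 1510),
    carbohydrate_g = c(318, 295, 276, 257, 242, 225),
    protein_g = c(99, 86, 94, 74, 68, 67),
    fat_g = c(59, 54, 48, 43, 47, 38),
    stringsAsFactors = FALSE
  )
}

#' Bundled fatty-liver-disease diet plans
#'
#' Plans for 100 kg obese subjects: one for a healthy obese person and one
#' per Child-Pugh score.
#'
#' @return data.frame with columns `name`, `kcal`, `carbohydrate_g`,
#'   `protein_g`, `fat_g`.
#' @export
nafld_diet_table <- function() {
  data.frame(
    name = c("healthy_obese", "childpugh_A", "childpugh_B", "childpugh_C"),
    kcal = c(3100, 3000, 3200, 3300),
    carbohydrate_g = c(430, 428, 416, 470),
    protein_g = c(150, 130, 160, 165),
    fat_g = c(98, 92, 110, 79),
    stringsAsFactors = FALSE
  )
}
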