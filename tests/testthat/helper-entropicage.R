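# shared fixtures for the suite
db <- default_thermo_db()
healthy <- utilization_profile("healthy", db)

# Independent brute-force oracle for the gas exchange: derives the product
# and O2 coefficients from raw C/H/N/O atom balances of each fuel's formula
# (nitrogen to urea CH4N2O, sulfur dropped), never touching the shipped
# reaction-coefficient table.
oracle_gas_exchange <- function(d, profile, db) {
  d <- as_diet(d)
  ox <- c(glucose = d$carbohydrate_g * profile[["carbohydrate"]],
          amino = d$protein_g * profile[["protein"]],
          palmitate = d$fat_g * profile[["fat"]])
  tot <- c(o2 = 0, co2 = 0, h2o = 0, urea = 0)
  for (fuel in names(ox)) {
    sp <- get_species(db, fuel)
    n_fuel <- ox[[fuel]] / sp$molar_mass
    cnt <- parse_formula(sp$formula)
    cnt <- cnt[names(cnt) != "S"]
    el <- function(e) if (e %in% names(cnt)) cnt[[e]] else 0
    urea <- el("N") / 2                     # urea CH4N2O carries 2 N
    co2 <- el("C") - urea * 1               # 1 C per urea
    h2o <- (el("H") - urea * 4) / 2         # 4 H per urea
    o2 <- (2 * co2 + h2o + urea * 1 - el("O")) / 2  # O balance, 1 O per urea
    tot <- tot + n_fuel * c(o2 = o2, co2 = co2, h2o = h2o, urea = urea)
  }
  list(mol = tot,
       g = tot * c(o2 = 32, co2 = 44, h2o = 18, urea = 60))
}
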