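#' Thermodynamic property database and metabolic constants
#'
#' The package ships a small plain-text property table
#' (`inst/extdata/species_properties.csv`) with, for each chemical species
#' taking part in macronutrient oxidation, the molar mass, the standard
#' formation enthalpy at 298 K, absolute entropies at 298 K and 310 K, and
#' (for gases) sensible enthalpies at the two temperatures.  Enthalpies are
#' in kJ/kmol and entropies in kJ/(kmol K).  Alongside the species table a
#' set of metabolic constants is defined: digestibilities, Child-Pugh
#' oxidation fractions, metabolic efficiencies, ATP yields, the urea/urine
#' rule, body temperature, the lifetime specific-entropy budget, and unit
#' conversion factors.
#'
#' `thermo_db()` builds the default database and optionally merges
#' user overrides key-wise (a list with elements `species` and/or
#' `constants`); `default_thermo_db()` is the no-override shortcut.
#'
#' @param overrides optional named list.  `overrides$species` is a list of
#'   per-species named lists (e.g. `list(glucose = list(s_298 = 210))`);
#'   `overrides$constants` replaces individual constants by name.  May also
#'   be a path to a YAML or JSON file with the same structure.
#' @return an object of class `thermo_db`: a list with elements `species`
#'   (data.frame) and `constants` (named list).
#' @examples
#' db <- default_thermo_db()
#' get_species(db, "glucose")$molar_mass
#' @export
thermo_db <- function(overrides = NULL) {
  species <- utils::read.csv(
    system.file("extdata", "species_properties.csv", package = "entropicage",
                mustWork = TRUE),
    stringsAsFactors = FALSE
  )
  names(species) <- sub("_g_mol$|_kJ_kmol(_K)?$", "", names(species))
  constants <- default_metabolic_constants()

  if (!is.null(overrides)) {
    if (is.character(overrides) && length(overrides) == 1L) {
      overrides <- read_override_file(overrides)
    }
    stopifnot(is.list(overrides))
    if (!is.null(overrides$species)) {
      for (nm in names(overrides$species)) {
        i <- match(nm, species$name)
        if (is.na(i)) stop("override for unknown species '", nm, "'")
        for (fld in names(overrides$species[[nm]])) {
          if (!fld %in% names(species)) {
            stop("unknown species field '", fld, "' in override for '", nm, "'")
          }
          species[i, fld] <- overrides$species[[nm]][[fld]]
        }
      }
    }
    if (!is.null(overrides$constants)) {
      constants <- utils::modifyList(constants, overrides$constants)
    }
  }

  structure(list(species = species, constants = constants),
            class = "thermo_db")
}

#' @rdname thermo_db
#' @export
default_thermo_db <- function() thermo_db()

# constants of the metabolic model; fractions dimensionless, masses g,
# temperatures K, entropy budget kJ/(kg K)
default_metabolic_constants <- function() {
  list(
    digestibility_healthy = c(carbohydrate = 0.99, protein = 0.92, fat = 0.95),
    oxidation_fractions = list(
      childpugh_A = c(carbohydrate = 0.88, protein = 0.28, fat = 0.46),
      childpugh_B = c(carbohydrate = 0.86, protein = 0.31, fat = 0.55),
      childpugh_C = c(carbohydrate = 0.88, protein = 0.24, fat = 0.59)
    ),
    efficiency = c(glucose = 0.346, palmitate = 0.322, amino = 0.104),
    atp_yield = c(glucose = 32, palmitate = 106, amino = 8),
    urea_urine_conc_g_per_L = 20,
    urea_excreted_fraction = 0.65,
    body_temperature_K = 310.15,
    lifespan_entropy_limit_kJ_per_kgK = 11404,
    caloric_need_multiplier = 1.2,
    survival_fractions = c(childpugh_A = 0.95, childpugh_B = 0.80,
                           childpugh_C = 0.44),
    kcal_to_kJ = 4.184,
    days_per_year = 365,
    atwater_kcal_per_g = c(carbohydrate = 4, protein = 4, fat = 9)
  )
}

read_override_file <- function(path) {
  if (!file.exists(path)) stop("override file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Look up one species record
#'
#' @param db a `thermo_db` object.
#' @param name species identifier; one of `"glucose"`, `"palmitate"`,
#'   `"amino"`, `"O2"`, `"CO2"`, `"H2O"`, `"H2O_liq"`, `"urea"`.
#' @return a named list with the species' fields (`formula`, `molar_mass`,
#'   `h_form_298`, `s_298`, `h_sens_298`, `h_sens_310`, `s_310`, ...).
#' @export
get_species <- function(db, name) {
  stopifnot(inherits(db, "thermo_db"))
  i <- match(name, db$species$name)
  if (is.na(i)) {
    stop("unknown species '", name, "'; registered species: ",
         paste(db$species$name, collapse = ", "))
  }
  as.list(db$species[i, ])
}

#' Metabolic constants of a database
#'
#' @inheritParams get_species
#' @return the named list of constants.
#' @export
metabolic_constants <- function(db) {
  stopifnot(inherits(db, "thermo_db"))
  db$constants
}

#' Parse a chemical formula into element counts
#'
#' Fractional subscripts are allowed (composite species such as the average
#' amino acid C4.57H9.03N1.27O2.25S0.046).
#'
#' @param formula a formula string such as `"C6H12O6"`.
#' @return named numeric vector of element counts.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  tokens <- regmatches(formula,
                       gregexpr("[A-Z][a-z]?[0-9]*\\.?[0-9]*", formula))[[1]]
  if (length(tokens) == 0L || nchar(paste(tokens, collapse = "")) != nchar(formula)) {
    stop("cannot parse formula '", formula, "'")
  }
  elems <- sub("[0-9.]*$", "", tokens)
  counts <- sub("^[A-Z][a-z]?", "", tokens)
  counts <- ifelse(nchar(counts) == 0L, "1", counts)
  stats::setNames(as.numeric(counts), elems)
}

# IUPAC 2021 standard atomic weights for the elements the model uses
.atomic_masses <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, S = 32.06)

#' Molar mass implied by a chemical formula
#'
#' @inheritParams parse_formula
#' @return g/mol.
#' @export
formula_mass <- function(formula) {
  counts <- parse_formula(formula)
  unknown <- setdiff(names(counts), names(.atomic_masses))
  if (length(unknown)) stop("no atomic mass for element(s): ",
                            paste(unknown, collapse = ", "))
  sum(counts * .atomic_masses[names(counts)])
}

#' Self-check of the property database
#'
#' Verifies that every stored molar mass agrees with its formula within
#' 1.5% (the shipped masses are rounded to integers, e.g. glucose 180 vs
#' 180.16 from atomic masses), that all constant fractions lie in \[0, 1\],
#' and that temperature and entropy-budget constants are positive.
#' Violations are returned, not raised.
#'
#' @inheritParams get_species
#' @param mass_tolerance relative tolerance for the formula-mass check.
#' @return character vector of violation messages; empty if the database is
#'   consistent.
#' @export
check_consistency <- function(db, mass_tolerance = 0.015) {
  stopifnot(inherits(db, "thermo_db"))
  violations <- character()
  for (i in seq_len(nrow(db$species))) {
    rec <- db$species[i, ]
    if (!is.finite(rec$molar_mass) || rec$molar_mass <= 0) {
      violations <- c(violations, sprintf(
        "species '%s': molar_mass must be > 0 (got %s)", rec$name,
        format(rec$molar_mass)))
      next
    }
    fm <- formula_mass(rec$formula)
    rel <- abs(rec$molar_mass - fm) / fm
    if (rel > mass_tolerance) {
      violations <- c(violations, sprintf(
        "species '%s': molar_mass %.3f disagrees with formula %s (%.3f g/mol, %.2f%%)",
        rec$name, rec$molar_mass, rec$formula, fm, 100 * rel))
    }
  }
  cn <- db$constants
  fracs <- c(cn$digestibility_healthy, unlist(cn$oxidation_fractions),
             cn$efficiency,
             urea_excreted_fraction = cn$urea_excreted_fraction,
             cn$survival_fractions)
  bad <- fracs[!is.finite(fracs) | fracs < 0 | fracs > 1]
  for (i in seq_along(bad)) {
    violations <- c(violations, sprintf(
      "constant fraction '%s' outside [0, 1]: %s", names(bad)[i],
      format(bad[[i]])))
  }
  if (!is.finite(cn$body_temperature_K) || cn$body_temperature_K <= 0) {
    violations <- c(violations, "body_temperature_K must be > 0")
  }
  if (!is.finite(cn$lifespan_entropy_limit_kJ_per_kgK) ||
      cn$lifespan_entropy_limit_kJ_per_kgK <= 0) {
    violations <- c(violations, "lifespan_entropy_limit_kJ_per_kgK must be > 0")
  }
  violations
}

#' Oxidation reactions of the three fuel surrogates
#'
#' Carbohydrate, fat and protein oxidation are represented by glucose,
#' palmitic acid and the average amino acid.  Each reaction lists the molar
#' coefficients per mole of fuel; the amino-acid reaction routes nitrogen
#' to urea:
#' \itemize{
#'   \item glucose + 6 O2 -> 6 H2O + 6 CO2
#'   \item palmitate + 23 O2 -> 16 CO2 + 16 H2O
#'   \item amino + 4.75 O2 -> 3.245 H2O + 3.935 CO2 + 0.635 urea
#' }
#' Sulfur (S:C = 0.01 in the average amino acid) is neglected throughout.
#'
#' @return named list with one entry per fuel; each entry has named numeric
#'   vectors `reactants` and `products` (coefficients per mol fuel).
#' @export
oxidation_reactions <- function() {
  list(
    glucose = list(
      reactants = c(glucose = 1, O2 = 6),
      products  = c(H2O = 6, CO2 = 6)
    ),
    palmitate = list(
      reactants = c(palmitate = 1, O2 = 23),
      products  = c(CO2 = 16, H2O = 16)
    ),
    amino = list(
      reactants = c(amino = 1, O2 = 4.75),
      products  = c(H2O = 3.245, CO2 = 3.935, urea = 0.635)
    )
  )
}

#' @export
print.thermo_db <- function(x, ...) {
  cat("<thermo_db>", nrow(x$species), "species;",
      length(x$constants), "constant groups\n")
  print(x$species[, c("name", "formula", "molar_mass")], row.names = FALSE)
  invisible(x)
}

.onLoad <- function(libname, pkgname) {
  # cheap import-time sanity check: shipped data must self-validate and the
  # reaction coefficients must balance C/H/O/N
  db <- tryCatch(thermo_db(), error = function(e) NULL)
  if (is.null(db)) {
    warning("entropicage: could not load shipped property database")
    return(invisible())
  }
  v <- check_consistency(db)
  bal <- element_balance_errors(db)
  if (length(v) || any(bal > 0.003)) {
    warning("entropicage: shipped property data failed self-validation: ",
            paste(c(v, names(bal)[bal > 0.003]), collapse = "; "))
  }
  invisible()
}

# relative element-balance error of each oxidation reaction, max over
# C, H, O, N (S excluded by design)
element_balance_errors <- function(db = default_thermo_db()) {
  rxs <- oxidation_reactions()
  vapply(rxs, function(rx) {
    count_side <- function(side) {
      tot <- c(C = 0, H = 0, O = 0, N = 0)
      for (nm in names(side)) {
        counts <- parse_formula(get_species(db, nm)$formula)
        counts <- counts[names(counts) != "S"]
        tot[names(counts)] <- tot[names(counts)] + side[[nm]] * counts
      }
      tot
    }
    lhs <- count_side(rx$reactants)
    rhs <- count_side(rx$products)
    denom <- pmax(lhs, 1e-12)
    max(abs(lhs - rhs) / denom)
  }, numeric(1))
}
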