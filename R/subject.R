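#' Subjects: anthropometrics and health state
#'
#' A subject carries the anthropometric inputs of the Harris-Benedict
#' equation plus the body-mass basis used to express specific entropy and
#' a health state selecting the macronutrient utilization profile.
#'
#' @param weight_kg body weight, kg (> 0).
#' @param height_cm height, cm (> 0).
#' @param age_years age, years (>= 0).
#' @param health_state one of `"healthy"`, `"childpugh_A"`, `"childpugh_B"`,
#'   `"childpugh_C"`.
#' @param mass_basis_kg body mass used as the per-kg divisor of specific
#'   entropy; defaults to `weight_kg` and stays fixed for a scenario even
#'   when weight changes.
#' @return an object of class `ea_subject`.
#' @examples
#' s <- subject(66, 170, 50)
#' bmr_harris_benedict(s)
#' @export
subject <- function(weight_kg, height_cm, age_years,
                    health_state = c("healthy", "childpugh_A",
                                     "childpugh_B", "childpugh_C"),
                    mass_basis_kg = weight_kg) {
  health_state <- match.arg(health_state)
  stopifnot(is.numeric(weight_kg), weight_kg > 0,
            is.numeric(height_cm), height_cm > 0,
            is.numeric(age_years), age_years >= 0,
            is.numeric(mass_basis_kg), mass_basis_kg > 0)
  structure(list(weight_kg = weight_kg, height_cm = height_cm,
                 age_years = age_years, health_state = health_state,
                 mass_basis_kg = mass_basis_kg),
            class = "ea_subject")
}

#' @export
print.ea_subject <- function(x, ...) {
  cat(sprintf("<subject> %g kg, %g cm, %g y, %s (entropy basis %g kg)\n",
              x$weight_kg, x$height_cm, x$age_years, x$health_state,
              x$mass_basis_kg))
  invisible(x)
}

#' Basal metabolic rate (Harris-Benedict)
#'
#' BMR = 66.5 + 13.76 W + 5.003 H - 5.755 A, with W in kg, H in cm, A in
#' years; the result is kcal/day at full precision.  Use
#' [round_kcal()] for the conventional nearest-integer report.
#'
#' @param subj an [subject()] or a list with `weight_kg`, `height_cm`,
#'   `age_years`.
#' @return kcal/day, unrounded.
#' @export
bmr_harris_benedict <- function(subj) {
  66.5 + 13.76 * subj$weight_kg + 5.003 * subj$height_cm -
    5.755 * subj$age_years
}

#' Nearest-integer energy report
#'
#' @param kcal energy in kcal/day.
#' @return nearest integer.
#' @export
round_kcal <- function(kcal) round(kcal)

#' Daily caloric need
#'
#' BMR scaled by the activity multiplier (default 1.2).
#'
#' @inheritParams bmr_harris_benedict
#' @param db a [thermo_db()]; supplies `caloric_need_multiplier`.
#' @param multiplier overrides the database multiplier when given.
#' @return kcal/day, unrounded.
#' @export
daily_caloric_need <- function(subj, db = default_thermo_db(),
                               multiplier = NULL) {
  m <- if (is.null(multiplier)) db$constants$caloric_need_multiplier else multiplier
  bmr_harris_benedict(subj) * m
}

#' Convert kcal/day to kJ/day
#'
#' 1 kcal = 4.184 kJ everywhere in the package.
#'
#' @param kcal energy in kcal.
#' @return energy in kJ.
#' @export
kcal_to_kJ <- function(kcal) kcal * 4.184

#' Read a subject from a JSON or YAML file
#'
#' Expected keys: `weight_kg`, `height_cm`, `age_years`, optional
#' `health_state` and `mass_basis_kg`.
#'
#' @param path file path (`.json`, `.yml` or `.yaml`).
#' @return an `ea_subject`.
#' @export
read_subject <- function(path) {
  if (!file.exists(path)) stop("subject file not found: ", path)
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  for (k in c("weight_kg", "height_cm", "age_years")) {
    if (is.null(x[[k]])) stop("subject file missing field '", k, "'")
  }
  subject(x$weight_kg, x$height_cm, x$age_years,
          health_state = if (is.null(x$health_state)) "healthy" else x$health_state,
          mass_basis_kg = if (is.null(x$mass_basis_kg)) x$weight_kg else x$mass_basis_kg)
}
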