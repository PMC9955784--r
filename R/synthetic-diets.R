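#' Generate guideline-constrained synthetic diet plans
#'
#' Emulates the structure of daily diet tables: a calorie target is split
#' across macronutrients by calorie fractions and converted to grams with
#' Atwater factors (4 kcal/g carbohydrate and protein, 9 kcal/g fat).
#' Optional multiplicative lognormal noise (unit mean, coefficient of
#' variation `noise_cv`) perturbs each macronutrient independently, so
#' masses stay positive.  By default the split must lie inside the adult
#' dietary-guideline envelope: 45-65% of calories from carbohydrate,
#' 10-35% from protein, 20-35% from fat.
#'
#' @param n number of diets.
#' @param kcal_target kcal/day (guideline adult intakes span roughly
#'   1800-3000 kcal/day).
#' @param macro_split named calorie fractions (`carbohydrate`, `protein`,
#'   `fat`) summing to 1.
#' @param noise_cv coefficient of variation of the per-macronutrient noise
#'   (0 = deterministic).
#' @param seed optional integer; same seed, same diets.  The global RNG
#'   state is restored afterwards.
#' @param enforce_guidelines set `FALSE` to allow splits outside the
#'   guideline envelope.
#' @return data.frame with columns `name`, `kcal` (recomputed from the
#'   generated grams), `carbohydrate_g`, `protein_g`, `fat_g`.
#' @examples
#' generate_diets(3, kcal_target = 2400, noise_cv = 0.05, seed = 1)
#' @export
generate_diets <- function(n = 1,
                           kcal_target = 2400,
                           macro_split = c(carbohydrate = 0.55,
                                           protein = 0.17, fat = 0.28),
                           noise_cv = 0.05,
                           seed = NULL,
                           enforce_guidelines = TRUE) {
  stopifnot(n >= 1, kcal_target > 0, noise_cv >= 0)
  req <- c("carbohydrate", "protein", "fat")
  if (!all(req %in% names(macro_split))) {
    stop("macro_split must name carbohydrate, protein and fat fractions")
  }
  macro_split <- macro_split[req]
  if (abs(sum(macro_split) - 1) > 1e-9) {
    stop("infeasible macro_split: fractions sum to ",
         format(sum(macro_split)), ", not 1")
  }
  if (any(macro_split < 0)) stop("infeasible macro_split: negative fraction")
  if (enforce_guidelines) {
    env <- list(carbohydrate = c(0.45, 0.65), protein = c(0.10, 0.35),
                fat = c(0.20, 0.35))
    for (m in req) {
      if (macro_split[[m]] < env[[m]][1] || macro_split[[m]] > env[[m]][2]) {
        stop("macro_split[", m, "] = ", macro_split[[m]],
             " outside the guideline envelope [", env[[m]][1], ", ",
             env[[m]][2], "]; pass enforce_guidelines = FALSE to override")
      }
    }
  }

  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old_seed, envir = globalenv())
      }
    })
    set.seed(seed)
  }

  atwater <- c(carbohydrate = 4, protein = 4, fat = 9)
  base_g <- kcal_target * macro_split / atwater[req]
  # lognormal with unit mean: sdlog^2 = log(1 + cv^2), meanlog = -sdlog^2/2
  sdlog <- sqrt(log(1 + noise_cv^2))
  grams <- t(vapply(seq_len(n), function(i) {
    if (noise_cv == 0) return(unname(base_g))
    unname(base_g) * stats::rlnorm(3, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }, numeric(3)))
  colnames(grams) <- req
  data.frame(
    name = sprintf("synthetic_%03d", seq_len(n)),
    kcal = as.vector(grams %*% atwater[req]),
    carbohydrate_g = grams[, "carbohydrate"],
    protein_g = grams[, "protein"],
    fat_g = grams[, "fat"],
    stringsAsFactors = FALSE
  )
}

#' Preset subjects for the bundled scenarios
#'
#' `"if_25"` and `"if_50"`: 80 kg, 170 cm intermittent-fasting subjects
#' aged 25 and 50 (overweight: BMI 80/1.70^2 = 27.7 kg/m2).
#' `"nafld_obese"`: a 100 kg obese subject (BMI > 30) at the
#' disease-onset age of 40; height defaults to 170 cm.
#'
#' @param preset one of `"if_25"`, `"if_50"`, `"nafld_obese"`.
#' @return an [subject()].
#' @export
generate_subject <- function(preset = c("if_25", "if_50", "nafld_obese")) {
  preset <- match.arg(preset)
  switch(preset,
         if_25 = subject(80, 170, 25),
         if_50 = subject(80, 170, 50),
         nafld_obese = subject(100, 170, 40))
}
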