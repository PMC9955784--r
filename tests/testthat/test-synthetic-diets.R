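test_that("noise-free generation is deterministic calorie arithmetic", {
  g <- generate_diets(2, kcal_target = 2400,
                      macro_split = c(carbohydrate = 0.55, protein = 0.17,
                                      fat = 0.28),
                      noise_cv = 0)
  expect_equal(g[1, -1], g[2, -1], ignore_attr = TRUE)
  expect_equal(g$carbohydrate_g[1], 2400 * 0.55 / 4)
  expect_equal(g$protein_g[1], 2400 * 0.17 / 4)
  expect_equal(g$fat_g[1], 2400 * 0.28 / 9)
  expect_equal(g$kcal[1], 2400)
})

test_that("the split back-computed from the obese plan regenerates it", {
  # 430/150/98 g at Atwater 4/4/9 -> calorie fractions of a 3202 kcal plan
  kc <- c(430 * 4, 150 * 4, 98 * 9)
  split <- setNames(kc / sum(kc), c("carbohydrate", "protein", "fat"))
  g <- generate_diets(1, kcal_target = 3100, macro_split = split,
                      noise_cv = 0)
  expect_equal(g$carbohydrate_g, 430, tolerance = 0.05)
  expect_equal(g$protein_g, 150, tolerance = 0.05)
  expect_equal(g$fat_g, 98, tolerance = 0.05)
})

test_that("generation is reproducible under a seed and restores the RNG", {
  a <- generate_diets(5, noise_cv = 0.1, seed = 7)
  set.seed(123)
  before <- runif(1)
  b <- generate_diets(5, noise_cv = 0.1, seed = 7)
  set.seed(123)
  expect_equal(runif(1), before)  # global RNG untouched by seeded call
  expect_identical(a, b)
  c <- generate_diets(5, noise_cv = 0.1, seed = 8)
  expect_false(identical(a$carbohydrate_g, c$carbohydrate_g))
})

test_that("generated diets satisfy diet invariants and calorie consistency", {
  g <- generate_diets(50, kcal_target = 2000, noise_cv = 0.15, seed = 11)
  expect_true(all(g$carbohydrate_g > 0 & g$protein_g > 0 & g$fat_g > 0))
  expect_equal(g$kcal,
               4 * g$carbohydrate_g + 4 * g$protein_g + 9 * g$fat_g)
  for (i in seq_len(nrow(g))) expect_s3_class(as_diet(g[i, ]), "ea_diet")
})

test_that("noisy means converge to the noise-free grams (3 SE)", {
  n <- 1000
  cv <- 0.1
  g <- generate_diets(n, kcal_target = 2400, noise_cv = cv, seed = 99)
  base <- c(2400 * 0.55 / 4, 2400 * 0.17 / 4, 2400 * 0.28 / 9)
  got <- c(mean(g$carbohydrate_g), mean(g$protein_g), mean(g$fat_g))
  se <- base * cv / sqrt(n)
  expect_true(all(abs(got - base) <= 3 * se))
})

test_that("infeasible or off-guideline splits raise explicit errors", {
  expect_error(generate_diets(1, macro_split = c(carbohydrate = 0.5,
                                                 protein = 0.2, fat = 0.2)),
               "infeasible")
  expect_error(generate_diets(1, macro_split = c(carbohydrate = 0.70,
                                                 protein = 0.10, fat = 0.20)),
               "guideline")
  # same split allowed when guidelines are explicitly relaxed
  g <- generate_diets(1, macro_split = c(carbohydrate = 0.70, protein = 0.10,
                                         fat = 0.20),
                      noise_cv = 0, enforce_guidelines = FALSE)
  expect_equal(g$carbohydrate_g, 2400 * 0.70 / 4)
})

test_that("subject presets carry the study anthropometrics", {
  s25 <- generate_subject("if_25")
  expect_equal(c(s25$weight_kg, s25$height_cm, s25$age_years), c(80, 170, 25))
  expect_equal(s25$weight_kg / (s25$height_cm / 100)^2, 27.7, tolerance = 0.01)
  expect_equal(generate_subject("if_50")$age_years, 50)
  ob <- generate_subject("nafld_obese")
  expect_equal(ob$weight_kg, 100)
  expect_gt(ob$weight_kg / (ob$height_cm / 100)^2, 30)
  expect_error(generate_subject("if_75"))
})
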