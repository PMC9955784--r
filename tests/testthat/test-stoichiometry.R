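test_that("oxidized masses are the component-wise diet x profile product", {
  expect_equal(oxidized_masses(diet(0, 150, 0), healthy)[["protein"]], 138)
  none <- utilization_profile(carbohydrate = 0, protein = 0, fat = 0)
  expect_equal(unname(oxidized_masses(diet(430, 150, 98), none)), c(0, 0, 0))
  ox <- oxidized_masses(diet(430, 150, 98), healthy)
  expect_equal(unname(ox), c(425.7, 138, 93.1))
})

test_that("fuel moles divide oxidized mass by the fuel molar mass", {
  fm <- fuel_moles(c(carbohydrate = 180, protein = 0, fat = 0), db)
  expect_equal(fm[["glucose"]], 1)
  fm <- fuel_moles(c(carbohydrate = 425.7, protein = 138, fat = 93.1), db)
  expect_equal(fm[["glucose"]], 425.7 / 180)
  expect_equal(fm[["amino"]], 138 / 119)
  expect_equal(fm[["palmitate"]], 93.1 / 256)
})

test_that("gas exchange reproduces the two anchor diets", {
  # 3100 kcal obese plan: 430/150/98 g -> 898 / 1081 / 428 g/day
  ex <- exchange_table(diet(430, 150, 98), healthy, db)
  expect_equal(round(ex$o2_g), 898)
  expect_equal(round(ex$co2_g), 1081)
  expect_equal(round(ex$h2o_g), 428)

  # 2210 kcal fasting plan: 318/99/59 g -> 613.2 / 296.6 / 748.4 g/day
  ex2 <- exchange_table(diet(318, 99, 59), healthy, db)
  expect_equal(ex2$o2_g, 613.2, tolerance = 0.2 / 613.2)
  expect_equal(ex2$h2o_g, 296.6, tolerance = 0.2 / 296.6)
  expect_equal(ex2$co2_g, 748.4, tolerance = 0.2 / 748.4)

  zero <- exchange_table(diet(0, 0, 0), healthy, db)
  expect_equal(unname(unlist(zero[-1])), rep(0, ncol(zero) - 1))
})

test_that("gas exchange is linear in the diet", {
  d1 <- exchange_table(diet(100, 40, 30), healthy, db)
  d2 <- exchange_table(diet(200, 80, 60), healthy, db)
  num <- vapply(d1, is.numeric, logical(1))
  expect_equal(unname(unlist(d2[num])), 2 * unname(unlist(d1[num])))
  # additivity across separate macronutrients
  parts <- exchange_table(diet(100, 0, 0), healthy, db)$o2_g +
    exchange_table(diet(0, 40, 0), healthy, db)$o2_g +
    exchange_table(diet(0, 0, 30), healthy, db)$o2_g
  expect_equal(parts, d1$o2_g)
})

test_that("gas exchange matches the atom-balance oracle on random diets", {
  set.seed(42)
  for (i in 1:100) {
    d <- diet(runif(1, 0, 500), runif(1, 0, 200), runif(1, 0, 150))
    p <- utilization_profile(carbohydrate = runif(1), protein = runif(1),
                             fat = runif(1))
    got <- gas_exchange(fuel_moles(oxidized_masses(d, p), db), db)
    want <- oracle_gas_exchange(d, p, db)
    expect_equal(got$mol, want$mol, tolerance = 1e-12)
    expect_equal(got$g, want$g, tolerance = 1e-12)
  }
})

test_that("urine model dissolves 65% of urea at 20 g/L", {
  expect_equal(unname(urine_mass(0, db)), c(0, 0))
  # constructed so the constants cancel: exactly one litre
  u <- urine_mass(20 / 0.65, db)
  expect_equal(u[["urine_g"]], 1000)
  # obese-plan urea production of 44.18 g/day gives about 1436 g urine
  ex <- exchange_table(diet(430, 150, 98), healthy, db)
  expect_equal(ex$urine_g, 1436, tolerance = 1e-3)
  expect_lte(ex$urea_excreted_g, ex$urea_produced_g)
})

test_that("dry feces collect the non-utilized dry matter", {
  all_used <- utilization_profile(carbohydrate = 1, protein = 1, fat = 1)
  expect_equal(feces_mass(diet(430, 150, 98), all_used), 0)
  none <- utilization_profile(carbohydrate = 0, protein = 0, fat = 0)
  expect_equal(feces_mass(diet(430, 150, 98), none), 678)
  expect_equal(feces_mass(diet(430, 150, 98), healthy),
               430 * 0.01 + 150 * 0.08 + 98 * 0.05)
})

test_that("utilization profiles expose the shipped fractions", {
  expect_equal(unname(healthy), c(0.99, 0.92, 0.95))
  cpA <- utilization_profile("childpugh_A", db)
  expect_equal(unname(cpA), c(0.88, 0.28, 0.46))
  expect_equal(unname(utilization_profile("childpugh_B", db)),
               c(0.86, 0.31, 0.55))
  expect_equal(unname(utilization_profile("childpugh_C", db)),
               c(0.88, 0.24, 0.59))
  expect_error(utilization_profile("childpugh_D", db), "childpugh_D")
  expect_error(utilization_profile(carbohydrate = 1.2, protein = 0.5,
                                   fat = 0.5))
})

test_that("bundled diet tables carry the published plan compositions", {
  it <- if_diet_table()
  expect_equal(nrow(it), 6)
  expect_equal(it$carbohydrate_g[it$name == "maintain_25"], 318)
  nt <- nafld_diet_table()
  ho <- nt[nt$name == "healthy_obese", ]
  expect_equal(c(ho$carbohydrate_g, ho$protein_g, ho$fat_g), c(430, 150, 98))
  # every row is a valid diet
  for (i in seq_len(nrow(nt))) expect_s3_class(as_diet(nt[i, ]), "ea_diet")
})
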