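test_that("substrate partition reproduces hand-computed COD fluxes", {
  # zero intake stays zero
  zero <- partition_substrates(intake_row())
  expect_equal(zero$cod_total, 0)

  # hand arithmetic: ass = (100 - 10 - 20) * 1.185, rs = 10 * 1.185,
  # nsp = 20 * 1.185
  out <- partition_substrates(intake_row(cho_g = 100, fiber_g = 20, rs_g = 10))
  expect_equal(out$cod_ass, 82.95)
  expect_equal(out$cod_rs, 11.85)
  expect_equal(out$cod_nsp, 23.7)
  expect_equal(out$cod_protein, 0)
  expect_equal(out$cod_fat, 0)

  # the mean WD day lands in the stoichiometric band implied by measured
  # fecal COD and metabolizable energy (~698 gCOD/day)
  wd <- wd_substrates()
  expect_gt(wd$cod_total, 660)
  expect_lt(wd$cod_total, 720)
})

test_that("substrate partition rejects inconsistent macronutrient rows", {
  bad <- intake_row(cho_g = 25, fiber_g = 20, rs_g = 10)
  expect_error(partition_substrates(bad), "row\\(s\\) 1")
  expect_error(partition_substrates(intake_row(cho_g = -1)), "negative")
})

test_that("COD is additive across diets", {
  a <- random_intakes(8, seed = 3)
  b <- random_intakes(8, seed = 4)
  ab <- a
  for (col in c("cho_g", "fiber_g", "rs_g", "protein_g", "fat_g")) {
    ab[[col]] <- a[[col]] + b[[col]]
  }
  expect_equal(
    partition_substrates(ab)$cod_total,
    partition_substrates(a)$cod_total + partition_substrates(b)$cod_total
  )
})

test_that("host metabolizable energy matches the fecal/intake COD ratio", {
  expect_equal(host_me(100, 0), 100)
  # inversion of the arm means: fecal 32.1 and 73.0 gCOD/day on ~698 gCOD
  # intake
  expect_equal(host_me(698, 32.1), 95.4, tolerance = 0.001)
  expect_equal(host_me(698, 73.0), 89.5, tolerance = 0.002)
  expect_error(host_me(0, 10), "intake_cod")
  expect_error(host_me(100, -1), "fecal_cod")
})

test_that("host ME is decreasing in fecal COD and scale invariant", {
  fecal <- seq(0, 600, by = 25)
  me <- host_me(700, fecal)
  expect_true(all(diff(me) < 0))
  withr::with_seed(5, {
    intake <- runif(20, 100, 900)
    fec <- runif(20, 0, 1) * intake
    c <- runif(20, 0.1, 10)
    expect_equal(host_me(c * intake, c * fec), host_me(intake, fec))
  })
})

test_that("non-metabolizable kcal follows the ME percentage", {
  expect_equal(nonmetabolizable_kcal(100, 2000), 0)
  expect_equal(nonmetabolizable_kcal(89.5, 2113.6), 221.9, tolerance = 1e-3)
  expect_equal(nonmetabolizable_kcal(95.4, 2126), 97.8, tolerance = 1e-3)
  expect_error(nonmetabolizable_kcal(101, 100), "host_me_pct")
})

test_that("methane volume converts to combustion energy", {
  expect_equal(methane_energy(0), 0)
  # the printed volume range endpoints
  expect_equal(methane_energy(1613), 14, tolerance = 0.5 / 14)
  expect_equal(signif(methane_energy(0.28), 1), 0.002)
  # linearity and the 25 C molar volume anchor
  expect_equal(methane_energy(1000), 212.8 / 24450 * 1000, tolerance = 1e-9)
  expect_equal(methane_energy(c(1, 10, 100)), methane_energy(1) * c(1, 10, 100))
  expect_error(methane_energy(-1), "volume")
})

test_that("energy balance is intake minus expenditure", {
  expect_equal(energy_balance(2000, 2000), 0)
  expect_equal(energy_balance(2130.4, 2126.3), 4.1)
  expect_error(energy_balance(-1, 0), ">= 0")
})

test_that("kcal/COD interconversion round-trips exactly", {
  expect_equal(kcal_to_cod(0), 0)
  wd <- diet_templates()[1, ]
  f <- cod_kcal_factor(wd)
  expect_gt(f, 2.9)
  expect_lt(f, 3.3)
  withr::with_seed(6, kcal <- runif(25, 500, 4000))
  expect_equal(cod_to_kcal(kcal_to_cod(kcal)), kcal, tolerance = 1e-9)
  expect_equal(cod_to_kcal(kcal_to_cod(kcal, wd), wd), kcal, tolerance = 1e-9)
  bad <- wd
  bad$kcal <- 0
  expect_error(cod_kcal_factor(bad), "zero kcal")
})
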