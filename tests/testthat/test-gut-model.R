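test_that("upper GI absorption respects the digestibility fractions", {
  # complete digestion of a fiber-free, RS-free diet leaves the colon empty
  sub <- partition_substrates(intake_row(cho_g = 100, protein_g = 50,
                                         fat_g = 40))
  full <- gut_params(d_ass = 1, d_prot = 1, d_fat = 1)
  out <- upper_gi(sub, full)
  expect_equal(out$upper_absorbed, sub$cod_total)
  expect_equal(out$influent_ass + out$influent_rs + out$influent_nsp +
                 out$influent_protein + out$influent_fat, 0)

  none <- gut_params(d_ass = 0, d_prot = 0, d_fat = 0)
  out0 <- upper_gi(sub, none)
  expect_equal(out0$upper_absorbed, 0)
  expect_equal(out0$influent_ass, sub$cod_ass)

  # RS and NSP always pass to the colon in full
  wd <- upper_gi(wd_substrates(), gut_params())
  expect_equal(wd$influent_rs, wd_substrates()$cod_rs)
  expect_equal(wd$influent_nsp, wd_substrates()$cod_nsp)

  # mean WD colonic influent (including the endogenous input) sits in the
  # band implied by the fecal + SCFA + biomass ledger
  pred <- gut_predict(wd_substrates(), ctt_h = 48)
  expect_gt(pred$colon_influent, 40)
  expect_lt(pred$colon_influent, 70)
})

test_that("colonic fermentation follows first-order CSTR kinetics", {
  infl <- tibble::tibble(influent_ass = 0, influent_rs = 10, influent_nsp = 0,
                         influent_protein = 0, influent_fat = 0)
  p0 <- gut_params(k_rs = 0, e0 = 0)
  expect_equal(ferment(infl, p0, ctt_h = 48)$fermented_total, 0)

  # k * tau / (1 + k * tau): 0.05/h over 48 h ferments 70.6 % of the pool
  p <- gut_params(k_rs = 0.05, e0 = 0)
  expect_equal(ferment(infl, p, ctt_h = 48)$fermented_rs,
               0.05 * 48 / (1 + 0.05 * 48) * 10)
  expect_equal(ferment(infl, p, ctt_h = 48)$fermented_rs, 7.06,
               tolerance = 1e-3)

  # saturation: as k * tau grows the whole influent ferments
  psat <- gut_params(k_rs = 50, e0 = 0)
  expect_equal(ferment(infl, psat, ctt_h = 1e5)$fermented_rs, 10,
               tolerance = 1e-5)
})

test_that("CSTR and plug-flow idioms agree in the slow-kinetics limit", {
  infl <- tibble::tibble(influent_ass = 0, influent_rs = 10, influent_nsp = 0,
                         influent_protein = 0, influent_fat = 0)
  k <- 1e-5
  tau <- 10
  cstr <- ferment(infl, gut_params(k_rs = k, e0 = 0), ctt_h = tau)
  pf <- ferment(infl, gut_params(k_rs = k, e0 = 0, reactor = "plugflow"),
                ctt_h = tau)
  # both reduce to k * tau * influent when k * tau << 1
  expect_equal(cstr$fermented_rs, k * tau * 10, tolerance = 1e-3)
  expect_equal(pf$fermented_rs, k * tau * 10, tolerance = 1e-3)
  expect_equal(cstr$fermented_rs, pf$fermented_rs, tolerance = 1e-3)
})

test_that("fermented COD partitions exactly into biomass, SCFA and methane", {
  p <- gut_params(y_biomass = 0.25, f_ch4 = 0.01)
  expect_equal(unlist(partition_fermented(0, p)),
               c(biomass = 0, scfa_gross = 0, methane = 0))
  out <- partition_fermented(100, p)
  expect_equal(out$biomass, 25)
  expect_equal(out$scfa_gross, 74)
  expect_equal(out$methane, 1)
  withr::with_seed(4, {
    for (i in 1:10) {
      y <- runif(1, 0, 0.9)
      f <- runif(1, 0, 1 - y)
      pf <- gut_params(y_biomass = y, f_ch4 = f)
      tot <- runif(1, 0, 300)
      parts <- partition_fermented(tot, pf)
      expect_equal(parts$biomass + parts$scfa_gross + parts$methane, tot)
    }
  })
  expect_error(gut_params(y_biomass = 0.7, f_ch4 = 0.4), "exceed 1")
})

test_that("the electron balance closes for arbitrary diets and parameters", {
  diets <- partition_substrates(random_intakes(12, seed = 21))
  for (seed in 1:5) {
    p <- random_gut_params(seed)
    tau <- withr::with_seed(seed, runif(12, 6, 120))
    pred <- gut_predict(diets, p, ctt_h = tau)
    expect_lt(max(abs(pred$balance_residual)) /
                max(pred$intake_cod + p$e0), 1e-9)
    expect_true(all(pred[, c("upper_absorbed", "scfa_absorbed_total",
                             "biomass_fecal", "fecal_total",
                             "methane_cod")] >= 0))
    # the fecal partition sums to the fecal total
    expect_equal(pred$fecal_substrate + pred$biomass_fecal +
                   pred$fecal_scfa + pred$fecal_endogenous,
                 pred$fecal_total)
  }
})

test_that("predictions are homogeneous in substrates; ME is scale free", {
  sub <- mbd_substrates()
  scaled <- sub
  for (col in c("cod_ass", "cod_rs", "cod_nsp", "cod_protein", "cod_fat")) {
    scaled[[col]] <- sub[[col]] * 2.5
  }
  p <- gut_params(e0 = 0)
  a <- gut_predict(sub, p, ctt_h = 37)
  b <- gut_predict(scaled, p, ctt_h = 37)
  expect_equal(b$fecal_total, 2.5 * a$fecal_total)
  expect_equal(b$scfa_absorbed_total, 2.5 * a$scfa_absorbed_total)
  expect_equal(b$me_pct, a$me_pct)
})

test_that("with no colonic input, ME equals the digestibility-weighted mean", {
  sub <- partition_substrates(intake_row(cho_g = 100, protein_g = 50,
                                         fat_g = 40))
  p <- gut_params(e0 = 0)
  pred <- gut_predict(sub, p, ctt_h = 48)
  # zero fiber/RS, zero endogenous: feces carry only unfermented
  # malabsorbed substrate and unabsorbed SCFA; with d_* = 1 nothing enters
  # the colon at all
  full <- gut_params(d_ass = 1, d_prot = 1, d_fat = 1, e0 = 0)
  pred_full <- gut_predict(sub, full, ctt_h = 48)
  expect_equal(pred_full$me_pct, 100)
  weighted <- 100 * (p$d_ass * sub$cod_ass + p$d_prot * sub$cod_protein +
                       p$d_fat * sub$cod_fat) / sub$cod_total
  expect_equal(pred$upper_absorbed / sub$cod_total * 100, weighted)
})

test_that("endogenous ME limit: fully digestible diet leaves only e0 in feces", {
  sub <- partition_substrates(intake_row(cho_g = 200, protein_g = 80,
                                         fat_g = 70))
  p <- gut_params(d_ass = 1, d_prot = 1, d_fat = 1, k_nsp = 0, e0 = 20)
  pred <- gut_predict(sub, p, ctt_h = 48)
  expect_equal(pred$fecal_total, 20)
  expect_equal(pred$me_pct, 100 * (1 - 20 / sub$cod_total))
})

test_that("the fast scalar core agrees with the tibble pipeline", {
  sub <- mbd_substrates()
  p <- random_gut_params(31)
  fast <- gutcod:::.predict_core(
    p, c(ass = sub$cod_ass, rs = sub$cod_rs, nsp = sub$cod_nsp,
         protein = sub$cod_protein, fat = sub$cod_fat), 33.3
  )
  slow <- gut_predict(sub, p, ctt_h = 33.3)
  for (q in c("me_pct", "scfa_absorbed_total", "biomass_fecal",
              "fecal_total", "methane_cod")) {
    expect_equal(fast[[q]], slow[[q]])
  }
})

test_that("transit-time sensitivity spans the observed ME variability", {
  sub <- mbd_substrates()
  single <- sensitivity_ctt(sub, ctt_grid = 48)
  expect_equal(single$me_pct, gut_predict(sub, ctt_h = 48)$me_pct)

  grid <- seq(16, 72, by = 2)
  sens <- sensitivity_ctt(sub, ctt_grid = grid)
  expect_equal(nrow(sens), length(grid))
  # residence time is the dominant driver of MBD ME spread
  expect_gte(diff(range(sens$me_pct)), 4)
  # longer residence never decreases SCFA uptake
  expect_true(all(diff(sens$scfa_absorbed_total) >= 0))
  expect_lt(max(abs(sens$balance_residual)), 1e-9 * max(sens$intake_cod))
  expect_error(sensitivity_ctt(sub, ctt_grid = c(0, 48)), "> 0")
})

test_that("calibration recovers a self-generated target set", {
  diets <- list(WD = wd_substrates(), MBD = mbd_substrates())
  truth <- gut_params()
  targets <- tibble::tibble(
    diet = c("WD", "MBD", "WD", "MBD", "WD", "MBD"),
    ctt_h = c(48, 48, 39.2, 29.7, 39.2, 29.7),
    quantity = rep(c("me_pct", "scfa_absorbed_total", "biomass_fecal"),
                   each = 2)
  )
  targets$value <- gutcod:::.cal_predict_targets(truth, diets, targets)

  # start away from the truth; the fit must reproduce every target closely
  p0 <- gut_params(d_ass = 0.97, d_fat = 0.92, k_rs = 0.06, k_nsp = 0.05,
                   k_prot = 0.05, k_fat = 0.01, y_biomass = 0.25)
  fit <- calibrate_gut_model(diets, targets, p0 = p0,
                             free = c("d_ass", "d_fat", "k_rs", "k_nsp",
                                      "k_prot", "k_fat", "y_biomass"),
                             maxit = 5000, restarts = 2, tol = 1e-6)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$fitted$rel_error)), 1e-3)
  # identifiable directions: the yield split is pinned by the
  # biomass-to-SCFA ratio
  expect_equal(fit$params$y_biomass, truth$y_biomass, tolerance = 0.01)
})

test_that("calibration warns and returns best params on a starved budget", {
  diets <- list(WD = wd_substrates())
  targets <- tibble::tibble(diet = "WD", ctt_h = 48, quantity = "me_pct",
                            value = 80)
  expect_warning(
    fit <- calibrate_gut_model(diets, targets, maxit = 2, restarts = 0,
                               tol = 1e-12),
    "best-found"
  )
  expect_s3_class(fit$params, "gut_params")
  expect_false(fit$converged)
})
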