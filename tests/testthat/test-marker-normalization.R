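composite_row <- function(total_weight_g = 600, days = 6,
                          cod_conc_g_per_g = 0.3, peg_g_total = 9,
                          acetate_mg_g = 0, propionate_mg_g = 0,
                          butyrate_mg_g = 0) {
  tibble::tibble(
    total_weight_g = total_weight_g, days = days,
    cod_conc_g_per_g = cod_conc_g_per_g, peg_g_total = peg_g_total,
    acetate_mg_g = acetate_mg_g, propionate_mg_g = propionate_mg_g,
    butyrate_mg_g = butyrate_mg_g
  )
}

test_that("PEG recovery is recovered dose over administered dose", {
  expect_equal(peg_recovery(composite_row(peg_g_total = 9))$recovery, 1)
  expect_equal(peg_recovery(composite_row(peg_g_total = 7.2))$recovery, 0.8)
})

test_that("unusable and out-of-band PEG recoveries are flagged, not dropped", {
  expect_warning(peg_recovery(composite_row(peg_g_total = 0)), "unusable")
  out <- suppressWarnings(peg_recovery(composite_row(peg_g_total = 0)))
  expect_equal(nrow(out), 1)
  expect_true(is.na(out$recovery))
  expect_true(out$recovery_flag)

  expect_warning(peg_recovery(composite_row(peg_g_total = 18)), "outside")
  high <- suppressWarnings(peg_recovery(composite_row(peg_g_total = 18)))
  expect_equal(high$recovery, 2) # retained
  expect_true(high$recovery_flag)
})

test_that("daily fecal COD matches the composite arithmetic", {
  out <- composite_row(total_weight_g = 642) |>
    peg_recovery() |>
    daily_fecal_cod()
  expect_equal(out$fecal_cod_g_day, 32.1)

  # halving recovery doubles the daily estimate
  half <- composite_row(total_weight_g = 642, peg_g_total = 4.5) |>
    peg_recovery() |>
    daily_fecal_cod()
  expect_equal(half$fecal_cod_g_day, 2 * 32.1)

  zero <- composite_row(total_weight_g = 0) |>
    peg_recovery() |>
    daily_fecal_cod()
  expect_equal(zero$fecal_cod_g_day, 0)
})

test_that("daily SCFA outputs scale per species and sum to the total", {
  out <- composite_row(acetate_mg_g = 1, propionate_mg_g = 2,
                       butyrate_mg_g = 3) |>
    normalize_fecal()
  expect_equal(out$acetate_mg_day, 100)
  expect_equal(out$propionate_mg_day, 200)
  expect_equal(out$butyrate_mg_day, 300)
  expect_equal(out$scfa_total_mg_day, 600)

  withr::with_seed(9, {
    rnd <- composite_row(
      total_weight_g = runif(10, 100, 1500),
      peg_g_total = runif(10, 5, 12),
      acetate_mg_g = runif(10, 0, 5), propionate_mg_g = runif(10, 0, 5),
      butyrate_mg_g = runif(10, 0, 5)
    ) |>
      normalize_fecal()
    expect_equal(rnd$scfa_total_mg_day,
                 rnd$acetate_mg_day + rnd$propionate_mg_day +
                   rnd$butyrate_mg_day)
  })
})

test_that("normalization is homogeneous and conserves composite totals", {
  base <- composite_row(total_weight_g = 800, peg_g_total = 8,
                        acetate_mg_g = 2)
  scaled <- base
  # scaling all composite masses and PEG by c leaves daily outputs unchanged
  # (concentrations are per gram, so they do not scale)
  c <- 3.7
  scaled$total_weight_g <- base$total_weight_g * c
  scaled$peg_g_total <- base$peg_g_total * c
  a <- normalize_fecal(base)
  b <- suppressWarnings(normalize_fecal(scaled)) # recovery scaled out of band
  expect_equal(b$fecal_cod_g_day, a$fecal_cod_g_day)
  expect_equal(b$acetate_mg_day, a$acetate_mg_day)

  # conservation: daily value x days x recovery = composite total
  expect_equal(a$fecal_cod_g_day * a$days * a$recovery,
               a$cod_conc_g_per_g * a$total_weight_g)
})

test_that("the PEG protocol ties daily dose to capsule dosing", {
  p <- peg_protocol()
  expect_equal(p$dose_g_per_day, 1.5)
  expect_equal(p$dose_g_per_day,
               p$capsule_g * p$capsules_per_meal * p$meals_per_day)
})
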