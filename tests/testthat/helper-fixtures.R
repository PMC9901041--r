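# small builders shared across test files

intake_row <- function(cho_g = 0, fiber_g = 0, rs_g = 0, protein_g = 0,
                       fat_g = 0, kcal = 0, ...) {
  tibble::tibble(kcal = kcal, cho_g = cho_g, fiber_g = fiber_g, rs_g = rs_g,
                 protein_g = protein_g, fat_g = fat_g, ...)
}

random_intakes <- function(n, seed = 7L) {
  withr::with_seed(seed, {
    cho <- runif(n, 50, 400)
    fiber <- runif(n, 0, 0.2) * cho
    rs <- runif(n, 0, 0.1) * cho
    tibble::tibble(
      kcal = runif(n, 1200, 3200), cho_g = cho, fiber_g = fiber, rs_g = rs,
      protein_g = runif(n, 30, 150), fat_g = runif(n, 20, 140)
    )
  })
}

random_gut_params <- function(seed = 11L) {
  withr::with_seed(seed, gut_params(
    d_ass = runif(1, 0.8, 1), d_prot = runif(1, 0.7, 1),
    d_fat = runif(1, 0.8, 1),
    k_rs = runif(1, 0, 0.3), k_nsp = runif(1, 0, 0.2),
    k_prot = runif(1, 0, 0.2), k_fat = runif(1, 0, 0.05),
    y_biomass = runif(1, 0.05, 0.4), f_ch4 = runif(1, 0, 0.1),
    a_scfa = runif(1, 0.5, 1), e0 = runif(1, 0, 40)
  ))
}

wd_substrates <- function() {
  partition_substrates(diet_templates()[diet_templates()$diet == "WD", ])
}

mbd_substrates <- function() {
  partition_substrates(diet_templates()[diet_templates()$diet == "MBD", ])
}

# a cohort object with empty tables but intact schemas
empty_cohort <- function() {
  co <- generate_cohort(cohort_config(n = 2, seed = 1))
  for (tb in c("intake", "fecal", "qpcr", "ctt", "methane", "ee", "truth")) {
    co[[tb]] <- co[[tb]][0, ]
  }
  co
}
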