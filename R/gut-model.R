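.substrate_cols <- c("cod_ass", "cod_rs", "cod_nsp", "cod_protein", "cod_fat")

#' Parameters of the three-compartment gut model
#'
#' The model tracks dietary electron equivalents through (i) the upper
#' gastrointestinal tract, where fractions `d_ass`, `d_prot`, `d_fat` of
#' available sugar/starch, protein and fat are absorbed by the host while
#' resistant starch and non-starch polysaccharides pass through entirely;
#' (ii) the colon, treated as a steady-state continuously stirred tank
#' reactor with residence time equal to the colonic transit time, where each
#' substrate class ferments with first-order rate constant `k_*` (extent
#' `k*tau / (1 + k*tau)`); and (iii) the host body, which absorbs a fraction
#' `a_scfa` of the short-chain fatty acids produced. Fermented COD splits
#' into microbial biomass (`y_biomass`), methane (`f_ch4`) and SCFA (the
#' remainder); `e0` is the endogenous colonic COD input (mucins, sloughed
#' epithelium), fermentable at the `k_nsp` rate, present in feces but not in
#' dietary intake. `scfa_split` partitions SCFA COD among acetate,
#' propionate, n-butyrate and iso-butyrate.
#'
#' The shipped defaults are the calibrated set reproducing the six benchmark
#' model outputs for the two study diets (fixed-transit metabolizable energy,
#' SCFA uptake and fecal biomass at the arm-mean measured transit times); see
#' the methods vignette and [calibrate_gut_model()].
#'
#' @param d_ass,d_prot,d_fat upper-GI absorption fractions, in \[0, 1\].
#' @param k_rs,k_nsp,k_prot,k_fat colonic fermentation rate constants, 1/h.
#' @param y_biomass fraction of fermented COD incorporated into biomass.
#' @param f_ch4 fraction of fermented COD released as methane.
#' @param a_scfa fraction of SCFA COD absorbed by the host.
#' @param e0 endogenous colonic COD input, gCOD/day.
#' @param scfa_split named fractions (acetate, propionate, butyrate,
#'   isobutyrate) summing to 1.
#' @param reactor colonic reactor idiom: `"cstr"` (closed-form steady state,
#'   default) or `"plugflow"` (extent `1 - exp(-k*tau)`).
#' @return object of class `gut_params`.
#' @examples
#' gut_params()
#' @export
gut_params <- function(d_ass = 0.99635,
                       d_prot = 0.91,
                       d_fat = 0.94531,
                       k_rs = 0.14595,
                       k_nsp = 0.08443,
                       k_prot = 0.03117,
                       k_fat = 0.02484,
                       y_biomass = 0.19871,
                       f_ch4 = 0.01068,
                       a_scfa = 0.95,
                       e0 = 25,
                       scfa_split = c(acetate = 0.60, propionate = 0.20,
                                      butyrate = 0.15, isobutyrate = 0.05),
                       reactor = c("cstr", "plugflow")) {
  reactor <- match.arg(reactor)
  fracs <- c(d_ass = d_ass, d_prot = d_prot, d_fat = d_fat,
             y_biomass = y_biomass, f_ch4 = f_ch4, a_scfa = a_scfa)
  if (any(fracs < 0 | fracs > 1)) {
    abort("gut_params(): all fractions must lie in [0, 1]")
  }
  if (y_biomass + f_ch4 > 1) {
    abort("gut_params(): y_biomass + f_ch4 must not exceed 1")
  }
  rates <- c(k_rs = k_rs, k_nsp = k_nsp, k_prot = k_prot, k_fat = k_fat)
  if (any(rates < 0)) {
    abort("gut_params(): rate constants must be >= 0")
  }
  if (e0 < 0) {
    abort("gut_params(): e0 must be >= 0")
  }
  need <- c("acetate", "propionate", "butyrate", "isobutyrate")
  if (!setequal(names(scfa_split), need) ||
      abs(sum(scfa_split) - 1) > 1e-8 || any(scfa_split < 0)) {
    abort("gut_params(): scfa_split must be nonnegative fractions over acetate/propionate/butyrate/isobutyrate summing to 1")
  }
  structure(
    list(d_ass = d_ass, d_prot = d_prot, d_fat = d_fat,
         k_rs = k_rs, k_nsp = k_nsp, k_prot = k_prot, k_fat = k_fat,
         y_biomass = y_biomass, f_ch4 = f_ch4, a_scfa = a_scfa, e0 = e0,
         scfa_split = scfa_split[need], reactor = reactor),
    class = "gut_params"
  )
}

#' @export
print.gut_params <- function(x, ...) {
  cat("<gut_params> (", x$reactor, "colon )\n")
  cat("  upper-GI digestibility: ass", signif(x$d_ass, 4),
      "| protein", signif(x$d_prot, 4), "| fat", signif(x$d_fat, 4), "\n")
  cat("  fermentation k (1/h): rs", signif(x$k_rs, 4),
      "| nsp", signif(x$k_nsp, 4), "| protein", signif(x$k_prot, 4),
      "| fat", signif(x$k_fat, 4), "\n")
  cat("  yields: biomass", signif(x$y_biomass, 4),
      "| methane", signif(x$f_ch4, 4),
      "| SCFA absorbed", signif(x$a_scfa, 4),
      "| endogenous", signif(x$e0, 4), "gCOD/day\n")
  invisible(x)
}

# Fast scalar core of the model, used by the calibrator's inner loop.
# `sub` is a named numeric vector (ass, rs, nsp, protein, fat) in gCOD/day;
# returns the headline fluxes. Must agree with gut_predict() exactly
# (covered by a consistency test).
.predict_core <- function(params, sub, tau) {
  ext <- function(k) .ferment_extent(k, tau, params$reactor)
  infl <- c(
    ass = (1 - params$d_ass) * sub[["ass"]],
    rs = sub[["rs"]],
    nsp = sub[["nsp"]],
    protein = (1 - params$d_prot) * sub[["protein"]],
    fat = (1 - params$d_fat) * sub[["fat"]]
  )
  ferm <- infl[["ass"]] * ext(params$k_rs) + infl[["rs"]] * ext(params$k_rs) +
    infl[["nsp"]] * ext(params$k_nsp) +
    infl[["protein"]] * ext(params$k_prot) +
    infl[["fat"]] * ext(params$k_fat)
  ferm_e0 <- params$e0 * ext(params$k_nsp)
  total_ferm <- ferm + ferm_e0
  biomass <- params$y_biomass * total_ferm
  scfa_gross <- (1 - params$y_biomass - params$f_ch4) * total_ferm
  intake <- sum(sub)
  fecal <- (sum(infl) - ferm) + biomass + (1 - params$a_scfa) * scfa_gross +
    (params$e0 - ferm_e0)
  list(
    me_pct = 100 * (intake - fecal) / intake,
    scfa_absorbed_total = params$a_scfa * scfa_gross,
    biomass_fecal = biomass,
    fecal_total = fecal,
    methane_cod = params$f_ch4 * total_ferm
  )
}

.check_substrates <- function(data) {
  miss <- setdiff(.substrate_cols, names(data))
  if (length(miss) > 0) {
    abort(paste0("expected substrate columns (run partition_substrates()): ",
                 paste(miss, collapse = ", ")))
  }
  invisible(data)
}

.ferment_extent <- function(k, tau, reactor) {
  kt <- k * tau
  if (reactor == "plugflow") 1 - exp(-kt) else kt / (1 + kt)
}

#' Upper gastrointestinal digestion and absorption
#'
#' Host absorption of available sugar and starch, protein and fat in the
#' small intestine; resistant starch and non-starch polysaccharides pass to
#' the colon entirely.
#'
#' @param data data frame with substrate columns from
#'   [partition_substrates()].
#' @param params a [gut_params()] object.
#' @return `data` with added `upper_absorbed` (gCOD/day) and colonic
#'   influent columns `influent_ass`, `influent_rs`, `influent_nsp`,
#'   `influent_protein`, `influent_fat`.
#' @export
upper_gi <- function(data, params = gut_params()) {
  .check_substrates(data)
  dplyr::mutate(
    tibble::as_tibble(data),
    upper_absorbed = params$d_ass * .data$cod_ass +
      params$d_prot * .data$cod_protein + params$d_fat * .data$cod_fat,
    influent_ass = (1 - params$d_ass) * .data$cod_ass,
    influent_rs = .data$cod_rs,
    influent_nsp = .data$cod_nsp,
    influent_protein = (1 - params$d_prot) * .data$cod_protein,
    influent_fat = (1 - params$d_fat) * .data$cod_fat
  )
}

#' Colonic fermentation of the influent substrate classes
#'
#' Steady-state first-order conversion over the colonic residence time:
#' class `i` ferments to extent `k_i * tau / (1 + k_i * tau)` (CSTR idiom;
#' `1 - exp(-k_i * tau)` under the plug-flow option). The endogenous input
#' `e0` ferments at the `k_nsp` rate.
#'
#' @param data data frame with `influent_*` columns from [upper_gi()] and a
#'   `ctt_h` column, or supply `ctt_h` directly.
#' @param params a [gut_params()] object.
#' @param ctt_h optional colonic transit time (hours, > 0) overriding the
#'   column.
#' @return `data` with added `fermented_ass/rs/nsp/protein/fat`,
#'   `fermented_endogenous` and `fermented_total` (gCOD/day).
#' @export
ferment <- function(data, params = gut_params(), ctt_h = NULL) {
  data <- tibble::as_tibble(data)
  if (!is.null(ctt_h)) {
    if (nrow(data) == 1 && length(ctt_h) > 1) {
      data <- data[rep(1L, length(ctt_h)), ]
    }
    data$ctt_h <- ctt_h
  }
  if (!"ctt_h" %in% names(data)) {
    abort("ferment(): provide a ctt_h column or the ctt_h argument")
  }
  if (any(data$ctt_h <= 0, na.rm = TRUE)) {
    abort("ferment(): colonic transit time must be > 0")
  }
  tau <- data$ctt_h
  k <- c(ass = params$k_rs, rs = params$k_rs, nsp = params$k_nsp,
         protein = params$k_prot, fat = params$k_fat)
  # malabsorbed sugar/starch is as fermentable as resistant starch
  out <- dplyr::mutate(
    data,
    fermented_ass = .data$influent_ass *
      .ferment_extent(k[["ass"]], tau, params$reactor),
    fermented_rs = .data$influent_rs *
      .ferment_extent(k[["rs"]], tau, params$reactor),
    fermented_nsp = .data$influent_nsp *
      .ferment_extent(k[["nsp"]], tau, params$reactor),
    fermented_protein = .data$influent_protein *
      .ferment_extent(k[["protein"]], tau, params$reactor),
    fermented_fat = .data$influent_fat *
      .ferment_extent(k[["fat"]], tau, params$reactor),
    fermented_endogenous = params$e0 *
      .ferment_extent(params$k_nsp, tau, params$reactor),
    fermented_total = .data$fermented_ass + .data$fermented_rs +
      .data$fermented_nsp + .data$fermented_protein + .data$fermented_fat +
      .data$fermented_endogenous
  )
  out
}

#' Partition fermented COD into biomass, SCFA and methane
#'
#' Electron balance of fermentation: of each fermented gram COD, `y_biomass`
#' is assimilated into microbial cells, `f_ch4` leaves as methane, and the
#' remainder appears as gross SCFA. The three parts sum to the input exactly.
#'
#' @param fermented_total fermented COD, gCOD/day (vectorized).
#' @param params a [gut_params()] object.
#' @return tibble with columns `biomass`, `scfa_gross`, `methane` (gCOD/day).
#' @examples
#' partition_fermented(100)
#' @export
partition_fermented <- function(fermented_total, params = gut_params()) {
  if (any(fermented_total < 0, na.rm = TRUE)) {
    abort("partition_fermented(): fermented_total must be >= 0")
  }
  tibble::tibble(
    biomass = params$y_biomass * fermented_total,
    scfa_gross = (1 - params$y_biomass - params$f_ch4) * fermented_total,
    methane = params$f_ch4 * fermented_total
  )
}

#' Predict host metabolizable energy and colonic fluxes for a diet
#'
#' Runs the full three-compartment model: upper-GI digestion, colonic
#' fermentation over the transit time, fermentation partitioning, SCFA
#' absorption, and the fecal ledger. Metabolizable energy is defined against
#' dietary intake only (`me_pct = 100 * (intake - fecal_total) / intake`),
#' while feces also carry the unfermented endogenous residual, mirroring how
#' the measurement is made. Every prediction satisfies the COD balance
#' `intake + e0 = upper_absorbed + scfa_absorbed + fecal_total + methane`
#' to floating-point accuracy (`balance_residual`).
#'
#' @param data data frame with substrate columns from
#'   [partition_substrates()] and a `ctt_h` column (hours), unless `ctt_h`
#'   is supplied.
#' @param params a [gut_params()] object.
#' @param ctt_h optional transit time overriding the column (recycled).
#' @return tibble: the input columns plus `intake_cod`, `upper_absorbed`,
#'   `colon_influent`, `fermented_total`, `biomass_fecal`, `methane_cod`,
#'   `scfa_absorbed_total`, `scfa_absorbed_acetate/propionate/butyrate/
#'   isobutyrate`, fecal partition columns `fecal_substrate`, `fecal_scfa`,
#'   `fecal_endogenous`, `fecal_total`, `me_pct` and `balance_residual`.
#' @examples
#' diet_templates() |>
#'   partition_substrates() |>
#'   gut_predict(ctt_h = 48)
#' @export
gut_predict <- function(data, params = gut_params(), ctt_h = NULL) {
  .check_substrates(data)
  staged <- data |>
    upper_gi(params) |>
    ferment(params, ctt_h = ctt_h)
  part <- partition_fermented(staged$fermented_total, params)
  split <- params$scfa_split
  out <- dplyr::mutate(
    staged,
    intake_cod = .data$cod_ass + .data$cod_rs + .data$cod_nsp +
      .data$cod_protein + .data$cod_fat,
    colon_influent = .data$influent_ass + .data$influent_rs +
      .data$influent_nsp + .data$influent_protein + .data$influent_fat +
      params$e0,
    biomass_fecal = part$biomass,
    methane_cod = part$methane,
    scfa_gross = part$scfa_gross,
    scfa_absorbed_total = params$a_scfa * part$scfa_gross,
    scfa_absorbed_acetate = split[["acetate"]] * .data$scfa_absorbed_total,
    scfa_absorbed_propionate = split[["propionate"]] * .data$scfa_absorbed_total,
    scfa_absorbed_butyrate = split[["butyrate"]] * .data$scfa_absorbed_total,
    scfa_absorbed_isobutyrate = split[["isobutyrate"]] * .data$scfa_absorbed_total,
    fecal_substrate = (.data$influent_ass - .data$fermented_ass) +
      (.data$influent_rs - .data$fermented_rs) +
      (.data$influent_nsp - .data$fermented_nsp) +
      (.data$influent_protein - .data$fermented_protein) +
      (.data$influent_fat - .data$fermented_fat),
    fecal_scfa = (1 - params$a_scfa) * part$scfa_gross,
    fecal_endogenous = params$e0 - .data$fermented_endogenous,
    fecal_total = .data$fecal_substrate + .data$biomass_fecal +
      .data$fecal_scfa + .data$fecal_endogenous,
    me_pct = 100 * (.data$intake_cod - .data$fecal_total) / .data$intake_cod,
    balance_residual = .data$intake_cod + params$e0 -
      (.data$upper_absorbed + .data$scfa_absorbed_total + .data$fecal_total +
         .data$methane_cod)
  )
  drop <- c("influent_ass", "influent_rs", "influent_nsp", "influent_protein",
            "influent_fat", "fermented_ass", "fermented_rs", "fermented_nsp",
            "fermented_protein", "fermented_fat", "fermented_endogenous")
  dplyr::select(out, -dplyr::all_of(drop))
}

#' Model response to a grid of colonic transit times
#'
#' Evaluates [gut_predict()] for one diet across a grid of transit times,
#' e.g. to examine how transit modulates fermentation extent, SCFA uptake
#' and metabolizable energy.
#'
#' @param data one-row data frame with substrate columns from
#'   [partition_substrates()].
#' @param params a [gut_params()] object.
#' @param ctt_grid transit times in hours (all > 0).
#' @return tibble with one row per grid value.
#' @examples
#' sensitivity_ctt(partition_substrates(diet_templates()[2, ]),
#'                 ctt_grid = c(16, 48, 72))
#' @export
sensitivity_ctt <- function(data, params = gut_params(), ctt_grid) {
  .check_substrates(data)
  if (nrow(data) != 1) {
    abort("sensitivity_ctt(): data must be a single diet (one row)")
  }
  if (any(ctt_grid <= 0)) {
    abort("sensitivity_ctt(): all grid values must be > 0")
  }
  purrr::map_dfr(ctt_grid, function(tau) gut_predict(data, params, ctt_h = tau))
}
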