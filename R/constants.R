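#' Stoichiometric COD conversion factors for dietary macronutrients
#'
#' Chemical oxygen demand (COD) expresses the energy content of organic matter
#' as the mass of O2 required to oxidize it fully, a currency shared by host
#' and microbial metabolism. The defaults are theoretical oxygen demands:
#' 1.185 gCOD/g for carbohydrate on a polysaccharide (C6H10O5)n basis, 1.50
#' gCOD/g for protein, and 2.90 gCOD/g for fat. Dietary fiber and resistant
#' starch receive the carbohydrate factor: COD counts electrons, irrespective
#' of whether the host or its microbes can access them.
#'
#' `kcal_per_gcod` is the scalar used when converting kilocalories to COD
#' without a known macronutrient composition; 3.06 kcal/gCOD is a
#' mixed-diet-weighted value. When a composition is available,
#' [cod_kcal_factor()] derives the diet-specific factor instead.
#'
#' @param carbohydrate gCOD per gram carbohydrate (also applied to fiber and
#'   resistant starch).
#' @param protein gCOD per gram protein.
#' @param fat gCOD per gram fat.
#' @param kcal_per_gcod default scalar kcal per gCOD for composition-free
#'   conversions.
#' @return An object of class `cod_factors`.
#' @examples
#' cod_factors()
#' @export
cod_factors <- function(carbohydrate = 1.185, protein = 1.50, fat = 2.90,
                        kcal_per_gcod = 3.06) {
  stopifnot(
    "carbohydrate COD factor outside [1.0, 1.3]" =
      carbohydrate >= 1.0 && carbohydrate <= 1.3,
    "protein COD factor outside [1.3, 1.7]" = protein >= 1.3 && protein <= 1.7,
    "fat COD factor outside [2.7, 3.0]" = fat >= 2.7 && fat <= 3.0,
    "kcal_per_gcod outside [2.8, 3.5]" =
      kcal_per_gcod >= 2.8 && kcal_per_gcod <= 3.5
  )
  structure(
    list(
      carbohydrate = carbohydrate, protein = protein, fat = fat,
      kcal_per_gcod = kcal_per_gcod
    ),
    class = "cod_factors"
  )
}

#' @export
print.cod_factors <- function(x, ...) {
  cat("<cod_factors> gCOD per g: carbohydrate", x$carbohydrate,
      "| protein", x$protein, "| fat", x$fat,
      "| default", x$kcal_per_gcod, "kcal/gCOD\n")
  invisible(x)
}

#' Physical constants used across the package
#'
#' Bundles the methane combustion enthalpy (212.8 kcal/mol), the ideal-gas
#' molar volume at a reference temperature, Avogadro's number, and the mean
#' molar mass of a DNA base pair. The molar volume is anchored to the
#' conventional 24,450 ml/mol at 25 degrees C (1 atm) and scaled linearly in
#' absolute temperature for other reference temperatures.
#'
#' @param temperature_c reference temperature in degrees Celsius for gas
#'   volumes (default 25).
#' @return An object of class `physical_constants` with fields
#'   `ch4_combustion_kcal_mol`, `molar_volume_ml`, `avogadro`, `bp_mass_g_mol`
#'   and `temperature_c`.
#' @examples
#' physical_constants()$molar_volume_ml # 24450 at 25 C
#' @export
physical_constants <- function(temperature_c = 25) {
  structure(
    list(
      ch4_combustion_kcal_mol = 212.8,
      molar_volume_ml = 24450 * (273.15 + temperature_c) / 298.15,
      avogadro = 6.022e23,
      bp_mass_g_mol = 660,
      temperature_c = temperature_c
    ),
    class = "physical_constants"
  )
}

#' @export
print.physical_constants <- function(x, ...) {
  cat("<physical_constants> CH4 212.8 kcal/mol | molar volume",
      round(x$molar_volume_ml), "ml/mol at", x$temperature_c, "C\n")
  invisible(x)
}

# COD content of the individual SCFA species (gCOD per g acid), from full
# oxidation stoichiometry: acetate C2H4O2 (64 gCOD / 60 g), propionate C3H6O2
# (112/74), butyrate and iso-butyrate C4H8O2 (160/88).
scfa_cod_per_g <- c(
  acetate = 64 / 60, propionate = 112 / 74,
  butyrate = 160 / 88, isobutyrate = 160 / 88
)
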