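#' Partition a diet into fermentation substrate classes, in gCOD/day
#'
#' Splits daily macronutrient intake into the five substrate classes carried
#' through the gut model: available sugar and starch (total carbohydrate minus
#' resistant starch minus fiber), resistant starch, non-starch polysaccharides
#' (fiber), protein, and fat, each converted to electron equivalents
#' (gCOD/day) with the stoichiometric factors in [cod_factors()].
#'
#' @param data a data frame with numeric columns `cho_g` (total carbohydrate
#'   including fiber), `fiber_g`, `rs_g` (resistant starch), `protein_g` and
#'   `fat_g`, all in g/day. Other columns pass through untouched.
#' @param factors a [cod_factors()] object.
#' @return `data` as a tibble with added columns `cod_ass`, `cod_rs`,
#'   `cod_nsp`, `cod_protein`, `cod_fat` and `cod_total` (gCOD/day).
#' @examples
#' tibble::tibble(cho_g = 100, fiber_g = 20, rs_g = 10,
#'                protein_g = 0, fat_g = 0) |>
#'   partition_substrates()
#' @export
partition_substrates <- function(data, factors = cod_factors()) {
  need <- c("cho_g", "fiber_g", "rs_g", "protein_g", "fat_g")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    abort(paste0("partition_substrates(): missing columns: ",
                 paste(miss, collapse = ", ")))
  }
  data <- tibble::as_tibble(data)
  for (col in need) {
    if (any(data[[col]] < 0, na.rm = TRUE)) {
      abort(paste0("partition_substrates(): negative values in '", col, "'"))
    }
  }
  bad <- which(data$rs_g + data$fiber_g > data$cho_g + 1e-9)
  if (length(bad) > 0) {
    abort(paste0(
      "partition_substrates(): rs_g + fiber_g exceeds cho_g in row(s) ",
      paste(bad, collapse = ", ")
    ))
  }
  dplyr::mutate(
    data,
    cod_ass = (.data$cho_g - .data$rs_g - .data$fiber_g) * factors$carbohydrate,
    cod_rs = .data$rs_g * factors$carbohydrate,
    cod_nsp = .data$fiber_g * factors$carbohydrate,
    cod_protein = .data$protein_g * factors$protein,
    cod_fat = .data$fat_g * factors$fat,
    cod_total = .data$cod_ass + .data$cod_rs + .data$cod_nsp +
      .data$cod_protein + .data$cod_fat
  )
}

#' Host metabolizable energy from intake and fecal COD
#'
#' The fraction of dietary electron equivalents retained by the host:
#' `100 * (1 - fecal_cod / intake_cod)` percent.
#'
#' @param intake_cod daily dietary intake in gCOD/day (> 0).
#' @param fecal_cod daily fecal output in gCOD/day (>= 0).
#' @return metabolizable energy in percent (vectorized).
#' @examples
#' host_me(698, 32.1) # ~95.4 %
#' @export
host_me <- function(intake_cod, fecal_cod) {
  if (any(intake_cod <= 0, na.rm = TRUE)) {
    abort("host_me(): intake_cod must be > 0")
  }
  if (any(fecal_cod < 0, na.rm = TRUE)) {
    abort("host_me(): fecal_cod must be >= 0")
  }
  100 * (1 - fecal_cod / intake_cod)
}

#' Daily non-metabolizable energy in kcal
#'
#' Converts a metabolizable-energy percentage back to the kilocalories lost
#' to feces per day: `ei_kcal * (1 - host_me_pct / 100)`.
#'
#' @param host_me_pct host metabolizable energy in percent, in \[0, 100\].
#' @param ei_kcal energy intake in kcal/day.
#' @return kcal/day not absorbed by the host (vectorized).
#' @examples
#' nonmetabolizable_kcal(89.5, 2113.6)
#' @export
nonmetabolizable_kcal <- function(host_me_pct, ei_kcal) {
  if (any(host_me_pct < 0 | host_me_pct > 100, na.rm = TRUE)) {
    abort("nonmetabolizable_kcal(): host_me_pct must be within [0, 100]")
  }
  if (any(ei_kcal < 0, na.rm = TRUE)) {
    abort("nonmetabolizable_kcal(): ei_kcal must be >= 0")
  }
  ei_kcal * (1 - host_me_pct / 100)
}

#' Energy lost as exhaled/eructed methane
#'
#' Converts a 24-h methane volume to kcal/day via the ideal-gas molar volume
#' and the combustion enthalpy of methane (212.8 kcal/mol).
#'
#' @param vol_ml_per_day methane volume in ml/day (>= 0).
#' @param constants a [physical_constants()] object fixing the reference
#'   temperature for the molar volume.
#' @return kcal/day (vectorized).
#' @examples
#' methane_energy(1613) # ~14 kcal/day
#' @export
methane_energy <- function(vol_ml_per_day, constants = physical_constants()) {
  if (any(vol_ml_per_day < 0, na.rm = TRUE)) {
    abort("methane_energy(): volume must be >= 0")
  }
  vol_ml_per_day / constants$molar_volume_ml * constants$ch4_combustion_kcal_mol
}

#' Daily energy balance
#'
#' Energy balance = energy intake minus energy expenditure (kcal/day).
#'
#' @param ei_kcal energy intake, kcal/day (>= 0).
#' @param ee_kcal energy expenditure, kcal/day (>= 0).
#' @return kcal/day (vectorized); positive values indicate surplus.
#' @export
energy_balance <- function(ei_kcal, ee_kcal) {
  if (any(ei_kcal < 0, na.rm = TRUE) || any(ee_kcal < 0, na.rm = TRUE)) {
    abort("energy_balance(): intake and expenditure must be >= 0")
  }
  ei_kcal - ee_kcal
}

#' Diet-specific kcal per gCOD conversion factor
#'
#' When the macronutrient composition of a diet is known, the kcal/gCOD
#' factor is the ratio of total dietary energy to total dietary COD from
#' [partition_substrates()]. Without a composition, the default scalar in
#' [cod_factors()] applies.
#'
#' @param composition one-row data frame with `kcal`, `cho_g`, `fiber_g`,
#'   `rs_g`, `protein_g`, `fat_g`; or `NULL` for the default scalar.
#' @param factors a [cod_factors()] object.
#' @return kcal per gCOD (scalar).
#' @examples
#' cod_kcal_factor(diet_templates()[1, ])
#' @export
cod_kcal_factor <- function(composition = NULL, factors = cod_factors()) {
  if (is.null(composition)) {
    return(factors$kcal_per_gcod)
  }
  stopifnot(nrow(composition) == 1, "kcal" %in% names(composition))
  total <- partition_substrates(composition, factors)$cod_total
  if (composition$kcal <= 0) {
    if (total > 0) {
      abort("cod_kcal_factor(): zero kcal with nonzero macronutrient mass")
    }
    return(factors$kcal_per_gcod)
  }
  composition$kcal / total
}

#' Convert kilocalories to gCOD (and back)
#'
#' `kcal_to_cod()` and `cod_to_kcal()` interconvert dietary energy between
#' kilocalories and electron equivalents, using the composition-weighted
#' factor when a composition is supplied. The round trip is exact.
#'
#' @param kcal,gcod value to convert (vectorized).
#' @param composition optional one-row composition data frame, see
#'   [cod_kcal_factor()].
#' @param factors a [cod_factors()] object.
#' @return converted value(s).
#' @examples
#' cod_to_kcal(kcal_to_cod(2126))
#' @export
kcal_to_cod <- function(kcal, composition = NULL, factors = cod_factors()) {
  kcal / cod_kcal_factor(composition, factors)
}

#' @rdname kcal_to_cod
#' @export
cod_to_kcal <- function(gcod, composition = NULL, factors = cod_factors()) {
  gcod * cod_kcal_factor(composition, factors)
}

#' Mean daily diet templates for the two study arms
#'
#' Daily macronutrient intakes for the Western Diet (WD) control and the
#' Microbiome Enhancer Diet (MBD, high fiber and resistant starch, minimally
#' processed). Defaults are the study-mean targets: WD 2126 kcal/day at
#' 48/35/16 percent of kcal from carbohydrate/fat/protein with 6.4 g fiber
#' and 1.2 g resistant starch per 1000 kcal; MBD 2113.6 kcal/day at 49/34/17
#' percent with 26.0 g fiber and 10.3 g resistant starch per 1000 kcal.
#'
#' Macronutrient percentages refer to metabolizable kilocalories under the
#' menu-software ledger in which dietary fiber contributes 0 kcal; `cho_g`
#' therefore equals digestible carbohydrate (pct * kcal / 4) plus fiber.
#'
#' @param kcal daily energy intake per diet (named numeric, kcal/day).
#' @param cho_pct,fat_pct,protein_pct macronutrient energy fractions per diet.
#' @param fiber_per_1000,rs_per_1000 fiber and resistant starch density,
#'   g per 1000 kcal, per diet.
#' @return tibble with one row per diet: `diet`, `kcal`, `cho_g`, `fiber_g`,
#'   `rs_g`, `protein_g`, `fat_g`.
#' @examples
#' diet_templates() |> partition_substrates()
#' @export
diet_templates <- function(kcal = c(WD = 17008 / 8, MBD = 16909 / 8),
                           cho_pct = c(WD = 0.48, MBD = 0.49),
                           fat_pct = c(WD = 0.35, MBD = 0.34),
                           protein_pct = c(WD = 0.16, MBD = 0.17),
                           fiber_per_1000 = c(WD = 6.4, MBD = 26.0),
                           rs_per_1000 = c(WD = 1.2, MBD = 10.3)) {
  diets <- names(kcal)
  stopifnot(!is.null(diets), length(diets) >= 1)
  tibble::tibble(
    diet = diets,
    kcal = unname(kcal),
    fiber_g = unname(fiber_per_1000[diets]) * unname(kcal) / 1000,
    rs_g = unname(rs_per_1000[diets]) * unname(kcal) / 1000,
    cho_g = unname(cho_pct[diets]) * unname(kcal) / 4 + .data$fiber_g,
    protein_g = unname(protein_pct[diets]) * unname(kcal) / 4,
    fat_g = unname(fat_pct[diets]) * unname(kcal) / 9
  ) |>
    dplyr::select("diet", "kcal", "cho_g", "fiber_g", "rs_g",
                  "protein_g", "fat_g")
}

#' Read a per-participant daily intake table
#'
#' Expects the columns `participant_id`, `diet`, `kcal`, `cho_g`, `fiber_g`,
#' `rs_g`, `protein_g`, `fat_g` (units: kcal/day and g/day).
#'
#' @param path CSV file path.
#' @return tibble.
#' @export
read_intake <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("participant_id", "diet", "kcal", "cho_g", "fiber_g", "rs_g",
            "protein_g", "fat_g")
  miss <- setdiff(need, names(out))
  if (length(miss) > 0) {
    abort(paste0("read_intake(): ", path, " lacks columns: ",
                 paste(miss, collapse = ", ")))
  }
  out
}
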