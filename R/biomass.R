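#' qPCR plasmid standard copy number
#'
#' Absolute copy number of a plasmid standard per microliter, from its DNA
#' concentration and length:
#' `copies/uL = dna_ng_per_ul * 6.022e23 / (plasmid_length_bp * 1e9 * 660)`
#' (1e9 converts ng to g; 660 g/mol is the mean molar mass per base pair).
#'
#' @param dna_ng_per_ul DNA concentration, ng/uL (>= 0).
#' @param plasmid_length_bp plasmid length in base pairs (> 0).
#' @param constants a [physical_constants()] object (Avogadro, bp mass).
#' @return copies per microliter (vectorized).
#' @examples
#' plasmid_copy_number(10, 3000) # ~3.04e9
#' @export
plasmid_copy_number <- function(dna_ng_per_ul, plasmid_length_bp,
                                constants = physical_constants()) {
  if (any(plasmid_length_bp <= 0, na.rm = TRUE)) {
    abort("plasmid_copy_number(): plasmid length must be > 0")
  }
  if (any(dna_ng_per_ul < 0, na.rm = TRUE)) {
    abort("plasmid_copy_number(): DNA concentration must be >= 0")
  }
  dna_ng_per_ul * constants$avogadro /
    (plasmid_length_bp * 1e9 * constants$bp_mass_g_mol)
}

#' Daily 16S rRNA gene output in feces
#'
#' Scales a per-gram 16S copy density to a marker-normalized daily output:
#' `copies_per_g * fecal_g_per_day / recovery`.
#'
#' @param copies_per_g 16S gene copies per gram wet feces.
#' @param fecal_g_per_day fecal wet weight output, g/day.
#' @param recovery PEG recovery fraction (> 0), see [peg_recovery()].
#' @return copies per day (vectorized).
#' @export
daily_16s_copies <- function(copies_per_g, fecal_g_per_day, recovery) {
  if (any(recovery <= 0, na.rm = TRUE)) {
    abort("daily_16s_copies(): recovery must be > 0")
  }
  if (any(copies_per_g < 0, na.rm = TRUE) ||
      any(fecal_g_per_day < 0, na.rm = TRUE)) {
    abort("daily_16s_copies(): inputs must be >= 0")
  }
  copies_per_g * fecal_g_per_day / recovery
}

#' Parameters converting 16S gene counts to biomass COD
#'
#' Bacterial genomes carry several 16S rRNA gene copies (gut-community mean
#' about 4); a bacterial cell has a dry mass of roughly 2.8e-13 g; and
#' standard biomass stoichiometry (C5H7O2N) carries 1.42 gCOD per g dry
#' weight. All three are exposed because community composition shifts them.
#'
#' @param copies_per_genome mean 16S copies per genome (>= 1).
#' @param cell_dry_mass_g dry mass per cell, g.
#' @param cod_per_dw gCOD per g dry weight, in \[1.2, 1.6\].
#' @return object of class `biomass_params`.
#' @export
biomass_params <- function(copies_per_genome = 4, cell_dry_mass_g = 2.8e-13,
                           cod_per_dw = 1.42) {
  stopifnot(
    "copies_per_genome must be >= 1" = copies_per_genome >= 1,
    "cell_dry_mass_g must be > 0" = cell_dry_mass_g > 0,
    "cod_per_dw outside [1.2, 1.6]" = cod_per_dw >= 1.2 && cod_per_dw <= 1.6
  )
  structure(
    list(copies_per_genome = copies_per_genome,
         cell_dry_mass_g = cell_dry_mass_g, cod_per_dw = cod_per_dw),
    class = "biomass_params"
  )
}

#' @export
print.biomass_params <- function(x, ...) {
  cat("<biomass_params>", x$copies_per_genome, "16S copies/genome |",
      format(x$cell_dry_mass_g), "g dry/cell |", x$cod_per_dw, "gCOD/g dry\n")
  invisible(x)
}

#' Fecal bacterial biomass in COD currency
#'
#' Converts a daily 16S gene output to biomass electron equivalents:
#' `copies_per_day / copies_per_genome * cell_dry_mass_g * cod_per_dw`
#' (gCOD/day).
#'
#' @param copies_per_day daily 16S gene output, see [daily_16s_copies()].
#' @param params a [biomass_params()] object.
#' @return gCOD/day of bacterial biomass (vectorized).
#' @examples
#' biomass_cod(2e14) # ~19.9 gCOD/day
#' @export
biomass_cod <- function(copies_per_day, params = biomass_params()) {
  if (any(copies_per_day < 0, na.rm = TRUE)) {
    abort("biomass_cod(): copies_per_day must be >= 0")
  }
  copies_per_day / params$copies_per_genome * params$cell_dry_mass_g *
    params$cod_per_dw
}
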