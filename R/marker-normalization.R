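#' PEG marker dosing protocol
#'
#' PEG3350 is a non-absorbable, non-digestible marker dosed with each meal;
#' its fecal recovery converts multi-day composite collections into 24-hour
#' outputs. Default protocol: one 0.5 g capsule per meal, three meals per
#' day, 1.5 g/day total.
#'
#' @param capsule_g grams PEG per capsule.
#' @param capsules_per_meal capsules taken with each meal.
#' @param meals_per_day meals per day.
#' @return object of class `peg_protocol` with the daily dose in
#'   `dose_g_per_day`.
#' @export
peg_protocol <- function(capsule_g = 0.5, capsules_per_meal = 1,
                         meals_per_day = 3) {
  dose <- capsule_g * capsules_per_meal * meals_per_day
  stopifnot(dose > 0)
  structure(
    list(
      dose_g_per_day = dose, capsule_g = capsule_g,
      capsules_per_meal = capsules_per_meal, meals_per_day = meals_per_day
    ),
    class = "peg_protocol"
  )
}

#' @export
print.peg_protocol <- function(x, ...) {
  cat("<peg_protocol>", x$dose_g_per_day, "g PEG3350/day (",
      x$capsules_per_meal, "x", x$capsule_g, "g per meal,",
      x$meals_per_day, "meals )\n")
  invisible(x)
}

#' PEG recovery fraction of a composite fecal collection
#'
#' Recovery is the PEG mass recovered per collection day relative to the
#' administered daily dose, assuming steady-state excretion of the
#' non-absorbable marker. Recoveries outside `flag_range` are physiologically
#' unusual and are flagged with a warning but retained; non-positive PEG
#' masses make the marker unusable and yield `NA` recovery with a warning
#' (the row is flagged, never dropped).
#'
#' @param data data frame with columns `peg_g_total` (g PEG in the composite)
#'   and `days` (collection window length).
#' @param protocol a [peg_protocol()].
#' @param flag_range recoveries outside this interval are flagged.
#' @return `data` with added `recovery` and logical `recovery_flag` columns.
#' @examples
#' tibble::tibble(peg_g_total = 7.2, days = 6) |> peg_recovery()
#' @export
peg_recovery <- function(data, protocol = peg_protocol(),
                         flag_range = c(0.5, 1.5)) {
  stopifnot(all(c("peg_g_total", "days") %in% names(data)))
  data <- tibble::as_tibble(data)
  if (any(data$days <= 0, na.rm = TRUE)) {
    abort("peg_recovery(): days must be > 0")
  }
  rec <- (data$peg_g_total / data$days) / protocol$dose_g_per_day
  unusable <- !is.na(data$peg_g_total) & data$peg_g_total <= 0
  if (any(unusable)) {
    warn(paste0(
      "peg_recovery(): unusable marker (peg_g_total <= 0) in row(s) ",
      paste(which(unusable), collapse = ", "), "; recovery set to NA"
    ))
    rec[unusable] <- NA_real_
  }
  out_of_band <- !is.na(rec) & (rec < flag_range[1] | rec > flag_range[2])
  if (any(out_of_band)) {
    warn(paste0(
      "peg_recovery(): recovery outside [", flag_range[1], ", ",
      flag_range[2], "] in row(s) ", paste(which(out_of_band), collapse = ", "),
      "; values retained"
    ))
  }
  dplyr::mutate(data, recovery = rec,
                recovery_flag = unusable | out_of_band)
}

#' Marker-normalized daily fecal COD output
#'
#' Converts the composite COD measurement to a 24-hour output:
#' `cod_conc_g_per_g * total_weight_g / days / recovery` (gCOD/day).
#'
#' @param data data frame with `cod_conc_g_per_g` (gCOD per g wet feces),
#'   `total_weight_g`, `days` and a `recovery` column (see [peg_recovery()]).
#' @return `data` with added `fecal_cod_g_day`.
#' @export
daily_fecal_cod <- function(data) {
  stopifnot(all(c("cod_conc_g_per_g", "total_weight_g", "days", "recovery")
                %in% names(data)))
  if (any(data$recovery <= 0, na.rm = TRUE)) {
    abort("daily_fecal_cod(): recovery must be > 0")
  }
  dplyr::mutate(
    tibble::as_tibble(data),
    fecal_cod_g_day = .data$cod_conc_g_per_g * .data$total_weight_g /
      .data$days / .data$recovery
  )
}

#' Marker-normalized daily fecal SCFA outputs
#'
#' Per-species daily outputs `conc * weight / days / recovery` (mg/day) for
#' acetate, propionate and butyrate, plus their sum as total fecal SCFA.
#'
#' @param data data frame with `acetate_mg_g`, `propionate_mg_g`,
#'   `butyrate_mg_g`, `total_weight_g`, `days` and `recovery`.
#' @return `data` with added `acetate_mg_day`, `propionate_mg_day`,
#'   `butyrate_mg_day` and `scfa_total_mg_day`.
#' @export
daily_fecal_scfa <- function(data) {
  species <- c("acetate_mg_g", "propionate_mg_g", "butyrate_mg_g")
  stopifnot(all(c(species, "total_weight_g", "days", "recovery")
                %in% names(data)))
  if (any(data$recovery <= 0, na.rm = TRUE)) {
    abort("daily_fecal_scfa(): recovery must be > 0")
  }
  scale <- data$total_weight_g / data$days / data$recovery
  dplyr::mutate(
    tibble::as_tibble(data),
    acetate_mg_day = .data$acetate_mg_g * scale,
    propionate_mg_day = .data$propionate_mg_g * scale,
    butyrate_mg_day = .data$butyrate_mg_g * scale,
    scfa_total_mg_day = .data$acetate_mg_day + .data$propionate_mg_day +
      .data$butyrate_mg_day
  )
}

#' Normalize a composite fecal table to 24-hour outputs
#'
#' Convenience wrapper chaining [peg_recovery()], [daily_fecal_cod()] and
#' [daily_fecal_scfa()].
#'
#' @inheritParams peg_recovery
#' @return tibble with recovery, daily COD and daily SCFA columns added.
#' @export
normalize_fecal <- function(data, protocol = peg_protocol()) {
  data |>
    peg_recovery(protocol) |>
    daily_fecal_cod() |>
    daily_fecal_scfa()
}

#' Read a composite fecal measurement table
#'
#' Expects `participant_id`, `diet`, `total_weight_g`, `days`,
#' `cod_conc_g_per_g`, `peg_g_total`, `acetate_mg_g`, `propionate_mg_g`,
#' `butyrate_mg_g`.
#'
#' @param path CSV file path.
#' @return tibble.
#' @export
read_fecal <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("participant_id", "diet", "total_weight_g", "days",
            "cod_conc_g_per_g", "peg_g_total", "acetate_mg_g",
            "propionate_mg_g", "butyrate_mg_g")
  miss <- setdiff(need, names(out))
  if (length(miss) > 0) {
    abort(paste0("read_fecal(): ", path, " lacks columns: ",
                 paste(miss, collapse = ", ")))
  }
  out
}
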