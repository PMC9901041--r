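#' Run the full measurement pipeline on a cohort
#'
#' Joins the observable tables of a (synthetic or real) crossover dataset
#' and computes, per participant-diet: intake COD from the macronutrient
#' composition, PEG recovery, marker-normalized daily fecal COD and SCFA
#' outputs, host metabolizable energy, non-metabolizable kcal, energy
#' balance, methane energy, and the qPCR-route fecal bacterial biomass.
#'
#' @param cohort a [generate_cohort()] result, a [read_cohort()] result, or
#'   a directory containing the cohort CSVs.
#' @param factors [cod_factors()].
#' @param protocol [peg_protocol()].
#' @param biomass [biomass_params()].
#' @param constants [physical_constants()].
#' @return tibble with one row per participant-diet, carrying the substrate
#'   columns (`cod_*`), `recovery`, `fecal_cod_g_day`, SCFA outputs,
#'   `me_pct`, `nonmetab_kcal`, `balance_kcal`, `methane_kcal`,
#'   `copies_per_day`, `biomass_cod_g_day` and `ctt_h`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 4, seed = 1))
#' analyze_cohort(cohort)
#' @export
analyze_cohort <- function(cohort, factors = cod_factors(),
                           protocol = peg_protocol(),
                           biomass = biomass_params(),
                           constants = physical_constants()) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "gutcod_cohort"))
  keys <- c("participant_id", "diet")

  intake <- partition_substrates(cohort$intake, factors)
  fecal <- normalize_fecal(cohort$fecal, protocol)

  out <- intake |>
    dplyr::inner_join(fecal, by = keys) |>
    dplyr::left_join(cohort$qpcr, by = keys) |>
    dplyr::left_join(cohort$ctt, by = keys) |>
    dplyr::left_join(cohort$methane, by = keys) |>
    dplyr::left_join(cohort$ee, by = keys) |>
    dplyr::mutate(
      me_pct = host_me(.data$cod_total, .data$fecal_cod_g_day),
      nonmetab_kcal = nonmetabolizable_kcal(pmin(pmax(.data$me_pct, 0), 100),
                                            .data$kcal),
      balance_kcal = energy_balance(.data$kcal, .data$ee_kcal),
      methane_kcal = methane_energy(.data$methane_ml_day, constants),
      fecal_wet_g_day = .data$total_weight_g / .data$days / .data$recovery,
      copies_per_day = daily_16s_copies(.data$copies_per_g,
                                        .data$total_weight_g / .data$days,
                                        .data$recovery),
      biomass_cod_g_day = biomass_cod(.data$copies_per_day, biomass)
    )
  out
}

#' Write the per-participant energy summary to CSV
#'
#' Persists the energy columns of an [analyze_cohort()] result (intake and
#' fecal COD in gCOD/day, host metabolizable energy in percent,
#' non-metabolizable kcal/day and energy balance in kcal/day).
#'
#' @param analysis output of [analyze_cohort()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_energy_summary <- function(analysis, path) {
  cols <- c("participant_id", "diet", "kcal", "cod_total", "fecal_cod_g_day",
            "me_pct", "nonmetab_kcal", "balance_kcal")
  keep <- intersect(cols, names(analysis))
  readr::write_csv(dplyr::select(analysis, dplyr::all_of(keep)), path)
  invisible(path)
}

#' Model predictions matched to a cohort analysis
#'
#' Runs the gut model on each participant-diet's substrate intake, either at
#' one fixed transit time for everyone or at each participant's measured
#' transit time.
#'
#' @param analysis output of [analyze_cohort()] (needs the `cod_*` and
#'   `ctt_h` columns).
#' @param params a [gut_params()] object.
#' @param ctt `"measured"` (per-participant `ctt_h`) or `"fixed"`.
#' @param fixed_ctt_h transit time used when `ctt = "fixed"` (hours).
#' @return tibble keyed by participant and diet with modeled `me_pct`,
#'   `scfa_absorbed_total`, `biomass_fecal`, `fecal_total` and the transit
#'   time used.
#' @export
model_cohort <- function(analysis, params = gut_params(),
                         ctt = c("measured", "fixed"), fixed_ctt_h = 48) {
  ctt <- match.arg(ctt)
  tau <- if (ctt == "fixed") fixed_ctt_h else analysis$ctt_h
  pred <- gut_predict(analysis, params, ctt_h = tau)
  tibble::tibble(
    participant_id = analysis$participant_id, diet = analysis$diet,
    ctt_mode = ctt, ctt_h_used = tau,
    me_pct_model = pred$me_pct,
    scfa_absorbed_total = pred$scfa_absorbed_total,
    biomass_fecal = pred$biomass_fecal,
    fecal_total_model = pred$fecal_total
  )
}

.sem <- function(x) sd(x) / sqrt(length(x))

#' Study report: per-diet summaries, crossover tests and model agreement
#'
#' Produces the summary tables of a crossover bioenergetics study: per-diet
#' means with standard errors for daily fecal COD, host metabolizable
#' energy, non-metabolizable kcal, modeled SCFA uptake and fecal biomass
#' (both the qPCR measurement route and the model route); paired crossover
#' tests of the diet effect; and measured-versus-modeled agreement
#' (Bland-Altman, Lin's concordance, R squared) under both a fixed transit
#' time and the measured per-participant transit times.
#'
#' @param cohort a [generate_cohort()] result (or directory).
#' @param params gut model parameters for the model comparison.
#' @param fixed_ctt_h fixed transit time for the population-level model run.
#' @param ... passed to [analyze_cohort()].
#' @return object of class `gutcod_report`: list with `summary`, `paired`,
#'   `agreement` tibbles and the underlying `analysis`. An empty cohort
#'   yields empty tibbles with intact schemas.
#' @export
build_report <- function(cohort, params = gut_params(), fixed_ctt_h = 48,
                         ...) {
  analysis <- analyze_cohort(cohort, ...)
  metrics <- c(
    fecal_cod_g_day = "fecal COD (gCOD/day)",
    me_pct = "host metabolizable energy (%)",
    nonmetab_kcal = "non-metabolizable energy (kcal/day)",
    scfa_total_mg_day = "fecal SCFA (mg/day)",
    biomass_cod_g_day = "fecal biomass, qPCR route (gCOD/day)",
    balance_kcal = "energy balance (kcal/day)"
  )
  model_metrics <- c(
    me_pct_model = "modeled host metabolizable energy (%)",
    scfa_absorbed_total = "modeled SCFA absorbed (gCOD/day)",
    biomass_fecal = "modeled fecal biomass (gCOD/day)"
  )

  empty_summary <- tibble::tibble(
    metric = character(), diet = character(), mean = numeric(),
    sem = numeric(), n = integer()
  )
  empty_paired <- tibble::tibble(
    metric = character(), estimate = numeric(), sem = numeric(),
    statistic = numeric(), p.value = numeric(), n_pairs = integer(),
    n_excluded = integer()
  )
  empty_agreement <- tibble::tibble(
    ctt_mode = character(), bias = numeric(), loa_low = numeric(),
    loa_high = numeric(), proportional_slope = numeric(), ccc = numeric(),
    r_squared = numeric(), n = integer()
  )

  if (nrow(analysis) == 0) {
    return(structure(
      list(summary = empty_summary, paired = empty_paired,
           agreement = empty_agreement, analysis = analysis),
      class = "gutcod_report"
    ))
  }

  modeled <- dplyr::bind_rows(
    model_cohort(analysis, params, "fixed", fixed_ctt_h),
    model_cohort(analysis, params, "measured")
  )
  model_measured <- dplyr::filter(modeled, .data$ctt_mode == "measured")

  long <- analysis |>
    dplyr::left_join(
      model_measured[, c("participant_id", "diet", "me_pct_model",
                         "scfa_absorbed_total", "biomass_fecal")],
      by = c("participant_id", "diet")
    ) |>
    tidyr::pivot_longer(dplyr::all_of(names(c(metrics, model_metrics))),
                        names_to = "metric_key", values_to = "value") |>
    dplyr::mutate(metric = unname(c(metrics, model_metrics)[.data$metric_key]))
  summary <- long |>
    dplyr::group_by(.data$metric, .data$diet) |>
    dplyr::summarise(mean = mean(.data$value), sem = .sem(.data$value),
                     n = dplyr::n(), .groups = "drop")

  paired <- purrr::map_dfr(unname(c(metrics, model_metrics)), function(lbl) {
    joined <- long |> dplyr::filter(.data$metric == lbl)
    dplyr::bind_cols(tibble::tibble(metric = lbl),
                     paired_crossover(joined, value))
  })

  agreement <- purrr::map_dfr(c("fixed", "measured"), function(mode) {
    mod <- dplyr::filter(modeled, .data$ctt_mode == mode)
    joined <- dplyr::inner_join(
      analysis[, c("participant_id", "diet", "me_pct")], mod,
      by = c("participant_id", "diet")
    )
    ba <- bland_altman(joined$me_pct, joined$me_pct_model)
    dplyr::bind_cols(
      tibble::tibble(ctt_mode = mode),
      glance(ba)[, c("bias", "loa_low", "loa_high", "proportional_slope")],
      tibble::tibble(
        ccc = lin_ccc(joined$me_pct, joined$me_pct_model),
        r_squared = cor(joined$me_pct, joined$me_pct_model)^2,
        n = nrow(joined)
      )
    )
  })

  structure(
    list(summary = summary, paired = paired, agreement = agreement,
         analysis = analysis, modeled = modeled),
    class = "gutcod_report"
  )
}

#' @export
print.gutcod_report <- function(x, ...) {
  cat("<gutcod_report>\n\nPer-diet summaries (mean +/- SEM):\n")
  print(x$summary, n = Inf)
  cat("\nPaired crossover effects (second arm - first):\n")
  print(x$paired)
  cat("\nMeasured vs modeled metabolizable energy:\n")
  print(x$agreement)
  invisible(x)
}

#' @rdname build_report
#' @param x a `gutcod_report` object.
#' @method tidy gutcod_report
#' @export
tidy.gutcod_report <- function(x, ...) {
  x$summary
}

#' @rdname build_report
#' @method glance gutcod_report
#' @export
glance.gutcod_report <- function(x, ...) {
  x$agreement
}
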