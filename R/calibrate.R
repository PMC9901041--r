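.logit <- function(p) log(p / (1 - p))
.inv_logit <- function(x) 1 / (1 + exp(-x))

# free parameters and their unconstrained transforms
.cal_free <- c("d_ass", "d_prot", "d_fat", "k_rs", "k_nsp", "k_prot",
               "k_fat", "y_biomass", "f_ch4", "a_scfa", "e0")

.cal_encode <- function(p, free) {
  enc <- c(
    d_ass = .logit(p$d_ass), d_prot = .logit(p$d_prot),
    d_fat = .logit(p$d_fat),
    k_rs = log(p$k_rs), k_nsp = log(p$k_nsp), k_prot = log(p$k_prot),
    k_fat = log(p$k_fat),
    # (y, f) jointly constrained to the simplex y + f <= 1
    y_biomass = .logit(p$y_biomass),
    f_ch4 = .logit(p$f_ch4 / (1 - p$y_biomass)),
    a_scfa = .logit(p$a_scfa),
    e0 = log(p$e0)
  )
  enc[free]
}

.cal_decode <- function(theta, p0, free) {
  p <- p0
  full <- .cal_encode(p0, .cal_free)
  full[free] <- theta
  p$d_ass <- .inv_logit(full[["d_ass"]])
  p$d_prot <- .inv_logit(full[["d_prot"]])
  p$d_fat <- .inv_logit(full[["d_fat"]])
  p$k_rs <- exp(full[["k_rs"]])
  p$k_nsp <- exp(full[["k_nsp"]])
  p$k_prot <- exp(full[["k_prot"]])
  p$k_fat <- exp(full[["k_fat"]])
  p$y_biomass <- .inv_logit(full[["y_biomass"]])
  p$f_ch4 <- (1 - p$y_biomass) * .inv_logit(full[["f_ch4"]])
  p$a_scfa <- .inv_logit(full[["a_scfa"]])
  p$e0 <- exp(full[["e0"]])
  do.call(gut_params, p[setdiff(names(p), character(0))])
}

.cal_sub_vec <- function(d) {
  c(ass = d$cod_ass, rs = d$cod_rs, nsp = d$cod_nsp,
    protein = d$cod_protein, fat = d$cod_fat)
}

.cal_predict_targets <- function(params, diets, targets) {
  subs <- lapply(diets, .cal_sub_vec)
  purrr::map_dbl(seq_len(nrow(targets)), function(i) {
    row <- targets[i, ]
    .predict_core(params, subs[[row$diet]], row$ctt_h)[[row$quantity]]
  })
}

#' Calibrate the gut model against benchmark fluxes
#'
#' Derivative-free (Nelder-Mead) minimization of the sum of squared relative
#' errors between model predictions and a set of target fluxes, over the
#' kinetic, digestibility and yield parameters. The search runs in an
#' unconstrained transform of the parameter space (logit for fractions, log
#' for rates and the endogenous input; the biomass/methane split is encoded
#' on its simplex) and restarts from the incumbent a fixed number of times,
#' so the result is deterministic given `p0`.
#'
#' @param diets named list of one-row substrate data frames (from
#'   [partition_substrates()]); names are referenced by `targets$diet`.
#' @param targets data frame with columns `diet`, `ctt_h`, `quantity` (one
#'   of `"me_pct"`, `"scfa_absorbed_total"`, `"biomass_fecal"`) and `value`.
#' @param p0 starting [gut_params()].
#' @param free character vector of parameter names allowed to move.
#' @param maxit Nelder-Mead iteration budget per start.
#' @param restarts number of restarts from the best point found.
#' @param tol objective value considered converged.
#' @return object of class `gutcod_calibration` with elements `params`
#'   (calibrated [gut_params()]), `objective`, `fitted` (per-target tibble),
#'   `converged`, and `p0`. [tidy()] returns the per-target fit; [glance()]
#'   the objective summary.
#' @examples
#' diets <- diet_templates() |> partition_substrates()
#' diets <- split(diets, diets$diet)
#' targets <- tibble::tibble(
#'   diet = c("WD", "MBD"), ctt_h = 48,
#'   quantity = "me_pct",
#'   value = gut_predict(dplyr::bind_rows(diets[c("WD", "MBD")]),
#'                       ctt_h = 48)$me_pct
#' )
#' fit <- calibrate_gut_model(diets, targets, maxit = 200, restarts = 0)
#' glance(fit)
#' @export
calibrate_gut_model <- function(diets, targets, p0 = gut_params(),
                                free = c("d_ass", "d_prot", "d_fat", "k_rs",
                                         "k_nsp", "k_prot", "k_fat",
                                         "y_biomass", "f_ch4", "a_scfa", "e0"),
                                maxit = 2000, restarts = 3, tol = 1e-3) {
  stopifnot(is.list(diets), length(diets) >= 1)
  targets <- tibble::as_tibble(targets)
  need <- c("diet", "ctt_h", "quantity", "value")
  if (!all(need %in% names(targets))) {
    abort("calibrate_gut_model(): targets needs columns diet, ctt_h, quantity, value")
  }
  allowed <- c("me_pct", "scfa_absorbed_total", "biomass_fecal")
  if (!all(targets$quantity %in% allowed)) {
    abort(paste0("calibrate_gut_model(): quantity must be one of ",
                 paste(allowed, collapse = ", ")))
  }
  if (!all(targets$diet %in% names(diets))) {
    abort("calibrate_gut_model(): targets reference diets not in `diets`")
  }
  free <- match.arg(free, .cal_free, several.ok = TRUE)

  p0_list <- unclass(p0)[c(.cal_free, "scfa_split", "reactor")]
  objective <- function(theta) {
    params <- .cal_decode(theta, p0_list, free)
    pred <- .cal_predict_targets(params, diets, targets)
    sum(((pred - targets$value) / targets$value)^2)
  }

  theta <- .cal_encode(p0_list, free)
  best <- list(par = theta, value = objective(theta))
  for (i in seq_len(restarts + 1)) {
    fit <- optim(best$par, objective, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-12))
    if (fit$value < best$value) best <- fit
    if (best$value <= tol * 1e-3) break
  }

  params <- .cal_decode(best$par, p0_list, free)
  pred <- .cal_predict_targets(params, diets, targets)
  fitted <- dplyr::mutate(targets, fitted = pred,
                          rel_error = (pred - .data$value) / .data$value)
  converged <- best$value <= tol
  if (!converged) {
    warn(paste0("calibrate_gut_model(): objective ", format(best$value),
                " above tolerance ", format(tol),
                " after the search budget; returning best-found parameters"))
  }
  structure(
    list(params = params, objective = best$value, fitted = fitted,
         converged = converged, p0 = p0),
    class = "gutcod_calibration"
  )
}

#' @export
print.gutcod_calibration <- function(x, ...) {
  cat("<gutcod_calibration> objective", format(x$objective, digits = 4),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(x$fitted)
  invisible(x)
}

#' @rdname calibrate_gut_model
#' @param x a `gutcod_calibration` object.
#' @param ... unused.
#' @method tidy gutcod_calibration
#' @export
tidy.gutcod_calibration <- function(x, ...) {
  x$fitted
}

#' @rdname calibrate_gut_model
#' @method glance gutcod_calibration
#' @export
glance.gutcod_calibration <- function(x, ...) {
  tibble::tibble(
    objective = x$objective,
    n_targets = nrow(x$fitted),
    max_abs_rel_error = max(abs(x$fitted$rel_error)),
    converged = x$converged
  )
}

#' @rdname calibrate_gut_model
#' @param object a `gutcod_calibration` object.
#' @method autoplot gutcod_calibration
#' @export
autoplot.gutcod_calibration <- function(object, ...) {
  ggplot2::ggplot(object$fitted,
                  ggplot2::aes(x = .data$value, y = .data$fitted,
                               colour = .data$diet,
                               shape = .data$quantity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = "target flux", y = "calibrated model flux",
                  colour = "diet", shape = "quantity") +
    ggplot2::theme_minimal()
}
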