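#' Within-participant crossover comparison of the two diet arms
#'
#' Pairs each participant's value on the two arms, computes per-participant
#' differences (second arm minus first, default MBD - WD) and summarizes
#' them with a paired t statistic. In a balanced complete crossover this
#' estimates the within-participant diet effect; participants missing either
#' arm are excluded and their count reported.
#'
#' @param data data frame in long format.
#' @param value column holding the measured value (tidy-eval).
#' @param id participant identifier column.
#' @param arm treatment arm column.
#' @param arms length-2 character: reference arm first; the estimate is
#'   `arms[2] - arms[1]`.
#' @return one-row tibble: `estimate` (mean difference), `sem`, `statistic`
#'   (t), `p.value` (two-sided, n-1 df), `n_pairs`, `n_excluded`.
#' @examples
#' d <- tibble::tibble(id = rep(1:3, 2),
#'                     diet = rep(c("WD", "MBD"), each = 3),
#'                     y = c(1, 2, 3, 2, 4, 6))
#' paired_crossover(d, y, id = id, arm = diet)
#' @export
paired_crossover <- function(data, value, id = participant_id, arm = diet,
                             arms = c("WD", "MBD")) {
  wide <- data |>
    dplyr::select(id = {{ id }}, arm = {{ arm }}, value = {{ value }}) |>
    dplyr::filter(.data$arm %in% arms) |>
    tidyr::pivot_wider(names_from = "arm", values_from = "value")
  for (a in arms) if (!a %in% names(wide)) wide[[a]] <- NA_real_
  complete <- stats::complete.cases(wide[, arms])
  n_excluded <- sum(!complete)
  wide <- wide[complete, ]
  n <- nrow(wide)
  if (n < 3) {
    abort("paired_crossover(): fewer than 3 complete pairs")
  }
  diffs <- wide[[arms[2]]] - wide[[arms[1]]]
  m <- mean(diffs)
  sem <- sd(diffs) / sqrt(n)
  if (sem == 0) {
    statistic <- if (m == 0) 0 else Inf * sign(m)
    p <- if (m == 0) 1 else 0
  } else {
    statistic <- m / sem
    p <- 2 * pt(-abs(statistic), df = n - 1)
  }
  tibble::tibble(estimate = m, sem = sem, statistic = statistic,
                 p.value = p, n_pairs = n, n_excluded = n_excluded)
}

#' Bland-Altman agreement between a measured and a modeled series
#'
#' Systematic bias is the mean of the differences `y - x`; the limits of
#' agreement are `bias +/- 1.96 * sd(differences)`; proportional bias is the
#' ordinary least squares slope of the differences on the pairwise means
#' `(x + y) / 2`.
#'
#' @param x measured values.
#' @param y modeled (or second-method) values, same length and units.
#' @return object of class `bland_altman`; see [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @examples
#' ba <- bland_altman(c(10, 20, 30), 1.1 * c(10, 20, 30))
#' glance(ba)
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) {
    abort("bland_altman(): x and y must have equal length")
  }
  keep <- stats::complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) {
    abort("bland_altman(): need at least 3 complete pairs")
  }
  d <- y - x
  m <- (x + y) / 2
  bias <- mean(d)
  sd_d <- sd(d)
  slope <- if (var(m) > 0) {
    sum((m - mean(m)) * (d - bias)) / sum((m - mean(m))^2)
  } else {
    NA_real_
  }
  structure(
    list(
      data = tibble::tibble(x = x, y = y, mean = m, diff = d),
      bias = bias, sd_diff = sd_d,
      loa_low = bias - 1.96 * sd_d, loa_high = bias + 1.96 * sd_d,
      proportional_slope = slope, n = n
    ),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat("<bland_altman> n =", x$n, "| bias", signif(x$bias, 4),
      "| LoA [", signif(x$loa_low, 4), ",", signif(x$loa_high, 4),
      "] | proportional slope", signif(x$proportional_slope, 4), "\n")
  invisible(x)
}

#' @rdname bland_altman
#' @param x,object a `bland_altman` object.
#' @param ... unused.
#' @method tidy bland_altman
#' @export
tidy.bland_altman <- function(x, ...) {
  x$data
}

#' @rdname bland_altman
#' @method glance bland_altman
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(
    bias = x$bias, loa_low = x$loa_low, loa_high = x$loa_high,
    proportional_slope = x$proportional_slope, sd_diff = x$sd_diff, n = x$n
  )
}

#' @rdname bland_altman
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_hline(yintercept = object$bias, linetype = 1) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "mean of methods", y = "difference (modeled - measured)") +
    ggplot2::theme_minimal()
}

#' Lin's concordance correlation coefficient
#'
#' Agreement measure penalizing both imprecision and location/scale shift:
#' `ccc = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)` with
#' population (1/n) moments.
#'
#' @param x,y numeric vectors of equal length (>= 3), at least one with
#'   nonzero variance.
#' @return the concordance correlation coefficient, in \[-1, 1\].
#' @examples
#' lin_ccc(1:10, 1:10) # 1
#' @export
lin_ccc <- function(x, y) {
  if (length(x) != length(y)) {
    abort("lin_ccc(): x and y must have equal length")
  }
  keep <- stats::complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) {
    abort("lin_ccc(): need at least 3 complete pairs")
  }
  vx <- mean((x - mean(x))^2)
  vy <- mean((y - mean(y))^2)
  if (vx == 0 && vy == 0) {
    abort("lin_ccc(): undefined when both series are constant")
  }
  cxy <- mean((x - mean(x)) * (y - mean(y)))
  2 * cxy / (vx + vy + (mean(x) - mean(y))^2)
}

#' Incremental area under a postprandial curve (trapezoidal rule)
#'
#' Subtracts the pre-meal baseline (the mean of values at negative times,
#' unless `baseline` is supplied) and integrates the excess concentration
#' over the whole sampling grid with the trapezoidal rule. Negative
#' increments are retained (net iAUC).
#'
#' @param times sampling times in minutes, strictly increasing, length >= 2;
#'   pre-meal samples have negative times.
#' @param values concentrations at `times`.
#' @param baseline optional explicit baseline; by default the mean of
#'   pre-meal values.
#' @return net incremental area, in concentration x minutes.
#' @examples
#' trapezoid_iauc(c(0, 30, 60, 90), c(0, 10, 10, 0), baseline = 0) # 600
#' @export
trapezoid_iauc <- function(times, values, baseline = NULL) {
  if (length(times) != length(values) || length(times) < 2) {
    abort("trapezoid_iauc(): times and values must have equal length >= 2")
  }
  if (any(diff(times) <= 0)) {
    abort("trapezoid_iauc(): times must be strictly increasing")
  }
  if (is.null(baseline)) {
    pre <- values[times < 0]
    if (length(pre) == 0) {
      abort("trapezoid_iauc(): no pre-meal (negative-time) samples and no explicit baseline")
    }
    baseline <- mean(pre)
  }
  v <- values - baseline
  sum(diff(times) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
}
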