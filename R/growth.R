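## Cell-cycle and growth-curve kinetics.

#' Growth rate from cell-cycle period durations
#'
#' For a bacterial cell cycle partitioned into the B (birth-to-initiation),
#' C (chromosome replication) and D (replication-end-to-division) periods,
#' the steady-state growth rate is r = 1 / (TB + TC + TD). The B period may
#' be zero (it is skipped entirely under fast growth).
#'
#' @param TB,TC,TD period durations (min), each >= 0, summing to > 0.
#' @return growth rate r (1/min).
#' @examples
#' growthRateFromPeriods(8, 54, 34)   # 1/96 ~ 0.0104, rounds to 0.01
#' @export
growthRateFromPeriods <- function(TB, TC, TD) {
  if (any(c(TB, TC, TD) < 0))
    .stopValidation("period durations must be >= 0")
  total <- TB + TC + TD
  if (total <= 0)
    .stopValidation("total cell-cycle duration must be > 0")
  1 / total
}

#' Doubling time from a growth rate
#'
#' tau = ln(2) / r, defined for r > 0 only.
#'
#' @param object growth rate r (1/min), or a [GrowthFit-class] (for which a
#'   non-positive fitted rate yields NaN with a warning instead of an error).
#' @return doubling time tau (min).
#' @examples
#' doublingTime(0.00246)  # ~282 min
#' @export
setMethod("doublingTime", "numeric", function(object) {
  if (any(object <= 0))
    .stopValidation("doubling time is undefined for growth rate <= 0")
  log(2) / object
})

#' @rdname doublingTime
#' @export
setMethod("doublingTime", "GrowthFit", function(object) {
  if (object@rate <= 0) {
    warning("non-positive fitted rate: doubling time undefined")
    return(NaN)
  }
  log(2) / object@rate
})

#' Log-linear fit of an exponential growth curve
#'
#' Ordinary least squares of ln(counts) on time restricted to the fit
#' window (default 0-1000 min, the exponential regime of the study design):
#' ln N(t) = a + r t. The slope standard error is the classical OLS one
#' (residual normality assumed); the Pearson correlation of (t, ln N) inside
#' the window is recorded.
#'
#' @param curve a [GrowthCurve-class].
#' @param window numeric(2) fit window in minutes.
#' @return a [GrowthFit-class].
#' @examples
#' gc <- GrowthCurve(seq(0, 1000, 100), 1e6 * exp(0.0026 * seq(0, 1000, 100)))
#' fit <- fitLogLinear(gc)
#' growthRate(fit); doublingTime(fit)
#' @export
fitLogLinear <- function(curve, window = c(0, 1000)) {
  stopifnot(is(curve, "GrowthCurve"))
  if (length(window) != 2L || window[1] > window[2])
    .stopValidation("'window' must be (t_lo, t_hi) with t_lo <= t_hi")
  keep <- curve@times >= window[1] & curve@times <= window[2]
  if (sum(keep) < 3L)
    .stopValidation("need at least 3 points inside the fit window")
  t <- curve@times[keep]
  y <- log(curve@counts[keep])
  if (stats::var(t) == 0)
    .stopValidation("zero time variance inside the fit window")
  fit <- stats::lm(y ~ t)
  ## summary.lm warns on exactly exponential (zero-residual) input; the fit
  ## itself is valid there, with stderr 0
  sm <- suppressWarnings(summary(fit)$coefficients)
  pr <- stats::cor(t, y)
  new("GrowthFit",
      intercept = unname(sm[1, 1]), rate = unname(sm[2, 1]),
      stderrRate = unname(sm[2, 2]),
      pearsonR = if (is.na(pr)) NA_real_ else pr,
      window = as.numeric(window), nPoints = as.integer(sum(keep)),
      condition = curve@condition)
}

#' @rdname growthRate
#' @export
setMethod("growthRate", "GrowthFit", function(object) object@rate)

#' @rdname growthRate
#' @export
setMethod("condition", "GrowthFit", function(object) object@condition)

#' @rdname growthRate
#' @export
setMethod("condition", "GrowthCurve", function(object) object@condition)

setMethod("show", "GrowthFit", function(object) {
  tau <- if (object@rate > 0) log(2) / object@rate else NaN
  cat(sprintf(
    "GrowthFit [%s]: r = %.5f +/- %.5f 1/min (pearson %.4f), tau = %.0f min\n",
    object@condition, object@rate, object@stderrRate, object@pearsonR, tau))
  cat(sprintf("  window [%g, %g] min, %d points, intercept %.3f\n",
              object@window[1], object@window[2], object@nPoints,
              object@intercept))
})

setMethod("show", "GrowthCurve", function(object) {
  cat(sprintf("GrowthCurve [%s]: %d points, t in [%g, %g] min, N in [%.3g, %.3g]/mL\n",
              object@condition, length(object@times), min(object@times),
              max(object@times), min(object@counts), max(object@counts)))
})

#' Relative growth-rate change
#'
#' 100 * (r_new - r_ref) / r_ref, in percent.
#'
#' @param rRef reference rate (> 0).
#' @param rNew comparison rate.
#' @return percent change.
#' @examples
#' relativeRateChange(0.00246, 0.00260)  # 5.7 at one decimal
#' @export
relativeRateChange <- function(rRef, rNew) {
  if (any(rRef <= 0)) .stopValidation("'rRef' must be > 0")
  100 * (rNew - rRef) / rRef
}

#' Predicted growth speed-up from mitosis shortening
#'
#' If the mitotic phase occupies a fraction phi of the cycle time T and an
#' assisting force multiplies the division-driving force by k (so, via the
#' Stokes-flow proportionality of velocity and force, divides the mitotic
#' duration by k), the cycle shortens to T' = T * (1 - phi * (1 - 1/k)).
#' The exact rate gain is 1/(1 - phi*(1 - 1/k)) - 1; to first order in phi
#' it equals the cycle-shortening fraction phi * (1 - 1/k), and the exact
#' gain is always >= the first-order one (convexity of 1/(1 - x)).
#'
#' @param object a [MitosisSpeedupModel-class], or the mitotic fraction phi
#'   (numeric in (0, 1)) with `k` supplied.
#' @param k force ratio F0/F >= 1 (numeric method only).
#' @param ... unused.
#' @return data.frame with `cycleShorteningPct` (also the first-order rate
#'   gain) and `rateGainPct` (exact).
#' @examples
#' predictSpeedup(0.10, k = 2)  # 5% shortening, 5.26% exact rate gain
#' @export
setMethod("predictSpeedup", "MitosisSpeedupModel", function(object, ...) {
  phi <- object@mitoticFraction
  k <- object@forceRatio
  shrink <- phi * (1 - 1 / k)
  if (shrink >= 1)
    .stopValidation("degenerate cycle: phi * (1 - 1/k) must be < 1")
  data.frame(cycleShorteningPct = 100 * shrink,
             rateGainPct = 100 * (1 / (1 - shrink) - 1))
})

#' @rdname predictSpeedup
#' @export
setMethod("predictSpeedup", "numeric", function(object, k, ...) {
  predictSpeedup(MitosisSpeedupModel(mitoticFraction = object, forceRatio = k))
})

#' Compare fitted growth rates across culture conditions
#'
#' Tabulates per-condition rate, standard error, doubling time and percent
#' change versus a reference condition, and flags pairs whose
#' rate +/- 2*stderr intervals do not overlap the reference's (a coarse
#' significance screen).
#'
#' @param fits list of [GrowthFit-class] with distinct condition labels.
#' @param reference reference condition label (default "ST").
#' @return data.frame with one row per fit: `condition`, `r_per_min`,
#'   `stderr_r`, `pearson_r`, `tau_min`, `pct_change`, `distinct`.
#' @examples
#' gc1 <- GrowthCurve(seq(0, 1000, 100), 1e6 * exp(0.00246 * seq(0, 1000, 100)), "ST")
#' gc2 <- GrowthCurve(seq(0, 1000, 100), 1e6 * exp(0.00260 * seq(0, 1000, 100)), "ST+MF")
#' compareConditions(list(fitLogLinear(gc1), fitLogLinear(gc2)))
#' @export
compareConditions <- function(fits, reference = "ST") {
  if (is(fits, "GrowthFit")) fits <- list(fits)
  labs <- vapply(fits, condition, character(1))
  if (anyDuplicated(labs))
    .stopValidation("duplicate condition labels in 'fits'")
  if (!reference %in% labs)
    .stopValidation(sprintf("reference condition '%s' not present", reference))
  ref <- fits[[match(reference, labs)]]
  rows <- lapply(fits, function(f) {
    lo <- f@rate - 2 * f@stderrRate
    hi <- f@rate + 2 * f@stderrRate
    rlo <- ref@rate - 2 * ref@stderrRate
    rhi <- ref@rate + 2 * ref@stderrRate
    data.frame(condition = f@condition, r_per_min = f@rate,
               stderr_r = f@stderrRate, pearson_r = f@pearsonR,
               tau_min = if (f@rate > 0) log(2) / f@rate else NaN,
               pct_change = relativeRateChange(ref@rate, f@rate),
               distinct = (lo > rhi) || (hi < rlo))
  })
  do.call(rbind, rows)
}
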