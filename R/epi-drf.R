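#' @include AllClasses.R AllGenerics.R epi-curves.R
NULL

#' Attributable burden for one stratum
#'
#' PAF times the total attributable burden pool: the share of the outcomes'
#' DALY rate attributable to the current intake distribution relative to the
#' TMREL counterfactual.
#'
#' @param curve an [RRCurve-class].
#' @param dist an [IntakeDistribution-class].
#' @param burden_rates numeric vector of outcome burden rates,
#'   DALY per person-year (one per associated outcome; all must be >= 0).
#' @return attributable burden, DALY per person-year.
#' @export
attributableBurden <- function(curve, dist, burden_rates) {
  if (anyNA(burden_rates) || any(burden_rates < 0))
    stop("burden rates must be non-negative")
  paf(curve, dist) * sum(burden_rates)
}

#' Derive a marginal Dietary Risk Factor
#'
#' The Dietary Risk Factor for marginal consumption changes: the central
#' finite difference of the attributable burden under a rigid +/-delta g/day
#' shift of the population intake distribution,
#'
#'   DRF = (AB(+delta) - AB(-delta)) / (2 delta x 365) x 1e6   (microDALY/g)
#'
#' where AB = PAF x sum of outcome burden rates (DALY per person-year). The
#' 1/365 converts the per-(g/day) sensitivity of an annual burden into a
#' per-gram-consumed factor, and 1e6 converts DALY to microDALY. The result
#' is 0 whenever the shifted support stays inside the TMREL (no active-range
#' exposure). If the downward shift would push intakes below zero, mass is
#' clamped at zero and the result carries attribute `clamped = TRUE`.
#'
#' @param curve an [RRCurve-class].
#' @param dist an [IntakeDistribution-class].
#' @param burden_rates numeric vector of associated outcomes' burden rates,
#'   DALY per person-year.
#' @param delta perturbation, g/day; must be > 0 and small relative to the
#'   distribution spread (default 1 g/day; halving it changes the result by
#'   O(delta^2) for smooth curves).
#' @return DRF in microDALY per gram of component consumed (negative =
#'   beneficial), with logical attribute `clamped`.
#' @examples
#' cv <- RRCurve("sodium", intake = c(1, 5), rr = c(1, 2),
#'               tmrel = TMRELRange(0, 1))
#' marginalDRF(cv, intakePoint(3), burden_rates = 0.01)
#' @export
marginalDRF <- function(curve, dist, burden_rates, delta = 1) {
  if (length(delta) != 1L || !is.finite(delta) || delta <= 0)
    stop("delta must be a single positive number")
  up <- shiftIntake(dist, +delta)
  down <- shiftIntake(dist, -delta)
  clamped <- down@clamped || up@clamped
  if (clamped)
    warning("shift pushed intakes below zero; mass clamped at zero")
  abUp <- attributableBurden(curve, up, burden_rates)
  abDown <- attributableBurden(curve, down, burden_rates)
  drf <- (abUp - abDown) / (2 * delta * 365) * 1e6
  attr(drf, "clamped") <- clamped
  drf
}

#' Aggregate per-stratum DRFs with population weights
#'
#' Dietary Risk Factors are derived per (age group, sex) stratum; the
#' aggregate factor is the population-weighted mean. Weights must be
#' non-negative and sum to 1; every stratum with a DRF must have a weight.
#'
#' @param drfs named numeric vector, stratum -> DRF (microDALY/g).
#' @param weights named numeric vector, stratum -> population fraction.
#' @return the weighted-mean DRF, bounded by the stratum extremes.
#' @examples
#' aggregateStrata(c(a = 0, b = 8), c(a = 0.25, b = 0.75))  # 6
#' @export
aggregateStrata <- function(drfs, weights) {
  if (is.null(names(drfs)) || is.null(names(weights)))
    stop("drfs and weights must be named by stratum")
  missing_w <- setdiff(names(drfs), names(weights))
  if (length(missing_w))
    stop("stratum without a population weight: ",
         paste(missing_w, collapse = ", "))
  w <- weights[names(drfs)]
  if (any(w < 0)) stop("weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1 (within 1e-9)")
  sum(unname(drfs) * unname(w))
}
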