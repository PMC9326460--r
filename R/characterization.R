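#' @include AllClasses.R AllGenerics.R
NULL

#' Characterize a risk-component vector with Dietary Risk Factors
#'
#' Multiplies each inventory-flow amount d_r (g per functional unit) by its
#' Dietary Risk Factor DRF_r (microDALY per g) and sums across risk
#' components to obtain the dietary human-health impact per functional unit,
#' together with its Health Nutrient Index expression in minutes of healthy
#' life gained (`-0.526 x microDALY`). Components present in the vector but
#' missing from the DRF table are reported in the `uncharacterized` slot for
#' midpoint-level treatment; they are never silently dropped nor folded into
#' the DALY total. Components absent from the vector contribute zero.
#'
#' @param vector a [RiskComponentVector-class].
#' @param drf a [DRFTable-class].
#' @param reporting_basis optional basis the caller expects the result on; a
#'   mismatch with the vector's basis is an error (convert first with
#'   [convertFunctionalUnit()]).
#' @return a [HealthImpactResult-class].
#' @examples
#' fx <- yogurtFixture()
#' res <- dietaryImpact(resolveComponents(fx$recipe), fx$drf)
#' totalUDALY(res)   # ~ -0.93 microDALY/serving
#' heniMinutes(res)  # ~ +0.49 min healthy life gained/serving
#' @export
dietaryImpact <- function(vector, drf, reporting_basis = NULL) {
  stopifnot(is(vector, "RiskComponentVector"), is(drf, "DRFTable"))
  validObject(vector); validObject(drf)
  if (!is.null(reporting_basis) && !identical(vector@basis, reporting_basis))
    stop(sprintf("basis mismatch: vector is on '%s' but '%s' was requested; convert first",
                 vector@basis, reporting_basis))
  d <- vector@amounts
  factors <- drf@entries
  characterized <- intersect(names(d), names(factors))
  missing_drf <- setdiff(names(d), names(factors))
  udaly <- d[characterized] * factors[characterized]
  total <- sum(udaly)
  new("HealthImpactResult",
      basis = vector@basis,
      perComponentUDALY = udaly,
      totalUDALY = total,
      perComponentMinutes = -.MIN_PER_UDALY * udaly,
      heniMinutes = -.MIN_PER_UDALY * total,
      uncharacterized = missing_drf)
}

#' Split a health-impact result into beneficial and detrimental contributions
#'
#' Beneficial minutes are the summed positive per-component minute
#' contributions (negative DRFs: avoided DALYs), detrimental minutes the
#' magnitude of the negative ones (positive DRFs). By construction
#' `beneficial - detrimental == heniMinutes` exactly.
#'
#' @param result a [HealthImpactResult-class].
#' @return list with `beneficial_minutes`, `detrimental_minutes`, and `table`
#'   (`data.frame` of per-component minutes and microDALY, with direction).
#' @examples
#' fx <- yogurtFixture()
#' contributionSplit(dietaryImpact(resolveComponents(fx$recipe), fx$drf))
#' @export
contributionSplit <- function(result) {
  stopifnot(is(result, "HealthImpactResult"))
  m <- result@perComponentMinutes
  beneficial <- sum(m[m > 0])
  detrimental <- -sum(m[m < 0])
  list(
    beneficial_minutes = beneficial,
    detrimental_minutes = detrimental,
    table = data.frame(
      component = names(m),
      udaly = unname(result@perComponentUDALY),
      minutes_gained = unname(m),
      direction = ifelse(m > 0, "beneficial", ifelse(m < 0, "detrimental", "neutral")),
      stringsAsFactors = FALSE
    )
  )
}

#' Combine dietary impact with environmental damage-level impacts
#'
#' Dietary health impacts are expressed in DALYs (or avoided DALYs), so they
#' can be compared and summed directly at damage level with environmental
#' human-health impacts such as fine-particulate or climate-change damages,
#' while keeping track of each contribution. Shares are computed over the
#' absolute contributions so that beneficial (negative) and detrimental
#' contributions both count toward the denominator.
#'
#' @param dietary a [HealthImpactResult-class].
#' @param environmental `data.frame` with columns `label` and `udaly_per_fu`
#'   (microDALY per functional unit), or a named numeric vector. May be
#'   empty. All contributions must be on the dietary result's basis.
#' @param environmental_basis basis the environmental results are expressed
#'   on; must match the dietary basis.
#' @return list with `basis`, `total_udaly`, `heni_minutes`, and
#'   `contributions` (`data.frame` of label, microDALY, absolute share).
#' @examples
#' fx <- yogurtFixture()
#' res <- dietaryImpact(resolveComponents(fx$recipe), fx$drf)
#' combineWithEnvironmental(res,
#'   data.frame(label = "fine_particulate", udaly_per_fu = 0.05))
#' @export
combineWithEnvironmental <- function(dietary, environmental = NULL,
                                     environmental_basis = basis(dietary)) {
  stopifnot(is(dietary, "HealthImpactResult"))
  if (!identical(environmental_basis, dietary@basis))
    stop(sprintf("mixed functional-unit bases: dietary on '%s', environmental on '%s'",
                 dietary@basis, environmental_basis))
  if (is.null(environmental))
    environmental <- data.frame(label = character(0), udaly_per_fu = numeric(0))
  if (is.numeric(environmental) && !is.null(names(environmental)))
    environmental <- data.frame(label = names(environmental),
                                udaly_per_fu = unname(environmental))
  if (!all(c("label", "udaly_per_fu") %in% names(environmental)))
    stop("environmental contributions need `label` and `udaly_per_fu`")
  if (any(!is.finite(environmental$udaly_per_fu)))
    stop("environmental contributions must be finite")
  labels <- c("dietary", environmental$label)
  if (anyDuplicated(labels))
    stop("duplicate contribution labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  udaly <- c(dietary@totalUDALY, environmental$udaly_per_fu)
  total <- sum(udaly)
  denom <- sum(abs(udaly))
  share <- if (denom > 0) abs(udaly) / denom else rep(NA_real_, length(udaly))
  list(
    basis = dietary@basis,
    total_udaly = total,
    heni_minutes = -.MIN_PER_UDALY * total,
    contributions = data.frame(label = labels, udaly_per_fu = udaly,
                               abs_share = share, stringsAsFactors = FALSE)
  )
}
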