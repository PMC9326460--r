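#' @import methods
NULL

## ---- composition -----------------------------------------------------------

#' Recipe: ingredient masses, energies and component composition
#'
#' A recipe is an ordered list of ingredients, each with a mass per serving
#' (g), an energy per serving (kcal), an ingredient category (used by
#' double-counting exclusion rules, e.g. `"fluid_milk"`), and a composition
#' profile giving the content of each dietary risk component as a mass
#' fraction (g of component per g of ingredient).
#'
#' @slot name recipe name.
#' @slot ingredients character vector of ingredient names (ordered).
#' @slot category character vector of ingredient categories, same length.
#' @slot mass numeric, g per serving for each ingredient.
#' @slot energy numeric, kcal per serving for each ingredient.
#' @slot composition numeric matrix, ingredients x components, mass fractions
#'   (g/g); column names are registry component ids. Absent component = 0.
#' @aliases Recipe
#' @exportClass Recipe
setClass("Recipe",
  representation(
    name = "character",
    ingredients = "character",
    category = "character",
    mass = "numeric",
    energy = "numeric",
    composition = "matrix"
  )
)

setValidity("Recipe", function(object) {
  n <- length(object@ingredients)
  msg <- character()
  if (length(object@name) != 1L) msg <- c(msg, "name must be a single string")
  if (length(object@category) != n) msg <- c(msg, "category length must match ingredients")
  if (length(object@mass) != n) msg <- c(msg, "mass length must match ingredients")
  if (length(object@energy) != n) msg <- c(msg, "energy length must match ingredients")
  if (n > 0L && nrow(object@composition) != n)
    msg <- c(msg, "composition must have one row per ingredient")
  if (anyNA(object@mass) || any(object@mass < 0))
    msg <- c(msg, "ingredient masses must be non-negative")
  if (anyNA(object@energy) || any(object@energy < 0))
    msg <- c(msg, "ingredient energies must be non-negative")
  comp <- object@composition
  if (length(comp) > 0L) {
    if (is.null(colnames(comp))) msg <- c(msg, "composition must have component ids as colnames")
    if (anyNA(comp) || any(comp < 0))
      msg <- c(msg, "component contents must be non-negative mass fractions")
    if (anyDuplicated(colnames(comp)))
      msg <- c(msg, "at most one composition column per component id")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Recipe
#'
#' @param name recipe name.
#' @param ingredients `data.frame` with columns `ingredient`, `mass_g`,
#'   `energy_kcal` and optionally `category` (default `"other"`).
#' @param composition numeric matrix of mass fractions (g component per g
#'   ingredient), one row per ingredient in the same order, component ids as
#'   column names. `NULL` means no characterized components.
#' @param registry component registry; composition columns must be drawn
#'   from it.
#' @return a [Recipe-class] object.
#' @examples
#' r <- Recipe("jam",
#'   data.frame(ingredient = "berries", mass_g = 100, energy_kcal = 50),
#'   composition = matrix(0.05, 1, 1, dimnames = list(NULL, "fruits")))
#' servingMass(r)
#' @export
Recipe <- function(name, ingredients, composition = NULL,
                   registry = componentRegistry()) {
  stopifnot(is.data.frame(ingredients))
  need <- c("ingredient", "mass_g", "energy_kcal")
  if (!all(need %in% names(ingredients)))
    stop("`ingredients` must have columns: ", paste(need, collapse = ", "))
  n <- nrow(ingredients)
  category <- if ("category" %in% names(ingredients))
    as.character(ingredients$category) else rep("other", n)
  if (is.null(composition))
    composition <- matrix(numeric(0), nrow = n, ncol = 0,
                          dimnames = list(NULL, character(0)))
  composition <- as.matrix(composition)
  storage.mode(composition) <- "double"
  unknown <- setdiff(colnames(composition), componentIds(registry))
  if (length(unknown))
    stop("unknown component id(s) in composition profile: ",
         paste(unknown, collapse = ", "))
  new("Recipe",
      name = as.character(name),
      ingredients = as.character(ingredients$ingredient),
      category = category,
      mass = as.numeric(ingredients$mass_g),
      energy = as.numeric(ingredients$energy_kcal),
      composition = composition)
}

#' Risk-component inventory vector
#'
#' Amounts d_r (grams) of each dietary risk component per functional unit.
#' The functional-unit basis is one of `"serving"`, `"per100g"` (per 100 g of
#' food) or `"perkcal"` (per kcal). An absent component means 0 g.
#'
#' @slot basis functional-unit basis.
#' @slot amounts named numeric, component id -> grams per basis unit.
#' @aliases RiskComponentVector
#' @exportClass RiskComponentVector
setClass("RiskComponentVector",
  representation(basis = "character", amounts = "numeric")
)

setValidity("RiskComponentVector", function(object) {
  msg <- character()
  if (length(object@basis) != 1L || !object@basis %in% .validBases)
    msg <- c(msg, paste("basis must be one of:", paste(.validBases, collapse = ", ")))
  a <- object@amounts
  if (length(a) && (is.null(names(a)) || any(!nzchar(names(a)))))
    msg <- c(msg, "amounts must be named by component id")
  if (anyNA(a) || any(a < 0)) msg <- c(msg, "amounts must be non-negative")
  if (anyDuplicated(names(a))) msg <- c(msg, "duplicate component ids in amounts")
  if (length(msg)) msg else TRUE
})

#' Construct a RiskComponentVector
#' @param amounts named numeric vector, grams of each component per basis unit.
#' @param basis `"serving"`, `"per100g"` or `"perkcal"`.
#' @return a [RiskComponentVector-class] object.
#' @export
RiskComponentVector <- function(amounts = numeric(0), basis = "serving") {
  new("RiskComponentVector", basis = basis,
      amounts = if (length(amounts)) stats::setNames(as.numeric(amounts), names(amounts))
                else stats::setNames(numeric(0), character(0)))
}

## ---- characterization ------------------------------------------------------

#' Dietary Risk Factor table
#'
#' Characterization factors DRF_r in microDALY per gram of component
#' consumed. Negative values are beneficial (avoided DALYs), positive values
#' detrimental. Optionally stratified by age group and sex; the aggregate
#' entry is then the population-weighted mean over strata.
#'
#' @slot entries named numeric, component id -> microDALY/g.
#' @slot strata `data.frame` with columns `component_id`, `age_group`, `sex`,
#'   `drf_udaly_per_g` (zero rows when unstratified).
#' @slot provenance free-text source note.
#' @aliases DRFTable
#' @exportClass DRFTable
setClass("DRFTable",
  representation(entries = "numeric", strata = "data.frame",
                 provenance = "character")
)

setValidity("DRFTable", function(object) {
  msg <- character()
  e <- object@entries
  if (length(e) && (is.null(names(e)) || any(!nzchar(names(e)))))
    msg <- c(msg, "entries must be named by component id")
  if (anyNA(e) || any(!is.finite(e))) msg <- c(msg, "DRF values must be finite")
  if (anyDuplicated(names(e))) msg <- c(msg, "duplicate component ids in entries")
  if (nrow(object@strata) > 0L) {
    need <- c("component_id", "age_group", "sex", "drf_udaly_per_g")
    if (!all(need %in% names(object@strata)))
      msg <- c(msg, paste("strata needs columns:", paste(need, collapse = ", ")))
    else if (any(!is.finite(object@strata$drf_udaly_per_g)))
      msg <- c(msg, "stratified DRF values must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a DRFTable
#' @param entries named numeric vector of DRFs (microDALY/g).
#' @param strata optional `data.frame` with columns `component_id`,
#'   `age_group`, `sex`, `drf_udaly_per_g`.
#' @param provenance free-text source note.
#' @return a [DRFTable-class] object.
#' @export
DRFTable <- function(entries, strata = NULL, provenance = "unspecified") {
  if (is.null(strata))
    strata <- data.frame(component_id = character(0), age_group = character(0),
                         sex = character(0), drf_udaly_per_g = numeric(0),
                         stringsAsFactors = FALSE)
  new("DRFTable", entries = entries, strata = strata,
      provenance = as.character(provenance))
}

#' Dietary health-impact result
#'
#' Per-component and total dietary human-health impact for one functional
#' unit, in microDALY (positive = damage) and in Health Nutrient Index
#' minutes (positive = healthy life gained; minutes = -0.526 x microDALY).
#'
#' @slot basis functional-unit basis of the scored vector.
#' @slot perComponentUDALY named numeric, d_r x DRF_r in microDALY/FU.
#' @slot totalUDALY total microDALY/FU.
#' @slot perComponentMinutes named numeric, minutes gained per FU.
#' @slot heniMinutes total minutes of healthy life gained per FU.
#' @slot uncharacterized component ids present in the vector but lacking a
#'   DRF; surfaced for midpoint-level reporting, never folded into DALYs.
#' @exportClass HealthImpactResult
setClass("HealthImpactResult",
  representation(
    basis = "character",
    perComponentUDALY = "numeric",
    totalUDALY = "numeric",
    perComponentMinutes = "numeric",
    heniMinutes = "numeric",
    uncharacterized = "character"
  )
)

setValidity("HealthImpactResult", function(object) {
  msg <- character()
  tot <- sum(object@perComponentUDALY)
  scale <- max(abs(object@totalUDALY), abs(tot), 1e-300)
  if (abs(object@totalUDALY - tot) > 1e-9 * scale)
    msg <- c(msg, "totalUDALY must equal the sum of per-component impacts")
  if (abs(object@heniMinutes - (-.MIN_PER_UDALY * object@totalUDALY)) >
      1e-9 * max(abs(object@heniMinutes), 1e-300))
    msg <- c(msg, "heniMinutes must equal -0.526 x totalUDALY")
  if (length(object@perComponentMinutes) != length(object@perComponentUDALY) ||
      any(abs(object@perComponentMinutes +
              .MIN_PER_UDALY * object@perComponentUDALY) >
          1e-9 * pmax(abs(object@perComponentMinutes), 1e-300)))
    msg <- c(msg, "perComponentMinutes must equal -0.526 x perComponentUDALY")
  if (length(msg)) msg else TRUE
})

## ---- epidemiology ----------------------------------------------------------

#' Theoretical minimum-risk exposure level (TMREL) range
#'
#' Intake range (g/day) over which marginal consumption changes carry no
#' benefit or harm; the relative risk is clamped to 1 inside it. Either bound
#' may be infinite.
#'
#' @slot low lower bound, g/day.
#' @slot high upper bound, g/day.
#' @aliases TMRELRange
#' @exportClass TMRELRange
setClass("TMRELRange", representation(low = "numeric", high = "numeric"))

setValidity("TMRELRange", function(object) {
  if (length(object@low) != 1L || length(object@high) != 1L)
    return("low and high must be single values")
  if (is.na(object@low) || is.na(object@high)) return("bounds must not be NA")
  if (object@low > object@high) return("low must be <= high")
  TRUE
})

#' Construct a TMRELRange
#' @param low lower bound g/day (`-Inf` for unbounded below).
#' @param high upper bound g/day (`Inf` for unbounded above).
#' @return a [TMRELRange-class] object.
#' @export
TMRELRange <- function(low = -Inf, high = Inf)
  new("TMRELRange", low = as.numeric(low), high = as.numeric(high))

#' Relative-risk dose-response curve
#'
#' Piecewise log-linear relative-risk curve over daily intake, with constant
#' extrapolation beyond the outermost knots and RR clamped to 1 inside the
#' TMREL range. Log-linear interpolation is the convention for ratio-scale
#' monotone dose-response segments.
#'
#' @slot component_id the dietary risk component the curve describes.
#' @slot intake ordered knot intakes, g/day (strictly increasing).
#' @slot rr relative risk at each knot (> 0).
#' @slot tmrel a [TMRELRange-class].
#' @aliases RRCurve
#' @exportClass RRCurve
setClass("RRCurve",
  representation(component_id = "character", intake = "numeric",
                 rr = "numeric", tmrel = "TMRELRange")
)

setValidity("RRCurve", function(object) {
  msg <- character()
  if (length(object@intake) < 1L) msg <- c(msg, "at least one knot required")
  if (length(object@intake) != length(object@rr))
    msg <- c(msg, "intake and rr must have equal length")
  if (anyNA(object@intake) || any(object@intake < 0))
    msg <- c(msg, "knot intakes must be non-negative")
  if (is.unsorted(object@intake, strictly = TRUE))
    msg <- c(msg, "knot intakes must be strictly increasing")
  if (anyNA(object@rr) || any(object@rr <= 0))
    msg <- c(msg, "relative risks must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct an RRCurve
#' @param component_id component the curve refers to.
#' @param intake knot intakes, g/day, strictly increasing.
#' @param rr relative risks at the knots (> 0).
#' @param tmrel a [TMRELRange-class]; RR is 1 inside it.
#' @return an [RRCurve-class] object.
#' @examples
#' cv <- RRCurve("sodium", intake = c(1, 5), rr = c(1, 2),
#'               tmrel = TMRELRange(-Inf, 1))
#' rrEvaluate(cv, 3)
#' @export
RRCurve <- function(component_id, intake, rr, tmrel = TMRELRange()) {
  new("RRCurve", component_id = as.character(component_id),
      intake = as.numeric(intake), rr = as.numeric(rr), tmrel = tmrel)
}

#' Population intake distribution
#'
#' Daily-intake distribution of a population for one risk component. Three
#' representations: a point mass (everyone consumes the same amount), a
#' histogram of uniform-density bins, or a lognormal. A rigid location shift
#' (diet scenarios, marginal perturbations) is carried in `shift`; mass that
#' a negative shift would push below zero intake is lumped at zero and the
#' `clamped` flag is raised.
#'
#' @slot type `"point"`, `"histogram"` or `"lognormal"`.
#' @slot value point-mass intake (g/day), `"point"` only.
#' @slot bins `data.frame(lower, upper, prob)`, `"histogram"` only.
#' @slot meanlog,sdlog lognormal parameters, `"lognormal"` only.
#' @slot shift rigid location shift applied to the base distribution, g/day.
#' @slot clamped whether shifting truncated mass at zero intake.
#' @aliases IntakeDistribution
#' @exportClass IntakeDistribution
setClass("IntakeDistribution",
  representation(type = "character", value = "numeric", bins = "data.frame",
                 meanlog = "numeric", sdlog = "numeric", shift = "numeric",
                 clamped = "logical")
)

setValidity("IntakeDistribution", function(object) {
  msg <- character()
  if (!object@type %in% c("point", "histogram", "lognormal"))
    return("type must be 'point', 'histogram' or 'lognormal'")
  if (object@type == "point") {
    if (length(object@value) != 1L || is.na(object@value) || object@value < 0)
      msg <- c(msg, "point mass requires a single non-negative intake")
  }
  if (object@type == "histogram") {
    b <- object@bins
    if (!all(c("lower", "upper", "prob") %in% names(b)))
      return("histogram bins need columns lower, upper, prob")
    if (any(b$lower < 0)) msg <- c(msg, "intake support must be non-negative")
    if (any(b$upper < b$lower)) msg <- c(msg, "bin upper must be >= lower")
    if (any(b$prob < 0)) msg <- c(msg, "bin probabilities must be non-negative")
    if (abs(sum(b$prob) - 1) > 1e-9)
      msg <- c(msg, "bin probabilities must sum to 1 (within 1e-9)")
  }
  if (object@type == "lognormal") {
    if (!is.finite(object@meanlog) || !is.finite(object@sdlog) || object@sdlog <= 0)
      msg <- c(msg, "lognormal requires finite meanlog and positive sdlog")
  }
  if (length(msg)) msg else TRUE
})

.newIntake <- function(type, value = NA_real_, bins = NULL,
                       meanlog = NA_real_, sdlog = NA_real_,
                       shift = 0, clamped = FALSE) {
  if (is.null(bins))
    bins <- data.frame(lower = numeric(0), upper = numeric(0), prob = numeric(0))
  new("IntakeDistribution", type = type, value = value, bins = bins,
      meanlog = meanlog, sdlog = sdlog, shift = shift, clamped = clamped)
}

#' Point-mass intake distribution
#' @param value intake, g/day.
#' @return an [IntakeDistribution-class].
#' @export
intakePoint <- function(value) .newIntake("point", value = as.numeric(value))

#' Histogram intake distribution (uniform-density bins)
#' @param lower,upper bin edges, g/day.
#' @param prob probability mass per bin; must sum to 1.
#' @return an [IntakeDistribution-class].
#' @export
intakeHistogram <- function(lower, upper, prob)
  .newIntake("histogram",
             bins = data.frame(lower = as.numeric(lower),
                               upper = as.numeric(upper),
                               prob = as.numeric(prob)))

#' Lognormal intake distribution
#' @param meanlog,sdlog parameters on the log scale.
#' @return an [IntakeDistribution-class].
#' @export
intakeLognormal <- function(meanlog, sdlog)
  .newIntake("lognormal", meanlog = as.numeric(meanlog), sdlog = as.numeric(sdlog))

## ---- scenarios -------------------------------------------------------------

#' Diet-change scenario
#'
#' A named set of signed shifts in population mean daily intake (g/day) for
#' registry components, describing a substantial (non-marginal) diet change.
#'
#' @slot name scenario name.
#' @slot shifts named numeric, component id -> change in mean intake, g/day.
#' @aliases DietScenario
#' @exportClass DietScenario
setClass("DietScenario",
  representation(name = "character", shifts = "numeric"))

setValidity("DietScenario", function(object) {
  msg <- character()
  s <- object@shifts
  if (length(s) && (is.null(names(s)) || any(!nzchar(names(s)))))
    msg <- c(msg, "shifts must be named by component id")
  if (anyNA(s) || any(!is.finite(s))) msg <- c(msg, "shifts must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a DietScenario
#' @param name scenario name.
#' @param shifts named numeric vector of intake shifts, g/day (signed).
#' @param registry component registry the shift names must belong to.
#' @return a [DietScenario-class] object.
#' @export
DietScenario <- function(name, shifts, registry = componentRegistry()) {
  unknown <- setdiff(names(shifts), componentIds(registry))
  if (length(unknown))
    stop("unknown component id(s) in scenario shifts: ",
         paste(unknown, collapse = ", "))
  new("DietScenario", name = as.character(name), shifts = shifts)
}
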