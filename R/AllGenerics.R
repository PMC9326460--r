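#' @include AllClasses.R
NULL

#' Total mass of a recipe serving
#' @param x a [Recipe-class].
#' @return grams per serving (sum of ingredient masses; exact sum, no
#'   renormalization).
#' @export
setGeneric("servingMass", function(x) standardGeneric("servingMass"))

#' @rdname servingMass
#' @export
setMethod("servingMass", "Recipe", function(x) sum(x@mass))

#' Total energy of a recipe serving
#' @param x a [Recipe-class].
#' @return kcal per serving (sum of ingredient energies).
#' @export
setGeneric("servingEnergy", function(x) standardGeneric("servingEnergy"))

#' @rdname servingEnergy
#' @export
setMethod("servingEnergy", "Recipe", function(x) sum(x@energy))

#' Ingredient table of a recipe
#' @param x a [Recipe-class].
#' @return `data.frame` with columns `ingredient`, `category`, `mass_g`,
#'   `energy_kcal`.
#' @export
setGeneric("ingredientTable", function(x) standardGeneric("ingredientTable"))

#' @rdname ingredientTable
#' @export
setMethod("ingredientTable", "Recipe", function(x)
  data.frame(ingredient = x@ingredients, category = x@category,
             mass_g = x@mass, energy_kcal = x@energy,
             stringsAsFactors = FALSE))

#' Composition matrix of a recipe
#' @param x a [Recipe-class].
#' @return numeric matrix of mass fractions (g/g), ingredients x components.
#' @export
setGeneric("composition", function(x) standardGeneric("composition"))

#' @rdname composition
#' @export
setMethod("composition", "Recipe", function(x) x@composition)

#' Functional-unit basis
#' @param x a [RiskComponentVector-class] or [HealthImpactResult-class].
#' @return `"serving"`, `"per100g"` or `"perkcal"`.
#' @export
setGeneric("basis", function(x) standardGeneric("basis"))

#' @rdname basis
#' @export
setMethod("basis", "RiskComponentVector", function(x) x@basis)

#' @rdname basis
#' @export
setMethod("basis", "HealthImpactResult", function(x) x@basis)

#' Component amounts of a risk vector
#' @param x a [RiskComponentVector-class].
#' @return named numeric vector, grams per functional unit.
#' @export
setGeneric("amounts", function(x) standardGeneric("amounts"))

#' @rdname amounts
#' @export
setMethod("amounts", "RiskComponentVector", function(x) x@amounts)

#' DRF entries
#' @param x a [DRFTable-class].
#' @return named numeric vector, microDALY per gram.
#' @export
setGeneric("drfEntries", function(x) standardGeneric("drfEntries"))

#' @rdname drfEntries
#' @export
setMethod("drfEntries", "DRFTable", function(x) x@entries)

#' Total dietary impact in microDALY per functional unit
#' @param x a [HealthImpactResult-class].
#' @return microDALY per functional unit (positive = damage).
#' @export
setGeneric("totalUDALY", function(x) standardGeneric("totalUDALY"))

#' @rdname totalUDALY
#' @export
setMethod("totalUDALY", "HealthImpactResult", function(x) x@totalUDALY)

#' Per-component impacts in microDALY per functional unit
#' @param x a [HealthImpactResult-class].
#' @return named numeric vector.
#' @export
setGeneric("perComponentUDALY", function(x) standardGeneric("perComponentUDALY"))

#' @rdname perComponentUDALY
#' @export
setMethod("perComponentUDALY", "HealthImpactResult", function(x) x@perComponentUDALY)

#' Per-component Health Nutrient Index minutes
#' @param x a [HealthImpactResult-class].
#' @return named numeric vector, minutes gained per functional unit.
#' @export
setGeneric("perComponentMinutes", function(x) standardGeneric("perComponentMinutes"))

#' @rdname perComponentMinutes
#' @export
setMethod("perComponentMinutes", "HealthImpactResult", function(x) x@perComponentMinutes)

#' Health Nutrient Index in minutes of healthy life gained
#'
#' Converts a dietary impact in microDALY to Health Nutrient Index minutes:
#' `minutes = -0.526 x microDALY`. One DALY is a year of healthy life and a
#' year holds ~0.526 million minutes, so 1 microDALY is 0.526 minutes; the
#' leading minus makes positive minutes mean healthy life gained. A strictly
#' decreasing linear map with an exact sign flip.
#'
#' @param x total impact in microDALY per functional unit (numeric), or a
#'   [HealthImpactResult-class] whose stored score is returned.
#' @return minutes of healthy life gained per functional unit.
#' @examples
#' heniMinutes(-0.925)  # ~ +0.49 minutes gained
#' heniMinutes(1)       # -0.526 minutes
#' @export
setGeneric("heniMinutes", function(x) standardGeneric("heniMinutes"))

#' @rdname heniMinutes
#' @export
setMethod("heniMinutes", "numeric", function(x) {
  if (anyNA(x) || any(!is.finite(x))) stop("impact must be finite")
  -.MIN_PER_UDALY * x
})

#' @rdname heniMinutes
#' @export
setMethod("heniMinutes", "HealthImpactResult", function(x) x@heniMinutes)

#' Components without a characterization factor
#' @param x a [HealthImpactResult-class].
#' @return character vector of component ids present in the scored vector but
#'   absent from the DRF table; candidates for midpoint-level reporting.
#' @export
setGeneric("uncharacterized", function(x) standardGeneric("uncharacterized"))

#' @rdname uncharacterized
#' @export
setMethod("uncharacterized", "HealthImpactResult", function(x) x@uncharacterized)

#' Mean daily intake of a distribution
#' @param x an [IntakeDistribution-class].
#' @return mean intake, g/day (after any shift and zero-clamping).
#' @export
setGeneric("meanIntake", function(x) standardGeneric("meanIntake"))

## ---- show methods ----------------------------------------------------------

setMethod("show", "Recipe", function(object) {
  cat(sprintf("Recipe \"%s\": %d ingredient(s), %.1f g, %.1f kcal per serving\n",
              object@name, length(object@ingredients),
              sum(object@mass), sum(object@energy)))
  if (length(object@ingredients)) print(ingredientTable(object))
  if (ncol(object@composition))
    cat("components:", paste(colnames(object@composition), collapse = ", "), "\n")
})

setMethod("show", "RiskComponentVector", function(object) {
  cat(sprintf("RiskComponentVector (basis: %s)\n", object@basis))
  if (length(object@amounts)) {
    df <- data.frame(component = names(object@amounts), g = unname(object@amounts))
    print(df, row.names = FALSE)
  } else cat("  (all components zero)\n")
})

setMethod("show", "DRFTable", function(object) {
  cat(sprintf("DRFTable: %d component(s)%s [%s]\n", length(object@entries),
              if (nrow(object@strata)) sprintf(", %d strata rows", nrow(object@strata)) else "",
              object@provenance))
  if (length(object@entries))
    print(data.frame(component = names(object@entries),
                     drf_udaly_per_g = unname(object@entries)), row.names = FALSE)
})

setMethod("show", "HealthImpactResult", function(object) {
  cat(sprintf("HealthImpactResult (basis: %s)\n", object@basis))
  if (length(object@perComponentUDALY))
    print(data.frame(component = names(object@perComponentUDALY),
                     udaly = unname(object@perComponentUDALY),
                     min_gained = unname(object@perComponentMinutes)),
          row.names = FALSE)
  cat(sprintf("total: %.4f uDALY/FU | HENI: %+.2f min healthy life gained/FU\n",
              object@totalUDALY, object@heniMinutes))
  if (length(object@uncharacterized))
    cat("uncharacterized (midpoint-level):",
        paste(object@uncharacterized, collapse = ", "), "\n")
})

setMethod("show", "RRCurve", function(object) {
  cat(sprintf("RRCurve [%s]: %d knot(s), TMREL [%g, %g] g/day\n",
              object@component_id, length(object@intake),
              object@tmrel@low, object@tmrel@high))
})

setMethod("show", "IntakeDistribution", function(object) {
  cat(sprintf("IntakeDistribution (%s), mean %.3f g/day%s%s\n", object@type,
              meanIntake(object),
              if (object@shift != 0) sprintf(", shift %+g", object@shift) else "",
              if (object@clamped) ", clamped at zero" else ""))
})

setMethod("show", "DietScenario", function(object) {
  cat(sprintf("DietScenario \"%s\": %d shift(s)\n", object@name,
              length(object@shifts)))
  if (length(object@shifts))
    print(data.frame(component = names(object@shifts),
                     shift_g_per_day = unname(object@shifts)), row.names = FALSE)
})
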