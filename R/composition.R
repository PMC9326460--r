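#' @include AllClasses.R AllGenerics.R
NULL

#' Resolve a recipe into risk-component inventory flows
#'
#' Computes the amount d_r of each dietary risk component delivered by one
#' serving of a recipe: for every component, the sum over ingredients of
#' ingredient mass times component content (mass fraction). Declarative
#' exclusion rules zero the contribution of (ingredient category, component)
#' pairs to avoid double counting — e.g. calcium is excluded for fluid milk
#' because milk itself is a risk component, while yogurt is not considered
#' milk and its calcium counts.
#'
#' @param recipe a [Recipe-class].
#' @param exclusions `data.frame` with columns `category`, `component_id`;
#'   default [defaultExclusionRules()]. Use a zero-row data.frame for none.
#' @param registry component registry used to validate identifiers.
#' @return a [RiskComponentVector-class] on the serving basis.
#' @examples
#' fx <- yogurtFixture()
#' resolveComponents(fx$recipe)
#' @export
resolveComponents <- function(recipe, exclusions = defaultExclusionRules(),
                              registry = componentRegistry()) {
  stopifnot(is(recipe, "Recipe"))
  validObject(recipe)
  comp <- recipe@composition
  known <- componentIds(registry)
  unknown <- setdiff(colnames(comp), known)
  if (length(unknown))
    stop("unknown component id(s) in composition profile: ",
         paste(unknown, collapse = ", "))
  if (nrow(exclusions) > 0L) {
    if (!all(c("category", "component_id") %in% names(exclusions)))
      stop("exclusion rules need columns `category` and `component_id`")
    bad <- setdiff(exclusions$component_id, known)
    if (length(bad))
      stop("exclusion rule references unknown component id(s): ",
           paste(bad, collapse = ", "))
  }
  if (length(recipe@ingredients) == 0L || ncol(comp) == 0L)
    return(RiskComponentVector(basis = "serving"))

  mask <- matrix(1, nrow = nrow(comp), ncol = ncol(comp),
                 dimnames = dimnames(comp))
  if (nrow(exclusions) > 0L) {
    for (k in seq_len(nrow(exclusions))) {
      cid <- exclusions$component_id[k]
      if (cid %in% colnames(mask))
        mask[recipe@category == exclusions$category[k], cid] <- 0
    }
  }
  amounts <- colSums(recipe@mass * comp * mask)
  RiskComponentVector(amounts = amounts, basis = "serving")
}

#' Mass and energy totals of a recipe
#'
#' Componentwise exact sums over ingredients — no renormalization.
#'
#' @param recipe a [Recipe-class].
#' @return named numeric `c(mass_g = ..., energy_kcal = ...)`.
#' @examples
#' recipeTotals(yogurtFixture()$recipe)  # 170 g, 127.4 kcal
#' @export
recipeTotals <- function(recipe) {
  stopifnot(is(recipe, "Recipe"))
  validObject(recipe)
  c(mass_g = sum(recipe@mass), energy_kcal = sum(recipe@energy))
}

#' Convert a risk-component vector between functional units
#'
#' Functional-unit bases supported: `"serving"`, `"per100g"` (per 100 g of
#' food as consumed) and `"perkcal"`. Conversion always rescales through the
#' serving basis: serving -> per100g multiplies every amount by
#' `100 / serving_mass`; serving -> perkcal by `1 / serving_energy`.
#' Conversions compose and invert consistently (round trips reproduce the
#' input to machine precision).
#'
#' @param vector a [RiskComponentVector-class].
#' @param target one of `"serving"`, `"per100g"`, `"perkcal"`.
#' @param serving_mass serving mass, g (required whenever per100g is involved).
#' @param serving_energy serving energy, kcal (required whenever perkcal is
#'   involved).
#' @return a [RiskComponentVector-class] on the target basis.
#' @examples
#' v <- RiskComponentVector(c(sodium = 0.114), "serving")
#' convertFunctionalUnit(v, "per100g", serving_mass = 170)  # 0.06706 g/100 g
#' @export
convertFunctionalUnit <- function(vector, target,
                                  serving_mass = NULL, serving_energy = NULL) {
  stopifnot(is(vector, "RiskComponentVector"))
  target <- match.arg(target, .validBases)
  from <- vector@basis
  if (from == target) return(vector)

  # factor taking a basis to the serving basis
  toServing <- function(b) {
    switch(b,
      serving = 1,
      per100g = {
        if (is.null(serving_mass) || !is.finite(serving_mass) || serving_mass <= 0)
          stop("per100g conversion needs serving_mass > 0 (degenerate denominator otherwise)")
        serving_mass / 100
      },
      perkcal = {
        if (is.null(serving_energy) || !is.finite(serving_energy) || serving_energy <= 0)
          stop("perkcal conversion needs serving_energy > 0 (degenerate denominator otherwise)")
        serving_energy
      })
  }
  factor <- toServing(from) / toServing(target)
  RiskComponentVector(amounts = vector@amounts * factor, basis = target)
}
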