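#' Dietary risk component registry
#'
#' The Global Burden of Disease (GBD) framework attaches health effects to a
#' fixed list of dietary risk components: beneficial ones (fluid milk, nuts
#' and seeds, fruits, calcium, seafood omega-3 fatty acids, fiber, and
#' polyunsaturated fatty acids) and detrimental ones (processed meat, red
#' meat, trans fatty acids, sugar-sweetened beverages, and sodium). Fiber
#' from fruits, vegetables, legumes and whole grains carries its own
#' dose-response evidence and is therefore registered separately from fiber
#' of other origin, each with its own characterization factor.
#'
#' All amounts are standardized in grams of component per functional unit.
#' Sugar-sweetened beverages are accounted in beverage grams (not sugar
#' grams); this convention is provisional and recorded here so downstream
#' Dietary Risk Factors must be expressed on the same basis.
#'
#' @param extra optional `data.frame` with columns `component_id`, `label`,
#'   `direction` (`"beneficial"` or `"detrimental"`) to append user-defined
#'   components (e.g. midpoint-level nutrients).
#' @return `data.frame` with columns `component_id`, `label`, `direction`.
#' @examples
#' componentRegistry()
#' @export
componentRegistry <- function(extra = NULL) {
  reg <- data.frame(
    component_id = c(
      "fluid_milk", "nuts_seeds", "fruits", "calcium", "seafood_omega3",
      "fiber_fruit", "fiber_other", "pufa",
      "processed_meat", "red_meat", "tfa", "ssb", "sodium"
    ),
    label = c(
      "Fluid milk", "Nuts and seeds", "Fruits", "Calcium",
      "Seafood omega-3 fatty acids",
      "Fiber (fruits, vegetables, legumes, whole grains)",
      "Fiber (other sources)", "Polyunsaturated fatty acids",
      "Processed meat", "Red meat", "Trans fatty acids",
      "Sugar-sweetened beverages (beverage grams)", "Sodium"
    ),
    direction = c(rep("beneficial", 8L), rep("detrimental", 5L)),
    stringsAsFactors = FALSE
  )
  if (!is.null(extra)) {
    need <- c("component_id", "label", "direction")
    if (!all(need %in% names(extra)))
      stop("`extra` must have columns: ", paste(need, collapse = ", "))
    if (any(extra$component_id %in% reg$component_id))
      stop("`extra` redefines built-in component ids: ",
           paste(intersect(extra$component_id, reg$component_id), collapse = ", "))
    if (!all(extra$direction %in% c("beneficial", "detrimental")))
      stop("`direction` must be 'beneficial' or 'detrimental'")
    reg <- rbind(reg, extra[, need])
  }
  reg
}

#' Known component identifiers
#' @param registry registry `data.frame` as returned by [componentRegistry()].
#' @return character vector of valid component ids.
#' @export
componentIds <- function(registry = componentRegistry()) registry$component_id

#' Default double-counting exclusion rules
#'
#' Declarative (ingredient category, component) pairs whose contribution is
#' zeroed when resolving a recipe, to avoid counting the same exposure twice.
#' The GBD treats fluid milk itself as a risk component, so the calcium it
#' contains must not also be counted; fermented dairy such as yogurt is not
#' considered milk, so its calcium does count.
#'
#' @return `data.frame` with columns `category`, `component_id`.
#' @examples
#' defaultExclusionRules()
#' @export
defaultExclusionRules <- function() {
  data.frame(
    category = "fluid_milk",
    component_id = "calcium",
    stringsAsFactors = FALSE
  )
}

#' Functional-unit bases
#' @keywords internal
.validBases <- c("serving", "per100g", "perkcal")

#' Minutes of healthy life per microDALY
#'
#' One DALY is one year of healthy life; a year holds about 0.526 million
#' minutes (525,960), so 1 microDALY corresponds to 0.526 minutes. The Health
#' Nutrient Index applies a leading minus so that positive minutes mean
#' healthy life gained.
#' @keywords internal
.MIN_PER_UDALY <- 0.526
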