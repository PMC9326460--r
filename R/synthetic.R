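#' @include AllClasses.R AllGenerics.R composition.R characterization.R
NULL

#' Generate a synthetic recipe, DRF table and independently computed result
#'
#' Draws a random but realistic recipe and characterization table for
#' testing: ingredient masses uniform on 5-200 g (typical recipe ingredient
#' range), energies 0-4 kcal per g of ingredient (the physiological energy
#' density range from water to pure fat), component contents uniform on
#' 0-0.2 g/g with ~50% structural zeros (composition profiles are sparse),
#' and DRFs uniform on -6 to +14 microDALY/g (the span of published
#' beneficial to detrimental factors). The expected health impact is
#' computed by an independent plain-loop summation, deliberately separate
#' from the package's matrix code path, so generator and pipeline cross-check
#' each other. Same seed, same output.
#'
#' @param seed integer random seed.
#' @param n_ingredients number of ingredients (>= 0).
#' @param n_components number of distinct risk components to draw from the
#'   registry.
#' @param registry component registry to sample component ids from.
#' @return list with `recipe` ([Recipe-class]), `drf` ([DRFTable-class]) and
#'   `expected` ([HealthImpactResult-class] from the independent summation,
#'   serving basis, no exclusion rules).
#' @examples
#' syn <- generateSynthetic(seed = 7, n_ingredients = 4)
#' totalUDALY(syn$expected)
#' @export
generateSynthetic <- function(seed, n_ingredients = 5L, n_components = 6L,
                              registry = componentRegistry()) {
  stopifnot(n_ingredients >= 0L, n_components >= 1L)
  set.seed(seed)
  ids <- sample(componentIds(registry), n_components)
  drf <- DRFTable(stats::setNames(stats::runif(n_components, -6, 14), ids),
                  provenance = sprintf("synthetic (seed %d)", seed))

  if (n_ingredients == 0L) {
    recipe <- Recipe("synthetic recipe",
                     data.frame(ingredient = character(0),
                                mass_g = numeric(0), energy_kcal = numeric(0)),
                     registry = registry)
    expected <- new("HealthImpactResult", basis = "serving",
                    perComponentUDALY = stats::setNames(numeric(0), character(0)),
                    totalUDALY = 0,
                    perComponentMinutes = stats::setNames(numeric(0), character(0)),
                    heniMinutes = 0, uncharacterized = character(0))
    return(list(recipe = recipe, drf = drf, expected = expected))
  }

  mass <- stats::runif(n_ingredients, 5, 200)
  energy <- mass * stats::runif(n_ingredients, 0, 4)
  content <- matrix(stats::runif(n_ingredients * n_components, 0, 0.2),
                    nrow = n_ingredients,
                    dimnames = list(NULL, ids))
  content[matrix(stats::runif(length(content)) < 0.5, nrow = n_ingredients)] <- 0
  recipe <- Recipe("synthetic recipe",
                   data.frame(ingredient = paste0("ingredient_", seq_len(n_ingredients)),
                              mass_g = mass, energy_kcal = energy,
                              stringsAsFactors = FALSE),
                   content, registry = registry)

  # independent expected result: explicit loops, no matrix algebra, no reuse
  # of resolveComponents()/dietaryImpact()
  factors <- drfEntries(drf)
  udaly <- stats::setNames(numeric(n_components), ids)
  for (cid in ids) {
    d <- 0
    for (i in seq_len(n_ingredients)) d <- d + mass[i] * content[i, cid]
    udaly[cid] <- d * factors[[cid]]
  }
  total <- 0
  for (cid in ids) total <- total + udaly[[cid]]
  expected <- new("HealthImpactResult", basis = "serving",
                  perComponentUDALY = udaly,
                  totalUDALY = total,
                  perComponentMinutes = -.MIN_PER_UDALY * udaly,
                  heniMinutes = -.MIN_PER_UDALY * total,
                  uncharacterized = character(0))
  list(recipe = recipe, drf = drf, expected = expected)
}
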