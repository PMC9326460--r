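# shared generators for property-style tests

# random recipe-free component vector + matching DRF table
randomVectorAndDRF <- function(seed, n = 5L) {
  set.seed(seed)
  ids <- sample(componentIds(), n)
  list(
    vec = RiskComponentVector(stats::setNames(runif(n, 0, 10), ids), "serving"),
    drf = DRFTable(stats::setNames(runif(n, -6, 14), ids))
  )
}

# small random recipe for permutation/additivity properties
randomRecipe <- function(seed, n = 4L) {
  set.seed(seed)
  ids <- sample(componentIds(), 3L)
  comp <- matrix(runif(n * 3L, 0, 0.3), nrow = n, dimnames = list(NULL, ids))
  Recipe(paste0("r", seed),
         data.frame(ingredient = paste0("i", seq_len(n)),
                    mass_g = runif(n, 1, 150), energy_kcal = runif(n, 0, 200),
                    stringsAsFactors = FALSE),
         comp)
}

permuteRecipe <- function(recipe, perm) {
  it <- ingredientTable(recipe)[perm, ]
  Recipe(recipe@name, it, composition(recipe)[perm, , drop = FALSE])
}

# log-linear test curve rising as exp(beta * (x - t)) above a TMREL at [0, t]
expCurve <- function(t = 1, beta = 0.3, span = 10, component = "sodium") {
  RRCurve(component, intake = c(t, t + span), rr = c(1, exp(beta * span)),
          tmrel = TMRELRange(0, t))
}
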