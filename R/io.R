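#' @include AllClasses.R AllGenerics.R composition.R characterization.R
NULL

# Composition tables and DRF tables in the wild use a typographic en-dash or
# unicode minus for negative values; normalize before numeric conversion.
.normalizeMinus <- function(x) {
  x <- gsub("–", "-", x)
  gsub("−", "-", x)
}

.numericOrStop <- function(x, what, lines) {
  x <- .normalizeMinus(trimws(x))
  x[x == ""] <- "0"
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out))
  if (length(bad))
    stop(sprintf("non-numeric %s at line %s of input", what,
                 paste(lines[bad], collapse = ", ")))
  out
}

#' Read a recipe from CSV or JSON
#'
#' CSV dialect: UTF-8, comma-separated, period decimal separator, header
#' `ingredient,mass_g,energy_kcal[,category],<component_id>...` where the
#' component columns give contents in g per 100 g of ingredient (the form
#' composition databases publish); they are converted to mass fractions at
#' parse time. The JSON mirror declares its content basis explicitly
#' (`"per_100g"` or `"mass_fraction"`). Malformed rows are rejected with
#' their line number.
#'
#' @param path path to a `.csv` or `.json` recipe file.
#' @param name recipe name; defaults to the file name without extension.
#' @param registry component registry the component columns must belong to.
#' @return a [Recipe-class].
#' @export
readRecipe <- function(path, name = NULL,
                       registry = componentRegistry()) {
  if (!file.exists(path)) stop("recipe file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]+$", "", basename(path))
  if (grepl("\\.json$", path, ignore.case = TRUE))
    return(.readRecipeJSON(path, name, registry))

  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  need <- c("ingredient", "mass_g", "energy_kcal")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("recipe CSV missing header column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(names(df)))
    stop("duplicate column(s) in recipe CSV: ",
         paste(unique(names(df)[duplicated(names(df))]), collapse = ", "))
  lines <- seq_len(nrow(df)) + 1L  # +1 for the header row
  compCols <- setdiff(names(df), c(need, "category"))
  unknown <- setdiff(compCols, componentIds(registry))
  if (length(unknown))
    stop("unknown component id(s) in recipe CSV header: ",
         paste(unknown, collapse = ", "))

  mass <- .numericOrStop(df$mass_g, "mass_g", lines)
  energy <- .numericOrStop(df$energy_kcal, "energy_kcal", lines)
  if (any(mass < 0))
    stop("negative mass_g at line ", paste(lines[mass < 0], collapse = ", "))
  if (any(energy < 0))
    stop("negative energy_kcal at line ", paste(lines[energy < 0], collapse = ", "))

  comp <- matrix(0, nrow = nrow(df), ncol = length(compCols),
                 dimnames = list(NULL, compCols))
  for (cc in compCols) {
    v <- .numericOrStop(df[[cc]], paste0("'", cc, "' content"), lines)
    if (any(v < 0))
      stop(sprintf("negative content for '%s' at line %s", cc,
                   paste(lines[v < 0], collapse = ", ")))
    comp[, cc] <- v / 100  # g per 100 g -> mass fraction
  }
  ing <- data.frame(ingredient = df$ingredient, mass_g = mass,
                    energy_kcal = energy, stringsAsFactors = FALSE)
  if ("category" %in% names(df)) ing$category <- df$category
  Recipe(name, ing, comp, registry = registry)
}

.readRecipeJSON <- function(path, name, registry) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(x$content_basis) ||
      !x$content_basis %in% c("per_100g", "mass_fraction"))
    stop("recipe JSON must declare content_basis: 'per_100g' or 'mass_fraction'")
  scale <- if (x$content_basis == "per_100g") 1 / 100 else 1
  if (!is.null(x$name)) name <- x$name
  ings <- x$ingredients
  n <- length(ings)
  compIds <- unique(unlist(lapply(ings, function(i) names(i$composition))))
  comp <- matrix(0, nrow = n, ncol = length(compIds),
                 dimnames = list(NULL, compIds))
  ing <- data.frame(ingredient = character(n), mass_g = numeric(n),
                    energy_kcal = numeric(n), category = character(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    e <- ings[[i]]
    if (is.null(e$ingredient) || is.null(e$mass_g) || is.null(e$energy_kcal))
      stop("recipe JSON ingredient ", i,
           " must have fields ingredient, mass_g, energy_kcal")
    ing$ingredient[i] <- e$ingredient
    ing$mass_g[i] <- as.numeric(e$mass_g)
    ing$energy_kcal[i] <- as.numeric(e$energy_kcal)
    ing$category[i] <- if (is.null(e$category)) "other" else e$category
    for (cc in names(e$composition))
      comp[i, cc] <- as.numeric(e$composition[[cc]]) * scale
  }
  Recipe(name, ing, comp, registry = registry)
}

#' Write a recipe to JSON (lossless, full precision)
#'
#' Serializes on the mass-fraction content basis so that
#' `readRecipe(writeRecipe(r, f))` reproduces `r` exactly.
#'
#' @param recipe a [Recipe-class].
#' @param path output path (`.json`).
#' @return the path, invisibly.
#' @export
writeRecipe <- function(recipe, path) {
  stopifnot(is(recipe, "Recipe"))
  comp <- recipe@composition
  ings <- lapply(seq_along(recipe@ingredients), function(i) {
    profile <- if (ncol(comp)) as.list(comp[i, , drop = TRUE]) else
      stats::setNames(list(), character(0))
    list(ingredient = recipe@ingredients[i],
         category = recipe@category[i],
         mass_g = recipe@mass[i],
         energy_kcal = recipe@energy[i],
         composition = profile)
  })
  jsonlite::write_json(
    list(name = recipe@name, content_basis = "mass_fraction",
         ingredients = ings),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a Dietary Risk Factor table from CSV
#'
#' Dialect: header `component_id,drf_udaly_per_g[,age_group,sex]`. Rows with
#' empty `age_group` and `sex` (or files without those columns) are aggregate
#' factors; other rows are per-stratum factors. A component supplied only in
#' stratified form needs `weights` (stratum `"age_group|sex"` -> population
#' fraction) to form its aggregate as the population-weighted mean.
#'
#' @param path path to the CSV.
#' @param weights optional named numeric vector of population fractions for
#'   aggregating stratified rows.
#' @param provenance free-text source note stored in the table.
#' @return a [DRFTable-class].
#' @export
readDRF <- function(path, weights = NULL, provenance = basename(path)) {
  if (!file.exists(path)) stop("DRF file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  need <- c("component_id", "drf_udaly_per_g")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("DRF CSV missing header column(s): ",
         paste(missing_cols, collapse = ", "))
  lines <- seq_len(nrow(df)) + 1L
  drf <- .numericOrStop(df$drf_udaly_per_g, "drf_udaly_per_g", lines)
  hasStrata <- all(c("age_group", "sex") %in% names(df))
  strat <- if (hasStrata) nzchar(trimws(df$age_group)) | nzchar(trimws(df$sex))
           else rep(FALSE, nrow(df))

  entries <- stats::setNames(drf[!strat], df$component_id[!strat])
  if (anyDuplicated(names(entries)))
    stop("duplicate aggregate DRF for component(s): ",
         paste(unique(names(entries)[duplicated(names(entries))]), collapse = ", "))
  strata <- if (any(strat))
    data.frame(component_id = df$component_id[strat],
               age_group = df$age_group[strat], sex = df$sex[strat],
               drf_udaly_per_g = drf[strat], stringsAsFactors = FALSE)
  else NULL

  onlyStrat <- setdiff(if (is.null(strata)) character(0) else strata$component_id,
                       names(entries))
  for (cid in onlyStrat) {
    sub <- strata[strata$component_id == cid, ]
    key <- paste(sub$age_group, sub$sex, sep = "|")
    if (is.null(weights))
      stop("component '", cid, "' has only stratified DRFs; supply `weights` ",
           "to aggregate them")
    entries[cid] <- aggregateStrata(stats::setNames(sub$drf_udaly_per_g, key),
                                    weights)
  }
  DRFTable(entries, strata = strata, provenance = provenance)
}

#' Read registry and exclusion configuration from YAML
#'
#' Schema: optional `components:` list (entries with `component_id`, `label`,
#' `direction`) appended to the built-in registry, and optional `exclusions:`
#' list (entries with `category`, `component_id`). Unknown top-level keys are
#' rejected.
#'
#' @param path path to the YAML file.
#' @return list with elements `registry` and `exclusions`.
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), c("components", "exclusions"))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  extra <- if (!is.null(cfg$components))
    do.call(rbind, lapply(cfg$components, function(e)
      data.frame(component_id = e$component_id, label = e$label,
                 direction = e$direction, stringsAsFactors = FALSE)))
  else NULL
  registry <- componentRegistry(extra)
  exclusions <- if (!is.null(cfg$exclusions))
    do.call(rbind, lapply(cfg$exclusions, function(e)
      data.frame(category = e$category, component_id = e$component_id,
                 stringsAsFactors = FALSE)))
  else defaultExclusionRules()
  bad <- setdiff(exclusions$component_id, componentIds(registry))
  if (length(bad))
    stop("exclusion rule references unknown component id(s): ",
         paste(bad, collapse = ", "))
  list(registry = registry, exclusions = exclusions)
}

#' Read a relative-risk curve from JSON
#'
#' Schema: `{"component_id": ..., "knots": [{"intake": g/day, "rr": ...},
#' ...], "tmrel": {"low": ..., "high": ...}}`; omitted TMREL bounds are
#' unbounded.
#'
#' @param path path to the JSON file.
#' @return an [RRCurve-class].
#' @export
readRRCurve <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(x$component_id) || is.null(x$knots))
    stop("RR curve JSON needs 'component_id' and 'knots'")
  intake <- vapply(x$knots, function(k) as.numeric(k$intake), numeric(1))
  rr <- vapply(x$knots, function(k) as.numeric(k$rr), numeric(1))
  low <- if (is.null(x$tmrel$low)) -Inf else as.numeric(x$tmrel$low)
  high <- if (is.null(x$tmrel$high)) Inf else as.numeric(x$tmrel$high)
  RRCurve(x$component_id, intake, rr, TMRELRange(low, high))
}

#' Read an intake distribution from JSON
#'
#' Schema: `{"type": "point", "value": ...}`,
#' `{"type": "histogram", "bins": [{"lower": ..., "upper": ..., "prob": ...},
#' ...]}` or `{"type": "lognormal", "meanlog": ..., "sdlog": ...}`.
#'
#' @param path path to the JSON file.
#' @return an [IntakeDistribution-class].
#' @export
readIntakeDistribution <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(x$type)) stop("intake JSON needs a 'type'")
  switch(x$type,
    point = intakePoint(as.numeric(x$value)),
    histogram = intakeHistogram(
      vapply(x$bins, function(b) as.numeric(b$lower), numeric(1)),
      vapply(x$bins, function(b) as.numeric(b$upper), numeric(1)),
      vapply(x$bins, function(b) as.numeric(b$prob), numeric(1))),
    lognormal = intakeLognormal(as.numeric(x$meanlog), as.numeric(x$sdlog)),
    stop("unknown intake distribution type: ", x$type))
}

#' Read burden rates from CSV
#'
#' Dialect: header `outcome,age_group,sex,daly_per_person_year`; an optional
#' `component_id` column links each outcome to a risk component for
#' scenario-level bookkeeping.
#'
#' @param path path to the CSV.
#' @return `data.frame` of burden rows.
#' @export
readBurdens <- function(path) {
  if (!file.exists(path)) stop("burden file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("outcome", "daly_per_person_year")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("burden CSV missing header column(s): ",
         paste(missing_cols, collapse = ", "))
  if (any(!is.finite(df$daly_per_person_year) | df$daly_per_person_year < 0))
    stop("burden rates must be non-negative numbers")
  df
}

#' Write a health-impact report
#'
#' JSON report with the per-component breakdown in both sign conventions
#' (microDALY, positive = damage; minutes gained, positive = benefit; and
#' the minute-scaled microDALY-sign row as printed in composition tables),
#' the functional-unit basis, any uncharacterized components, and
#' reproducibility metadata (tool version, seed, config hash).
#'
#' @param result a [HealthImpactResult-class].
#' @param path output path (`.json`).
#' @param seed the run's random seed (recorded for reproducibility; use
#'   `NA` for a deterministic run).
#' @param config optional list of run configuration to hash into the report.
#' @return the path, invisibly.
#' @export
writeReport <- function(result, path, seed = NA_integer_, config = list()) {
  stopifnot(is(result, "HealthImpactResult"))
  m <- result@perComponentMinutes
  report <- list(
    tool = "heni",
    version = as.character(utils::packageVersion("heni")),
    seed = seed,
    config_hash = {
      bytes <- utf8ToInt(paste(deparse(config), collapse = ""))
      sprintf("%08x", as.integer(sum(bytes * seq_along(bytes)) %% 2^31))
    },
    basis = result@basis,
    per_component = lapply(stats::setNames(names(m), names(m)), function(cid)
      list(udaly = unname(result@perComponentUDALY[cid]),
           minutes_gained = unname(m[cid]),
           minutes_udaly_sign = -unname(m[cid]))),
    total_udaly = result@totalUDALY,
    heni_minutes_gained = result@heniMinutes,
    total_minutes_udaly_sign = -result@heniMinutes,
    uncharacterized = as.list(result@uncharacterized)
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}
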