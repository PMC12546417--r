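#' Configuration for the synthetic species-table generator
#'
#' Ranges for the uniform sampling of trophic and composition parameters.
#' The transfer-efficiency range is the plausible across-ecosystem range
#' (3.51 % to 38.1 %); trophic levels span typical forage fish to piscivores;
#' moisture, yield and energy-density ranges reflect whole fish and reduction
#' coproducts (fishmeal around 18-22 MJ/kg, fish oil around 35-42 MJ/kg).
#'
#' @param n_species number of records to generate.
#' @param seed integer seed; generation is reproducible given the seed.
#' @param TL_range,TE_range,TL_SD_range sampling ranges for trophic level,
#'   transfer efficiency (fraction) and trophic-level SD.
#' @param moisture_range moisture range in g/kg fresh mass.
#' @param yield_meal_range,yield_oil_range coproduct yield ranges (fractions).
#' @param energy_meal_range,energy_oil_range energy-density ranges, MJ/kg.
#' @return An object of class `fixture_config` (a list).
#' @export
fixture_config <- function(n_species = 10, seed = 1,
                           TL_range = c(2.0, 4.5),
                           TE_range = c(0.0351, 0.381),
                           TL_SD_range = c(0, 0.5),
                           moisture_range = c(600, 800),
                           yield_meal_range = c(0.15, 0.30),
                           yield_oil_range = c(0.02, 0.12),
                           energy_meal_range = c(16, 22),
                           energy_oil_range = c(35, 42)) {
  ranges <- list(TL_range = TL_range, TE_range = TE_range,
                 TL_SD_range = TL_SD_range, moisture_range = moisture_range,
                 yield_meal_range = yield_meal_range,
                 yield_oil_range = yield_oil_range,
                 energy_meal_range = energy_meal_range,
                 energy_oil_range = energy_oil_range)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || !all(is.finite(r)) || r[1] > r[2]) {
      stop(sprintf("%s must be an ordered pair", nm), call. = FALSE)
    }
  }
  if (TE_range[1] <= 0 || TE_range[2] >= 1) {
    stop("TE_range must lie within (0, 1)", call. = FALSE)
  }
  structure(c(list(n_species = n_species, seed = seed), ranges),
            class = "fixture_config")
}

runif_range <- function(n, r) stats::runif(n, r[1], r[2])

#' Generate a synthetic species table
#'
#' Draws `n_species` records with the statistical structure the NPPU method
#' assumes: trophic level, transfer efficiency and TL standard deviation
#' uniform over the configured ranges; moisture uniform over its range with
#' protein, lipid, ash and carbohydrate partitioning the dry remainder
#' (closure to exactly 1000 g/kg, so carbohydrate-by-difference is exercised
#' at its boundary); carbon content from the composition; NPPU from the
#' record's own TE and TL. The result follows the `marine_fresh` internal
#' table layout and passes [validate_nppu_table()] after writing.
#'
#' @param config a [fixture_config()].
#' @return A data frame in the `marine_fresh` internal layout, with
#'   attribute `schema_id`.
#' @examples
#' generate_species(fixture_config(n_species = 3, seed = 42))
#' @export
generate_species <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  n <- config$n_species

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  if (n == 0) {
    out <- generate_species(fixture_config(n_species = 1, seed = config$seed))
    out <- out[0, , drop = FALSE]
    attr(out, "schema_id") <- "marine_fresh"
    return(out)
  }

  TL <- runif_range(n, config$TL_range)
  TL_SD <- runif_range(n, config$TL_SD_range)
  TE <- runif_range(n, config$TE_range)
  moisture <- runif_range(n, config$moisture_range)

  # partition the dry remainder: random proportions for protein, lipid and
  # ash; carbohydrate is the exact residual, so the table closes to 1000
  dry <- 1000 - moisture
  w <- matrix(stats::runif(4 * n), ncol = 4)
  w <- w / rowSums(w)
  protein <- dry * w[, 1]
  lipid <- dry * w[, 2]
  ash <- dry * w[, 3]
  carbohydrate <- pmax(0, dry - protein - lipid - ash)

  C_content <- vapply(seq_len(n), function(i) {
    carbon_content(proximate_composition(protein[i], lipid[i], ash[i],
                                         moisture[i],
                                         carbohydrate = carbohydrate[i]))
  }, numeric(1))
  nppu_g <- C_content * amplification_factor(TE, TL)

  out <- data.frame(
    species = sprintf("Synthetica piscis_%03d", seq_len(n)),
    common_name = sprintf("synthetic fish %03d", seq_len(n)),
    common_name_fr = sprintf("poisson synthetique %03d", seq_len(n)),
    ecosystem = sample(c("Upwelling", "Temperate shelf", "Tropical shelf",
                         "Open ocean"), n, replace = TRUE),
    TL = TL, TL_SD = TL_SD, TE = TE,
    comment = "synthetic record",
    moisture = moisture, protein = protein, lipid = lipid, ash = ash,
    carbohydrate = carbohydrate,
    source_tl = "synthetic", source_body_composition = "synthetic",
    source_te = "synthetic",
    C_content = C_content, nppu_g = nppu_g, nppu_kg = nppu_g / 1000,
    stringsAsFactors = FALSE
  )
  attr(out, "schema_id") <- "marine_fresh"
  out
}

#' Generate random coproduct specifications
#'
#' Draws `n` [coproduct_spec()] objects with yields and energy densities
#' uniform over the configured ranges; used for property-style checks of the
#' allocation rules.
#'
#' @param n number of specifications.
#' @param seed integer seed.
#' @param config a [fixture_config()] supplying the ranges.
#' @return A list of `coproduct_spec` objects.
#' @export
generate_coproduct_specs <- function(n, seed = 1, config = fixture_config()) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ym <- runif_range(n, config$yield_meal_range)
  yo <- runif_range(n, config$yield_oil_range)
  em <- runif_range(n, config$energy_meal_range)
  eo <- runif_range(n, config$energy_oil_range)
  lapply(seq_len(n), function(i) {
    coproduct_spec(ym[i], yo[i], em[i], eo[i])
  })
}

#' Reference constants bundle
#'
#' The published constants in one place, for tests and worked examples:
#' generic trophic defaults, carbon coefficients, molar masses, and the
#' fixed trophic levels for plant (1) and milk (2) ingredients.
#'
#' @return A list with components `defaults` ([generic_defaults()]),
#'   `coefficients` ([default_carbon_coefficients()]), `molar_masses`
#'   ([molar_mass_table()]), `TE_generic`, `C_generic`, `plant_TL`,
#'   `milk_TL`.
#' @examples
#' worked_example_fixture()$C_generic  # 111.1 g C per kg fresh fish
#' @export
worked_example_fixture <- function() {
  defaults <- generic_defaults()
  list(defaults = defaults,
       coefficients = default_carbon_coefficients(),
       molar_masses = molar_mass_table(),
       TE_generic = defaults$TE_generic,
       C_generic = defaults$C_generic,
       plant_TL = 1,
       milk_TL = 2)
}
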