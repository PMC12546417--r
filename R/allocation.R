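#' Coproduct specification for fishmeal and fish oil
#'
#' Yields of meal and oil per kg of fresh raw material, and their energy
#' densities, used by the allocation rules. Yields are fractions of fresh
#' mass; the non-meal, non-oil residual (1 - Y_meal - Y_oil, e.g.
#' stickwater) carries no NPPU.
#'
#' @param yield_meal,yield_oil coproduct yields, fractions in (0, 1) with
#'   `yield_meal + yield_oil <= 1`.
#' @param energy_meal,energy_oil energy densities, MJ per kg, > 0.
#' @param yield_source `"generic"` or `"specific"` — provenance label of the
#'   yields, carried through to tier-by-yield variant labels.
#' @return An object of class `coproduct_spec` (a list).
#' @examples
#' coproduct_spec(yield_meal = 0.2, yield_oil = 0.05,
#'                energy_meal = 18.5, energy_oil = 39.0)
#' @export
coproduct_spec <- function(yield_meal, yield_oil, energy_meal, energy_oil,
                           yield_source = c("generic", "specific")) {
  yield_source <- match.arg(yield_source)
  v <- c(yield_meal, yield_oil, energy_meal, energy_oil)
  if (!all(is.finite(v)) || any(v <= 0)) {
    stop("yields and energy densities must be finite and strictly positive",
         call. = FALSE)
  }
  if (yield_meal >= 1 || yield_oil >= 1 || yield_meal + yield_oil > 1) {
    stop("yields must be fractions in (0, 1) with yield_meal + yield_oil <= 1",
         call. = FALSE)
  }
  structure(list(yield_meal = yield_meal, yield_oil = yield_oil,
                 energy_meal = energy_meal, energy_oil = energy_oil,
                 yield_source = yield_source),
            class = "coproduct_spec")
}

#' Energy allocation factors
#'
#' Shares of the fresh-organism burden attributed to meal and oil in
#' proportion to the energy leaving in each coproduct:
#' `factor_meal = Y_m*E_m / (Y_m*E_m + Y_o*E_o)`, and the complement for
#' oil. The factors are positive and sum to one.
#'
#' @param spec a [coproduct_spec()].
#' @return Named numeric vector `c(meal = ..., oil = ...)`.
#' @examples
#' energy_allocation_factors(coproduct_spec(0.2, 0.05, 18.5, 39.0))
#' @export
energy_allocation_factors <- function(spec) {
  stopifnot(inherits(spec, "coproduct_spec"))
  em <- spec$yield_meal * spec$energy_meal
  eo <- spec$yield_oil * spec$energy_oil
  if (em + eo <= 0) stop("total coproduct energy is zero", call. = FALSE)
  c(meal = em / (em + eo), oil = eo / (em + eo))
}

as_fresh_nppu <- function(x) {
  if (inherits(x, "nppu_value")) {
    if (x$basis != "fresh") {
      stop("allocation requires an NPPU value on the fresh basis", call. = FALSE)
    }
    x
  } else if (is.numeric(x) && length(x) == 1) {
    # bare numbers are taken as kg C/kg fresh
    nppu_value(x * 1000, basis = "fresh")
  } else {
    stop("`nppu` must be an nppu_value or a single number in kg C/kg",
         call. = FALSE)
  }
}

allocation_result <- function(fresh, spec, factors, method, tier_label) {
  g_meal <- fresh$value_g / spec$yield_meal * factors[["meal"]]
  g_oil <- fresh$value_g / spec$yield_oil * factors[["oil"]]
  structure(
    list(
      nppu_meal = nppu_value(g_meal, basis = "ingredient",
                             tier_label = tier_label, allocation_label = method),
      nppu_oil = nppu_value(g_oil, basis = "ingredient",
                            tier_label = tier_label, allocation_label = method),
      method = method,
      factor_meal = unname(factors[["meal"]]),
      factor_oil = unname(factors[["oil"]]),
      spec = spec, nppu_fresh = fresh
    ),
    class = "allocation_result"
  )
}

#' @export
print.allocation_result <- function(x, ...) {
  cat(sprintf("NPPU %s allocation (factors %.4f meal / %.4f oil):\n",
              x$method, x$factor_meal, x$factor_oil))
  cat(sprintf("  meal: %.4g kg C/kg\n  oil:  %.4g kg C/kg\n",
              x$nppu_meal$value_kg, x$nppu_oil$value_kg))
  invisible(x)
}

#' Allocate fresh-organism NPPU to meal and oil by energy
#'
#' `NPPU_meal = (NPPU_fresh / Y_meal) * Y_m E_m / (Y_m E_m + Y_o E_o)` and
#' the analogous expression for oil. Mass balance holds by construction:
#' `Y_m * NPPU_meal + Y_o * NPPU_oil = NPPU_fresh`.
#'
#' @param nppu an [nppu_value()] on the fresh basis, or a single number in
#'   kg C per kg fresh mass.
#' @param spec a [coproduct_spec()].
#' @return An `allocation_result` with per-kg-ingredient NPPU values for
#'   meal and oil, the allocation factors, and the inputs.
#' @examples
#' allocate_energy(10, coproduct_spec(0.2, 0.05, 20, 40))
#' @export
allocate_energy <- function(nppu, spec) {
  fresh <- as_fresh_nppu(nppu)
  stopifnot(inherits(spec, "coproduct_spec"))
  allocation_result(fresh, spec, energy_allocation_factors(spec),
                    "energy", fresh$tier_label)
}

#' Allocate fresh-organism NPPU to meal and oil by mass
#'
#' The total fresh burden is spread over the coproduct masses, giving the
#' same per-kg value `NPPU_fresh / (Y_meal + Y_oil)` for both meal and oil.
#' Equivalent to energy allocation with equal energy densities.
#'
#' @inheritParams allocate_energy
#' @return An `allocation_result`.
#' @examples
#' allocate_mass(10, coproduct_spec(0.2, 0.05, 18.5, 39.0))
#' @export
allocate_mass <- function(nppu, spec) {
  fresh <- as_fresh_nppu(nppu)
  stopifnot(inherits(spec, "coproduct_spec"))
  ys <- spec$yield_meal + spec$yield_oil
  factors <- c(meal = spec$yield_meal / ys, oil = spec$yield_oil / ys)
  allocation_result(fresh, spec, factors, "mass", fresh$tier_label)
}

#' Allocate fresh-organism NPPU by user-supplied weights
#'
#' Same algebra as energy allocation with the energy densities replaced by
#' arbitrary positive per-kg weights (e.g. prices for an economic
#' allocation): `factor_meal = Y_m w_m / (Y_m w_m + Y_o w_o)`. With equal
#' weights it reduces to mass allocation; with weights equal to the energy
#' densities it reproduces energy allocation. No price table is shipped —
#' the weights are the user's.
#'
#' @inheritParams allocate_energy
#' @param weight_meal,weight_oil strictly positive per-kg weights.
#' @return An `allocation_result` with method `"custom"`.
#' @export
allocate_custom <- function(nppu, spec, weight_meal, weight_oil) {
  fresh <- as_fresh_nppu(nppu)
  stopifnot(inherits(spec, "coproduct_spec"))
  if (!all(is.finite(c(weight_meal, weight_oil))) ||
      weight_meal <= 0 || weight_oil <= 0) {
    stop("allocation weights must be finite and strictly positive", call. = FALSE)
  }
  wm <- spec$yield_meal * weight_meal
  wo <- spec$yield_oil * weight_oil
  factors <- c(meal = wm / (wm + wo), oil = wo / (wm + wo))
  allocation_result(fresh, spec, factors, "custom", fresh$tier_label)
}

#' Tier-by-yield NPPU variant matrix for fishmeal and fish oil
#'
#' For each tier of the ingredient class (marine: T1, T2, T3; freshwater:
#' T1, T2) crossed with generic and specific coproduct yields, computes the
#' allocated meal and oil NPPU. Variants are labelled `T<tier><1|2>` with
#' `1` = generic yields and `2` = specific yields, e.g. `T31` is tier-3
#' parameters with generic yields.
#'
#' @param record a [species_record()] carrying every field the highest tier
#'   demands.
#' @param spec_generic,spec_specific [coproduct_spec()] objects with
#'   generic and specific yields.
#' @param method `"mass"` or `"energy"`.
#' @param class `"marine"` (3 tiers, 6 variants) or `"freshwater"` (2 tiers,
#'   4 variants).
#' @param defaults a [generic_defaults()] object.
#' @return A data frame with one row per variant: `label`, `tier`,
#'   `yield_source`, `nppu_fresh_kg`, `nppu_meal_kg`, `nppu_oil_kg`,
#'   `factor_meal`, `factor_oil`.
#' @export
tier_yield_matrix <- function(record, spec_generic, spec_specific,
                              method = c("mass", "energy"),
                              class = c("marine", "freshwater"),
                              defaults = generic_defaults()) {
  method <- match.arg(method)
  class <- match.arg(class)
  stopifnot(inherits(spec_generic, "coproduct_spec"),
            inherits(spec_specific, "coproduct_spec"))
  tiers <- if (class == "marine") c("T1", "T2", "T3") else c("T1", "T2")
  specs <- list(spec_generic, spec_specific)
  alloc_fun <- switch(method, mass = allocate_mass, energy = allocate_energy)

  rows <- list()
  for (tier in tiers) {
    fresh <- nppu_for_class(record, tier_policy(class, tier), defaults)
    for (j in 1:2) {
      res <- alloc_fun(fresh, specs[[j]])
      label <- paste0(tier, j)
      rows[[label]] <- data.frame(
        label = label, tier = tier,
        yield_source = c("generic", "specific")[j],
        nppu_fresh_kg = fresh$value_kg,
        nppu_meal_kg = res$nppu_meal$value_kg,
        nppu_oil_kg = res$nppu_oil$value_kg,
        factor_meal = res$factor_meal, factor_oil = res$factor_oil,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
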