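#' An NPPU indicator value
#'
#' Container for one Net Primary Production Use value, carried in both g C/kg
#' and kg C/kg (the two unit columns of the reference tables), together with
#' its basis (fresh organism vs processed ingredient), tier label and
#' allocation label. The kg value is always `value_g / 1000` exactly.
#'
#' @param value_g NPPU in g C per kg, non-negative.
#' @param basis `"fresh"` (whole fresh organism) or `"ingredient"`.
#' @param tier_label free-text tier label, e.g. `"T1"`, `"plant"`.
#' @param allocation_label one of `"none"`, `"mass"`, `"energy"`, `"custom"`.
#' @return An object of class `nppu_value`.
#' @export
nppu_value <- function(value_g, basis = c("fresh", "ingredient"),
                       tier_label = "", allocation_label = "none") {
  basis <- match.arg(basis)
  allocation_label <- match.arg(allocation_label,
                                c("none", "mass", "energy", "custom"))
  if (!is.finite(value_g) || value_g < 0) {
    stop("NPPU value must be finite and non-negative", call. = FALSE)
  }
  structure(
    list(value_g = value_g, value_kg = value_g / 1000, basis = basis,
         tier_label = tier_label, allocation_label = allocation_label),
    class = "nppu_value"
  )
}

#' @export
print.nppu_value <- function(x, ...) {
  lab <- x$tier_label
  if (!nzchar(lab)) lab <- "-"
  cat(sprintf("NPPU [%s, tier %s, allocation %s]: %.4g g C/kg = %.4g kg C/kg\n",
              x$basis, lab, x$allocation_label, x$value_g, x$value_kg))
  invisible(x)
}

#' @export
as.numeric.nppu_value <- function(x, ...) x$value_kg

#' Generic trophic defaults
#'
#' The generic parameter set for fish-based tiers: a trophic transfer
#' efficiency of 10 % and a whole-fish carbon content of 111.1 g C per kg
#' fresh mass. The plausible TE range across ecosystems (3.51 % to 38.1 %,
#' mean 11.9 %) is carried for reference and for fixture generation.
#'
#' @param TE_generic generic transfer efficiency (fraction).
#' @param C_generic generic carbon content, g C per kg fresh fish.
#' @param TE_range plausible transfer-efficiency range (fractions).
#' @param TE_mean mean ecosystem transfer efficiency (fraction).
#' @return An object of class `generic_defaults` (a list).
#' @export
generic_defaults <- function(TE_generic = 0.10, C_generic = 111.1,
                             TE_range = c(0.0351, 0.381), TE_mean = 0.119) {
  if (TE_generic < TE_range[1] || TE_generic > TE_range[2]) {
    stop("TE_generic must lie within TE_range", call. = FALSE)
  }
  if (C_generic <= 0) stop("C_generic must be positive", call. = FALSE)
  structure(list(TE_generic = TE_generic, C_generic = C_generic,
                 TE_range = TE_range, TE_mean = TE_mean),
            class = "generic_defaults")
}

#' Trophic parameters of a species
#'
#' @param TL trophic level, >= 1 (primary producers are 1).
#' @param TL_SD standard deviation of the trophic level, >= 0.
#' @param TE trophic transfer efficiency as a fraction in (0, 1].
#' @param ecosystem free-text ecosystem label the TE refers to.
#' @return An object of class `trophic_parameters` (a list).
#' @export
trophic_parameters <- function(TL, TL_SD = 0, TE = NA_real_, ecosystem = "") {
  if (!is.finite(TL) || TL < 1) stop("TL must be >= 1", call. = FALSE)
  if (!is.finite(TL_SD) || TL_SD < 0) stop("TL_SD must be >= 0", call. = FALSE)
  if (!is.na(TE) && (TE <= 0 || TE > 1)) {
    stop("TE must be a fraction in (0, 1]", call. = FALSE)
  }
  structure(list(TL = TL, TL_SD = TL_SD, TE = TE, ecosystem = ecosystem),
            class = "trophic_parameters")
}

#' Tier policies for parameter resolution
#'
#' A tier policy declares, for an ingredient class, which of the transfer
#' efficiency, carbon content and trophic level come from generic defaults
#' and which from species-specific records:
#'
#' * marine: `T1` generic TE + generic C, `T2` specific TE + generic C,
#'   `T3` specific TE + specific C (TL always species-specific);
#' * freshwater: `T1` generic TE + generic C, `T2` generic TE + specific C;
#' * other_animal: a single tier, generic TE + specific C + specific TL;
#' * milk: carbon content from the ingredient composition with the trophic
#'   level fixed at 2;
#' * plant: trophic level fixed at 1 (NPPU equals carbon content).
#'
#' @param class ingredient class, one of `"marine"`, `"freshwater"`,
#'   `"other_animal"`, `"milk"`, `"plant"`.
#' @param tier tier label within the class (`"T1"`, `"T2"`, `"T3"` for
#'   marine; `"T1"`, `"T2"` for freshwater; ignored for single-tier classes).
#' @return An object of class `tier_policy` (a list with fields `class`,
#'   `tier_label`, `te_source`, `c_source`, `tl_source`, `fixed_TL`).
#' @examples
#' tier_policy("marine", "T2")
#' tier_policy("milk")
#' @export
tier_policy <- function(class = c("marine", "freshwater", "other_animal",
                                  "milk", "plant"),
                        tier = "T1") {
  class <- match.arg(class)
  pol <- switch(
    class,
    marine = switch(
      tier,
      T1 = list(te_source = "generic", c_source = "generic"),
      T2 = list(te_source = "specific", c_source = "generic"),
      T3 = list(te_source = "specific", c_source = "specific"),
      stop(sprintf("marine tiers are T1, T2, T3; got '%s'", tier), call. = FALSE)
    ),
    freshwater = switch(
      tier,
      T1 = list(te_source = "generic", c_source = "generic"),
      T2 = list(te_source = "generic", c_source = "specific"),
      stop(sprintf("freshwater tiers are T1, T2; got '%s'", tier), call. = FALSE)
    ),
    other_animal = {
      tier <- "T1"
      list(te_source = "generic", c_source = "specific")
    },
    milk = {
      tier <- "milk"
      list(te_source = "generic", c_source = "specific")
    },
    plant = {
      tier <- "plant"
      list(te_source = "generic", c_source = "specific")
    }
  )
  structure(
    list(class = class, tier_label = tier,
         te_source = pol$te_source, c_source = pol$c_source,
         tl_source = if (class %in% c("milk", "plant")) "fixed" else "specific",
         fixed_TL = switch(class, milk = 2, plant = 1, NULL)),
    class = "tier_policy"
  )
}

#' Species record
#'
#' One species (or ingredient) row: identity, trophic parameters, optional
#' species-specific carbon content and proximate composition, and the
#' bibliographic source fields of the reference tables.
#'
#' @param species scientific name.
#' @param trophic a [trophic_parameters()] object.
#' @param common_name,common_name_fr common names (English / French).
#' @param C_specific optional species-specific carbon content, g C per kg
#'   fresh mass.
#' @param composition optional [proximate_composition()].
#' @param sources named character vector of bibliographic sources
#'   (`Source_TL`, `Source_Body_Composition`, `Source_TE`).
#' @param comment free-text comment.
#' @return An object of class `species_record` (a list).
#' @export
species_record <- function(species, trophic, common_name = "",
                           common_name_fr = "", C_specific = NA_real_,
                           composition = NULL,
                           sources = c(Source_TL = "",
                                       Source_Body_Composition = "",
                                       Source_TE = ""),
                           comment = "") {
  stopifnot(inherits(trophic, "trophic_parameters"))
  if (!is.null(composition) && !inherits(composition, "proximate_composition")) {
    stop("`composition` must be a proximate_composition", call. = FALSE)
  }
  structure(
    list(species = species, common_name = common_name,
         common_name_fr = common_name_fr, trophic = trophic,
         C_specific = C_specific, composition = composition,
         sources = sources, comment = comment),
    class = "species_record"
  )
}

#' Trophic amplification factor
#'
#' The Pauly–Christensen amplification `(1/TE)^(TL - 1)`: the mass of
#' primary production required per unit of biomass at trophic level `TL`
#' when a fraction `TE` of production passes between successive levels.
#' Equals 1 at `TL = 1` and grows geometrically with TL.
#'
#' @param TE transfer efficiency, a fraction in (0, 1].
#' @param TL trophic level, >= 1.
#' @return Dimensionless amplification factor >= 1.
#' @examples
#' amplification_factor(0.10, 2.0)   # 10
#' amplification_factor(0.10, 3.5)   # 10^2.5
#' @export
amplification_factor <- function(TE, TL) {
  if (!all(is.finite(TE)) || any(TE <= 0) || any(TE > 1)) {
    stop("TE must be a fraction in (0, 1]", call. = FALSE)
  }
  if (!all(is.finite(TL)) || any(TL < 1)) {
    stop("TL must be >= 1", call. = FALSE)
  }
  (1 / TE)^(TL - 1)
}

#' NPPU of a fresh organism
#'
#' Carbon content amplified up the food web:
#' `NPPU = C_content * (1/TE)^(TL - 1)` in g C per kg fresh mass.
#'
#' @param C_content carbon content of the fresh organism, g C per kg.
#' @inheritParams amplification_factor
#' @param tier_label tier label to attach to the result.
#' @return An [nppu_value()] with basis `"fresh"`.
#' @examples
#' nppu_fresh(111.1, 0.10, 3.5)
#' @export
nppu_fresh <- function(C_content, TE, TL, tier_label = "") {
  if (!is.finite(C_content) || C_content < 0) {
    stop("C_content must be finite and non-negative", call. = FALSE)
  }
  nppu_value(C_content * amplification_factor(TE, TL),
             basis = "fresh", tier_label = tier_label)
}

#' Resolve the effective (C, TE, TL) triple for a record under a tier policy
#'
#' Generic sources resolve to the generic defaults (TE = 10 %, C = 111.1
#' g/kg); specific sources resolve to the record's own fields; fixed-TL
#' policies (plant = 1, milk = 2) override the record's trophic level.
#' A policy demanding a specific field the record does not carry is an
#' error naming the field — tiers never silently downgrade.
#'
#' @param record a [species_record()].
#' @param policy a [tier_policy()].
#' @param defaults a [generic_defaults()] object.
#' @return A list with elements `C_content` (g C/kg), `TE` (fraction),
#'   `TL` (dimensionless).
#' @examples
#' rec <- species_record("Engraulis ringens", trophic_parameters(TL = 3.2))
#' resolve_parameters(rec, tier_policy("marine", "T1"))
#' @export
resolve_parameters <- function(record, policy, defaults = generic_defaults()) {
  stopifnot(inherits(record, "species_record"), inherits(policy, "tier_policy"))

  TE <- if (policy$te_source == "generic") {
    defaults$TE_generic
  } else {
    if (is.na(record$trophic$TE)) {
      stop(sprintf("tier %s requires a specific transfer efficiency (TE) but record '%s' has none",
                   policy$tier_label, record$species), call. = FALSE)
    }
    record$trophic$TE
  }

  C_content <- if (policy$c_source == "generic") {
    defaults$C_generic
  } else if (!is.na(record$C_specific)) {
    record$C_specific
  } else if (!is.null(record$composition)) {
    carbon_content(record$composition)
  } else {
    stop(sprintf("tier %s requires a specific carbon content (C_specific or composition) but record '%s' has neither",
                 policy$tier_label, record$species), call. = FALSE)
  }

  TL <- if (policy$tl_source == "fixed") policy$fixed_TL else record$trophic$TL

  list(C_content = C_content, TE = TE, TL = TL)
}

#' NPPU of a record under a tier policy
#'
#' Resolves the effective parameter triple for the record under the policy
#' and applies the trophic amplification. Plant-class policies delegate to
#' [plant_nppu()] on the record's composition.
#'
#' @inheritParams resolve_parameters
#' @return An [nppu_value()]; basis `"fresh"` for animal classes,
#'   `"ingredient"` for plant and milk (computed directly on the ingredient).
#' @export
nppu_for_class <- function(record, policy, defaults = generic_defaults()) {
  stopifnot(inherits(record, "species_record"), inherits(policy, "tier_policy"))
  if (policy$class == "plant") {
    if (is.null(record$composition)) {
      stop(sprintf("plant policy requires a composition but record '%s' has none",
                   record$species), call. = FALSE)
    }
    return(plant_nppu(record$composition))
  }
  p <- resolve_parameters(record, policy, defaults)
  out <- nppu_fresh(p$C_content, p$TE, p$TL, tier_label = policy$tier_label)
  if (policy$class == "milk") {
    # milk NPPU is computed directly on the ingredient, not a fresh organism
    out <- nppu_value(out$value_g, basis = "ingredient",
                      tier_label = policy$tier_label)
  }
  out
}
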