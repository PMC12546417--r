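#' Molar mass table
#'
#' The atomic molar masses used in the carbon-stoichiometry calculations.
#' Defaults are the rounded integer values conventionally used with the
#' empirical formulas for protein, lipid and carbohydrate, so that the
#' published carbon-fraction constants reproduce exactly.
#'
#' @param M_C,M_H,M_O,M_N molar masses of carbon, hydrogen, oxygen and
#'   nitrogen in g/mol. All must be strictly positive.
#' @return An object of class `molar_mass_table` (a named numeric vector).
#' @examples
#' molar_mass_table()
#' @export
molar_mass_table <- function(M_C = 12, M_H = 1, M_O = 16, M_N = 14) {
  m <- c(M_C = M_C, M_H = M_H, M_O = M_O, M_N = M_N)
  if (!all(is.finite(m)) || any(m <= 0)) {
    stop("all molar masses must be finite and strictly positive", call. = FALSE)
  }
  structure(m, class = "molar_mass_table")
}

#' Empirical formula
#'
#' An empirical formula C_nC H_nH O_nO N_nN given as non-negative integer
#' atom counts. At least one carbon atom is required, since the formula is
#' used to compute a carbon mass fraction.
#'
#' @param C,H,O,N non-negative integer atom counts.
#' @return An object of class `empirical_formula` (a named integer vector).
#' @examples
#' empirical_formula(C = 5, H = 7, O = 2, N = 1)  # generic protein monomer
#' empirical_formula(C = 57, H = 104, O = 6)      # triglyceride
#' @export
empirical_formula <- function(C, H = 0, O = 0, N = 0) {
  n <- c(C = C, H = H, O = O, N = N)
  if (!all(is.finite(n)) || any(n < 0) || any(n != round(n))) {
    stop("atom counts must be non-negative integers", call. = FALSE)
  }
  if (n[["C"]] < 1) {
    stop("empirical formula must contain at least one carbon atom", call. = FALSE)
  }
  structure(as.integer(round(n)), names = names(n), class = "empirical_formula")
}

#' Carbon mass fraction of an empirical formula
#'
#' Fraction of the molecular mass contributed by carbon:
#' `n_C * M_C / (n_C*M_C + n_H*M_H + n_O*M_O + n_N*M_N)`.
#'
#' With the default integer molar masses this reproduces the published
#' constants: 0.531 for protein (C5H7O2N) and 0.774 for lipid (C57H104O6).
#' The anhydroglucose polysaccharide unit C6H10O5 gives 72/162 = 0.444.
#'
#' @param formula an [empirical_formula()], or a named vector with elements
#'   `C`, `H`, `O`, `N`.
#' @param masses a [molar_mass_table()].
#' @return Dimensionless carbon mass fraction in (0, 1].
#' @examples
#' carbon_mass_fraction(empirical_formula(5, 7, 2, 1))    # 0.531
#' carbon_mass_fraction(empirical_formula(57, 104, 6))    # 0.774
#' carbon_mass_fraction(empirical_formula(6, 10, 5))      # 0.444
#' @export
carbon_mass_fraction <- function(formula, masses = molar_mass_table()) {
  if (!inherits(formula, "empirical_formula")) {
    formula <- do.call(empirical_formula, as.list(formula))
  }
  n <- as.numeric(formula)
  total <- n[1] * masses[["M_C"]] + n[2] * masses[["M_H"]] +
    n[3] * masses[["M_O"]] + n[4] * masses[["M_N"]]
  n[1] * masses[["M_C"]] / total
}

#' Default carbon-content coefficients
#'
#' The published mass fractions of carbon in protein, lipid and carbohydrate
#' used by the plant-ingredient carbon-content formula: 0.531, 0.774 and
#' 0.444. These are the printed reference constants, returned verbatim rather
#' than recomputed; use [carbon_mass_fraction()] to derive coefficients from
#' other empirical formulas or molar masses.
#'
#' @return An object of class `carbon_coefficients`: named numeric vector
#'   with elements `c_protein`, `c_lipid`, `c_carbohydrate`.
#' @export
default_carbon_coefficients <- function() {
  carbon_coefficients(c_protein = 0.531, c_lipid = 0.774, c_carbohydrate = 0.444)
}

#' @rdname default_carbon_coefficients
#' @param c_protein,c_lipid,c_carbohydrate carbon mass fractions, each
#'   strictly in (0, 1).
#' @export
carbon_coefficients <- function(c_protein, c_lipid, c_carbohydrate) {
  k <- c(c_protein = c_protein, c_lipid = c_lipid, c_carbohydrate = c_carbohydrate)
  if (!all(is.finite(k)) || any(k <= 0) || any(k >= 1)) {
    stop("carbon coefficients must lie strictly in (0, 1)", call. = FALSE)
  }
  structure(k, class = "carbon_coefficients")
}

#' Carbohydrate content by difference
#'
#' Fills the carbohydrate fraction of a proximate composition as the as-fed
#' remainder after protein, lipid, ash and moisture, floored at zero:
#' `max(0, 1000 - protein - lipid - ash - moisture)` g/kg.
#'
#' @param protein,lipid,ash,moisture contents in g per kg as-fed ingredient.
#' @param tol closure tolerance in g/kg; inputs summing above `1000 + tol`
#'   are rejected.
#' @return Carbohydrate content in g/kg.
#' @examples
#' carbohydrate_by_difference(200, 50, 60, 120)  # 570
#' @export
carbohydrate_by_difference <- function(protein, lipid, ash, moisture, tol = 1) {
  x <- c(protein = protein, lipid = lipid, ash = ash, moisture = moisture)
  if (!all(is.finite(x)) || any(x < 0)) {
    stop("composition fields must be finite and non-negative", call. = FALSE)
  }
  s <- sum(x)
  if (s > 1000 + tol) {
    stop(sprintf("composition fields sum to %.6g g/kg, above 1000 + %g", s, tol),
         call. = FALSE)
  }
  max(0, 1000 - s)
}

#' Proximate composition of a feed ingredient
#'
#' Mass partitioning of one kilogram of as-fed ingredient into crude protein,
#' lipid, ash, moisture and carbohydrate, all in g/kg. If `carbohydrate` is
#' omitted it is filled by difference ([carbohydrate_by_difference()]).
#'
#' @param protein,lipid,ash,moisture,carbohydrate contents in g/kg as-fed.
#' @param dry_matter optional dry-matter content in g/kg; when supplied it
#'   must equal `1000 - moisture` within `tol`.
#' @param tol closure tolerance in g/kg.
#' @return An object of class `proximate_composition` (named numeric vector).
#' @examples
#' proximate_composition(protein = 200, lipid = 50, ash = 60, moisture = 120)
#' @export
proximate_composition <- function(protein, lipid, ash, moisture,
                                  carbohydrate = NULL, dry_matter = NULL,
                                  tol = 1) {
  if (is.null(carbohydrate)) {
    carbohydrate <- carbohydrate_by_difference(protein, lipid, ash, moisture,
                                               tol = tol)
  }
  x <- c(protein = protein, lipid = lipid, ash = ash, moisture = moisture,
         carbohydrate = carbohydrate)
  if (!all(is.finite(x)) || any(x < 0)) {
    stop("composition fields must be finite and non-negative", call. = FALSE)
  }
  if (sum(x) > 1000 + tol) {
    stop(sprintf("composition sums to %.6g g/kg, above 1000 + %g", sum(x), tol),
         call. = FALSE)
  }
  if (!is.null(dry_matter)) {
    if (abs(dry_matter - (1000 - moisture)) > tol) {
      stop(sprintf("dry_matter (%.6g) inconsistent with 1000 - moisture (%.6g)",
                   dry_matter, 1000 - moisture), call. = FALSE)
    }
    x <- c(x, dry_matter = dry_matter)
  }
  structure(x, class = "proximate_composition")
}

#' Carbon content of an ingredient from its proximate composition
#'
#' Linear combination of the organic fractions with their carbon mass
#' fractions: `c_carbohydrate*carbohydrate + c_protein*protein +
#' c_lipid*lipid`, in g C per kg ingredient. Ash and moisture carry no
#' carbon.
#'
#' @param comp a [proximate_composition()].
#' @param coeffs a set of carbon coefficients; defaults to the published
#'   constants ([default_carbon_coefficients()]).
#' @return Carbon content in g C per kg ingredient.
#' @examples
#' comp <- proximate_composition(500, 100, 40, 60, carbohydrate = 300)
#' carbon_content(comp)  # 476.1
#' @export
carbon_content <- function(comp, coeffs = default_carbon_coefficients()) {
  if (!inherits(comp, "proximate_composition")) {
    stop("`comp` must be a proximate_composition", call. = FALSE)
  }
  unname(coeffs[["c_protein"]] * comp[["protein"]] +
           coeffs[["c_lipid"]] * comp[["lipid"]] +
           coeffs[["c_carbohydrate"]] * comp[["carbohydrate"]])
}

#' NPPU of a plant-based ingredient
#'
#' Primary producers sit at trophic level 1, so the trophic amplification
#' factor is 1 and the NPPU of a plant ingredient equals its carbon content:
#' in g C/kg directly, in kg C/kg after division by 1000.
#'
#' @inheritParams carbon_content
#' @return An [nppu_value()] with basis `"ingredient"` and tier label
#'   `"plant"`.
#' @examples
#' plant_nppu(proximate_composition(500, 100, 40, 60, carbohydrate = 300))
#' @export
plant_nppu <- function(comp, coeffs = default_carbon_coefficients()) {
  g <- carbon_content(comp, coeffs)
  nppu_value(g, basis = "ingredient", tier_label = "plant")
}
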