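#' Compute NPPU columns for a plant ingredient table
#'
#' Fills `C_content`, `NPPU_g/kg` and `NPPU_kg/kg` for every row of a table
#' in the `plant` internal layout from its proximate composition (trophic
#' level 1: NPPU equals carbon content). A missing carbohydrate cell is
#' filled by difference when a moisture column is available, otherwise it is
#' an error.
#'
#' @param tab data frame in the `plant` internal layout (see
#'   [read_nppu_table()]).
#' @param coeffs carbon coefficients, default [default_carbon_coefficients()].
#' @return The table with `C_content`, `nppu_g`, `nppu_kg` filled.
#' @export
compute_plant_table <- function(tab, coeffs = default_carbon_coefficients()) {
  n <- nrow(tab)
  for (i in seq_len(n)) {
    comp <- proximate_composition(
      protein = tab$protein[i], lipid = tab$lipid[i], ash = tab$ash[i],
      moisture = if ("moisture" %in% names(tab) && !is.na(tab$moisture[i]))
        tab$moisture[i] else 0,
      carbohydrate = if (is.na(tab$carbohydrate[i])) NULL
        else tab$carbohydrate[i]
    )
    tab$carbohydrate[i] <- comp[["carbohydrate"]]
    v <- plant_nppu(comp, coeffs)
    tab$C_content[i] <- carbon_content(comp, coeffs)
    tab$nppu_g[i] <- v$value_g
    tab$nppu_kg[i] <- v$value_kg
  }
  attr(tab, "schema_id") <- "plant"
  tab
}

row_species_record <- function(tab, i) {
  comp <- NULL
  comp_fields <- c("protein", "lipid", "ash", "moisture", "carbohydrate")
  if (all(comp_fields %in% names(tab)) &&
      !anyNA(unlist(tab[i, comp_fields]))) {
    comp <- proximate_composition(tab$protein[i], tab$lipid[i], tab$ash[i],
                                  tab$moisture[i],
                                  carbohydrate = tab$carbohydrate[i])
  }
  name_col <- if ("species" %in% names(tab)) "species" else "ingredient"
  species_record(
    species = tab[[name_col]][i],
    trophic = trophic_parameters(
      TL = tab$TL[i],
      TL_SD = if (!is.na(tab$TL_SD[i])) tab$TL_SD[i] else 0,
      TE = if ("TE" %in% names(tab)) tab$TE[i] else NA_real_,
      ecosystem = if ("ecosystem" %in% names(tab) && !is.na(tab$ecosystem[i]))
        tab$ecosystem[i] else ""
    ),
    composition = comp
  )
}

#' Compute NPPU columns for a fresh-organism table under a tier policy
#'
#' For every row of a table in a fresh-organism internal layout
#' (`marine_fresh`, `freshwater_fresh`, `other_animal_fresh`, `milk`),
#' resolves the effective (C, TE, TL) triple under the class/tier policy and
#' fills `C_content` (the resolved carbon content actually used),
#' `NPPU_g/kg` and `NPPU_kg/kg`. Specific carbon contents are derived from
#' the row's proximate composition.
#'
#' @param tab data frame in a fresh-organism internal layout.
#' @param class ingredient class: `"marine"`, `"freshwater"`,
#'   `"other_animal"` or `"milk"`.
#' @param tier tier label within the class (see [tier_policy()]).
#' @param defaults a [generic_defaults()] object.
#' @return The table with `C_content`, `nppu_g`, `nppu_kg` filled.
#' @export
compute_fresh_table <- function(tab, class, tier = "T1",
                                defaults = generic_defaults()) {
  policy <- tier_policy(class, tier)
  for (i in seq_len(nrow(tab))) {
    rec <- row_species_record(tab, i)
    p <- resolve_parameters(rec, policy, defaults)
    v <- nppu_for_class(rec, policy, defaults)
    tab$C_content[i] <- p$C_content
    tab$nppu_g[i] <- v$value_g
    tab$nppu_kg[i] <- v$value_kg
  }
  tab
}
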