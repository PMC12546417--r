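# independent oracles and small generators shared across test files

# central finite-difference gradient of f(C, TE, TL) = C * (1/TE)^(TL - 1),
# independent of the analytic expressions under test
fd_nppu_gradient <- function(C, TE, TL, h = 1e-6) {
  f <- function(C, TE, TL) C * (1 / TE)^(TL - 1)
  list(
    d_dC = (f(C + h, TE, TL) - f(C - h, TE, TL)) / (2 * h),
    d_dTE = (f(C, TE + h, TL) - f(C, TE - h, TL)) / (2 * h),
    d_dTL = (f(C, TE, TL + h) - f(C, TE, TL - h)) / (2 * h)
  )
}

rel_diff <- function(a, b) abs(a - b) / pmax(abs(a), abs(b), .Machine$double.eps)

# a plain composition used in several files
example_composition <- function() {
  proximate_composition(protein = 500, lipid = 100, ash = 40, moisture = 60,
                        carbohydrate = 300)
}

# write a CSV fixture from header + rows (character vectors)
write_csv_lines <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

# minimal marine_fresh file content with controllable cells
marine_fresh_lines <- function(TL = "3.2", TE = "0.119", nppu_g = "500",
                               nppu_kg = NULL, sep = ",", dec = ".") {
  if (is.null(nppu_kg)) nppu_kg <- as.character(as.numeric(nppu_g) / 1000)
  num <- function(x) if (dec == ",") gsub(".", ",", x, fixed = TRUE) else x
  hdr <- c("Specie", "Common_name", "Common_name_FR", "Ecosystem",
           "Trophic_level", "Trophic_level_SD", "Transfer_efficiency",
           "Comment", "Moisture_%", "Protein_%", "Fat_%", "Ash_%",
           "Carbohydrates_%", "Source_TL", "Source_Body_Composition",
           "Source_TE", "C_content", "NPPU_g/kg", "NPPU_kg/kg")
  row <- c("Engraulis ringens", "anchoveta", "anchois", "Upwelling",
           num(TL), num("0.2"), num(TE), "", num("70.5"), num("18.0"),
           num("6.0"), num("3.5"), num("2.0"), "src", "src", "src",
           num("111.1"), num(nppu_g), num(nppu_kg))
  c(paste(hdr, collapse = sep), paste(row, collapse = sep))
}
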