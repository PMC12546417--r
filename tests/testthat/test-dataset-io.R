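test_that("the schema registry covers the published file layouts", {
  ids <- schema_ids()
  expect_setequal(ids, c("plant", "marine_fresh", "marine_ingredient",
                         "freshwater_fresh", "freshwater_ingredient",
                         "other_animal_fresh", "other_animal_ingredient",
                         "milk", "nppu_sd"))
  for (id in ids) {
    s <- table_schema(id)
    expect_false(any(duplicated(s$file)))
    expect_false(any(duplicated(s$internal)))
  }
  # every schema carrying a full NPPU pair has both unit columns
  for (id in c("plant", "marine_fresh", "freshwater_fresh",
               "other_animal_fresh", "milk", "nppu_sd")) {
    s <- table_schema(id)
    expect_true(all(c("NPPU_g/kg", "NPPU_kg/kg") %in% s$file))
  }
  expect_error(table_schema("nope"), "unknown schema")
})

test_that("write then read round-trips a synthetic table value-identically", {
  tab <- generate_species(fixture_config(n_species = 8, seed = 21))
  path <- tempfile(fileext = ".csv")
  write_nppu_table(tab, path, "marine_fresh")
  back <- read_nppu_table(path, "marine_fresh")
  expect_identical(names(back), names(tab))
  for (col in names(tab)) {
    if (is.numeric(tab[[col]])) {
      expect_lt(max(rel_diff(back[[col]], tab[[col]])), 1e-9)
    } else {
      expect_identical(back[[col]], tab[[col]])
    }
  }
  # read then write reproduces the file
  path2 <- tempfile(fileext = ".csv")
  write_nppu_table(back, path2, "marine_fresh")
  expect_identical(readLines(path2), readLines(path))
})

test_that("a header-only file yields an empty record set", {
  path <- write_csv_lines(marine_fresh_lines()[1])
  tab <- read_nppu_table(path, "marine_fresh")
  expect_equal(nrow(tab), 0)
  # and writing an empty table emits a header-only file
  out <- tempfile(fileext = ".csv")
  write_nppu_table(tab, out, "marine_fresh")
  expect_equal(length(readLines(out)), 1)
})

test_that("transfer efficiencies in percent dialect are normalized to fractions", {
  path <- write_csv_lines(marine_fresh_lines(TE = "10"))
  tab <- read_nppu_table(path, "marine_fresh")
  expect_equal(tab$TE, 0.10)
  frac <- read_nppu_table(write_csv_lines(marine_fresh_lines(TE = "0.119")),
                          "marine_fresh")
  expect_equal(frac$TE, 0.119)
})

test_that("semicolon-delimited, comma-decimal files are sniffed and read", {
  path <- write_csv_lines(marine_fresh_lines(TL = "3.2", sep = ";", dec = ","))
  tab <- read_nppu_table(path, "marine_fresh")
  expect_equal(tab$TL, 3.2)
  expect_equal(tab$moisture, 705)   # 70.5 % -> g/kg
  expect_identical(tab$species, "Engraulis ringens")
})

test_that("percent composition columns convert to g/kg and back", {
  path <- write_csv_lines(marine_fresh_lines())
  tab <- read_nppu_table(path, "marine_fresh")
  expect_equal(tab$protein, 180)
  out <- tempfile(fileext = ".csv")
  write_nppu_table(tab, out, "marine_fresh")
  line <- strsplit(readLines(out)[2], ",")[[1]]
  hdr <- strsplit(readLines(out)[1], ",")[[1]]
  expect_equal(as.numeric(line[hdr == "Protein_%"]), 18.0)
})

test_that("missing required columns and unparseable cells are reported by name and row", {
  lines <- marine_fresh_lines()
  broken <- sub("Trophic_level,", "TL_level,", lines[1], fixed = TRUE)
  expect_error(read_nppu_table(write_csv_lines(c(broken, lines[2])),
                               "marine_fresh"),
               "Trophic_level")
  bad_cell <- sub("3.2", "three", lines[2], fixed = TRUE)
  expect_error(read_nppu_table(write_csv_lines(c(lines[1], bad_cell)),
                               "marine_fresh"),
               "row 1")
})

test_that("writing refuses records with missing required fields, before any bytes", {
  tab <- generate_species(fixture_config(n_species = 2, seed = 3))
  tab$nppu_g[2] <- NA
  out <- tempfile(fileext = ".csv")
  expect_error(write_nppu_table(tab, out, "marine_fresh"), "nppu_g")
  expect_false(file.exists(out))
})

test_that("emitted NPPU unit columns always satisfy kg = g/1000", {
  tab <- generate_species(fixture_config(n_species = 4, seed = 9))
  tab$nppu_kg <- tab$nppu_kg * 1.5  # corrupt; writer re-derives
  out <- tempfile(fileext = ".csv")
  write_nppu_table(tab, out, "marine_fresh")
  back <- read_nppu_table(out, "marine_fresh")
  expect_equal(back$nppu_kg, back$nppu_g / 1000, tolerance = 1e-12)
})

test_that("validation flags injected faults at the right rows and rules", {
  ok <- validate_nppu_table(write_csv_lines(marine_fresh_lines()),
                            "marine_fresh")
  expect_true(ok$passed)
  expect_equal(nrow(ok$findings), 0)

  bad_units <- validate_nppu_table(
    write_csv_lines(marine_fresh_lines(nppu_g = "500", nppu_kg = "0.9")),
    "marine_fresh")
  expect_false(bad_units$passed)
  expect_true(any(bad_units$findings$rule == "nppu_unit_consistency" &
                    bad_units$findings$row == 1))

  low_tl <- validate_nppu_table(
    write_csv_lines(marine_fresh_lines(TL = "0.5")), "marine_fresh")
  expect_true(any(low_tl$findings$rule == "tl_minimum"))

  bad_te <- validate_nppu_table(
    write_csv_lines(marine_fresh_lines(TE = "-0.2")), "marine_fresh")
  expect_true(any(bad_te$findings$rule == "te_range"))

  lines <- marine_fresh_lines()
  missing_col <- sub("Trophic_level,", "X,", lines[1], fixed = TRUE)
  rep <- validate_nppu_table(write_csv_lines(c(missing_col, lines[2])),
                             "marine_fresh")
  expect_true(any(rep$findings$rule == "missing_column"))
  bad_cell <- sub("3.2", "three", lines[2], fixed = TRUE)
  rep2 <- validate_nppu_table(write_csv_lines(c(lines[1], bad_cell)),
                              "marine_fresh")
  expect_true(any(rep2$findings$rule == "unparseable"))
})

test_that("tables produced by the computation pipeline validate cleanly", {
  tab <- generate_species(fixture_config(n_species = 6, seed = 31))
  tab <- compute_fresh_table(tab, "marine", "T3")
  path <- tempfile(fileext = ".csv")
  write_nppu_table(tab, path, "marine_fresh")
  rep <- validate_nppu_table(path, "marine_fresh")
  expect_true(rep$passed)
})

test_that("plant tables are computed and round-tripped", {
  plant <- data.frame(
    feed_name = c("rapeseed meal", "wheat"), feed_name_fr = c("colza", "ble"),
    category = "plant", protein = c(340, 120), lipid = c(25, 18),
    ash = c(70, 17), carbohydrate = c(NA, 700), moisture = c(110, 130),
    C_content = NA_real_, nppu_g = NA_real_, nppu_kg = NA_real_,
    source = "synthetic", stringsAsFactors = FALSE
  )
  out <- compute_plant_table(plant)
  expect_equal(out$nppu_g, out$C_content)
  # first row: carbohydrate filled by difference
  expect_equal(out$carbohydrate[1], 1000 - 340 - 25 - 70 - 110)
  expect_equal(out$nppu_kg[2],
               (0.531 * 120 + 0.774 * 18 + 0.444 * 700) / 1000)
  path <- tempfile(fileext = ".csv")
  write_nppu_table(out, path, "plant")
  rep <- validate_nppu_table(path, "plant")
  expect_true(rep$passed)
})
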