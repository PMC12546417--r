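#' Reference table schemas
#'
#' Column layouts of the published NPPU reference CSV files. Nine schemas
#' cover the eleven files: the three marine fresh-fish tier files share one
#' schema, as do the two freshwater fresh-fish tier files.
#'
#' On disk, composition columns are percentages and column names keep their
#' verbatim `%` and `/` characters; internally compositions are g/kg and
#' names are safe identifiers. Transfer efficiencies are stored internally
#' as fractions; files carrying them as percentages (values above 1) are
#' normalized on read.
#'
#' @param schema_id one of `"plant"`, `"marine_fresh"`, `"marine_ingredient"`,
#'   `"freshwater_fresh"`, `"freshwater_ingredient"`, `"other_animal_fresh"`,
#'   `"other_animal_ingredient"`, `"milk"`, `"nppu_sd"`.
#' @return A data frame describing the schema: file column name, internal
#'   name, type (`"text"`/`"numeric"`), unit handling, and whether required.
#' @export
table_schema <- function(schema_id) {
  schemas <- schema_registry()
  if (!schema_id %in% names(schemas)) {
    stop(sprintf("unknown schema '%s'; known schemas: %s", schema_id,
                 paste(names(schemas), collapse = ", ")), call. = FALSE)
  }
  schemas[[schema_id]]
}

#' @rdname table_schema
#' @export
schema_ids <- function() names(schema_registry())

# column helper: unit is one of
#   none     - read verbatim
#   percent  - file %  <-> internal g/kg (x10 on read)
#   te       - transfer efficiency; values > 1 on file are percent
#   numeric  - plain number
col_ <- function(file, internal, type = "numeric", unit = "numeric",
                 required = TRUE) {
  data.frame(file = file, internal = internal, type = type, unit = unit,
             required = required, stringsAsFactors = FALSE)
}

identity_cols <- function() rbind(
  col_("Specie", "species", "text", "none"),
  col_("Common_name", "common_name", "text", "none", required = FALSE),
  col_("Common_name_FR", "common_name_fr", "text", "none", required = FALSE)
)

trophic_cols <- function() rbind(
  col_("Ecosystem", "ecosystem", "text", "none", required = FALSE),
  col_("Trophic_level", "TL"),
  col_("Trophic_level_SD", "TL_SD", required = FALSE),
  col_("Transfer_efficiency", "TE", unit = "te", required = FALSE),
  col_("Comment", "comment", "text", "none", required = FALSE)
)

composition_cols <- function(dry_matter = FALSE) {
  out <- if (dry_matter) col_("Dry_matter_%", "dry_matter", unit = "percent",
                              required = FALSE) else NULL
  rbind(out,
        col_("Moisture_%", "moisture", unit = "percent"),
        col_("Protein_%", "protein", unit = "percent"),
        col_("Fat_%", "lipid", unit = "percent"),
        col_("Ash_%", "ash", unit = "percent"),
        col_("Carbohydrates_%", "carbohydrate", unit = "percent"))
}

source_cols <- function() rbind(
  col_("Source_TL", "source_tl", "text", "none", required = FALSE),
  col_("Source_Body_Composition", "source_body_composition", "text", "none",
       required = FALSE),
  col_("Source_TE", "source_te", "text", "none", required = FALSE)
)

nppu_cols <- function() rbind(
  col_("C_content", "C_content", required = FALSE),
  col_("NPPU_g/kg", "nppu_g"),
  col_("NPPU_kg/kg", "nppu_kg")
)

schema_registry <- function() {
  fresh_fish <- rbind(identity_cols(), trophic_cols(), composition_cols(),
                      source_cols(), nppu_cols())
  fresh_fish_dm <- rbind(identity_cols(), trophic_cols(),
                         composition_cols(dry_matter = TRUE),
                         source_cols(), nppu_cols())
  list(
    plant = rbind(
      col_("Feed_name", "feed_name", "text", "none"),
      col_("Feed_name_FR", "feed_name_fr", "text", "none", required = FALSE),
      col_("Category", "category", "text", "none", required = FALSE),
      col_("Protein_%", "protein", unit = "percent"),
      col_("Fat_%", "lipid", unit = "percent"),
      col_("Ash_%", "ash", unit = "percent"),
      col_("Carbohydrates_%", "carbohydrate", unit = "percent"),
      col_("C_content", "C_content", required = FALSE),
      col_("NPPU_g/kg", "nppu_g"),
      col_("NPPU_kg/kg", "nppu_kg"),
      col_("Source", "source", "text", "none", required = FALSE)
    ),
    marine_fresh = fresh_fish,
    marine_ingredient = rbind(
      identity_cols(),
      col_("NPPU_kg/kg", "nppu_kg"),
      col_("Yield_meal_generic", "yield_meal_generic"),
      col_("Yield_oil_generic", "yield_oil_generic"),
      col_("Yield_meal_specific", "yield_meal_specific", required = FALSE),
      col_("Yield_oil_specific", "yield_oil_specific", required = FALSE),
      col_("Energy_meal", "energy_meal"),
      col_("Energy_oil", "energy_oil"),
      col_("Factor_meal", "factor_meal", required = FALSE),
      col_("Factor_oil", "factor_oil", required = FALSE),
      col_("NPPU_meal_mass", "nppu_meal_mass", required = FALSE),
      col_("NPPU_oil_mass", "nppu_oil_mass", required = FALSE),
      do.call(rbind, lapply(c("T11", "T21", "T31", "T12", "T22", "T32"),
        function(v) rbind(
          col_(paste0("NPPU_meal_", v), paste0("nppu_meal_", v),
               required = FALSE),
          col_(paste0("NPPU_oil_", v), paste0("nppu_oil_", v),
               required = FALSE))))
    ),
    freshwater_fresh = fresh_fish_dm,
    freshwater_ingredient = rbind(
      identity_cols(),
      col_("NPPU_T1(kg/kg)", "nppu_t1_kg"),
      col_("NPPU_T2(kg/kg)", "nppu_t2_kg"),
      col_("Yield_meal_generic", "yield_meal_generic"),
      col_("Yield_oil_generic", "yield_oil_generic"),
      col_("Yield_meal_specific", "yield_meal_specific", required = FALSE),
      col_("Yield_oil_specific", "yield_oil_specific", required = FALSE),
      col_("Energy_meal", "energy_meal"),
      col_("Energy_oil", "energy_oil"),
      col_("Factor_meal", "factor_meal", required = FALSE),
      col_("Factor_oil", "factor_oil", required = FALSE),
      do.call(rbind, lapply(c("T11", "T21", "T12", "T22"),
        function(v) rbind(
          col_(paste0("NPPU_meal_mass_", v), paste0("nppu_meal_mass_", v),
               required = FALSE),
          col_(paste0("NPPU_meal_energy_", v), paste0("nppu_meal_energy_", v),
               required = FALSE))))
    ),
    other_animal_fresh = fresh_fish_dm,
    other_animal_ingredient = rbind(
      col_("Ingredient", "ingredient", "text", "none"),
      col_("Specie", "species", "text", "none"),
      col_("NPPU_T1(kg/kg)", "nppu_t1_kg"),
      col_("Comment", "comment", "text", "none", required = FALSE)
    ),
    milk = rbind(
      col_("Ingredient", "ingredient", "text", "none"),
      col_("Ingredient_FR", "ingredient_fr", "text", "none", required = FALSE),
      trophic_cols()[-1, ],   # no Ecosystem column in the milk table
      composition_cols(),
      source_cols(),
      nppu_cols()
    ),
    nppu_sd = rbind(
      col_("Specie", "species", "text", "none"),
      col_("Trophic_level", "TL", required = FALSE),
      col_("Trophic_level_SD", "TL_SD", required = FALSE),
      col_("NPPU_g/kg", "nppu_g"),
      col_("NPPU_kg/kg", "nppu_kg"),
      col_("NPPU_SD_g/kg", "nppu_sd_g"),
      col_("NPPU_SD_kg/kg", "nppu_sd_kg")
    )
  )
}

# strip spaces when matching headers: extracted sources sometimes show
# "Moisture_ %" for "Moisture_%"
canonical_header <- function(x) gsub("[[:space:]]+", "", x)

sniff_dialect <- function(path) {
  first <- readLines(path, n = 1L, encoding = "UTF-8", warn = FALSE)
  n_semi <- lengths(regmatches(first, gregexpr(";", first, fixed = TRUE)))
  n_comma <- lengths(regmatches(first, gregexpr(",", first, fixed = TRUE)))
  if (length(first) == 0 || n_semi > n_comma) {
    list(sep = ";", dec = ",")
  } else {
    list(sep = ",", dec = ".")
  }
}

# raw read: all columns as character, headers verbatim
read_raw_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  dialect <- sniff_dialect(path)
  raw <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                           quote = "\"", colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = character(0), fileEncoding = "UTF-8",
                           comment.char = "")
  list(data = raw, dialect = dialect)
}

parse_numeric_cell <- function(x, dec) {
  if (dec == ",") x <- gsub(",", ".", x, fixed = TRUE)
  suppressWarnings(as.numeric(x))
}

#' Read a reference NPPU table
#'
#' Reads a CSV file following one of the published layouts
#' ([table_schema()]). The reader sniffs the delimiter (comma vs semicolon)
#' and decimal mark (dot vs comma), maps columns by header name
#' (order-insensitive, whitespace-tolerant), converts percentage
#' composition columns to g/kg, normalizes transfer efficiencies given as
#' percentages to fractions, and turns empty cells into `NA`.
#'
#' @param path path to a delimited text file.
#' @param schema_id schema identifier, see [schema_ids()].
#' @return A data frame with the schema's internal column names, carrying
#'   attribute `schema_id`.
#' @export
read_nppu_table <- function(path, schema_id) {
  schema <- table_schema(schema_id)
  raw <- read_raw_table(path)
  hdr <- canonical_header(names(raw$data))
  want <- canonical_header(schema$file)

  missing_req <- schema$file[schema$required & !(want %in% hdr)]
  if (length(missing_req) > 0) {
    stop(sprintf("schema '%s': missing required column(s): %s", schema_id,
                 paste(missing_req, collapse = ", ")), call. = FALSE)
  }

  n <- nrow(raw$data)
  out <- vector("list", nrow(schema))
  names(out) <- schema$internal
  for (i in seq_len(nrow(schema))) {
    pos <- match(want[i], hdr)
    if (is.na(pos)) {
      out[[i]] <- if (schema$type[i] == "text") rep(NA_character_, n)
                  else rep(NA_real_, n)
      next
    }
    cell <- raw$data[[pos]]
    cell[!nzchar(trimws(cell))] <- NA
    if (schema$type[i] == "text") {
      out[[i]] <- cell
    } else {
      val <- parse_numeric_cell(cell, raw$dialect$dec)
      bad <- which(!is.na(cell) & is.na(val))
      if (length(bad) > 0) {
        stop(sprintf("schema '%s', column '%s': unparseable numeric cell at row %d ('%s')",
                     schema_id, schema$file[i], bad[1], cell[bad[1]]),
             call. = FALSE)
      }
      if (schema$unit[i] == "percent") val <- val * 10          # % -> g/kg
      if (schema$unit[i] == "te") {
        val <- ifelse(!is.na(val) & val > 1, val / 100, val)    # % -> fraction
      }
      out[[i]] <- val
    }
  }
  out <- as.data.frame(out, check.names = FALSE, stringsAsFactors = FALSE)
  attr(out, "schema_id") <- schema_id
  out
}

#' Write a reference NPPU table
#'
#' Writes a data frame in the internal layout of a schema (as produced by
#' [read_nppu_table()] or the computation functions) to a canonical CSV:
#' comma-separated, dot-decimal, UTF-8, header row exactly matching the
#' schema's published column names. Internal g/kg composition columns are
#' emitted as percentages; absent values become empty cells.
#'
#' @param records a data frame with the schema's internal column names.
#' @param path output file path.
#' @param schema_id schema identifier.
#' @return The path, invisibly.
#' @export
write_nppu_table <- function(records, path, schema_id) {
  schema <- table_schema(schema_id)
  missing_cols <- schema$internal[schema$required &
                                    !(schema$internal %in% names(records))]
  if (length(missing_cols) > 0) {
    stop(sprintf("schema '%s': records are missing required field(s): %s",
                 schema_id, paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  n <- nrow(records)
  for (i in which(schema$required)) {
    v <- records[[schema$internal[i]]]
    if (n > 0 && anyNA(v)) {
      stop(sprintf("schema '%s': required field '%s' has missing values",
                   schema_id, schema$internal[i]), call. = FALSE)
    }
  }
  # kg/g unit consistency is enforced at write time for NPPU pairs
  if (all(c("nppu_g", "nppu_kg") %in% names(records)) && n > 0) {
    records$nppu_kg <- records$nppu_g / 1000
  }

  cols <- vector("list", nrow(schema))
  for (i in seq_len(nrow(schema))) {
    v <- if (schema$internal[i] %in% names(records)) {
      records[[schema$internal[i]]]
    } else if (schema$type[i] == "text") rep(NA_character_, n) else rep(NA_real_, n)
    if (schema$type[i] == "numeric") {
      v <- as.numeric(v)
      if (schema$unit[i] == "percent") v <- v / 10   # g/kg -> %
      cols[[i]] <- ifelse(is.na(v), "", formatC(v, digits = 15, format = "g"))
    } else {
      v <- as.character(v)
      v[is.na(v)] <- ""
      needs_quote <- grepl('[",\n]', v)
      v[needs_quote] <- paste0('"', gsub('"', '""', v[needs_quote]), '"')
      cols[[i]] <- v
    }
  }
  lines <- c(paste(schema$file, collapse = ","),
             if (n > 0) do.call(paste, c(cols, sep = ",")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = FALSE)
  invisible(path)
}

finding <- function(row, column, rule, severity, message) {
  data.frame(row = row, column = column, rule = rule, severity = severity,
             message = message, stringsAsFactors = FALSE)
}

#' Validate a reference NPPU table
#'
#' Checks a CSV file against a schema's structural and semantic rules and
#' returns findings rather than raising errors. Rules:
#' * `missing_column`: a required column is absent (error);
#' * `unparseable`: a non-empty numeric cell does not parse (error);
#' * `nppu_unit_consistency`: `NPPU_g/kg` and `NPPU_kg/kg` must agree
#'   within 0.5 g/kg (error);
#' * `te_range`: transfer efficiency in (0, 1] after normalization (error);
#' * `tl_minimum`: trophic level >= 1 (error);
#' * `composition_range`: each composition percentage in \[0, 100\] (error);
#' * `composition_closure`: composition percentages sum to at most 101 (error);
#' * `negative_sd`: standard deviations must be non-negative (error).
#'
#' @inheritParams read_nppu_table
#' @return An object of class `validation_report`: a list with `findings`
#'   (a data frame of row/column/rule/severity/message), `summary` counts,
#'   and `passed` (`TRUE` iff no error-severity finding).
#' @export
validate_nppu_table <- function(path, schema_id) {
  schema <- table_schema(schema_id)
  findings <- list()
  add <- function(f) findings[[length(findings) + 1]] <<- f

  raw <- read_raw_table(path)
  hdr <- canonical_header(names(raw$data))
  want <- canonical_header(schema$file)
  for (i in which(schema$required)) {
    if (!(want[i] %in% hdr)) {
      add(finding(NA_integer_, schema$file[i], "missing_column", "error",
                  sprintf("required column '%s' is absent", schema$file[i])))
    }
  }

  n <- nrow(raw$data)
  vals <- list()
  for (i in seq_len(nrow(schema))) {
    pos <- match(want[i], hdr)
    if (is.na(pos) || schema$type[i] == "text") next
    cell <- raw$data[[pos]]
    cell[!nzchar(trimws(cell))] <- NA
    v <- parse_numeric_cell(cell, raw$dialect$dec)
    for (r in which(!is.na(cell) & is.na(v))) {
      add(finding(r, schema$file[i], "unparseable", "error",
                  sprintf("cell '%s' is not a number", cell[r])))
    }
    if (schema$unit[i] == "te") v <- ifelse(!is.na(v) & v > 1, v / 100, v)
    vals[[schema$internal[i]]] <- v
  }

  check_rows <- function(v, bad, column, rule, msg_fmt) {
    for (r in which(!is.na(v) & bad)) {
      add(finding(r, column, rule, "error", sprintf(msg_fmt, v[r])))
    }
  }

  if (!is.null(vals$nppu_g) && !is.null(vals$nppu_kg)) {
    d <- abs(vals$nppu_g - 1000 * vals$nppu_kg)
    check_rows(d, d > 0.5, "NPPU_kg/kg", "nppu_unit_consistency",
               "NPPU g/kg and kg/kg columns disagree by %.4g g/kg")
  }
  if (!is.null(vals$TE)) {
    check_rows(vals$TE, vals$TE <= 0 | vals$TE > 1, "Transfer_efficiency",
               "te_range", "transfer efficiency %.4g outside (0, 1]")
  }
  if (!is.null(vals$TL)) {
    check_rows(vals$TL, vals$TL < 1, "Trophic_level", "tl_minimum",
               "trophic level %.4g is below 1")
  }
  comp_fields <- intersect(c("protein", "lipid", "ash", "moisture",
                             "carbohydrate"), names(vals))
  if (length(comp_fields) > 0) {
    pct <- lapply(vals[comp_fields], function(v) v / 10)  # back to %
    for (f in comp_fields) {
      fcol <- schema$file[schema$internal == f]
      check_rows(pct[[f]], pct[[f]] < 0 | pct[[f]] > 100, fcol,
                 "composition_range", "composition percentage %.4g outside [0, 100]")
    }
    tot <- Reduce(`+`, lapply(pct, function(v) ifelse(is.na(v), 0, v)))
    check_rows(tot, tot > 101, "composition", "composition_closure",
               "composition percentages sum to %.4g, above 101")
  }
  sd_fields <- intersect(c("TL_SD", "nppu_sd_g", "nppu_sd_kg"), names(vals))
  for (f in sd_fields) {
    fcol <- schema$file[schema$internal == f]
    check_rows(vals[[f]], vals[[f]] < 0, fcol, "negative_sd",
               "standard deviation %.4g is negative")
  }

  findings <- if (length(findings) > 0) {
    do.call(rbind, findings)
  } else {
    finding(integer(0), character(0), character(0), character(0), character(0))
  }
  structure(
    list(findings = findings,
         summary = c(errors = sum(findings$severity == "error"),
                     warnings = sum(findings$severity == "warning"),
                     rows = n),
         passed = !any(findings$severity == "error"),
         schema_id = schema_id, path = path),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation of '%s' against schema '%s': %s\n", x$path,
              x$schema_id, if (x$passed) "PASS" else "FAIL"))
  cat(sprintf("  %d row(s), %d error(s), %d warning(s)\n",
              x$summary[["rows"]], x$summary[["errors"]],
              x$summary[["warnings"]]))
  if (nrow(x$findings) > 0) {
    print(utils::head(x$findings, 20))
    if (nrow(x$findings) > 20) cat(sprintf("  ... and %d more finding(s)\n",
                                           nrow(x$findings) - 20))
  }
  invisible(x)
}
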