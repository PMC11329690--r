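#' @title Typed tabular readers for pipeline inputs
#'
#' @description
#' All pipeline inputs are delimiter-separated text with a header row, UTF-8,
#' "." decimal separator. Each reader validates the declared invariants of its
#' table type and fails with an informative error naming the offending column
#' or row. Locale decimal commas are rejected (cells that do not parse as
#' numbers raise an error with the row index).
#'
#' Table types:
#' \itemize{
#'   \item Food registry: \code{food_id}, \code{name}, \code{food_group}.
#'   \item Intake table: \code{person_id} plus one column per food, g/day, non-negative.
#'   \item Nutrient table: \code{person_id} plus nutrient columns; must contain
#'     \code{energy_kj} (> 0 for every person).
#'   \item Person table: \code{person_id}, \code{sex}, \code{age},
#'     \code{education}, \code{income}, \code{municipality}, \code{smoking},
#'     \code{physical_activity}, \code{bmi}, \code{waist}, \code{survey_weight}.
#'   \item Impact factor table: \code{food_id}, \code{gwp}, \code{land_use},
#'     \code{marine_eutroph}, \code{freshwater_eutroph} (all per gram, >= 0),
#'     optional \code{origin_flag}, \code{adapted}.
#' }
#'
#' @param path path to a CSV/TSV file (delimiter sniffed from the header line).
#' @param per_kg if \code{TRUE}, impact factors in the file are per kg of food
#'   and are divided by 1000 at load so the in-memory table is always per gram;
#'   the conversion is recorded in \code{attr(, "converted_from_per_kg")}.
#' @return A validated \code{data.frame}.
#' @name core-io
NULL

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, fileEncoding = "UTF-8")
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(what, ": missing mandatory column(s): ", paste(missing, collapse = ", "))
  invisible(df)
}

coerce_numeric_cols <- function(df, cols, what) {
  for (cl in cols) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(parsed) & !is.na(v) & v != "")
      if (length(bad))
        stop(what, ": column '", cl, "' has unparsable value at row ", bad[1L],
             " ('", v[bad[1L]], "')")
      v <- parsed
    }
    df[[cl]] <- v
  }
  df
}

#' @rdname core-io
#' @export
read_food_registry <- function(path) {
  df <- read_delim_auto(path)
  require_columns(df, c("food_id", "name", "food_group"), "food registry")
  if (anyDuplicated(df$food_id))
    stop("food registry: duplicated food_id: ",
         paste(unique(df$food_id[duplicated(df$food_id)]), collapse = ", "))
  df
}

#' @rdname core-io
#' @export
read_intake_table <- function(path) {
  df <- read_delim_auto(path)
  require_columns(df, "person_id", "intake table")
  foods <- setdiff(names(df), "person_id")
  if (!length(foods)) stop("intake table: no food columns")
  df <- coerce_numeric_cols(df, foods, "intake table")
  for (cl in foods) {
    bad <- which(df[[cl]] < 0)
    if (length(bad))
      stop("intake table: negative intake for '", cl, "' at row ", bad[1L])
  }
  if (anyDuplicated(df$person_id)) stop("intake table: duplicated person_id")
  df
}

#' @rdname core-io
#' @export
read_nutrient_table <- function(path) {
  df <- read_delim_auto(path)
  require_columns(df, c("person_id", "energy_kj"), "nutrient table")
  nut <- setdiff(names(df), "person_id")
  df <- coerce_numeric_cols(df, nut, "nutrient table")
  if (any(df$energy_kj <= 0))
    stop("nutrient table: energy_kj must be > 0 for every person (row ",
         which(df$energy_kj <= 0)[1L], ")")
  if (all(c("protein_g", "plant_protein_g", "animal_protein_g") %in% names(df))) {
    excess <- df$plant_protein_g + df$animal_protein_g - df$protein_g
    if (any(excess > 1e-6 * pmax(df$protein_g, 1)))
      stop("nutrient table: plant + animal protein exceeds total protein (row ",
           which(excess > 1e-6 * pmax(df$protein_g, 1))[1L], ")")
  }
  df
}

person_categorical_ranges <- list(
  education = 1:3, income = 1:10, smoking = 1:4, physical_activity = 1:4
)

#' @rdname core-io
#' @export
read_person_table <- function(path) {
  df <- read_delim_auto(path)
  require_columns(df, c("person_id", "sex", "age", "survey_weight"), "person table")
  num_cols <- intersect(c("age", "bmi", "waist", "survey_weight",
                          names(person_categorical_ranges)), names(df))
  df <- coerce_numeric_cols(df, num_cols, "person table")
  if (any(df$survey_weight <= 0))
    stop("person table: survey_weight must be > 0 (row ",
         which(df$survey_weight <= 0)[1L], ")")
  bad_sex <- !df$sex %in% c("male", "female", "missing")
  if (any(bad_sex))
    stop("person table: sex must be 'male' or 'female' (row ", which(bad_sex)[1L], ")")
  for (cl in intersect(names(person_categorical_ranges), names(df))) {
    v <- df[[cl]]
    ok <- is.na(v) | v %in% person_categorical_ranges[[cl]]
    if (!all(ok))
      stop("person table: '", cl, "' outside declared range (row ", which(!ok)[1L], ")")
  }
  if ("municipality" %in% names(df)) {
    ok <- df$municipality %in% c("urban", "semi-urban", "rural", "missing")
    if (!all(ok))
      stop("person table: unknown municipality class (row ", which(!ok)[1L], ")")
  }
  df
}

#' @rdname core-io
#' @export
read_impact_factor_table <- function(path, per_kg = FALSE) {
  df <- read_delim_auto(path)
  impacts <- c("gwp", "land_use", "marine_eutroph", "freshwater_eutroph")
  require_columns(df, c("food_id", impacts), "impact factor table")
  df <- coerce_numeric_cols(df, impacts, "impact factor table")
  if (anyDuplicated(df$food_id)) stop("impact factor table: duplicated food_id")
  for (cl in impacts) {
    if (any(df[[cl]] < 0))
      stop("impact factor table: negative factor in '", cl, "'")
  }
  if (per_kg) for (cl in impacts) df[[cl]] <- df[[cl]] / 1000
  if (!"adapted" %in% names(df)) df$adapted <- FALSE
  attr(df, "converted_from_per_kg") <- per_kg
  df
}

#' Cross-table consistency check
#'
#' Verifies that the four pipeline inputs resolve against each other: every
#' person in the intake table has attributes, every consumed food has an
#' impact factor and a registry entry, and vice versa. The pipeline refuses
#' to proceed when a consumed food lacks an impact factor unless
#' \code{drop_missing_factors = TRUE}.
#'
#' @param intakes intake table (persons x foods).
#' @param persons person attribute table.
#' @param factors impact factor table.
#' @param foods food registry.
#' @param drop_missing_factors drop foods without factors instead of failing.
#' @return An object of class \code{"diet_consistency"}: a list of id vectors
#'   (\code{persons_without_attributes}, \code{foods_without_factors},
#'   \code{factors_without_foods}, \code{foods_not_registered}) plus
#'   \code{ok} and, when dropping was requested, the cleaned intake table.
#' @export
join_consistency_check <- function(intakes, persons, factors, foods,
                                   drop_missing_factors = FALSE) {
  food_cols <- setdiff(names(intakes), "person_id")
  common_persons <- intersect(intakes$person_id, persons$person_id)
  if (!length(common_persons))
    stop("fatal: intake and person tables share no person_id")
  rep <- list(
    persons_without_attributes = setdiff(intakes$person_id, persons$person_id),
    foods_without_factors      = setdiff(food_cols, factors$food_id),
    factors_without_foods      = setdiff(factors$food_id, food_cols),
    foods_not_registered       = setdiff(food_cols, foods$food_id)
  )
  rep$ok <- !length(rep$persons_without_attributes) &&
    !length(rep$foods_without_factors) && !length(rep$foods_not_registered)
  if (length(rep$foods_without_factors)) {
    if (drop_missing_factors) {
      warning("dropping foods without impact factors: ",
              paste(rep$foods_without_factors, collapse = ", "))
      rep$intakes <- intakes[, c("person_id",
                                 setdiff(food_cols, rep$foods_without_factors))]
    }
  }
  class(rep) <- "diet_consistency"
  rep
}

#' @export
print.diet_consistency <- function(x, ...) {
  cat("Consistency check:", if (x$ok) "OK" else "issues found", "\n")
  for (nm in c("persons_without_attributes", "foods_without_factors",
               "factors_without_foods", "foods_not_registered")) {
    if (length(x[[nm]]))
      cat("  ", nm, ": ", paste(x[[nm]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

fmt_num <- function(x, digits) formatC(x, format = "f", digits = digits)

#' Write cluster report tables
#'
#' Renders the impact/diet-quality summary and the food-group means per
#' cluster as CSV files with deterministic column order and fixed decimal
#' formatting (2 decimals for means, 4 for v statistics). Writing the same
#' results twice yields byte-identical files.
#'
#' @param results list with elements \code{impact_summary} (data.frame of
#'   cluster means per impact/score) and \code{food_summary} (data.frame of
#'   food-group means per cluster); numeric columns are formatted, v-test
#'   columns (name containing \code{"v"}) get 4 decimals.
#' @param dir output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_report_tables <- function(results, dir) {
  if (is.null(results$impact_summary) || !nrow(results$impact_summary))
    stop("no clusters: empty cluster solution")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt_df <- function(df) {
    df <- df[, sort(names(df))[order(sort(names(df)) != "variable")], drop = FALSE]
    df <- df[, c(intersect("variable", names(df)),
                 sort(setdiff(names(df), "variable"))), drop = FALSE]
    for (cl in names(df)) {
      if (is.numeric(df[[cl]]))
        df[[cl]] <- fmt_num(df[[cl]], if (grepl("^v_|_v$|vtest", cl)) 4L else 2L)
    }
    df
  }
  paths <- character(0)
  for (nm in c("impact_summary", "food_summary")) {
    if (is.null(results[[nm]])) next
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(fmt_df(results[[nm]]), p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write a table and read it back without loss
#'
#' Round-trip helper used by the pipeline for intermediate matrices: values
#' survive a write/read cycle to at least 12 significant digits.
#'
#' @param df data.frame to write.
#' @param path destination CSV path.
#' @return The path, invisibly.
#' @export
write_table <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (cl in names(df)[num]) out[[cl]] <- formatC(df[[cl]], format = "g", digits = 15)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
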