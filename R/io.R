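#' Read and write the tabular inputs
#'
#' All four input tables are CSV/TSV files with a header row; the delimiter
#' is inferred from the file extension (`.tsv`/`.tab`/`.txt` are
#' tab-separated, everything else comma-separated). Files are UTF-8. The
#' column dictionary shipped at `inst/extdata/column-dictionary.md`
#' documents every column. Each `read_*` has a matching `write_*` and
#' read-write-read round trips are value-identical.
#'
#' @name table-io
NULL

#' Read a demographic table
#'
#' @param source Path to a CSV/TSV file (or a connection) with columns
#'   `municipality`, `sex`, `age_group`, `count`.
#' @return A [demographic_table()].
#' @family table-io
#' @export
read_demographics <- function(source) {
  df <- read_table_file(source)
  require_columns(df, c("municipality", "sex", "age_group", "count"), "demographics")
  muni <- unique(df$municipality)
  if (length(muni) != 1L) {
    schema_error("demographics: expected exactly one municipality per file")
  }
  demographic_table(muni, df[, c("sex", "age_group", "count")])
}

#' Write a demographic table
#' @param demo A `demographic_table`.
#' @param path Output path (extension decides the delimiter).
#' @family table-io
#' @export
write_demographics <- function(demo, path) {
  stopifnot(inherits(demo, "demographic_table"))
  df <- cbind(municipality = demo$municipality, demo$strata)
  write_table_file(df, path)
}

#' Read a DRI table (long format)
#'
#' @param source Path to a CSV/TSV file with columns `nutrient_id`,
#'   `unit`, `sex`, `age_group`, `value` and optionally `nutrient_name`.
#' @return A [dri_table()].
#' @family table-io
#' @export
read_dri_table <- function(source) {
  df <- read_table_file(source)
  require_columns(df, c("nutrient_id", "unit", "sex", "age_group", "value"), "DRI")
  if (is.null(df$nutrient_name)) df$nutrient_name <- df$nutrient_id
  first <- !duplicated(df$nutrient_id)
  nutrients <- data.frame(id = df$nutrient_id[first],
                          name = df$nutrient_name[first],
                          unit = df$unit[first],
                          stringsAsFactors = FALSE)
  # a nutrient's unit must not vary across rows
  unit_map <- nutrients$unit[match(df$nutrient_id, nutrients$id)]
  if (any(unit_map != df$unit)) {
    schema_error("DRI: inconsistent unit for a nutrient across rows")
  }
  dri_table(nutrients, df[, c("nutrient_id", "sex", "age_group", "value")])
}

#' Write a DRI table (long format)
#' @param dri A `dri_table`.
#' @param path Output path.
#' @family table-io
#' @export
write_dri_table <- function(dri, path) {
  stopifnot(inherits(dri, "dri_table"))
  grid <- expand.grid(stratum = seq_len(nrow(dri$strata)),
                      nutrient = seq_len(nrow(dri$nutrients)))
  keys <- stratum_key(dri$strata$sex, dri$strata$age_group)
  df <- data.frame(
    nutrient_id = dri$nutrients$id[grid$nutrient],
    nutrient_name = dri$nutrients$name[grid$nutrient],
    unit = dri$nutrients$unit[grid$nutrient],
    sex = dri$strata$sex[grid$stratum],
    age_group = dri$strata$age_group[grid$stratum],
    value = dri$values[cbind(grid$nutrient, match(keys[grid$stratum], colnames(dri$values)))],
    stringsAsFactors = FALSE)
  write_table_file(df, path)
}

CATALOG_FIXED_COLS <- c("id", "name", "category", "shelf_stable",
                        "requires_cooking", "contains_wheat", "pack_grams",
                        "cost_per_pack", "volume_per_pack")

#' Read a food catalog
#'
#' One row per food. Fixed columns are `id`, `name`, `category` plus the
#' optional flag/pack/cost columns; every remaining column is interpreted as
#' a per-100 g nutrient composition column. When `nutrients` is supplied,
#' composition columns not in it are rejected, and declared nutrients with
#' no column are filled with 0 (with a warning), mirroring the "Tr"/"--"
#' entries of printed food-composition tables.
#'
#' @param source Path to a CSV/TSV file.
#' @param nutrients Optional character vector of declared nutrient ids.
#' @return A [food_catalog()].
#' @family table-io
#' @export
read_food_catalog <- function(source, nutrients = NULL) {
  df <- read_table_file(source)
  require_columns(df, c("id", "name", "category"), "food catalog")
  comp_cols <- setdiff(names(df), CATALOG_FIXED_COLS)
  if (!is.null(nutrients)) {
    unknown <- setdiff(comp_cols, nutrients)
    if (length(unknown)) {
      schema_error(sprintf("catalog: undeclared nutrient column(s): %s",
                           paste(unknown, collapse = ", ")))
    }
    absent <- setdiff(nutrients, comp_cols)
    if (length(absent)) {
      warning(sprintf("catalog: declared nutrient(s) absent, treated as 0: %s",
                      paste(absent, collapse = ", ")), call. = FALSE)
    }
    comp <- matrix(0, nrow(df), length(nutrients),
                   dimnames = list(df$id, nutrients))
    for (col in intersect(nutrients, comp_cols)) comp[, col] <- as.numeric(df[[col]])
  } else {
    comp <- as.matrix(df[, comp_cols, drop = FALSE])
    if (ncol(comp)) storage.mode(comp) <- "double"
  }
  food_catalog(df[, intersect(CATALOG_FIXED_COLS, names(df)), drop = FALSE], comp)
}

#' Write a food catalog
#' @param catalog A `food_catalog`.
#' @param path Output path.
#' @family table-io
#' @export
write_food_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "food_catalog"))
  df <- catalog$items
  if (ncol(catalog$per100g)) df <- cbind(df, as.data.frame(catalog$per100g))
  write_table_file(df, path)
}

#' Read a stockpile inventory
#'
#' Accepts either a `quantity_grams` column or a `packs` column; packs are
#' converted to grams at binding time using each item's `pack_grams` from
#' `catalog`. An empty file (header only) is a valid empty inventory.
#'
#' @param source Path to a CSV/TSV file with `food_id` and one of
#'   `quantity_grams` | `packs`.
#' @param catalog A `food_catalog`; required when the file uses `packs`.
#' @return An [inventory()].
#' @family table-io
#' @export
read_inventory <- function(source, catalog = NULL) {
  df <- read_table_file(source)
  require_columns(df, "food_id", "inventory")
  if (!is.null(df$quantity_grams)) {
    grams <- as.numeric(df$quantity_grams)
  } else if (!is.null(df$packs)) {
    if (is.null(catalog)) {
      schema_error("inventory: 'packs' dialect requires a catalog to bind pack_grams")
    }
    if (any(is.na(df$packs)) || any(df$packs < 0)) {
      value_error("inventory: packs must be non-negative")
    }
    idx <- match(df$food_id, catalog$items$id)
    if (anyNA(idx)) {
      reference_error(sprintf("inventory: unknown food id(s): %s",
                              paste(df$food_id[is.na(idx)], collapse = ", ")))
    }
    grams <- as.numeric(df$packs) * catalog$items$pack_grams[idx]
  } else {
    schema_error("inventory: need a quantity_grams or packs column")
  }
  inventory(data.frame(food_id = df$food_id, quantity_grams = grams,
                       stringsAsFactors = FALSE))
}

#' Write an inventory
#' @param inv An `inventory`.
#' @param path Output path.
#' @family table-io
#' @export
write_inventory <- function(inv, path) {
  stopifnot(inherits(inv, "inventory"))
  write_table_file(inv$entries, path)
}
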