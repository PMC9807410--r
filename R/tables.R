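#' Construct a demographic table
#'
#' A demographic table holds the resident population of one municipality,
#' stratified by sex and age group. It is the weighting basis for the
#' population-weighted dietary reference intake: requirements are averaged
#' over strata proportionally to head counts.
#'
#' Strata are ordered canonically: age groups in order of first appearance,
#' males before females within each age group. Stratum labels are free
#' strings but must match the DRI table exactly; no fuzzy age-bin mapping is
#' attempted, since silent re-binning would corrupt the weighting.
#'
#' @param municipality Name of the municipality.
#' @param counts Data frame with columns `sex` (`"male"`/`"female"`),
#'   `age_group` (character label) and `count` (non-negative integers).
#' @return An object of class `demographic_table` with elements
#'   `municipality` and `strata` (the validated, canonically ordered counts).
#' @examples
#' demographic_table("Toy City", data.frame(
#'   sex = c("male", "female"), age_group = "adult", count = c(50, 50)))
#' @export
demographic_table <- function(municipality, counts) {
  require_columns(counts, c("sex", "age_group", "count"), "demographics")
  counts$sex <- as.character(counts$sex)
  counts$age_group <- as.character(counts$age_group)
  bad_sex <- setdiff(unique(counts$sex), c("male", "female"))
  if (length(bad_sex)) {
    schema_error(sprintf("demographics: sex must be 'male' or 'female', got: %s",
                         paste(bad_sex, collapse = ", ")))
  }
  key <- stratum_key(counts$sex, counts$age_group)
  if (anyDuplicated(key)) {
    schema_error(sprintf("demographics: duplicate stratum: %s",
                         paste(unique(key[duplicated(key)]), collapse = ", ")))
  }
  if (any(is.na(counts$count)) || any(counts$count < 0)) {
    value_error("demographics: counts must be non-negative")
  }
  if (any(counts$count != round(counts$count))) {
    value_error("demographics: counts must be whole persons")
  }
  total <- sum(counts$count)
  if (total <= 0) value_error("demographics: total population must be positive")
  age_order <- unique(counts$age_group)
  ord <- order(match(counts$age_group, age_order),
               match(counts$sex, c("male", "female")))
  strata <- counts[ord, c("sex", "age_group", "count")]
  rownames(strata) <- NULL
  structure(list(municipality = as.character(municipality), strata = strata),
            class = "demographic_table")
}

#' @export
print.demographic_table <- function(x, ...) {
  cat(sprintf("Demographic table: %s (%d strata, population %s)\n",
              x$municipality, nrow(x$strata),
              format(total_population(x), big.mark = ",")))
  print(x$strata)
  invisible(x)
}

#' Total population of a demographic table
#' @param demo A `demographic_table`.
#' @return Total head count (numeric scalar).
#' @export
total_population <- function(demo) {
  stopifnot(inherits(demo, "demographic_table"))
  sum(demo$strata$count)
}

#' Construct a dietary reference intake (DRI) table
#'
#' Per-person per-day reference values for each nutrient in each sex and age
#' stratum. Which DRI statistic (EAR, RDA, DG ...) the values represent is the
#' data supplier's choice; the engine treats them as opaque "reference value
#' per day".
#'
#' @param nutrients Data frame with columns `id`, `name`, `unit` describing
#'   the nutrient set. Ids must be unique and units non-empty.
#' @param values Long-format data frame with columns `nutrient_id`, `sex`,
#'   `age_group`, `value`: one row per (nutrient, stratum) cell. The grid
#'   must be complete over nutrients x strata, all values >= 0.
#' @return An object of class `dri_table` with elements `nutrients`, `strata`
#'   and a `values` matrix (nutrients x strata, dimnames nutrient ids x
#'   stratum keys `"sex|age_group"`).
#' @export
dri_table <- function(nutrients, values) {
  require_columns(nutrients, c("id", "name", "unit"), "DRI nutrient set")
  nutrients$id <- as.character(nutrients$id)
  nutrients$unit <- as.character(nutrients$unit)
  if (anyDuplicated(nutrients$id)) {
    schema_error("DRI: nutrient ids must be unique")
  }
  if (any(!nzchar(nutrients$unit)) || any(is.na(nutrients$unit))) {
    schema_error("DRI: nutrient units must be non-empty")
  }
  require_columns(values, c("nutrient_id", "sex", "age_group", "value"), "DRI values")
  values$nutrient_id <- as.character(values$nutrient_id)
  unknown <- setdiff(unique(values$nutrient_id), nutrients$id)
  if (length(unknown)) {
    schema_error(sprintf("DRI: values reference undeclared nutrient(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  if (any(is.na(values$value)) || any(values$value < 0)) {
    value_error("DRI: values must be non-negative")
  }
  strata <- unique(values[, c("sex", "age_group")])
  bad_sex <- setdiff(unique(strata$sex), c("male", "female"))
  if (length(bad_sex)) {
    schema_error(sprintf("DRI: sex must be 'male' or 'female', got: %s",
                         paste(bad_sex, collapse = ", ")))
  }
  age_order <- unique(strata$age_group)
  strata <- strata[order(match(strata$age_group, age_order),
                         match(strata$sex, c("male", "female"))), , drop = FALSE]
  rownames(strata) <- NULL
  keys <- stratum_key(strata$sex, strata$age_group)
  cell_key <- stratum_key(values$sex, values$age_group)
  idx <- paste(values$nutrient_id, cell_key)
  if (anyDuplicated(idx)) {
    schema_error("DRI: duplicate (nutrient, stratum) cell")
  }
  mat <- matrix(NA_real_, nrow = nrow(nutrients), ncol = length(keys),
                dimnames = list(nutrients$id, keys))
  mat[cbind(match(values$nutrient_id, nutrients$id), match(cell_key, keys))] <-
    values$value
  if (anyNA(mat)) {
    miss <- which(is.na(mat), arr.ind = TRUE)
    completeness_error(sprintf(
      "DRI: incomplete grid, first missing cell: nutrient '%s' stratum '%s'",
      rownames(mat)[miss[1, 1]], colnames(mat)[miss[1, 2]]))
  }
  structure(list(nutrients = nutrients[, c("id", "name", "unit")],
                 strata = strata, values = mat),
            class = "dri_table")
}

#' @export
print.dri_table <- function(x, ...) {
  cat(sprintf("DRI table: %d nutrients x %d strata\n",
              nrow(x$nutrients), nrow(x$strata)))
  print(x$nutrients)
  invisible(x)
}

#' Construct a food catalog
#'
#' A catalog of food items with per-100 g nutrient composition, category
#' membership and stockpilability flags. Costs and storage volumes are
#' optional and only used by the purchase planners.
#'
#' @param items Data frame with columns `id`, `name`, `category` and
#'   optionally `shelf_stable`, `requires_cooking`, `contains_wheat`
#'   (logical; defaults TRUE/FALSE/FALSE), `pack_grams` (default 100),
#'   `cost_per_pack`, `volume_per_pack` (default NA).
#' @param per100g Numeric matrix (items x nutrients) of nutrient content per
#'   100 g, rownames = item ids, colnames = nutrient ids. All values >= 0.
#' @param categories Ordered character vector of category labels; defaults to
#'   the categories present in `items` in order of first appearance.
#' @return An object of class `food_catalog`.
#' @export
food_catalog <- function(items, per100g, categories = NULL) {
  require_columns(items, c("id", "name", "category"), "food catalog")
  items$id <- as.character(items$id)
  items$category <- as.character(items$category)
  if (anyDuplicated(items$id)) {
    schema_error(sprintf("catalog: duplicate item id(s): %s",
                         paste(unique(items$id[duplicated(items$id)]), collapse = ", ")))
  }
  defaults <- list(shelf_stable = TRUE, requires_cooking = FALSE,
                   contains_wheat = FALSE, pack_grams = 100,
                   cost_per_pack = NA_real_, volume_per_pack = NA_real_)
  for (col in names(defaults)) {
    if (is.null(items[[col]])) items[[col]] <- defaults[[col]]
  }
  for (col in c("shelf_stable", "requires_cooking", "contains_wheat")) {
    items[[col]] <- as.logical(items[[col]])
    if (anyNA(items[[col]])) schema_error(sprintf("catalog: %s must be logical", col))
  }
  if (any(is.na(items$pack_grams)) || any(items$pack_grams <= 0)) {
    value_error("catalog: pack_grams must be positive")
  }
  categories <- categories %||% unique(items$category)
  bad <- setdiff(unique(items$category), categories)
  if (length(bad)) {
    schema_error(sprintf("catalog: item category not in category list: %s",
                         paste(bad, collapse = ", ")))
  }
  per100g <- as.matrix(per100g)
  if (is.null(dim(per100g)) || nrow(per100g) != nrow(items)) {
    schema_error("catalog: per100g must have one row per item")
  }
  if (ncol(per100g) > 0) {
    storage.mode(per100g) <- "double"
    if (anyNA(per100g) || any(per100g < 0)) {
      value_error("catalog: per-100 g composition values must be non-negative")
    }
  }
  rownames(per100g) <- items$id
  cols <- c("id", "name", "category", "shelf_stable", "requires_cooking",
            "contains_wheat", "pack_grams", "cost_per_pack", "volume_per_pack")
  items <- items[, cols]
  rownames(items) <- NULL
  structure(list(items = items, per100g = per100g, categories = categories),
            class = "food_catalog")
}

#' @export
print.food_catalog <- function(x, ...) {
  cat(sprintf("Food catalog: %d items, %d categories, %d nutrient column(s)\n",
              nrow(x$items), length(x$categories), ncol(x$per100g)))
  tab <- table(factor(x$items$category, levels = x$categories))
  for (cat_i in names(tab)) cat(sprintf("  %-45s %3d item(s)\n", cat_i, tab[[cat_i]]))
  invisible(x)
}

#' Construct a stockpile inventory
#'
#' Quantities are held in grams, the canonical unit (composition is per
#' 100 g). A `packs` column is a convenience dialect converted at binding
#' time against the catalog's `pack_grams`; see [read_inventory()].
#'
#' @param entries Data frame with columns `food_id` and `quantity_grams`
#'   (>= 0). An empty data frame is a valid (empty) inventory.
#' @return An object of class `inventory`.
#' @export
inventory <- function(entries = data.frame(food_id = character(),
                                           quantity_grams = numeric())) {
  require_columns(entries, c("food_id", "quantity_grams"), "inventory")
  entries$food_id <- as.character(entries$food_id)
  if (any(is.na(entries$quantity_grams)) || any(entries$quantity_grams < 0)) {
    value_error("inventory: quantities must be non-negative")
  }
  entries <- entries[, c("food_id", "quantity_grams")]
  rownames(entries) <- NULL
  structure(list(entries = entries), class = "inventory")
}

#' @export
print.inventory <- function(x, ...) {
  cat(sprintf("Inventory: %d entr%s, %s g total\n", nrow(x$entries),
              if (nrow(x$entries) == 1) "y" else "ies",
              format(sum(x$entries$quantity_grams), big.mark = ",")))
  if (nrow(x$entries)) print(x$entries)
  invisible(x)
}

#' Check that a DRI table covers a demographic table
#'
#' Reports (never raises) the strata present in the demographics but absent
#' from the DRI table. An empty result guarantees that the requirement
#' pipeline will find every (nutrient, stratum) cell it needs. Extra strata
#' on the DRI side are harmless reference rows and are not reported.
#'
#' @param demo A `demographic_table`.
#' @param dri A `dri_table`.
#' @return Character vector of issue messages; empty when aligned.
#' @export
validate_alignment <- function(demo, dri) {
  stopifnot(inherits(demo, "demographic_table"), inherits(dri, "dri_table"))
  demo_keys <- stratum_key(demo$strata$sex, demo$strata$age_group)
  missing <- setdiff(demo_keys, colnames(dri$values))
  if (!length(missing)) return(character())
  sprintf("stratum '%s' present in demographics but missing from the DRI table",
          missing)
}
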