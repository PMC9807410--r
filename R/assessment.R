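#' Total nutrient supply of an inventory
#'
#' Sums, per nutrient, `quantity_grams / 100 * per100g` over all inventory
#' entries. Additive over inventory partitions. Nutrients requested but
#' absent from the catalog's composition matrix contribute 0 with a warning
#' (the "Tr"/"--" convention of printed food-composition tables).
#'
#' @param inv An `inventory`; all `food_id`s must resolve in `catalog`.
#' @param catalog A `food_catalog`.
#' @param nutrients Character vector of nutrient ids to total.
#' @return A named numeric vector (one total per requested nutrient).
#' @examples
#' # 5000 g of a food with 350 kcal/100 g supplies 17500 kcal
#' @export
total_supply <- function(inv, catalog, nutrients) {
  stopifnot(inherits(inv, "inventory"), inherits(catalog, "food_catalog"))
  totals <- stats::setNames(numeric(length(nutrients)), nutrients)
  if (!nrow(inv$entries)) return(totals)
  idx <- match(inv$entries$food_id, catalog$items$id)
  if (anyNA(idx)) {
    reference_error(sprintf("inventory references unknown food id(s): %s",
                            paste(unique(inv$entries$food_id[is.na(idx)]), collapse = ", ")))
  }
  absent <- setdiff(nutrients, colnames(catalog$per100g))
  if (length(absent)) {
    warning(sprintf("catalog has no composition column for: %s (treated as 0)",
                    paste(absent, collapse = ", ")), call. = FALSE)
  }
  present <- intersect(nutrients, colnames(catalog$per100g))
  if (length(present)) {
    comp <- catalog$per100g[idx, present, drop = FALSE]
    totals[present] <- as.vector(crossprod(comp, inv$entries$quantity_grams / 100))
  }
  totals
}

#' Excess/deficiency ratio
#'
#' `supplied / required * 100` (percent). Degenerate conventions keep zero-
#' requirement rows from crashing a report: required 0 with supplied 0 gives
#' 100 (vacuously met); required 0 with supplied > 0 gives `Inf`.
#'
#' @param supplied Supplied amount (>= 0).
#' @param required Required amount (>= 0).
#' @return Ratio in percent (may be `Inf`). Vectorized.
#' @export
excess_deficiency_ratio <- function(supplied, required) {
  if (any(is.na(supplied)) || any(is.na(required)) ||
      any(supplied < 0) || any(required < 0)) {
    value_error("supplied and required amounts must be non-negative")
  }
  out <- ifelse(required > 0, supplied / required * 100,
                ifelse(supplied > 0, Inf, 100))
  as.numeric(out)
}

#' Pass/fail mark for a ratio
#'
#' The stockpile evaluation rule: a passing mark for an excess/deficiency ratio
#' at or above 100% (boundary configurable via `boundary = "gt"`, which
#' awards the pass only strictly above 100). Machine formats use the ASCII
#' tokens `"O"` / `"x"`; [mark_glyph()] maps them to the display glyphs.
#'
#' The boundary is evaluated with a 1e-9 relative tolerance so that ratios
#' computed to be exactly 100% do not flip marks on floating-point round-off.
#'
#' @param ratio_pct Ratio in percent (may be `Inf`). Vectorized.
#' @param boundary `"gte"` (default) or `"gt"`.
#' @return Character vector of `"O"` / `"x"` tokens.
#' @export
adequacy_mark <- function(ratio_pct, boundary = "gte") {
  if (!boundary %in% c("gte", "gt")) config_error("boundary must be 'gte' or 'gt'")
  if (any(is.na(ratio_pct)) || any(ratio_pct < 0)) {
    value_error("ratio must be non-negative or Inf")
  }
  pass <- if (boundary == "gte") ratio_pct >= 100 * (1 - 1e-9)
          else ratio_pct > 100 * (1 + 1e-9)
  ifelse(pass, "O", "x")
}

#' Display glyph for a mark token
#' @param mark Character vector of `"O"` / `"x"` tokens.
#' @return The display glyphs "Ο" (capital omicron) / "×".
#' @export
mark_glyph <- function(mark) {
  ifelse(mark == "O", "Ο", "×")
}

#' People covered by current stock
#'
#' How many people's full-period requirement for a nutrient the current
#' supply can meet: `floor(supplied / (per_capita_daily * days))`, or 0 when
#' the denominator is 0. Proposed as an easier-to-read alternative to
#' percentage ratios.
#'
#' @param supplied Supplied amount (>= 0).
#' @param per_capita_daily Per-person per-day requirement (>= 0).
#' @param days Days the stockpile must cover (>= 1).
#' @return Whole persons. Vectorized.
#' @export
people_covered <- function(supplied, per_capita_daily, days) {
  if (any(days < 1)) value_error("days must be >= 1")
  denom <- per_capita_daily * days
  out <- ifelse(denom > 0, floor(supplied / denom), 0)
  as.numeric(out)
}

#' Assess a stockpile against scenario requirements
#'
#' The end-to-end evaluation: estimates victims, computes population-
#' weighted total requirements for the active nutrient profile, totals the
#' inventory's supply, and derives per-nutrient excess/deficiency ratios,
#' pass/fail marks, and people-covered counts. Deterministic in its inputs.
#'
#' @param demo A `demographic_table`.
#' @param dri A `dri_table` covering the demographics (see
#'   [validate_alignment()]).
#' @param catalog A `food_catalog`.
#' @param inv An `inventory` whose food ids resolve in `catalog`.
#' @param config A `scenario_config`.
#' @return An object of class `stockpile_assessment`: a list with
#'   `municipality`, `scenario` (config echo), `victims`, and `rows`, a data
#'   frame with one row per profile nutrient and columns `nutrient`, `name`,
#'   `unit`, `per_capita_daily`, `required`, `supplied`, `ratio_pct`, `mark`
#'   (`"O"`/`"x"`), `people_covered`. Ratios are kept at full precision;
#'   display rounding to 1 decimal happens only in `print`/[render_report()].
#' @examples
#' spec <- fixture_spec(seed = 1, total_population = 1000)
#' demo <- gen_demographics(spec); dri <- gen_dri(spec)
#' cat1 <- gen_catalog(spec); inv <- gen_inventory(spec, cat1)
#' assess(demo, dri, cat1, inv, scenario_config(profile = "shelter5"))
#' @export
assess <- function(demo, dri, catalog, inv, config = scenario_config()) {
  issues <- validate_alignment(demo, dri)
  if (length(issues)) schema_error(paste(issues, collapse = "; "))
  req <- total_required(dri, demo, config)
  supplied <- total_supply(inv, catalog, req$nutrients)
  ratio <- excess_deficiency_ratio(supplied, req$total_required)
  nut_idx <- match(req$nutrients, dri$nutrients$id)
  rows <- data.frame(
    nutrient = req$nutrients,
    name = dri$nutrients$name[nut_idx],
    unit = dri$nutrients$unit[nut_idx],
    per_capita_daily = unname(req$per_capita_daily),
    required = unname(req$total_required),
    supplied = unname(supplied),
    ratio_pct = ratio,
    mark = adequacy_mark(ratio, config$mark_boundary),
    people_covered = people_covered(supplied, req$per_capita_daily, config$days),
    stringsAsFactors = FALSE)
  rownames(rows) <- NULL
  structure(list(municipality = demo$municipality, scenario = config,
                 victims = req$victims, rows = rows),
            class = "stockpile_assessment")
}

#' @export
print.stockpile_assessment <- function(x, ...) {
  cat(sprintf("Stockpile assessment: %s\n", x$municipality))
  cat(sprintf("  victims: %s (%.0f%% affected), days: %d, profile: %s\n",
              format(x$victims, big.mark = ","),
              100 * x$scenario$affected_fraction, x$scenario$days,
              x$scenario$profile))
  df <- x$rows
  df$ratio_pct <- sprintf("%.1f", df$ratio_pct)
  df$mark <- mark_glyph(df$mark)
  df$required <- signif(df$required, 6)
  df$supplied <- signif(df$supplied, 6)
  df$per_capita_daily <- signif(df$per_capita_daily, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.stockpile_assessment <- function(object, ...) {
  rows <- object$rows
  res <- list(municipality = object$municipality, victims = object$victims,
              n_nutrients = nrow(rows), n_pass = sum(rows$mark == "O"),
              worst = rows$nutrient[which.min(rows$ratio_pct)],
              worst_ratio = min(rows$ratio_pct),
              min_people_covered = min(rows$people_covered))
  class(res) <- "summary.stockpile_assessment"
  res
}

#' @export
print.summary.stockpile_assessment <- function(x, ...) {
  cat(sprintf("%s: %d/%d nutrients at or above 100%%; worst %s at %.1f%%; min people covered %d\n",
              x$municipality, x$n_pass, x$n_nutrients, x$worst, x$worst_ratio,
              x$min_people_covered))
  invisible(x)
}

#' @export
as.data.frame.stockpile_assessment <- function(x, ...) x$rows
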