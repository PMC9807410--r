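#' The five shelter-reference nutrients
#'
#' Nutrient ids of the reduced profile used for shelter meal provision:
#' energy, protein and vitamins B1, B2 and C. Vitamins B1 and B2 are needed
#' to metabolize carbohydrates, which dominate shelter diets, and tend to be
#' short when stockpiles are staple-heavy.
#'
#' @return Character vector of five nutrient ids.
#' @export
shelter_nutrients <- function() c("energy", "protein", "vit_b1", "vit_b2", "vit_c")

#' Scenario configuration
#'
#' Settings for one assessment run: what fraction of the resident population
#' is affected, for how many days the stockpile must last, which nutrient
#' profile is evaluated and how the victim count is rounded.
#'
#' @param affected_fraction Proportion of the population affected, in
#'   \[0, 1\]. Default 0.20, the reference planning tool's printed default of 20%.
#' @param days Number of days the stockpile must cover; positive integer.
#'   Default 3 (the printed default).
#' @param profile Nutrient profile name: `"full"` (every nutrient in the DRI
#'   table) or `"shelter5"` (see [shelter_nutrients()]). Default `"full"`.
#' @param victim_rounding How `affected_fraction * population` is rounded to
#'   whole persons: `"ceil"` (default, conservative for relief planning),
#'   `"round"` or `"floor"`.
#' @param mark_boundary Whether the passing mark is awarded at exactly 100%
#'   (`"gte"`, the default) or only above it (`"gt"`). The source tool's
#'   documentation states the rule both ways; `"gte"` follows its step-7
#'   wording.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(affected_fraction = 0.20, days = 3L,
                            profile = "full", victim_rounding = "ceil",
                            mark_boundary = "gte") {
  if (!is.numeric(affected_fraction) || length(affected_fraction) != 1L ||
      is.na(affected_fraction) || affected_fraction < 0 || affected_fraction > 1) {
    config_error("affected_fraction must be a number in [0, 1]")
  }
  if (!is.numeric(days) || length(days) != 1L || is.na(days) ||
      days < 1 || days != round(days)) {
    config_error("days must be a positive integer")
  }
  if (!is.character(profile) || length(profile) != 1L) {
    config_error("profile must be a single profile name")
  }
  if (!victim_rounding %in% c("ceil", "round", "floor")) {
    config_error("victim_rounding must be one of ceil, round, floor")
  }
  if (!mark_boundary %in% c("gte", "gt")) {
    config_error("mark_boundary must be 'gte' or 'gt'")
  }
  structure(list(affected_fraction = affected_fraction,
                 days = as.integer(days), profile = profile,
                 victim_rounding = victim_rounding,
                 mark_boundary = mark_boundary),
            class = "scenario_config")
}

#' Read a scenario configuration from a YAML or JSON file
#'
#' Keys mirror the arguments of [scenario_config()]; absent keys take the
#' defaults. The format is chosen by extension (`.json` vs `.yaml`/`.yml`).
#'
#' @param path Path to the config file.
#' @return A `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) io_error(sprintf("config file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  vals <- tryCatch(
    if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path),
    error = function(e) io_error(sprintf("failed to parse config: %s",
                                         conditionMessage(e))))
  known <- c("affected_fraction", "days", "profile", "victim_rounding",
             "mark_boundary")
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    config_error(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(scenario_config, vals[intersect(names(vals), known)])
}

#' Estimate the number of victims
#'
#' Applies the configured affected fraction to the municipality's total
#' population and rounds to whole persons per `config$victim_rounding`.
#'
#' @param demo A `demographic_table`.
#' @param config A `scenario_config`.
#' @return Number of victims (non-negative integer-valued numeric).
#' @examples
#' demo <- demographic_table("Toy", data.frame(
#'   sex = c("male", "female"), age_group = "adult", count = c(170, 163)))
#' estimate_victims(demo, scenario_config())  # ceil(0.2 * 333) = 67
#' @export
estimate_victims <- function(demo, config = scenario_config()) {
  stopifnot(inherits(demo, "demographic_table"), inherits(config, "scenario_config"))
  raw <- config$affected_fraction * total_population(demo)
  switch(config$victim_rounding,
         ceil = ceiling(raw), round = round(raw), floor = floor(raw))
}

#' Population-weighted per-capita daily requirement
#'
#' The reference intake of one "average inhabitant": stratum DRI values
#' weighted by the municipality's sex and age-group head counts,
#' `sum(count_s * dri_s) / sum(count_s)`. By convexity the result always
#' lies within the range of the stratum values.
#'
#' @param dri A `dri_table`.
#' @param demo A `demographic_table`; every stratum must have DRI values
#'   (see [validate_alignment()]).
#' @param nutrient A nutrient id present in `dri`.
#' @return Amount per person per day, in the nutrient's unit.
#' @examples
#' # counts 10/30 with DRI 2000/1600 -> (10*2000 + 30*1600)/40 = 1700
#' @export
per_capita_daily_requirement <- function(dri, demo, nutrient) {
  stopifnot(inherits(dri, "dri_table"), inherits(demo, "demographic_table"))
  if (!nutrient %in% rownames(dri$values)) {
    completeness_error(sprintf("nutrient '%s' not in the DRI table", nutrient))
  }
  keys <- stratum_key(demo$strata$sex, demo$strata$age_group)
  missing <- setdiff(keys, colnames(dri$values))
  if (length(missing)) {
    completeness_error(sprintf("no DRI values for stratum '%s'", missing[1]))
  }
  counts <- demo$strata$count
  sum(counts * dri$values[nutrient, keys]) / sum(counts)
}

#' Resolve a nutrient profile to nutrient ids
#'
#' `"full"` selects every nutrient in the DRI table, in table order.
#' `"shelter5"` selects the five shelter-reference nutrients
#' ([shelter_nutrients()]) and errors if any is absent from the table.
#'
#' @param name Profile name.
#' @param dri A `dri_table`.
#' @return Character vector of nutrient ids.
#' @export
nutrient_profile <- function(name, dri) {
  stopifnot(inherits(dri, "dri_table"))
  if (identical(name, "full")) return(dri$nutrients$id)
  if (identical(name, "shelter5")) {
    want <- shelter_nutrients()
    absent <- setdiff(want, dri$nutrients$id)
    if (length(absent)) {
      profile_error(sprintf("shelter5 profile needs nutrient(s) missing from the DRI table: %s",
                            paste(absent, collapse = ", ")))
    }
    return(want)
  }
  config_error(sprintf("unknown nutrient profile: '%s'", name))
}

#' Total scenario requirement
#'
#' For each nutrient in the active profile, the whole-scenario requirement:
#' per-capita daily requirement x victims x days. This is linear in days
#' and, for any rounding mode, monotone non-decreasing in the affected
#' fraction.
#'
#' @param dri A `dri_table`.
#' @param demo A `demographic_table`.
#' @param config A `scenario_config`.
#' @return A list of class `requirement_result` with elements `victims`,
#'   `days`, `nutrients` (profile ids), `per_capita_daily` and
#'   `total_required` (named numeric vectors over the profile).
#' @export
total_required <- function(dri, demo, config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  profile <- nutrient_profile(config$profile, dri)
  victims <- estimate_victims(demo, config)
  per_cap <- vapply(profile, function(n) per_capita_daily_requirement(dri, demo, n),
                    numeric(1))
  structure(list(victims = victims, days = config$days, nutrients = profile,
                 per_capita_daily = per_cap,
                 total_required = per_cap * victims * config$days),
            class = "requirement_result")
}
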