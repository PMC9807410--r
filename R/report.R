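#' Serialize an assessment report
#'
#' JSON carries full-precision values (plus 1-decimal display strings and
#' the display glyphs in label fields); CSV mirrors the row grid with one
#' row per nutrient. Machine mark tokens are ASCII `"O"`/`"x"`; the glyphs
#' live in `mark_label`. An infinite ratio (supply against a zero
#' requirement) serializes as the string `"Inf"` in JSON. The JSON schema is
#' shipped at `inst/schema/assessment-report.schema.json`.
#'
#' @param report A `stockpile_assessment`.
#' @param format `"json"` or `"csv"`.
#' @param manifest Optional run manifest list to embed (JSON only; the CSV
#'   carries it as `#`-prefixed comment lines).
#' @return A character scalar holding the serialized document.
#' @export
render_report <- function(report, format = c("json", "csv"), manifest = NULL) {
  stopifnot(inherits(report, "stockpile_assessment"))
  format <- match.arg(format)
  rows <- report$rows
  rows$ratio_display <- sprintf("%.1f", rows$ratio_pct)
  rows$mark_label <- mark_glyph(rows$mark)
  ord <- c("nutrient", "name", "unit", "per_capita_daily", "required",
           "supplied", "ratio_pct", "ratio_display", "mark", "mark_label",
           "people_covered")
  rows <- rows[, ord]
  if (format == "json") {
    rows$ratio_pct <- ifelse(is.finite(rows$ratio_pct), rows$ratio_pct, "Inf")
    body <- list(municipality = report$municipality,
                 scenario = unclass(report$scenario),
                 victims = report$victims,
                 rows = rows)
    if (!is.null(manifest)) body$manifest <- manifest
    as.character(jsonlite::toJSON(body, auto_unbox = TRUE, digits = NA,
                                  dataframe = "rows", pretty = TRUE))
  } else {
    con <- textConnection("out", "w", local = TRUE)
    on.exit(close(con))
    if (!is.null(manifest)) {
      writeLines(paste0("# ", names(manifest), ": ",
                        vapply(manifest, function(v) paste(format(v), collapse = " "),
                               character(1))), con)
    }
    writeLines(sprintf("# municipality: %s | victims: %s | days: %d | profile: %s",
                       report$municipality, format(report$victims),
                       report$scenario$days, report$scenario$profile), con)
    utils::write.csv(format(rows, digits = 17, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, quote = TRUE)
    flush(con)
    paste0(paste(out, collapse = "\n"), "\n")
  }
}

#' Write an assessment report to a file
#' @param report A `stockpile_assessment`.
#' @param path Output path.
#' @inheritParams render_report
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "csv"), manifest = NULL) {
  txt <- render_report(report, format, manifest)
  writeLines(txt, path, sep = "", useBytes = TRUE)
  invisible(path)
}

#' Read a JSON assessment report back into an object
#'
#' Inverse of the JSON serialization: `read_report(write_report(x))` is
#' value-identical to `x`.
#'
#' @param path Path to a JSON report.
#' @return A `stockpile_assessment`.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) io_error(sprintf("report file not found: %s", path))
  body <- jsonlite::read_json(path, simplifyVector = TRUE)
  rows <- body$rows
  rows$ratio_pct <- suppressWarnings(
    ifelse(rows$ratio_pct == "Inf", Inf, as.numeric(rows$ratio_pct)))
  rows <- rows[, c("nutrient", "name", "unit", "per_capita_daily", "required",
                   "supplied", "ratio_pct", "mark", "people_covered")]
  config <- do.call(scenario_config, body$scenario)
  structure(list(municipality = body$municipality, scenario = config,
                 victims = body$victims, rows = rows),
            class = "stockpile_assessment")
}
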