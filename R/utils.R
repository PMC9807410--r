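`%||%` <- function(a, b) if (is.null(a)) b else a

# stratum key used to index DRI value matrices: "sex|age_group"
stratum_key <- function(sex, age_group) paste(sex, age_group, sep = "|")

# delimiter inferred from file extension (.tsv/.tab/.txt -> tab, else comma)
infer_delim <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tsv", "tab", "txt")) "\t" else ","
}

read_table_file <- function(source) {
  if (is.character(source) && length(source) == 1L && !file.exists(source)) {
    io_error(sprintf("input file not found: %s", source))
  }
  delim <- if (is.character(source)) infer_delim(source) else ","
  out <- tryCatch(
    utils::read.table(source, header = TRUE, sep = delim, quote = "\"",
                      stringsAsFactors = FALSE, check.names = FALSE,
                      fileEncoding = "UTF-8", comment.char = ""),
    error = function(e) io_error(sprintf("failed to read table: %s", conditionMessage(e)))
  )
  out
}

write_table_file <- function(df, path) {
  delim <- infer_delim(path)
  # doubles are printed with 17 significant digits so read-write-read round
  # trips are value-identical
  for (col in names(df)) {
    if (is.double(df[[col]])) df[[col]] <- sprintf("%.17g", df[[col]])
  }
  utils::write.table(df, path, sep = delim, quote = TRUE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    schema_error(sprintf("%s: missing required column(s): %s",
                         what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# evaluate expr under a deterministic RNG state without disturbing the caller's
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647L))
  force(expr)
}
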