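BUNDLED_CATEGORIES <- c(
  "Rice and the like",
  "Wheat flour, rice flour, rice cakes",
  "Dried noodles, instant noodles, cup noodles",
  "Dried bread, cookies, and the like",
  "Pouched, sterilized food",
  "Canned food",
  "Dried food",
  "Milk and juice",
  "Seasonings")

#' The bundled food catalog
#'
#' Returns the transcription of the reference planning tool's printed food-product lists:
#' four staple-food groups (rice; flours and rice cakes; dried/instant/cup
#' noodles; dried bread and cookies) and five main/side-dish groups
#' (pouched sterilized, canned, dried, milk and juice, seasonings). Item
#' names are kept verbatim as printed, including transliterated Japanese
#' terms; "Milk and juice" and "Seasonings" are carried as empty categories
#' because no items are printed for them.
#'
#' The printed lists carry names only. Per-100 g compositions are therefore
#' absent (a zero-column composition matrix: assessing against this catalog
#' treats every nutrient as 0 with a warning) and the stockpilability,
#' cooking and wheat flags are synthetic keyword annotations, not printed
#' data. Users supply their own composition table for real assessments;
#' the synthetic generators ([gen_catalog()]) provide compositions for
#' testing.
#'
#' @return A [food_catalog()] with 124 items in 9 categories.
#' @examples
#' cat9 <- bundled_catalog()
#' table(cat9$items$category)[["Canned food"]]  # 29
#' @export
bundled_catalog <- function() {
  path <- system.file("extdata", "bundled_catalog.csv", package = "nutristock",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                        check.names = FALSE)
  food_catalog(df, matrix(numeric(), nrow = nrow(df), ncol = 0),
               categories = BUNDLED_CATEGORIES)
}
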