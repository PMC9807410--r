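test_that("demographics assemble, validate and round-trip", {
  demo <- toy_demo()
  expect_s3_class(demo, "demographic_table")
  expect_equal(total_population(demo), 100)

  # 2-sex x 3-age grid sums by hand: 10+20+30+40+50+60 = 210
  grid <- expand.grid(sex = c("male", "female"), age_group = c("child", "adult", "senior"),
                      stringsAsFactors = FALSE)
  grid$count <- c(10, 20, 30, 40, 50, 60)
  expect_equal(total_population(demographic_table("G", grid)), 210)

  dup <- data.frame(sex = c("male", "male"), age_group = "adult", count = c(1, 2))
  expect_error(demographic_table("D", dup), class = "nutristock_schema_error")
  expect_error(toy_demo(c(male = -1, female = 5)), class = "nutristock_value_error")
  expect_error(toy_demo(c(male = 0, female = 0)), class = "nutristock_value_error")

  path <- withr::local_tempfile(fileext = ".csv")
  write_demographics(demo, path)
  expect_equal(read_demographics(path), demo)
  # tab-separated dialect round-trips identically
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_demographics(demo, tsv)
  expect_equal(read_demographics(tsv), demo)
})

test_that("DRI tables enforce a complete non-negative grid and round-trip", {
  dri <- toy_dri()
  expect_equal(unname(dri$values["energy", ]), c(2000, 1600))

  vals <- data.frame(nutrient_id = "energy", sex = "male", age_group = "adult",
                     value = 2000)
  nuts <- data.frame(id = "energy", name = "Energy", unit = "kcal")
  two_strata <- rbind(vals, data.frame(nutrient_id = "protein", sex = "male",
                                       age_group = "adult", value = 50))
  expect_error(dri_table(rbind(nuts, data.frame(id = "protein", name = "P", unit = "g")),
                         rbind(two_strata[1, ],
                               data.frame(nutrient_id = "protein", sex = "female",
                                          age_group = "adult", value = 50))),
               class = "nutristock_completeness_error")
  vals$value <- -1
  expect_error(dri_table(nuts, vals), class = "nutristock_value_error")

  dri8 <- gen_dri(fixture_spec(seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dri_table(dri8, path)
  back <- read_dri_table(path)
  expect_identical(back$values, dri8$values)
  expect_equal(back$nutrients, dri8$nutrients)
})

test_that("food catalogs validate ids, compositions and flags and round-trip", {
  cat1 <- toy_catalog()
  expect_equal(nrow(cat1$items), 3)
  expect_false(anyDuplicated(cat1$items$id) > 0)

  items <- cat1$items; items$id[2] <- "alpha_rice"
  expect_error(food_catalog(items, cat1$per100g), class = "nutristock_schema_error")
  comp <- cat1$per100g; comp[1, "energy"] <- -5
  expect_error(food_catalog(cat1$items, comp), class = "nutristock_value_error")

  path <- withr::local_tempfile(fileext = ".csv")
  write_food_catalog(cat1, path)
  back <- read_food_catalog(path)
  expect_identical(back$per100g, cat1$per100g)
  expect_equal(back$items, cat1$items)

  # declared-nutrient handling: unknown column rejected, absent declared is 0
  expect_error(read_food_catalog(path, nutrients = c("energy", "protein")),
               class = "nutristock_schema_error")
  expect_warning(back2 <- read_food_catalog(path, nutrients = c(colnames(cat1$per100g), "fibre")),
                 "fibre")
  expect_equal(unname(back2$per100g[, "fibre"]), rep(0, 3))
})

test_that("inventories read in both gram and pack dialects", {
  cat1 <- toy_catalog()
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(food_id = "alpha_rice", quantity_grams = 5000), path,
            row.names = FALSE)
  inv <- read_inventory(path)
  expect_equal(inv$entries$quantity_grams, 5000)

  write.csv(data.frame(food_id = "tuna_can", packs = 3), path, row.names = FALSE)
  inv <- read_inventory(path, cat1)
  expect_equal(inv$entries$quantity_grams, 210)   # 3 packs x 70 g

  write.csv(data.frame(food_id = character(), quantity_grams = numeric()), path,
            row.names = FALSE)
  expect_equal(nrow(read_inventory(path)$entries), 0)

  write.csv(data.frame(food_id = "tuna_can", quantity_grams = -1), path,
            row.names = FALSE)
  expect_error(read_inventory(path), class = "nutristock_value_error")

  inv <- toy_inventory(alpha_rice = 100, tuna_can = 50)
  out <- withr::local_tempfile(fileext = ".csv")
  write_inventory(inv, out)
  expect_equal(read_inventory(out), inv)
})

test_that("the bundled catalog reproduces the printed category counts verbatim", {
  cat9 <- bundled_catalog()
  counts <- table(factor(cat9$items$category, levels = cat9$categories))
  expect_equal(counts[["Rice and the like"]], 10)
  expect_equal(counts[["Wheat flour, rice flour, rice cakes"]], 10)
  expect_equal(counts[["Dried noodles, instant noodles, cup noodles"]], 13)
  expect_equal(counts[["Dried bread, cookies, and the like"]], 6)
  expect_equal(counts[["Pouched, sterilized food"]], 9)
  expect_equal(counts[["Canned food"]], 29)
  expect_equal(counts[["Dried food"]], 47)
  # the two groups with no printed items are carried as empty categories
  expect_equal(counts[["Milk and juice"]], 0)
  expect_equal(counts[["Seasonings"]], 0)
  expect_equal(nrow(cat9$items), 124)
  # spot-check verbatim names
  expect_true("Alpha rice" %in% cat9$items$name)
  expect_true("Balanced, nutritional food" %in% cat9$items$name)
  expect_true("Sweet red bean jelly (Youkan)" %in% cat9$items$name)
})

test_that("alignment validation reports exactly the uncovered strata", {
  demo <- toy_demo()
  dri <- toy_dri()
  expect_identical(validate_alignment(demo, dri), character())

  # demographic stratum absent from the DRI is named
  demo3 <- demographic_table("T", data.frame(
    sex = c("male", "female", "male"), age_group = c("adult", "adult", "child"),
    count = c(1, 1, 1)))
  issues <- validate_alignment(demo3, dri)
  expect_length(issues, 1)
  expect_match(issues, "male|child")

  # extra DRI strata are harmless
  dri_extra <- dri_table(
    data.frame(id = "energy", name = "Energy", unit = "kcal"),
    data.frame(nutrient_id = "energy", sex = c("male", "female", "male"),
               age_group = c("adult", "adult", "child"),
               value = c(2000, 1600, 1400)))
  expect_identical(validate_alignment(demo, dri_extra), character())
  # and an aligned pair never raises downstream (contract coupling)
  expect_silent(total_required(dri_extra, demo, scenario_config()))
})
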