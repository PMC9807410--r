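test_that("stockpilability filtering applies flags and whitelist", {
  items <- data.frame(
    id = c("keeper", "perishable", "cooker", "wheaty"),
    name = c("Keeper", "Perishable", "Cooker", "Wheaty"),
    category = "side",
    shelf_stable = c(TRUE, FALSE, TRUE, TRUE),
    requires_cooking = c(FALSE, FALSE, TRUE, FALSE),
    contains_wheat = c(FALSE, FALSE, FALSE, TRUE))
  cat1 <- food_catalog(items, matrix(1, 4, 1, dimnames = list(NULL, "energy")))

  expect_identical(filter_stockpilable(cat1)$items$id, c("keeper", "wheaty"))
  expect_identical(filter_stockpilable(cat1, planning_constraints(exclude_wheat = TRUE))$items$id,
                   "keeper")
  # all flags off: identity
  all_off <- planning_constraints(require_shelf_stable = FALSE, exclude_cooking = FALSE)
  expect_identical(filter_stockpilable(cat1, all_off)$items$id, items$id)
  # whitelist intersects with flags
  expect_identical(filter_stockpilable(cat1, planning_constraints(candidate_ids = "wheaty"))$items$id,
                   "wheaty")
  # nothing left: a warning, not an error
  wheat_only <- food_catalog(items[4, ], matrix(1, 1, 1, dimnames = list(NULL, "energy")))
  expect_warning(res <- filter_stockpilable(wheat_only, planning_constraints(exclude_wheat = TRUE)),
                 "no catalog item")
  expect_equal(nrow(res$items), 0)
  expect_error(planning_constraints(budget = -1), class = "nutristock_config_error")
})

test_that("deficits are the positive part of required minus supplied", {
  spec <- fixture_spec(seed = 2, total_population = 1000)
  demo <- gen_demographics(spec); dri <- gen_dri(spec); cat1 <- gen_catalog(spec)
  cfg <- scenario_config(profile = "shelter5")
  rep_full <- assess(demo, dri, cat1, exact_cover_inventory(demo, dri, cat1, cfg), cfg)
  expect_true(all(deficits(rep_full) <= 1e-6 * rep_full$rows$required))

  rep0 <- assess(demo, dri, cat1, inventory(), cfg)
  expect_equal(unname(deficits(rep0)), rep0$rows$required)

  # hand case: required 1000, supplied 400 -> short 600; and 0 exactly at 100%
  fake <- rep0
  fake$rows$required <- c(1000, 1000, 1, 1, 1)
  fake$rows$supplied <- c(400, 1000, 2, 1, 0)
  expect_equal(unname(deficits(fake)), c(600, 0, 0, 0, 1))
})

single_nutrient_report <- function(required, supplied) {
  structure(list(municipality = "T", scenario = scenario_config(profile = "full"),
                 victims = 1,
                 rows = data.frame(nutrient = "energy", name = "Energy",
                                   unit = "kcal", per_capita_daily = required / 3,
                                   required = required, supplied = supplied,
                                   ratio_pct = excess_deficiency_ratio(supplied, required),
                                   mark = adequacy_mark(excess_deficiency_ratio(supplied, required)),
                                   people_covered = 0, stringsAsFactors = FALSE)),
            class = "stockpile_assessment")
}

one_food_catalog <- function(energy_per_100g = 300, pack_grams = 100,
                             cost_per_pack = NA_real_) {
  food_catalog(
    data.frame(id = "bar", name = "Bar", category = "side",
               shelf_stable = TRUE, requires_cooking = FALSE, contains_wheat = FALSE,
               pack_grams = pack_grams, cost_per_pack = cost_per_pack),
    matrix(energy_per_100g, 1, 1, dimnames = list("bar", "energy")))
}

test_that("greedy closes a single deficit with the arithmetic pack count", {
  # deficit 600 kcal, candidate delivers 300 kcal/pack -> exactly 2 packs
  rep1 <- single_nutrient_report(required = 1000, supplied = 400)
  plan <- greedy_plan(rep1, one_food_catalog())
  expect_true(plan$feasible)
  expect_equal(plan$suggestions$packs, 2L)
  expect_equal(plan$suggestions$add_grams, 200)
  expect_equal(unname(plan$achieved_ratios["energy"]), 100)
  expect_equal(plan$objective, 200)          # unpriced: grams
  expect_identical(plan$objective_unit, "grams")
  expect_silent(verify_plan(plan, rep1, one_food_catalog()))

  # zero deficits in: empty feasible plan, objective 0
  plan0 <- greedy_plan(single_nutrient_report(1000, 1200), one_food_catalog())
  expect_true(plan0$feasible)
  expect_equal(nrow(plan0$suggestions), 0)
  expect_equal(plan0$objective, 0)

  # budget below one pack's cost: empty infeasible plan
  planb <- greedy_plan(rep1, one_food_catalog(cost_per_pack = 500),
                       planning_constraints(budget = 499))
  expect_false(planb$feasible)
  expect_equal(nrow(planb$suggestions), 0)
  expect_match(planb$note, "cap")

  suppressWarnings(
    expect_error(greedy_plan(rep1, one_food_catalog(),
                             planning_constraints(candidate_ids = "ghost")),
                 class = "nutristock_planning_error"))
})

test_that("lp plan matches the closed form and reports infeasibility causes", {
  # deficit 600, 350 kcal per 100 g -> 600/3.5 g
  rep1 <- single_nutrient_report(required = 1000, supplied = 400)
  plan <- lp_plan(rep1, one_food_catalog(energy_per_100g = 350))
  expect_true(plan$feasible)
  expect_equal(plan$suggestions$add_grams, 600 / 3.5, tolerance = 1e-9)
  expect_equal(unname(plan$achieved_ratios["energy"]), 100, tolerance = 1e-9)

  # every candidate lacking the deficient nutrient: infeasible, named
  no_energy <- food_catalog(
    data.frame(id = "water", name = "Water", category = "side"),
    matrix(0, 1, 1, dimnames = list("water", "energy")))
  planx <- lp_plan(rep1, no_energy)
  expect_false(planx$feasible)
  expect_match(planx$note, "energy")
})

test_that("plans verify through the independent assessment path; tampering is caught", {
  spec <- fixture_spec(seed = 13, total_population = 1500)
  demo <- gen_demographics(spec); dri <- gen_dri(spec)
  cat1 <- gen_catalog(spec); inv <- gen_inventory(spec, cat1)
  rep1 <- assess(demo, dri, cat1, inv, scenario_config(profile = "shelter5"))

  gp <- greedy_plan(rep1, cat1)
  lp <- lp_plan(rep1, cat1)
  expect_silent(verify_plan(gp, rep1, cat1))
  expect_silent(verify_plan(lp, rep1, cat1))

  tampered <- gp
  tampered$suggestions <- tampered$suggestions[-1, , drop = FALSE]
  expect_error(verify_plan(tampered, rep1, cat1), class = "nutristock_consistency_error")

  # empty plan on a zero-deficit report passes
  cfg <- scenario_config(profile = "shelter5")
  repc <- assess(demo, dri, cat1, exact_cover_inventory(demo, dri, cat1, cfg), cfg)
  plan0 <- greedy_plan(repc, cat1)
  expect_equal(nrow(plan0$suggestions), 0)
  expect_silent(verify_plan(plan0, repc, cat1))
})

test_that("greedy is deterministic and the LP bounds it from below", {
  for (s in c(3, 17, 29)) {
    spec <- fixture_spec(seed = s, total_population = 1200)
    demo <- gen_demographics(spec); dri <- gen_dri(spec)
    cat1 <- gen_catalog(spec); inv <- gen_inventory(spec, cat1)
    rep1 <- assess(demo, dri, cat1, inv, scenario_config(profile = "shelter5"))
    g1 <- greedy_plan(rep1, cat1); g2 <- greedy_plan(rep1, cat1)
    expect_identical(g1$suggestions, g2$suggestions)
    l1 <- lp_plan(rep1, cat1)
    expect_lte(l1$objective, g1$objective * (1 + 1e-9))
  }
  # single-nutrient single-candidate: both equal the closed form deficit/content
  rep1 <- single_nutrient_report(1000, 400)
  cat1 <- one_food_catalog(energy_per_100g = 300, pack_grams = 200)
  g <- greedy_plan(rep1, cat1); l <- lp_plan(rep1, cat1)
  expect_equal(l$suggestions$add_grams, 200)   # 600 kcal / 3 kcal-per-g
  expect_equal(g$suggestions$add_grams, 200)   # one 200 g pack, exact fit
  expect_equal(g$objective, l$objective)
})

test_that("enlarging the candidate set never worsens the LP objective", {
  spec <- fixture_spec(seed = 23, total_population = 1200)
  demo <- gen_demographics(spec); dri <- gen_dri(spec)
  cat1 <- gen_catalog(spec); inv <- gen_inventory(spec, cat1)
  rep1 <- assess(demo, dri, cat1, inv, scenario_config(profile = "shelter5"))
  ids <- filter_stockpilable(cat1)$items$id
  prev <- Inf
  for (k in seq(2, length(ids))) {
    plan <- lp_plan(rep1, cat1, planning_constraints(candidate_ids = ids[1:k]))
    if (plan$feasible) {
      expect_lte(plan$objective, prev * (1 + 1e-9))
      prev <- plan$objective
    }
  }
  expect_true(is.finite(prev))   # the full set was feasible
})
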