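#' Specification for the synthetic-fixture generators
#'
#' One seed drives one documented pseudo-random stream per generator, so all
#' fixtures are pure functions of their spec: the same seed yields
#' bit-identical outputs. Magnitudes loosely follow real-world scales
#' (energy ~10^2 kcal/100 g, vitamins ~10^-1..10^0 mg/100 g) so rounding
#' behaviour is realistic, but the exact values are arbitrary and synthetic.
#'
#' The default `carb_skew` of 0.85 emulates the documented real-world
#' pattern of municipal stockpiles being heavily skewed toward carbohydrate
#' staples, which leaves vitamins short.
#'
#' @param seed Integer seed.
#' @param n_age_groups Number of age groups (>= 1).
#' @param total_population Total municipal population (>= 1).
#' @param n_staples Number of staple foods in the generated catalog (>= 1).
#' @param n_sides Number of main/side-dish foods (>= 1).
#' @param carb_skew Proportion of inventory mass drawn from staples, in
#'   \[0, 1\]. Default 0.85.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_age_groups = 6L, total_population = 50000L,
                         n_staples = 6L, n_sides = 8L, carb_skew = 0.85) {
  if (n_age_groups < 1 || total_population < 1 || n_staples < 1 || n_sides < 1) {
    config_error("fixture counts must be >= 1")
  }
  if (carb_skew < 0 || carb_skew > 1) config_error("carb_skew must be in [0, 1]")
  structure(list(seed = as.integer(seed), n_age_groups = as.integer(n_age_groups),
                 total_population = as.integer(total_population),
                 n_staples = as.integer(n_staples), n_sides = as.integer(n_sides),
                 carb_skew = carb_skew),
            class = "fixture_spec")
}

FIXTURE_AGE_LABELS <- c("0-5", "6-11", "12-17", "18-29", "30-49", "50-64",
                        "65-74", "75+")

fixture_age_groups <- function(n) {
  if (n <= length(FIXTURE_AGE_LABELS)) FIXTURE_AGE_LABELS[seq_len(n)]
  else c(FIXTURE_AGE_LABELS, paste0("extra_", seq_len(n - length(FIXTURE_AGE_LABELS))))
}

# full synthetic nutrient set; the first five are the shelter profile
fixture_nutrients <- function() {
  data.frame(
    id = c("energy", "protein", "vit_b1", "vit_b2", "vit_c",
           "fat", "calcium", "iron"),
    name = c("Energy", "Protein", "Vitamin B1", "Vitamin B2", "Vitamin C",
             "Fat", "Calcium", "Iron"),
    unit = c("kcal", "g", "mg", "mg", "mg", "g", "mg", "mg"),
    stringsAsFactors = FALSE)
}

# per-day adult reference magnitudes the synthetic DRI values are built from
FIXTURE_DRI_BASE <- c(energy = 2000, protein = 50, vit_b1 = 1.1, vit_b2 = 1.2,
                      vit_c = 100, fat = 60, calcium = 650, iron = 7.5)

#' Generate a synthetic demographic table
#'
#' Positive head counts in every sex x age-group stratum, summing exactly to
#' `total_population`; deterministic per seed.
#'
#' @param spec A [fixture_spec()].
#' @return A `demographic_table`.
#' @export
gen_demographics <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  ages <- fixture_age_groups(spec$n_age_groups)
  grid <- expand.grid(sex = c("male", "female"), age_group = ages,
                      stringsAsFactors = FALSE)
  with_seed(spec$seed + 101L, {
    w <- stats::runif(nrow(grid), 0.3, 1)
    w <- w / sum(w)
    counts <- floor(w * spec$total_population)
    counts[counts == 0] <- 1L
    # largest-remainder style fix-up to conserve the total exactly
    diff <- spec$total_population - sum(counts)
    while (diff != 0) {
      i <- if (diff > 0) which.max(w) else which.max(counts)
      counts[i] <- counts[i] + sign(diff)
      diff <- diff - sign(diff)
    }
    demographic_table(sprintf("Synthetic City %d", spec$seed),
                      data.frame(sex = grid$sex, age_group = grid$age_group,
                                 count = counts, stringsAsFactors = FALSE))
  })
}

#' Generate a synthetic DRI table
#'
#' Always contains the five shelter nutrients (plus fat, calcium and iron),
#' with positive per-day values that vary by sex and age group around
#' realistic adult magnitudes; deterministic per seed.
#'
#' @param spec A [fixture_spec()].
#' @return A `dri_table` on which the `shelter5` profile always resolves.
#' @export
gen_dri <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  nutrients <- fixture_nutrients()
  ages <- fixture_age_groups(spec$n_age_groups)
  grid <- expand.grid(sex = c("male", "female"), age_group = ages,
                      stringsAsFactors = FALSE)
  with_seed(spec$seed + 202L, {
    # age multiplier: children lower, working-age peak, old slightly lower
    age_mult <- stats::runif(length(ages), 0.55, 1.1)
    sex_mult <- c(male = 1.1, female = 0.9)
    # each stratum is a scaled copy of the reference adult profile: one
    # multiplicative factor per stratum (sex x age x jitter), identical
    # across nutrients. Real DRI tables also vary the ratios between
    # nutrients across strata; the generator deliberately does not, so a
    # catalog carrying a balanced ration item always spans the weighted
    # requirement exactly (see the methods vignette).
    rows <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
      mult <- sex_mult[[grid$sex[i]]] * age_mult[match(grid$age_group[i], ages)] *
        stats::runif(1, 0.95, 1.05)
      data.frame(nutrient_id = nutrients$id, sex = grid$sex[i],
                 age_group = grid$age_group[i],
                 value = FIXTURE_DRI_BASE[nutrients$id] * mult,
                 stringsAsFactors = FALSE)
    }))
    dri_table(nutrients, rows)
  })
}

# staples alternate between two sub-types mirroring the staple food groups:
# grains (rice/flour/noodles: starch plus a little protein) and
# confectionery (dried bread, cookies, sweet bean jelly: almost pure energy).
# All are energy-rich and essentially vitamin-free.
staple_compositions <- function(n) {
  type <- rep_len(1:2, n)
  draw <- function(lo, hi) stats::runif(n, lo[type], hi[type])
  cbind(energy  = draw(c(330, 280), c(370, 360)),
        protein = draw(c(5, 0.2),   c(9, 1.5)),
        vit_b1  = draw(c(0, 0),     c(0.05, 0.02)),
        vit_b2  = draw(c(0, 0),     c(0.04, 0.02)),
        vit_c   = rep(0, n),
        fat     = draw(c(0.5, 0),   c(3, 2)),
        calcium = draw(c(3, 2),     c(15, 20)),
        iron    = draw(c(0.2, 0.1), c(1.2, 0.8)))
}

# side dishes: the first is always a fortified balanced ration (a real
# stockpile product class, formulated so 100 g supplies about a fifth of an
# adult day's reference amounts across the board); the rest cycle through
# three realistic sub-types so the catalog's nutrient span is broad: canned
# fish/meat (protein, B vitamins, fat), vegetable/fruit (vitamin C, little
# protein or energy) and dairy/seaweed (calcium, iron, riboflavin, fat).
# Matrix is n x 8 in fixture_nutrients order.
side_compositions <- function(n) {
  m <- n - 1L
  type <- rep_len(1:3, m)
  draw <- function(lo, hi) stats::runif(m, lo[type], hi[type])
  rest <- cbind(energy  = draw(c(120, 30, 50),    c(250, 80, 150)),
                protein = draw(c(15, 0.5, 3),     c(25, 2, 8)),
                vit_b1  = draw(c(0.1, 0.05, 0.05), c(0.9, 0.2, 0.3)),
                vit_b2  = draw(c(0.1, 0.05, 0.2), c(0.9, 0.2, 0.9)),
                vit_c   = draw(c(0, 20, 0),       c(5, 60, 10)),
                fat     = draw(c(5, 0.1, 1),      c(15, 0.5, 8)),
                calcium = draw(c(20, 10, 100),    c(60, 40, 400)),
                iron    = draw(c(1, 0.3, 1),      c(3, 1, 8)))
  rbind(matrix(FIXTURE_DRI_BASE * 0.2, nrow = 1,
               dimnames = list(NULL, names(FIXTURE_DRI_BASE))),
        rest)[seq_len(n), , drop = FALSE]
}

#' Generate a synthetic food catalog
#'
#' Staples are energy-rich and vitamin-poor (near-zero B1/B2/C); main/side
#' dishes carry the protein and vitamins — mirroring the structural reason
#' staple-only stockpiles fail on everything but calories. Flags are
#' assigned so at least one item fails the default stockpilable filters
#' (one staple requires cooking, one side is perishable), exercising the
#' planner's filtering. All items carry pack sizes, costs and volumes.
#'
#' @param spec A [fixture_spec()].
#' @return A `food_catalog` with categories `"staple"` and `"side"`.
#' @export
gen_catalog <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n_s <- spec$n_staples; n_m <- spec$n_sides
  with_seed(spec$seed + 303L, {
    ids <- c(sprintf("staple_%02d", seq_len(n_s)), sprintf("side_%02d", seq_len(n_m)))
    names <- c(sprintf("Synthetic staple %02d", seq_len(n_s)),
               "Synthetic fortified ration",
               sprintf("Synthetic side dish %02d", seq_len(n_m))[-1])
    names <- names[seq_len(n_s + n_m)]
    category <- c(rep("staple", n_s), rep("side", n_m))
    comp <- rbind(staple_compositions(n_s), side_compositions(n_m))
    rownames(comp) <- ids
    pack_grams <- c(rep(100, n_s), sample(c(70, 100, 150), n_m, replace = TRUE))
    items <- data.frame(
      id = ids, name = names, category = category,
      shelf_stable = TRUE, requires_cooking = FALSE, contains_wheat = FALSE,
      pack_grams = pack_grams,
      cost_per_pack = round(stats::runif(n_s + n_m, 100, 500)),
      volume_per_pack = round(pack_grams / 1000 * stats::runif(n_s + n_m, 0.8, 1.5), 3),
      stringsAsFactors = FALSE)
    # guaranteed filter exercise: last staple needs cooking, last side perishable,
    # first staple contains wheat
    items$requires_cooking[n_s] <- TRUE
    items$shelf_stable[n_s + n_m] <- FALSE
    items$contains_wheat[1] <- TRUE
    food_catalog(items, comp, categories = c("staple", "side"))
  })
}

#' Generate a synthetic stockpile inventory
#'
#' Splits the total stocked mass `carb_skew : (1 - carb_skew)` between
#' staples and sides, then spreads each share randomly over the items of
#' that category; deterministic per seed. The stocked mass is sized at
#' roughly half of what the affected population would need in food mass
#' (about 400 g/person/day for the default three days and 20% affected
#' fraction), emulating an understocked, carbohydrate-heavy reserve.
#'
#' @param spec A [fixture_spec()].
#' @param catalog A catalog from [gen_catalog()].
#' @return An `inventory`.
#' @export
gen_inventory <- function(spec, catalog) {
  stopifnot(inherits(spec, "fixture_spec"), inherits(catalog, "food_catalog"))
  with_seed(spec$seed + 404L, {
    total_mass <- 0.20 * spec$total_population * 3 * 400 * 0.5
    staples <- catalog$items$id[catalog$items$category == "staple"]
    sides <- catalog$items$id[catalog$items$category == "side"]
    split_mass <- function(ids, mass) {
      if (!length(ids) || mass <= 0)
        return(data.frame(food_id = character(), quantity_grams = numeric()))
      w <- stats::runif(length(ids), 0.2, 1)
      data.frame(food_id = ids, quantity_grams = mass * w / sum(w),
                 stringsAsFactors = FALSE)
    }
    entries <- rbind(split_mass(staples, total_mass * spec$carb_skew),
                     split_mass(sides, total_mass * (1 - spec$carb_skew)))
    inventory(entries)
  })
}

#' Construct an exact-cover inventory
#'
#' A synthetic stockpile whose assessment yields a ratio of exactly 100%
#' (to within 1e-9 relative) for every profile nutrient — the package's
#' parameter-recovery fixture. Built by solving the minimum-mass linear
#' programme `min sum(x)` subject to `per-gram composition %*% x = total
#' required`, `x >= 0` over all catalog items.
#'
#' @param demo A `demographic_table`.
#' @param dri A `dri_table`.
#' @param catalog A `food_catalog` whose nutrient span covers the profile.
#' @param config A `scenario_config`.
#' @return An `inventory`. Raises a planning error when the catalog cannot
#'   span the profile requirement exactly.
#' @export
exact_cover_inventory <- function(demo, dri, catalog, config = scenario_config()) {
  req <- total_required(dri, demo, config)
  if (!length(req$nutrients) || all(req$total_required == 0)) return(inventory())
  comp <- matrix(0, length(req$nutrients), nrow(catalog$items),
                 dimnames = list(req$nutrients, catalog$items$id))
  present <- intersect(req$nutrients, colnames(catalog$per100g))
  comp[present, ] <- t(catalog$per100g[, present, drop = FALSE]) / 100
  sol <- solve_lp(rep(1, ncol(comp)), A_eq = comp, b_eq = req$total_required)
  if (sol$status != "optimal") {
    planning_error(sprintf(
      "catalog cannot exactly cover the '%s' profile requirement (LP %s)",
      config$profile, sol$status))
  }
  x <- sol$x
  keep <- x > 1e-9
  inventory(data.frame(food_id = catalog$items$id[keep],
                       quantity_grams = x[keep], stringsAsFactors = FALSE))
}
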