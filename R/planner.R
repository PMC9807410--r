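#' Purchase-planning constraints
#'
#' Which catalog items are admissible purchase candidates and which resource
#' caps bind the plan. Defaults keep only shelf-stable items that need no
#' cooking — the genuinely stockpilable subset of a catalog.
#'
#' @param require_shelf_stable Keep only shelf-stable items. Default TRUE.
#' @param exclude_cooking Drop items that require cooking. Default TRUE.
#' @param exclude_wheat Drop items containing wheat (for wheat-allergy
#'   provisioning). Default FALSE.
#' @param budget Optional currency cap on total plan cost (>= 0).
#' @param volume_cap Optional cap on total added storage volume, litres.
#' @param candidate_ids Optional whitelist of item ids.
#' @return An object of class `planning_constraints`.
#' @export
planning_constraints <- function(require_shelf_stable = TRUE,
                                 exclude_cooking = TRUE,
                                 exclude_wheat = FALSE,
                                 budget = NULL, volume_cap = NULL,
                                 candidate_ids = NULL) {
  for (cap in list(budget = budget, volume_cap = volume_cap)) {
    if (!is.null(cap) && (!is.numeric(cap) || length(cap) != 1L || is.na(cap) || cap < 0)) {
      config_error("caps must be single non-negative numbers when present")
    }
  }
  structure(list(require_shelf_stable = isTRUE(require_shelf_stable),
                 exclude_cooking = isTRUE(exclude_cooking),
                 exclude_wheat = isTRUE(exclude_wheat),
                 budget = budget, volume_cap = volume_cap,
                 candidate_ids = candidate_ids),
            class = "planning_constraints")
}

#' Filter a catalog to stockpilable foods
#'
#' Keeps the items passing every active flag filter and the whitelist. An
#' empty result warns (it is a data problem, not a usage error).
#'
#' @param catalog A `food_catalog`.
#' @param constraints A `planning_constraints`.
#' @return A `food_catalog` restricted to the admissible items (categories
#'   list preserved).
#' @export
filter_stockpilable <- function(catalog, constraints = planning_constraints()) {
  stopifnot(inherits(catalog, "food_catalog"),
            inherits(constraints, "planning_constraints"))
  keep <- rep(TRUE, nrow(catalog$items))
  if (constraints$require_shelf_stable) keep <- keep & catalog$items$shelf_stable
  if (constraints$exclude_cooking) keep <- keep & !catalog$items$requires_cooking
  if (constraints$exclude_wheat) keep <- keep & !catalog$items$contains_wheat
  if (!is.null(constraints$candidate_ids)) {
    keep <- keep & catalog$items$id %in% constraints$candidate_ids
  }
  if (!any(keep)) {
    warning("no catalog item passes the stockpilability filters", call. = FALSE)
  }
  food_catalog(catalog$items[keep, , drop = FALSE],
               catalog$per100g[keep, , drop = FALSE],
               categories = catalog$categories)
}

#' Per-nutrient deficits of an assessment
#'
#' `max(0, required - supplied)` for every profile nutrient; zero exactly at
#' a ratio of 100%.
#'
#' @param report A `stockpile_assessment`.
#' @return Named numeric vector of amounts short, one per profile nutrient.
#' @export
deficits <- function(report) {
  stopifnot(inherits(report, "stockpile_assessment"))
  stats::setNames(pmax(0, report$rows$required - report$rows$supplied),
                  report$rows$nutrient)
}

# shared planner preamble: admissible candidates and their per-pack data
plan_candidates <- function(report, catalog, constraints) {
  cand <- filter_stockpilable(catalog, constraints)
  if (!nrow(cand$items)) planning_error("no purchase candidates after filtering")
  nutrients <- report$rows$nutrient
  comp <- matrix(0, nrow(cand$items), length(nutrients),
                 dimnames = list(cand$items$id, nutrients))
  present <- intersect(nutrients, colnames(cand$per100g))
  comp[, present] <- cand$per100g[, present]
  priced <- all(is.finite(cand$items$cost_per_pack))
  list(catalog = cand, comp = comp, priced = priced, nutrients = nutrients)
}

new_purchase_plan <- function(mode, suggestions, achieved, objective,
                              objective_unit, feasible, note = NULL) {
  structure(list(mode = mode, suggestions = suggestions,
                 achieved_ratios = achieved, objective = objective,
                 objective_unit = objective_unit, feasible = feasible,
                 note = note),
            class = "purchase_plan")
}

#' @export
print.purchase_plan <- function(x, ...) {
  cat(sprintf("Purchase plan (%s, %s): %s, objective %s %s\n", x$mode,
              if (x$feasible) "feasible" else "infeasible",
              if (nrow(x$suggestions)) sprintf("%d item(s)", nrow(x$suggestions)) else "empty",
              format(signif(x$objective, 6), big.mark = ","), x$objective_unit))
  if (nrow(x$suggestions)) print(x$suggestions, row.names = FALSE)
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  cat("achieved ratios (%):\n")
  print(round(x$achieved_ratios, 1))
  invisible(x)
}

#' Greedy integer-pack purchase plan
#'
#' Builds an actionable whole-pack shopping list that closes the
#' assessment's per-nutrient deficits. Each step buys one pack of the
#' candidate with the best reduction in total normalized deficit
#' (`sum_n max(0, 1 - supplied_n/required_n)`, unitless so kcal and mg
#' nutrients are commensurable) per unit cost — per gram when the catalog
#' is unpriced. Ties break by lower pack cost, then lexicographic food id,
#' making the plan fully deterministic. Stops when every deficit is zero
#' (feasible), or when no candidate reduces any deficit or a budget/volume
#' cap blocks every helpful candidate (infeasible). Runs of packs between
#' score-changing breakpoints are bought in batches, which is exactly
#' equivalent to one-pack-at-a-time.
#'
#' @param report A `stockpile_assessment`.
#' @param catalog A `food_catalog`.
#' @param constraints A `planning_constraints`.
#' @return A `purchase_plan` with integer `packs` per suggestion.
#' @export
greedy_plan <- function(report, catalog, constraints = planning_constraints()) {
  stopifnot(inherits(report, "stockpile_assessment"))
  pc <- plan_candidates(report, catalog, constraints)
  items <- pc$catalog$items
  nutrients <- pc$nutrients
  required <- stats::setNames(report$rows$required, nutrients)
  supplied <- stats::setNames(report$rows$supplied, nutrients)
  pack_content <- pc$comp * items$pack_grams / 100      # per pack, items x nutrients
  unit_cost <- if (pc$priced) items$cost_per_pack else items$pack_grams
  unit_vol <- items$volume_per_pack

  packs <- stats::setNames(integer(nrow(items)), items$id)
  spent <- 0; vol_used <- 0
  active <- required > 0          # zero-requirement rows can have no deficit
  deficit <- pmax(required - supplied, 0)

  # deterministic candidate order for tie-breaking: cost, then id
  tie_ord <- order(unit_cost, items$id)

  max_iter <- 1e6L
  iter <- 0L
  while (any(deficit > 0)) {
    iter <- iter + 1L
    if (iter > max_iter) planning_error("greedy planner exceeded iteration budget")
    # score: normalized deficit reduction per unit cost for one pack
    red <- sweep(pmin(pack_content, rep(deficit, each = nrow(items))), 2,
                 ifelse(active, required, Inf), "/")
    score <- rowSums(red) / unit_cost
    # cap admissibility for one more pack
    ok <- score > 0
    if (!is.null(constraints$budget) && pc$priced) {
      ok <- ok & (spent + items$cost_per_pack <= constraints$budget + 1e-9)
    }
    if (!is.null(constraints$volume_cap)) {
      ok <- ok & is.finite(unit_vol) & (vol_used + unit_vol <= constraints$volume_cap + 1e-9)
    }
    if (!any(ok)) {
      reason <- if (!any(score > 0)) "no candidate reduces any remaining deficit"
                else "budget/volume cap blocks every helpful candidate"
      return(finish_greedy(packs, items, pc, supplied, required, pack_content,
                           feasible = FALSE, note = reason))
    }
    best <- tie_ord[ok[tie_ord]][which.max(score[tie_ord[ok[tie_ord]]])]
    # batch: scores are constant while every deficit stays above the largest
    # single-pack contribution for that nutrient; jump to the next breakpoint
    thresh <- apply(pack_content, 2, max)
    contrib <- pack_content[best, ]
    relevant <- contrib > 0 & deficit > 0
    room <- ifelse(relevant,
                   ifelse(deficit > thresh,
                          pmax(0, floor((deficit - thresh) / contrib)), 0),
                   Inf)
    k <- min(room, Inf)
    if (!is.finite(k)) k <- 1        # no relevant nutrient: lone final pack
    k <- max(1, k)
    if (!is.null(constraints$budget) && pc$priced) {
      k <- min(k, floor((constraints$budget - spent + 1e-9) / items$cost_per_pack[best]))
    }
    if (!is.null(constraints$volume_cap) && is.finite(unit_vol[best]) && unit_vol[best] > 0) {
      k <- min(k, floor((constraints$volume_cap - vol_used + 1e-9) / unit_vol[best]))
    }
    k <- max(1, k)
    packs[best] <- packs[best] + as.integer(k)
    spent <- spent + k * (if (pc$priced) items$cost_per_pack[best] else 0)
    vol_used <- vol_used + k * (if (is.finite(unit_vol[best])) unit_vol[best] else 0)
    deficit <- pmax(0, deficit - k * contrib)
  }
  finish_greedy(packs, items, pc, supplied, required, pack_content,
                feasible = TRUE, note = NULL)
}

finish_greedy <- function(packs, items, pc, supplied, required, pack_content,
                          feasible, note) {
  chosen <- which(packs > 0)
  sugg <- data.frame(
    food_id = items$id[chosen],
    packs = as.integer(packs[chosen]),
    add_grams = unname(packs[chosen] * items$pack_grams[chosen]),
    cost = if (pc$priced) unname(packs[chosen] * items$cost_per_pack[chosen])
           else rep(NA_real_, length(chosen)),
    stringsAsFactors = FALSE)
  sugg <- sugg[order(sugg$food_id), , drop = FALSE]
  rownames(sugg) <- NULL
  added <- if (length(chosen)) colSums(pack_content[chosen, , drop = FALSE] * packs[chosen])
           else stats::setNames(numeric(length(required)), names(required))
  achieved <- excess_deficiency_ratio(supplied + added, required)
  names(achieved) <- names(required)
  objective <- if (pc$priced) sum(sugg$cost) else sum(sugg$add_grams)
  new_purchase_plan("greedy", sugg, achieved, objective,
                    if (pc$priced) "cost" else "grams", feasible, note)
}

#' Least-cost continuous purchase plan (linear programme)
#'
#' The auditable lower bound on the greedy plan: minimizes total cost (total
#' grams when the catalog is unpriced) over continuous gram amounts, subject
#' to `supplied_n + sum_i x_i * per100g[i, n] / 100 >= required_n` for every
#' profile nutrient, `x >= 0`, and optional budget / storage-volume rows.
#' No fractional-pack rounding is applied — use [greedy_plan()] when whole
#' packs are needed, since silent rounding can break feasibility.
#'
#' @inheritParams greedy_plan
#' @return A `purchase_plan` with continuous `add_grams` per suggestion; on
#'   an infeasible model, an empty plan with `feasible = FALSE` and the
#'   violated constraints named in `note`.
#' @export
lp_plan <- function(report, catalog, constraints = planning_constraints()) {
  stopifnot(inherits(report, "stockpile_assessment"))
  pc <- plan_candidates(report, catalog, constraints)
  items <- pc$catalog$items
  nutrients <- pc$nutrients
  required <- stats::setNames(report$rows$required, nutrients)
  supplied <- stats::setNames(report$rows$supplied, nutrients)
  need <- pmax(required - supplied, 0)
  per_gram <- t(pc$comp) / 100                       # nutrients x items
  cost_per_gram <- if (pc$priced) items$cost_per_pack / items$pack_grams
                   else rep(1, nrow(items))

  deficient <- need > 0
  A_geq <- per_gram[deficient, , drop = FALSE]
  b_geq <- need[deficient]
  A_leq <- NULL; b_leq <- NULL; cap_names <- character()
  if (!is.null(constraints$budget) && pc$priced) {
    A_leq <- rbind(A_leq, cost_per_gram); b_leq <- c(b_leq, constraints$budget)
    cap_names <- c(cap_names, "budget")
  }
  if (!is.null(constraints$volume_cap)) {
    vol_per_gram <- items$volume_per_pack / items$pack_grams
    if (any(!is.finite(vol_per_gram))) {
      planning_error("volume cap requires volume_per_pack for every candidate")
    }
    A_leq <- rbind(A_leq, vol_per_gram); b_leq <- c(b_leq, constraints$volume_cap)
    cap_names <- c(cap_names, "volume")
  }
  sol <- solve_lp(cost_per_gram, A_leq = A_leq, b_leq = b_leq,
                  A_geq = A_geq, b_geq = b_geq)
  if (sol$status != "optimal") {
    unreachable <- names(need)[deficient & apply(per_gram, 1, max) <= 0]
    note <- if (sol$status == "infeasible") {
      sprintf("infeasible: %s", if (length(unreachable))
        paste("no candidate supplies", paste(unreachable, collapse = ", "))
        else paste("binding cap(s):", paste(cap_names, collapse = ", ")))
    } else sol$status
    empty <- data.frame(food_id = character(), packs = integer(),
                        add_grams = numeric(), cost = numeric(),
                        stringsAsFactors = FALSE)
    achieved <- excess_deficiency_ratio(supplied, required)
    names(achieved) <- nutrients
    return(new_purchase_plan("lp", empty, achieved, NA_real_,
                             if (pc$priced) "cost" else "grams",
                             feasible = FALSE, note = note))
  }
  x <- sol$x
  x[x < 1e-9] <- 0
  chosen <- which(x > 0)
  sugg <- data.frame(
    food_id = items$id[chosen],
    packs = rep(NA_integer_, length(chosen)),
    add_grams = unname(x[chosen]),
    cost = if (pc$priced) unname(x[chosen] * cost_per_gram[chosen])
           else rep(NA_real_, length(chosen)),
    stringsAsFactors = FALSE)
  sugg <- sugg[order(sugg$food_id), , drop = FALSE]
  rownames(sugg) <- NULL
  added <- as.vector(per_gram %*% x)
  achieved <- excess_deficiency_ratio(pmax(supplied + added, 0), required)
  names(achieved) <- nutrients
  # the simplex meets constraints to machine precision; call it feasible
  # when every ratio reaches 100 within 1e-9 relative
  feasible <- all(achieved >= 100 * (1 - 1e-9))
  new_purchase_plan("lp", sugg, achieved, sol$value,
                    if (pc$priced) "cost" else "grams", feasible, NULL)
}

#' Verify a purchase plan by independent recomputation
#'
#' Rebuilds the plan's additions as an inventory, recomputes the achieved
#' supply through the assessment module ([total_supply()] and
#' [excess_deficiency_ratio()]), and checks the plan's own `achieved_ratios`
#' against that independent path within 1e-9 relative tolerance. A feasible
#' plan must reach 100% for every profile nutrient.
#'
#' @param plan A `purchase_plan` produced for `report` and `catalog`.
#' @param report The `stockpile_assessment` the plan was built from.
#' @param catalog The `food_catalog` the plan was built from.
#' @return Invisibly, a list with `achieved_ratios` (recomputed) and `ok =
#'   TRUE`. Raises a consistency error on mismatch.
#' @export
verify_plan <- function(plan, report, catalog) {
  stopifnot(inherits(plan, "purchase_plan"),
            inherits(report, "stockpile_assessment"),
            inherits(catalog, "food_catalog"))
  nutrients <- report$rows$nutrient
  add_inv <- inventory(data.frame(food_id = plan$suggestions$food_id,
                                  quantity_grams = plan$suggestions$add_grams,
                                  stringsAsFactors = FALSE))
  added <- suppressWarnings(total_supply(add_inv, catalog, nutrients))
  achieved <- excess_deficiency_ratio(report$rows$supplied + added,
                                      report$rows$required)
  names(achieved) <- nutrients
  rel_ok <- function(a, b) {
    (is.infinite(a) & is.infinite(b)) |
      abs(a - b) <= 1e-9 * pmax(abs(a), abs(b), 1)
  }
  if (!all(rel_ok(achieved, plan$achieved_ratios[nutrients]))) {
    bad <- nutrients[!rel_ok(achieved, plan$achieved_ratios[nutrients])]
    consistency_error(sprintf(
      "plan's achieved ratios disagree with independent recomputation for: %s",
      paste(bad, collapse = ", ")))
  }
  if (plan$feasible && !all(achieved >= 100 * (1 - 1e-9))) {
    consistency_error("plan claims feasibility but a nutrient stays below 100%")
  }
  invisible(list(achieved_ratios = achieved, ok = TRUE))
}
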