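# Small hand-built tables shared across tests. Everything is constructed in
# code; no files are read except through the read_* round trips.

toy_demo <- function(counts = c(male = 50, female = 50), municipality = "Toy City") {
  demographic_table(municipality, data.frame(
    sex = names(counts), age_group = "adult", count = unname(counts),
    stringsAsFactors = FALSE))
}

# one-nutrient DRI over male/female adult strata
toy_dri <- function(male = 2000, female = 1600, id = "energy", unit = "kcal") {
  dri_table(
    data.frame(id = id, name = id, unit = unit, stringsAsFactors = FALSE),
    data.frame(nutrient_id = id, sex = c("male", "female"), age_group = "adult",
               value = c(male, female), stringsAsFactors = FALSE))
}

# shelter-profile DRI, flat values across the two adult strata
shelter_dri <- function(values = c(energy = 2000, protein = 50, vit_b1 = 1.1,
                                   vit_b2 = 1.2, vit_c = 100)) {
  ids <- names(values)
  grid <- expand.grid(nutrient_id = ids, sex = c("male", "female"),
                      stringsAsFactors = FALSE)
  dri_table(
    data.frame(id = ids, name = ids,
               unit = c("kcal", "g", "mg", "mg", "mg")[seq_along(ids)],
               stringsAsFactors = FALSE),
    data.frame(nutrient_id = grid$nutrient_id, sex = grid$sex,
               age_group = "adult", value = unname(values[grid$nutrient_id]),
               stringsAsFactors = FALSE))
}

toy_catalog <- function() {
  items <- data.frame(
    id = c("alpha_rice", "tuna_can", "veg_juice"),
    name = c("Alpha rice", "Canned tuna", "Vegetable juice"),
    category = c("staple", "side", "side"),
    shelf_stable = TRUE, requires_cooking = FALSE, contains_wheat = FALSE,
    pack_grams = c(100, 70, 200),
    cost_per_pack = c(200, 300, 150),
    volume_per_pack = c(0.15, 0.08, 0.2),
    stringsAsFactors = FALSE)
  comp <- rbind(alpha_rice = c(energy = 350, protein = 7,  vit_b1 = 0.05, vit_b2 = 0.02, vit_c = 0),
                tuna_can   = c(energy = 180, protein = 20, vit_b1 = 0.1,  vit_b2 = 0.3,  vit_c = 0),
                veg_juice  = c(energy = 40,  protein = 1,  vit_b1 = 0.05, vit_b2 = 0.05, vit_c = 30))
  food_catalog(items, comp, categories = c("staple", "side"))
}

toy_inventory <- function(...) {
  q <- c(...)
  if (!length(q)) return(inventory())
  inventory(data.frame(food_id = names(q), quantity_grams = unname(q),
                       stringsAsFactors = FALSE))
}

# brute-force LP oracle: enumerates all candidate vertices (intersections of
# n active constraints drawn from the constraint rows and the x >= 0 bounds)
# and returns the best feasible objective. Independent of solve_lp's path.
lp_oracle <- function(objective, A_leq = NULL, b_leq = NULL,
                      A_geq = NULL, b_geq = NULL, A_eq = NULL, b_eq = NULL,
                      tol = 1e-7) {
  n <- length(objective)
  rows <- list(); rhs <- c(); kind <- c()
  add <- function(A, b, k) {
    if (is.null(A)) return()
    A <- matrix(A, ncol = n)
    for (i in seq_len(nrow(A))) {
      rows[[length(rows) + 1L]] <<- A[i, ]; rhs <<- c(rhs, b[i]); kind <<- c(kind, k)
    }
  }
  add(A_leq, b_leq, "leq"); add(A_geq, b_geq, "geq"); add(A_eq, b_eq, "eq")
  for (i in seq_len(n)) { # x_i >= 0 as candidate active constraints
    e <- numeric(n); e[i] <- 1
    rows[[length(rows) + 1L]] <- e; rhs <- c(rhs, 0); kind <- c(kind, "bound")
  }
  M <- do.call(rbind, rows)
  feasible <- function(x) {
    all(vapply(seq_along(rhs), function(i) {
      v <- sum(M[i, ] * x)
      switch(kind[i],
             leq = v <= rhs[i] + tol, geq = v >= rhs[i] - tol,
             eq = abs(v - rhs[i]) <= tol, bound = v >= -tol)
    }, logical(1)))
  }
  best <- Inf; best_x <- NULL
  for (combo in utils::combn(length(rhs), n, simplify = FALSE)) {
    A_act <- M[combo, , drop = FALSE]
    if (abs(det(A_act)) < 1e-12) next
    x <- tryCatch(solve(A_act, rhs[combo]), error = function(e) NULL)
    if (is.null(x) || !feasible(x)) next
    v <- sum(objective * x)
    if (v < best - 1e-12) { best <- v; best_x <- x }
  }
  if (is.null(best_x)) list(status = "infeasible", value = NA_real_)
  else list(status = "optimal", value = best, x = best_x)
}
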