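# Small dense linear-programming solver (two-phase simplex, Bland's rule).
#
# The purchase planner and the exact-cover fixture builder need a reliable
# solver for tiny LPs (tens of variables, at most a dozen or so rows):
#   min c'x  s.t.  A_leq x <= b_leq, A_geq x >= b_geq, A_eq x = b_eq, x >= 0.
# Bland's entering/leaving rule guards against cycling; rows are rescaled to
# unit magnitude so tolerances are meaningful across the very different
# scales of energy (kcal, ~1e6 per scenario) and vitamins (mg).

solve_lp <- function(objective, A_leq = NULL, b_leq = NULL,
                     A_geq = NULL, b_geq = NULL,
                     A_eq = NULL, b_eq = NULL, tol = 1e-9) {
  n <- length(objective)
  block <- function(A, b, dir) {
    if (is.null(A)) return(NULL)
    A <- matrix(as.numeric(A), ncol = n)
    stopifnot(nrow(A) == length(b))
    list(A = A, b = as.numeric(b), dir = rep(dir, nrow(A)))
  }
  blocks <- Filter(Negate(is.null), list(block(A_leq, b_leq, "leq"),
                                         block(A_geq, b_geq, "geq"),
                                         block(A_eq, b_eq, "eq")))
  if (!length(blocks)) {
    return(list(status = "optimal", x = numeric(n), value = 0))
  }
  A <- do.call(rbind, lapply(blocks, `[[`, "A"))
  b <- do.call(c, lapply(blocks, `[[`, "b"))
  dir <- do.call(c, lapply(blocks, `[[`, "dir"))
  m <- nrow(A)

  # normalize to b >= 0
  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
    dir[neg] <- c(leq = "geq", geq = "leq", eq = "eq")[dir[neg]]
  }
  # row scaling for numerical comparability
  scale <- pmax(apply(abs(A), 1, max), abs(b), 1e-12)
  A <- A / scale
  b <- b / scale

  n_slack <- sum(dir == "leq")
  n_surp  <- sum(dir == "geq")
  n_art   <- sum(dir != "leq")
  N <- n + n_slack + n_surp + n_art
  tab <- matrix(0, m, N + 1L)
  tab[, seq_len(n)] <- A
  tab[, N + 1L] <- b
  basis <- integer(m)
  s_i <- n; u_i <- n + n_slack; a_i <- n + n_slack + n_surp
  art_cols <- integer(0)
  for (i in seq_len(m)) {
    if (dir[i] == "leq") {
      s_i <- s_i + 1L; tab[i, s_i] <- 1; basis[i] <- s_i
    } else {
      if (dir[i] == "geq") { u_i <- u_i + 1L; tab[i, u_i] <- -1 }
      a_i <- a_i + 1L; tab[i, a_i] <- 1; basis[i] <- a_i
      art_cols <- c(art_cols, a_i)
    }
  }

  pivot <- function(tab, basis, i, j) {
    tab[i, ] <- tab[i, ] / tab[i, j]
    for (k in seq_len(nrow(tab))) {
      if (k != i && abs(tab[k, j]) > 0) tab[k, ] <- tab[k, ] - tab[k, j] * tab[i, ]
    }
    basis[i] <- j
    list(tab = tab, basis = basis)
  }

  # entering: smallest eligible index (Bland); leaving: lexicographic ratio
  # test among near-ties, which breaks the degenerate cycles a plain
  # tolerance-banded Bland rule can fall into in floating point. `target`
  # lets phase 1 stop as soon as the artificial objective reaches zero.
  # entering: smallest eligible index (Bland); leaving: lexicographic ratio
  # test among near-ties. `target` lets phase 1 stop as soon as the
  # artificial objective reaches zero. Columns beyond `rhs_col` ride along
  # through the pivots untouched by the ratio test (used to carry the
  # unperturbed right-hand side during anti-cycling restarts).
  run <- function(tab, basis, cost, allowed, target = -Inf, max_iter = 5000L,
                  rhs_col = ncol(tab)) {
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) return(list(tab = tab, basis = basis, status = "cycling"))
      if (sum(cost[basis] * tab[, rhs_col]) <= target) {
        return(list(tab = tab, basis = basis, status = "optimal"))
      }
      cb <- cost[basis]
      red <- cost - as.vector(cb %*% tab[, seq_along(cost), drop = FALSE])
      red[!allowed] <- 0
      enter <- which(red < -tol)
      if (!length(enter)) return(list(tab = tab, basis = basis, status = "optimal"))
      j <- min(enter)
      col <- tab[, j]
      pos <- which(col > tol)
      if (!length(pos)) return(list(tab = tab, basis = basis, status = "unbounded"))
      ratio <- tab[pos, rhs_col] / col[pos]
      rmin <- min(ratio)
      cand <- pos[ratio <= rmin + tol * max(1, abs(rmin))]
      if (length(cand) > 1L) {
        # lexicographic comparison of the scaled rows
        rows <- tab[cand, , drop = FALSE] / col[cand]
        best <- 1L
        for (k in seq_along(cand)[-1]) {
          d <- rows[k, ] - rows[best, ]
          nz <- which(abs(d) > 1e-12)
          if (length(nz) && d[nz[1]] < 0) best <- k
        }
        i <- cand[best]
      } else i <- cand
      pv <- pivot(tab, basis, i, j)
      tab <- pv$tab; basis <- pv$basis
    }
  }

  # phase 1: drive artificials to zero
  if (n_art > 0) {
    cost1 <- numeric(N); cost1[art_cols] <- 1
    res <- run(tab, basis, cost1, allowed = rep(TRUE, N), target = 1e-11)
    tab <- res$tab; basis <- res$basis
    p1 <- sum(cost1[basis] * tab[, N + 1L])
    if (p1 > 1e-7) {
      status <- if (res$status == "cycling") "cycling" else "infeasible"
      return(list(status = status, x = rep(NA_real_, n), value = NA_real_))
    }
    # pivot remaining (degenerate) artificials out of the basis where possible
    for (i in which(basis %in% art_cols)) {
      j <- which(abs(tab[i, setdiff(seq_len(N), art_cols)]) > tol)
      cols_ok <- setdiff(seq_len(N), art_cols)
      j <- cols_ok[abs(tab[i, cols_ok]) > tol][1]
      if (!is.na(j)) {
        pv <- pivot(tab, basis, i, j)
        tab <- pv$tab; basis <- pv$basis
      }
    }
  }

  # phase 2 on structural + slack/surplus columns only. A degenerate optimum
  # can make the float Bland rule stall; a stalled run is retried with a
  # tiny deterministic right-hand-side perturbation, which removes the
  # degeneracy (the classic remedy). The unperturbed rhs rides along as an
  # extra column so the returned solution solves the original system.
  cost2 <- numeric(N)
  cost2[seq_len(n)] <- objective
  allowed <- rep(TRUE, N)
  allowed[art_cols] <- FALSE
  for (attempt in 0:3) {
    tab_try <- cbind(tab, orig = tab[, N + 1L])
    if (attempt > 0) {
      tab_try[, N + 1L] <- tab_try[, N + 1L] + 10^(-8 + attempt) * seq_len(m) / m
    }
    res <- run(tab_try, basis, cost2, allowed, rhs_col = N + 1L)
    if (res$status != "cycling") break
  }
  if (res$status %in% c("unbounded", "cycling")) {
    return(list(status = res$status, x = rep(NA_real_, n), value = NA_real_))
  }
  x <- numeric(N)
  x[res$basis] <- res$tab[, N + 2L]
  x <- pmax(x[seq_len(n)], 0)
  list(status = "optimal", x = x, value = sum(objective * x))
}
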