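# Independent LP oracle: brute-force vertex enumeration over the
# polytope {x : A x = 0, lb <= x <= ub}. Every vertex has n - rank(A)
# variables pinned at a bound; enumerate all choices, solve the square
# system for the rest, keep feasible points, and take the best
# objective. Exponential, so only for networks with <= ~10 reactions.
lp_vertex_oracle <- function(obj, A, lb, ub, maximize = TRUE, tol = 1e-8) {
  A <- as.matrix(A)
  n <- ncol(A)
  r <- qr(A)$rank
  k <- n - r
  sets <- if (k == 0) list(integer(0)) else utils::combn(n, k, simplify = FALSE)
  best <- -Inf
  bestx <- NULL
  for (Fset in sets) {
    Bset <- setdiff(seq_len(n), Fset)
    AB <- A[, Bset, drop = FALSE]
    if (qr(AB)$rank < r) next
    combos <- if (k == 0) matrix(1, 1, 0) else
      as.matrix(expand.grid(rep(list(1:2), k)))
    for (ci in seq_len(nrow(combos))) {
      xF <- ifelse(combos[ci, ] == 1, lb[Fset], ub[Fset])
      if (any(!is.finite(xF))) next
      rhs <- if (k == 0) rep(0, nrow(A)) else -A[, Fset, drop = FALSE] %*% xF
      xB <- tryCatch(qr.solve(AB, rhs, tol = 1e-12), error = function(e) NULL)
      if (is.null(xB)) next
      if (max(abs(AB %*% xB - rhs)) > tol) next
      x <- numeric(n)
      x[Fset] <- xF
      x[Bset] <- xB
      if (any(x < lb - tol) || any(x > ub + tol)) next
      val <- sum(obj * x)
      score <- if (maximize) val else -val
      if (score > best) {
        best <- score
        bestx <- x
      }
    }
  }
  if (is.null(bestx)) return(list(feasible = FALSE))
  list(feasible = TRUE,
       objective = if (maximize) best else -best,
       x = bestx)
}

# oracle applied to a metabolic model: optimum of its objective reaction
fba_oracle <- function(model) {
  S <- as.matrix(stoich_matrix(model))
  rx <- model$reactions
  lp_vertex_oracle(as.numeric(rx$id == model$objective$reaction), S,
                   rx$lower_bound, rx$upper_bound,
                   maximize = model$objective$direction == "maximize")
}

# random small metabolic-style LP with finite bounds, for property tests
random_lp <- function(n_mets, n_rxns) {
  A <- matrix(0, n_mets, n_rxns)
  for (j in seq_len(n_rxns)) {
    rows <- sample(n_mets, sample(1:2, 1))
    A[rows, j] <- sample(c(-2, -1, 1, 2), length(rows), replace = TRUE)
  }
  lb <- ifelse(stats::runif(n_rxns) < 0.3, -stats::runif(n_rxns, 0, 2), 0)
  ub <- lb + stats::runif(n_rxns, 0.5, 3)
  obj <- stats::rnorm(n_rxns)
  list(obj = obj, A = A, lb = lb, ub = ub)
}
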