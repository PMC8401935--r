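#' Solve a bounded-variable linear program
#'
#' Maximises (or minimises) `obj %*% x` subject to `A %*% x = b` and
#' `lb <= x <= ub`, using a two-phase primal simplex with bounded variables
#' and Bland's anti-cycling rule. This is the solver primitive behind
#' [fba()] and [fva()]; metabolic LPs are equality-constrained (steady
#' state) with box bounds (flux capacities), which is exactly the form
#' handled here.
#'
#' One-sided infinite bounds are supported. Variables with both bounds
#' infinite are rejected: flux variables always carry at least one finite
#' capacity in this pipeline.
#'
#' @param obj numeric objective coefficients, length n.
#' @param A constraint matrix (m x n), dense or `Matrix` sparse.
#' @param b right-hand side, length m (defaults to zeros: steady state).
#' @param lb,ub variable bounds, length n.
#' @param maximize logical; maximise (default) or minimise.
#' @param tol feasibility tolerance on bounds and residuals.
#' @param max_iter iteration cap; exceeded => error.
#' @return list with `status` ("optimal", "infeasible" or "unbounded"),
#'   `objective` (the optimum, on the original maximise/minimise scale;
#'   `NA` unless optimal) and `x` (the optimal point, `NULL` unless optimal).
#' @export
solve_lp <- function(obj, A, b = NULL, lb, ub, maximize = TRUE,
                     tol = 1e-9, max_iter = 10000L) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  if (is.null(b)) b <- numeric(m)
  stopifnot(length(obj) == n, length(lb) == n, length(ub) == n, length(b) == m)
  if (any(lb > ub + tol)) {
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  }
  if (any(is.infinite(lb) & is.infinite(ub))) {
    stop("variables with two infinite bounds are not supported; supply a finite capacity")
  }
  obj <- as.numeric(obj)
  cmax <- if (maximize) obj else -obj

  ## start all structural variables nonbasic at a finite bound
  start <- ifelse(is.finite(lb), lb, ub)
  resid <- b - as.numeric(A %*% start)

  ## artificial columns: signed identity so artificials start >= 0
  sgn <- ifelse(resid >= 0, 1, -1)
  Afull <- cbind(A, diag(sgn, m))
  art <- seq.int(n + 1L, n + m)

  simplex_phase <- function(cost, basis, nb, at_ub, lbf, ubf, enter_ok) {
    xN <- ifelse(at_ub, ubf[nb], lbf[nb])
    for (it in seq_len(max_iter)) {
      B <- Afull[, basis, drop = FALSE]
      xB <- as.numeric(solve(B, b - Afull[, nb, drop = FALSE] %*% xN))
      y <- as.numeric(solve(t(B), cost[basis]))
      rc <- cost[nb] - as.numeric(crossprod(Afull[, nb, drop = FALSE], y))

      cand <- which(enter_ok[nb] &
                      ((!at_ub & rc > tol) | (at_ub & rc < -tol)) &
                      (ubf[nb] - lbf[nb]) > tol)
      if (!length(cand)) {
        return(list(status = "optimal", basis = basis, nb = nb,
                    at_ub = at_ub, xB = xB, xN = xN,
                    obj = sum(cost[basis] * xB) + sum(cost[nb] * xN)))
      }
      e <- cand[which.min(nb[cand])]              # Bland: smallest variable index
      j <- nb[e]
      d <- as.numeric(solve(B, Afull[, j]))
      dir <- if (at_ub[e]) -1 else 1              # entering moves up from lb / down from ub
      move <- -dir * d                            # change in xB per unit step t >= 0

      ## step limits: entering variable's own span, then each basic variable
      lim <- rep(Inf, m)
      for (i in seq_len(m)) {
        if (move[i] > tol) {
          lim[i] <- (ubf[basis[i]] - xB[i]) / move[i]
        } else if (move[i] < -tol) {
          lim[i] <- (xB[i] - lbf[basis[i]]) / (-move[i])
        }
      }
      lim <- pmax(lim, 0)
      span <- ubf[j] - lbf[j]
      tmax <- min(span, lim)
      if (!is.finite(tmax)) return(list(status = "unbounded"))

      blockers <- which(lim <= tmax + tol)
      if (span <= tmax + tol && !length(blockers)) {
        ## entering variable flips to its opposite bound
        at_ub[e] <- !at_ub[e]
        xN[e] <- if (at_ub[e]) ubf[j] else lbf[j]
      } else {
        r <- blockers[which.min(basis[blockers])] # Bland on leaving variable
        out <- basis[r]
        leave_to_ub <- move[r] > 0
        basis[r] <- j
        nb[e] <- out
        at_ub[e] <- leave_to_ub
        xN[e] <- if (leave_to_ub) ubf[out] else lbf[out]
      }
    }
    stop("simplex iteration limit reached")
  }

  lbf <- c(lb, rep(0, m))
  ubf <- c(ub, rep(Inf, m))
  enter_struct <- c(rep(TRUE, n), rep(FALSE, m))  # artificials never re-enter

  ## phase 1: drive artificials to zero
  c1 <- c(rep(0, n), rep(-1, m))
  p1 <- simplex_phase(c1, basis = art, nb = seq_len(n),
                      at_ub = !is.finite(lb), lbf = lbf, ubf = ubf,
                      enter_ok = enter_struct)
  if (p1$status != "optimal" || p1$obj < -1e-7) {
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  }

  ## phase 2: pin artificials at zero, optimise the real objective
  lbf[art] <- 0
  ubf[art] <- 0
  c2 <- c(cmax, rep(0, m))
  p2 <- simplex_phase(c2, basis = p1$basis, nb = p1$nb, at_ub = p1$at_ub,
                      lbf = lbf, ubf = ubf, enter_ok = enter_struct)
  if (p2$status == "unbounded") {
    return(list(status = "unbounded", objective = NA_real_, x = NULL))
  }

  x <- numeric(n + m)
  x[p2$basis] <- p2$xB
  x[p2$nb] <- p2$xN
  x <- pmin(pmax(x[seq_len(n)], lb), ub)          # clip roundoff at bounds
  val <- sum(cmax * x)
  list(status = "optimal",
       objective = if (maximize) val else -val,
       x = x)
}
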