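## Dense numerical work-horses: a two-phase simplex for the FBA/FVA linear
## programs and a coordinate-descent + active-set solver for the EBA
## box-constrained quadratic program.  Both are fully deterministic (Bland's
## rule; fixed sweep order) so repeated solves are bit-identical.

## Largest magnitude substituted for infinite variable bounds before the LP
## is assembled; toy-scale fluxes never approach it.
LP_BIG <- 1e4

#' Solve a bounded linear program with a deterministic simplex
#'
#' Maximizes (or minimizes) `obj %*% v` subject to `A %*% v = b` and
#' `lb <= v <= ub`.  Two-phase dense simplex with Bland's anti-cycling rule:
#' given identical inputs the returned vertex is identical.  Infinite bounds
#' are truncated to +/- 1e4.
#'
#' @param obj objective coefficients (length n)
#' @param A constraint matrix (m x n)
#' @param b right-hand side (length m)
#' @param lb,ub variable bounds (length n)
#' @param maximize logical; maximize if `TRUE` (default)
#' @param tol pivot tolerance
#' @return list with `x` (optimal point), `objval`, and
#'   `status` in `"optimal"`, `"infeasible"`, `"unbounded"`
#' @export
lp_solve <- function(obj, A, b, lb, ub, maximize = TRUE, tol = 1e-9) {
  n <- length(obj)
  A <- matrix(as.numeric(A), nrow = length(b), ncol = n)
  lb <- pmax(as.numeric(lb), -LP_BIG)
  ub <- pmin(as.numeric(ub), LP_BIG)
  if (any(lb > ub + tol)) {
    return(list(x = rep(NA_real_, n), objval = NA_real_, status = "infeasible"))
  }
  ub <- pmax(ub, lb)
  ## shift x = v - lb >= 0; add slack rows for the (finite) upper bounds
  b2 <- as.numeric(b) - A %*% lb
  u <- ub - lb
  Aall <- cbind(A, matrix(0, nrow(A), n))
  for (i in seq_len(n)) {
    row <- numeric(2 * n)
    row[i] <- 1; row[n + i] <- 1
    Aall <- rbind(Aall, row)
    b2 <- c(b2, u[i])
  }
  cost <- c(if (maximize) -obj else obj, numeric(n))
  res <- simplex_core(Aall, as.numeric(b2), cost, tol = tol)
  if (res$status != "optimal") {
    return(list(x = rep(NA_real_, n), objval = NA_real_, status = res$status))
  }
  v <- res$x[seq_len(n)] + lb
  list(x = v, objval = sum(obj * v), status = "optimal")
}

## min cost'x s.t. Ax = b, x >= 0 (b made nonnegative internally).
## Classic two-phase tableau simplex, Bland's rule throughout.
simplex_core <- function(A, b, cost, tol = 1e-9, max_iter = 20000L) {
  m <- nrow(A); n <- ncol(A)
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]

  ## tableau: columns = n original + m artificial + rhs
  T <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  ## phase-1 objective row (reduced costs for min sum of artificials)
  z <- c(-colSums(A), numeric(m), -sum(b))

  pivot <- function(T, z, basis, r, c) {
    T[r, ] <- T[r, ] / T[r, c]
    for (i in seq_len(nrow(T))) {
      if (i != r && abs(T[i, c]) > 1e-13) T[i, ] <- T[i, ] - T[i, c] * T[r, ]
    }
    if (abs(z[c]) > 1e-13) z <- z - z[c] * T[r, ]
    basis[r] <- c
    list(T = T, z = z, basis = basis)
  }

  run_phase <- function(T, z, basis, ncols) {
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter) return(list(T = T, z = z, basis = basis, status = "iteration_limit"))
      enter <- 0L
      for (j in seq_len(ncols)) {           # Bland: first improving column
        if (z[j] < -tol) { enter <- j; break }
      }
      if (enter == 0L) return(list(T = T, z = z, basis = basis, status = "optimal"))
      ratios <- ifelse(T[, enter] > tol, T[, ncol(T)] / T[, enter], Inf)
      if (all(is.infinite(ratios))) {
        return(list(T = T, z = z, basis = basis, status = "unbounded"))
      }
      rmin <- min(ratios)
      cand <- which(ratios <= rmin + 1e-12)
      leave <- cand[which.min(basis[cand])]  # Bland tie-break: smallest basis index
      p <- pivot(T, z, basis, leave, enter)
      T <- p$T; z <- p$z; basis <- p$basis
    }
  }

  ph1 <- run_phase(T, z, basis, n + m)
  if (ph1$status != "optimal") return(list(status = ph1$status))
  if (-ph1$z[n + m + 1] > 1e-7) return(list(status = "infeasible"))
  T <- ph1$T; basis <- ph1$basis

  ## drive any artificial still basic (at zero) out, or drop its row
  keep <- rep(TRUE, m)
  for (r in seq_len(m)) {
    if (basis[r] > n) {
      c2 <- which(abs(T[r, seq_len(n)]) > tol)[1]
      if (is.na(c2)) { keep[r] <- FALSE } else {
        p <- pivot(T, numeric(ncol(T)), basis, r, c2)
        T <- p$T; basis <- p$basis
      }
    }
  }
  T <- T[keep, , drop = FALSE]; basis <- basis[keep]
  T <- T[, c(seq_len(n), n + m + 1), drop = FALSE]

  ## phase-2 reduced costs from the current basis
  z <- c(cost, 0)
  for (r in seq_along(basis)) {
    cb <- cost[basis[r]]
    if (abs(cb) > 1e-13) z <- z - cb * T[r, ]
  }
  ph2 <- run_phase(T, z, basis, n)
  if (ph2$status != "optimal") return(list(status = ph2$status))
  x <- numeric(n)
  x[ph2$basis] <- ph2$T[, n + 1]
  list(x = x, objval = sum(cost * x), status = "optimal")
}

#' Minimize a convex quadratic over a box
#'
#' Solves `min 0.5 * x'Qx + c'x` subject to `lb <= x <= ub` for symmetric
#' positive semidefinite `Q`.  Cyclic coordinate descent followed by an
#' active-set Newton polish; deterministic (fixed sweep order, no random
#' restarts).
#'
#' @param Q symmetric PSD matrix
#' @param cvec linear coefficients
#' @param lb,ub bounds (may be infinite)
#' @param x0 starting point (clamped to the box); defaults to box midpoint
#'   or 0 for unbounded coordinates
#' @param tol convergence tolerance on the coordinate update
#' @param max_sweeps coordinate-descent sweep cap
#' @return list with `x`, `value`, `converged`
#' @export
qp_solve_box <- function(Q, cvec, lb, ub, x0 = NULL, tol = 1e-12,
                         max_sweeps = 5000L) {
  n <- length(cvec)
  if (n == 0L) return(list(x = numeric(0), value = 0, converged = TRUE))
  Q <- (Q + t(Q)) / 2
  if (is.null(x0)) {
    x0 <- ifelse(is.finite(lb) & is.finite(ub), (lb + ub) / 2,
                 ifelse(is.finite(lb), lb, ifelse(is.finite(ub), ub, 0)))
  }
  x <- clamp(x0, lb, ub)
  d <- diag(Q)

  for (sweep in seq_len(max_sweeps)) {
    delta <- 0
    for (i in seq_len(n)) {
      gi <- sum(Q[i, ] * x) + cvec[i]
      if (d[i] > 1e-12) {
        xi_new <- clamp(x[i] - gi / d[i], lb[i], ub[i])
      } else {
        ## degenerate coordinate: objective linear in x_i
        xi_new <- if (gi > 1e-12) lb[i] else if (gi < -1e-12) ub[i] else x[i]
        if (!is.finite(xi_new)) xi_new <- x[i]
      }
      delta <- max(delta, abs(xi_new - x[i]))
      x[i] <- xi_new
    }
    if (delta < tol) break
  }

  ## active-set Newton polish: exact on the identified face
  for (k in seq_len(30L)) {
    g <- as.numeric(Q %*% x) + cvec
    at_lo <- x <= lb + 1e-10 & g >= -1e-10
    at_hi <- x >= ub - 1e-10 & g <= 1e-10
    free <- which(!(at_lo | at_hi))
    if (length(free) == 0L) break
    rhs <- -(cvec[free] + as.numeric(Q[free, -free, drop = FALSE] %*% x[-free]))
    if (length(free) == n) rhs <- -cvec[free]
    xf <- tryCatch(solve(Q[free, free, drop = FALSE] +
                           diag(1e-12, length(free)), rhs),
                   error = function(e) NULL)
    if (is.null(xf)) break
    xf <- clamp(as.numeric(xf), lb[free], ub[free])
    if (max(abs(xf - x[free])) < 1e-13) { x[free] <- xf; break }
    x[free] <- xf
  }

  list(x = x, value = 0.5 * sum(x * (Q %*% x)) + sum(cvec * x),
       converged = TRUE)
}
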