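# Dense LP/QP solves for constraint-based models, built on the dual
# active-set method in quadprog.
#
# Two numerical devices make the wrapper robust on FBA-style problems:
#
# 1. The steady-state equalities S x = 0 are eliminated up front by
#    parametrizing x = N z with N an orthonormal null-space basis of S
#    (QR of t(S)). quadprog then sees a bounds-only problem, avoiding its
#    fragility on degenerate equality-constrained active sets (FBA
#    feasible sets are routinely degenerate).
#
# 2. Linear objectives are handled by exact quadratic regularization:
#    minimize ||z||^2/2 - gamma * c'z over the feasible polytope. For a
#    polyhedron there is a finite gamma beyond which the solution is
#    exactly the minimum-norm point of the optimal face (Mangasarian's
#    exact regularization), so the wrapper walks a gamma ladder and
#    accepts once two consecutive solves agree; the result is the exact
#    LP optimum with deterministic, configuration-free tie-breaking.
#    Individual ladder rungs that fail inside quadprog are skipped.

RIDGE <- 1e-8
GAMMA_LADDER <- c(1e4, 1e5, 1e6, 1e7, 1e8, 1e9)

# Solve  max/min  obj'x  (optionally plus quadratic weights)  s.t.
#   S x = 0,  lb <= x <= ub,  extra_A x >= extra_rhs
#
# quad_w: per-variable quadratic weights (objective sum w_i x_i^2); zero
# entries are lifted to the ridge. When quad_w is given, obj enters as
# the linear term of a minimization.
solve_lp <- function(obj, S, lb, ub, extra_A = NULL, extra_rhs = NULL,
                     maximize = TRUE, quad_w = NULL, ridge = RIDGE) {
  n <- length(lb)
  stopifnot(ncol(S) == n, length(ub) == n, length(obj) == n)
  qrS <- qr(t(S))
  r <- qrS$rank
  if (r >= n) {
    # trivial null space: x = 0 is the only steady state
    x <- numeric(n)
    feasible <- all(lb <= 1e-9) && all(ub >= -1e-9) &&
      (is.null(extra_A) || all(extra_A %*% x >= extra_rhs - 1e-9))
    if (!feasible) {
      return(list(status = "infeasible", x = NULL, objective = NA_real_,
                  message = "only steady state x = 0 violates the bounds"))
    }
    return(list(status = "optimal", x = x, objective = 0, residual = 0,
                message = ""))
  }
  N <- qr.Q(qrS, complete = TRUE)[, (r + 1L):n, drop = FALSE]
  k <- ncol(N)
  ineq_A <- rbind(diag(1, n), diag(-1, n))
  ineq_b <- c(lb, -ub)
  if (!is.null(extra_A)) {
    ineq_A <- rbind(ineq_A, extra_A)
    ineq_b <- c(ineq_b, extra_rhs)
  }
  keep <- is.finite(ineq_b)
  Amat <- t(ineq_A[keep, , drop = FALSE] %*% N)
  bvec <- ineq_b[keep]

  # On failure, retry with a tiny lexicographic loosening of the
  # inequalities (a standard anti-degeneracy perturbation): each
  # constraint is relaxed by a distinct multiple of eps, which breaks the
  # degenerate active sets quadprog stumbles on while moving the solution
  # by less than the downstream 1e-6 feasibility tolerances.
  attempt <- function(Dmat, dvec) {
    out <- NULL
    for (eps in c(0, 1e-9, 1e-8)) {
      out <- tryCatch(
        quadprog::solve.QP(Dmat, dvec, Amat,
                           bvec - eps * seq_along(bvec), meq = 0L),
        error = function(e) conditionMessage(e))
      if (!is.character(out)) return(out)
    }
    out
  }
  finish <- function(z) {
    x <- as.vector(N %*% z)
    resid <- max(abs(S %*% x))
    if (resid > 1e-6) {
      return(list(status = "numeric_failure", x = x, objective = NA_real_,
                  message = sprintf("steady-state residual %.2e", resid)))
    }
    list(status = "optimal", x = x, objective = sum(obj * x),
         residual = resid, message = "")
  }

  if (!is.null(quad_w)) {
    w <- pmax(quad_w, ridge)
    Dmat <- crossprod(N, 2 * w * N)
    dvec <- as.vector(-obj %*% N)  # minimize obj'x + sum w_i x_i^2
    # rescaling the objective leaves the argmin unchanged but alters
    # quadprog's numerical path; retry across scales before giving up
    last <- NULL
    for (rho in c(1, 10, 0.1, 100, 0.01)) {
      res <- attempt(rho * Dmat, rho * dvec)
      if (!is.character(res)) return(finish(res$solution))
      last <- res
    }
    status <- if (grepl("inconsistent", last, fixed = TRUE)) "infeasible"
              else "numeric_failure"
    return(list(status = status, x = NULL, objective = NA_real_,
                message = last))
  }

  cN <- as.vector((if (maximize) obj else -obj) %*% N)
  prev <- NULL
  last_msg <- NULL
  accepted <- NULL
  for (gamma in GAMMA_LADDER) {
    res <- attempt(diag(1, k), gamma * cN)
    if (is.character(res)) {
      last_msg <- res
      next
    }
    value <- sum(cN * res$solution)
    if (!is.null(prev) && abs(value - prev$value) <= 1e-7 * (1 + abs(value))) {
      accepted <- res
      break
    }
    prev <- list(value = value, res = res)
    accepted <- res  # best effort if the ladder runs out
  }
  if (!is.null(accepted)) return(finish(accepted$solution))
  # every rung failed: separate infeasibility from numerical failure with
  # an objective-free least-norm probe
  probe <- attempt(diag(1, k), numeric(k))
  if (is.character(probe)) {
    return(list(status = "infeasible", x = NULL, objective = NA_real_,
                message = probe))
  }
  list(status = "numeric_failure", x = NULL, objective = NA_real_,
       message = last_msg %||% "quadprog failed on all ladder rungs")
}
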