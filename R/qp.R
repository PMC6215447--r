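#' Box- and equality-constrained diagonal quadratic program
#'
#' Minimizes sum(w * x^2) subject to A x = b and lb <= x <= ub, with w > 0,
#' by a primal active-set method on the box bounds. Phase 1 finds a feasible
#' point by repeatedly clamping bound-violating variables of the
#' equality-constrained minimizer; phase 2 performs standard active-set
#' iterations (ratio-test steps toward the free minimizer, single-variable
#' multiplier releases). The objective is strictly convex, so the solution
#' is unique and the iteration terminates.
#'
#' @param w positive objective weights (length n).
#' @param A m x n equality constraint matrix.
#' @param b length-m right-hand side.
#' @param lb,ub bounds (length n).
#' @param tol feasibility/KKT tolerance.
#' @param max_iter iteration cap.
#' @return list with `x`, `lambda` (equality multipliers), `objective`,
#'   `residual` (||Ax - b||), `iterations`.
#' @export
solve_box_eq_qp <- function(w, A, b, lb, ub, tol = 1e-10, max_iter = NULL) {
  A <- as.matrix(A)
  n <- ncol(A); m <- nrow(A)
  stopifnot(length(w) == n, length(b) == m, length(lb) == n, length(ub) == n,
            all(w > 0), all(lb <= ub))
  if (is.null(max_iter)) max_iter <- 200L * (n + m)
  scale_b <- max(1, max(abs(b)))
  feas_tol <- 1e-9 * max(1, max(abs(ub - lb)))

  eq_solve <- function(clamp) {
    free <- which(clamp == 0L)
    xc <- ifelse(clamp == -1L, lb, ifelse(clamp == 1L, ub, 0))
    rhs_eq <- b - if (any(clamp != 0L))
      as.numeric(A[, clamp != 0L, drop = FALSE] %*% xc[clamp != 0L]) else numeric(m) * 0
    nf <- length(free)
    if (nf == 0L)
      return(list(x = xc, lambda = numeric(m),
                  resid = sqrt(sum((as.numeric(A %*% xc) - b)^2))))
    H <- diag(2 * w[free], nf)
    Af <- A[, free, drop = FALSE]
    K <- rbind(cbind(H, t(Af)), cbind(Af, matrix(0, m, m)))
    rhs <- c(numeric(nf), rhs_eq)
    sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
    if (is.null(sol)) sol <- as.numeric(pinv_svd(K) %*% rhs)
    x <- xc; x[free] <- sol[seq_len(nf)]
    list(x = x, lambda = sol[nf + seq_len(m)],
         resid = sqrt(sum((as.numeric(A %*% x) - b)^2)))
  }

  clamp <- integer(n)
  # phase 1: feasible start. Fast path: clamp violated variables of the
  # equality-constrained minimizer. If that over-clamps (equality becomes
  # unsatisfiable), fall back to alternating projections between the
  # affine set {Ax = b} and the box, which converges to a feasible point
  # whenever one exists.
  x_cur <- NULL
  for (it1 in seq_len(n + 1L)) {
    es <- eq_solve(clamp)
    if (es$resid > 1e-7 * scale_b) break
    viol <- (es$x < lb - feas_tol) | (es$x > ub + feas_tol)
    if (!any(viol)) { x_cur <- es$x; break }
    clamp[viol & es$x < lb] <- -1L
    clamp[viol & es$x > ub] <- 1L
  }
  if (is.null(x_cur)) {
    G <- A %*% t(A)
    Gi <- tryCatch(solve(G), error = function(e) pinv_svd(G))
    proj <- t(A) %*% Gi
    x <- pmin(pmax((lb + ub) / 2, lb), ub)
    resid <- Inf
    for (it in 1:5000) {
      x <- x + as.numeric(proj %*% (b - as.numeric(A %*% x)))
      x <- pmin(pmax(x, lb), ub)
      resid <- sqrt(sum((as.numeric(A %*% x) - b)^2))
      if (resid < 1e-9 * scale_b) break
    }
    if (resid > 1e-6 * scale_b)
      stop("QP infeasible: no bound-feasible point satisfies the equality ",
           "constraints (residual ", signif(resid, 3), ")")
    x_cur <- x
    clamp <- integer(n)
    clamp[x_cur <= lb + feas_tol] <- -1L
    clamp[x_cur >= ub - feas_tol] <- 1L
  }

  lambda <- numeric(m)
  for (it in seq_len(max_iter)) {
    es <- eq_solve(clamp)
    free <- which(clamp == 0L)
    viol <- (es$x < lb - feas_tol) | (es$x > ub + feas_tol)
    if (any(viol[free])) {
      # ratio-test step from the feasible iterate toward the minimizer
      d <- es$x - x_cur
      alpha <- 1; blocker <- 0L; block_side <- 0L
      for (j in free) {
        if (d[j] > feas_tol) {
          a_j <- (ub[j] - x_cur[j]) / d[j]
          if (a_j < alpha) { alpha <- a_j; blocker <- j; block_side <- 1L }
        } else if (d[j] < -feas_tol) {
          a_j <- (lb[j] - x_cur[j]) / d[j]
          if (a_j < alpha) { alpha <- a_j; blocker <- j; block_side <- -1L }
        }
      }
      x_cur <- x_cur + max(0, alpha) * d
      if (blocker > 0L) {
        clamp[blocker] <- block_side
        x_cur[blocker] <- if (block_side == 1L) ub[blocker] else lb[blocker]
      }
      next
    }
    x_cur <- es$x; lambda <- es$lambda
    # multiplier (reduced-gradient) check on clamped variables
    g <- 2 * w * x_cur + as.numeric(t(A) %*% lambda)
    rel_lo <- which(clamp == -1L & g < -tol * max(1, max(abs(g))))
    rel_hi <- which(clamp == 1L & g > tol * max(1, max(abs(g))))
    cand <- c(rel_lo, rel_hi)
    if (length(cand) == 0L) {
      return(list(x = x_cur, lambda = lambda, objective = sum(w * x_cur^2),
                  residual = sqrt(sum((as.numeric(A %*% x_cur) - b)^2)),
                  iterations = it))
    }
    j <- cand[which.max(abs(g[cand]))]
    clamp[j] <- 0L
  }
  stop("QP active-set iteration cap reached without convergence")
}

# Moore-Penrose pseudoinverse via SVD (kept internal; avoids extra deps)
pinv_svd <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > max(tol * s$d[1], 0)
  if (!any(pos)) return(matrix(0, ncol(X), nrow(X)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}
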