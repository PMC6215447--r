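# Shared fixtures, built once per test run. The default synthetic limb is
# expensive enough (meshing + stiffness factorization) that tests share a
# single instance through these memoized getters.

.fixtures <- new.env(parent = emptyenv())

test_model <- function() {
  if (is.null(.fixtures$model))
    .fixtures$model <- generate_synthetic_limb(default_limb_params(), seed = 1L)
  .fixtures$model
}

# an admissible mid-stance posture on the shared model
test_posture <- function() {
  if (is.null(.fixtures$posture))
    .fixtures$posture <- repair_posture(test_model(), posture(), search_config())
  .fixtures$posture
}

# statics solution bundle at the shared posture
test_statics <- function() {
  if (is.null(.fixtures$statics)) {
    m <- test_model()
    p <- test_posture()
    posed <- pose_limb(m, p, check = FALSE)
    loads <- build_external_loads(posed, m)
    sol <- solve_static_optimization(m, posed, loads)
    jl <- joint_reactions(m, posed, sol, loads)
    .fixtures$statics <- list(posed = posed, loads = loads, sol = sol, jl = jl)
  }
  .fixtures$statics
}

# small steel bar mesh shared by FE tests
test_bar <- function(h = 0.0025, L = 0.1, a = 0.01) {
  key <- paste0("bar_", h, "_", L, "_", a)
  if (is.null(.fixtures[[key]])) {
    vm <- lattice_tet_mesh(function(p)
      as.integer(p[, 1] >= 0 & p[, 1] <= a & p[, 2] >= 0 & p[, 2] <= a &
                 p[, 3] >= 0 & p[, 3] <= L),
      c(0, 0, 0), c(a, a, L), h)
    .fixtures[[key]] <- vm
  }
  .fixtures[[key]]
}

steel <- function() list(steel = material(7800, 200e9, 0.3))

# independent dense assembly oracle: per-element B' D B V with explicit
# 6 x 12 B matrices, accumulated into a dense matrix
dense_stiffness_oracle <- function(vm, E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  n <- nrow(vm$nodes)
  K <- matrix(0, 3 * n, 3 * n)
  for (e in seq_len(nrow(vm$tets))) {
    id <- vm$tets[e, ]
    x <- vm$nodes[id, ]
    J <- rbind(x[2, ] - x[1, ], x[3, ] - x[1, ], x[4, ] - x[1, ])
    V <- det(J) / 6
    G <- solve(J)             # columns: grad of N2..N4
    grads <- cbind(-rowSums(G), G)  # 3 x 4, grad of N1..N4
    B <- matrix(0, 6, 12)
    for (k in 1:4) {
      g <- grads[, k]
      c0 <- 3 * (k - 1)
      B[1, c0 + 1] <- g[1]; B[2, c0 + 2] <- g[2]; B[3, c0 + 3] <- g[3]
      B[4, c0 + 1] <- g[2]; B[4, c0 + 2] <- g[1]
      B[5, c0 + 2] <- g[3]; B[5, c0 + 3] <- g[2]
      B[6, c0 + 1] <- g[3]; B[6, c0 + 3] <- g[1]
    }
    Ke <- V * t(B) %*% D %*% B
    dofs <- as.vector(rbind(3 * (id - 1) + 1, 3 * (id - 1) + 2, 3 * (id - 1) + 3))
    K[dofs, dofs] <- K[dofs, dofs] + Ke
  }
  K
}
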