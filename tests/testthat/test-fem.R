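test_that("assembled stiffness matches a dense per-element oracle", {
  vm <- lattice_tet_mesh(function(p)
    as.integer(p[, 1] <= 0.01 & p[, 2] <= 0.01 & p[, 3] <= 0.015),
    c(0, 0, 0), c(0.01, 0.01, 0.015), 0.005)
  asm <- assemble_stiffness(vm, steel(), "steel")
  K_oracle <- dense_stiffness_oracle(vm, 200e9, 0.3)
  expect_equal(as.matrix(asm$K), K_oracle, tolerance = 1e-10,
               ignore_attr = TRUE)
  # symmetric, and translations are zero-energy modes before restraints
  expect_equal(as.matrix(asm$K), t(as.matrix(asm$K)), tolerance = 1e-8,
               ignore_attr = TRUE)
  n <- nrow(vm$nodes)
  for (d in 1:3) {
    u <- numeric(3 * n); u[seq(d, 3 * n, 3)] <- 1
    expect_lt(max(abs(asm$K %*% u)), 1e-4 * max(abs(asm$K)))
  }
  # exactly 6 rigid-body zero-energy modes
  ev <- eigen(K_oracle, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(ev < 1e-6 * max(ev)), 6)
})

test_that("patch test: affine displacement gives exact constant stress", {
  vm <- test_bar(h = 0.005, L = 0.02, a = 0.01)
  asm <- assemble_stiffness(vm, steel(), "steel")
  G <- matrix(c(1e-4, 2e-5, -1e-5,
                3e-5, -4e-5, 5e-5,
                -2e-5, 1e-5, 6e-5), 3, 3, byrow = TRUE)
  u <- t(G %*% t(vm$nodes))
  uv <- as.vector(t(u))
  sig <- matrix(as.numeric(asm$S %*% uv), ncol = 6, byrow = TRUE)
  # oracle: isotropic Hooke's law on the symmetric strain of G
  eps <- (G + t(G)) / 2
  E <- 200e9; nu <- 0.3
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu)); mu <- E / (2 * (1 + nu))
  tr <- sum(diag(eps))
  expected <- c(lam * tr + 2 * mu * eps[1, 1],
                lam * tr + 2 * mu * eps[2, 2],
                lam * tr + 2 * mu * eps[3, 3],
                2 * mu * eps[1, 2], 2 * mu * eps[2, 3], 2 * mu * eps[1, 3])
  for (cc in 1:6)
    expect_equal(sig[, cc], rep(expected[cc], nrow(sig)), tolerance = 1e-9)
  # internal force residual vanishes at interior nodes
  f <- as.numeric(asm$K %*% uv)
  interior <- which(vm$nodes[, 1] > 0 & vm$nodes[, 1] < 0.01 &
                    vm$nodes[, 2] > 0 & vm$nodes[, 2] < 0.01 &
                    vm$nodes[, 3] > 0 & vm$nodes[, 3] < 0.02)
  dofs <- as.vector(rbind(3 * (interior - 1) + 1, 3 * (interior - 1) + 2,
                          3 * (interior - 1) + 3))
  expect_lt(max(abs(f[dofs])), 1e-6 * max(abs(f)))
  # rigid-body translation produces zero stress
  urig <- rep(c(1e-3, -2e-3, 5e-4), nrow(vm$nodes))
  expect_lt(max(abs(asm$S %*% urig)), 1e-8 * max(abs(asm$S)))
})

test_that("uniaxial bar stress matches F/A within 1 percent", {
  vm <- test_bar()
  bottom <- which(abs(vm$nodes[, 3]) < 1e-12)
  top <- which(abs(vm$nodes[, 3] - 0.1) < 1e-9)
  ctx <- fe_context(vm, steel(), "steel", bottom)
  Fz <- -100
  loads <- data.frame(node = top, fx = 0, fy = 0, fz = Fz / length(top))
  sf <- solve_linear_static(ctx, loads, use_inertia_relief = FALSE)
  interior <- which(vm$nodes[, 3] > 0.03 & vm$nodes[, 3] < 0.07)
  szz <- mean(sf$nodal_stress[interior, 3])
  expect_lt(abs(szz - Fz / 1e-4) / abs(Fz / 1e-4), 0.01)
  # restrained reactions balance the applied loads exactly
  rz <- sum(sf$reactions[seq(3, length(sf$reactions), 3)])
  expect_equal(rz, -Fz, tolerance = 1e-8)
  # linearity: scaling loads scales every stress component
  sf2 <- solve_linear_static(ctx, transform(loads, fz = 3 * fz),
                             use_inertia_relief = FALSE)
  expect_equal(sf2$element_stress, 3 * sf$element_stress, tolerance = 1e-10)
})

test_that("point-force spreading conserves the force vector", {
  vm <- test_bar()
  surf <- entity_surface_nodes(vm)
  top <- which(abs(vm$nodes[, 3] - 0.1) < 1e-9)
  ld <- distribute_point_force(vm, c(0, 0, -10), top[1], surf, 20)
  expect_equal(nrow(ld), 20)
  expect_equal(unique(ld$fz), -0.5)
  expect_equal(c(sum(ld$fx), sum(ld$fy), sum(ld$fz)), c(0, 0, -10),
               tolerance = 1e-12)
  expect_warning(distribute_point_force(vm, c(1, 0, 0), top[1], surf[1:5], 20),
                 "fewer surface nodes")
})

test_that("remote force is statically equivalent through the remote point", {
  vm <- test_bar()
  scoped <- which(vm$nodes[, 3] > 0.09)
  remote <- c(0.02, -0.01, 0.12)   # offset from the scoped centroid
  Fv <- c(3, -2, 7)
  ld <- apply_remote_force(vm, remote, Fv, scoped)
  res <- fabpose:::load_resultant(vm, ld, about = remote)
  expect_equal(res$force, Fv, tolerance = 1e-10)
  expect_equal(res$moment, c(0, 0, 0), tolerance = 1e-10)
  # oracle: pseudo-inverse minimum-norm distribution
  skip_if_not_installed("pracma")
  pts <- vm$nodes[scoped, , drop = FALSE]
  k <- nrow(pts)
  A <- matrix(0, 6, 3 * k)
  for (i in seq_len(k)) {
    c0 <- 3 * (i - 1)
    A[1:3, c0 + 1:3] <- diag(3)
    r <- pts[i, ] - remote
    A[4:6, c0 + 1:3] <- matrix(c(0, -r[3], r[2], r[3], 0, -r[1],
                                 -r[2], r[1], 0), 3, 3, byrow = TRUE)
  }
  f_oracle <- as.numeric(pracma::pinv(A) %*% c(Fv, 0, 0, 0))
  expect_equal(as.vector(t(as.matrix(ld[, c("fx", "fy", "fz")]))), f_oracle,
               tolerance = 1e-8)
  expect_error(apply_remote_force(vm, remote, Fv, integer(0)),
               "empty node scope")
})

test_that("surface moment applies a pure couple", {
  vm <- test_bar()
  scoped <- which(vm$nodes[, 3] > 0.09)
  Mv <- c(0.5, -0.2, 0.9)
  ld <- apply_surface_moment(vm, Mv, scoped)
  res <- fabpose:::load_resultant(vm, ld,
                                  about = colMeans(vm$nodes[scoped, ]))
  expect_equal(res$force, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(res$moment, Mv, tolerance = 1e-10)
})

test_that("inertia relief cancels net force and moment of any load set", {
  vm <- test_bar()
  asm <- assemble_stiffness(vm, steel(), "steel")
  # already-balanced set: equal and opposite forces at the same point
  bal <- data.frame(node = c(1L, 1L), fx = c(1, -1), fy = 0, fz = 0)
  corr0 <- inertia_relief(vm, asm$nodal_mass, bal)
  expect_lt(max(abs(corr0[, c("fx", "fy", "fz")])), 1e-12)
  # single unbalanced force: correction totals -F, distributed by mass
  one <- data.frame(node = 5L, fx = 0, fy = 0, fz = -10)
  corr1 <- inertia_relief(vm, asm$nodal_mass, one)
  expect_equal(c(sum(corr1$fx), sum(corr1$fy), sum(corr1$fz)), c(0, 0, 10),
               tolerance = 1e-10)
  # random load sets: residuals below 1e-9 relative (summation oracle)
  set.seed(99)
  for (trial in 1:5) {
    nl <- 15
    ld <- data.frame(node = sample(nrow(vm$nodes), nl),
                     fx = rnorm(nl), fy = rnorm(nl), fz = rnorm(nl))
    corr <- inertia_relief(vm, asm$nodal_mass, ld)
    tot <- rbind(ld, corr)
    res <- fabpose:::load_resultant(vm, tot)
    scale <- max(abs(as.matrix(ld[, 2:4])))
    expect_lt(max(abs(res$force)), 1e-9 * scale)
    expect_lt(max(abs(res$moment)), 1e-9 * scale)
  }
})

test_that("inverted elements are rejected at assembly", {
  vm <- test_bar(h = 0.005, L = 0.02, a = 0.01)
  bad <- vm
  bad$nodes[1, ] <- bad$nodes[1, ] + c(0.1, 0.1, 0.1)  # invert adjacent tets
  bad$volumes <- tet_volumes(bad$nodes, bad$tets)
  expect_error(assemble_stiffness(bad, steel(), "steel"), "inverted")
})
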