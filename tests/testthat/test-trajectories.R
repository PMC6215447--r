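test_that("principal stresses sort, orient and flag degeneracy", {
  # hydrostatic: all equal, degenerate
  ps <- principal_stresses(diag(c(-5, -5, -5)))
  expect_equal(ps$values, c(-5, -5, -5))
  expect_true(ps$degenerate)
  # uniaxial compression along z
  ps2 <- principal_stresses(c(0, 0, -10, 0, 0, 0))
  expect_equal(ps2$values[3], -10)
  expect_equal(abs(ps2$vectors[3, 3]), 1)
  expect_equal(ps2$values[1], 0)
  expect_error(principal_stresses(matrix(c(1, 5, 0, 0, 1, 0, 0, 0, 1), 3, 3)),
               "not symmetric")
})

test_that("eigenvalues match a characteristic-polynomial root oracle", {
  set.seed(7)
  for (i in 1:1000) {
    v <- rnorm(6)
    Tm <- fabpose:::voigt_to_tensor(v)
    ps <- principal_stresses(Tm)
    # oracle: roots of det(T - x I) via polyroot on the cubic
    I1 <- sum(diag(Tm))
    I2 <- (I1^2 - sum(Tm * Tm)) / 2
    I3 <- det(Tm)
    roots <- sort(Re(polyroot(c(-I3, I2, -I1, 1))), decreasing = TRUE)
    scale <- max(abs(roots), 1e-12)
    expect_lt(max(abs(ps$values - roots)) / scale, 1e-9)
    # eigen residual and orthogonality
    for (k in 1:3) {
      r <- Tm %*% ps$vectors[, k] - ps$values[k] * ps$vectors[, k]
      expect_lt(max(abs(r)), 1e-8 * max(abs(Tm)))
    }
    expect_equal(t(ps$vectors) %*% ps$vectors, diag(3), tolerance = 1e-8)
  }
})

test_that("regional mean directions are axial (sign-free)", {
  v <- unit3(c(1, 2, 3))
  pts <- matrix(rnorm(60), 20, 3) * 0.001
  reg <- region_spec(c(0, 0, 0), 1, "all")
  same <- fabric_field(pts, matrix(v, 20, 3, byrow = TRUE))
  expect_equal(abs(sum(regional_mean_direction(same, reg) * v)), 1,
               tolerance = 1e-12)
  # half the samples flipped: identical axial mean
  flip <- rbind(matrix(v, 10, 3, byrow = TRUE),
                matrix(-v, 10, 3, byrow = TRUE))
  mixed <- fabric_field(pts, flip)
  expect_equal(abs(sum(regional_mean_direction(mixed, reg) * v)), 1,
               tolerance = 1e-12)
  # dispersed samples: mean within 2 degrees of the true axis
  set.seed(11)
  axes <- matrix(v, 500, 3, byrow = TRUE)
  noisy <- fabpose:::perturb_axes(axes, 8, seed = 11)
  disp <- fabric_field(matrix(rnorm(1500), 500, 3) * 0.001, noisy)
  mu <- regional_mean_direction(disp, reg)
  expect_lt(angular_deviation(mu, v), 2)
  # error paths
  far <- region_spec(c(10, 10, 10), 0.1, "far")
  expect_error(regional_mean_direction(same, far), "empty region")
})

test_that("angular deviation is the axial arccos in [0, 90]", {
  a <- unit3(c(1, 0, 0))
  expect_equal(angular_deviation(a, a), 0)
  expect_equal(angular_deviation(a, -a), 0)
  expect_equal(angular_deviation(a, unit3(c(1, 1, 0))), 45, tolerance = 1e-10)
  expect_equal(angular_deviation(a, c(0, 1, 0)), 90)
  expect_warning(angular_deviation(c(2, 0, 0), c(0, 1, 0)), "non-unit")
})

test_that("alignment score is zero for matching fields and order-invariant", {
  set.seed(3)
  n <- 200
  pts <- matrix(runif(3 * n, -0.01, 0.01), n, 3)
  stress <- t(vapply(seq_len(n), function(i) {
    # random triaxial state with well-separated eigenvalues
    A <- matrix(rnorm(9), 3, 3)
    Q <- qr.Q(qr(A))
    Tm <- Q %*% diag(c(3e5, 1e5, -5e5)) %*% t(Q)
    c(Tm[1, 1], Tm[2, 2], Tm[3, 3], Tm[1, 2], Tm[2, 3], Tm[1, 3])
  }, numeric(6)))
  pf <- principal_field(pts, stress)
  fab <- fabric_field(pts, pf$v3, valid = !pf$degenerate)
  regions <- list(region_spec(c(0, 0, 0), 0.006, "a"),
                  region_spec(c(0.005, 0.005, 0), 0.006, "b"))
  sc <- alignment_score(pf, fab, regions)
  expect_lt(sc$score, 1e-5)
  expect_lt(max(sc$regions$deviation_deg), 1e-5)
  # permuting the regions leaves the (weight-matched) scalar unchanged
  sc2 <- alignment_score(pf, fab, rev(regions), weights = c(1, 1))
  sc1 <- alignment_score(pf, fab, regions, weights = c(1, 1))
  expect_equal(sc1$score, sc2$score, tolerance = 1e-10)
  # score >= 0 and positive when the fabric is rotated away
  rotfab <- fabric_field(pts, t(rot_x(20) %*% t(pf$v3)))
  sc3 <- alignment_score(pf, rotfab, regions)
  expect_gt(sc3$score, 0)
  # a region outside the support is reported, scalar from the rest
  regions_bad <- c(regions, list(region_spec(c(1, 1, 1), 0.001, "off")))
  expect_warning(sc4 <- alignment_score(pf, fab, regions_bad), "skipped")
  expect_lt(sc4$score, 1e-5)
  expect_true(any(grepl("off", sc4$errors)))
})

test_that("frame invariance: co-rotating stress and fabric preserves angles", {
  set.seed(5)
  n <- 100
  pts <- matrix(runif(3 * n, -0.01, 0.01), n, 3)
  stress <- t(vapply(seq_len(n), function(i) {
    A <- matrix(rnorm(9), 3, 3); Tm <- (A + t(A)) / 2
    c(Tm[1, 1], Tm[2, 2], Tm[3, 3], Tm[1, 2], Tm[2, 3], Tm[1, 3])
  }, numeric(6)))
  pf <- principal_field(pts, stress)
  fabv <- fabpose:::perturb_axes(pf$v3, 10, seed = 2)
  fab <- fabric_field(pts, fabv, valid = !pf$degenerate)
  reg <- region_spec(c(0, 0, 0), 0.02, "all")
  sc_before <- alignment_score(pf, fab, list(reg))
  R <- rot_z(33) %*% rot_x(-21)
  stress_rot <- t(vapply(seq_len(n), function(i) {
    Tm <- R %*% fabpose:::voigt_to_tensor(stress[i, ]) %*% t(R)
    c(Tm[1, 1], Tm[2, 2], Tm[3, 3], Tm[1, 2], Tm[2, 3], Tm[1, 3])
  }, numeric(6)))
  pf_rot <- principal_field(t(R %*% t(pts)), stress_rot)
  fab_rot <- fabric_field(t(R %*% t(pts)), t(R %*% t(fabv)),
                          valid = !pf$degenerate)
  reg_rot <- region_spec(c(0, 0, 0), 0.02, "all")
  sc_after <- alignment_score(pf_rot, fab_rot, list(reg_rot))
  expect_equal(sc_before$score, sc_after$score, tolerance = 1e-6)
})

test_that("grid downsampling equals per-cell orientation-tensor means", {
  set.seed(9)
  n <- 300
  pts <- matrix(runif(3 * n, 0, 0.03), n, 3)
  vecs <- t(vapply(seq_len(n), function(i) unit3(rnorm(3)), numeric(3)))
  ds <- downsample_field(pts, vecs, 0.01)
  # uniform field stays uniform
  uni <- downsample_field(pts, matrix(c(1, 0, 0), n, 3, byrow = TRUE), 0.01)
  expect_true(all(abs(unname(uni$vectors[, 1])) > 1 - 1e-12))
  # per-cell oracle
  lo <- apply(pts, 2, min)
  idx <- floor(sweep(pts, 2, lo) / 0.01)
  key <- paste(idx[, 1], idx[, 2], idx[, 3])
  for (k in unique(key)[1:5]) {
    g <- which(key == k)
    M <- crossprod(vecs[g, , drop = FALSE]) / length(g)
    vk <- eigen(M, symmetric = TRUE)$vectors[, 1]
    row <- which.min(colSums((t(ds$points) -
                              colMeans(pts[g, , drop = FALSE]))^2))
    expect_lt(angular_deviation(ds$vectors[row, ], vk), 1e-6)
  }
  expect_warning(downsample_field(pts, vecs, 10), NA)
})

test_that("mid-shaft summary identifies axial, torsional and bending regimes", {
  vm <- test_bar(h = 0.0025, L = 0.1, a = 0.02)
  bottom <- which(abs(vm$nodes[, 3]) < 1e-12)
  top <- which(abs(vm$nodes[, 3] - 0.1) < 1e-9)
  ctx <- fe_context(vm, steel(), "steel", bottom)
  mid <- which(vm$nodes[, 3] > 0.04 & vm$nodes[, 3] < 0.06)
  # pure axial compression: obliquity ~ 0, no torsion
  lda <- data.frame(node = top, fx = 0, fy = 0, fz = -100 / length(top))
  sfa <- solve_linear_static(ctx, lda, use_inertia_relief = FALSE)
  pfa <- principal_field(vm$nodes[mid, ], sfa$nodal_stress[mid, ])
  msa <- midshaft_loading_summary(pfa, 0.05, 0.01)
  expect_lt(msa$obliquity_deg, 5)
  # pure torsion: +/-45 degree helices, sense matching the applied twist
  ldt <- apply_surface_moment(vm, c(0, 0, 2), top, about = c(0.01, 0.01, 0.1))
  sft <- solve_linear_static(ctx, ldt, use_inertia_relief = FALSE)
  pft <- principal_field(vm$nodes[mid, ], sft$nodal_stress[mid, ])
  mst <- midshaft_loading_summary(pft, 0.05, 0.01)
  expect_equal(mst$obliquity_deg, 45, tolerance = 2)
  expect_equal(mst$torsion_sense, 1)
  ldt2 <- apply_surface_moment(vm, c(0, 0, -2), top, about = c(0.01, 0.01, 0.1))
  sft2 <- solve_linear_static(ctx, ldt2, use_inertia_relief = FALSE)
  pft2 <- principal_field(vm$nodes[mid, ], sft2$nodal_stress[mid, ])
  expect_equal(midshaft_loading_summary(pft2, 0.05, 0.01)$torsion_sense, -1)
  # bending about the y axis: neutral surface along the mediolateral axis
  ldb <- data.frame(node = top, fx = 50 / length(top), fy = 0, fz = 0)
  sfb <- solve_linear_static(ctx, ldb, use_inertia_relief = FALSE)
  pfb <- principal_field(vm$nodes[mid, ], sfb$nodal_stress[mid, ])
  msb <- midshaft_loading_summary(pfb, 0.05, 0.01)
  expect_lt(msb$neutral_angle_deg, 5)
  expect_error(midshaft_loading_summary(pfb, 10), "empty")
})
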