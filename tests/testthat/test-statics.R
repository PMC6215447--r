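test_that("external loads build a vertical 1-BW GRF and equilibrating couple", {
  m <- test_model()
  posed <- pose_limb(m, test_posture(), check = FALSE)
  loads <- build_external_loads(posed, m)
  expect_equal(loads$grf, c(0, 0, m$bw))
  expect_equal(norm3(loads$grf), 15.30360, tolerance = 1e-8)
  # mediolateral moment magnitude: BW times the COP-COM y offset
  fake <- posed
  fake$cop[2] <- fake$com[2] + 0.020
  l2 <- build_external_loads(fake, m)
  expect_equal(abs(l2$m_x), 1.56 * 9.81 * 0.020, tolerance = 1e-10)
  expect_equal(abs(l2$m_x), 0.30607, tolerance = 1e-4)
  fake$cop[2] <- fake$com[2]
  expect_equal(build_external_loads(fake, m)$m_x, 0)
  # global static equilibrium of GRF + couple + segment weights
  Fnet <- loads$grf + c(0, 0, -m$body_mass * m$gravity)
  expect_equal(Fnet, c(0, 0, 0), tolerance = 1e-12)
  Mnet <- cross3(loads$cop, loads$grf) + loads$couple +
    cross3(posed$com, c(0, 0, -m$body_mass * m$gravity))
  expect_equal(Mnet, c(0, 0, 0), tolerance = 1e-12)
})

test_that("tendon-excursion moment arms match an analytic oracle", {
  m <- test_model()
  # two-point path crossing only the knee: origin on thigh, insertion on
  # shank; closed-form dL/dtheta from the rotating-frame geometry
  A <- c(0.011, -0.007, -0.060)        # thigh frame
  B <- c(0.009, -0.002, -0.020)        # shank frame
  act <- list(name = "probe", kind = "muscle", active = TRUE, f_max = 1,
              path = list(list(segment = "thigh", p = A),
                          list(segment = "shank", p = B)))
  ck <- m$joints$knee$centre_parent
  closed_form <- function(theta_deg) {
    th <- theta_deg * pi / 180
    Ry <- rot_y(theta_deg)
    dRy <- matrix(c(-sin(th), 0, cos(th), 0, 0, 0,
                    -cos(th), 0, -sin(th)), 3, 3, byrow = TRUE)
    d <- A - (ck + as.numeric(Ry %*% B))
    L <- sqrt(sum(d^2))
    dL_dth <- -sum(d * as.numeric(dRy %*% B)) / L
    -dL_dth
  }
  for (theta in c(40, 93, 120)) {
    p <- posture(-30, 0, 0, theta, 46, 16, ranges = list())
    r <- moment_arm(act, m, p, "knee_flexion")
    expect_equal(r, closed_form(theta), tolerance = 1e-6 * max(1, abs(r)))
    # and zero about every joint the path does not cross
    for (dof in c("ankle_flexion", "mtp_angle"))
      expect_equal(moment_arm(act, m, p, dof), 0, tolerance = 1e-12)
  }
})

test_that("straight path tangent to a circle about the hinge has arm = d", {
  m <- test_model()
  ck <- m$joints$knee$centre_parent
  d <- 0.012
  # a path parallel to the femur long axis at horizontal offset d from the
  # knee axis: at knee angle 0 the crossing segment is tangent to the
  # circle of radius d about the axis
  act <- list(name = "probe", kind = "muscle", active = TRUE, f_max = 1,
              path = list(list(segment = "thigh", p = ck + c(d, 0, 0.03)),
                          list(segment = "shank", p = c(d, 0, -0.03))))
  p <- posture(-30, 0, 0, 0, 0, 0, ranges = list())
  r <- moment_arm(act, m, p, "knee_flexion")
  expect_equal(abs(r), d, tolerance = 1e-6)
})

test_that("actuator force directions are unit tangents pointing into tension", {
  m <- test_model()
  posed <- pose_limb(m, test_posture(), check = FALSE)
  # straight vertical path
  act <- list(name = "v", kind = "muscle", active = TRUE, f_max = 1,
              path = list(list(segment = "pelvis", p = c(0, 0, 0.02)),
                          list(segment = "pelvis", p = c(0, 0, -0.04))))
  fd <- actuator_force_directions(act, posed)
  expect_equal(fd$directions[1, ], c(0, 0, -1))
  expect_equal(fd$directions[2, ], c(0, 0, 1))
  # right-angle via point: endpoint directions orthogonal
  act2 <- list(name = "L", kind = "muscle", active = TRUE, f_max = 1,
               path = list(list(segment = "pelvis", p = c(0, 0, 0.02)),
                           list(segment = "pelvis", p = c(0, 0, 0)),
                           list(segment = "pelvis", p = c(0.02, 0, 0))))
  fd2 <- actuator_force_directions(act2, posed)
  expect_equal(sum(fd2$directions[1, ] * fd2$directions[3, ]), 0,
               tolerance = 1e-12)
  # net cable force on the system is zero and end tangents are unit
  expect_equal(colSums(fd2$directions), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(norm3(fd2$directions[1, ]), 1)
  # real actuator paths: all endpoint tangents unit length
  for (nm in c("GM", "FCLP", "ILPO")) {
    fd3 <- actuator_force_directions(m$actuators[[nm]], posed)
    k <- nrow(fd3$points)
    expect_equal(norm3(fd3$directions[1, ]), 1, tolerance = 1e-12)
    expect_equal(norm3(fd3$directions[k, ]), 1, tolerance = 1e-12)
    expect_equal(colSums(fd3$directions), c(0, 0, 0), tolerance = 1e-12)
  }
})

test_that("static optimization balances every free DOF within tolerance", {
  st <- test_statics()
  expect_true(all(abs(st$sol$residuals) < 1e-6))
  expect_true(all(st$sol$activations >= -1e-12 & st$sol$activations <= 1 + 1e-12))
  expect_lt(abs(st$sol$mtp_reserve), 1000)
  # inactive actuators are excluded entirely
  expect_false("IC" %in% names(st$sol$activations))
  expect_true("KMCL" %in% names(st$sol$activations))
})

test_that("solution is invariant to actuator ordering", {
  m <- test_model()
  st <- test_statics()
  m2 <- m
  m2$actuators <- rev(m$actuators)
  sol2 <- solve_static_optimization(m2, st$posed, st$loads)
  nm <- names(st$sol$activations)
  expect_equal(st$sol$activations[nm], sol2$activations[nm], tolerance = 1e-7)
})

test_that("doubling every F_max halves activations and keeps forces", {
  m <- test_model()
  st <- test_statics()
  # no activation saturates at this posture, so the scale property is exact
  expect_lt(max(st$sol$activations), 0.999)
  m2 <- scale_fmax(m, 2)
  sol2 <- solve_static_optimization(m2, st$posed, st$loads)
  nm <- names(st$sol$activations)
  expect_equal(sol2$activations[nm], st$sol$activations[nm] / 2,
               tolerance = 1e-6)
  expect_equal(sol2$forces[nm], st$sol$forces[nm], tolerance = 1e-6)
})

test_that("joint reactions satisfy quasi-static equilibrium", {
  m <- test_model()
  st <- test_statics()
  # ball-and-socket hip resists no moment
  expect_lt(norm3(st$jl$joints$hip$moment), 1e-4)
  # hinge joints carry no moment about their own axis (it is balanced by
  # muscles), except the MTP where the reserve actuator provides it
  knee_axis <- as.numeric(st$posed$transforms$thigh$R %*% c(0, 1, 0))
  expect_lt(abs(sum(st$jl$joints$knee$moment * knee_axis)), 1e-4)
  mtp_axis <- as.numeric(st$posed$transforms$tmt$R %*% c(0, 1, 0))
  expect_equal(sum(st$jl$joints$mtp$moment * mtp_axis), -st$sol$mtp_reserve,
               tolerance = 1e-4)
  # hand Newton-Euler: with no muscles and massless segments the reaction
  # passes the GRF through unchanged
  m0 <- m
  for (k in names(m0$segments)) m0$segments[[k]]$mass <- 0
  m0$body_mass <- 0
  sol0 <- st$sol
  sol0$activations[] <- 0
  sol0$forces[] <- 0
  sol0$mtp_reserve <- 0
  loads0 <- st$loads
  loads0$couple <- c(0, 0, 0)
  loads0$weights <- lapply(loads0$weights, function(w) {
    w$force <- c(0, 0, 0); w
  })
  jl0 <- suppressWarnings(joint_reactions(m0, st$posed, sol0, loads0))
  for (j in c("mtp", "ankle", "knee", "hip"))
    expect_equal(jl0$joints[[j]]$force, -loads0$grf, tolerance = 1e-9)
  # with segment weights only: hip reaction equals -(GRF + distal weights)
  sol0b <- sol0
  jl0b <- suppressWarnings(joint_reactions(m, st$posed, sol0b, loads0))
  wdist <- sum(vapply(m$segments[c("thigh", "shank", "tmt", "pes")],
                      function(s) s$mass, numeric(1))) * m$gravity
  expect_equal(jl0b$joints$hip$force, -(loads0$grf + c(0, 0, -wdist)),
               tolerance = 1e-9)
})

test_that("sensitivity mode runs the identical solver path", {
  m <- apply_muscle_specific_fmax(test_model())
  st <- test_statics()
  sol <- solve_static_optimization(m, st$posed, st$loads)
  expect_true(all(abs(sol$residuals) < 1e-6))
  expect_true(all(sol$activations <= 1 + 1e-12))
})
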