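test_that("hip rotation composes FE, then AB-AD, then LAR", {
  p <- posture(-30, 5, 20, 93, 46, 16)
  # independent rotation-composition oracle
  oracle <- rot_y(-(90 + -30)) %*% rot_x(-5) %*% rot_z(-20)
  expect_equal(hip_rotation(p), oracle, tolerance = 1e-12)
  # posing then unwinding in reverse order restores neutral
  unwind <- hip_rotation(p) %*% rot_z(20) %*% rot_x(5) %*% rot_y(90 - 30)
  expect_equal(unwind, diag(3), tolerance = 1e-12)
})

test_that("segment transforms are orthonormal and chain correctly", {
  m <- test_model()
  p <- posture(-30, 5, 20, 93, 46, 16)
  posed <- pose_limb(m, p)
  for (tr in posed$transforms) {
    expect_equal(t(tr$R) %*% tr$R, diag(3), tolerance = 1e-12)
    expect_equal(det(tr$R), 1, tolerance = 1e-12)
  }
  expect_equal(posed$transforms$pelvis$R, diag(3))
  # hinge knee: shank frame equals thigh frame rotated about the knee axis
  expect_equal(posed$transforms$shank$R,
               posed$transforms$thigh$R %*% rot_y(93), tolerance = 1e-12)
  # fully vertical column: hip height equals functional limb length
  q <- m$params
  neutral <- posture(-90, 0, 0, 0, 0, 0, ranges = list())
  pn <- pose_limb(m, neutral, check = FALSE)
  L <- q$femur_length + q$tibio_length + q$tmt_length + 0.004 + q$pes_thickness
  expect_equal(pn$hip_height, L, tolerance = 1e-12)
  expect_equal(degree_of_crouch(pn, m)$value, 0, tolerance = 1e-12)
})

test_that("posture ranges are validated", {
  expect_error(posture(hip_extension = -200), "outside declared range")
  expect_silent(posture(hip_extension = -200, ranges = list()))
})

test_that("whole-body COM equals the direct mass-weighted sum", {
  m <- test_model()
  posed <- pose_limb(m, posture(-30, 5, 20, 93, 46, 16))
  keys <- c(pelvis = "pelvis", thigh = "thigh", shank = "shank",
            tmt = "tmt", pes = "pes")
  num <- c(0, 0, 0); den <- 0
  for (k in names(keys)) {
    s <- m$segments[[k]]
    num <- num + s$mass * apply_transform(posed$transforms[[k]], s$com_local)
    den <- den + s$mass
  }
  expect_equal(posed$com, num / den, tolerance = 1e-12)
})

test_that("degree of crouch halves when hip height halves", {
  m <- test_model()
  posed <- pose_limb(m, test_posture(), check = FALSE)
  fake <- posed
  q <- m$params
  L <- q$femur_length + q$tibio_length + q$tmt_length + 0.004 + q$pes_thickness
  fake$hip_height <- L / 2
  expect_equal(degree_of_crouch(fake, m)$value, 0.5)
  # alternate metric is selectable and recorded
  alt <- degree_of_crouch(posed, m, metric = function(po, mo) 42)
  expect_equal(alt$value, 42)
  expect_equal(alt$metric, "custom")
})

test_that("step-width criterion passes below and fails above 15% hip height", {
  m <- test_model()
  posed <- pose_limb(m, test_posture(), check = FALSE)
  mid <- m$params$hip_to_midline
  for (ratio in c(0.14, 0.16)) {
    fake <- posed
    fake$cop[2] <- mid - ratio * posed$hip_height / 2
    fake$cop[1] <- fake$com[1]   # keep criterion 2 satisfied
    cc <- check_posture_constraints(fake, m)
    expect_equal(cc$step_width$pass, ratio < 0.15, label = paste("ratio", ratio))
  }
})

test_that("COP-under-COM criterion reports its margin", {
  m <- test_model()
  posed <- pose_limb(m, test_posture(), check = FALSE)
  fake <- posed
  fake$cop[1] <- fake$com[1] + 0.005
  cc <- check_posture_constraints(fake, m)
  expect_false(cc$cop_under_com$pass)
  expect_equal(cc$cop_under_com$offset_x, 0.005, tolerance = 1e-12)
  expect_gt(cc$cop_under_com$margin, 0)
})

test_that("interpenetration is detected for overlapping bones", {
  m <- test_model()
  # an extreme posture folding the tarsometatarsus back into the shank
  p <- posture(-30, 5, 20, 93, 178, 0, ranges = list())
  posed <- pose_limb(m, p, check = FALSE)
  cc <- check_posture_constraints(posed, m)
  expect_false(cc$interpenetration$pass)
  expect_gt(length(cc$interpenetration$pairs), 0)
  # the admissible test posture has none
  cc2 <- check_posture_constraints(pose_limb(m, test_posture(), check = FALSE), m)
  expect_true(cc2$interpenetration$pass)
})

test_that("flat-foot repair makes the pes long axis horizontal", {
  m <- test_model()
  p <- flat_foot_mtp(m, posture(-35, 8, 15, 90, 50, 0, ranges = list()))
  posed <- pose_limb(m, p, check = FALSE)
  xg <- posed$transforms$pes$R %*% c(1, 0, 0)
  expect_lt(abs(xg[3]), 1e-10)
  expect_gt(xg[1], 0)
})
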