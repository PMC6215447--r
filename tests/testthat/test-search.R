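test_that("repair produces admissible postures without touching hip/knee", {
  m <- test_model()
  cfg <- search_config()
  p <- repair_posture(m, posture(-32, 5, 20, 90, 46, 16), cfg)
  expect_equal(p$hip_extension, -32)
  expect_equal(p$knee_flexion, 90)
  posed <- pose_limb(m, p, check = FALSE)
  cc <- check_posture_constraints(posed, m, cop_tol = cfg$cop_tol)
  expect_true(cc$all_pass)
  expect_lt(cc$step_width$ratio, 0.15)
  # pes is flat on the ground
  xg <- posed$transforms$pes$R %*% c(1, 0, 0)
  expect_lt(abs(xg[3]), 1e-8)
  # unreachable geometry raises a search stall
  expect_error(repair_posture(m, posture(-50, 5, 20, 100, 46, 16,
                                         ranges = list()), cfg),
               "search stall")
})

test_that("posture evaluation is deterministic and self-consistent", {
  m <- test_model()
  P <- test_posture()
  fab <- fabric_from_posture(m, P, fabric_gen_spec(noise_sd = 0))
  r1 <- evaluate_posture(m, P, fab, run_shank = FALSE)
  r2 <- evaluate_posture(m, P, fab, run_shank = FALSE)
  # fabric forward-generated at the same posture scores zero everywhere
  expect_equal(r1$score$score, 0, tolerance = 1e-8)
  expect_equal(r1$score$regions$deviation_deg, c(0, 0), tolerance = 1e-8)
  # two evaluations of one posture are identical
  expect_identical(r1$score$regions, r2$score$regions)
  expect_identical(r1$activations$activations, r2$activations$activations)
})

test_that("doubling all actuator strengths leaves the score unchanged", {
  m <- test_model()
  P <- test_posture()
  fab <- fabric_from_posture(m, P, fabric_gen_spec(noise_sd = 4, seed = 3))
  r1 <- evaluate_posture(m, P, fab, run_shank = FALSE)
  m2 <- scale_fmax(m, 2)
  r2 <- evaluate_posture(m2, P, fab, run_shank = FALSE)
  # halved activations produce identical forces, hence identical stress
  # directions and identical alignment (linearity of the FE solve)
  expect_equal(r2$score$score, r1$score$score, tolerance = 1e-4)
})

test_that("search accepts only improvements and stays admissible", {
  m <- test_model()
  cfg <- search_config(start = posture(-30, 5, 20, 93, 46, 16),
                       steps = c(5, 2.5), max_evals = 40)
  truth <- repair_posture(m, posture(-35, 5, 20, 95, 46, 16), cfg)
  fab <- fabric_from_posture(m, truth, fabric_gen_spec(noise_sd = 0))
  res <- run_search(m, fab, cfg)
  # accepted-score sequence is monotone non-increasing
  acc <- res$history[which(res$history$accepted), ]
  expect_true(all(diff(acc$score) <= 0))
  # returned score never worse than the start posture's
  expect_lte(res$score, res$history$score[1])
  # every evaluated posture in the audit trail is admissible
  for (i in seq_len(nrow(res$history))) {
    h <- res$history[i, ]
    if (is.na(h$score)) next
    p <- posture(h$hip_extension, h$hip_abduction, h$hip_lar,
                 h$knee_flexion, h$ankle_flexion, h$mtp_angle,
                 ranges = list())
    cc <- check_posture_constraints(pose_limb(m, p, check = FALSE), m,
                                    cop_tol = cfg$cop_tol)
    expect_true(cc$all_pass, label = paste("eval", h$eval))
  }
  # noiseless fabric: the generating posture is recovered within one step
  expect_lte(abs(res$posture$hip_extension - truth$hip_extension), 2.5)
  expect_lte(abs(res$posture$knee_flexion - truth$knee_flexion), 2.5)
})

test_that("fit_posture returns a full fitted object with methods", {
  m <- test_model()
  cfg <- search_config(start = posture(-30, 5, 20, 93, 46, 16),
                       steps = c(5), max_evals = 12, min_improve = 0.5)
  truth <- repair_posture(m, posture(-35, 5, 20, 95, 46, 16), cfg)
  fab <- fabric_from_posture(m, truth, fabric_gen_spec(noise_sd = 2, seed = 6))
  fit <- fit_posture(m, fab, cfg)
  expect_s3_class(fit, "posture_fit")
  co <- coef(fit)
  expect_named(co, fabpose:::.free_dofs)
  expect_output(print(fit), "Characteristic posture")
  expect_output(summary(fit), "degree of crouch")
  tmpplot <- tempfile(fileext = ".pdf")
  grDevices::pdf(tmpplot)
  plot(fit)
  grDevices::dev.off()
  expect_true(file.exists(tmpplot))
  # rerun with the same config: identical trajectory of iterates
  fit2 <- fit_posture(m, fab, cfg)
  expect_identical(fit$history$score, fit2$history$score)
  expect_identical(coef(fit), coef(fit2))
})
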