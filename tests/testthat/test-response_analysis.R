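test_that("pole summaries match direct eigenvalue computation", {
  mdl <- test_model()
  ps <- pole_summary(mdl$open)
  ev <- eigen(mdl$open$A, only.values = TRUE)$values
  expect_equal(sort(ps$poles$re), sort(Re(ev)))
  expect_equal(ps$n_real + ps$n_complex, 44)
  expect_equal(ps$n_real, 30)
  expect_equal(ps$n_complex, 14)
  # complex-pole statistics exclude real poles by construction
  expect_equal(sum(!is.na(ps$poles$wn_hz)), ps$n_complex)
  # a pure two-lag SISO muscle has exactly its two real poles
  one <- build_muscle_dynamics(0.03, 0.2, 500, "m")
  p1 <- pole_summary(one)
  expect_equal(p1$n_real, 2)
  expect_equal(sort(p1$poles$re), sort(c(-1 / 0.03, -1 / 0.2)))
})

test_that("step grids cover the channel matrix and respect linearity", {
  mdl <- test_model()
  t <- seq(0, 0.8, by = 0.004)
  sg <- step_response_grid(mdl$sys, "uCNS", "q", t = t)
  expect_equal(dim(sg$trajectories), c(length(t), 7L, 15L))
  sg2 <- step_response_grid(mdl$sys, "uCNS", "q", magnitude = 2, t = t)
  expect_equal(sg2$trajectories, 2 * sg$trajectories, tolerance = 1e-12)
  tg <- step_response_grid(mdl$sys, "tau_ext", "u", t = t)
  expect_equal(dim(tg$trajectories), c(length(t), 15L, 7L))
  # open loop: no muscular response to torque
  tg0 <- step_response_grid(mdl$open, "tau_ext", "u", t = t)
  expect_equal(max(abs(tg0$trajectories)), 0)
  # unstable configurations are refused with a diagnostic
  fx <- test_fixture(1)
  bad <- build_closed_loop(fx$params, mdl$fb, mdl$delays,
                           c = 3 * mdl$c_max)
  expect_error(step_response_grid(bad, "uCNS", "q", t = t), "unstable")
})

test_that("largest drive-to-displacement responses concentrate on spanned DOF", {
  mdl <- test_model()
  fx <- test_fixture(1)
  sg <- step_response_grid(mdl$sys, "uCNS", "q",
                           t = seq(0, 2, by = 0.01))
  peak <- apply(abs(sg$trajectories), c(2, 3), max)   # DOF x muscle
  hits <- 0
  for (j in seq_len(15)) {
    spanned <- which(fx$params$M[, j] != 0)
    if (which.max(peak[, j]) %in% spanned) hits <- hits + 1
  }
  expect_gt(hits / 15, 0.5)   # rank test, not exact values
})

test_that("steady states agree with the closed-loop DC gain", {
  mdl <- test_model()
  t <- seq(0, 25, by = 0.05)
  y <- ss_step(mdl$sys, t, input = "uCNS:FCR")
  dc <- ss_dcgain(mdl$sys)[, "uCNS:FCR"]
  expect_equal(unname(y[nrow(y), ]), unname(dc), tolerance = 1e-4)
})

test_that("stretch classification labels and bootstrap are reproducible", {
  mdl <- test_model()
  c1 <- classify_stretch_response(mdl$sys, mdl$delays, n_boot = 500,
                                  seed = 3)
  c2 <- classify_stretch_response(mdl$sys, mdl$delays, n_boot = 500,
                                  seed = 3)
  expect_identical(c1$labels, c2$labels)
  expect_identical(c1$ci95, c2$ci95)
  expect_equal(c1$n_cases, 105)
  expect_true(c1$concordance > 0.5)           # majority concordant
  expect_true(c1$ci95[1] < c1$concordance,
              c1$concordance < c1$ci95[2])
  # without feedback no muscle responds at all
  c0 <- classify_stretch_response(mdl$open, mdl$delays, n_boot = 10)
  expect_true(all(c0$labels$activity == "none"))
  expect_true(is.na(c0$concordance))
})

test_that("random-gain experiments are seed-stable and sign-sensitive", {
  mdl <- test_model()
  fx <- test_fixture(1)
  r0 <- random_gain_experiment(fx$params, mdl$fb, mdl$delays,
                               n_draws = 0)
  expect_equal(nrow(r0$draws), 0)
  r1 <- random_gain_experiment(fx$params, mdl$fb, mdl$delays,
                               mode = "preserve_sign", n_draws = 2,
                               seed = 9)
  r2 <- random_gain_experiment(fx$params, mdl$fb, mdl$delays,
                               mode = "preserve_sign", n_draws = 2,
                               seed = 9)
  expect_identical(r1$draws, r2$draws)
  rs <- random_gain_experiment(fx$params, mdl$fb, mdl$delays,
                               mode = "shuffle_all", n_draws = 2,
                               seed = 9)
  # sign-preserving draws keep majority concordance; full shuffles
  # should not systematically exceed them
  expect_gt(mean(r1$draws$concordance), 0.5)
  expect_gt(mean(r1$draws$concordance), mean(rs$draws$concordance) - 0.15)
})

test_that("feedback reduces DC gain and its effect fades at high frequency", {
  mdl <- test_model()
  f_hz <- seq(0, 20, by = 0.25)
  frc <- frequency_response_grid(mdl$sys, f_hz)
  fro <- frequency_response_grid(mdl$open, f_hz)
  # DC gain reduced on most drive-to-displacement channels
  expect_gt(mean(frc$dc <= fro$dc + 1e-12), 0.7)
  # relative effect of feedback on the magnitude ratio decays above 8 Hz
  rel <- abs(frc$mag - fro$mag) / (abs(fro$mag) + 1e-12)
  low <- f_hz > 0.5 & f_hz < 6
  high <- f_hz > 12
  expect_gt(mean(rel[, , low]), mean(rel[, , high]))
})
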