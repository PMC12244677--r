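test_that("central-delay imputation follows the measured class means", {
  ecd <- ul_ecd_matrix()
  g <- ul_gain_matrix()
  cen <- impute_central_delays(ecd, g)
  expect_equal(cen["Bi", "Tri"], 2.22)          # measured: ecd + 1
  expect_equal(unname(diag(cen)), rep(1, 11))   # homonymous single synapse
  # oracle: recompute the excitatory mean from the raw table
  meas <- !is.na(ecd); diag(meas) <- FALSE
  m_exc <- mean(ecd[meas & ecd < 0.5] + 1)
  m_inh <- mean(ecd[meas & ecd >= 0.5] + 1)
  expect_equal(attr(cen, "mean_excitatory"), m_exc)
  expect_equal(attr(cen, "mean_inhibitory"), m_inh)
  # an imputed excitatory pair carries exactly the excitatory mean
  # (Tri -> Brd has no measured ecd; collapsed gain is negative -> inh)
  g11 <- collapse_gain_to_delay(g)$values
  imputable <- which(is.na(ecd) & !is.na(g11) & g11 != 0, arr.ind = TRUE)
  imputable <- imputable[imputable[, 1] != imputable[, 2], , drop = FALSE]
  expect_gt(nrow(imputable), 0)
  i <- imputable[1, 1]; j <- imputable[1, 2]
  expect_equal(cen[i, j], if (g11[i, j] > 0) m_exc else m_inh)
  # pairs with neither measurement nor sign are flagged, not guessed
  expect_true(is.data.frame(attr(cen, "unresolved")))
})

test_that("the design matrix has one afferent and one efferent unit per pair", {
  m1 <- matrix(5.5, 1, 1, dimnames = list("A", "A"))
  c1 <- matrix(1, 1, 1, dimnames = list("A", "A"))
  sys <- assemble_delay_system(m1, c1)
  expect_equal(dim(sys$A), c(1L, 2L))
  expect_equal(unname(sys$A[1, ]), c(1, 1))
  expect_equal(sys$rhs, 4.5)

  cen <- impute_central_delays(ul_ecd_matrix())
  rt <- synthetic_roundtrip_delays()
  s <- assemble_delay_system(rt, cen)
  expect_true(all(rowSums(s$A) == 2))
  expect_false("Bra" %in% s$afferent_muscles)   # no measured Bra pair
  expect_false("Bra" %in% s$efferent_muscles)
  expect_equal(nrow(s$A), sum(!is.na(rt) & !is.na(cen)))
  expect_error(assemble_delay_system(m1 * NA, c1), "no measured")
})

test_that("noise-free full-grid delays are recovered exactly after anchoring", {
  fx <- test_fixture(2)
  d <- fx$delays
  sys <- assemble_delay_system(d$roundtrip, d$central)
  sol <- solve_delays(sys, anchor = list(muscle = "Delt",
                                         value = d$afferent[["Delt"]]))
  expect_true(sol$shift_indeterminate)
  expect_lt(max(abs(sol$afferent - d$afferent)), 1e-9)
  expect_lt(max(abs(sol$efferent - d$efferent)), 1e-9)
  expect_lt(max(abs(sol$residuals)), 1e-9)
  # minimum-norm single-pair solution splits the sum evenly
  m1 <- matrix(5.5, 1, 1, dimnames = list("A", "A"))
  c1 <- matrix(1, 1, 1, dimnames = list("A", "A"))
  s1 <- solve_delays(assemble_delay_system(m1, c1))
  expect_equal(unname(c(s1$afferent, s1$efferent)), c(2.25, 2.25))
})

test_that("reconstruction residuals equal the least-squares residuals", {
  cen <- impute_central_delays(ul_ecd_matrix())
  rt <- synthetic_roundtrip_delays()
  sys <- assemble_delay_system(rt, cen)
  sol <- solve_delays(sys)
  # per pair: a_i + c_ij + e_j - T_ij equals the equation residual
  recon <- sol$afferent[sys$pairs$source] + sys$pairs$central_ms +
    sol$efferent[sys$pairs$target] - sys$pairs$roundtrip_ms
  expect_equal(unname(recon), sol$residuals)
  # consistent synthetic data: solution matches the packaged per-muscle
  # delays once the common shift is anchored
  mp <- ul_muscle_parameters()
  a_true <- collapse_to_delay(stats::setNames(mp$afferent_ms, mp$abbrev))
  e_true <- collapse_to_delay(stats::setNames(mp$efferent_ms, mp$abbrev))
  sol2 <- solve_delays(sys, anchor = list(muscle = "Delt",
                                          value = a_true[["Delt"]]))
  expect_equal(sol2$afferent, a_true[names(sol2$afferent)],
               tolerance = 1e-9)
  expect_equal(sol2$efferent, e_true[names(sol2$efferent)],
               tolerance = 1e-9)
})

test_that("recovery error shrinks as the measurement set grows", {
  fx <- test_fixture(3)
  d <- fx$delays
  set.seed(11)
  rmse_for <- function(keep_frac) {
    errs <- replicate(8, {
      rt <- d$roundtrip +
        matrix(stats::rnorm(121, sd = 0.5), 11, 11)
      drop <- matrix(stats::runif(121) > keep_frac, 11, 11)
      diag(drop) <- FALSE               # keep homonymous anchors
      rt[drop] <- NA
      sys <- assemble_delay_system(rt, d$central)
      sol <- solve_delays(sys, anchor = list(muscle = "Delt",
                                             value = d$afferent[["Delt"]]))
      sqrt(mean(c(sol$afferent - d$afferent[names(sol$afferent)],
                  sol$efferent - d$efferent[names(sol$efferent)])^2))
    })
    mean(errs)
  }
  expect_lt(rmse_for(1), rmse_for(0.3))
})

test_that("delay-length regression returns conduction velocities", {
  lengths <- stats::setNames(seq(0.35, 0.95, length.out = 11),
                             UL_MUSCLES_11)
  # exact line with slope 20 ms/m = 1/50 s per m
  a <- 20 * lengths + 2
  fit <- regress_vs_innervation_length(a, lengths)
  expect_equal(fit$velocity, 50)
  expect_equal(fit$R, 1)
  # two fits of the same synthetic limb at the reference velocities
  aff <- 1000 * lengths / 56.8 + 0.5
  eff <- 1000 * lengths / 29.1 + 0.3
  fa <- regress_vs_innervation_length(aff, lengths)
  fe <- regress_vs_innervation_length(eff, lengths)
  expect_equal(fa$velocity / fe$velocity, 56.8 / 29.1, tolerance = 1e-9)
  expect_equal(round(fa$velocity / fe$velocity, 2), 1.95)
  # noisy synthetic data recovers the generating slope within its CI
  set.seed(5)
  noisy <- 20 * lengths + 2 + stats::rnorm(11, sd = 0.4)
  fn <- regress_vs_innervation_length(noisy, lengths)
  ci <- stats::confint(fn$fit)[2, ]
  expect_true(ci[1] <= 20 && 20 <= ci[2])
  expect_error(regress_vs_innervation_length(a, lengths * 0 + 0.5),
               "degenerate")
})

test_that("missing-muscle delays come from the regression lines", {
  lengths <- stats::setNames(seq(0.35, 0.95, length.out = 11),
                             UL_MUSCLES_11)
  fa <- regress_vs_innervation_length(18 * lengths + 1, lengths)
  fe <- regress_vs_innervation_length(33 * lengths + 2, lengths)
  cen <- impute_central_delays(ul_ecd_matrix())
  out <- extrapolate_missing_muscle(fa, fe, length = 0.6, sign = -1,
                                    central = cen)
  expect_equal(out$afferent, 18 * 0.6 + 1, tolerance = 1e-9)
  expect_equal(out$efferent, 33 * 0.6 + 2, tolerance = 1e-9)
  expect_equal(out$central, attr(cen, "mean_inhibitory"))
  # zero length returns the intercepts
  out0 <- extrapolate_missing_muscle(fa, fe, length = 0)
  expect_equal(out0$afferent, 1, tolerance = 1e-9)
  expect_equal(out0$efferent, 2, tolerance = 1e-9)
})
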