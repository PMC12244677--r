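test_that("closing the loop adds the delay states and preserves channels", {
  mdl <- test_model()
  expect_equal(mdl$sys$n_states, 44 + 3 * 15)
  expect_identical(mdl$sys$inputs, mdl$open$inputs)
  expect_identical(mdl$sys$outputs, mdl$open$outputs)
  expect_true(ss_is_stable(mdl$sys))
})

test_that("zero gains reduce the closed loop to the open loop", {
  fx <- test_fixture(1)
  fb0 <- feedback_params(ul_gain_matrix(), c = 0, k = 0,
                         override = TRUE)
  sys <- build_closed_loop(fx$params, fb0, lumped_feedback_delays(),
                           c = 0)
  ol <- assemble_forward_path(fx$params)
  expect_equal(sys$n_states, ol$n_states)
  expect_equal(sort(Re(ss_poles(sys))), sort(Re(ss_poles(ol))))
})

test_that("the bisection margin brackets the instability boundary", {
  mdl <- test_model()
  fx <- test_fixture(1)
  fb <- mdl$fb
  dl <- mdl$delays
  cmax <- mdl$c_max
  below <- build_closed_loop(fx$params, fb, dl, c = 0.995 * cmax)
  above <- build_closed_loop(fx$params, fb, dl, c = 1.02 * cmax)
  expect_true(ss_is_stable(below))
  expect_false(ss_is_stable(above))
  # dominant pole real part grows monotonically with c near the margin
  re_at <- function(cc) max(Re(ss_poles(
    build_closed_loop(fx$params, fb, dl, c = cc))))
  res <- vapply(cmax * c(0.5, 0.8, 0.95, 1.05), re_at, 1)
  expect_true(all(diff(res) > 0))
})

test_that("bisection and the disk-style frequency bound agree within 5 percent", {
  fx <- test_fixture(1)
  fb <- feedback_params(ul_gain_matrix(), c = 0)
  sr <- system_gain_margin(fx$params, fb, lumped_feedback_delays(),
                           method = "both")
  expect_lt(abs(sr$c_disk - sr$c_bisection) / sr$c_bisection, 0.05)
})

test_that("removing force feedback changes the spindle gain margin", {
  fx <- test_fixture(1)
  fb <- feedback_params(ul_gain_matrix(), c = 0)
  dl <- lumped_feedback_delays()
  with_gto <- system_gain_margin(fx$params, fb, dl)$c_max
  without <- system_gain_margin(fx$params, fb, dl,
                                include_gto = FALSE)$c_max
  expect_false(isTRUE(all.equal(with_gto, without, tolerance = 1e-3)))
  expect_gt(without, with_gto)  # force feedback consumes part of the margin
})

test_that("the single-loop margin matches the characteristic-polynomial oracle", {
  toy <- toy_single_loop()
  fb <- feedback_params(toy$G, c = 0, r = 0.1, k = 0, override = TRUE)
  sr <- system_gain_margin(toy$params, fb, toy$delays, pade_order = 3,
                           tol = 1e-6)
  oracle <- toy_cmax_polyroot(toy, r = 0.1)
  expect_equal(sr$c_max, oracle, tolerance = 1e-3)
})

test_that("the gain margin obeys the exact quadratic and linear scaling laws", {
  fx <- test_fixture(1)
  fb <- feedback_params(ul_gain_matrix(), c = 0)
  dl <- lumped_feedback_delays()
  sa <- sensitivity_analysis(fx$params, fb, dl, scales = c(0.5, 1, 2),
                             parameters = c("C", "M"), tol = 1e-5)
  base <- sa$c_max[sa$parameter == "M" & sa$scale == 1]
  expect_equal(sa$c_max[sa$parameter == "M" & sa$scale == 0.5] / base, 4,
               tolerance = 1e-3)
  expect_equal(sa$c_max[sa$parameter == "M" & sa$scale == 2] / base, 0.25,
               tolerance = 1e-3)
  expect_equal(sa$c_max[sa$parameter == "C" & sa$scale == 0.5] / base, 2,
               tolerance = 1e-3)
  expect_equal(sa$c_max[sa$parameter == "C" & sa$scale == 2] / base, 0.5,
               tolerance = 1e-3)
})

test_that("dynamic parameters stay below the exact quadratic law", {
  # only M (both paths) and C (forward path) carry exact power laws;
  # parameters acting through the dynamics perturb the margin less than
  # the quadratic M law and not by an exact power
  fx <- test_fixture(1)
  fb <- feedback_params(ul_gain_matrix(), c = 0)
  sa <- sensitivity_analysis(fx$params, fb, lumped_feedback_delays(),
                             scales = c(0.5, 1, 2),
                             parameters = c("T2", "I", "K"))
  for (nm in c("T2", "I", "K")) {
    base <- sa$c_max[sa$parameter == nm & sa$scale == 1]
    for (s in c(0.5, 2)) {
      ratio <- sa$c_max[sa$parameter == nm & sa$scale == s] / base
      expect_lt(abs(log(ratio)), 2 * abs(log(s)) * (1 - 1e-3))
    }
  }
  # inertia and stiffness act through the mode shapes only: sub-linear
  for (nm in c("I", "K")) {
    base <- sa$c_max[sa$parameter == nm & sa$scale == 1]
    for (s in c(0.5, 2)) {
      ratio <- sa$c_max[sa$parameter == nm & sa$scale == s] / base
      expect_lt(abs(log(ratio)), abs(log(s)))
    }
  }
})

test_that("the loop-at-a-time diagnostic is inert at c = 0 and responsive at c > 0", {
  fx <- test_fixture(1)
  fb <- feedback_params(ul_gain_matrix(), c = 0)
  chk0 <- loop_at_a_time_check(fx$params, fb, c = 0,
                               omega = 10^seq(0, 2, length.out = 20))
  expect_false(any(chk0$violated))        # real(1) is never negative
  expect_equal(min(chk0$min_real), 1)
  mdl <- test_model()
  chk <- loop_at_a_time_check(fx$params, mdl$fb, c = 20 * mdl$c_max,
                              omega = 10^seq(0, 2, length.out = 40))
  expect_true(any(chk$violated))
  # permutation symmetry: duplicate-head channels respond identically
  expect_equal(chk$min_real["Bi Long", "Tri Long"],
               chk$min_real["Bi Short", "Tri Long"], tolerance = 1e-9)
})
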