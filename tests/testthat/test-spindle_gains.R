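test_that("histogram gains follow the count formula and stay in [-1, 1]", {
  expect_equal(psth_gain(5, 0, 10), 0.5)
  expect_equal(psth_gain(3, 7, 10), -0.4)
  for (n in c(1, 4, 9)) expect_equal(psth_gain(0, 0, n), 0)
  expect_error(psth_gain(2, 1, 0), "n_tot")
  expect_error(psth_gain(6, 6, 10), "exceed")
  set.seed(42)
  for (i in 1:50) {
    nt <- sample(1:40, 1)
    np <- sample(0:nt, 1)
    nm <- sample(0:(nt - np), 1)
    expect_true(abs(psth_gain(np, nm, nt)) <= 1)
  }
})

test_that("EMG-averaging gains follow p b / s and invert the forward model", {
  expect_equal(emg_gain(0.2, 0.05, 0.9), 0.2 * 0.05 / 0.9)
  expect_equal(emg_gain(0, 0.07, 0.85), 0)
  expect_error(emg_gain(0.1, 0.05, 0), "stimulus")
  # algebraic round trip: u = b + G s, p = (u - b)/b, then p b / s
  g_true <- 0.01; b <- 0.05; s <- 0.9
  u <- b + g_true * s
  p <- (u - b) / b
  expect_equal(emg_gain(p, b, s), g_true)
  # EMG gains are not confined to [-1, 1]
  expect_gt(emg_gain(50, 0.1, 0.9), 1)
})

test_that("nerve-stimulation totals are distributed over innervated muscles", {
  out <- split_nerve_stimulus(0.6, c(FCR = 0.2, FCU = NA))
  expect_equal(unname(out["FCU"]), 0.4)
  out2 <- split_nerve_stimulus(0.6, c(FCR = NA, FCU = NA))
  expect_equal(unname(out2), c(0.3, 0.3))
  out3 <- split_nerve_stimulus(0, c(FCR = NA, FCU = NA))
  expect_equal(unname(out3), c(0, 0))
  expect_warning(split_nerve_stimulus(0.9, c(a = NA, b = NA, d = NA)),
                 "equally")
})

test_that("within-method averaging takes cell means and keeps empties missing", {
  obs <- data.frame(method = "psth_el",
                    source = c("Bi", "Bi", "Tri"),
                    target = c("Tri", "Tri", "Bi"),
                    n_plus = c(8, 12, 2), n_minus = c(0, 0, 8),
                    n_tot = c(20, 20, 20))
  m <- average_within_method(obs)
  expect_equal(m["Bi", "Tri"], mean(c(0.4, 0.6)))
  expect_equal(m["Tri", "Bi"], -0.3)        # single observation -> itself
  expect_true(is.na(m["Bi", "Bi"]))         # empty cell stays missing
  obs$method[1] <- "other"
  expect_error(average_within_method(obs), "more than one method")
})

test_that("through-origin method scaling matches the normal-equations oracle", {
  mk <- function(vals) {
    m <- matrix(NA_real_, 13, 13,
                dimnames = list(UL_MUSCLES_13, UL_MUSCLES_13))
    m[seq_along(vals)] <- vals
    m
  }
  s <- fit_method_scale(mk(c(1, 2)), mk(c(2, 4)))
  expect_equal(s$slope, 2)
  expect_equal(s$R, 1)
  expect_equal(s$n_shared, 2)
  s1 <- fit_method_scale(mk(0.5), mk(0.25))
  expect_equal(s1$slope, 0.5)               # one-point through-origin fit
  a <- c(1, 2, 3); ref <- c(2.1, 3.9, 6.2)
  s3 <- fit_method_scale(mk(a), mk(ref))
  expect_equal(s3$slope, sum(a * ref) / sum(a^2))  # normal equations
  # homogeneity: scaling the method table by lambda scales slope by 1/lambda
  lam <- 3.7
  s4 <- fit_method_scale(mk(a * lam), mk(ref))
  expect_equal(s4$slope, s3$slope / lam)
  expect_error(fit_method_scale(mk(1), mk(numeric(0))), "no shared")
})

test_that("compiling synthetic precursor tables reconstructs the packaged matrix", {
  pre <- synthetic_precursor_tables()
  out <- compile_gain_matrix(pre$tables, pre$chain, pre$reference,
                             pre$bridge)
  G <- ul_gain_matrix()
  expect_equal(out$G$values, G$values, tolerance = 1e-12)
  expect_identical(out$G$mask, G$mask)
  expect_equal(gain_value(out$G, "FCU", "FCU"), 2.6)
  # all regression slopes positive on the packaged data
  expect_true(all(vapply(out$scales, function(s) s$slope, 1) > 0))
  # a single method already on the reference scale is returned unchanged
  one <- compile_gain_matrix(pre$tables["psth_el"],
                             chain = c(psth_el = "psth_el"),
                             reference = "psth_el")
  expect_equal(one$G$values, pre$tables$psth_el,
               ignore_attr = FALSE)
  # idempotence: recompiling the compiled matrix leaves it unchanged
  twice <- compile_gain_matrix(list(red = out$G$values),
                               chain = c(red = "red"), reference = "red")
  expect_equal(twice$G$values, out$G$values)
})

test_that("observation-level pipeline approximates the table within quantization", {
  pre <- synthetic_precursor_tables()
  # EMG-type observations reproduce their table exactly
  tab_e <- pre$tables$emga_el
  obs_e <- synthetic_observations(tab_e, "emga_el")
  expect_equal(average_within_method(obs_e), tab_e, tolerance = 1e-12)
  # histogram-type observations quantize to 1/n_tot
  tab_p <- matrix(NA_real_, 13, 13,
                  dimnames = list(UL_MUSCLES_13, UL_MUSCLES_13))
  tab_p[cbind(1:4, 2:5)] <- c(0.3171, -0.482, 0.0909, 0.75)
  obs_p <- synthetic_observations(tab_p, "psth_tap", n_tot = 1000)
  back <- average_within_method(obs_p)
  expect_lt(max(abs(back - tab_p), na.rm = TRUE), 5e-4 + 1e-12)
  expect_error(synthetic_observations(tab_p * 3, "psth_tap"), "-1, 1")
})

test_that("symmetry statistics reproduce the bidirectional-pair structure", {
  g <- ul_gain_matrix()
  s <- symmetry_stats(g)
  expect_equal(s$n_pairs, 20)
  lab <- paste(s$discordant$muscle_a, s$discordant$muscle_b, sep = "-")
  for (p in c("Bi-PT", "Bi-FCR", "Bi-FCU", "Tri-ECR", "Brd-PT"))
    expect_true(p %in% lab)
  # Bi-ECR has one direction measured 0: sign-neutral, never discordant
  expect_false("Bi-ECR" %in% lab)
  bp <- s$pairs[s$pairs$muscle_a == "Bi" & s$pairs$muscle_b == "PT", ]
  expect_equal(c(bp$g_ab, bp$g_ba), c(-0.50, 0.43))
  # a symmetric matrix is perfectly concordant
  m <- matrix(NA_real_, 13, 13,
              dimnames = list(UL_MUSCLES_13, UL_MUSCLES_13))
  m[1:3, 1:3] <- c(1, 0.5, 0.2, 0.5, 1, -0.3, 0.2, -0.3, 1)
  ss <- symmetry_stats(gain_matrix(m))
  expect_equal(ss$n_sign_discordant, 0)
  expect_equal(ss$pearson_R, 1)
})

test_that("gain signs agree with excess central delay on every overlapping pair", {
  g <- ul_gain_matrix()
  ecd <- ul_ecd_matrix()
  v <- sign_vs_ecd_validation(g, ecd, threshold = 0.5)
  expect_equal(v$n_consistent, v$n_overlap)   # perfect agreement
  expect_gt(v$n_overlap, 30)
  pec <- v$detail[v$detail$source == "Pec" & v$detail$target == "Delt", ]
  expect_equal(pec$gain, -0.052)
  expect_equal(pec$ecd_ms, 1.5)
  expect_true(pec$consistent)
  empty <- ecd; empty[] <- NA
  v0 <- sign_vs_ecd_validation(g, empty)
  expect_equal(c(v0$n_overlap, v0$n_consistent), c(0L, 0L))
})
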