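passive_params <- function(e_rev = -60) {
  p <- neuron_params("WT", noise_sd_cc = 0, noise_sd_vc = 0)
  p$fast_nav$gmax <- 0
  p$delayed_rectifier_k$gmax <- 0
  p$kna$gmax_wholecell <- 0
  p$passive_leak$e_rev <- e_rev
  p
}

test_that("passive limit: leak-only cell rests exactly at the leak reversal", {
  p <- passive_params(-57.5)
  pr <- step_protocol(0, 200, 0, "cc", pre_ms = 0, post_ms = 0)
  s <- simulate_current_clamp(p, pr, seed = 1, adjust_to = NULL)$sweeps$cc[[1]]
  expect_equal(s$recorded, rep(-57.5, length(s$recorded)), tolerance = 1e-9)
})

test_that("identical seed gives identical output; different seed differs", {
  p <- neuron_params("WT")
  pr <- step_protocol(100, 50, 0, "cc", pre_ms = 10, post_ms = 10)
  a <- simulate_current_clamp(p, pr, seed = 7)$sweeps$cc[[1]]
  b <- simulate_current_clamp(p, pr, seed = 7)$sweeps$cc[[1]]
  d <- simulate_current_clamp(p, pr, seed = 8)$sweeps$cc[[1]]
  expect_identical(a$recorded, b$recorded)
  expect_false(identical(a$recorded, d$recorded))
  vp <- step_protocol(-120, 50, -80, "vc", pre_ms = 20, post_ms = 5)
  va <- simulate_voltage_clamp(p, vp, 70, 180, seed = 3)$sweeps$vc[[1]]
  vb <- simulate_voltage_clamp(p, vp, 70, 180, seed = 3)$sweeps$vc[[1]]
  expect_identical(va$recorded, vb$recorded)
})

test_that("with no injected current V stays within the reversal bounds", {
  p <- neuron_params("WT", noise_sd_cc = 0)
  pr <- step_protocol(0, 500, 0, "cc", pre_ms = 0, post_ms = 0)
  s <- simulate_current_clamp(p, pr, seed = 1, adjust_to = NULL)$sweeps$cc[[1]]
  e_revs <- c(p$fast_nav$e_na, p$delayed_rectifier_k$e_k,
              p$passive_leak$e_rev, p$kna$e_k)
  expect_true(all(s$recorded >= min(e_revs) - 5))
  expect_true(all(s$recorded <= max(e_revs) + 5))
})

test_that("AP count agrees with an independent pure-R RK4 at 10x finer dt", {
  p <- neuron_params("WT", noise_sd_cc = 0)
  dur <- 400
  pr <- step_protocol(200, dur, 0, "cc", pre_ms = 10, post_ms = 10,
                      dt_ms = 0.02)
  s <- simulate_current_clamp(p, pr, seed = 1)$sweeps$cc[[1]]
  n_pkg <- nrow(detect_aps(s))
  bias <- oracle_bias(p, -60, p$na_handling$resting_na)
  n_fine <- round((dur + 20) / 0.002)
  inj <- rep(bias, n_fine)
  inj[seq(round(10 / 0.002), round((10 + dur) / 0.002))] <- bias + 200
  v_o <- oracle_rk4_cc(p, inj, 0.002, -60, p$na_handling$resting_na)
  n_oracle <- oracle_crossing_count(v_o, 0)
  expect_gt(n_oracle, 0)
  expect_lte(abs(n_pkg - n_oracle), ceiling(0.3 * n_oracle))
})

test_that("KNa deletion increases the AP count at 60 pA (same seed)", {
  pr <- step_protocol(60, 1000, 0, "cc", pre_ms = 100, post_ms = 100)
  n_wt <- nrow(detect_aps(
    simulate_current_clamp(neuron_params("WT"), pr, seed = 4)$sweeps$cc[[1]]))
  n_dko <- nrow(detect_aps(
    simulate_current_clamp(neuron_params("dKO"), pr, seed = 4)$sweeps$cc[[1]]))
  expect_gte(n_dko, n_wt)
  expect_gt(n_dko, 0)
})

test_that("halving the integration step changes AP counts by at most 1", {
  for (g in c("WT", "dKO")) {
    p <- neuron_params(g)
    for (amp in c(60, 200)) {
      counts <- vapply(c(0.02, 0.01), function(dt) {
        pr <- step_protocol(amp, 1000, 0, "cc", pre_ms = 100, post_ms = 100,
                            dt_ms = dt)
        nrow(detect_aps(simulate_current_clamp(p, pr, seed = 2)$sweeps$cc[[1]]))
      }, numeric(1))
      expect_lte(abs(diff(counts)), 1)
    }
  }
})

test_that("integration failure names the offending time point", {
  p <- neuron_params("WT")
  p$membrane_capacitance <- 1e-6   # forces a numerical blow-up
  pr <- step_protocol(200, 20, 0, "cc", pre_ms = 2, post_ms = 2)
  expect_error(simulate_current_clamp(p, pr, seed = 1), "non-finite")
})

test_that("voltage-clamp dialysis scaling matches the closed form", {
  p <- neuron_params("WT", noise_sd_vc = 0)
  lp <- step_protocol(-120, 100, -80, "vc", pre_ms = 50, post_ms = 10)
  # at break-in the KNa contribution is exactly zero: leak only
  s0 <- simulate_voltage_clamp(p, lp, 70, 0, seed = 1)$sweeps$vc[[1]]
  expect_equal(leak_difference_current(s0), p$passive_leak$g * -40,
               tolerance = 0.01)
  # at 3 min the difference current equals (g_KNa(t) + g_leak) * dV
  s3 <- simulate_voltage_clamp(p, lp, 70, 180, seed = 1)$sweeps$vc[[1]]
  g_kna <- p$kna$gmax_wholecell * kna_hill(70) * dialysis_factor(180)
  expect_equal(leak_difference_current(s3), -(g_kna + p$passive_leak$g) * 40,
               tolerance = 0.001)
  # with recording noise the measurement stays within 3 sd of the mean
  pn <- neuron_params("WT")
  sn <- simulate_voltage_clamp(pn, lp, 70, 180, seed = 2)$sweeps$vc[[1]]
  n_plat <- sum(sn$time_ms >= 125 & sn$time_ms <= 150)
  sigma <- pn$noise_sd_vc * sqrt(2 / n_plat)
  expect_lt(abs(leak_difference_current(sn) + (g_kna + 0.8) * 40), 3 * sigma)
})

test_that("0 mM pipette Na gives a near-zero difference current", {
  p <- neuron_params("WT")
  lp <- step_protocol(-120, 100, -80, "vc", pre_ms = 50, post_ms = 10)
  s <- simulate_voltage_clamp(p, lp, 0, 180, seed = 3)$sweeps$vc[[1]]
  # only the ohmic leak and residual basal KNa remain: tens of pA, not nA
  expect_lt(abs(leak_difference_current(s)), 80)
  expect_error(simulate_voltage_clamp(p, lp, -1, 180), "pipette_na")
})

test_that("KNa-null with 70 mM Na matches WT with 0 mM Na (leak floor)", {
  lp <- step_protocol(-120, 100, -80, "vc", pre_ms = 50, post_ms = 10)
  p0 <- neuron_params("WT", noise_sd_vc = 0)
  p0$kna$gmax_wholecell <- 0
  d_null <- leak_difference_current(
    simulate_voltage_clamp(p0, lp, 70, 180, seed = 1)$sweeps$vc[[1]])
  d_wt0 <- leak_difference_current(
    simulate_voltage_clamp(neuron_params("WT", noise_sd_vc = 0), lp,
                           0, 180, seed = 1)$sweeps$vc[[1]])
  expect_lt(abs(d_null - d_wt0), 25)
})

test_that("single-channel records have the Ohmic amplitude and Hill Po", {
  p <- neuron_params("WT")
  # bath 0 Na: flat record (no openings beyond noise)
  r0 <- simulate_single_channel(p, -80, 5000, 0, seed = 1)
  expect_identical(r0$po_true, 0)
  expect_lt(max(abs(r0$current)), 6 * 0.8)
  # amplitude closed form: 127 pS x (-80 - 18.35) mV
  r <- simulate_single_channel(p, -80, 60000, 70, seed = 2)
  expect_equal(r$unitary_pa, 0.127 * (-80 - nernst(152.5, 73.6)),
               tolerance = 1e-3)
  # empirical open fraction matches the Hill Po over a 60 s record
  open <- r$current < r$unitary_pa / 2
  expect_lt(abs(mean(open) - r$po_true), 0.03)
})

test_that("cohorts are reproducible and respect the variability setting", {
  c0 <- make_cohort(3, "WT", variability = 0, seed = 5)
  tmpl <- neuron_params("WT")
  tmpl$na_handling$resting_na <- 10
  for (cl in c0) expect_equal(cl$params$fast_nav$gmax, tmpl$fast_nav$gmax)
  a <- make_cohort(4, "WT", seed = 9)
  b <- make_cohort(4, "WT", seed = 9)
  expect_identical(vapply(a, function(x) x$params$kna$gmax_wholecell,
                          numeric(1)),
                   vapply(b, function(x) x$params$kna$gmax_wholecell,
                          numeric(1)))
  # leak difference current across a cohort has CV near the requested value
  lp <- step_protocol(-120, 100, -80, "vc", pre_ms = 50, post_ms = 10,
                      dt_ms = 0.05)
  cells <- make_cohort(40, "WT", pipette_na = 70, variability = 0.25,
                       seed = 11)
  di <- vapply(cells, function(cl) {
    leak_difference_current(
      simulate_voltage_clamp(cl$params, lp, 70, 180,
                             seed = cl$seed)$sweeps$vc[[1]])
  }, numeric(1))
  cv <- sd(di) / abs(mean(di))
  expect_gt(cv, 0.15)
  expect_lt(cv, 0.35)
})
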