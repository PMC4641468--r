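test_that("spike detection: flat trace, constructed train, crossing oracle", {
  dt <- 0.02
  flat <- make_cc_sweep(rep(-60, 5000), dt)
  expect_equal(nrow(detect_aps(flat)), 0)
  # ten stereotyped spikes at known positions
  spk <- triangle_spike(dt = dt)
  v <- rep(-60, 50000)
  pos <- round(seq(2000, 48000, length.out = 10))
  for (p0 in pos) v[p0 + seq_along(spk) - 1] <- spk
  tr <- make_cc_sweep(v, dt)
  aps <- detect_aps(tr)
  expect_equal(nrow(aps), 10)
  true_peaks <- (pos + (length(spk) - 1) / 2 - 1) * dt
  expect_true(all(abs(aps$peak_time_ms - true_peaks) <= dt + 1e-9))
  # simulated sweep: count equals brute-force upward 0-crossing count
  s <- simulate_current_clamp(neuron_params("WT"),
                              step_protocol(200, 1000, 0, "cc", pre_ms = 100,
                                            post_ms = 100), seed = 2)
  sw <- s$sweeps$cc[[1]]
  expect_equal(nrow(detect_aps(sw)),
               oracle_crossing_count(knaephys:::.smooth_ma(sw$recorded, 5), 0))
})

test_that("phase-plane threshold matches the analytic exponential upstroke", {
  # V rises exponentially: dV/dt is proportional to (V - V0), so the voltage
  # at fraction f of peak dV/dt is exactly V0 + f * (V_peak - V0)
  dt <- 0.01
  v0 <- -60; tau <- 1.5
  t_up <- seq(0, 10.5, by = dt)
  v_up <- v0 + 0.6 * exp(t_up / tau)
  v_up <- v_up[v_up <= 40]
  v <- c(rep(v0, 2000), v_up, seq(40, -70, by = -0.5 * 50 * dt / 0.5),
         rep(-70, 2000))
  tr <- make_cc_sweep(v, dt)
  v_pk <- max(v_up)
  expect_equal(ap_threshold(tr, fraction = 0.10),
               v0 + 0.10 * (v_pk - v0), tolerance = 0.2)
  expect_equal(ap_threshold(tr, fraction = 0.25),
               v0 + 0.25 * (v_pk - v0), tolerance = 0.25)
  # degenerate fraction: returns V at peak dV/dt itself
  vs <- knaephys:::.smooth_ma(v, 5)
  dv <- knaephys:::.dvdt(vs, dt)
  expect_equal(ap_threshold(tr, fraction = 1), vs[which.max(dv)])
  # no AP: clear signal
  expect_error(ap_threshold(make_cc_sweep(rep(-60, 1000), dt)), "no action")
})

test_that("threshold shifts with a voltage offset and survives resampling", {
  p <- neuron_params("WT", noise_sd_cc = 0)
  pr <- step_protocol(100, 20, 0, "cc", pre_ms = 10, post_ms = 80)
  s <- simulate_current_clamp(p, pr, seed = 3)$sweeps$cc[[1]]
  th <- ap_threshold(s)
  s_off <- s; s_off$recorded <- s$recorded + 7
  expect_equal(ap_threshold(s_off), th + 7, tolerance = 1e-6)
  # decimating 2x changes the estimate by less than a millivolt
  keep <- seq(1, length(s$time_ms), by = 2)
  s2 <- kna_sweep(s$time_ms[keep] - s$time_ms[1], s$command[keep],
                  s$recorded[keep], "cc")
  expect_lt(abs(ap_threshold(s2) - th), 1)
})

test_that("dKO threshold is more negative than WT (cohort means)", {
  fw <- cohort_features(make_cohort(8, "WT", seed = 11))
  fd <- cohort_features(make_cohort(8, "dKO", seed = 22))
  expect_lt(mean(fd$threshold, na.rm = TRUE), mean(fw$threshold, na.rm = TRUE))
})

test_that("rheobase: direct family definition and bisection-vs-scan", {
  # constructed family where only steps >= 90 pA spike
  dt <- 0.02
  spk <- triangle_spike(dt = dt)
  sweeps <- lapply(c(70, 80, 90, 100), function(amp) {
    v <- rep(-60, 3000)
    if (amp >= 90) v[1000 + seq_along(spk) - 1] <- spk
    cmd <- c(rep(0, 500), rep(amp, 1000), rep(0, 1500))
    kna_sweep((seq_len(3000) - 1) * dt, cmd, v, "cc", level = amp)
  })
  cell <- kna_cell("x", sweeps = list(cc = sweeps))
  expect_equal(rheobase(cell), 90)
  none <- kna_cell("y", sweeps = list(cc = sweeps[1:2]))
  expect_error(rheobase(none), "unbounded")
  # simulator-driven bisection equals the exhaustive scan on the same grid
  p <- neuron_params("dKO")
  rb <- rheobase(p, seed = 3)
  grid <- seq(20, 300, by = 2)
  spikes <- function(a) {
    pr <- step_protocol(a, 20, 0, "cc", pre_ms = 10, post_ms = 20)
    nrow(detect_aps(simulate_current_clamp(p, pr, seed = 3)$sweeps$cc[[1]])) >= 1
  }
  exhaustive <- grid[which(vapply(grid, spikes, logical(1)))[1]]
  expect_equal(rb, exhaustive)
})

test_that("dKO rheobase is below WT rheobase", {
  expect_lt(rheobase(neuron_params("dKO"), seed = 4),
            rheobase(neuron_params("WT"), seed = 4))
})

test_that("rheobase does not increase as the KNa conductance is reduced", {
  rbs <- vapply(c(69, 35, 17, 0), function(g) {
    p <- neuron_params(if (g == 0) "dKO" else "WT")
    p$kna$gmax_wholecell <- g
    rheobase(p, seed = 4)
  }, numeric(1))
  expect_true(all(diff(rbs) <= 0))
})

test_that("AP shape features: triangular geometry and constructed crossings", {
  dt <- 0.005
  spk <- triangle_spike(base_v = -60, peak_v = 40, base_ms = 4, dt = dt)
  v <- c(rep(-60, 4000), spk, rep(-60, 12000))
  tr <- make_cc_sweep(v, dt)
  f <- ap_shape_features(tr)
  # threshold for a linear upstroke sits at the foot; amplitude ~ 100 mV, so
  # half-amplitude crossings are at half the rise: width = base/2
  expect_equal(f$half_width_ms, 2, tolerance = 0.15)
  expect_equal(f$peak_v, 40, tolerance = 0.5)
  expect_lt(f$threshold_v, -50)
  expect_false(f$clipped)
  # clipping flag: flatten the peak
  vc <- pmin(v, 20)
  expect_true(ap_shape_features(make_cc_sweep(vc, dt))$clipped)
})

test_that("WT template AHP is near the -74 mV scale", {
  p <- neuron_params("WT")
  pr <- step_protocol(100, 20, 0, "cc", pre_ms = 10, post_ms = 80)
  f <- ap_shape_features(simulate_current_clamp(p, pr, seed = 3)$sweeps$cc[[1]])
  expect_gt(f$ahp_v, -88)
  expect_lt(f$ahp_v, -64)
  expect_lt(f$threshold_v, f$peak_v)
  expect_gt(f$half_width_ms, 0)
})

test_that("f-I curves: passive silence, genotype ordering, crossing oracle", {
  pr <- step_protocol(c(60, 100, 200), 1000, 0, "cc", pre_ms = 100,
                      post_ms = 100)
  passive <- neuron_params("WT", noise_sd_cc = 0)
  passive$fast_nav$gmax <- 0
  fp <- fi_curve(simulate_current_clamp(passive, pr, seed = 1))
  expect_true(all(fp$count == 0))
  cw <- simulate_current_clamp(neuron_params("WT"), pr, seed = 2)
  cd <- simulate_current_clamp(neuron_params("dKO"), pr, seed = 2)
  fw <- fi_curve(cw); fd <- fi_curve(cd)
  expect_true(all(fd$count >= fw$count))
  expect_gt(sum(fd$count), sum(fw$count))
  # monotone non-decreasing in injected current for both genotypes
  expect_true(all(diff(fw$count) >= 0))
  expect_true(all(diff(fd$count) >= 0))
  # counts equal the brute-force crossing oracle
  oc <- vapply(cd$sweeps$cc, function(s)
    oracle_crossing_count(knaephys:::.smooth_ma(s$recorded, 5), 0), numeric(1))
  expect_equal(fd$count, oc)
})

test_that("ramp zero crossing: linear current, ordering, oversampling", {
  # linear I(V) = g (V - E): the unique crossing is at E
  rp <- ramp_protocol(-60, -5, 40)
  cmd <- protocol_command(rp, 1)
  i <- 1.2 * (cmd$command + 35)
  s <- kna_sweep(cmd$time_ms, cmd$command, i, "vc")
  expect_equal(ramp_zero_crossing(s), -35, tolerance = 0.05)
  # no crossing: all outward
  s_pos <- kna_sweep(cmd$time_ms, cmd$command, abs(i) + 5, "vc")
  expect_error(ramp_zero_crossing(s_pos), "no zero crossing")
  # genotype ordering on the simulated ramp (0 mM pipette Na)
  cr <- vapply(c("WT", "dKO"), function(g) {
    ramp_zero_crossing(simulate_voltage_clamp(neuron_params(g), rp, 0, 180,
                                              seed = 4)$sweeps$vc[[1]])
  }, numeric(1))
  expect_lt(cr["dKO"], cr["WT"])
  # interpolated crossing within one coarse sample of a 100x-oversampled
  # evaluation of the same smooth current (outward hump then inward surge)
  f_i <- function(v) 20 + 2 * (v + 60) - 300 / (1 + exp(-(v + 25) / 2))
  coarse <- kna_sweep(cmd$time_ms, cmd$command, f_i(cmd$command), "vc")
  x <- ramp_zero_crossing(coarse, smooth_points = 1)
  vv_fine <- seq(-60, -5, length.out = sum(cmd$command > -60 | TRUE) * 100)
  ii_fine <- f_i(vv_fine)
  k <- which(ii_fine[-length(ii_fine)] >= 0 & ii_fine[-1] < 0)
  x_fine <- vv_fine[k[length(k)]]
  dv_per_sample <- 55 / (40 / rp$dt_ms)
  expect_lt(abs(x - x_fine), dv_per_sample + 1e-9)
})

test_that("input resistance: reciprocal law, template scale, regression", {
  s <- ohmic_vc_sweep(0.8, -60, pre = -60, step = -70)
  r <- input_resistance(s)
  expect_equal(r$r_mohm, 1250, tolerance = 1e-6)
  expect_false(r$unreliable)
  # matches the closed-form OLS slope across the two plateau means
  expect_equal(r$r_mohm, 1000 * r$delta_v_mv / r$delta_i_pa)
  # WT template lands on the GOhm scale
  rinp <- step_protocol(-70, 100, -60, "vc", pre_ms = 50, post_ms = 10)
  rw <- input_resistance(simulate_voltage_clamp(neuron_params("WT"), rinp, 10,
                                                180, seed = 6)$sweeps$vc[[1]])
  expect_gt(rw$r_mohm, 300)
  expect_lt(rw$r_mohm, 3000)
  # near-zero deflection flags unreliability
  s0 <- ohmic_vc_sweep(1e-5, -60, pre = -60, step = -70)
  expect_true(input_resistance(s0)$unreliable)
})

test_that("train AHP: zero-pulse control, injected dip, train invariance", {
  dt <- 0.02
  # zero pulses returns 0 by definition
  flat <- kna_sweep((0:9999) * dt, rep(0, 10000), rep(-50, 10000), "cc")
  expect_identical(train_ahp(flat, 0), 0)
  # injected artificial slow hyperpolarization is recovered
  n <- 120000
  cmd <- rep(0, n)
  cmd[5001:5500] <- 200                      # one 10 ms pulse
  v <- rep(-50, n)
  dip <- 5501 + 1:25000
  v[dip] <- -50 - 5 * exp(-(seq_along(dip) * dt) / 100)  # -5 mV slow AHP
  tr <- kna_sweep((seq_len(n) - 1) * dt, cmd, v, "cc")
  expect_equal(train_ahp(tr, 1), -5, tolerance = 0.15)
  expect_error(train_ahp(tr, 5), "mismatch")
  # simulated trains: no slow AHP develops with more pulses
  p <- neuron_params("WT")
  ahps <- vapply(c(1, 5, 10), function(np) {
    s <- simulate_current_clamp(p, pulse_train_protocol(np), seed = 3,
                                adjust_to = -50)$sweeps$cc[[1]]
    train_ahp(s, np)
  }, numeric(1))
  expect_lt(abs(ahps[3] - ahps[1]), 1.5)
  expect_lt(abs(ahps[2] - ahps[1]), 1.5)
})

test_that("free resting potential is more negative in WT than dKO", {
  pr <- step_protocol(0, 400, 0, "cc", pre_ms = 0, post_ms = 100)
  mp <- vapply(c("WT", "dKO"), function(g) {
    resting_potential(simulate_current_clamp(neuron_params(g), pr, seed = 5,
                                             adjust_to = NULL)$sweeps$cc[[1]])
  }, numeric(1))
  expect_lt(mp["WT"], mp["dKO"])
  expect_gt(mp["dKO"], -65)
  expect_lt(mp["dKO"], -40)
})
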