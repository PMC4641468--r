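# Independent oracles used across the suite. These re-derive quantities by a
# different route than the package (pure-R integration, exhaustive search,
# closed forms) and are deliberately kept free of package internals.

# Pure-R fixed-step RK4 integration of the same membrane equations, written
# independently of the compiled integrator.
oracle_rk4_cc <- function(p, i_inj_pa, dt, v0, na0) {
  rtf <- 1000 * 8.31446262 * (273.15 + p$temperature) / 96485.33212
  km <- rtf / p$fast_nav$act_z
  kh <- rtf / p$fast_nav$inact_z
  kn <- rtf / p$delayed_rectifier_k$z
  hill <- function(na) {
    r <- (max(na, 0) / p$kna$na_ec50)^p$kna$na_hill
    r / (1 + r)
  }
  der <- function(s, ii) {
    v <- s[1]; m <- s[2]; h <- s[3]; n <- s[4]; na <- s[5]
    ina <- p$fast_nav$gmax * m * h * (v - p$fast_nav$e_na)
    ik <- p$delayed_rectifier_k$gmax * n * (v - p$delayed_rectifier_k$e_k)
    ikna <- p$kna$gmax_wholecell * hill(na) * (v - p$kna$e_k)
    il <- p$passive_leak$g * (v - p$passive_leak$e_rev)
    c((-(ina + ik + ikna + il) + ii) / p$membrane_capacitance,
      (1 / (1 + exp(-(v - p$fast_nav$act_vh) / km)) - m) / p$fast_nav$tau_m,
      (1 / (1 + exp((v - p$fast_nav$inact_vh) / kh)) - h) / p$fast_nav$tau_h,
      (1 / (1 + exp(-(v - p$delayed_rectifier_k$vh) / kn)) - n) /
        p$delayed_rectifier_k$tau_n,
      -ina / (96485.33212 * p$na_handling$shell_volume) -
        (na - p$na_handling$resting_na) / p$na_handling$extrusion_tau)
  }
  m0 <- 1 / (1 + exp(-(v0 - p$fast_nav$act_vh) / km))
  h0 <- 1 / (1 + exp((v0 - p$fast_nav$inact_vh) / kh))
  n0 <- 1 / (1 + exp(-(v0 - p$delayed_rectifier_k$vh) / kn))
  st <- c(v0, m0, h0, n0, na0)
  nst <- length(i_inj_pa)
  v_out <- numeric(nst)
  for (i in seq_len(nst)) {
    v_out[i] <- st[1]
    ii <- i_inj_pa[i]
    k1 <- der(st, ii)
    k2 <- der(st + dt / 2 * k1, ii)
    k3 <- der(st + dt / 2 * k2, ii)
    k4 <- der(st + dt * k3, ii)
    st <- st + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  v_out
}

# steady-state bias current holding the oracle model at v0
oracle_bias <- function(p, v0, na0) {
  rtf <- 1000 * 8.31446262 * (273.15 + p$temperature) / 96485.33212
  m0 <- 1 / (1 + exp(-(v0 - p$fast_nav$act_vh) * p$fast_nav$act_z / rtf))
  h0 <- 1 / (1 + exp((v0 - p$fast_nav$inact_vh) * p$fast_nav$inact_z / rtf))
  n0 <- 1 / (1 + exp(-(v0 - p$delayed_rectifier_k$vh) *
                       p$delayed_rectifier_k$z / rtf))
  r <- (max(na0, 0) / p$kna$na_ec50)^p$kna$na_hill
  po <- r / (1 + r)
  p$fast_nav$gmax * m0 * h0 * (v0 - p$fast_nav$e_na) +
    p$delayed_rectifier_k$gmax * n0 * (v0 - p$delayed_rectifier_k$e_k) +
    p$kna$gmax_wholecell * po * (v0 - p$kna$e_k) +
    p$passive_leak$g * (v0 - p$passive_leak$e_rev)
}

# brute-force AP count: upward crossings of a voltage level
oracle_crossing_count <- function(v, level = 0) {
  sum(v[-length(v)] <= level & v[-1] > level)
}

# exhaustive two-sample KS statistic: sup |Fx - Fy| over all pooled points
oracle_ks_d <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}

# closed-form OLS slope/intercept from the normal equations
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

# build a synthetic current-clamp sweep from a voltage vector
make_cc_sweep <- function(v, dt = 0.02, command = rep(0, length(v))) {
  kna_sweep((seq_along(v) - 1) * dt, command, v, "cc")
}

# stereotyped triangular spike rising from base to peak and back
triangle_spike <- function(base_v = -60, peak_v = 40, base_ms = 4,
                           dt = 0.01) {
  n_half <- round(base_ms / 2 / dt)
  c(seq(base_v, peak_v, length.out = n_half + 1),
    seq(peak_v, base_v, length.out = n_half + 1)[-1])
}

# ideal ohmic voltage-clamp step sweep: I = g (V - E)
ohmic_vc_sweep <- function(g_ns, e_rev, pre = -80, step = -120, dt = 0.02,
                           pre_ms = 50, step_ms = 100, noise = 0) {
  n_pre <- round(pre_ms / dt); n_stp <- round(step_ms / dt)
  cmd <- c(rep(pre, n_pre), rep(step, n_stp), rep(pre, round(10 / dt)))
  i <- g_ns * (cmd - e_rev) + rnorm(length(cmd), 0, noise)
  kna_sweep((seq_along(cmd) - 1) * dt, cmd, i, "vc")
}
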