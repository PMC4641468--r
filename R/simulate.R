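# Sweep and cell-record containers plus the protocol simulators.

#' Construct a sweep
#'
#' A sweep pairs one recorded signal (mV in current clamp, pA in voltage
#' clamp) with its command waveform on a uniform time base.
#'
#' @param time_ms uniform time base (ms).
#' @param command command waveform (pA for "cc", mV for "vc").
#' @param recorded recorded signal (mV for "cc", pA for "vc").
#' @param mode "cc" or "vc".
#' @param time_since_breakin_s seconds since whole-cell break-in (NA if not
#'   applicable).
#' @param bath bath condition, "control" or "Cs20mM".
#' @param protocol optional \code{kna_protocol} the sweep belongs to.
#' @param level stimulus level of this sweep (pA or mV).
#' @return an object of class \code{kna_sweep}.
#' @export
kna_sweep <- function(time_ms, command, recorded, mode,
                      time_since_breakin_s = NA_real_, bath = "control",
                      protocol = NULL, level = NA_real_) {
  if (length(time_ms) != length(command) || length(command) != length(recorded))
    stop("time, command and recorded arrays must have equal length")
  s <- list(time_ms = time_ms, command = command, recorded = recorded,
            mode = mode, dt_ms = time_ms[2] - time_ms[1],
            time_since_breakin_s = time_since_breakin_s, bath = bath,
            protocol = protocol, level = level)
  class(s) <- "kna_sweep"
  s
}

#' @export
print.kna_sweep <- function(x, ...) {
  cat(sprintf("%s sweep: %d samples @ %g ms (%.0f ms), level %g, bath %s\n",
              x$mode, length(x$time_ms), x$dt_ms,
              max(x$time_ms), x$level, x$bath))
  invisible(x)
}

#' @export
plot.kna_sweep <- function(x, ...) {
  ylab <- if (x$mode == "cc") "V (mV)" else "I (pA)"
  graphics::plot(x$time_ms, x$recorded, type = "l", xlab = "time (ms)",
                 ylab = ylab, ...)
  invisible(x)
}

#' Construct a cell record
#'
#' @param id cell identifier.
#' @param genotype genotype label.
#' @param pipette_na pipette Na+ concentration (mM).
#' @param capacitance membrane capacitance (pF).
#' @param ib4_status "IB4+" or "IB4-".
#' @param params the \code{kna_params} used to generate the cell (or NULL for
#'   imported data).
#' @param sweeps named list of sweep lists, grouped by protocol name.
#' @param seed per-cell RNG seed used by the generator.
#' @return an object of class \code{kna_cell}.
#' @export
kna_cell <- function(id, genotype = "WT", pipette_na = 10,
                     capacitance = NA_real_, ib4_status = "IB4+",
                     params = NULL, sweeps = list(), seed = NA_integer_) {
  if (pipette_na < 0) stop("pipette_na must be >= 0")
  c0 <- list(id = id, genotype = genotype, pipette_na = pipette_na,
             capacitance = capacitance, ib4_status = ib4_status,
             params = params, sweeps = sweeps, seed = seed)
  class(c0) <- "kna_cell"
  c0
}

#' @export
print.kna_cell <- function(x, ...) {
  cat(sprintf("cell %s (%s, %s, %g mM pipette Na+)\n",
              x$id, x$genotype, x$ib4_status, x$pipette_na))
  for (nm in names(x$sweeps))
    cat(sprintf("  %s: %d sweep(s)\n", nm, length(x$sweeps[[nm]])))
  invisible(x)
}

# pack model parameters for the compiled integrator
.pack_pars <- function(p, gkna = p$kna$gmax_wholecell, narest = NULL) {
  rtf <- rtf_mv(p$temperature)
  if (is.null(narest)) narest <- p$na_handling$resting_na
  list(C = p$membrane_capacitance,
       gna = p$fast_nav$gmax, vhm = p$fast_nav$act_vh,
       km = rtf / p$fast_nav$act_z,
       vhh = p$fast_nav$inact_vh, kh = rtf / p$fast_nav$inact_z,
       taum = p$fast_nav$tau_m, tauh = p$fast_nav$tau_h,
       ena = p$fast_nav$e_na,
       gk = p$delayed_rectifier_k$gmax, vhn = p$delayed_rectifier_k$vh,
       kn = rtf / p$delayed_rectifier_k$z,
       taun = p$delayed_rectifier_k$tau_n, ek = p$delayed_rectifier_k$e_k,
       gl = p$passive_leak$g, el = p$passive_leak$e_rev,
       gkna = gkna, ec50 = p$kna$na_ec50, hill = p$kna$na_hill,
       ekna = p$kna$e_k,
       navol = p$na_handling$shell_volume,
       taux = p$na_handling$extrusion_tau,
       narest = narest)
}

.gate_ss <- function(pp, v) {
  list(m = 1 / (1 + exp(-(v - pp$vhm) / pp$km)),
       h = 1 / (1 + exp((v - pp$vhh) / pp$kh)),
       n = 1 / (1 + exp(-(v - pp$vhn) / pp$kn)))
}

# total steady-state ionic current at voltage v with shell Na at rest
.iss <- function(pp, v) {
  g <- .gate_ss(pp, v)
  po <- kna_hill(pp$narest, pp$ec50, pp$hill)
  pp$gna * g$m * g$h * (v - pp$ena) + pp$gk * g$n * (v - pp$ek) +
    pp$gkna * po * (v - pp$ekna) + pp$gl * (v - pp$el)
}

#' Zero-current resting potential of the model
#'
#' Solves the steady-state current balance for the free resting potential
#' (no bias current), with submembrane Na+ at its resting value.
#'
#' @param params a \code{kna_params} object.
#' @param interval search interval (mV).
#' @return resting potential (mV).
#' @export
model_resting_potential <- function(params, interval = c(-95, -20)) {
  pp <- .pack_pars(params)
  uniroot(function(v) .iss(pp, v), interval, tol = 1e-10)$root
}

#' Simulate a current-clamp protocol
#'
#' Integrates the membrane equation C dV/dt = -sum(I_ion) + I_inj with a
#' fixed-step fourth-order Runge-Kutta method at the protocol's sample
#' interval. Submembrane [Na+] increments with Nav influx and decays back to
#' its resting value with the extrusion time constant; the KNa conductance
#' follows [Na+] instantaneously through a Hill function. Before the stimulus
#' the membrane is held at \code{adjust_to} by a constant bias current (as in
#' recordings where the resting potential is adjusted by DC injection);
#' \code{adjust_to = NULL} leaves the cell at its free resting potential.
#' Gaussian recording noise is added to the voltage trace.
#'
#' @param params a \code{kna_params} object.
#' @param protocol a current-clamp \code{kna_protocol} ("cc").
#' @param seed integer seed; identical seeds give identical output.
#' @param adjust_to holding potential maintained by bias current (mV), or
#'   NULL for the free resting potential.
#' @param pipette_na pipette Na+ (mM), recorded as metadata. Over the 0-10 mM
#'   range used in current clamp the submembrane resting Na+ stays at its
#'   basal value (\code{na_handling$resting_na}): extrusion keeps the shell
#'   below the KNa activation range, which is why firing is insensitive to
#'   pipette Na+ in this range.
#' @return a \code{kna_cell} with one sweep per protocol level under
#'   \code{sweeps$cc}.
#' @export
simulate_current_clamp <- function(params, protocol, seed = 1,
                                   adjust_to = -60, pipette_na = NULL) {
  validate_params(params)
  stopifnot(inherits(protocol, "kna_protocol"), protocol$mode == "cc")
  if (is.null(pipette_na)) pipette_na <- params$na_handling$resting_na
  if (pipette_na < 0) stop("pipette_na must be >= 0")
  pp <- .pack_pars(params, narest = params$na_handling$resting_na)
  if (is.null(adjust_to)) {
    v0 <- uniroot(function(v) .iss(pp, v), c(-95, -20), tol = 1e-10)$root
    bias <- 0
  } else {
    v0 <- adjust_to
    bias <- .iss(pp, v0)
  }
  g0 <- .gate_ss(pp, v0)
  set.seed(seed)
  sweeps <- vector("list", length(protocol$levels))
  for (i in seq_along(protocol$levels)) {
    cmd <- protocol_command(protocol, i)
    out <- .cc_rk4(pp, cmd$command + bias, protocol$dt_ms,
                   v0, g0$m, g0$h, g0$n, params$na_handling$resting_na)
    v <- out$V + rnorm(length(out$V), 0, params$noise_sd_cc)
    sweeps[[i]] <- kna_sweep(cmd$time_ms, cmd$command, v, "cc",
                             protocol = protocol,
                             level = protocol$levels[i])
  }
  kna_cell(id = sprintf("sim-cc-%d", seed), genotype = params$genotype,
           pipette_na = pipette_na, capacitance = params$membrane_capacitance,
           params = params, sweeps = list(cc = sweeps), seed = seed)
}

#' Simulate a voltage-clamp protocol
#'
#' The membrane potential follows the command exactly; gating variables and
#' submembrane [Na+] are integrated along it and the total ionic current is
#' returned per sweep. The whole-cell KNa conductance is scaled by the
#' pipette-dialysis factor (1 - exp(-t/tau_eq)) * exp(-t/tau_run) evaluated at
#' each sweep's time since break-in, so it is exactly zero at break-in, rises
#' over the first minutes and runs down slowly thereafter; the Nav conductance
#' is unaffected by dialysis. With \code{bath = "Cs20mM"} all K+ currents are
#' scaled by (1 - f(V)) where f is the voltage-dependent Cs+ block curve.
#'
#' @param params a \code{kna_params} object.
#' @param protocol a voltage-clamp \code{kna_protocol} ("vc").
#' @param pipette_na pipette Na+ (mM), the dialysed submembrane resting Na+.
#' @param times_since_breakin vector of sweep times since break-in (s).
#' @param bath "control" or "Cs20mM".
#' @param seed integer seed.
#' @param block \code{cs_block} parameters used when bath is "Cs20mM".
#' @return a \code{kna_cell} with sweeps under \code{sweeps$vc}, ordered by
#'   time since break-in then protocol level.
#' @export
simulate_voltage_clamp <- function(params, protocol, pipette_na = 70,
                                   times_since_breakin = 180,
                                   bath = c("control", "Cs20mM"), seed = 1,
                                   block = cs_block()) {
  validate_params(params)
  stopifnot(inherits(protocol, "kna_protocol"), protocol$mode == "vc")
  bath <- match.arg(bath)
  if (pipette_na < 0) stop("pipette_na must be >= 0")
  cs_on <- bath == "Cs20mM"
  cs_k <- rtf_mv(block$temperature) / block$z
  # dialysed submembrane Na+: the pipette level once it exceeds the basal
  # submembrane value maintained by extrusion
  na_rest <- max(params$na_handling$resting_na, pipette_na)
  set.seed(seed)
  sweeps <- list()
  for (t_s in times_since_breakin) {
    scale <- dialysis_factor(t_s, params$dialysis$equilibration_tau,
                             params$dialysis$rundown_tau)
    pp <- .pack_pars(params, gkna = params$kna$gmax_wholecell * scale,
                     narest = na_rest)
    for (i in seq_along(protocol$levels)) {
      cmd <- protocol_command(protocol, i)
      g0 <- .gate_ss(pp, protocol$holding)
      cur <- .vc_rk4(pp, cmd$command, protocol$dt_ms,
                     g0$m, g0$h, g0$n, na_rest,
                     cs_on, block$A, block$v_h, cs_k)
      cur <- cur + rnorm(length(cur), 0, params$noise_sd_vc)
      sweeps[[length(sweeps) + 1]] <-
        kna_sweep(cmd$time_ms, cmd$command, cur, "vc",
                  time_since_breakin_s = t_s, bath = bath,
                  protocol = protocol, level = protocol$levels[i])
    }
  }
  kna_cell(id = sprintf("sim-vc-%d", seed), genotype = params$genotype,
           pipette_na = pipette_na, capacitance = params$membrane_capacitance,
           params = params, sweeps = list(vc = sweeps), seed = seed)
}

#' Simulate a single-channel record from an inside-out patch
#'
#' Two-state Markov gating with stationary open probability given by the Hill
#' function of bath (cytosolic-face) Na+; the open-level amplitude is
#' unitary_conductance * (V - E_K) with E_K for the inside-out solutions.
#' Dwell times are exponential with the stated mean open time.
#'
#' @param params a \code{kna_params} object.
#' @param voltage patch potential (mV).
#' @param duration_ms record duration (ms).
#' @param bath_na Na+ at the cytosolic face (mM).
#' @param seed integer seed.
#' @param dt_ms sample interval (ms).
#' @param e_k reversal potential for the inside-out solutions (mV); the
#'   default is the Nernst potential of the 152.5/73.6 mM K+ solution pair.
#' @param mean_open_ms mean open dwell time (ms).
#' @param noise_sd recording noise sd (pA).
#' @return an object of class \code{kna_single_channel} with fields
#'   \code{time_ms}, \code{current}, \code{voltage}, \code{bath_na},
#'   \code{po_true}, \code{unitary_pa}.
#' @export
simulate_single_channel <- function(params, voltage, duration_ms = 30000,
                                    bath_na = 70, seed = 1, dt_ms = 0.1,
                                    e_k = NULL, mean_open_ms = 4,
                                    noise_sd = 0.8) {
  validate_params(params)
  stopifnot(duration_ms > 0, bath_na >= 0)
  if (is.null(e_k)) e_k <- nernst(152.5, 73.6, 1, params$temperature)
  po <- kna_hill(bath_na, params$kna$na_ec50, params$kna$na_hill)
  amp <- params$kna$unitary_conductance / 1000 * (voltage - e_k)  # pA
  n <- round(duration_ms / dt_ms)
  tm <- (seq_len(n) - 1) * dt_ms
  set.seed(seed)
  if (po <= 0) {
    open <- rep(0, n)
  } else if (po >= 1) {
    open <- rep(1, n)
  } else {
    rate_open <- 1 / mean_open_ms                      # close rate
    rate_closed <- po / (1 - po) / mean_open_ms        # open rate
    s0 <- as.integer(runif(1) < po)
    dwells <- numeric(0)
    while (sum(dwells) < duration_ms) {
      k <- length(dwells)
      states <- (s0 + k + seq_len(2048) - 1) %% 2      # 1 = open
      rates <- ifelse(states == 1, rate_open, rate_closed)
      dwells <- c(dwells, rexp(2048, rate = rates))
    }
    edges <- cumsum(dwells)
    idx <- findInterval(tm, edges) + 1                 # dwell index per sample
    open <- (s0 + idx - 1) %% 2
  }
  cur <- open * amp + rnorm(n, 0, noise_sd)
  rec <- list(time_ms = tm, current = cur, voltage = voltage,
              bath_na = bath_na, po_true = po, unitary_pa = amp,
              e_k = e_k, dt_ms = dt_ms)
  class(rec) <- "kna_single_channel"
  rec
}

#' @export
print.kna_single_channel <- function(x, ...) {
  cat(sprintf(
    "single-channel record: %.1f s @ %g mV, bath Na+ %g mM, Po %.3f, i %.2f pA\n",
    max(x$time_ms) / 1000, x$voltage, x$bath_na, x$po_true, x$unitary_pa))
  invisible(x)
}

#' Generate a cohort of model cells
#'
#' Draws \code{n_cells} parameter sets around a genotype template by
#' log-normal perturbation of the maximal conductances and the capacitance
#' (multiplicative factors with mean 1 and fractional sd \code{variability}).
#' Each cell carries its own RNG sub-seed, derived deterministically from the
#' cohort seed by a fixed-stride counter, so cohorts are reproducible and
#' cells independent.
#'
#' @param n_cells number of cells (>= 1).
#' @param genotype genotype template passed to \code{\link{neuron_params}}.
#' @param pipette_na pipette Na+ (mM).
#' @param variability fractional sd of the perturbed parameters (>= 0).
#' @param seed cohort seed.
#' @param template optional \code{kna_params} to perturb instead of the
#'   genotype default.
#' @return list of \code{kna_cell} objects (sweeps empty; simulate per cell).
#' @export
make_cohort <- function(n_cells, genotype = "WT", pipette_na = 10,
                        variability = 0.25, seed = 1, template = NULL) {
  stopifnot(n_cells >= 1, variability >= 0)
  if (is.null(template)) template <- neuron_params(genotype)
  sdlog <- sqrt(log(1 + variability^2))
  cells <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    sub_seed <- (seed + 104729L * i) %% .Machine$integer.max
    set.seed(sub_seed)
    f <- if (variability > 0)
      exp(rnorm(5, mean = -sdlog^2 / 2, sd = sdlog)) else rep(1, 5)
    p <- template
    p$membrane_capacitance <- p$membrane_capacitance * f[1]
    p$fast_nav$gmax <- p$fast_nav$gmax * f[2]
    p$delayed_rectifier_k$gmax <- p$delayed_rectifier_k$gmax * f[3]
    p$passive_leak$g <- p$passive_leak$g * f[4]
    p$kna$gmax_wholecell <- p$kna$gmax_wholecell * f[5]
    cells[[i]] <- kna_cell(id = sprintf("%s-%03d", genotype, i),
                           genotype = genotype, pipette_na = pipette_na,
                           capacitance = p$membrane_capacitance,
                           params = p, seed = sub_seed)
  }
  cells
}
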