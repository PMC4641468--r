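#' @useDynLib knaephys, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats coef lm median nls predict quantile rnorm runif sd setNames
#'   t.test ks.test uniroot complete.cases dnorm rexp var
#' @importFrom utils read.csv write.csv head tail
NULL

# Physical constants
.FARADAY <- 96485.33212   # C/mol
.GAS_R   <- 8.31446262    # J/(mol K)

#' Thermal voltage RT/F in mV
#'
#' @param temperature temperature in degrees Celsius.
#' @return RT/F in mV.
#' @export
rtf_mv <- function(temperature = 19) {
  1000 * .GAS_R * (273.15 + temperature) / .FARADAY
}

#' Conductance-based DRG neuron model parameters
#'
#' Builds the parameter set of the single-compartment model: a fast transient
#' Nav conductance (Boltzmann activation, first-order inactivation), a delayed
#' rectifier K conductance, a passive leak, and a KNa conductance gated
#' instantaneously by submembrane [Na+] through a Hill function. Na+ entering
#' through Nav channels accumulates in a thin submembrane shell and is cleared
#' with a first-order extrusion time constant, so KNa activation tracks Na+
#' influx at the foot of the action potential. Whole-cell dialysis dynamics
#' (equilibration and rundown of the KNa conductance during pipette dialysis)
#' are described by two time constants.
#'
#' The dKO genotype (deletion of both Slo2 subunits) removes the KNa
#' conductance entirely; Slo2.2KO does the same since Slo2.2 carries the
#' current in these neurons, while Slo2.1KO leaves it intact.
#'
#' @param genotype one of "WT", "Slo2.1KO", "Slo2.2KO", "dKO".
#' @param membrane_capacitance cell capacitance (pF).
#' @param fast_nav list: gmax (nS), act_vh (mV), act_z (e), inact_vh (mV),
#'   inact_z (e), tau_m (ms), tau_h (ms), e_na (mV).
#' @param delayed_rectifier_k list: gmax (nS), vh (mV), z (e), tau_n (ms),
#'   e_k (mV).
#' @param passive_leak list: g (nS), e_rev (mV).
#' @param kna list: gmax_wholecell (nS), unitary_conductance (pS), e_k (mV),
#'   na_ec50 (mM), na_hill, voltage_dependence_flag.
#' @param na_handling list: shell_volume (pl), extrusion_tau (ms),
#'   resting_na (mM).
#' @param dialysis list: equilibration_tau (s), rundown_tau (s).
#' @param noise_sd_cc current-clamp recording noise sd (mV).
#' @param noise_sd_vc voltage-clamp recording noise sd (pA).
#' @param temperature recording temperature (degrees C).
#' @return an object of class \code{kna_params}.
#' @export
neuron_params <- function(genotype = "WT",
                          membrane_capacitance = 16.1,
                          fast_nav = list(gmax = 60, act_vh = -10, act_z = 4.1,
                                          inact_vh = -42, inact_z = 4.5,
                                          tau_m = 0.3, tau_h = 14, e_na = 60),
                          delayed_rectifier_k = list(gmax = 80, vh = -5, z = 4,
                                                     tau_n = 14, e_k = -80),
                          passive_leak = list(g = 0.8, e_rev = -60),
                          kna = list(gmax_wholecell = 69,
                                     unitary_conductance = 127,
                                     e_k = -80, na_ec50 = 40, na_hill = 3.5,
                                     voltage_dependence_flag = FALSE),
                          na_handling = list(shell_volume = 0.002,
                                             extrusion_tau = 25,
                                             resting_na = 10),
                          dialysis = list(equilibration_tau = 60,
                                          rundown_tau = 900),
                          noise_sd_cc = 0.3,
                          noise_sd_vc = 5,
                          temperature = 19) {
  genotype <- match.arg(genotype, c("WT", "Slo2.1KO", "Slo2.2KO", "dKO"))
  if (genotype %in% c("Slo2.2KO", "dKO")) kna$gmax_wholecell <- 0
  p <- list(genotype = genotype,
            membrane_capacitance = membrane_capacitance,
            fast_nav = fast_nav,
            delayed_rectifier_k = delayed_rectifier_k,
            passive_leak = passive_leak,
            kna = kna,
            na_handling = na_handling,
            dialysis = dialysis,
            noise_sd_cc = noise_sd_cc,
            noise_sd_vc = noise_sd_vc,
            temperature = temperature)
  class(p) <- "kna_params"
  validate_params(p)
  p
}

#' Validate a neuron parameter set
#'
#' Checks the structural invariants of the model: non-negative conductances,
#' positive EC50 and capacitance, dialysis equilibration faster than rundown,
#' and zero KNa conductance for KNa-null genotypes.
#'
#' @param p a \code{kna_params} object.
#' @return \code{p}, invisibly; signals an error on violation.
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "kna_params"))
  gs <- c(p$fast_nav$gmax, p$delayed_rectifier_k$gmax, p$passive_leak$g,
          p$kna$gmax_wholecell)
  if (any(!is.finite(gs)) || any(gs < 0))
    stop("all conductances must be finite and >= 0")
  if (p$membrane_capacitance <= 0) stop("membrane_capacitance must be > 0")
  if (p$kna$na_ec50 <= 0) stop("kna$na_ec50 must be > 0")
  if (p$na_handling$shell_volume <= 0) stop("shell_volume must be > 0")
  if (p$na_handling$extrusion_tau <= 0) stop("extrusion_tau must be > 0")
  if (p$dialysis$equilibration_tau >= p$dialysis$rundown_tau)
    stop("dialysis equilibration_tau must be < rundown_tau")
  if (p$genotype %in% c("dKO", "Slo2.2KO") && p$kna$gmax_wholecell != 0)
    stop("KNa-null genotype requires kna$gmax_wholecell == 0")
  invisible(p)
}

#' @export
print.kna_params <- function(x, ...) {
  cat("DRG neuron model parameters (", x$genotype, ")\n", sep = "")
  cat(sprintf("  Cm = %.1f pF, T = %.0f C\n",
              x$membrane_capacitance, x$temperature))
  cat(sprintf("  Nav: gmax %.0f nS, Vh %.1f mV, z %.1f e\n",
              x$fast_nav$gmax, x$fast_nav$act_vh, x$fast_nav$act_z))
  cat(sprintf("  Kdr: gmax %.0f nS; leak: %.2f nS @ %.0f mV\n",
              x$delayed_rectifier_k$gmax, x$passive_leak$g,
              x$passive_leak$e_rev))
  cat(sprintf("  KNa: gmax %.0f nS, EC50 %.0f mM, Hill %.1f, unitary %.0f pS\n",
              x$kna$gmax_wholecell, x$kna$na_ec50, x$kna$na_hill,
              x$kna$unitary_conductance))
  invisible(x)
}

#' Hill activation of the KNa conductance by Na+
#'
#' @param na submembrane or bath Na+ concentration (mM).
#' @param ec50 half-activation concentration (mM).
#' @param hill Hill coefficient.
#' @return open probability in [0, 1].
#' @export
kna_hill <- function(na, ec50 = 40, hill = 3.5) {
  na <- pmax(na, 0)
  na^hill / (na^hill + ec50^hill)
}

#' Dialysis scaling of the whole-cell KNa conductance
#'
#' The KNa conductance grows as pipette Na+ equilibrates into the cell
#' (1 - exp(-t/tau_eq)) and declines by slow rundown (exp(-t/tau_run));
#' at break-in (t = 0) the factor is exactly 0.
#'
#' @param t_s time since whole-cell break-in (s).
#' @param equilibration_tau equilibration time constant (s).
#' @param rundown_tau rundown time constant (s).
#' @return dimensionless scale factor in [0, 1].
#' @export
dialysis_factor <- function(t_s, equilibration_tau = 60, rundown_tau = 900) {
  stopifnot(all(t_s >= 0))
  (1 - exp(-t_s / equilibration_tau)) * exp(-t_s / rundown_tau)
}
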