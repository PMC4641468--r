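# Closed-form biophysical calculations: chord-conductance resting potential,
# Nernst potentials, Boltzmann chord-conductance fits, linear resting
# conductance, single-channel conductance.

#' Chord-conductance membrane potential model
#'
#' The resting potential is modelled as the conductance-weighted average of
#' the branch reversal potentials, V_m = sum(g_i E_i) / sum(g_i) — the unique
#' zero of the total chord current sum(g_i (V - E_i)). The defaults are a
#' background K+, Na+ and Cl- conductance balance for a small DRG neuron
#' (total 1.165 nS, basal V_m = -52.4 mV); an added KNa branch reverses at
#' E_K.
#'
#' @param g_k,g_na,g_cl branch conductances (nS).
#' @param e_k,e_na,e_cl branch reversal potentials (mV).
#' @param g_kna added KNa conductance (nS, >= 0, reversal \code{e_k}).
#' @return an object of class \code{chord_model}.
#' @export
chord_model <- function(g_k = 0.7, g_na = 0.165, g_cl = 0.3, g_kna = 0,
                        e_k = -80, e_na = 60, e_cl = -50) {
  if (g_kna < 0) stop("g_kna must be >= 0")
  m <- list(branches = data.frame(
    label = c("K", "Na", "Cl", "KNa"),
    g = c(g_k, g_na, g_cl, g_kna),
    e_rev = c(e_k, e_na, e_cl, e_k),
    stringsAsFactors = FALSE))
  if (any(m$branches$g < 0)) stop("conductances must be >= 0")
  if (sum(m$branches$g) <= 0) stop("total conductance must be > 0")
  class(m) <- "chord_model"
  m
}

#' @export
print.chord_model <- function(x, ...) {
  cat("chord-conductance membrane potential model\n")
  print(x$branches, row.names = FALSE)
  cat(sprintf("  V_m = %.2f mV (total g = %.3f nS)\n",
              chord_vm(x), sum(x$branches$g)))
  invisible(x)
}

#' Membrane potential of a chord-conductance model
#'
#' @param model a \code{chord_model}, or a data.frame with columns \code{g}
#'   and \code{e_rev}.
#' @return membrane potential (mV).
#' @export
chord_vm <- function(model) {
  br <- if (inherits(model, "chord_model")) model$branches else model
  g <- br$g
  if (sum(g) <= 0) stop("total conductance must be > 0")
  sum(g * br$e_rev) / sum(g)
}

#' Sweep the added KNa conductance of a chord model
#'
#' Adds KNa conductance in fixed increments and tabulates the resulting
#' membrane potential, total conductance, effective open probability
#' Po = g_KNa / g_max_kna (fraction of the maximal whole-cell KNa
#' conductance), and the expected KNa current g_KNa * (V - E_K) at a stated
#' evaluation voltage. Two current columns are reported: at the fixed
#' \code{eval_voltage} and at the model's own V_m for each row.
#'
#' @param model base \code{chord_model} (its g_kna is replaced by the sweep).
#' @param increment g_KNa increment (nS).
#' @param n_steps number of increments beyond zero.
#' @param g_max_kna maximal whole-cell KNa conductance (nS).
#' @param eval_voltage voltage at which the expected KNa current is reported
#'   (mV).
#' @return data.frame of class \code{gkna_sweep} with columns \code{g_kna},
#'   \code{v_m}, \code{g_total}, \code{po}, \code{i_kna_eval},
#'   \code{i_kna_at_vm}.
#' @export
gkna_sweep <- function(model = chord_model(), increment = 0.02, n_steps = 50,
                       g_max_kna = 69, eval_voltage = -50) {
  stopifnot(increment > 0, n_steps >= 1, g_max_kna > 0)
  e_k <- model$branches$e_rev[model$branches$label == "K"]
  g <- seq(0, by = increment, length.out = n_steps + 1)
  base <- model$branches[model$branches$label != "KNa", ]
  vm <- vapply(g, function(gk) {
    chord_vm(rbind(base, data.frame(label = "KNa", g = gk, e_rev = e_k)))
  }, numeric(1))
  out <- data.frame(g_kna = g, v_m = vm, g_total = sum(base$g) + g,
                    po = g / g_max_kna,
                    i_kna_eval = g * (eval_voltage - e_k),
                    i_kna_at_vm = g * (vm - e_k))
  attr(out, "eval_voltage") <- eval_voltage
  class(out) <- c("gkna_sweep", "data.frame")
  out
}

#' @export
plot.gkna_sweep <- function(x, ...) {
  graphics::plot(x$g_kna, x$v_m, type = "l", xlab = "g_KNa (nS)",
                 ylab = "V_m (mV)", ...)
  invisible(x)
}

#' Nernst equilibrium potential
#'
#' E = (RT / zF) ln(c_out / c_in).
#'
#' @param c_out,c_in outer and inner concentrations (mM, > 0).
#' @param valence ion valence z.
#' @param temperature temperature (degrees C).
#' @return equilibrium potential (mV).
#' @export
nernst <- function(c_out, c_in, valence = 1, temperature = 19) {
  if (any(c_out <= 0) || any(c_in <= 0))
    stop("concentrations must be > 0")
  rtf_mv(temperature) / valence * log(c_out / c_in)
}

# shared Boltzmann kernel: rising sigmoid with slope RT/(zF)
.boltzmann <- function(v, v_h, z, temperature) {
  1 / (1 + exp(-(v - v_h) * z / rtf_mv(temperature)))
}

# multi-start Levenberg-Marquardt fit helper; returns best converged fit
.multistart_fit <- function(formula, data, start_grid, lower, upper) {
  best <- NULL
  for (i in seq_len(nrow(start_grid))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = data,
                        start = lapply(as.list(start_grid[i, , drop = FALSE]),
                                       unname),
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    stop("fit failure: no start converged; inspect the data range")
  best
}

#' Boltzmann fit to chord-conductance activation data
#'
#' Converts peak inward currents to chord conductances g = I / (V - E_rev)
#' (default E_rev = +75 mV for Nav) and fits the two-state activation curve
#' g(V) = g_max / (1 + exp(-zF (V - V_h) / RT)) by multi-start
#' Levenberg-Marquardt least squares.
#'
#' @param iv data.frame or list with columns/fields \code{v} (mV) and
#'   \code{i} (pA peak current), or \code{g} (nS) directly.
#' @param reversal assumed reversal potential for the chord conversion (mV).
#' @param temperature temperature (degrees C) for the RT/F slope.
#' @return object of class \code{boltzmann_fit} with fields \code{g_max}
#'   (nS), \code{v_h} (mV), \code{z} (e), \code{reversal}, \code{residual_norm},
#'   \code{vcov}, \code{large_z_flag}.
#' @export
boltzmann_chord_fit <- function(iv, reversal = 75, temperature = 19) {
  iv <- as.data.frame(iv)
  if (!"g" %in% names(iv)) {
    if (any(iv$v == reversal))
      stop("all voltages must differ from the assumed reversal")
    iv$g <- iv$i / (iv$v - reversal)
  }
  if (nrow(iv) < 5) stop("need >= 5 (V, I) points spanning activation")
  if (all(abs(iv$g) < 1e-12)) stop("fit failure: all conductances are zero")
  rtf <- rtf_mv(temperature)
  grid <- expand.grid(g_max = max(iv$g) * c(1, 1.5),
                      v_h = quantile(iv$v, c(0.2, 0.4, 0.6, 0.8)),
                      z = c(1, 3, 6))
  best <- .multistart_fit(
    g ~ g_max / (1 + exp(-(v - v_h) * z / rtf)),
    data = cbind(iv, rtf = rtf), start_grid = grid,
    lower = c(g_max = 0, v_h = min(iv$v) - 50, z = 0.01),
    upper = c(g_max = Inf, v_h = max(iv$v) + 50, z = 100))
  cf <- coef(best$fit)
  out <- list(g_max = unname(cf["g_max"]), v_h = unname(cf["v_h"]),
              z = unname(cf["z"]), reversal = reversal,
              temperature = temperature,
              residual_norm = sqrt(best$rss),
              vcov = tryCatch(stats::vcov(best$fit), error = function(e) NULL),
              large_z_flag = unname(cf["z"]) > 20,
              data = iv)
  class(out) <- "boltzmann_fit"
  out
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf(
    "Boltzmann chord-conductance fit: g_max = %.3g nS, V_h = %.2f mV, z = %.2f e\n",
    x$g_max, x$v_h, x$z))
  if (x$large_z_flag)
    cat("  note: very steep activation (z > 20e); V_h marks a step\n")
  invisible(x)
}

#' @export
coef.boltzmann_fit <- function(object, ...) {
  c(g_max = object$g_max, v_h = object$v_h, z = object$z)
}

#' @export
predict.boltzmann_fit <- function(object, v, ...) {
  object$g_max * .boltzmann(v, object$v_h, object$z, object$temperature)
}

#' @export
plot.boltzmann_fit <- function(x, ...) {
  graphics::plot(x$data$v, x$data$g, xlab = "V (mV)", ylab = "g (nS)", ...)
  vv <- seq(min(x$data$v), max(x$data$v), length.out = 200)
  graphics::lines(vv, predict(x, vv))
  invisible(x)
}

#' Linear fit of the resting conductance from a steady-state I-V
#'
#' Ordinary least-squares slope of steady-state current vs voltage over a
#' hyperpolarized, ohmic voltage range.
#'
#' @param iv data.frame with columns \code{v} (mV) and \code{i} (pA).
#' @param v_range inclusive voltage range used for the fit (mV).
#' @return list with \code{g} (slope, nS), \code{intercept} (pA), \code{n},
#'   and \code{se_g}.
#' @export
linear_conductance_fit <- function(iv, v_range = c(-120, -60)) {
  iv <- as.data.frame(iv)
  keep <- iv$v >= min(v_range) & iv$v <= max(v_range)
  if (sum(keep) < 3)
    stop("insufficient data: need >= 3 points inside the voltage range")
  fit <- lm(i ~ v, data = iv[keep, ])
  cf <- coef(fit)
  se <- tryCatch(suppressWarnings(
    summary(fit)$coefficients["v", "Std. Error"]),
    error = function(e) NA_real_)
  list(g = unname(cf["v"]), intercept = unname(cf["(Intercept)"]),
       n = sum(keep), se_g = se)
}

#' Unitary current amplitude from an all-points histogram
#'
#' Builds the all-points amplitude histogram of a single-channel record and
#' fits the sum of two Gaussians (closed and open levels) to the bin counts;
#' the unitary amplitude is the separation of the two peaks.
#'
#' @param record a \code{kna_single_channel} object, or a numeric current
#'   vector (pA).
#' @param bins number of histogram bins.
#' @return list with \code{amplitude_pa} (open minus closed level),
#'   \code{mu_closed}, \code{mu_open}, \code{open_fraction}.
#' @export
unitary_amplitude <- function(record, bins = 200) {
  cur <- if (inherits(record, "kna_single_channel")) record$current else record
  h <- graphics::hist(cur, breaks = bins, plot = FALSE)
  d <- data.frame(x = h$mids, y = h$counts)
  # initial guesses: closed peak near the mode, open peak at the far tail
  mode_x <- d$x[which.max(d$y)]
  far_x <- if (abs(min(cur) - mode_x) > abs(max(cur) - mode_x))
    quantile(cur, 0.005) else quantile(cur, 0.995)
  s0 <- sd(cur) / 4
  grid <- expand.grid(a1 = max(d$y), mu1 = mode_x, s1 = s0,
                      a2 = max(d$y) * c(0.5, 0.1), mu2 = unname(far_x),
                      s2 = s0)
  best <- .multistart_fit(
    y ~ a1 * exp(-(x - mu1)^2 / (2 * s1^2)) +
        a2 * exp(-(x - mu2)^2 / (2 * s2^2)),
    data = d, start_grid = grid,
    lower = c(a1 = 0, mu1 = min(d$x), s1 = 1e-3,
              a2 = 0, mu2 = min(d$x), s2 = 1e-3),
    upper = c(a1 = Inf, mu1 = max(d$x), s1 = diff(range(d$x)),
              a2 = Inf, mu2 = max(d$x), s2 = diff(range(d$x))))
  cf <- coef(best$fit)
  # the closed level is the peak nearer zero current
  mus <- c(cf["mu1"], cf["mu2"])
  areas <- abs(c(cf["a1"] * cf["s1"], cf["a2"] * cf["s2"]))
  closed_i <- which.min(abs(mus))
  open_i <- 3 - closed_i
  list(amplitude_pa = unname(mus[open_i] - mus[closed_i]),
       mu_closed = unname(mus[closed_i]), mu_open = unname(mus[open_i]),
       open_fraction = unname(areas[open_i] / sum(areas)))
}

#' Single-channel conductance from unitary amplitudes
#'
#' Linear regression of unitary current amplitude on patch potential; the
#' slope is the single-channel (chord) conductance and the zero-current
#' intercept the reversal potential.
#'
#' @param amplitudes data.frame with columns \code{v} (mV) and \code{i}
#'   (unitary amplitude, pA).
#' @return list with \code{gamma_ps} (pS), \code{reversal_mv}, \code{n},
#'   \code{se_gamma_ps}.
#' @export
single_channel_conductance <- function(amplitudes) {
  a <- as.data.frame(amplitudes)
  if (nrow(a) < 2) stop("need amplitudes at >= 2 voltages")
  if (length(unique(a$v)) < 2)
    stop("singular design: amplitudes at a single voltage")
  fit <- lm(i ~ v, data = a)
  cf <- coef(fit)
  slope_ns <- unname(cf["v"])               # pA/mV = nS
  se <- if (nrow(a) > 2)
    suppressWarnings(summary(fit)$coefficients["v", "Std. Error"]) * 1000
  else NA_real_
  list(gamma_ps = slope_ns * 1000,
       reversal_mv = -unname(cf["(Intercept)"]) / slope_ns,
       n = nrow(a), se_gamma_ps = se)
}
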