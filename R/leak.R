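# Quantification of the Na+-dependent background (KNa) current from
# hyperpolarizing-step protocols, and the voltage-dependent Cs+ block model.

# plateau window of a segment [t0, t1]: last `frac` of the segment with the
# first settle_ms excluded.
.plateau_window <- function(t0, t1, frac = 0.25, settle_ms = 2) {
  w0 <- max(t1 - frac * (t1 - t0), t0 + settle_ms)
  c(w0, t1)
}

# locate the stimulus segment of a sweep from its command waveform
.step_bounds <- function(sweep) {
  cmd <- sweep$command
  chg <- which(diff(cmd) != 0)
  if (length(chg) < 1) stop("no step found in the command waveform")
  onset <- chg[1] + 1
  offset <- if (length(chg) >= 2) chg[2] else length(cmd)
  list(onset = sweep$time_ms[onset], offset = sweep$time_ms[offset])
}

.window_mean <- function(sweep, window) {
  if (window[1] < sweep$time_ms[1] || window[2] > tail(sweep$time_ms, 1) + sweep$dt_ms)
    stop(sprintf("window [%g, %g] ms lies outside the sweep", window[1], window[2]))
  sel <- sweep$time_ms >= window[1] & sweep$time_ms <= window[2]
  if (!any(sel)) stop("empty measurement window")
  mean(sweep$recorded[sel])
}

#' Net (difference) current of a hyperpolarizing step
#'
#' For a voltage step (default -80 to -120 mV) the difference current is
#' mean(recorded over the step plateau) minus mean(recorded over the pre-step
#' baseline). Plateau windows default to the last 25 percent of each segment
#' with the first 2 ms excluded to avoid uncompensated capacitive settling.
#' Sign convention: inward current negative, so a K+ background conductance
#' gives a negative difference current on the hyperpolarizing step.
#'
#' @param sweep a voltage-clamp \code{kna_sweep} containing one step.
#' @param step_window optional explicit (start, end) ms window on the step
#'   plateau.
#' @param base_window optional explicit window on the pre-step baseline.
#' @param settle_ms capacitive settling time excluded from each window (ms).
#' @return difference current (pA).
#' @export
leak_difference_current <- function(sweep, step_window = NULL,
                                    base_window = NULL, settle_ms = 2) {
  stopifnot(inherits(sweep, "kna_sweep"), sweep$mode == "vc")
  b <- .step_bounds(sweep)
  if (is.null(step_window))
    step_window <- .plateau_window(b$onset, b$offset, settle_ms = settle_ms)
  if (is.null(base_window))
    base_window <- .plateau_window(sweep$time_ms[1], b$onset - sweep$dt_ms,
                                   settle_ms = min(settle_ms, b$onset / 2))
  .window_mean(sweep, step_window) - .window_mean(sweep, base_window)
}

#' Time course of the Na+-dependent background current
#'
#' Orders the repeated-step sweeps of a cell by time since break-in, measures
#' the difference current of each, and fits the pipette-dialysis model. For
#' series confined to the rising phase the rise-only model
#' dI(t) = I_max (1 - exp(-t/tau_eq)) is fitted; for series extending past
#' ~10 min the full rise-then-rundown product
#' I_max (1 - exp(-t/tau_eq)) exp(-t/tau_run) is used, and a non-monotonic
#' rise-then-fall is flagged when the fitted (or observed) peak lies in the
#' interior of the series.
#'
#' @param cell a \code{kna_cell} whose \code{sweeps$vc} are repeated steps
#'   with \code{time_since_breakin_s} tags.
#' @param rundown_after_s series extending beyond this time fit the full
#'   rise-then-rundown model (s).
#' @return object of class \code{leak_time_course}: data.frame
#'   \code{series(t_s, delta_i_pa)}, \code{equilibration_tau},
#'   \code{rundown_tau}, \code{i_max}, \code{nonmonotonic},
#'   \code{slope_ci} (linear trend 95 percent CI, pA/s).
#' @export
leak_time_course <- function(cell, rundown_after_s = 600) {
  stopifnot(inherits(cell, "kna_cell"))
  sw <- cell$sweeps$vc
  if (is.null(sw) || length(sw) < 3)
    stop("insufficient data: need >= 3 timed step sweeps")
  t_s <- vapply(sw, function(s) s$time_since_breakin_s, numeric(1))
  if (any(is.na(t_s))) stop("sweeps lack time_since_breakin_s tags")
  di <- vapply(sw, leak_difference_current, numeric(1))
  o <- order(t_s)
  ser <- data.frame(t_s = t_s[o], delta_i_pa = di[o])
  lfit <- lm(delta_i_pa ~ t_s, data = ser)
  ci <- stats::confint(lfit)["t_s", ]
  amp0 <- di[which.max(abs(di))]
  full <- max(ser$t_s) > rundown_after_s
  # the rise and the slow rundown are fitted jointly: even series confined to
  # the first minutes carry enough rundown to bias a rise-only fit
  grid <- expand.grid(i_max = amp0 * c(1, 1.5), tau_eq = c(30, 60, 120),
                      tau_run = c(450, 900, 1800))
  fit <- tryCatch(.multistart_fit(
    delta_i_pa ~ i_max * (1 - exp(-t_s / tau_eq)) * exp(-t_s / tau_run),
    data = ser, start_grid = grid,
    lower = c(i_max = -Inf, tau_eq = 1, tau_run = 60),
    upper = c(i_max = Inf, tau_eq = 2000, tau_run = 5e4)),
    error = function(e) NULL)
  cf <- if (!is.null(fit)) coef(fit$fit)
        else c(i_max = NA, tau_eq = NA, tau_run = NA)
  # non-monotonic rise-then-fall: |dI| peaks strictly inside the series
  absd <- abs(ser$delta_i_pa)
  pk <- which.max(absd)
  nonmono <- pk < nrow(ser) &&
    absd[pk] - absd[nrow(ser)] > 0.15 * absd[pk] &&
    ser$t_s[pk] > min(ser$t_s)
  out <- list(series = ser,
              equilibration_tau = unname(cf["tau_eq"]),
              rundown_tau = if (full) unname(cf["tau_run"]) else NA_real_,
              rundown_tau_fitted = unname(cf["tau_run"]),
              i_max = unname(cf["i_max"]),
              nonmonotonic = nonmono,
              slope_ci = ci)
  class(out) <- "leak_time_course"
  out
}

#' @export
print.leak_time_course <- function(x, ...) {
  cat(sprintf("leak time course: %d points, tau_eq = %.1f s", nrow(x$series),
              x$equilibration_tau))
  if (!is.na(x$rundown_tau)) cat(sprintf(", tau_run = %.0f s", x$rundown_tau))
  cat(if (x$nonmonotonic) " (rise-then-fall)\n" else "\n")
  invisible(x)
}

#' @export
plot.leak_time_course <- function(x, ...) {
  graphics::plot(x$series$t_s, x$series$delta_i_pa, xlab = "time (s)",
                 ylab = "difference current (pA)", ...)
  invisible(x)
}

# steady-state current of one sweep: plateau of the step, or the tail of the
# sweep when the command is flat (step level equal to holding)
.steady_state_current <- function(s) {
  b <- tryCatch(.step_bounds(s), error = function(e) NULL)
  if (is.null(b)) {
    tmax <- tail(s$time_ms, 1)
    return(.window_mean(s, .plateau_window(s$time_ms[1], tmax)))
  }
  .window_mean(s, .plateau_window(b$onset, b$offset))
}

# steady-state current per level of a step-family cell record
.iv_from_cell <- function(cell) {
  sw <- cell$sweeps$vc
  v <- vapply(sw, function(s) s$level, numeric(1))
  i <- vapply(sw, .steady_state_current, numeric(1))
  data.frame(v = v, i = i)
}

#' Fractional inhibition by extracellular Cs+
#'
#' Computes f(V) = 1 - I_Cs(V) / I_ctrl(V) from matched steady-state I-V
#' measurements in control and Cs+ bath. An optional 0-Na+ reference (same
#' voltages) is subtracted from both conditions first so f is computed on the
#' Na+-dependent component; by default f is computed on the total current.
#' Voltages where the control current is below the noise floor are excluded
#' and reported; values outside [0, 1] are clipped and flagged.
#'
#' @param control,blocked matched \code{kna_cell} records (step-family
#'   voltage clamp) or data.frames with columns \code{v}, \code{i}.
#' @param baseline optional 0-Na+ reference in the same form.
#' @param noise_floor control currents with |I| below this are excluded (pA).
#' @return data.frame (v, f, clipped) with attribute \code{excluded} listing
#'   voltages dropped for small control current.
#' @export
fractional_inhibition <- function(control, blocked, baseline = NULL,
                                  noise_floor = 25) {
  as_iv <- function(x) if (inherits(x, "kna_cell")) .iv_from_cell(x)
                       else as.data.frame(x)
  ctl <- as_iv(control); blk <- as_iv(blocked)
  m <- merge(ctl, blk, by = "v", suffixes = c("_ctrl", "_cs"))
  if (!is.null(baseline)) {
    b <- as_iv(baseline)
    m <- merge(m, setNames(b, c("v", "i_base")), by = "v")
    m$i_ctrl <- m$i_ctrl - m$i_base
    m$i_cs <- m$i_cs - m$i_base
  }
  excl <- m$v[abs(m$i_ctrl) < noise_floor]
  m <- m[abs(m$i_ctrl) >= noise_floor, ]
  if (nrow(m) == 0) stop("all control currents below the noise floor")
  f <- 1 - m$i_cs / m$i_ctrl
  clipped <- f < 0 | f > 1
  if (any(clipped))
    warning(sprintf("%d fractional-inhibition value(s) clipped to [0, 1]",
                    sum(clipped)))
  out <- data.frame(v = m$v, f = pmin(pmax(f, 0), 1), clipped = clipped)
  attr(out, "excluded") <- excl
  out
}

#' Voltage-dependent Cs+ block parameters
#'
#' The steady-state fraction of K+ current blocked by 20 mM extracellular
#' Cs+ follows f(V) = 1 - A / (1 + exp(-zF (V - V_h) / RT)): complete block
#' in the hyperpolarized limit and a voltage-independent residual block of
#' (1 - A) at depolarized voltages. Defaults are the DRG KNa block values
#' (A = 0.39, V_h = -82.2 mV, z = 0.68 e).
#'
#' @param A amplitude of the voltage-dependent component (0 <= A <= 1).
#' @param v_h half-inhibition voltage of the voltage-dependent component (mV).
#' @param z effective charge of the block (e, > 0).
#' @param temperature temperature (degrees C).
#' @return an object of class \code{cs_block}.
#' @export
cs_block <- function(A = 0.39, v_h = -82.2, z = 0.68, temperature = 19) {
  if (A < 0 || A > 1) stop("A must lie in [0, 1]")
  if (z <= 0) stop("z must be > 0")
  b <- list(A = A, v_h = v_h, z = z, temperature = temperature)
  class(b) <- "cs_block"
  b
}

#' Evaluate the Cs+ block curve
#'
#' @param fit a \code{cs_block} or \code{cs_block_fit} object.
#' @param v voltage(s), mV.
#' @return blocked fraction f(v) in [1 - A, 1].
#' @export
eval_cs_block <- function(fit, v) {
  stopifnot(inherits(fit, "cs_block"))
  1 - fit$A * .boltzmann(v, fit$v_h, fit$z, fit$temperature)
}

#' Fit the voltage-dependent Cs+ block curve
#'
#' Least-squares fit of f(V) = 1 - A / (1 + exp(-zF (V - V_h) / RT)) to
#' fractional-inhibition points, with Levenberg-Marquardt iterations started
#' from a grid of V_h values to avoid local minima. Nearly
#' voltage-independent data (fitted z at its floor or A near 0) are flagged
#' as degenerate, with V_h unidentifiable.
#'
#' @param points data.frame with columns \code{v} (mV) and \code{f}.
#' @param temperature temperature (degrees C) for the RT/F slope.
#' @return object of classes \code{cs_block_fit}, \code{cs_block} with
#'   fields A, v_h, z, temperature, residual_norm, vcov, degenerate.
#' @export
fit_cs_block <- function(points, temperature = 19) {
  pts <- as.data.frame(points)
  if (length(unique(pts$v)) < 4)
    stop("need >= 4 distinct voltages to fit the block curve")
  rtf <- rtf_mv(temperature)
  grid <- expand.grid(A = c(0.2, 0.5, 0.9),
                      v_h = seq(min(pts$v) - 20, max(pts$v) + 20,
                                length.out = 6),
                      z = c(0.3, 0.7, 1.5))
  best <- .multistart_fit(
    f ~ 1 - A / (1 + exp(-(v - v_h) * z / rtf)),
    data = cbind(pts, rtf = rtf), start_grid = grid,
    lower = c(A = 0, v_h = min(pts$v) - 200, z = 0.01),
    upper = c(A = 1, v_h = max(pts$v) + 200, z = 50))
  cf <- coef(best$fit)
  # degenerate when the fitted curve is essentially flat over the data range:
  # the voltage-independent limit, where V_h is unidentifiable
  pred_range <- diff(range(1 - cf["A"] /
    (1 + exp(-(range(pts$v) - cf["v_h"]) * cf["z"] / rtf))))
  degen <- unname(cf["A"]) < 1e-3 || abs(pred_range) < 0.005
  out <- list(A = unname(cf["A"]), v_h = unname(cf["v_h"]),
              z = unname(cf["z"]), temperature = temperature,
              residual_norm = sqrt(best$rss),
              vcov = tryCatch(stats::vcov(best$fit), error = function(e) NULL),
              degenerate = degen, data = pts)
  class(out) <- c("cs_block_fit", "cs_block")
  out
}

#' @export
print.cs_block <- function(x, ...) {
  cat(sprintf("Cs+ block: A = %.3f, V_h = %.1f mV, z = %.2f e (T = %g C)\n",
              x$A, x$v_h, x$z, x$temperature))
  if (isTRUE(x$degenerate))
    cat("  degenerate: voltage-independent limit; V_h unidentifiable\n")
  invisible(x)
}

#' @export
coef.cs_block_fit <- function(object, ...) {
  c(A = object$A, v_h = object$v_h, z = object$z)
}

#' @export
predict.cs_block_fit <- function(object, v, ...) eval_cs_block(object, v)

#' @export
plot.cs_block_fit <- function(x, ...) {
  graphics::plot(x$data$v, x$data$f, xlab = "V (mV)",
                 ylab = "fractional inhibition", ylim = c(0, 1), ...)
  vv <- seq(min(x$data$v), max(x$data$v), length.out = 200)
  graphics::lines(vv, eval_cs_block(x, vv))
  invisible(x)
}
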