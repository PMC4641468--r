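#' Stimulation protocol constructors
#'
#' A protocol describes the command waveform of a family of sweeps: a holding
#' level, a pre-stimulus segment, one stimulus segment per sweep, and a
#' post-stimulus segment, all sampled at a fixed interval. In voltage clamp
#' the command is in mV; in current clamp it is injected current in pA
#' (relative to the bias current that holds the cell at its adjusted
#' potential).
#'
#' @param levels stimulus level for each sweep (mV for "vc", pA for "cc").
#' @param duration_ms stimulus segment duration (ms).
#' @param holding holding level (mV for "vc"; pA, usually 0, for "cc").
#' @param mode "vc" (voltage clamp) or "cc" (current clamp).
#' @param pre_ms,post_ms pre/post stimulus durations (ms).
#' @param dt_ms sample interval (ms).
#' @param inter_sweep_s interval between sweep onsets (s).
#' @return an object of class \code{kna_protocol}.
#' @export
step_protocol <- function(levels, duration_ms, holding, mode = c("vc", "cc"),
                          pre_ms = 10, post_ms = 10, dt_ms = 0.02,
                          inter_sweep_s = 1) {
  mode <- match.arg(mode)
  new_protocol(kind = "step", mode = mode, levels = levels,
               duration_ms = duration_ms, holding = holding,
               pre_ms = pre_ms, post_ms = post_ms, dt_ms = dt_ms,
               inter_sweep_s = inter_sweep_s)
}

#' @rdname step_protocol
#' @param from,to ramp start and end command (mV).
#' @export
ramp_protocol <- function(from = -60, to = -5, duration_ms = 40,
                          holding = -60, pre_ms = 10, post_ms = 5,
                          dt_ms = 0.02, inter_sweep_s = 1) {
  new_protocol(kind = "ramp", mode = "vc", from = from, to = to,
               duration_ms = duration_ms, holding = holding,
               pre_ms = pre_ms, post_ms = post_ms, dt_ms = dt_ms,
               levels = to, inter_sweep_s = inter_sweep_s)
}

#' @rdname step_protocol
#' @param n_pulses number of current pulses.
#' @param level pulse amplitude (pA).
#' @param width_ms pulse width (ms).
#' @param freq_hz pulse frequency (Hz).
#' @param tail_ms recording time after the last pulse (ms).
#' @export
pulse_train_protocol <- function(n_pulses, level = 200, width_ms = 10,
                                 freq_hz = 7.1, pre_ms = 100, tail_ms = 1000,
                                 dt_ms = 0.02, inter_sweep_s = 10) {
  stopifnot(n_pulses >= 0, width_ms > 0, freq_hz > 0)
  new_protocol(kind = "train", mode = "cc", n_pulses = n_pulses,
               levels = level, duration_ms = width_ms, freq_hz = freq_hz,
               holding = 0, pre_ms = pre_ms, post_ms = tail_ms, dt_ms = dt_ms,
               inter_sweep_s = inter_sweep_s)
}

new_protocol <- function(...) {
  p <- list(...)
  stopifnot(p$duration_ms > 0, p$dt_ms > 0, p$pre_ms >= 0, p$post_ms >= 0)
  # sample interval must divide the segment durations
  segs <- c(p$pre_ms, p$duration_ms, p$post_ms)
  if (any(abs(segs / p$dt_ms - round(segs / p$dt_ms)) > 1e-8))
    stop("sample interval dt_ms must divide all segment durations")
  class(p) <- "kna_protocol"
  p
}

#' @export
print.kna_protocol <- function(x, ...) {
  cat(sprintf("%s protocol (%s), %d sweep(s), dt = %g ms\n",
              x$kind, x$mode, length(x$levels), x$dt_ms))
  if (x$kind == "ramp")
    cat(sprintf("  ramp %g -> %g mV over %g ms from holding %g mV\n",
                x$from, x$to, x$duration_ms, x$holding))
  else
    cat(sprintf("  levels: %s; stimulus %g ms; holding %g\n",
                paste(x$levels, collapse = ", "), x$duration_ms, x$holding))
  invisible(x)
}

#' Build the command waveform of one sweep of a protocol
#'
#' @param protocol a \code{kna_protocol}.
#' @param sweep index of the sweep within the protocol family.
#' @return list with \code{time_ms} and \code{command} vectors.
#' @export
protocol_command <- function(protocol, sweep = 1) {
  stopifnot(inherits(protocol, "kna_protocol"),
            sweep >= 1, sweep <= length(protocol$levels))
  dt <- protocol$dt_ms
  if (protocol$kind == "train") {
    period_ms <- 1000 / protocol$freq_hz
    total <- protocol$pre_ms +
      (if (protocol$n_pulses > 0)
         (protocol$n_pulses - 1) * period_ms + protocol$duration_ms
       else 0) + protocol$post_ms
    n <- round(total / dt)
    cmd <- rep(protocol$holding, n)
    tms <- (seq_len(n) - 1) * dt
    if (protocol$n_pulses > 0) {
      for (k in seq_len(protocol$n_pulses)) {
        t0 <- protocol$pre_ms + (k - 1) * period_ms
        idx <- which(tms >= t0 & tms < t0 + protocol$duration_ms)
        cmd[idx] <- protocol$levels[sweep]
      }
    }
    return(list(time_ms = tms, command = cmd))
  }
  n_pre  <- round(protocol$pre_ms / dt)
  n_stim <- round(protocol$duration_ms / dt)
  n_post <- round(protocol$post_ms / dt)
  stim <- if (protocol$kind == "ramp")
    seq(protocol$from, protocol$to, length.out = n_stim)
  else
    rep(protocol$levels[sweep], n_stim)
  cmd <- c(rep(protocol$holding, n_pre), stim, rep(protocol$holding, n_post))
  list(time_ms = (seq_along(cmd) - 1) * dt, command = cmd)
}

#' Stimulus window of a protocol, in ms from sweep onset
#'
#' @param protocol a \code{kna_protocol}.
#' @return numeric length-2 vector (start, end) of the stimulus segment.
#' @export
stimulus_window <- function(protocol) {
  c(protocol$pre_ms, protocol$pre_ms + protocol$duration_ms)
}
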