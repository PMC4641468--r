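# Excitability measures from current-clamp and ramp recordings: spike
# detection, phase-plane (dV/dt) threshold, rheobase, AP shape, f-I curves,
# ramp zero-crossing, input resistance, train AHPs.

.check_uniform <- function(sweep) {
  dts <- diff(sweep$time_ms)
  if (max(dts) - min(dts) > 1e-6 * stats::median(dts))
    stop("schema error: non-uniform time base")
  invisible(sweep)
}

# k-point moving average, ends padded by replication
.smooth_ma <- function(x, k = 5) {
  if (k <= 1) return(x)
  half <- (k - 1) %/% 2
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, rep(1 / k, k), sides = 2))[half + seq_along(x)]
}

# centered-difference derivative (mV/ms), one-sided at the ends
.dvdt <- function(v, dt) {
  n <- length(v)
  d <- numeric(n)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt)
  d[1] <- (v[2] - v[1]) / dt
  d[n] <- (v[n] - v[n - 1]) / dt
  d
}

#' Detect action potentials in a voltage trace
#'
#' An action potential is a local voltage maximum exceeding
#' \code{peak_above} mV whose upstroke (smoothed dV/dt within the preceding
#' \code{lookback_ms}) exceeds \code{min_dvdt}; detected events are separated
#' by at least the refractory window.
#'
#' @param trace a current-clamp \code{kna_sweep}.
#' @param peak_above peak detection level (mV).
#' @param min_dvdt minimum preceding upstroke rate (mV/ms).
#' @param refractory_ms minimum separation between events (ms).
#' @param smooth_points moving-average width for the derivative (samples).
#' @param lookback_ms window before the peak searched for the upstroke (ms).
#' @param rearm_below after an event, the next event is accepted only once
#'   the voltage has fallen below this level (mV), so recording noise riding
#'   on one broad spike cannot split it into several events.
#' @return data.frame with one row per AP: \code{peak_time_ms},
#'   \code{peak_v}, \code{max_dvdt}, \code{peak_index}.
#' @export
detect_aps <- function(trace, peak_above = 0, min_dvdt = 10,
                       refractory_ms = 2, smooth_points = 5,
                       lookback_ms = 5, rearm_below = -20) {
  stopifnot(inherits(trace, "kna_sweep"), trace$mode == "cc")
  .check_uniform(trace)
  v <- trace$recorded
  dt <- trace$dt_ms
  n <- length(v)
  vs <- .smooth_ma(v, smooth_points)
  dv <- .dvdt(vs, dt)
  cand <- which(v > peak_above)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[v[cand] >= v[cand - 1] & v[cand] > v[cand + 1]]
  if (length(cand) == 0)
    return(data.frame(peak_time_ms = numeric(0), peak_v = numeric(0),
                      max_dvdt = numeric(0), peak_index = integer(0)))
  lb <- max(1, round(lookback_ms / dt))
  keep <- vapply(cand, function(i) {
    max(dv[max(1, i - lb):i]) > min_dvdt
  }, logical(1))
  cand <- cand[keep]
  events <- integer(0)
  last_i <- -Inf
  for (i in cand) {
    t <- trace$time_ms[i]
    if (length(events) == 0) {
      events <- i; last_i <- i
      next
    }
    rearmed <- t - trace$time_ms[last_i] >= refractory_ms &&
      min(vs[last_i:i]) < rearm_below
    if (rearmed) {
      events <- c(events, i); last_i <- i
    } else if (v[i] > v[events[length(events)]]) {
      events[length(events)] <- i   # keep the taller peak of the same spike
      last_i <- i
    }
  }
  data.frame(peak_time_ms = trace$time_ms[events], peak_v = v[events],
             max_dvdt = vapply(events, function(i)
               max(dv[max(1, i - lb):i]), numeric(1)),
             peak_index = events)
}

#' Phase-plane action-potential threshold
#'
#' The threshold is the membrane voltage at which dV/dt of the first AP's
#' upstroke last rises through \code{fraction} of its peak value. dV/dt is
#' estimated by centered differences on a 5-point moving-average-smoothed
#' trace; the crossing sample is refined by linear interpolation.
#'
#' @param trace a current-clamp \code{kna_sweep} containing at least one AP.
#' @param fraction fraction of peak dV/dt defining threshold, in (0, 1];
#'   1 returns the voltage at peak dV/dt itself.
#' @param smooth_points moving-average width (samples).
#' @return threshold voltage (mV).
#' @export
ap_threshold <- function(trace, fraction = 0.10, smooth_points = 5) {
  stopifnot(fraction > 0, fraction <= 1)
  aps <- detect_aps(trace, smooth_points = smooth_points)
  if (nrow(aps) == 0) stop("no action potential in the trace")
  dt <- trace$dt_ms
  vs <- .smooth_ma(trace$recorded, smooth_points)
  dv <- .dvdt(vs, dt)
  pk <- aps$peak_index[1]
  lo <- max(1, pk - round(20 / dt))
  ipk <- lo - 1 + which.max(dv[lo:pk])          # dV/dt peak of the first AP
  if (fraction >= 1) return(vs[ipk])
  level <- fraction * dv[ipk]
  seg <- dv[lo:ipk]
  below <- which(seg[-length(seg)] < level & seg[-1] >= level)
  if (length(below) == 0) return(vs[lo])        # already above at window start
  j <- lo - 1 + below[length(below)]            # last upward crossing
  w <- (level - dv[j]) / (dv[j + 1] - dv[j])
  vs[j] + w * (vs[j + 1] - vs[j])
}

#' Rheobase from a family of brief current steps
#'
#' The rheobase is the smallest injected current that elicits at least one
#' action potential during a brief (default 20 ms) step from the adjusted
#' holding potential. Given a \code{kna_cell} whose \code{sweeps$cc} form an
#' amplitude family, the family is scanned; given a \code{kna_params} object,
#' sweeps are simulated on demand and the spiking boundary is found by
#' bisection on the amplitude grid.
#'
#' @param cell a \code{kna_cell} with a current-step family, or a
#'   \code{kna_params} object for simulator-driven bisection.
#' @param step_duration_ms step duration for simulator-driven search (ms).
#' @param increment amplitude grid spacing (pA).
#' @param scan_range amplitude range searched (pA).
#' @param adjust_to holding potential (mV).
#' @param seed seed for the simulated sweeps.
#' @param dt_ms sample interval for simulated sweeps (ms).
#' @return rheobase (pA).
#' @export
rheobase <- function(cell, step_duration_ms = 20, increment = 2,
                     scan_range = c(20, 300), adjust_to = -60, seed = 1,
                     dt_ms = 0.02) {
  if (inherits(cell, "kna_params")) {
    spikes_at <- function(amp) {
      pr <- step_protocol(amp, step_duration_ms, 0, "cc", pre_ms = 10,
                          post_ms = 20, dt_ms = dt_ms)
      cc <- simulate_current_clamp(cell, pr, seed = seed,
                                   adjust_to = adjust_to)
      nrow(detect_aps(cc$sweeps$cc[[1]])) >= 1
    }
    grid <- seq(scan_range[1], scan_range[2], by = increment)
    if (!spikes_at(grid[length(grid)]))
      stop("unbounded rheobase: no amplitude in the scan range elicits an AP")
    if (spikes_at(grid[1])) return(grid[1])
    lo <- 1L; hi <- length(grid)                 # lo: no spike, hi: spike
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (spikes_at(grid[mid])) hi <- mid else lo <- mid
    }
    return(grid[hi])
  }
  stopifnot(inherits(cell, "kna_cell"))
  sw <- cell$sweeps$cc
  if (is.null(sw) || length(sw) == 0) stop("cell has no current-clamp sweeps")
  amps <- vapply(sw, function(s) s$level, numeric(1))
  o <- order(amps)
  for (i in o) {
    if (nrow(detect_aps(sw[[i]])) >= 1) return(amps[i])
  }
  stop("unbounded rheobase: no sweep in the family elicits an AP")
}

#' Shape features of the first action potential
#'
#' Half-width is the duration between the half-amplitude crossings, where
#' amplitude is peak V minus threshold V; the AHP is the voltage minimum in
#' the window after the spike peak. A quality flag marks peaks clipped at a
#' recording ceiling (consecutive samples at the maximum).
#'
#' @param trace a current-clamp \code{kna_sweep} with at least one AP.
#' @param ahp_window_ms window after the peak searched for the AHP minimum
#'   (ms).
#' @param fraction threshold fraction passed to \code{\link{ap_threshold}}.
#' @return object of class \code{ap_event}: list with \code{peak_time_ms},
#'   \code{peak_v}, \code{threshold_v}, \code{half_width_ms}, \code{ahp_v},
#'   \code{max_dvdt}, \code{clipped}.
#' @export
ap_shape_features <- function(trace, ahp_window_ms = 50, fraction = 0.10) {
  aps <- detect_aps(trace)
  if (nrow(aps) == 0) stop("no action potential in the trace")
  dt <- trace$dt_ms
  v <- trace$recorded
  pk <- aps$peak_index[1]
  thr <- ap_threshold(trace, fraction = fraction)
  peak_v <- aps$peak_v[1]
  half <- thr + 0.5 * (peak_v - thr)
  # last upward crossing of the half level before the peak
  pre <- which(v[seq_len(pk - 1)] < half & v[2:pk] >= half)
  # first downward crossing after the peak
  n <- length(v)
  post <- which(v[pk:(n - 1)] >= half & v[(pk + 1):n] < half)
  if (length(pre) == 0 || length(post) == 0)
    stop("half-amplitude crossings not found")
  j1 <- pre[length(pre)]
  t1 <- trace$time_ms[j1] + dt * (half - v[j1]) / (v[j1 + 1] - v[j1])
  j2 <- pk - 1 + post[1]
  t2 <- trace$time_ms[j2] + dt * (v[j2] - half) / (v[j2] - v[j2 + 1])
  ahp_sel <- trace$time_ms > aps$peak_time_ms[1] &
    trace$time_ms <= aps$peak_time_ms[1] + ahp_window_ms
  clipped <- any(rle(v == max(v))$lengths[rle(v == max(v))$values] >= 3)
  out <- list(peak_time_ms = aps$peak_time_ms[1], peak_v = peak_v,
              threshold_v = thr, half_width_ms = t2 - t1,
              ahp_v = min(.smooth_ma(v[ahp_sel], 5)),
              max_dvdt = aps$max_dvdt[1], clipped = clipped)
  class(out) <- "ap_event"
  out
}

#' @export
print.ap_event <- function(x, ...) {
  cat(sprintf(
    "AP: peak %.1f mV @ %.1f ms, threshold %.1f mV, half-width %.2f ms, AHP %.1f mV\n",
    x$peak_v, x$peak_time_ms, x$threshold_v, x$half_width_ms, x$ahp_v))
  if (x$clipped) cat("  warning: peak clipped at recording ceiling\n")
  invisible(x)
}

#' f-I curve: AP counts per current step
#'
#' @param cell a \code{kna_cell} whose \code{sweeps$cc} are a 1 s step family.
#' @return data.frame (\code{i_pa}, \code{count}) ordered by current.
#' @export
fi_curve <- function(cell) {
  stopifnot(inherits(cell, "kna_cell"))
  sw <- cell$sweeps$cc
  if (is.null(sw) || length(sw) == 0) stop("cell has no current-clamp sweeps")
  amps <- vapply(sw, function(s) s$level, numeric(1))
  counts <- vapply(sw, function(s) nrow(detect_aps(s)), numeric(1))
  o <- order(amps)
  data.frame(i_pa = amps[o], count = counts[o])
}

#' Zero-crossing voltage of a ramp-evoked current
#'
#' Returns the command voltage at which the recorded current turns net inward
#' during the ramp, refined by linear interpolation. The current is lightly
#' smoothed, the inward surge is located as the current minimum within the
#' ramp segment, and the crossing is the last downward zero crossing before
#' that minimum — robust against recording noise at the ramp foot. If the
#' current never turns from outward to inward, the first zero crossing of
#' either direction within the ramp is returned.
#'
#' @param sweep a voltage-clamp ramp \code{kna_sweep}.
#' @param smooth_points moving-average width applied to the current.
#' @return command voltage at the crossing (mV).
#' @export
ramp_zero_crossing <- function(sweep, smooth_points = 11) {
  stopifnot(inherits(sweep, "kna_sweep"), sweep$mode == "vc")
  .check_uniform(sweep)
  cmd <- sweep$command
  chg <- which(diff(cmd) != 0)
  if (length(chg) == 0) stop("no ramp found in the command waveform")
  onset <- chg[1] + 1
  offset <- if (any(diff(chg) > 1)) chg[which(diff(chg) > 1)[1] + 1]
            else chg[length(chg)] + 1
  i <- .smooth_ma(sweep$recorded, smooth_points)
  idx <- onset:offset
  x <- i[idx]
  imin <- which.min(x)
  seg <- seq_len(max(imin - 1, 1))
  down <- which(x[seg] >= 0 & x[seg + 1] < 0)
  cross <- if (length(down)) down[length(down)]
           else which(sign(x[-length(x)]) * sign(x[-1]) < 0)[1]
  if (is.na(cross) || length(cross) == 0)
    stop("no zero crossing of the ramp current")
  j <- idx[cross]
  w <- x[cross] / (x[cross] - x[cross + 1])
  cmd[j] + w * (cmd[j + 1] - cmd[j])
}

#' Input resistance from a small step
#'
#' R_in = dV / dI at the step plateau: for a voltage-clamp step (default
#' -60 to -70 mV) dV is the command step and dI the measured difference
#' current; for a current-clamp step the roles are exchanged.
#'
#' @param sweep a \code{kna_sweep} containing a small step.
#' @param noise_floor_pa current differences below this are flagged
#'   unreliable (pA).
#' @return list with \code{r_mohm}, \code{delta_v_mv}, \code{delta_i_pa},
#'   \code{unreliable}.
#' @export
input_resistance <- function(sweep, noise_floor_pa = 1) {
  stopifnot(inherits(sweep, "kna_sweep"))
  b <- .step_bounds(sweep)
  plat <- .plateau_window(b$onset, b$offset)
  base <- .plateau_window(sweep$time_ms[1], b$onset - sweep$dt_ms,
                          settle_ms = min(2, b$onset / 2))
  d_rec <- .window_mean(sweep, plat) - .window_mean(sweep, base)
  sel_p <- sweep$time_ms >= plat[1] & sweep$time_ms <= plat[2]
  sel_b <- sweep$time_ms >= base[1] & sweep$time_ms <= base[2]
  d_cmd <- mean(sweep$command[sel_p]) - mean(sweep$command[sel_b])
  if (sweep$mode == "vc") { dv <- d_cmd; di <- d_rec }
  else { dv <- d_rec; di <- d_cmd }
  unreliable <- abs(di) < noise_floor_pa
  list(r_mohm = 1000 * dv / di, delta_v_mv = dv, delta_i_pa = di,
       unreliable = unreliable)
}

#' Post-train afterhyperpolarization
#'
#' Measures the voltage minimum after the last pulse of a current-pulse
#' train, relative to the pre-train baseline, over a 1 s window (the slow-AHP
#' window). A zero-pulse control returns 0 by definition.
#'
#' @param trace a current-clamp pulse-train \code{kna_sweep}.
#' @param n_pulses expected number of pulses (checked against the command).
#' @param window_ms post-train window searched for the minimum (ms).
#' @param baseline_ms pre-train window used for the baseline (ms).
#' @return AHP amplitude (mV, negative = hyperpolarized relative to
#'   baseline).
#' @export
train_ahp <- function(trace, n_pulses, window_ms = 1000, baseline_ms = 50) {
  stopifnot(inherits(trace, "kna_sweep"), trace$mode == "cc")
  if (n_pulses == 0) return(0)
  cmd <- trace$command
  hold <- cmd[1]
  on <- which(diff(cmd != hold) == 1) + 1
  off <- which(diff(cmd != hold) == -1)
  if (length(on) != n_pulses)
    stop(sprintf("protocol mismatch: %d pulses found, %d expected",
                 length(on), n_pulses))
  t_end <- trace$time_ms[off[length(off)]]
  t_first <- trace$time_ms[on[1]]
  base_sel <- trace$time_ms >= max(0, t_first - baseline_ms) &
    trace$time_ms < t_first
  baseline <- mean(trace$recorded[base_sel])
  vs <- .smooth_ma(trace$recorded, 101)
  post_sel <- trace$time_ms > t_end + 5 & trace$time_ms <= t_end + window_ms
  if (!any(post_sel)) stop("protocol mismatch: no post-train window recorded")
  min(vs[post_sel]) - baseline
}

#' Free resting potential of a recorded cell
#'
#' Mean voltage of a zero-current current-clamp sweep (after an initial
#' settling time), i.e. the unadjusted resting potential.
#'
#' @param sweep a current-clamp \code{kna_sweep} at 0 pA injected current.
#' @param settle_ms initial settling time excluded (ms).
#' @return resting potential (mV).
#' @export
resting_potential <- function(sweep, settle_ms = 100) {
  stopifnot(inherits(sweep, "kna_sweep"), sweep$mode == "cc")
  sel <- sweep$time_ms >= settle_ms
  if (!any(sel)) stop("sweep shorter than the settling window")
  mean(sweep$recorded[sel])
}
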