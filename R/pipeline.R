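# Standard protocol set, per-cell feature extraction, sweep-set file format
# (CSV per sweep + JSON sidecar), and the end-to-end pipeline.

#' The standard recording protocol set
#'
#' The protocols used throughout: a 1 s f-I step family (60/100/200 pA), a
#' single 20 ms 100 pA step for AP shape and threshold, a -60 to -70 mV input
#' resistance step, the 40 ms -60 to -5 mV ramp, a 400 ms zero-current sweep
#' for the free resting potential, and the -80 to -120 mV leak step.
#'
#' @param dt_ms sample interval (ms).
#' @param fi_levels f-I step amplitudes (pA).
#' @return named list of \code{kna_protocol} objects.
#' @export
standard_protocols <- function(dt_ms = 0.02, fi_levels = c(60, 100, 200)) {
  list(
    fi = step_protocol(fi_levels, 1000, 0, "cc", pre_ms = 100, post_ms = 100,
                       dt_ms = dt_ms),
    single = step_protocol(100, 20, 0, "cc", pre_ms = 10, post_ms = 80,
                           dt_ms = dt_ms),
    rest = step_protocol(0, 400, 0, "cc", pre_ms = 0, post_ms = 100,
                         dt_ms = dt_ms),
    rin = step_protocol(-70, 100, -60, "vc", pre_ms = 50, post_ms = 10,
                        dt_ms = dt_ms),
    ramp = ramp_protocol(-60, -5, 40, holding = -60, pre_ms = 10,
                         post_ms = 5, dt_ms = dt_ms),
    leak = step_protocol(-120, 100, -80, "vc", pre_ms = 50, post_ms = 10,
                         dt_ms = dt_ms))
}

#' Simulate the standard protocol set for one cohort cell
#'
#' Fills the cell's sweep groups (fi, single, rest, rin, ramp) from its own
#' parameter draw and sub-seed.
#'
#' @param cell a \code{kna_cell} from \code{\link{make_cohort}}.
#' @param protocols protocol set from \code{\link{standard_protocols}}.
#' @param breakin_s time since break-in for the voltage-clamp sweeps (s).
#' @return the cell with sweeps attached.
#' @export
simulate_standard_cell <- function(cell, protocols = standard_protocols(),
                                   breakin_s = 180) {
  stopifnot(inherits(cell, "kna_cell"), inherits(cell$params, "kna_params"))
  p <- cell$params
  s <- cell$seed
  na <- cell$pipette_na
  cc_fi <- simulate_current_clamp(p, protocols$fi, seed = s, pipette_na = na)
  cc_1 <- simulate_current_clamp(p, protocols$single, seed = s + 1L,
                                 pipette_na = na)
  cc_rest <- simulate_current_clamp(p, protocols$rest, seed = s + 2L,
                                    adjust_to = NULL, pipette_na = na)
  vc_rin <- simulate_voltage_clamp(p, protocols$rin, pipette_na = na,
                                   times_since_breakin = breakin_s,
                                   seed = s + 3L)
  vc_ramp <- simulate_voltage_clamp(p, protocols$ramp, pipette_na = na,
                                    times_since_breakin = breakin_s,
                                    seed = s + 4L)
  cell$sweeps <- list(fi = cc_fi$sweeps$cc, single = cc_1$sweeps$cc,
                      rest = cc_rest$sweeps$cc, rin = vc_rin$sweeps$vc,
                      ramp = vc_ramp$sweeps$vc)
  cell
}

#' Extract the excitability feature set of one cell
#'
#' Computes the standard per-cell measures from the cell's sweeps: AP counts
#' of the f-I family, dV/dt threshold and AP shape from the single-step
#' sweep, input resistance, ramp zero-crossing, free resting potential, and
#' rheobase (by simulator bisection from the cell's own parameters). Features
#' whose protocol is absent, or where no AP was evoked, are NA.
#'
#' @param cell a \code{kna_cell} with standard sweeps (see
#'   \code{\link{simulate_standard_cell}}).
#' @return one-row data.frame with columns cm, mp, rin, rheobase, threshold,
#'   ap_peak, half_width, ahp, count60, count100, count200, ramp_crossing,
#'   plus id and genotype.
#' @export
extract_features <- function(cell) {
  stopifnot(inherits(cell, "kna_cell"))
  safely <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  counts <- c(count60 = NA_real_, count100 = NA_real_, count200 = NA_real_)
  if (!is.null(cell$sweeps$fi)) {
    fi <- fi_curve(list_cell(cell, "fi"))
    for (lv in c(60, 100, 200)) {
      k <- paste0("count", lv)
      if (lv %in% fi$i_pa) counts[k] <- fi$count[fi$i_pa == lv]
    }
  }
  shape <- if (!is.null(cell$sweeps$single))
    tryCatch(ap_shape_features(cell$sweeps$single[[1]]),
             error = function(e) NULL) else NULL
  data.frame(
    id = cell$id, genotype = cell$genotype,
    cm = cell$capacitance,
    mp = if (!is.null(cell$sweeps$rest))
      safely(resting_potential(cell$sweeps$rest[[1]])) else NA_real_,
    rin = if (!is.null(cell$sweeps$rin))
      safely(input_resistance(cell$sweeps$rin[[1]])$r_mohm) else NA_real_,
    rheobase = if (inherits(cell$params, "kna_params"))
      safely(rheobase(cell$params, seed = cell$seed)) else NA_real_,
    threshold = if (!is.null(shape)) shape$threshold_v else NA_real_,
    ap_peak = if (!is.null(shape)) shape$peak_v else NA_real_,
    half_width = if (!is.null(shape)) shape$half_width_ms else NA_real_,
    ahp = if (!is.null(shape)) shape$ahp_v else NA_real_,
    count60 = counts["count60"], count100 = counts["count100"],
    count200 = counts["count200"],
    ramp_crossing = if (!is.null(cell$sweeps$ramp))
      safely(ramp_zero_crossing(cell$sweeps$ramp[[1]])) else NA_real_,
    row.names = NULL, stringsAsFactors = FALSE)
}

# view of a cell with one sweep group exposed under the canonical cc/vc name
list_cell <- function(cell, group) {
  mode <- cell$sweeps[[group]][[1]]$mode
  cell$sweeps <- setNames(list(cell$sweeps[[group]]), mode)
  cell
}

#' Feature table of a cohort
#'
#' @param cells list of \code{kna_cell} (sweeps attached, or parameters only
#'   in which case the standard protocols are simulated first).
#' @param protocols protocol set used when simulation is needed.
#' @return data.frame, one row per cell (see \code{\link{extract_features}}).
#' @export
cohort_features <- function(cells, protocols = standard_protocols()) {
  rows <- lapply(cells, function(cl) {
    if (length(cl$sweeps) == 0) cl <- simulate_standard_cell(cl, protocols)
    extract_features(cl)
  })
  do.call(rbind, rows)
}

#' Write a cell record as CSV sweeps plus a JSON sidecar
#'
#' Each sweep becomes one CSV file (columns time_ms, command, recorded); the
#' sidecar \code{record.json} stores cell metadata, per-sweep metadata
#' (group, mode, level, time since break-in, bath, file name) and the
#' generator parameters, making the write/read round trip lossless to float
#' precision.
#'
#' @param record a \code{kna_cell}.
#' @param path directory to create/write into.
#' @return \code{path}, invisibly.
#' @export
write_sweeps <- function(record, path) {
  stopifnot(inherits(record, "kna_cell"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(id = record$id, genotype = record$genotype,
               pipette_na = record$pipette_na,
               capacitance = record$capacitance,
               ib4_status = record$ib4_status, seed = record$seed,
               params = unclass(record$params), sweeps = list())
  k <- 0
  for (grp in names(record$sweeps)) {
    for (j in seq_along(record$sweeps[[grp]])) {
      s <- record$sweeps[[grp]][[j]]
      k <- k + 1
      fn <- sprintf("sweep_%03d.csv", k)
      df <- data.frame(time_ms = s$time_ms, command = s$command,
                       recorded = s$recorded)
      write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                file.path(path, fn), row.names = FALSE, quote = FALSE)
      meta$sweeps[[k]] <- list(file = fn, group = grp, mode = s$mode,
                               level = s$level,
                               time_since_breakin_s = s$time_since_breakin_s,
                               bath = s$bath)
    }
  }
  jsonlite::write_json(meta, file.path(path, "record.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' Read a cell record written by \code{\link{write_sweeps}}
#'
#' @param path directory containing sweep CSVs and \code{record.json}.
#' @return a \code{kna_cell}.
#' @export
read_sweeps <- function(path) {
  sidecar <- file.path(path, "record.json")
  if (!file.exists(sidecar))
    stop(sprintf("missing sidecar: expected %s", sidecar))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  sweeps <- list()
  for (sm in meta$sweeps) {
    f <- file.path(path, sm$file)
    if (!file.exists(f)) stop(sprintf("missing sweep file: %s", f))
    df <- read.csv(f)
    need <- c("time_ms", "command", "recorded")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop(sprintf("schema violation in %s: missing column(s) %s",
                   sm$file, paste(miss, collapse = ", ")))
    bad <- which(!complete.cases(df[need]))
    if (length(bad))
      stop(sprintf("schema violation in %s: non-numeric/missing value at row %d",
                   sm$file, bad[1]))
    sw <- kna_sweep(df$time_ms, df$command, df$recorded, sm$mode,
                    time_since_breakin_s =
                      if (is.null(sm$time_since_breakin_s)) NA_real_
                      else sm$time_since_breakin_s,
                    bath = sm$bath,
                    level = if (is.null(sm$level)) NA_real_ else sm$level)
    grp <- sm$group
    sweeps[[grp]] <- c(sweeps[[grp]], list(sw))
  }
  params <- meta$params
  if (!is.null(params)) class(params) <- "kna_params"
  kna_cell(id = meta$id, genotype = meta$genotype,
           pipette_na = meta$pipette_na, capacitance = meta$capacitance,
           ib4_status = meta$ib4_status, params = params, sweeps = sweeps,
           seed = if (is.null(meta$seed)) NA_integer_ else meta$seed)
}

#' Pipeline run configuration
#'
#' @param seed master seed; every random draw in the run derives from it.
#' @param n_per_group cells per genotype cohort.
#' @param genotypes genotype labels to simulate.
#' @param pipette_na pipette Na+ for the excitability cohorts (mM).
#' @param leak_pipette_na pipette Na+ for the leak protocol (mM).
#' @param variability cohort fractional parameter sd.
#' @param leak_times_s leak-step times since break-in (s).
#' @param out_dir output directory.
#' @return list of class \code{kna_config}.
#' @export
run_config <- function(seed = 1, n_per_group = 4,
                       genotypes = c("WT", "dKO"), pipette_na = 10,
                       leak_pipette_na = 70, variability = 0.25,
                       leak_times_s = c(20, 45, 90, 180), out_dir = tempdir()) {
  cfg <- list(seed = seed, n_per_group = n_per_group, genotypes = genotypes,
              pipette_na = pipette_na, leak_pipette_na = leak_pipette_na,
              variability = variability, leak_times_s = leak_times_s,
              out_dir = out_dir)
  class(cfg) <- "kna_config"
  cfg
}

#' Write / read a run configuration (JSON round trip)
#'
#' @param config a \code{kna_config}.
#' @param path JSON file path.
#' @return \code{path} (write) or the configuration (read).
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$out_dir <- as.character(cfg$out_dir)
  class(cfg) <- "kna_config"
  cfg
}

#' Run the end-to-end analysis pipeline
#'
#' Simulates genotype cohorts, quantifies the Na+-dependent leak current time
#' course per cell, extracts the excitability feature set, compares cohorts,
#' and evaluates the chord-conductance model, writing a report bundle
#' (summary CSVs and JSON) into the configured output directory. The run is
#' deterministic under the configured seed.
#'
#' @param config a \code{kna_config}.
#' @return invisible list with the summary table, leak series, block fit,
#'   chord table and output paths.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "kna_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  # stage 1: cohorts and features
  feats <- stage("features", {
    lapply(seq_along(config$genotypes), function(gi) {
      cells <- make_cohort(config$n_per_group, config$genotypes[gi],
                           pipette_na = config$pipette_na,
                           variability = config$variability,
                           seed = config$seed + 7919L * gi)
      cohort_features(cells)
    })
  })
  names(feats) <- config$genotypes
  summary_tab <- stage("summary", {
    if (length(feats) >= 2)
      summarize_table(feats[[1]], feats[[2]], labels = names(feats)[1:2])
    else summarize_table(feats[[1]], feats[[1]][0, ],
                         labels = c(names(feats)[1], "none"))
  })
  # stage 2: leak time course per genotype template
  leak_prot <- standard_protocols()$leak
  leak_rows <- stage("leak", {
    do.call(rbind, lapply(config$genotypes, function(g) {
      p <- neuron_params(g)
      cell <- simulate_voltage_clamp(p, leak_prot,
                                     pipette_na = config$leak_pipette_na,
                                     times_since_breakin = config$leak_times_s,
                                     seed = config$seed)
      di <- vapply(cell$sweeps$vc, leak_difference_current, numeric(1))
      data.frame(genotype = g, t_s = config$leak_times_s, delta_i_pa = di)
    }))
  })
  # stage 3: Cs+ block on the WT template I-V
  block_fit <- stage("csblock", {
    p <- neuron_params("WT")
    iv_prot <- step_protocol(seq(-130, -70, by = 10), 100, -80, "vc",
                             pre_ms = 50, post_ms = 10)
    ctl <- simulate_voltage_clamp(p, iv_prot, pipette_na = 70,
                                  times_since_breakin = 180,
                                  seed = config$seed + 1L)
    blk <- simulate_voltage_clamp(p, iv_prot, pipette_na = 70,
                                  times_since_breakin = 180,
                                  bath = "Cs20mM", seed = config$seed + 2L)
    # KNa-free reference from the dKO template isolates the Na+-dependent
    # component, as in the dKO-vs-baseline comparison of the leak analysis
    base <- simulate_voltage_clamp(neuron_params("dKO"), iv_prot,
                                   pipette_na = 70, times_since_breakin = 180,
                                   seed = config$seed + 3L)
    fit_cs_block(fractional_inhibition(ctl, blk, baseline = base))
  })
  # stage 4: chord-conductance model table
  chord_tab <- stage("chord", gkna_sweep())
  # write the bundle
  paths <- list(
    summary = file.path(config$out_dir, "summary_table.csv"),
    leak = file.path(config$out_dir, "leak_time_course.csv"),
    block = file.path(config$out_dir, "cs_block_fit.json"),
    chord = file.path(config$out_dir, "chord_table.csv"),
    report = file.path(config$out_dir, "report.json"))
  stage("write", {
    write.csv(summary_tab, paths$summary, row.names = FALSE)
    write.csv(leak_rows, paths$leak, row.names = FALSE)
    jsonlite::write_json(block_fit[c("A", "v_h", "z", "temperature",
                                     "residual_norm")],
                         paths$block, auto_unbox = TRUE, digits = 8)
    write.csv(format(as.data.frame(chord_tab), digits = 10),
              paths$chord, row.names = FALSE, quote = FALSE)
    report <- list(seed = config$seed,
                   config = unclass(config),
                   chord_baseline_vm = chord_vm(chord_model()),
                   leak_max_abs_pa = max(abs(leak_rows$delta_i_pa)),
                   block = block_fit[c("A", "v_h", "z")],
                   features_n = vapply(feats, nrow, integer(1)))
    jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = 8,
                         pretty = TRUE)
  })
  invisible(list(summary = summary_tab, features = feats, leak = leak_rows,
                 block = block_fit, chord = chord_tab, paths = paths))
}
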