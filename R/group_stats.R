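# Cohort-level comparisons: two-sample Kolmogorov-Smirnov statistic with the
# small-sample switch to an unpaired Student's t-test, and a summary table in
# the standard layout (mean, sem, n per group, p per comparison).

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum over the pooled support of |F_x - F_y|; the p-value
#' comes from the exact two-sample distribution when n*m is small (and the
#' samples are tie-free) and from the asymptotic Kolmogorov distribution
#' otherwise.
#'
#' @param x,y numeric samples (non-empty).
#' @return list with \code{D} and \code{p}.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("samples must be non-empty")
  k <- suppressWarnings(ks.test(x, y))
  list(D = unname(k$statistic), p = unname(k$p.value))
}

#' Compare the same measure between two cohorts
#'
#' Applies the two-sample KS test when both groups have at least
#' \code{min_n_for_ks} entries, otherwise a two-tailed unpaired Student's
#' t-test (pooled variance by default), and records which was used.
#'
#' @param x,y numeric feature vectors of the same measure.
#' @param labels group labels, length 2.
#' @param min_n_for_ks smallest per-group n for which KS is used.
#' @param pooled_var use the pooled-variance (classic Student) t-test;
#'   FALSE gives Welch.
#' @return object of class \code{group_comparison}: labels, n, mean, sem,
#'   D, ks_p, t, t_p, \code{p} (from the test used), \code{test_used}.
#' @export
compare_cohorts <- function(x, y, labels = c("A", "B"), min_n_for_ks = 10,
                            pooled_var = TRUE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 1 || length(y) < 1) stop("each cohort needs >= 1 value")
  use_ks <- length(x) >= min_n_for_ks && length(y) >= min_n_for_ks
  ks <- if (length(x) > 1 && length(y) > 1) ks_two_sample(x, y)
        else list(D = NA_real_, p = NA_real_)
  tt <- if (length(x) > 1 && length(y) > 1)
    tryCatch(t.test(x, y, var.equal = pooled_var),
             error = function(e) list(statistic = NA_real_,
                                      p.value = NA_real_))
  else list(statistic = NA_real_, p.value = NA_real_)
  out <- list(labels = labels,
              n = c(length(x), length(y)),
              mean = c(mean(x), mean(y)),
              sem = c(sd(x) / sqrt(length(x)), sd(y) / sqrt(length(y))),
              D = ks$D, ks_p = ks$p,
              t = unname(tt$statistic), t_p = unname(tt$p.value),
              p = if (use_ks) ks$p else unname(tt$p.value),
              test_used = if (use_ks) "KS" else "t")
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %.3g +/- %.2g (n=%d)  vs  %s: %.3g +/- %.2g (n=%d)\n",
              x$labels[1], x$mean[1], x$sem[1], x$n[1],
              x$labels[2], x$mean[2], x$sem[2], x$n[2]))
  cat(sprintf("  %s test: p = %.4g (KS D = %.3f)\n", x$test_used, x$p,
              x$D))
  invisible(x)
}

# canonical row order of the summary table
.table1_rows <- c("Cm (pF)", "m.p. (mV)", "R_in (MOhm)", "rheobase (pA)",
                  "dV/dt AP threshold (mV)", "AP peak (mV)",
                  "AP half-width (ms)", "AHP (mV)", "60 pA AP count",
                  "100 pA AP count", "200 pA AP count")

.feature_keys <- c(cm = "Cm (pF)", mp = "m.p. (mV)", rin = "R_in (MOhm)",
                   rheobase = "rheobase (pA)",
                   threshold = "dV/dt AP threshold (mV)",
                   ap_peak = "AP peak (mV)", half_width = "AP half-width (ms)",
                   ahp = "AHP (mV)", count60 = "60 pA AP count",
                   count100 = "100 pA AP count", count200 = "200 pA AP count")

#' Summary table of two feature cohorts
#'
#' Produces the per-measure summary in the conventional layout: one row per
#' excitability measure (capacitance, resting potential, input resistance,
#' rheobase, dV/dt threshold, AP peak, half-width, AHP, and the 60/100/200 pA
#' AP counts), with mean, sem and n per group and the p-value of the
#' group comparison (KS, or t when either n < 10). Missing features are
#' listed with NA, never imputed.
#'
#' @param features_a,features_b data.frames of per-cell features (columns
#'   named cm, mp, rin, rheobase, threshold, ap_peak, half_width, ahp,
#'   count60, count100, count200; missing columns allowed).
#' @param labels group labels.
#' @param min_n_for_ks test-switch threshold, see
#'   \code{\link{compare_cohorts}}.
#' @return data.frame with columns measure, mean_a, sem_a, n_a, mean_b,
#'   sem_b, n_b, p, test.
#' @export
summarize_table <- function(features_a, features_b,
                            labels = c("WT", "dKO"), min_n_for_ks = 10) {
  rows <- lapply(names(.feature_keys), function(key) {
    a <- if (key %in% names(features_a)) features_a[[key]] else numeric(0)
    b <- if (key %in% names(features_b)) features_b[[key]] else numeric(0)
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) == 0 && length(b) == 0)
      return(data.frame(measure = .feature_keys[[key]], mean_a = NA, sem_a = NA,
                        n_a = 0L, mean_b = NA, sem_b = NA, n_b = 0L,
                        p = NA, test = "absent"))
    cmp <- if (length(a) >= 1 && length(b) >= 1)
      compare_cohorts(a, b, labels, min_n_for_ks)
    else NULL
    data.frame(measure = .feature_keys[[key]],
               mean_a = if (length(a)) mean(a) else NA,
               sem_a = if (length(a) > 1) sd(a) / sqrt(length(a)) else NA,
               n_a = length(a),
               mean_b = if (length(b)) mean(b) else NA,
               sem_b = if (length(b) > 1) sd(b) / sqrt(length(b)) else NA,
               n_b = length(b),
               p = if (!is.null(cmp)) cmp$p else NA,
               test = if (!is.null(cmp)) cmp$test_used else "absent")
  })
  out <- do.call(rbind, rows)
  names(out)[c(2:4, 5:7)] <- c(paste0(c("mean_", "sem_", "n_"), labels[1]),
                               paste0(c("mean_", "sem_", "n_"), labels[2]))
  rownames(out) <- NULL
  out
}
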