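#' Baseline mean and SD of a sweep
#'
#' Mean and standard deviation of the signal over a window, optionally
#' after spike blanking (required when quantifying subthreshold voltage
#' noise in current clamp, where the action potentials would otherwise
#' dominate the SD).
#'
#' @param sweep a [sweep_record()].
#' @param window `c(start, end)` in seconds, inside the sweep.
#' @param blank logical; detect and blank spikes first (current-clamp /
#'   extracellular sweeps only).
#' @param spikes optional precomputed [spike_train()] to use for blanking.
#' @return an object of class `"baseline_stats"`: `mean`, `sd` (mV or pA
#'   per the sweep modality), `window`, `blanked`, `modality`.
#' @export
baseline_stats <- function(sweep, window, blank = FALSE, spikes = NULL) {
  stopifnot(inherits(sweep, "sweep_record"))
  dur <- sweep_duration(sweep)
  if (window[1] < 0 || window[2] > dur + 1e-9 || window[2] <= window[1]) {
    stop("window [", window[1], ", ", window[2], "] s lies outside the sweep")
  }
  if (blank) {
    if (is.null(spikes)) spikes <- detect_spikes(sweep)
    sweep <- blank_spikes(sweep, spikes)
  }
  t <- sweep_times(sweep)
  x <- sweep$signal[t >= window[1] & t < window[2]]
  if (!length(x)) stop("window contains no samples")
  structure(list(mean = mean(x), sd = stats::sd(x), window = window,
                 blanked = isTRUE(blank), modality = sweep$modality),
            class = "baseline_stats")
}

#' Campbell-theorem moments of a shot-noise current
#'
#' For a Poisson train of unitary conductance events (peak A nS,
#' instant-rise exponential kernel with decay tau) at rate nu, driven
#' across a fixed driving force F (mV), the stationary current has
#' `mean = nu * A * F * tau` and `variance = nu * (A F)^2 * tau / 2`,
#' using the closed-form kernel integrals (integral of w = tau, integral
#' of w^2 = tau/2).  This is the independent oracle against which the
#' simulated shot-noise drive is checked, and it links unitary event size
#' to baseline current noise: at a fixed mean current, larger unitaries
#' give larger variance.
#'
#' @param rate_hz event rate nu, Hz (>= 0).
#' @param unit a [unitary_event()].
#' @param driving_force_mv driving force `V - E_rev`, mV.
#' @return list with `mean_pa` and `variance_pa2`.
#' @examples
#' campbell_moments(1000, unitary_event(0.1, 2), -60)
#' # mean -12 pA, variance 36 pA^2
#' @export
campbell_moments <- function(rate_hz, unit, driving_force_mv) {
  stopifnot(inherits(unit, "unitary_event"))
  if (rate_hz < 0) stop("rate must be >= 0")
  tau_s <- unit$tau_ms / 1000
  a_f <- unit$amplitude_ns * driving_force_mv  # nS * mV = pA
  list(mean_pa = rate_hz * a_f * tau_s,
       variance_pa2 = rate_hz * a_f^2 * tau_s / 2)
}

#' Compare two groups of per-cell measurements
#'
#' The statistical layer used throughout: a Shapiro-Wilk normality check
#' (advisory; a warning flag is attached on failure, the test is not
#' switched), a two-tailed paired or unpaired t-test, and an optional
#' Bonferroni correction `p_adj = min(1, m p)`.
#'
#' @param a,b numeric vectors of per-cell values (equal length for the
#'   paired design).
#' @param design `"paired"` or `"unpaired"`.
#' @param m_comparisons number of comparisons in the family for the
#'   Bonferroni correction (1 = no correction).
#' @param alpha significance level recorded with the result.
#' @return an object of class `"group_comparison"`: group means and SDs,
#'   n per group, `normality_p` (per group; on paired differences for the
#'   paired design), `p_value`, `p_adjusted`, `correction`, flags.
#' @export
compare_groups <- function(a, b, design = c("paired", "unpaired"),
                           m_comparisons = 1, alpha = 0.05) {
  design <- match.arg(design)
  if (design == "paired" && length(a) != length(b)) {
    stop("paired design needs equal-length groups")
  }
  if (design == "paired" && length(a) < 2) stop("paired design needs n >= 2")
  degenerate <- FALSE
  if (design == "paired") {
    d <- a - b
    norm_p <- if (length(unique(d)) > 2 && length(d) >= 3)
      stats::shapiro.test(d)$p.value else NA_real_
    if (stats::sd(d) == 0) {
      degenerate <- TRUE
      p <- if (mean(d) == 0) 1 else 0
      tstat <- NA_real_
    } else {
      tt <- stats::t.test(a, b, paired = TRUE)
      p <- tt$p.value; tstat <- unname(tt$statistic)
    }
  } else {
    norm_p <- c(
      if (length(unique(a)) > 2 && length(a) >= 3)
        stats::shapiro.test(a)$p.value else NA_real_,
      if (length(unique(b)) > 2 && length(b) >= 3)
        stats::shapiro.test(b)$p.value else NA_real_)
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      degenerate <- TRUE
      p <- if (mean(a) == mean(b)) 1 else 0
      tstat <- NA_real_
    } else {
      tt <- stats::t.test(a, b, paired = FALSE)
      p <- tt$p.value; tstat <- unname(tt$statistic)
    }
  }
  p_adj <- min(1, m_comparisons * p)
  structure(list(
    mean_a = mean(a), sd_a = stats::sd(a), n_a = length(a),
    mean_b = mean(b), sd_b = stats::sd(b), n_b = length(b),
    design = design, t_statistic = tstat,
    normality_p = norm_p,
    normality_warning = any(!is.na(norm_p) & norm_p < alpha),
    p_value = p, p_adjusted = p_adj,
    correction = if (m_comparisons > 1) "bonferroni" else "none",
    m_comparisons = m_comparisons, alpha = alpha,
    degenerate = degenerate
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>", x$design, "t-test\n")
  cat("  a:", signif(x$mean_a, 4), "+/-", signif(x$sd_a, 4), "( n =",
      x$n_a, ")\n")
  cat("  b:", signif(x$mean_b, 4), "+/-", signif(x$sd_b, 4), "( n =",
      x$n_b, ")\n")
  cat("  p =", signif(x$p_value, 3),
      if (x$correction == "bonferroni")
        paste("( Bonferroni adjusted:", signif(x$p_adjusted, 3), ")")
      else "", "\n")
  if (x$normality_warning) cat("  note: Shapiro-Wilk p <", x$alpha, "\n")
  invisible(x)
}
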