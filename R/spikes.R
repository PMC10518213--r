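#' Detect spikes with a derivative threshold
#'
#' Takes the first difference of the voltage trace (which removes slow
#' baseline drift), computes the standard deviation of the whole
#' derivative trace, and marks positive-going crossings of
#' `threshold_sd` times that SD as spike times, with a refractory lockout
#' so biphasic derivative transients are not double-counted.  Spike times
#' are reported at the crossing sample.
#'
#' @param sweep a [sweep_record()] of modality `"extracellular"` or
#'   `"current_clamp"`.
#' @param threshold_sd threshold multiplier on the derivative SD
#'   (default 3).
#' @param lockout_ms refractory lockout in ms (default 1).
#' @param polarity `"positive"` (default) or `"negative"` crossings.
#' @return an object of class `"spike_train"`: list with `spike_times`
#'   (seconds, strictly increasing), `threshold_sd`, `sweep_duration`,
#'   `sampling_rate` and the source `cell_id`.
#' @export
detect_spikes <- function(sweep, threshold_sd = 3, lockout_ms = 1,
                          polarity = c("positive", "negative")) {
  stopifnot(inherits(sweep, "sweep_record"))
  polarity <- match.arg(polarity)
  if (!sweep$modality %in% c("extracellular", "current_clamp")) {
    stop("spike detection needs an extracellular or current_clamp sweep")
  }
  x <- sweep$signal
  if (length(x) < 10L) stop("trace too short for spike detection")
  d <- diff(x)
  if (polarity == "negative") d <- -d
  s <- stats::sd(d)
  times <- numeric(0)
  if (s > 0) {
    thr <- threshold_sd * s
    above <- d > thr
    crossings <- which(above & !c(FALSE, above[-length(above)]))
    if (length(crossings)) {
      lock <- max(1L, round(lockout_ms / 1000 * sweep$sampling_rate))
      keep <- crossings[1]
      if (length(crossings) > 1L) {
        for (idx in crossings[-1]) {
          if (idx - keep[length(keep)] >= lock) keep <- c(keep, idx)
        }
      }
      times <- keep / sweep$sampling_rate  # derivative sample k spans [k, k+1)
    }
  }
  structure(list(spike_times = times, threshold_sd = threshold_sd,
                 sweep_duration = sweep_duration(sweep),
                 sampling_rate = sweep$sampling_rate,
                 cell_id = sweep$cell_id),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat("<spike_train>", length(x$spike_times), "spikes in",
      signif(x$sweep_duration, 4), "s ( threshold",
      x$threshold_sd, "SD )\n")
  invisible(x)
}

#' Blank spikes by linear interpolation
#'
#' Replaces the window from 1 ms before to 3 ms after each spike time
#' with the straight line between the window's boundary samples, so the
#' large depolarising transients no longer dominate subthreshold
#' statistics.  Overlapping windows are merged before interpolation;
#' windows clipped by the trace edge are anchored at the clipped edge
#' sample.
#'
#' @param sweep a [sweep_record()].
#' @param spikes a [spike_train()] from the same sweep, or a numeric
#'   vector of spike times in seconds.
#' @param pre_ms,post_ms window extent around each spike (defaults 1 and
#'   3 ms).
#' @return the sweep with blanked signal; samples outside the merged
#'   windows are bit-identical to the input.
#' @export
blank_spikes <- function(sweep, spikes, pre_ms = 1, post_ms = 3) {
  stopifnot(inherits(sweep, "sweep_record"))
  times <- if (inherits(spikes, "spike_train")) spikes$spike_times
           else as.numeric(spikes)
  if (!length(times)) return(sweep)
  if (any(times < 0 | times > sweep_duration(sweep))) {
    stop("spike times fall outside the sweep")
  }
  fs <- sweep$sampling_rate
  n <- length(sweep$signal)
  lo <- pmax(1L, floor((times - pre_ms / 1000) * fs) + 1L)
  hi <- pmin(n, ceiling((times + post_ms / 1000) * fs) + 1L)
  ord <- order(lo)
  lo <- lo[ord]; hi <- hi[ord]
  # merge overlapping or adjacent windows
  m_lo <- lo[1]; m_hi <- hi[1]
  merged <- list()
  for (k in seq_along(lo)[-1]) {
    if (lo[k] <= m_hi + 1L) {
      m_hi <- max(m_hi, hi[k])
    } else {
      merged[[length(merged) + 1L]] <- c(m_lo, m_hi)
      m_lo <- lo[k]; m_hi <- hi[k]
    }
  }
  merged[[length(merged) + 1L]] <- c(m_lo, m_hi)
  x <- sweep$signal
  for (w in merged) {
    a <- w[1]; b <- w[2]
    x[a:b] <- seq(x[a], x[b], length.out = b - a + 1L)
  }
  sweep$signal <- x
  sweep
}

#' Peristimulus time histogram
#'
#' Bins spikes from repeated trials into fixed-width bins; the rate in
#' each bin is the total count divided by (number of trials times bin
#' width), so the PSTH integral times trials times bin width conserves
#' the total spike count exactly.  Trials are grouped into blocks of
#' `n_per_block` and the across-block SD of the block-wise PSTHs is
#' reported per bin.
#'
#' @param trains list of [spike_train()] objects (or numeric vectors of
#'   spike times, in which case `duration` must be given); the number of
#'   trials must be a positive multiple of `n_per_block`.
#' @param bin_width_ms bin width in ms (default 20).
#' @param n_per_block trials per block (default 20).
#' @param duration sweep duration in seconds (taken from the trains when
#'   available).
#' @return an object of class `"psth"`: list with `bin_start_s`, `rate_hz`,
#'   `sd_hz` (NA with a single block), `bin_width_ms`, `n_trials`.
#' @export
compute_psth <- function(trains, bin_width_ms = 20, n_per_block = 20,
                         duration = NULL) {
  if (inherits(trains, "spike_train")) trains <- list(trains)
  n_trials <- length(trains)
  if (n_trials == 0L || n_trials %% n_per_block != 0L) {
    stop("number of trials (", n_trials, ") must be a positive multiple of ",
         n_per_block, "; trim trials explicitly before calling")
  }
  times_list <- lapply(trains, function(tr) {
    if (inherits(tr, "spike_train")) tr$spike_times else as.numeric(tr)
  })
  if (is.null(duration)) {
    durs <- vapply(trains, function(tr) {
      if (inherits(tr, "spike_train")) tr$sweep_duration else NA_real_
    }, numeric(1))
    if (all(is.na(durs))) stop("duration must be supplied for raw spike times")
    duration <- max(durs, na.rm = TRUE)
  }
  bw_s <- bin_width_ms / 1000
  n_bins <- ceiling(duration / bw_s - 1e-9)
  breaks <- (0:n_bins) * bw_s
  count_one <- function(times) {
    if (!length(times)) return(integer(n_bins))
    tabulate(pmin(n_bins, floor(times / bw_s) + 1L), nbins = n_bins)
  }
  counts <- vapply(times_list, count_one, integer(n_bins))
  counts <- matrix(counts, nrow = n_bins)
  total <- rowSums(counts)
  rate <- total / (n_trials * bw_s)
  n_blocks <- n_trials %/% n_per_block
  sd_hz <- rep(NA_real_, n_bins)
  if (n_blocks > 1L) {
    block_rates <- vapply(seq_len(n_blocks), function(b) {
      cols <- ((b - 1L) * n_per_block + 1L):(b * n_per_block)
      rowSums(counts[, cols, drop = FALSE]) / (n_per_block * bw_s)
    }, numeric(n_bins))
    sd_hz <- apply(matrix(block_rates, nrow = n_bins), 1, stats::sd)
  }
  structure(list(bin_start_s = breaks[-length(breaks)], rate_hz = rate,
                 sd_hz = sd_hz, bin_width_ms = bin_width_ms,
                 n_trials = n_trials, duration = duration),
            class = "psth")
}

#' @export
print.psth <- function(x, ...) {
  cat("<psth>", length(x$rate_hz), "bins of", x$bin_width_ms, "ms from",
      x$n_trials, "trials; mean rate", signif(mean(x$rate_hz), 4), "Hz\n")
  invisible(x)
}

#' Default analysis windows for response metrics
#'
#' The background window is the 300 ms immediately before stimulus onset,
#' the peak window the first 150 ms of the On-phase, and the sustained
#' window the last 250 ms of the On-phase.  These are a reading of the
#' usual measurement points on published histograms, not printed values,
#' and are therefore configuration, recorded in every result.
#'
#' @param stim a [stimulus_spec()].
#' @return list of `c(start, end)` windows in seconds: `background`,
#'   `peak`, `sustained`.
#' @export
default_response_windows <- function(stim) {
  on_start <- stim$phase_zero
  on_end <- stim$phase_zero + 0.5 / stim$frequency
  list(background = c(max(0, on_start - 0.3), on_start),
       peak = c(on_start, on_start + 0.15),
       sustained = c(on_end - 0.25, on_end))
}

#' Background, peak and sustained firing rates from a PSTH
#'
#' Background is the mean rate over the pre-stimulus window, peak the
#' maximum bin within the onset window after the On-phase start, and
#' sustained the mean over the late-On window.
#'
#' @param psth a [compute_psth()] result spanning at least one full
#'   stimulus cycle plus the pre-stimulus epoch.
#' @param stim the [stimulus_spec()] the trials used.
#' @param windows list of windows as from [default_response_windows()]
#'   (which is the default).
#' @return an object of class `"response_metrics"`: `background_rate`,
#'   `peak_rate`, `sustained_rate` (Hz) plus the windows used.
#' @export
response_metrics <- function(psth, stim,
                             windows = default_response_windows(stim)) {
  stopifnot(inherits(psth, "psth"), inherits(stim, "stimulus_spec"))
  bw_s <- psth$bin_width_ms / 1000
  bins_in <- function(w) {
    idx <- which(psth$bin_start_s >= w[1] - 1e-9 &
                   psth$bin_start_s + bw_s <= w[2] + 1e-9)
    if (!length(idx)) {
      stop("window [", w[1], ", ", w[2], "] s contains no complete PSTH bin")
    }
    idx
  }
  bg <- mean(psth$rate_hz[bins_in(windows$background)])
  pk <- max(psth$rate_hz[bins_in(windows$peak)])
  su <- mean(psth$rate_hz[bins_in(windows$sustained)])
  structure(list(background_rate = bg, peak_rate = pk, sustained_rate = su,
                 windows = windows),
            class = "response_metrics")
}

#' @export
print.response_metrics <- function(x, ...) {
  cat("<response_metrics> background", signif(x$background_rate, 4),
      "Hz | peak", signif(x$peak_rate, 4), "Hz | sustained",
      signif(x$sustained_rate, 4), "Hz\n")
  invisible(x)
}

#' Percent change between two rates or amplitudes
#'
#' `100 * (a - b) / a`, rounded half-away-from-zero to the nearest
#' integer for reporting (the reporting style used for group-mean
#' reductions); the unrounded value is retained in the `"exact"`
#' attribute.
#'
#' @param a reference value (> 0).
#' @param b comparison value in the same units.
#' @return integer-rounded percent change, with attribute `exact`.
#' @examples
#' percent_change(11.9, 6.1)   # 49
#' percent_change(86.8, 55.5)  # 36
#' @export
percent_change <- function(a, b) {
  if (!is.finite(a) || a <= 0) stop("reference value a must be positive")
  exact <- 100 * (a - b) / a
  out <- sign(exact) * floor(abs(exact) + 0.5)
  attr(out, "exact") <- exact
  out
}
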