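#' Net light-evoked current at one holding potential
#'
#' Averages voltage-clamp sweeps recorded at a common (junction-corrected)
#' holding potential and subtracts the mean over a pre-stimulus baseline
#' window.  The per-potential subtraction removes the leak current and
#' any tonic offset at that potential, leaving the net light-evoked
#' synaptic current.
#'
#' @param sweeps list of voltage-clamp [sweep_record()]s at one holding
#'   potential.
#' @param baseline_window `c(start, end)` in seconds, preceding the
#'   stimulus (default the first 300 ms).
#' @return an object of class `"net_current"`: list with `current` (pA),
#'   `v_hold` (mV), `sampling_rate`, `n_sweeps`, `baseline_window`.
#' @export
net_light_evoked <- function(sweeps, baseline_window = c(0, 0.3)) {
  if (inherits(sweeps, "sweep_record")) sweeps <- list(sweeps)
  if (!length(sweeps)) stop("no sweeps supplied")
  ok <- vapply(sweeps, function(s) {
    inherits(s, "sweep_record") && s$modality == "voltage_clamp"
  }, logical(1))
  if (!all(ok)) stop("all sweeps must be voltage_clamp sweep_records")
  vh <- vapply(sweeps, `[[`, numeric(1), "holding_potential")
  if (length(unique(vh)) != 1L) {
    stop("sweeps span multiple holding potentials: ",
         paste(unique(vh), collapse = ", "))
  }
  fs <- sweeps[[1]]$sampling_rate
  n <- length(sweeps[[1]]$signal)
  sig <- rowMeans(vapply(sweeps, `[[`, numeric(n), "signal"))
  idx <- which((seq_len(n) - 1) / fs >= baseline_window[1] &
                 (seq_len(n) - 1) / fs < baseline_window[2])
  if (!length(idx)) stop("baseline window contains no samples")
  net <- sig - mean(sig[idx])
  structure(list(current = net, v_hold = vh[1], sampling_rate = fs,
                 n_sweeps = length(sweeps),
                 baseline_window = baseline_window),
            class = "net_current")
}

#' Build a time-resolved I-V series from net currents
#'
#' Averages each net current trace within consecutive time bins (10 ms by
#' default), yielding one (V, I) point per holding potential per bin.
#'
#' @param nets list of [net_light_evoked()] results, one per holding
#'   potential, on a common time base.
#' @param bin_ms bin width in ms (default 10); bin centers form the time
#'   grid.
#' @return an object of class `"iv_series"`: `time_ms` (bin centers),
#'   `potentials` (mV), `currents` (bins x potentials matrix, pA),
#'   `n_sweeps` per potential.
#' @export
build_iv_series <- function(nets, bin_ms = 10) {
  if (inherits(nets, "net_current")) nets <- list(nets)
  if (length(nets) < 2L) stop("need net currents at >= 2 holding potentials")
  fs <- unique(vapply(nets, `[[`, numeric(1), "sampling_rate"))
  n <- unique(vapply(nets, function(x) length(x$current), integer(1)))
  if (length(fs) != 1L || length(n) != 1L) {
    stop("net currents must share a common time base")
  }
  pot <- vapply(nets, `[[`, numeric(1), "v_hold")
  ord <- order(pot)
  nets <- nets[ord]; pot <- pot[ord]
  samp_per_bin <- round(bin_ms / 1000 * fs)
  if (samp_per_bin < 1L) stop("bin_ms shorter than one sample")
  n_bins <- n %/% samp_per_bin
  bin_of <- rep(seq_len(n_bins), each = samp_per_bin)
  currents <- vapply(nets, function(x) {
    as.numeric(tapply(x$current[seq_along(bin_of)], bin_of, mean))
  }, numeric(n_bins))
  time_ms <- (seq_len(n_bins) - 0.5) * bin_ms
  structure(list(time_ms = time_ms, potentials = pot,
                 currents = matrix(currents, nrow = n_bins),
                 n_sweeps = vapply(nets, `[[`, integer(1) + 0, "n_sweeps")),
            class = "iv_series")
}

#' Fit a linear current-voltage relation
#'
#' Least-squares line through (V, I) points; the slope is the conductance
#' (nS when V is in mV and I in pA) and the reversal potential is where
#' the line crosses zero current.
#'
#' @param v holding potentials, mV (>= 2 distinct values).
#' @param i currents, pA.
#' @return an object of class `"linear_iv_fit"`: `conductance_ns`,
#'   `reversal_mv` (NaN with a `degenerate` flag when the slope is zero),
#'   `r_squared`, `n_points`.
#' @export
fit_linear_iv <- function(v, i) {
  if (length(v) != length(i)) stop("v and i must have equal length")
  if (length(unique(v)) < 2L) {
    stop("need >= 2 distinct potentials for a linear I-V fit")
  }
  fit <- stats::lm.fit(cbind(1, v), i)
  slope <- unname(fit$coefficients[2])
  intercept <- unname(fit$coefficients[1])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((i - mean(i))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  degenerate <- slope == 0
  reversal <- if (degenerate) NaN else -intercept / slope
  structure(list(conductance_ns = slope, reversal_mv = reversal,
                 r_squared = r2, n_points = length(v),
                 degenerate = degenerate),
            class = "linear_iv_fit")
}

#' @export
print.linear_iv_fit <- function(x, ...) {
  cat("<linear_iv_fit> G =", signif(x$conductance_ns, 4), "nS, E_rev =",
      signif(x$reversal_mv, 4), "mV ( R2 =", signif(x$r_squared, 4), ", n =",
      x$n_points, ")\n")
  invisible(x)
}

#' Decompose an I-V series into synaptic conductances
#'
#' Per time bin, solves the least-squares system
#' `I(V) = G_exc (V - E_exc) + G_inh (V - E_inh) + G_nmda B(V) (V - E_exc)`
#' for the component conductances, with the reversal potentials fixed by
#' assumption (E_exc = 0 mV, E_inh = -70 mV by default) and the NMDA
#' voltage dependence B(V) given by [mg_block()].  Conductances are not
#' constrained to be non-negative: negative values are meaningful and
#' indicate suppression of a baseline (pre-stimulus) conductance.
#'
#' @param iv an [build_iv_series()] result.
#' @param nmda logical; include the NMDA component (use `FALSE` for cells
#'   whose excitation is well fit by a linear I-V).
#' @param e_exc_mV,e_inh_mV assumed reversal potentials, mV.
#' @param mg a [mg_block_params()]; recorded in the result.
#' @param weights optional per-potential weights (e.g. sweep counts);
#'   equal weights by default.
#' @return an object of class `"conductance_trace"`: a data frame with
#'   columns `time_ms`, `g_exc_ns`, `g_inh_ns`, `g_nmda_ns`, `rmse_pa`,
#'   and attributes `e_exc_mV`, `e_inh_mV`, `mg` (the B(V) parameter
#'   record), `potentials` and `condition_number`.
#' @export
decompose_conductances <- function(iv, nmda = TRUE, e_exc_mV = 0,
                                   e_inh_mV = -70, mg = mg_block_params(),
                                   weights = NULL) {
  stopifnot(inherits(iv, "iv_series"))
  v <- iv$potentials
  n_par <- if (nmda) 3L else 2L
  if (length(v) < n_par) {
    stop("need at least ", n_par, " potentials per bin for this model")
  }
  X <- cbind(exc = v - e_exc_mV, inh = v - e_inh_mV)
  if (nmda) X <- cbind(X, nmda = mg_block(v, mg) * (v - e_exc_mV))
  if (!is.null(weights)) {
    if (length(weights) != length(v)) stop("one weight per potential needed")
    w <- sqrt(weights)
  } else {
    w <- rep(1, length(v))
  }
  Xw <- X * w
  cond <- kappa(Xw, exact = TRUE)
  if (cond > 1e6) {
    warning("ill-conditioned design (condition number ", signif(cond, 3),
            "): B(V) (V - E_exc) nearly collinear with the linear terms ",
            "over the supplied potentials")
  }
  n_bins <- nrow(iv$currents)
  coefs <- matrix(0, n_bins, 3,
                  dimnames = list(NULL, c("exc", "inh", "nmda")))
  rmse <- numeric(n_bins)
  qrX <- qr(Xw)
  for (b in seq_len(n_bins)) {
    y <- iv$currents[b, ] * w
    beta <- qr.coef(qrX, y)
    res <- y - Xw %*% beta
    coefs[b, seq_len(n_par)] <- beta
    rmse[b] <- sqrt(mean(res^2))
  }
  out <- data.frame(time_ms = iv$time_ms,
                    g_exc_ns = coefs[, "exc"],
                    g_inh_ns = coefs[, "inh"],
                    g_nmda_ns = coefs[, "nmda"],
                    rmse_pa = rmse)
  structure(out, class = c("conductance_trace", "data.frame"),
            e_exc_mV = e_exc_mV, e_inh_mV = e_inh_mV, mg = mg,
            potentials = v, condition_number = cond, nmda = nmda)
}

#' Reconstruct currents from a conductance trace
#'
#' Evaluates the forward model at one holding potential; on fitted data
#' this reproduces the input currents up to the reported per-bin fit
#' residual.
#'
#' @param g a `"conductance_trace"`.
#' @param v_hold holding potential, mV.
#' @return numeric current trace, pA, one value per time bin.
#' @export
reconstruct_currents <- function(g, v_hold) {
  stopifnot(inherits(g, "conductance_trace"))
  e_exc <- attr(g, "e_exc_mV"); e_inh <- attr(g, "e_inh_mV")
  b <- mg_block(v_hold, attr(g, "mg"))
  g$g_exc_ns * (v_hold - e_exc) + g$g_inh_ns * (v_hold - e_inh) +
    g$g_nmda_ns * b * (v_hold - e_exc)
}

#' Difference conductance between two conditions
#'
#' Component-wise control minus drug, used to isolate the conductance
#' blocked by an antagonist.  Requires identical time grids and B(V)
#' parameter records.
#'
#' @param ctrl,drug `"conductance_trace"` objects.
#' @return a `"conductance_trace"` of the differences (RMSE column set to
#'   NA; it is not meaningful for a difference).
#' @export
difference_conductance <- function(ctrl, drug) {
  stopifnot(inherits(ctrl, "conductance_trace"),
            inherits(drug, "conductance_trace"))
  if (!isTRUE(all.equal(ctrl$time_ms, drug$time_ms))) {
    stop("time grids differ between the two conductance traces")
  }
  if (!identical(attr(ctrl, "mg"), attr(drug, "mg"))) {
    stop("B(V) parameter records differ; traces are not comparable")
  }
  out <- ctrl
  out$g_exc_ns <- ctrl$g_exc_ns - drug$g_exc_ns
  out$g_inh_ns <- ctrl$g_inh_ns - drug$g_inh_ns
  out$g_nmda_ns <- ctrl$g_nmda_ns - drug$g_nmda_ns
  out$rmse_pa <- NA_real_
  out
}

#' Time-course similarity between two traces
#'
#' Finds the least-squares scale factor s minimising
#' `sum((a - s b)^2)` (closed form `sum(a b) / sum(b^2)`) together with
#' the Pearson correlation of the two traces, quantifying whether two
#' conductance components share a time course up to magnitude.
#'
#' @param a,b numeric traces on a common grid.
#' @return list with `scale` (NA with a flag when `b` is identically
#'   zero) and `correlation`.
#' @export
timecourse_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("traces must share a common grid")
  ss_b <- sum(b^2)
  if (ss_b == 0) {
    return(list(scale = NA_real_, correlation = NA_real_,
                degenerate = TRUE))
  }
  corr <- if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_
          else stats::cor(a, b)
  list(scale = sum(a * b) / ss_b,
       correlation = corr,
       degenerate = FALSE)
}
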