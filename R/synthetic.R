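#' Render a stimulus specification as an intensity trace
#'
#' Builds the square-wave contrast-modulated intensity trace for a
#' [stimulus_spec()]: background before `phase_zero`, then alternating
#' L_max / L_min half-cycles starting with the On-phase.  Modulation is
#' symmetric about the background, so
#' `contrast_percent = 100 * (L_max - L_min) / L_background` holds exactly.
#'
#' @param spec a [stimulus_spec()].
#' @param sampling_rate sampling rate in Hz.
#' @return numeric intensity trace (class `"stimulus_trace"`) with the
#'   spec and sampling rate attached as attributes.
#' @examples
#' st <- make_stimulus(stimulus_spec(600, 80, 1, duration = 2, phase_zero = 0),
#'                     sampling_rate = 1000)
#' range(st)  # 360, 840
#' @export
make_stimulus <- function(spec, sampling_rate) {
  stopifnot(inherits(spec, "stimulus_spec"))
  n <- round(spec$duration * sampling_rate)
  t <- (seq_len(n) - 1L) / sampling_rate
  half_amp <- spec$contrast_percent / 100 * spec$background_intensity / 2
  l_max <- spec$background_intensity + half_amp
  l_min <- spec$background_intensity - half_amp
  trace <- rep(spec$background_intensity, n)
  on_stim <- t >= spec$phase_zero
  # half-cycle index since phase_zero; even = On-phase, half-open bins
  half_idx <- floor((t[on_stim] - spec$phase_zero) * spec$frequency * 2)
  trace[on_stim] <- ifelse(half_idx %% 2 == 0, l_max, l_min)
  structure(trace, class = "stimulus_trace", spec = spec,
            sampling_rate = sampling_rate)
}

#' Unitary synaptic event
#'
#' The elementary conductance event of the shot-noise drive: instant rise
#' to the peak amplitude followed by a single-exponential decay, so the
#' normalised kernel satisfies w(0) = 1, integral tau, integral of w^2
#' tau/2.
#'
#' @param amplitude_ns peak conductance in nS.
#' @param tau_ms decay time constant in ms.
#' @return an object of class `"unitary_event"`.
#' @export
unitary_event <- function(amplitude_ns = 0.27, tau_ms = 2) {
  if (amplitude_ns < 0) stop("amplitude_ns must be >= 0")
  if (tau_ms <= 0) stop("tau_ms must be positive")
  structure(list(amplitude_ns = amplitude_ns, tau_ms = tau_ms),
            class = "unitary_event")
}

#' Magnesium-block parameters for the NMDA conductance
#'
#' Sigmoidal voltage dependence `B(V) = 1 / (1 + (Mg/c) * exp(-V/k))`.
#' Defaults are the classic fit to NMDA channel block (Mg = 1 mM,
#' c = 3.57 mM, k = 16.13 mV, i.e. the familiar
#' `1/(1 + exp(-0.062 V) [Mg]/3.57)` parameterisation).  These defaults
#' are configurable and are recorded in every conductance fit report so
#' decompositions are reproducible.
#'
#' @param mg_mM extracellular magnesium concentration, mM.
#' @param c_mM concentration scale, mM.
#' @param k_mV voltage steepness, mV per e-fold.
#' @return an object of class `"mg_block_params"`.
#' @export
mg_block_params <- function(mg_mM = 1, c_mM = 3.57, k_mV = 16.13) {
  stopifnot(mg_mM >= 0, c_mM > 0, k_mV > 0)
  structure(list(mg_mM = mg_mM, c_mM = c_mM, k_mV = k_mV),
            class = "mg_block_params")
}

#' Evaluate the magnesium-block nonlinearity B(V)
#'
#' @param v membrane potential(s) in mV.
#' @param params a [mg_block_params()].
#' @return unblocked fraction in (0, 1], same length as `v`.
#' @export
mg_block <- function(v, params = mg_block_params()) {
  stopifnot(inherits(params, "mg_block_params"))
  1 / (1 + (params$mg_mM / params$c_mM) * exp(-v / params$k_mV))
}

#' Conductance-based point-neuron model
#'
#' @param capacitance_pF membrane capacitance, pF (> 0).
#' @param g_leak_nS leak conductance, nS (>= 0).
#' @param e_leak_mV leak reversal potential, mV.
#' @param e_exc_mV excitatory reversal potential, mV (default 0).
#' @param e_inh_mV inhibitory reversal potential, mV (default -70).
#' @param spike spike mechanism for current-clamp simulations: a list with
#'   `threshold_mV`, `reset_mV`, `refractory_ms` and (for the pasted
#'   stereotyped waveform) `spike_amp_mV`; or `NULL` for non-spiking cells.
#' @param mg a [mg_block_params()] describing the NMDA voltage dependence.
#' @return an object of class `"cell_model"`.
#' @export
cell_model <- function(capacitance_pF = 60, g_leak_nS = 4, e_leak_mV = -65,
                       e_exc_mV = 0, e_inh_mV = -70,
                       spike = list(threshold_mV = -50, reset_mV = -56,
                                    refractory_ms = 3, spike_amp_mV = 60),
                       mg = mg_block_params()) {
  if (capacitance_pF <= 0) stop("capacitance_pF must be positive")
  if (g_leak_nS < 0) stop("g_leak_nS must be >= 0")
  if (e_inh_mV >= e_exc_mV) stop("E_inh must be below E_exc")
  structure(list(capacitance_pF = capacitance_pF, g_leak_nS = g_leak_nS,
                 e_leak_mV = e_leak_mV, e_exc_mV = e_exc_mV,
                 e_inh_mV = e_inh_mV, spike = spike, mg = mg),
            class = "cell_model")
}

#' Poisson shot-noise conductance
#'
#' Realises an inhomogeneous-Poisson train of unitary events convolved
#' with the event kernel (instant rise, exponential decay).  Event times
#' are drawn in continuous time by thinning and evaluated exactly at the
#' sample grid, so the sampled moments match the closed-form
#' [campbell_moments()] without discretisation bias.  A warm-up period of
#' ten decay constants (at the initial rate) precedes the returned trace
#' so it starts in the stationary regime.
#'
#' @param rate event-rate trace in Hz, one value per output sample
#'   (piecewise constant over each sample interval); all values >= 0.
#' @param unit a [unitary_event()].
#' @param sampling_rate sampling rate in Hz.
#' @param seed integer seed; identical seeds give identical traces.
#' @return conductance trace in nS, same length as `rate`.
#' @export
shot_noise_conductance <- function(rate, unit, sampling_rate, seed) {
  stopifnot(inherits(unit, "unitary_event"))
  if (any(rate < 0)) stop("event rate must be >= 0 everywhere")
  n <- length(rate)
  dt <- 1 / sampling_rate
  tau_s <- unit$tau_ms / 1000
  if (!missing(seed) && !is.null(seed)) set.seed(seed)
  n_warm <- ceiling(10 * tau_s / dt)
  rate_ext <- c(rep(rate[1], n_warm), rate)
  n_ext <- length(rate_ext)
  rate_max <- max(rate_ext)
  g <- numeric(n_ext)
  if (rate_max > 0 && unit$amplitude_ns > 0) {
    t_total <- n_ext * dt
    n_ev <- stats::rpois(1, rate_max * t_total)
    if (n_ev > 0) {
      t_ev <- stats::runif(n_ev, 0, t_total)
      # thinning against the piecewise-constant rate trace
      idx_rate <- pmin(floor(t_ev / dt) + 1L, n_ext)
      keep <- stats::runif(n_ev) < rate_ext[idx_rate] / rate_max
      t_ev <- t_ev[keep]
      if (length(t_ev)) {
        # first sample at or after each event; exact kernel value there
        i0 <- ceiling(t_ev / dt) + 1L
        w <- unit$amplitude_ns * exp(-((i0 - 1L) * dt - t_ev) / tau_s)
        inside <- i0 <= n_ext
        if (any(inside)) {
          impulses <- numeric(n_ext)
          agg <- rowsum(w[inside], i0[inside])
          impulses[as.integer(rownames(agg))] <- agg
          g <- as.numeric(stats::filter(impulses, exp(-dt / tau_s),
                                        method = "recursive"))
        }
      }
    }
  }
  g[(n_warm + 1):n_ext]
}

#' Generative specification of the synaptic drive to a ganglion cell
#'
#' Encodes the four input components the analyses dissect: a tonic
#' shot-noise excitatory conductance modulated by stimulus contrast (the
#' CP-AMPAR-dependent pathway through the AII amacrine network), a
#' rectified transient excitatory component triggered at On-phase onsets
#' (the direct cone bipolar pathway), an NMDA-type conductance riding on
#' the excitatory drive, and transient inhibition at On onset.  Drug
#' conditions act as multiplicative factors on these components.
#'
#' Defaults emulate an On-midget ganglion cell: the tonic component's
#' unitary size (0.27 nS), decay (2 ms) and baseline rate (2000 Hz) give
#' a standing inward current of roughly 65 pA and a current SD of roughly
#' 23 pA at a -60 mV holding potential, and the contrast gain of 1.1
#' suppresses roughly 45% of the tonic current during the Off-phase.
#'
#' @param tonic_exc list: `unitary` (a [unitary_event()]), `base_rate_hz`
#'   (Poisson rate at background), `contrast_gain` (rate modulation per
#'   unit Weber contrast).
#' @param transient_exc list: `amplitude_ns`, `latency_ms`, `decay_ms`,
#'   `rect_threshold` (minimum positive contrast step that triggers it).
#' @param nmda_fraction fraction (0-1) of total excitation carried by the
#'   NMDA-type conductance (at full unblock); 0 disables it.
#' @param inhibition list: `amplitude_ns`, `latency_ms`, `decay_ms` for
#'   the transient inhibitory conductance at On onset.
#' @param drug_sensitivity named list mapping condition labels to
#'   multiplicative factors `list(tonic, transient, nmda, inh)`; the
#'   control condition must map to identity factors.
#' @return an object of class `"synaptic_drive_spec"`.
#' @seealso [apply_condition()], [build_synaptic_drive()]
#' @export
synaptic_drive_spec <- function(
    tonic_exc = list(unitary = unitary_event(0.27, 2),
                     base_rate_hz = 2000, contrast_gain = 1.1),
    transient_exc = list(amplitude_ns = 8, latency_ms = 10, decay_ms = 60,
                         rect_threshold = 0),
    nmda_fraction = 0.3,
    inhibition = list(amplitude_ns = 2, latency_ms = 5, decay_ms = 30),
    drug_sensitivity = default_drug_sensitivity()) {
  if (tonic_exc$base_rate_hz < 0) stop("base_rate_hz must be >= 0")
  if (nmda_fraction < 0 || nmda_fraction >= 1) {
    stop("nmda_fraction must lie in [0, 1)")
  }
  ctrl <- drug_sensitivity[["control"]]
  if (is.null(ctrl) || !all(unlist(ctrl) == 1)) {
    stop("drug_sensitivity must map 'control' to identity factors")
  }
  if (any(unlist(drug_sensitivity) < 0)) stop("drug factors must be >= 0")
  structure(list(tonic_exc = tonic_exc, transient_exc = transient_exc,
                 nmda_fraction = nmda_fraction, nmda_scale = 1,
                 inhibition = inhibition,
                 drug_sensitivity = drug_sensitivity,
                 applied_conditions = character()),
            class = "synaptic_drive_spec")
}

#' Default pharmacological factor map
#'
#' IEM-1460 (CP-AMPAR antagonist) and meclofenamic acid (gap-junction
#' blocker) both silence the tonic component routed through the AII
#' network, so their factor maps coincide and compose idempotently
#' (occlusion).  D-AP5 removes the NMDA component; the inhibitory
#' cocktail removes inhibition.
#'
#' @return named list of factor lists, one per condition label.
#' @export
default_drug_sensitivity <- function() {
  id <- list(tonic = 1, transient = 1, nmda = 1, inh = 1)
  list(
    "control" = id,
    "IEM" = list(tonic = 0, transient = 1, nmda = 1, inh = 1),
    "AP5" = list(tonic = 1, transient = 1, nmda = 0, inh = 1),
    "AP5+IEM" = list(tonic = 0, transient = 1, nmda = 0, inh = 1),
    "inhibitors" = list(tonic = 1, transient = 1, nmda = 1, inh = 0),
    "inhibitors+IEM" = list(tonic = 0, transient = 1, nmda = 1, inh = 0),
    "MFA" = list(tonic = 0, transient = 1, nmda = 1, inh = 1),
    "MFA+IEM" = list(tonic = 0, transient = 1, nmda = 1, inh = 1)
  )
}

#' Fold a drug condition's factors into a drive specification
#'
#' Multiplies each component's magnitude by the condition's factor
#' (tonic unitary amplitude, transient amplitude, NMDA scale, inhibitory
#' amplitude) and records the applied condition.  The control condition
#' is the identity.  Conditions that zero the same component occlude one
#' another: applying both equals applying either alone to that component.
#'
#' @param spec a [synaptic_drive_spec()].
#' @param condition a condition label present in `spec$drug_sensitivity`.
#' @return the transformed spec.
#' @export
apply_condition <- function(spec, condition) {
  stopifnot(inherits(spec, "synaptic_drive_spec"))
  fac <- spec$drug_sensitivity[[condition]]
  if (is.null(fac)) {
    stop("condition '", condition, "' is not defined in drug_sensitivity")
  }
  spec$tonic_exc$unitary$amplitude_ns <-
    spec$tonic_exc$unitary$amplitude_ns * fac$tonic
  spec$transient_exc$amplitude_ns <-
    spec$transient_exc$amplitude_ns * fac$transient
  spec$nmda_scale <- spec$nmda_scale * fac$nmda
  spec$inhibition$amplitude_ns <- spec$inhibition$amplitude_ns * fac$inh
  spec$applied_conditions <- c(spec$applied_conditions, condition)
  spec
}

# exponential transient kernel summed over stimulus onsets (deterministic)
transient_trace <- function(onset_idx, n, fs, amplitude_ns, latency_ms,
                            decay_ms) {
  out <- numeric(n)
  if (amplitude_ns == 0 || !length(onset_idx)) return(out)
  dt_ms <- 1000 / fs
  for (i0 in onset_idx) {
    start <- i0 + round(latency_ms / dt_ms)
    if (start > n) next
    k <- seq.int(start, n)
    out[k] <- out[k] + amplitude_ns * exp(-(k - start) * dt_ms / decay_ms)
  }
  out
}

#' Build the synaptic conductance drive for one trial
#'
#' Composes the component conductance traces under a pharmacological
#' condition: the tonic shot-noise excitation with its rate modulated
#' multiplicatively by the stimulus contrast phase (up during On, down
#' during Off, floored at zero), the rectified transient excitation at
#' On-phase onsets, the NMDA-type conductance (a deterministic fraction
#' of the expected excitatory drive, at full unblock scale), and the
#' transient inhibition.  Ground-truth component traces are returned for
#' recovery tests.
#'
#' @param spec a [synaptic_drive_spec()].
#' @param stim a stimulus trace from [make_stimulus()].
#' @param condition condition label (must exist in the spec's factor map).
#' @param seed integer seed for the shot-noise realisation.
#' @return an object of class `"synaptic_drive"`: list with `g_ampa`,
#'   `g_nmda` (scale at full unblock), `g_inh` traces (nS),
#'   `sampling_rate`, `condition`, and a `truth` list holding the tonic
#'   and transient components and the rate trace.
#' @export
build_synaptic_drive <- function(spec, stim, condition = "control", seed = 1) {
  stopifnot(inherits(spec, "synaptic_drive_spec"),
            inherits(stim, "stimulus_trace"))
  if (is.null(spec$drug_sensitivity[[condition]])) {
    stop("condition '", condition, "' is not defined in drug_sensitivity")
  }
  spec2 <- apply_condition(spec, condition)
  fs <- attr(stim, "sampling_rate")
  sspec <- attr(stim, "spec")
  n <- length(stim)
  contrast <- (as.numeric(stim) - sspec$background_intensity) /
    sspec$background_intensity
  rate <- spec2$tonic_exc$base_rate_hz *
    pmax(0, 1 + spec2$tonic_exc$contrast_gain * contrast)
  g_tonic <- shot_noise_conductance(rate, spec2$tonic_exc$unitary, fs, seed)
  dstep <- diff(contrast)
  onsets <- which(dstep > spec2$transient_exc$rect_threshold) + 1L
  g_transient <- transient_trace(onsets, n, fs,
                                 spec2$transient_exc$amplitude_ns,
                                 spec2$transient_exc$latency_ms,
                                 spec2$transient_exc$decay_ms)
  g_ampa <- g_tonic + g_transient
  tonic_env <- rate * spec2$tonic_exc$unitary$amplitude_ns *
    (spec2$tonic_exc$unitary$tau_ms / 1000)
  f <- spec2$nmda_fraction
  nmda_gain <- if (f > 0) f / (1 - f) * spec2$nmda_scale else 0
  g_nmda <- nmda_gain * (tonic_env + g_transient)
  g_inh <- transient_trace(onsets, n, fs, spec2$inhibition$amplitude_ns,
                           spec2$inhibition$latency_ms,
                           spec2$inhibition$decay_ms)
  structure(list(g_ampa = g_ampa, g_nmda = g_nmda, g_inh = g_inh,
                 sampling_rate = fs, condition = condition,
                 truth = list(g_tonic = g_tonic, g_transient = g_transient,
                              rate = rate, tonic_env = tonic_env),
                 spec = spec2, stimulus = sspec),
            class = "synaptic_drive")
}

#' Assemble a synaptic drive directly from conductance traces
#'
#' Convenience constructor for tests and forward-model studies where the
#' component traces are specified directly rather than generated.
#'
#' @param g_ampa,g_nmda,g_inh conductance traces in nS (scalars are
#'   recycled to the common length).
#' @param sampling_rate sampling rate in Hz.
#' @param condition condition label attached to simulated sweeps.
#' @return a `"synaptic_drive"` object.
#' @export
conductance_drive <- function(g_ampa, g_nmda = 0, g_inh = 0, sampling_rate,
                              condition = "custom") {
  n <- max(length(g_ampa), length(g_nmda), length(g_inh))
  structure(list(g_ampa = rep_len(as.numeric(g_ampa), n),
                 g_nmda = rep_len(as.numeric(g_nmda), n),
                 g_inh = rep_len(as.numeric(g_inh), n),
                 sampling_rate = sampling_rate, condition = condition,
                 truth = NULL, spec = NULL, stimulus = NULL),
            class = "synaptic_drive")
}

#' Simulate a voltage-clamp sweep under ideal clamp
#'
#' Evaluates the membrane current at a fixed holding potential:
#' `I(t) = G_ampa (V - E_exc) + G_inh (V - E_inh) +
#'  G_nmda B(V) (V - E_exc) + g_leak (V - E_leak)`, with nS x mV giving
#' pA.  The clamp is ideal (no series-resistance error), so the simulated
#' currents are exact ground truth for conductance-recovery tests.
#' `v_hold` is taken as already junction-corrected.
#'
#' @param cell a [cell_model()].
#' @param drive a `"synaptic_drive"`.
#' @param v_hold holding potential in mV.
#' @param cell_id,trial_index metadata for the returned sweep.
#' @return a [sweep_record()] of modality `"voltage_clamp"` (pA).
#' @export
simulate_voltage_clamp <- function(cell, drive, v_hold, cell_id = "sim",
                                   trial_index = 0L) {
  stopifnot(inherits(cell, "cell_model"), inherits(drive, "synaptic_drive"))
  lens <- c(length(drive$g_ampa), length(drive$g_nmda), length(drive$g_inh))
  if (length(unique(lens)) != 1L) {
    stop("drive traces must share one sampling grid")
  }
  b <- mg_block(v_hold, cell$mg)
  i <- drive$g_ampa * (v_hold - cell$e_exc_mV) +
    drive$g_inh * (v_hold - cell$e_inh_mV) +
    drive$g_nmda * b * (v_hold - cell$e_exc_mV) +
    cell$g_leak_nS * (v_hold - cell$e_leak_mV)
  sweep_record(cell_id = cell_id, modality = "voltage_clamp",
               sampling_rate = drive$sampling_rate, signal = i,
               holding_potential = v_hold, ljp_corrected = TRUE,
               condition = drive$condition, trial_index = trial_index)
}

# stereotyped spike waveform pasted at each spike, relative to reset (mV);
# short enough to sit inside the -1/+3 ms blanking window
spike_waveform <- function(amp_mV, fs) {
  t_ms <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  shape <- c(0.55, 1.0, 0.6, 0.3, 0.12, 0.04)
  idx <- round(t_ms * fs / 1000)
  keep <- !duplicated(idx) & idx >= 1
  list(offset = idx[keep], v = amp_mV * shape[keep])
}

#' Simulate a current-clamp sweep with a spiking point neuron
#'
#' Leaky integrate-and-fire dynamics under conductance drive, integrated
#' with the exponential-Euler scheme (exact for piecewise-constant
#' conductances).  When the membrane crosses the spike threshold the
#' crossing time is recorded, a stereotyped depolarising transient is
#' pasted into the output voltage for detector realism, and the membrane
#' is reset and held for the refractory period.  The emitted spike times
#' are ground truth for spike-detector tests.
#'
#' @param cell a [cell_model()] with a spike mechanism (or `spike = NULL`
#'   for a passive cell).
#' @param drive a `"synaptic_drive"`.
#' @param seed optional integer seed (the integration itself is
#'   deterministic given the drive; kept for interface symmetry).
#' @param v0 initial membrane potential, mV (default: leak reversal).
#' @param cell_id,trial_index metadata for the returned sweep.
#' @return a [sweep_record()] of modality `"current_clamp"` (mV), with
#'   attribute `"spike_times"` holding the true spike times in seconds.
#' @export
simulate_current_clamp <- function(cell, drive, seed = NULL, v0 = NULL,
                                   cell_id = "sim", trial_index = 0L) {
  stopifnot(inherits(cell, "cell_model"), inherits(drive, "synaptic_drive"))
  if (!is.null(seed)) set.seed(seed)
  fs <- drive$sampling_rate
  dt_ms <- 1000 / fs
  n <- length(drive$g_ampa)
  g_max <- cell$g_leak_nS + max(drive$g_ampa + drive$g_inh + drive$g_nmda)
  tau_min <- cell$capacitance_pF / max(g_max, 1e-12)
  if (dt_ms > tau_min / 10) {
    stop("time step ", signif(dt_ms, 3), " ms too coarse for membrane time ",
         "constant ", signif(tau_min, 3), " ms (need dt <= tau/10)")
  }
  spiking <- !is.null(cell$spike)
  if (spiking) {
    thr <- cell$spike$threshold_mV
    vreset <- cell$spike$reset_mV
    ref_samp <- max(1L, round(cell$spike$refractory_ms / dt_ms))
    wf <- spike_waveform(cell$spike$spike_amp_mV %||% 60, fs)
  }
  v <- if (is.null(v0)) cell$e_leak_mV else v0
  out <- numeric(n)
  out[1] <- v
  spikes <- numeric(0)
  refr <- 0L
  for (i in 2:n) {
    if (refr > 0L) {
      refr <- refr - 1L
      if (out[i] == 0) out[i] <- v  # keep pasted waveform if already written
      next
    }
    g_n <- drive$g_nmda[i] * mg_block(v, cell$mg)
    g_tot <- cell$g_leak_nS + drive$g_ampa[i] + drive$g_inh[i] + g_n
    v_inf <- (cell$g_leak_nS * cell$e_leak_mV +
                drive$g_ampa[i] * cell$e_exc_mV +
                drive$g_inh[i] * cell$e_inh_mV +
                g_n * cell$e_exc_mV) / g_tot
    v <- v_inf + (v - v_inf) * exp(-dt_ms * g_tot / cell$capacitance_pF)
    out[i] <- v
    if (spiking && v >= thr) {
      spikes <- c(spikes, (i - 1) / fs)
      idx <- i + wf$offset
      ok <- idx <= n
      out[idx[ok]] <- vreset + wf$v[ok]
      v <- vreset
      out[i] <- thr  # crossing sample shows the take-off point
      refr <- ref_samp
    }
  }
  # fill any refractory samples not covered by the pasted waveform
  zero_holes <- which(out == 0)
  if (length(zero_holes)) out[zero_holes] <- if (spiking) vreset else v
  sw <- sweep_record(cell_id = cell_id, modality = "current_clamp",
                     sampling_rate = fs, signal = out,
                     condition = drive$condition, trial_index = trial_index)
  attr(sw, "spike_times") <- spikes
  sw
}

`%||%` <- function(a, b) if (is.null(a)) b else a
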