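#' Construct a single recorded or simulated sweep
#'
#' A sweep is one trial of a time series together with the acquisition
#' metadata needed by every downstream analysis: modality, sampling rate,
#' holding potential (voltage clamp only), pharmacological condition and
#' trial index.  Units are fixed package-wide: current signals in pA
#' (voltage clamp), voltage signals in mV (all other modalities), sampling
#' rate in Hz.  Inward current is negative.
#'
#' @param cell_id opaque cell identifier string.
#' @param modality one of `"extracellular"`, `"current_clamp"`,
#'   `"voltage_clamp"`.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param signal numeric vector of samples; pA for voltage clamp, mV
#'   otherwise.  Sample 0 is at t = 0.
#' @param holding_potential holding potential in mV.  Required exactly when
#'   `modality = "voltage_clamp"`, and must be absent otherwise.
#' @param ljp_corrected logical; has a liquid-junction-potential correction
#'   already been applied?
#' @param condition pharmacological condition label; one of
#'   `sweep_conditions()` or `"custom"`.
#' @param trial_index integer trial index, >= 0.
#' @param stimulus_id optional reference to a [stimulus_spec()] by name, or
#'   `NULL`.
#' @return an object of class `"sweep_record"`.
#' @seealso [correct_junction_potential()], [save_sweeps()], [load_sweeps()]
#' @export
sweep_record <- function(cell_id, modality, sampling_rate, signal,
                         holding_potential = NULL, ljp_corrected = FALSE,
                         condition = "control", trial_index = 0L,
                         stimulus_id = NULL) {
  modality <- match.arg(modality, c("extracellular", "current_clamp",
                                    "voltage_clamp"))
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be a single positive number (Hz)")
  }
  if (!is.numeric(signal) || length(signal) < 1L) {
    stop("signal must be a non-empty numeric vector")
  }
  if (modality == "voltage_clamp") {
    if (is.null(holding_potential) || !is.finite(holding_potential)) {
      stop("holding_potential (mV) is required for voltage_clamp sweeps")
    }
  } else if (!is.null(holding_potential)) {
    stop("holding_potential is only meaningful for voltage_clamp sweeps")
  }
  if (!condition %in% c(sweep_conditions(), "custom")) {
    stop("unknown condition label: ", condition)
  }
  if (trial_index < 0) stop("trial_index must be >= 0")
  structure(list(
    cell_id = as.character(cell_id),
    modality = modality,
    sampling_rate = as.numeric(sampling_rate),
    signal = as.numeric(signal),
    holding_potential = if (is.null(holding_potential)) NULL
                        else as.numeric(holding_potential),
    ljp_corrected = isTRUE(ljp_corrected),
    condition = condition,
    trial_index = as.integer(trial_index),
    stimulus_id = stimulus_id
  ), class = "sweep_record")
}

#' Canonical pharmacological condition labels
#'
#' @return character vector of the recognised condition labels.
#' @export
sweep_conditions <- function() {
  c("control", "IEM", "AP5", "AP5+IEM", "inhibitors", "inhibitors+IEM",
    "MFA", "MFA+IEM")
}

#' @export
print.sweep_record <- function(x, ...) {
  cat("<sweep_record>", x$cell_id, "|", x$modality, "|", x$condition,
      "| trial", x$trial_index, "\n")
  cat("  ", length(x$signal), "samples @", x$sampling_rate, "Hz (",
      signif(length(x$signal) / x$sampling_rate, 4), "s )\n")
  if (!is.null(x$holding_potential)) {
    cat("   V_hold:", x$holding_potential, "mV",
        if (x$ljp_corrected) "(LJP corrected)" else "(uncorrected)", "\n")
  }
  invisible(x)
}

#' Sweep duration in seconds
#' @param sweep a [sweep_record()].
#' @return duration in seconds.
#' @export
sweep_duration <- function(sweep) {
  length(sweep$signal) / sweep$sampling_rate
}

#' Sample times of a sweep
#' @param sweep a [sweep_record()].
#' @return numeric vector of sample times in seconds, starting at 0.
#' @export
sweep_times <- function(sweep) {
  (seq_along(sweep$signal) - 1L) / sweep$sampling_rate
}

#' Light stimulus specification
#'
#' Describes a square-wave contrast-modulated spot on a steady background.
#' Contrast follows the convention `100 * (L_max - L_min) / L_background`
#' with symmetric modulation about the background, so 80% contrast on a
#' background of 600 Rh*/rod/s gives L_max = 840 and L_min = 360.  The
#' first half-cycle after `phase_zero` is the On-phase.
#'
#' @param background_intensity steady background, Rh*/rod/s.
#' @param contrast_percent contrast in percent, 0-100.
#' @param frequency modulation frequency, Hz.
#' @param spot_diameter spot diameter, micrometres (carried as metadata).
#' @param duration total trace duration, seconds.
#' @param phase_zero time of the first On-phase onset, seconds; the trace
#'   is at background before this.
#' @return an object of class `"stimulus_spec"`.
#' @export
stimulus_spec <- function(background_intensity = 600, contrast_percent = 80,
                          frequency = 1, spot_diameter = 200,
                          duration = 2.5, phase_zero = 0.5) {
  if (contrast_percent < 0 || contrast_percent > 100) {
    stop("contrast_percent must lie in [0, 100] under the symmetric ",
         "modulation convention (L_min would go negative)")
  }
  if (background_intensity < 0) stop("background_intensity must be >= 0")
  if (frequency <= 0) stop("frequency must be positive")
  if (phase_zero < 0 || phase_zero > duration) {
    stop("phase_zero must lie within [0, duration]")
  }
  structure(list(
    background_intensity = background_intensity,
    contrast_percent = contrast_percent,
    frequency = frequency,
    spot_diameter = spot_diameter,
    duration = duration,
    phase_zero = phase_zero
  ), class = "stimulus_spec")
}

#' Liquid-junction-potential correction
#'
#' The three corrections used in the analysis chain are carried as dataset
#' metadata, never hard-coded: the Cs-internal ganglion-cell recording
#' correction (-16 mV), the correction applied within the conductance
#' analysis (-13 mV), and the AII-cell Cs-internal correction (-15 mV).
#' A custom value may be supplied instead.
#'
#' @param applies_to one of `"cs_internal_gc"`, `"conductance_analysis"`,
#'   `"aii_cs_internal"` or `"custom"`.
#' @param ljp correction in mV (negative by convention); required when
#'   `applies_to = "custom"`, ignored otherwise.
#' @return an object of class `"junction_correction"`.
#' @export
junction_correction <- function(applies_to = c("cs_internal_gc",
                                               "conductance_analysis",
                                               "aii_cs_internal", "custom"),
                                ljp = NULL) {
  applies_to <- match.arg(applies_to)
  presets <- c(cs_internal_gc = -16, conductance_analysis = -13,
               aii_cs_internal = -15)
  if (applies_to == "custom") {
    if (is.null(ljp) || !is.finite(ljp)) {
      stop("a custom junction_correction needs an explicit ljp (mV)")
    }
  } else {
    ljp <- unname(presets[[applies_to]])
  }
  structure(list(ljp = as.numeric(ljp), applies_to = applies_to),
            class = "junction_correction")
}

#' Apply a liquid-junction-potential correction to a sweep
#'
#' Shifts every voltage-valued field by the correction: the signal for
#' voltage modalities (extracellular, current clamp) and the holding
#' potential for voltage clamp.  Current signals are left untouched.
#' Applying a correction twice is rejected.
#'
#' @param sweep a [sweep_record()] with `ljp_corrected = FALSE`.
#' @param corr a [junction_correction()].
#' @return the corrected sweep, with `ljp_corrected = TRUE`.
#' @examples
#' sw <- sweep_record("c1", "voltage_clamp", 10000, rep(0, 100),
#'                    holding_potential = -60)
#' correct_junction_potential(sw, junction_correction("cs_internal_gc"))
#' @export
correct_junction_potential <- function(sweep, corr) {
  stopifnot(inherits(sweep, "sweep_record"),
            inherits(corr, "junction_correction"))
  if (isTRUE(sweep$ljp_corrected)) {
    stop("sweep is already junction-corrected; refusing to apply twice")
  }
  if (sweep$modality == "voltage_clamp") {
    sweep$holding_potential <- sweep$holding_potential + corr$ljp
  } else {
    sweep$signal <- sweep$signal + corr$ljp
  }
  sweep$ljp_corrected <- TRUE
  sweep
}

#' Bundle sweeps into an ordered sweep set
#'
#' Orders sweeps stably by (cell_id, condition, trial_index) and validates
#' each element.
#'
#' @param sweeps a list of [sweep_record()] objects.
#' @return an object of class `"sweep_set"` (a list of sweeps).
#' @export
sweep_set <- function(sweeps) {
  if (!is.list(sweeps)) stop("sweeps must be a list of sweep_record objects")
  ok <- vapply(sweeps, inherits, logical(1), what = "sweep_record")
  if (!all(ok)) stop("all elements must be sweep_record objects")
  if (length(sweeps)) {
    key_cell <- vapply(sweeps, `[[`, character(1), "cell_id")
    key_cond <- vapply(sweeps, `[[`, character(1), "condition")
    key_trial <- vapply(sweeps, `[[`, integer(1), "trial_index")
    sweeps <- sweeps[order(key_cell, key_cond, key_trial)]
  }
  structure(sweeps, class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat("<sweep_set> of", length(x), "sweeps\n")
  invisible(x)
}
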