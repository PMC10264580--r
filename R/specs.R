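#' Acquisition settings for epoched VEP recordings
#'
#' Describes how flash-locked EEG sweeps are digitized and blocked into
#' averages. Defaults reproduce a standard rodent flash-VEP session:
#' 500 ms epochs at 4096 Hz, three averages of 20 sweeps each, flashes
#' delivered at 1 Hz.
#'
#' @param sampling_rate Sampling frequency in Hz.
#' @param epoch_ms Epoch duration in milliseconds, measured from flash onset.
#' @param sweeps_per_average Number of sweeps pooled into one block average.
#' @param averages_per_session Number of block averages recorded per session.
#' @param flash_rate Flash stimulation rate in Hz.
#'
#' @return An object of class `acquisition_spec`.
#' @examples
#' acq <- acquisition_spec()
#' n_samples(acq)  # 2048
#' @export
acquisition_spec <- function(sampling_rate = 4096, epoch_ms = 500,
                             sweeps_per_average = 20, averages_per_session = 3,
                             flash_rate = 1) {
  stopifnot(sampling_rate > 0, epoch_ms > 0,
            sweeps_per_average >= 1, averages_per_session >= 1,
            flash_rate > 0)
  n <- sampling_rate * epoch_ms / 1000
  if (abs(n - round(n)) > 1e-9) {
    stop("epoch_ms x sampling_rate must give an integer sample count")
  }
  structure(list(sampling_rate = sampling_rate, epoch_ms = epoch_ms,
                 sweeps_per_average = as.integer(sweeps_per_average),
                 averages_per_session = as.integer(averages_per_session),
                 flash_rate = flash_rate),
            class = "acquisition_spec")
}

#' Number of samples in one epoch
#' @param acq An [acquisition_spec()].
#' @return Integer sample count.
#' @export
n_samples <- function(acq) as.integer(round(acq$sampling_rate * acq$epoch_ms / 1000))

#' Epoch time axis in milliseconds
#' @param acq An [acquisition_spec()].
#' @return Numeric vector of sample times (ms), 0 = flash onset.
#' @export
epoch_times <- function(acq) (seq_len(n_samples(acq)) - 1) / acq$sampling_rate * 1000

#' One VEP component of the waveform model
#'
#' A VEP component is a unimodal deflection with a fixed peak latency,
#' signed amplitude and half-width. P1 and P2 are positive, N1 negative.
#'
#' @param name One of `"P1"`, `"N1"`, `"P2"`.
#' @param latency Peak latency in ms after flash onset (> 0).
#' @param amplitude Peak amplitude in microvolts; must be positive for
#'   P1/P2 and negative for N1.
#' @param width Half-width at half maximum of the component bump, in ms.
#' @return An object of class `component_spec`.
#' @export
component_spec <- function(name, latency, amplitude, width) {
  name <- match.arg(name, c("P1", "N1", "P2"))
  stopifnot(latency > 0, width > 0, abs(amplitude) > 0)
  if (name == "N1" && amplitude >= 0) stop("N1 amplitude must be negative")
  if (name != "N1" && amplitude <= 0) stop(name, " amplitude must be positive")
  structure(list(name = name, latency = latency, amplitude = amplitude,
                 width = width),
            class = "component_spec")
}

#' Default triphasic mouse flash-VEP truth
#'
#' Baseline latencies for mouse flash-VEP components are configurable
#' placeholders typical of rodent recordings (P1 near 25 ms, N1 near
#' 50 ms, P2 near 90 ms), not measured population values.
#'
#' @param p1_ms,n1_ms,p2_ms Component latencies in ms.
#' @param p1_uv,n1_uv,p2_uv Component amplitudes in microvolts.
#' @return List of three `component_spec` objects ordered P1 < N1 < P2.
#' @export
default_components <- function(p1_ms = 25, n1_ms = 50, p2_ms = 90,
                               p1_uv = 10, n1_uv = -15, p2_uv = 12) {
  comps <- list(component_spec("P1", p1_ms, p1_uv, width = 5),
                component_spec("N1", n1_ms, n1_uv, width = 8),
                component_spec("P2", p2_ms, p2_uv, width = 12))
  validate_components(comps)
  comps
}

validate_components <- function(comps) {
  nm <- vapply(comps, `[[`, "", "name")
  lat <- vapply(comps, `[[`, 0, "latency")
  ord <- match(c("P1", "N1", "P2"), nm)
  present <- ord[!is.na(ord)]
  if (any(diff(lat[present]) <= 0)) {
    stop("component latencies must be strictly ordered P1 < N1 < P2")
  }
  invisible(comps)
}

#' Background noise model for simulated sweeps
#'
#' Simulated EEG background is Gaussian 1/f^alpha ("pink") noise, plus an
#' optional 50 Hz powerline sinusoid and per-sweep latency jitter of the
#' evoked components.
#'
#' @param background_sd Standard deviation of the background noise in
#'   microvolts (0 disables it).
#' @param spectral_exponent Exponent alpha of the 1/f^alpha spectrum,
#'   in `[0, 2]`; 0 is white noise, 1 the classic EEG-like pink slope.
#' @param powerline_amplitude Amplitude (microvolts) of a 50 Hz sinusoid
#'   with random phase per sweep; 0 disables it.
#' @param jitter_sd Per-sweep Gaussian jitter of component latencies, ms.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(background_sd = 5, spectral_exponent = 1,
                       powerline_amplitude = 0, jitter_sd = 1) {
  stopifnot(background_sd >= 0, spectral_exponent >= 0,
            spectral_exponent <= 2, powerline_amplitude >= 0, jitter_sd >= 0)
  structure(list(background_sd = background_sd,
                 spectral_exponent = spectral_exponent,
                 powerline_amplitude = powerline_amplitude,
                 jitter_sd = jitter_sd),
            class = "noise_spec")
}

#' Analysis filter chain
#'
#' Corner frequencies of the analysis bandpass plus an optional notch.
#' The chain is always applied zero-phase (forward-backward), so it
#' introduces no latency shift; see [apply_filters()].
#'
#' Any notch removes a sliver of the evoked response's own energy at the
#' line frequency, which visibly perturbs the flat top of slow components
#' on a fine sample grid. The notch is therefore gated: in `"auto"` mode
#' (the default) it engages only when narrowband line interference is
#' actually present in the trace (spectral power within 1 Hz of the notch
#' frequency exceeding `notch_ratio` times the neighbouring-band power),
#' so clean traces keep sample-exact peak latencies while contaminated
#' ones are cleaned.
#'
#' @param bandpass_low,bandpass_high Bandpass corner frequencies in Hz.
#' @param notch Notch centre frequency in Hz, or `NULL` to disable.
#' @param notch_q Quality factor of the notch (centre / -3 dB bandwidth).
#' @param notch_mode `"auto"` (engage on detected line interference),
#'   `"on"` (always), or `"off"`.
#' @param notch_ratio Line-power ratio above which `"auto"` engages.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(bandpass_low = 5, bandpass_high = 100, notch = 50,
                        notch_q = 30, notch_mode = c("auto", "on", "off"),
                        notch_ratio = 5) {
  notch_mode <- match.arg(notch_mode)
  stopifnot(bandpass_low > 0, bandpass_high > bandpass_low,
            is.null(notch) || notch > 0, notch_q > 0, notch_ratio > 0)
  structure(list(bandpass_low = bandpass_low, bandpass_high = bandpass_high,
                 notch = notch, notch_q = notch_q, notch_mode = notch_mode,
                 notch_ratio = notch_ratio),
            class = "filter_spec")
}

#' Component search windows for peak marking
#'
#' The ordinal component definitions (first positive peak, first negative
#' peak, second positive peak) are applied inside per-component latency
#' windows; the first `blank_ms` of the epoch are blanked for the
#' stimulus artifact. Window defaults are analysis settings, not
#' physiological constants.
#'
#' @param p1,n1,p2 Length-2 numeric `(t_min, t_max)` windows in ms.
#' @param blank_ms Initial blanking interval in ms.
#' @param smooth_ms Span of the moving-average smoother used only for
#'   candidate peak detection, in ms.
#' @param min_amplitude_uv Minimum absolute amplitude for a candidate
#'   peak, in microvolts. Residual background after 60-sweep averaging is
#'   a few tenths of a microvolt while genuine mouse VEP components are
#'   several microvolts; the floor keeps noise ripples from being marked
#'   as the "first" peak.
#' @param hyper_onset_ms,hyper_hold_ms,hyper_cap_ms Parameters of the
#'   operational "complete hyperpolarization" bound for the P2 search:
#'   the first sample after `hyper_onset_ms` where the trace stays at or
#'   below zero for at least `hyper_hold_ms` ends the search, with a hard
#'   cap at `hyper_cap_ms`.
#' @return An object of class `search_windows`.
#' @export
search_windows <- function(p1 = c(10, 45), n1 = c(25, 80), p2 = c(45, 150),
                           blank_ms = 10, smooth_ms = 1.2,
                           min_amplitude_uv = 1,
                           hyper_onset_ms = 60, hyper_hold_ms = 40,
                           hyper_cap_ms = 150) {
  for (w in list(p1, n1, p2)) {
    if (length(w) != 2 || w[2] <= w[1]) stop("windows must be (t_min, t_max) with t_min < t_max")
  }
  if (p1[1] < blank_ms) stop("P1 window must start after the blanking interval")
  stopifnot(min_amplitude_uv >= 0)
  structure(list(p1 = p1, n1 = n1, p2 = p2, blank_ms = blank_ms,
                 smooth_ms = smooth_ms, min_amplitude_uv = min_amplitude_uv,
                 hyper_onset_ms = hyper_onset_ms,
                 hyper_hold_ms = hyper_hold_ms, hyper_cap_ms = hyper_cap_ms),
            class = "search_windows")
}

#' Rule for stratifying EAE eyes by early latency delay
#'
#' EAE eyes are split into "with latency delay" (W LD) and "without
#' latency delay" (W/O LD) strata according to whether the percent change
#' of a reference measure at an early timepoint exceeds a threshold. By
#' default the threshold is derived from the cohort's Healthy eyes
#' (mean + 2 SD of their N1 percent change at 7 dpi); an absolute percent
#' threshold can be supplied instead.
#'
#' @param measure Reference measure, one of the six latency measures
#'   (`"N1"` by default).
#' @param day Timepoint (days post-immunization) at which the rule is
#'   evaluated.
#' @param threshold Absolute threshold in percent, or `NULL` to derive
#'   Healthy mean + `n_sd` * SD from the cohort.
#' @param n_sd Number of Healthy SDs above the Healthy mean used when
#'   `threshold` is `NULL`.
#' @param healthy_label Group label identifying Healthy eyes.
#' @return An object of class `stratification_rule`.
#' @export
stratification_rule <- function(measure = "N1", day = 7, threshold = NULL,
                                n_sd = 2, healthy_label = "Healthy") {
  measure <- match.arg(measure, c("P1", "N1", "P2", "P1-N1", "N1-P2", "P1-P2"))
  stopifnot(day >= 0, is.null(threshold) || is.finite(threshold), n_sd > 0)
  structure(list(measure = measure, day = day, threshold = threshold,
                 n_sd = n_sd, healthy_label = healthy_label),
            class = "stratification_rule")
}
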