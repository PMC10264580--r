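# All simulation randomness flows through R's RNG; entry points that take
# a `seed` save and restore the caller's RNG state so simulation never
# perturbs global reproducibility.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# Deterministic 32-bit sub-seed derivation (keeps derived seeds < 2^31).
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + as.double(k) * 69621) %% 2147483629) + 1L
}

#' Gaussian 1/f^alpha background noise
#'
#' Generates one epoch of Gaussian noise whose power spectrum falls as
#' 1/f^alpha, by spectrally shaping white Gaussian noise in the Fourier
#' domain (DC removed) and rescaling to the target standard deviation.
#'
#' @param n Number of samples.
#' @param sampling_rate Sampling frequency in Hz.
#' @param alpha Spectral exponent in `[0, 2]`.
#' @param sd Target standard deviation (microvolts).
#' @return Numeric vector of length `n`.
#' @export
pink_noise <- function(n, sampling_rate, alpha = 1, sd = 1) {
  if (sd <= 0) return(numeric(n))
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k) * sampling_rate / n  # two-sided frequency magnitude
  scale <- c(0, f[-1]^(-alpha / 2))        # zero out DC
  y <- Re(stats::fft(X * scale, inverse = TRUE)) / n
  y * sd / stats::sd(y)
}

#' Sampled waveform of one VEP component
#'
#' Renders a component as a Gaussian bump on the epoch's sample grid. The
#' peak is snapped to the sample nearest the nominal latency so the
#' rendered extremum equals the specified amplitude exactly; the bump
#' decays below 1% of its amplitude beyond three half-widths from the
#' peak.
#'
#' @param spec A [component_spec()].
#' @param acq An [acquisition_spec()].
#' @param center_ms Optional override of the peak position in ms (used
#'   for continuous per-sweep latency jitter); when supplied the peak is
#'   not snapped to the grid.
#' @return Numeric vector of length `n_samples(acq)`.
#' @export
make_component_kernel <- function(spec, acq, center_ms = NULL) {
  n <- n_samples(acq)
  t <- epoch_times(acq)
  if (spec$latency <= 0 || spec$latency >= acq$epoch_ms) {
    stop("component outside epoch")
  }
  if (is.null(center_ms)) {
    idx <- round(spec$latency / 1000 * acq$sampling_rate)  # 0-based offset
    center_ms <- idx / acq$sampling_rate * 1000
  }
  sigma <- spec$width / sqrt(2 * log(2))  # width is the half-width at half max
  spec$amplitude * exp(-(t - center_ms)^2 / (2 * sigma^2))
}

#' Simulate one flash-locked sweep
#'
#' One epoch is the sum of the component kernels (each optionally
#' jittered in latency), 1/f^alpha background noise, and a 50 Hz
#' powerline sinusoid with random phase.
#'
#' @param components List of [component_spec()] objects, ordered in latency.
#' @param noise A [noise_spec()].
#' @param acq An [acquisition_spec()].
#' @param seed Optional integer seed; when given the epoch is fully
#'   reproducible and the caller's RNG state is untouched.
#' @return Numeric vector (microvolts) of length `n_samples(acq)`.
#' @export
simulate_epoch <- function(components, noise = noise_spec(),
                           acq = acquisition_spec(), seed = NULL) {
  validate_components(components)
  with_seed(seed, {
    n <- n_samples(acq)
    y <- numeric(n)
    for (cs in components) {
      center <- NULL
      if (noise$jitter_sd > 0) {
        snapped <- round(cs$latency / 1000 * acq$sampling_rate) /
          acq$sampling_rate * 1000
        center <- snapped + stats::rnorm(1, 0, noise$jitter_sd)
      }
      y <- y + make_component_kernel(cs, acq, center_ms = center)
    }
    if (noise$background_sd > 0) {
      y <- y + pink_noise(n, acq$sampling_rate, noise$spectral_exponent,
                          noise$background_sd)
    }
    if (noise$powerline_amplitude > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      y <- y + noise$powerline_amplitude *
        sin(2 * pi * 50 * epoch_times(acq) / 1000 + phase)
    }
    y
  })
}

#' Simulate one recording session
#'
#' A session is `averages_per_session` blocks of `sweeps_per_average`
#' sweeps (60 epochs in 3 blocks of 20 at defaults), with the ground-truth
#' component latencies and amplitudes retained for recovery testing.
#'
#' @inheritParams simulate_epoch
#' @return An object of class `vep_session`: list with `epochs` (matrix,
#'   sweeps x samples), `block` (block index per sweep), `acq`, and
#'   `truth` (named latencies and amplitudes).
#' @export
simulate_session <- function(components, noise = noise_spec(),
                             acq = acquisition_spec(), seed = NULL) {
  validate_components(components)
  with_seed(seed, {
    n_sweeps <- acq$sweeps_per_average * acq$averages_per_session
    epochs <- matrix(0, nrow = n_sweeps, ncol = n_samples(acq))
    for (i in seq_len(n_sweeps)) {
      epochs[i, ] <- simulate_epoch(components, noise, acq)
    }
    block <- rep(seq_len(acq$averages_per_session),
                 each = acq$sweeps_per_average)
    nm <- vapply(components, `[[`, "", "name")
    truth <- list(
      latency = stats::setNames(vapply(components, `[[`, 0, "latency"), nm),
      amplitude = stats::setNames(vapply(components, `[[`, 0, "amplitude"), nm))
    structure(list(epochs = epochs, block = block, acq = acq, truth = truth),
              class = "vep_session")
  })
}

#' Latency-delay trajectory from a day table
#'
#' Builds a per-component percent-delay trajectory (percent latency
#' change versus baseline as a function of day) by linear interpolation
#' between tabulated days. Day 0 is forced to 0% delay for every
#' component, so trajectories return zero delay at baseline by
#' construction.
#'
#' @param days Numeric vector of days with tabulated delays.
#' @param P1,N1,P2 Percent delays per component at `days` (scalar or
#'   vector of `length(days)`).
#' @return A function `f(day)` returning a named numeric vector of
#'   percent delays `c(P1 =, N1 =, P2 =)`.
#' @examples
#' tr <- trajectory_table(days = c(7, 11), N1 = c(15, 20), P2 = c(15, 25))
#' tr(0)   # all zero at baseline
#' tr(7)   # N1 = 15, P2 = 15
#' @export
trajectory_table <- function(days, P1 = 0, N1 = 0, P2 = 0) {
  tab <- data.frame(day = days, P1 = P1, N1 = N1, P2 = P2)
  if (!0 %in% tab$day) tab <- rbind(data.frame(day = 0, P1 = 0, N1 = 0, P2 = 0), tab)
  tab[tab$day == 0, c("P1", "N1", "P2")] <- 0
  tab <- tab[order(tab$day), ]
  function(day) {
    vapply(c("P1", "N1", "P2"), function(comp) {
      stats::approx(tab$day, tab[[comp]], xout = day, rule = 2)$y
    }, numeric(1))
  }
}

#' Zero-delay trajectory (healthy course)
#' @return A trajectory function returning 0% delay at every day.
#' @export
trajectory_zero <- function() {
  function(day) c(P1 = 0, N1 = 0, P2 = 0)
}

#' Longitudinal cohort design
#'
#' @param groups List of group descriptions; each a list with `label`,
#'   `n_eyes`, `trajectory` (a function as returned by
#'   [trajectory_table()]), and optionally `dropout = list(n_eyes,
#'   last_day)` right-censoring the first `n_eyes` eyes of the group
#'   after `last_day`.
#' @param timepoints Days post-immunization at which sessions are
#'   recorded; must include 0 (baseline).
#' @param seed Integer seed governing all cohort randomness.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(groups, timepoints = c(0, 7, 11, 15, 23, 37),
                          seed = 1L) {
  if (length(groups) == 0) stop("cohort design needs at least one group")
  if (!0 %in% timepoints) stop("timepoints must include the baseline day 0")
  for (g in groups) {
    stopifnot(is.character(g$label), g$n_eyes >= 1, is.function(g$trajectory))
  }
  structure(list(groups = groups, timepoints = sort(unique(timepoints)),
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' Simulate a longitudinal VEP cohort
#'
#' Generates one session per eye per surviving timepoint. Each group's
#' component latencies at day `d` equal the baseline latency scaled by
#' `1 + trajectory(d)/100`; ground-truth latencies are recorded in the
#' manifest. Epoch data are regenerated on demand from per-session seeds
#' (see [cohort_session()]), so cohorts of any size stay lightweight.
#'
#' @param design A [cohort_design()].
#' @param base_truth List of [component_spec()]s giving baseline
#'   components shared by all eyes.
#' @param noise A [noise_spec()].
#' @param acq An [acquisition_spec()].
#' @return An object of class `vep_cohort_sim`: list with `manifest`
#'   (data frame: eye_id, mouse_id, group, day, session seed, true
#'   latencies) plus the design and specs needed to realize any session.
#' @export
simulate_cohort <- function(design, base_truth = default_components(),
                            noise = noise_spec(), acq = acquisition_spec()) {
  validate_components(base_truth)
  nm <- vapply(base_truth, `[[`, "", "name")
  base_lat <- stats::setNames(vapply(base_truth, `[[`, 0, "latency"), nm)

  rows <- list()
  eye_counter <- 0L
  for (g in design$groups) {
    censored_last <- rep(Inf, g$n_eyes)
    if (!is.null(g$dropout)) {
      k <- min(g$dropout$n_eyes, g$n_eyes)
      if (k > 0) censored_last[seq_len(k)] <- g$dropout$last_day
    }
    for (e in seq_len(g$n_eyes)) {
      eye_counter <- eye_counter + 1L
      eye_id <- sprintf("eye%03d", eye_counter)
      mouse_id <- sprintf("m%03d", (eye_counter + 1L) %/% 2L)
      for (day in design$timepoints) {
        if (day > censored_last[e]) next
        delay <- g$trajectory(day)
        true_lat <- base_lat * (1 + delay[names(base_lat)] / 100)
        rows[[length(rows) + 1L]] <- data.frame(
          eye_id = eye_id, mouse_id = mouse_id, group = g$label, day = day,
          session_seed = derive_seed(design$seed,
                                     eye_counter * 1000L + match(day, design$timepoints)),
          true_p1 = unname(true_lat["P1"]), true_n1 = unname(true_lat["N1"]),
          true_p2 = unname(true_lat["P2"]),
          stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  structure(list(manifest = manifest, design = design,
                 base_truth = base_truth, noise = noise, acq = acq),
            class = "vep_cohort_sim")
}

#' Realize one session of a simulated cohort
#'
#' Regenerates the epochs of manifest row `i` from its stored seed;
#' bit-identical across calls.
#'
#' @param sim A `vep_cohort_sim` from [simulate_cohort()].
#' @param i Manifest row index.
#' @return A `vep_session` (see [simulate_session()]).
#' @export
cohort_session <- function(sim, i) {
  row <- sim$manifest[i, ]
  true_lat <- c(P1 = row$true_p1, N1 = row$true_n1, P2 = row$true_p2)
  comps <- lapply(sim$base_truth, function(cs) {
    cs$latency <- unname(true_lat[cs$name])
    cs
  })
  simulate_session(comps, sim$noise, sim$acq, seed = row$session_seed)
}
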