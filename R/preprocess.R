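# Forward-backward filtering with reflection padding. Plain filtfilt on a
# short epoch leaves edge transients (the narrow notch rings for hundreds
# of samples); padding with the reflected, end-matched signal pushes the
# transient outside the retained segment. Zero-phase by construction, so
# peak latencies are untouched -- a hard requirement, since latency is the
# endpoint everything downstream measures.
filtfilt_padded <- function(b, a, x) {
  n <- length(x)
  pad <- n - 1L  # longer than the notch ring-in, so edge transients decay
  xp <- c(2 * x[1] - rev(x[2:(pad + 1)]),
          x,
          2 * x[n] - rev(x[(n - pad):(n - 1)]))
  y <- signal::filtfilt(filt = b, a = a, xp)
  y[(pad + 1):(pad + n)]
}

# RBJ biquad notch; Q = centre frequency / -3 dB bandwidth.
notch_coefficients <- function(freq, sampling_rate, q) {
  w0 <- 2 * pi * freq / sampling_rate
  alpha <- sin(w0) / (2 * q)
  list(b = c(1, -2 * cos(w0), 1) / (1 + alpha),
       a = c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha)))
}

# Ratio of periodogram power within +/- 1 Hz of `freq` to the mean power
# in the flanking bands (freq -5..-1 and +1..+5 Hz). A narrowband line
# interferer gives a large ratio; the smooth spectrum of an evoked
# response or of 1/f background stays near 1.
line_power_ratio <- function(x, freq, sampling_rate) {
  n <- length(x)
  p <- Mod(stats::fft(x - mean(x)))^2
  f <- (seq_len(n) - 1) * sampling_rate / n
  inband <- p[f >= freq - 1 & f <= freq + 1]
  flank <- p[(f >= freq - 5 & f < freq - 1) | (f > freq + 1 & f <= freq + 5)]
  if (length(inband) == 0 || length(flank) == 0 || mean(flank) == 0) return(0)
  mean(inband) / mean(flank)
}

#' Apply the analysis filter chain to a trace
#'
#' Applies the bandpass (4th-order Butterworth high-pass and low-pass
#' sections) and, when engaged, the notch (2nd-order IIR), all zero-phase
#' (forward-backward), so no latency shift is introduced. An engaged
#' notch attenuates its centre frequency by more than 20 dB. In the
#' default `"auto"` mode the notch engages only when narrowband line
#' interference is detected (see [filter_spec()]): a notch inevitably
#' removes the evoked response's own energy at the line frequency, and on
#' a clean trace that residual ripple would perturb peak latencies by a
#' few samples with no benefit.
#'
#' @param x Numeric trace (one epoch or average), microvolts.
#' @param spec A [filter_spec()].
#' @param sampling_rate Sampling frequency of `x` in Hz.
#' @return Filtered trace, same length as `x`.
#' @export
apply_filters <- function(x, spec = filter_spec(), sampling_rate = 4096) {
  nyq <- sampling_rate / 2
  if (spec$bandpass_high >= nyq) stop("bandpass edge at or above Nyquist")
  if (!is.null(spec$notch) && spec$notch >= nyq) stop("notch at or above Nyquist")
  use_notch <- !is.null(spec$notch) && spec$notch_mode != "off" &&
    (spec$notch_mode == "on" ||
       line_power_ratio(x, spec$notch, sampling_rate) > spec$notch_ratio)
  y <- x
  if (use_notch) {
    # regress out the stationary line component first (exact for any
    # phase, zero-phase by construction); the IIR notch then only has to
    # absorb residual drifting interference
    tt <- (seq_along(y) - 1) / sampling_rate
    basis <- cbind(sin(2 * pi * spec$notch * tt), cos(2 * pi * spec$notch * tt))
    y <- stats::lm.fit(basis, y)$residuals
  }
  hp <- signal::butter(4, spec$bandpass_low / nyq, type = "high")
  lp <- signal::butter(4, spec$bandpass_high / nyq, type = "low")
  y <- filtfilt_padded(hp$b, hp$a, y)
  y <- filtfilt_padded(lp$b, lp$a, y)
  if (use_notch) {
    nc <- notch_coefficients(spec$notch, sampling_rate, spec$notch_q)
    y <- filtfilt_padded(nc$b, nc$a, y)
  }
  y
}

#' Average a block of sweeps
#'
#' Pointwise arithmetic mean of the epochs in one block.
#'
#' @param epochs Numeric matrix (sweeps x samples) or list of equal-length
#'   numeric vectors.
#' @param sampling_rate Sampling frequency in Hz.
#' @param block_index Label of the block this average belongs to (an
#'   integer, or `"grand"`).
#' @return An object of class `vep_average`: the averaged samples with
#'   attributes `sampling_rate`, `n_sweeps` and `block_index`.
#' @export
average_sweeps <- function(epochs, sampling_rate = 4096, block_index = 1L) {
  if (is.list(epochs)) {
    len <- lengths(epochs)
    if (length(unique(len)) != 1) stop("epochs have mixed lengths")
    epochs <- do.call(rbind, epochs)
  }
  if (!is.matrix(epochs)) epochs <- matrix(epochs, nrow = 1)
  if (nrow(epochs) < 1) stop("need at least one epoch")
  structure(colMeans(epochs), class = "vep_average",
            sampling_rate = sampling_rate, n_sweeps = nrow(epochs),
            block_index = block_index)
}

#' Grand average across blocks
#'
#' Sweep-weighted mean of block averages; for equal-n blocks this equals
#' the mean of all underlying sweeps.
#'
#' @param blocks List of `vep_average` objects.
#' @return A `vep_average` with `block_index = "grand"`.
#' @export
grand_average <- function(blocks) {
  if (length(blocks) < 1) stop("need at least one block")
  len <- vapply(blocks, length, 0L)
  if (length(unique(len)) != 1) stop("blocks have mixed lengths")
  w <- vapply(blocks, function(b) attr(b, "n_sweeps"), 0L)
  y <- Reduce(`+`, Map(function(b, wi) unclass(b) * wi, blocks, w)) / sum(w)
  structure(y, class = "vep_average",
            sampling_rate = attr(blocks[[1]], "sampling_rate"),
            n_sweeps = sum(w), block_index = "grand")
}

#' Average and filter one simulated session
#'
#' Convenience wrapper: forms the block averages and the grand average of
#' a session and applies the filter chain to each. Filtering and
#' averaging are both linear, so filtering the averages is equivalent to
#' filtering every sweep.
#'
#' @param session A `vep_session`.
#' @param filt A [filter_spec()], or `NULL` to skip filtering.
#' @return List with `blocks` (list of filtered block `vep_average`s) and
#'   `grand` (filtered grand average).
#' @export
preprocess_session <- function(session, filt = filter_spec()) {
  fs <- session$acq$sampling_rate
  blocks <- lapply(sort(unique(session$block)), function(bk) {
    avg <- average_sweeps(session$epochs[session$block == bk, , drop = FALSE],
                          sampling_rate = fs, block_index = bk)
    if (!is.null(filt)) {
      avg[] <- apply_filters(unclass(avg), filt, fs)
    }
    avg
  })
  list(blocks = blocks, grand = grand_average(blocks))
}

#' @export
print.vep_average <- function(x, ...) {
  cat(sprintf("<vep_average> %d samples @ %g Hz, mean of %d sweeps (block %s)\n",
              length(x), attr(x, "sampling_rate"), attr(x, "n_sweeps"),
              as.character(attr(x, "block_index"))))
  invisible(x)
}

#' Plot an averaged VEP trace
#'
#' @param x A `vep_average`.
#' @param marks Optional `vep_marks` to overlay as labelled points.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.vep_average <- function(x, marks = NULL, ...) {
  fs <- attr(x, "sampling_rate")
  t <- (seq_along(x) - 1) / fs * 1000
  graphics::plot(t, unclass(x), type = "l", xlab = "time (ms)",
                 ylab = expression(paste("amplitude (", mu, "V)")), ...)
  graphics::abline(h = 0, col = "grey70", lty = 3)
  if (!is.null(marks)) {
    for (comp in c("p1", "n1", "p2")) {
      lat <- marks[[paste0(comp, "_latency")]]
      if (!is.na(lat)) {
        idx <- round(lat / 1000 * fs) + 1
        graphics::points(lat, x[idx], pch = 19, col = "red")
        graphics::text(lat, x[idx], toupper(comp), pos = 3, col = "red")
      }
    }
  }
  invisible(x)
}
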