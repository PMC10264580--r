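# Local extrema with "earliest sample wins" plateau/tie handling: index i
# is a local maximum if the trace rises into it and does not rise out of
# it. This realises "first peak" semantics for flat-topped peaks.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[x[i] > x[i - 1] & x[i] >= x[i + 1]]
}
local_minima <- function(x) local_maxima(-x)

moving_average <- function(x, span) {
  if (span <= 1) return(x)
  k <- rep(1 / span, span)
  pad <- span %/% 2
  xp <- c(rep(x[1], pad), x, rep(x[length(x)], pad))
  y <- stats::filter(xp, k, sides = 2)
  as.numeric(y[(pad + 1):(pad + length(x))])
}

# First candidate extremum of the requested sign inside [lo, hi] ms,
# detected on the smoothed trace, then relocated to the nearest raw-trace
# extremum of the same type (smoothing is for candidate screening only;
# the reported latency always comes from the unsmoothed trace). A
# candidate must clear `min_amp` so residual-noise ripples are never
# marked as the "first" peak.
first_signed_extremum <- function(y_raw, y_smooth, t, lo, hi, type,
                                  min_amp = 0) {
  if (hi <= lo) return(NA_integer_)
  ext <- if (type == "max") local_maxima else local_minima
  ok_sign <- if (type == "max") function(v) v >= max(min_amp, .Machine$double.xmin)
             else function(v) v <= -max(min_amp, .Machine$double.xmin)
  cand <- ext(y_smooth)
  cand <- cand[t[cand] >= lo & t[cand] <= hi & ok_sign(y_smooth[cand])]
  if (length(cand) == 0) return(NA_integer_)
  c0 <- cand[1]
  raw <- ext(y_raw)
  raw <- raw[ok_sign(y_raw[raw])]
  if (length(raw) == 0) return(c0)
  nearest <- raw[which.min(abs(raw - c0))]
  # only relocate within the smoothing neighbourhood; otherwise the
  # smoothed candidate itself is the best estimate
  if (abs(nearest - c0) <= max(3, attr(y_smooth, "span") %||% 3)) nearest else c0
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Operational "complete hyperpolarization" bound for the P2 search: the
# onset of the first excursion after `onset_ms` where the trace stays at
# or below zero for at least `hold_ms`, capped at `cap_ms`.
hyperpolarization_bound <- function(y, t, onset_ms, hold_ms, cap_ms, fs) {
  hold_n <- max(1L, round(hold_ms / 1000 * fs))
  neg <- y <= 0 & t > onset_ms
  r <- rle(neg)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= hold_n)
  if (length(hit) > 0) min(cap_ms, t[starts[hit[1]]]) else cap_ms
}

#' Detect P1, N1 and P2 on an averaged VEP trace
#'
#' Applies the ordinal component definitions: P1 is the first positive
#' local peak in its window, N1 the first negative local trough after P1,
#' and P2 the first subsequent positive local peak occurring before the
#' trace's sustained late negativity ("complete hyperpolarization",
#' operationalized by the windows' hyperpolarization rule). Candidate
#' peaks are screened on a lightly smoothed copy of the trace to ignore
#' single-sample noise ripples; reported latencies are read from the
#' unsmoothed trace. Components that cannot be found are flagged absent,
#' never fabricated, and the latency ordering P1 < N1 < P2 holds in every
#' emitted mark set.
#'
#' Amplitudes are measured peak-to-baseline, with the baseline taken as
#' the trace mean over the initial blanking interval; the N1-P2 amplitude
#' is peak-to-peak (`p2_amp - n1_amp`).
#'
#' @param avg A `vep_average` (or numeric trace, with `sampling_rate`).
#' @param windows A [search_windows()].
#' @param polarity `+1` if positivity is upward in the stored trace,
#'   `-1` for recordings referenced the opposite way.
#' @param sampling_rate Used when `avg` is a bare numeric vector.
#' @return An object of class `vep_marks`: component latencies (ms),
#'   amplitudes (microvolts), implicit times and per-component quality
#'   flags (`"ok"`, `"absent"` or `"no_signal"`).
#' @export
detect_components <- function(avg, windows = search_windows(), polarity = 1,
                              sampling_rate = NULL) {
  fs <- sampling_rate %||% attr(avg, "sampling_rate")
  if (is.null(fs)) stop("sampling_rate missing")
  y <- polarity * as.numeric(avg)
  t <- (seq_along(y) - 1) / fs * 1000

  flags <- c(P1 = "absent", N1 = "absent", P2 = "absent")
  lat <- c(P1 = NA_real_, N1 = NA_real_, P2 = NA_real_)
  amp <- c(P1 = NA_real_, N1 = NA_real_, P2 = NA_real_)

  if (max(y) == min(y)) {
    flags[] <- "no_signal"
    return(new_vep_marks(lat, amp, flags))
  }

  min_amp <- windows$min_amplitude_uv %||% 0
  span <- max(1L, round(windows$smooth_ms / 1000 * fs))
  if (span %% 2 == 0) span <- span + 1L
  ys <- moving_average(y, span)
  attr(ys, "span") <- span
  baseline <- mean(y[t < windows$blank_ms])

  i_p1 <- first_signed_extremum(y, ys, t, windows$p1[1], windows$p1[2], "max",
                                min_amp)
  if (!is.na(i_p1)) {
    lat["P1"] <- t[i_p1]; amp["P1"] <- y[i_p1] - baseline; flags["P1"] <- "ok"
  }

  n1_lo <- max(windows$n1[1], if (!is.na(i_p1)) t[i_p1] + 1000 / fs else -Inf)
  i_n1 <- first_signed_extremum(y, ys, t, n1_lo, windows$n1[2], "min", min_amp)
  if (!is.na(i_n1)) {
    lat["N1"] <- t[i_n1]; amp["N1"] <- y[i_n1] - baseline; flags["N1"] <- "ok"
  }

  bound <- hyperpolarization_bound(ys, t, windows$hyper_onset_ms,
                                   windows$hyper_hold_ms,
                                   windows$hyper_cap_ms, fs)
  after <- if (!is.na(i_n1)) t[i_n1] else if (!is.na(i_p1)) t[i_p1] else -Inf
  p2_lo <- max(windows$p2[1], after + 1000 / fs)
  i_p2 <- first_signed_extremum(y, ys, t, p2_lo, min(windows$p2[2], bound), "max",
                                min_amp)
  if (!is.na(i_p2)) {
    lat["P2"] <- t[i_p2]; amp["P2"] <- y[i_p2] - baseline; flags["P2"] <- "ok"
  }

  implicit_times(new_vep_marks(lat, amp, flags))
}

new_vep_marks <- function(lat, amp, flags) {
  structure(list(
    p1_latency = unname(lat["P1"]), n1_latency = unname(lat["N1"]),
    p2_latency = unname(lat["P2"]),
    p1_amp = unname(amp["P1"]), n1_amp = unname(amp["N1"]),
    p2_amp = unname(amp["P2"]),
    n1_p2_amplitude = if (!is.na(amp["P2"]) && !is.na(amp["N1"]))
      unname(amp["P2"] - amp["N1"]) else NA_real_,
    p1_n1_time = NA_real_, n1_p2_time = NA_real_, p1_p2_time = NA_real_,
    flags = flags), class = "vep_marks")
}

#' Populate implicit times (inter-peak latencies)
#'
#' The implicit time of a segment is the latency of its later peak minus
#' the latency of its earlier one: P1-N1 = N1 - P1, N1-P2 = P2 - N1, and
#' P1-P2 = P2 - P1 (the difference between the two positive peaks). An
#' absent operand yields an absent implicit time.
#'
#' @param marks A `vep_marks`.
#' @return The same `vep_marks` with implicit times filled in.
#' @export
implicit_times <- function(marks) {
  marks$p1_n1_time <- marks$n1_latency - marks$p1_latency
  marks$n1_p2_time <- marks$p2_latency - marks$n1_latency
  marks$p1_p2_time <- marks$p2_latency - marks$p1_latency
  marks
}

#' @export
print.vep_marks <- function(x, ...) {
  cat("<vep_marks>\n")
  for (comp in c("p1", "n1", "p2")) {
    lat <- x[[paste0(comp, "_latency")]]
    if (is.na(lat)) {
      cat(sprintf("  %s: %s\n", toupper(comp), x$flags[toupper(comp)]))
    } else {
      cat(sprintf("  %s: %.2f ms, %+.2f uV\n", toupper(comp), lat,
                  x[[paste0(comp, "_amp")]]))
    }
  }
  cat(sprintf("  implicit times (ms): P1-N1 %.2f | N1-P2 %.2f | P1-P2 %.2f\n",
              x$p1_n1_time, x$n1_p2_time, x$p1_p2_time))
  invisible(x)
}

#' @export
as.data.frame.vep_marks <- function(x, ...) {
  data.frame(p1_latency = x$p1_latency, n1_latency = x$n1_latency,
             p2_latency = x$p2_latency, p1_amp = x$p1_amp,
             n1_amp = x$n1_amp, p2_amp = x$p2_amp,
             n1_p2_amplitude = x$n1_p2_amplitude,
             p1_n1_time = x$p1_n1_time, n1_p2_time = x$n1_p2_time,
             p1_p2_time = x$p1_p2_time,
             p1_flag = unname(x$flags["P1"]), n1_flag = unname(x$flags["N1"]),
             p2_flag = unname(x$flags["P2"]))
}

#' Cross-block mark reproducibility
#'
#' Sessions record several block averages; a component is reproducible
#' when its latency agrees across blocks. Reports, per component, the
#' maximum pairwise latency spread across the marked blocks, flagging
#' components whose spread exceeds the tolerance or that are missing in
#' any block.
#'
#' @param block_marks List of two or more `vep_marks`, one per block.
#' @param tolerance_ms Maximum acceptable pairwise latency spread, ms.
#' @return Data frame with columns `component`, `spread_ms`, `status`
#'   (`"ok"`, `"spread"` or `"unstable"`).
#' @export
mark_reproducibility <- function(block_marks, tolerance_ms = 5) {
  if (length(block_marks) < 2) stop("need at least two marked blocks")
  comps <- c(P1 = "p1_latency", N1 = "n1_latency", P2 = "p2_latency")
  out <- lapply(names(comps), function(nm) {
    lats <- vapply(block_marks, function(m) m[[comps[nm]]], numeric(1))
    if (anyNA(lats)) {
      data.frame(component = nm, spread_ms = NA_real_, status = "unstable")
    } else {
      spread <- max(lats) - min(lats)
      data.frame(component = nm, spread_ms = spread,
                 status = if (spread > tolerance_ms) "spread" else "ok")
    }
  })
  do.call(rbind, out)
}
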