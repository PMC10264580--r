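# Independent brute-force oracle for the ordinal component definitions:
# enumerate every raw local extremum by sign and take the first one
# satisfying each definition inside its window. Shares no code with
# detect_components().
oracle_marks <- function(y, fs, w = search_windows()) {
  n <- length(y)
  t <- (seq_len(n) - 1) / fs * 1000
  is_max <- is_min <- logical(n)
  for (i in 2:(n - 1)) {
    if (y[i] > y[i - 1] && y[i] >= y[i + 1]) is_max[i] <- TRUE
    if (y[i] < y[i - 1] && y[i] <= y[i + 1]) is_min[i] <- TRUE
  }
  thr <- w$min_amplitude_uv
  first_in <- function(ok, lo, hi, positive) {
    for (i in which(ok)) {
      if (t[i] >= lo && t[i] <= hi && ((positive && y[i] >= thr) ||
                                       (!positive && y[i] <= -thr))) return(i)
    }
    NA_integer_
  }
  i_p1 <- first_in(is_max, w$p1[1], w$p1[2], TRUE)
  n1_lo <- if (!is.na(i_p1)) max(w$n1[1], t[i_p1] + 1000 / fs) else w$n1[1]
  i_n1 <- first_in(is_min, n1_lo, w$n1[2], FALSE)
  # hyperpolarization bound: onset of the first run of >= hold_ms at or
  # below zero after onset_ms, capped
  hold_n <- round(w$hyper_hold_ms / 1000 * fs)
  bound <- w$hyper_cap_ms
  for (i in seq_len(n - hold_n)) {
    if (t[i] > w$hyper_onset_ms && all(y[i:(i + hold_n - 1)] <= 0)) {
      bound <- min(bound, t[i]); break
    }
  }
  after <- if (!is.na(i_n1)) t[i_n1] else if (!is.na(i_p1)) t[i_p1] else -Inf
  i_p2 <- first_in(is_max, max(w$p2[1], after + 1000 / fs),
                   min(w$p2[2], bound), TRUE)
  c(P1 = if (is.na(i_p1)) NA_real_ else t[i_p1],
    N1 = if (is.na(i_n1)) NA_real_ else t[i_n1],
    P2 = if (is.na(i_p2)) NA_real_ else t[i_p2])
}

# Random smooth multi-bump fixture: 3-6 Gaussian bumps with widths >= 4 ms
# and centre separations >= 10 ms, on a slow sinusoidal baseline. Smooth
# by construction, so candidate smoothing cannot create or destroy peaks.
random_fixture <- function(acq = acquisition_spec()) {
  t <- epoch_times(acq)
  k <- sample(3:6, 1)
  centers <- numeric(0)
  while (length(centers) < k) {
    cand <- runif(1, 12, 140)
    if (all(abs(cand - centers) >= 10)) centers <- c(centers, cand)
  }
  y <- 0.8 * sin(2 * pi * t / runif(1, 200, 500) + runif(1, 0, 2 * pi))
  for (cm in centers) {
    amp <- sample(c(-1, 1), 1) * runif(1, 3, 15)
    sig <- runif(1, 4, 15) / sqrt(2 * log(2))
    y <- y + amp * exp(-(t - cm)^2 / (2 * sig^2))
  }
  y
}

# Noise-free triphasic trace through kernels only (no filtering)
clean_trace <- function(comps = default_components(), acq = acquisition_spec()) {
  Reduce(`+`, lapply(comps, make_component_kernel, acq = acq))
}

# Marks table built directly from numbers (no waveforms), for endpoint
# and statistics tests: one row per eye x day.
make_marks_df <- function(eyes, days, lat_fun) {
  rows <- list()
  for (e in seq_len(nrow(eyes))) {
    for (d in days) {
      lat <- lat_fun(eyes$group[e], d, e)
      rows[[length(rows) + 1L]] <- data.frame(
        eye_id = eyes$eye_id[e], mouse_id = eyes$eye_id[e],
        group = eyes$group[e], day = d,
        p1_latency = lat["P1"], n1_latency = lat["N1"], p2_latency = lat["P2"],
        p1_amp = 10, n1_amp = -15, p2_amp = 12, n1_p2_amplitude = 27,
        p1_n1_time = lat["N1"] - lat["P1"], n1_p2_time = lat["P2"] - lat["N1"],
        p1_p2_time = lat["P2"] - lat["P1"],
        p1_flag = "ok", n1_flag = "ok", p2_flag = "ok",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

eye_frame <- function(...) {
  spec <- list(...)
  eye_id <- character(0); group <- character(0)
  for (nm in names(spec)) {
    ids <- sprintf("%s_eye%02d", gsub("[^A-Za-z]", "", nm), seq_len(spec[[nm]]))
    eye_id <- c(eye_id, ids); group <- c(group, rep(nm, spec[[nm]]))
  }
  data.frame(eye_id = eye_id, group = group, stringsAsFactors = FALSE)
}
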