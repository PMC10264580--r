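test_that("noise-free triphasic marks recover the construction latencies", {
  fs <- 4096
  m <- detect_components(clean_trace(), sampling_rate = fs)
  expect_true(all(m$flags == "ok"))
  expect_lte(abs(m$p1_latency - 25), 1000 / fs)
  expect_lte(abs(m$n1_latency - 50), 1000 / fs)
  expect_lte(abs(m$p2_latency - 90), 1000 / fs)
  expect_true(m$p1_latency < m$n1_latency && m$n1_latency < m$p2_latency)
  # amplitudes are peak-to-baseline; baseline is ~0 on the clean trace
  expect_equal(m$p1_amp, 10, tolerance = 0.05)
  expect_equal(m$n1_amp, -15, tolerance = 0.05)
  expect_equal(m$n1_p2_amplitude, m$p2_amp - m$n1_amp)
})

test_that("polarity inversion leaves latencies unchanged", {
  y <- clean_trace()
  a <- detect_components(y, polarity = 1, sampling_rate = 4096)
  b <- detect_components(-y, polarity = -1, sampling_rate = 4096)
  expect_identical(a$p1_latency, b$p1_latency)
  expect_identical(a$n1_latency, b$n1_latency)
  expect_identical(a$p2_latency, b$p2_latency)
})

test_that("P1 is the first positive peak, not the largest", {
  acq <- acquisition_spec()
  y <- make_component_kernel(component_spec("P1", 20, 5, 4), acq) +
    make_component_kernel(component_spec("P1", 35, 12, 4), acq) +
    make_component_kernel(component_spec("N1", 55, -10, 6), acq) +
    make_component_kernel(component_spec("P2", 90, 8, 10), acq)
  m <- detect_components(y, sampling_rate = 4096)
  expect_lt(abs(m$p1_latency - 20), 1)
  expect_equal(unname(oracle_marks(y, 4096)["P1"]), m$p1_latency)
})

test_that("ties between equal adjacent extrema resolve to the earliest sample", {
  fs <- 4096
  t <- (0:2047) / fs * 1000
  y <- numeric(2048)
  y[t >= 28 & t <= 30] <- 5   # flat-topped positive plateau
  y[t >= 52 & t <= 56] <- -4  # flat-bottomed negative plateau
  m <- detect_components(y, sampling_rate = fs)
  expect_equal(m$p1_latency, t[min(which(y == 5))])
  expect_equal(m$n1_latency, t[min(which(y == -4))])
})

test_that("a flat trace yields no fabricated components", {
  m <- detect_components(rep(0, 2048), sampling_rate = 4096)
  expect_true(all(is.na(c(m$p1_latency, m$n1_latency, m$p2_latency))))
  expect_true(all(m$flags == "no_signal"))
})

test_that("a missing P1 is flagged absent while N1 and P2 are still reported", {
  acq <- acquisition_spec()
  y <- make_component_kernel(component_spec("N1", 40, -10, 6), acq) +
    make_component_kernel(component_spec("P2", 95, 8, 10), acq)
  m <- detect_components(y, sampling_rate = 4096)
  expect_true(is.na(m$p1_latency))
  expect_identical(unname(m$flags["P1"]), "absent")
  expect_lt(abs(m$n1_latency - 40), 1)
  expect_lt(abs(m$p2_latency - 95), 1)
  expect_true(is.na(m$p1_n1_time) && is.na(m$p1_p2_time))
  expect_false(is.na(m$n1_p2_time))
})

test_that("the P2 search stops at the sustained late negativity", {
  fs <- 4096
  t <- (0:2047) / fs * 1000
  # positive peak at 30, trough at 55, P2 candidate at 80; from 100 ms the
  # trace hyperpolarizes, and a later positive bump at 130 must be ignored
  y <- 8 * exp(-(t - 30)^2 / 40) - 10 * exp(-(t - 55)^2 / 60) +
    5 * exp(-(t - 80)^2 / 60) - 6 * exp(-(t - 115)^2 / 400) +
    4 * exp(-(t - 140)^2 / 20)
  m <- detect_components(y, sampling_rate = fs)
  expect_lt(abs(m$p2_latency - 80), 2)
})

test_that("implicit times are exact differences and absences propagate", {
  m <- flashvep:::new_vep_marks(c(P1 = 25, N1 = 50, P2 = 90),
                                c(P1 = 10, N1 = -15, P2 = 12),
                                c(P1 = "ok", N1 = "ok", P2 = "ok"))
  m <- implicit_times(m)
  expect_identical(m$p1_n1_time, 25)
  expect_identical(m$n1_p2_time, 40)
  expect_identical(m$p1_p2_time, 65)
  expect_identical(m$p1_n1_time + m$n1_p2_time, m$p1_p2_time)

  m2 <- flashvep:::new_vep_marks(c(P1 = NA, N1 = 50, P2 = 90),
                                 c(P1 = NA, N1 = -15, P2 = 12),
                                 c(P1 = "absent", N1 = "ok", P2 = "ok"))
  m2 <- implicit_times(m2)
  expect_true(is.na(m2$p1_n1_time) && is.na(m2$p1_p2_time))
  expect_identical(m2$n1_p2_time, 40)
})

test_that("detection equals the brute-force ordinal oracle on random fixtures", {
  set.seed(31)
  for (i in 1:40) {
    y <- random_fixture()
    m <- detect_components(y, sampling_rate = 4096)
    o <- oracle_marks(y, 4096)
    expect_identical(c(P1 = m$p1_latency, N1 = m$n1_latency, P2 = m$p2_latency),
                     o, label = paste("fixture", i))
  }
})

test_that("component recovery is accurate and unbiased under realistic noise", {
  set.seed(77)
  err <- replicate(60, {
    s <- simulate_session(default_components(),
                          noise_spec(background_sd = 3, jitter_sd = 1),
                          seed = sample.int(2^30, 1))
    m <- detect_components(preprocess_session(s)$grand)
    c(m$p1_latency - 25, m$n1_latency - 50, m$p2_latency - 90)
  })
  expect_lt(max(apply(abs(err), 1, median)), 2)       # median |error| <= 2 ms
  expect_lt(max(abs(rowMeans(err))), 1)               # bias <= 1 ms
})

test_that("cross-block reproducibility reports spreads and instability", {
  mk <- function(n1) flashvep:::new_vep_marks(
    c(P1 = 25, N1 = n1, P2 = 90), c(P1 = 10, N1 = -15, P2 = 12),
    c(P1 = "ok", N1 = "ok", P2 = "ok"))
  rep3 <- mark_reproducibility(list(mk(50), mk(51), mk(52)), tolerance_ms = 5)
  expect_equal(rep3$spread_ms[rep3$component == "N1"], 2)
  expect_true(all(rep3$status[rep3$component != "N1"] == "ok"))

  same <- mark_reproducibility(list(mk(50), mk(50)))
  expect_true(all(same$spread_ms == 0))

  missing <- flashvep:::new_vep_marks(
    c(P1 = 25, N1 = NA, P2 = 90), c(P1 = 10, N1 = NA, P2 = 12),
    c(P1 = "ok", N1 = "absent", P2 = "ok"))
  unst <- mark_reproducibility(list(mk(50), missing))
  expect_identical(unst$status[unst$component == "N1"], "unstable")
})
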