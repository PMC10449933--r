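test_that("sum_traces is an exact column sum", {
  set.seed(1)
  m <- matrix(rnorm(500), 5, 100)
  ts <- trace_set(m, 50000)
  s <- sum_traces(ts)
  brute <- vapply(seq_len(100), function(j) sum(m[, j]), numeric(1))
  expect_identical(s$values, brute)
  expect_equal(s$n_traces_summed, 5)

  t3 <- trace_set(rbind(m[1, ], m[1, ], m[1, ]), 50000)
  expect_equal(sum_traces(t3)$values, 3 * m[1, ])
  tpm <- trace_set(rbind(m[1, ], -m[1, ]), 50000)
  expect_equal(sum_traces(tpm)$values, rep(0, 100))
})

test_that("autocorrelation equals the quadratic-time oracle", {
  expect_equal(autocorrelation(c(1, 0, 0)), c(1, 0, 0))
  expect_equal(autocorrelation(c(1, 1)), c(2, 1))
  set.seed(2)
  for (n in c(17, 64, 256)) {
    s <- rnorm(n)
    a <- autocorrelation(s)
    b <- acf_brute(s)
    expect_lt(max(abs(a - b)) / max(abs(b)), 1e-10)
    expect_equal(which.max(a), 1L)  # lag 0 is the global maximum
  }
})

test_that("autocorrelation peaks recover planted echo lags", {
  fs <- 1000  # 1 ms sampling for easy lag arithmetic
  n <- 100
  pulse <- function(at) { v <- numeric(n); v[at + 1] <- 1; v }
  # one echo 25 ms after the pulse
  s <- pulse(10) + pulse(35)
  pk <- find_ac_peaks(autocorrelation(s), fs, prominence_frac = 0.01)
  expect_equal(pk$peak_lags_ms[1], 0)
  expect_true(any(abs(pk$peak_lags_ms - 25) <= 0.2))

  # two echoes at 25 and 40 ms produce lags {15, 25, 40} beyond zero
  s2 <- pulse(10) + pulse(35) + pulse(50)
  pk2 <- find_ac_peaks(autocorrelation(s2), fs, prominence_frac = 0.01)
  expect_true(any(abs(pk2$peak_lags_ms - 25) <= 0.2))
  expect_true(any(abs(pk2$peak_lags_ms - 40) <= 0.2))
  expect_true(any(abs(pk2$peak_lags_ms - 15) <= 0.2))

  # monotone-decaying acf: no candidate beyond lag 0
  mono <- find_ac_peaks(exp(-(0:50) / 5), fs, prominence_frac = 0.01)
  expect_equal(mono$peak_lags_ms, 0)
})

test_that("M peak search is window-limited with earliest tie-break", {
  fs <- 50000
  n <- 1000  # 20 ms
  t <- (seq_len(n) - 1) / fs * 1000
  mk <- function(v) structure(list(values = v, sampling_rate = fs,
                                   n_traces_summed = 1),
                              class = "sum_signal")
  peak_at <- function(ms, amp) amp * exp(-((t - ms) / 0.5)^2)
  expect_equal(locate_m_peak(mk(peak_at(5, 100))), 5, tolerance = 0.02)
  # constant signal: earliest sample wins
  expect_equal(locate_m_peak(mk(rep(1, n))), 0)
  # global max at 9 ms is outside the 7.5 ms window; the 4 ms bump wins
  v <- peak_at(9, 100) + peak_at(4, 40)
  expect_equal(locate_m_peak(mk(v)), 4, tolerance = 0.02)
})

test_that("slope angle follows the display-geometry definition", {
  fs <- 1000
  t_ms <- 0:49
  expect_equal(slope_angle(50 * t_ms, fs, scale = 50), 45, tolerance = 1e-9)
  expect_equal(slope_angle(rep(3, 50), fs, scale = 50), 0)
  b <- 50 * tan(16 * pi / 180)
  expect_equal(slope_angle(b * t_ms, fs, scale = 50), 16, tolerance = 1e-6)
  expect_lt(slope_angle(-50 * t_ms, fs, scale = 50), 0)  # signed
})

# -- constructed sum signals for the locate/validate logic ---------------

sum_sig <- function(v, fs = 50000, n_sum = 1)
  structure(list(values = v, sampling_rate = fs, n_traces_summed = n_sum),
            class = "sum_signal")

# sum signal with an M-response at m_ms and an F-bump at f_ms
construct_sum <- function(f_ms, f_amp = 3000, m_ms = 5, m_amp = 60000,
                          dur_ms = 98, fs = 50000) {
  n <- round(dur_ms * fs / 1000)
  t <- (seq_len(n) - 1) / fs * 1000
  m <- m_amp * sin(2 * pi * (t - m_ms + 1) / 4) *
    exp(-((t - m_ms) / 2.5)^2)
  f <- f_amp * exp(-((t - f_ms) / 2)^2)
  sum_sig(m + f, fs)
}

test_that("F location search accepts a clean construction", {
  s <- construct_sum(f_ms = 28)
  pk <- find_ac_peaks(autocorrelation(s), s$sampling_rate, 1e-3)
  cfg <- analysis_config()
  loc <- find_f_location(s, pk, cfg)
  expect_lt(abs(loc$fmax_loc_ms - 28), 0.5)
  rr <- loc$attempts$rejection_reason
  expect_identical(rr[length(rr)], "accepted")
  expect_equal(sum(rr == "accepted"), 1)  # exactly one accepted attempt
})

test_that("close-lag echo is rejected by the spacing rule, then accepted", {
  # M-response ringing: an echo of the M at 8 ms lag creates an early
  # autocorrelation peak; the true F bump sits at 28 ms
  s0 <- construct_sum(f_ms = 28)
  fs <- s0$sampling_rate
  t <- (seq_along(s0$values) - 1) / fs * 1000
  ring <- 30000 * sin(2 * pi * (t - 13 + 1) / 4) * exp(-((t - 13) / 2.5)^2)
  s <- sum_sig(s0$values + ring, fs)
  pk <- find_ac_peaks(autocorrelation(s), fs, 1e-3)
  expect_true(any(pk$peak_lags_ms[-1] < 12))
  loc <- find_f_location(s, pk, analysis_config())
  rr <- loc$attempts$rejection_reason
  expect_true("spacing<12ms" %in% rr)
  expect_equal(rr[length(rr)], "accepted")
  expect_lt(abs(loc$fmax_loc_ms - 28), 0.6)
})

test_that("early F-waves trip the latency rule and exhaust the search", {
  # M at 1 ms so the F lag (13 ms) clears the 12 ms spacing rule and the
  # candidate actually reaches the latency check
  s <- construct_sum(f_ms = 14, m_ms = 1)
  pk <- find_ac_peaks(autocorrelation(s), s$sampling_rate, 1e-3)
  err <- tryCatch(find_f_location(s, pk, analysis_config()),
                  fwave_no_corridor = function(e) e)
  expect_s3_class(err, "fwave_no_corridor")
  expect_true("latency<16ms" %in% err$attempts$rejection_reason)
  expect_match(conditionMessage(err), "manual")
})

test_that("corridor cutting window and left trimming behave as specified", {
  fs <- 50000
  dur <- 98
  n <- round(dur * fs / 1000)
  t <- (seq_len(n) - 1) / fs * 1000
  # flat left of the F-wave: no trimming, full 30 ms corridor
  f <- 3000 * exp(-((t - 28) / 2)^2)
  s <- sum_sig(f, fs)
  traces <- trace_set(rbind(f, f / 2), fs)
  ext <- extract_corridor(traces, s, 28, analysis_config())
  expect_equal(ext$corridor$duration_ms, 30, tolerance = 1e-6)
  expect_equal(ext$corridor$left_cut_ms, 18, tolerance = 0.01)
  expect_equal(ext$corridor$right_cut_ms, 48, tolerance = 0.01)
  expect_false(ext$corridor$degenerate)
  # cut applied identically to every trace
  expect_equal(nrow(ext$traces$samples), 2)
  expect_equal(ext$traces$samples[1, ], 2 * ext$traces$samples[2, ])

  # steep M-tail in the first 2 ms of the window: the sum signal rises
  # steeply out of the M-response minimum until 20 ms; those pieces are
  # trimmed away in whole 0.25 ms steps (>= 2 ms) and the corridor still
  # contains Fmax
  cfg <- analysis_config()
  scale45 <- cfg$slope_scale_uv_per_ms_45deg  # 1 trace summed
  steep <- pmin(0, t - 20) * scale45 * 3      # slope +150 uV/ms up to 20 ms
  s2 <- sum_sig(f + steep, fs)
  ext2 <- extract_corridor(trace_set(rbind(f + steep), fs), s2, 28, cfg)
  trim_amt <- ext2$corridor$left_cut_ms - 18
  expect_gte(trim_amt, 2 - 1e-9)
  pieces <- trim_amt / cfg$trim_piece_ms
  expect_equal(pieces, round(pieces), tolerance = 1e-6)
  expect_lt(ext2$corridor$left_cut_ms, 28)
  expect_true(ext2$corridor$left_cut_ms < 28 &&
                28 < ext2$corridor$right_cut_ms)

  # manual mode: the requested cuts pass through exactly
  ext3 <- extract_corridor(traces, s, NULL, cfg, manual_cuts = c(22, 52))
  expect_equal(ext3$corridor$left_cut_ms, 22, tolerance = 1e-6)
  expect_equal(ext3$corridor$right_cut_ms, 52, tolerance = 1e-6)
  expect_identical(ext3$corridor$mode, "manual")
  expect_error(extract_corridor(traces, s, NULL, cfg,
                                manual_cuts = c(52, 22)), "manual cuts")
})

test_that("detected location agrees with the planted modal F peak", {
  # property over seeded synthetic recordings (scaled-down count here;
  # the full 50-run study runs with the acceptance checks)
  hits <- 0L
  for (seed in 1:5) {
    sim <- synthesize(sim_config(n_traces = 300, seed = seed))
    work <- trim_stimulus_artifact(denoise(sim$traces), 2)
    s <- sum_traces(work)
    pk <- find_ac_peaks(autocorrelation(s), s$sampling_rate, 1e-3)
    loc <- find_f_location(s, pk, analysis_config())
    truth_mode <- modal_location(sim$truth$f_peak_loc_ms)
    if (abs(loc$fmax_loc_ms + 2 - truth_mode) <= 0.5) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("corridor result reports raw time as post-trim plus the trim", {
  s <- construct_sum(f_ms = 28)
  traces <- trace_set(rbind(s$values), s$sampling_rate)
  ext <- extract_corridor(traces, s, 28, analysis_config())
  expect_equal(ext$corridor$fmax_loc_raw_ms, ext$corridor$fmax_loc_ms + 2)
  expect_equal(ext$corridor$left_cut_raw_ms, ext$corridor$left_cut_ms + 2)
  expect_equal(ext$corridor$right_cut_raw_ms, ext$corridor$right_cut_ms + 2)
})
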