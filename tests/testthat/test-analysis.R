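# Helper: corridor trace set from a list of trace vectors.
corridor_of <- function(traces, fs = 10000) {
  trace_set(do.call(rbind, traces), fs)
}

test_that("F-wave measurement finds extrema, pp amplitude and power", {
  fs <- 10000
  # triangle up to +60 then down to -40
  tri <- c(seq(0, 60, length.out = 21), seq(57, -40, length.out = 34),
           seq(-38, 0, length.out = 20))
  m <- measure_fwave(tri, 1, fs)
  expect_equal(m$pp_amp, 100)
  expect_equal(m$fmax_amp, 60)
  expect_equal(m$fmin_amp, -40)
  expect_equal(m$fmax_loc, (which.max(tri) - 1) * 1000 / fs)

  z <- measure_fwave(rep(0, 50), 2, fs)
  expect_equal(z$pp_amp, 0)
  expect_equal(z$power, 0)

  set.seed(6)
  x <- rnorm(200, sd = 30)
  r <- measure_fwave(x, 3, fs)
  expect_equal(r$fmax_amp, max(x))          # brute-force scan oracle
  expect_equal(r$fmin_amp, min(x))
  expect_equal(r$pp_amp, max(x) - min(x))
  expect_equal(r$power, sum(x^2) / length(x))
})

test_that("amplitude and noise filters assign the designed statuses", {
  fs <- 10000
  n <- 300  # 30 ms corridor
  t <- (0:(n - 1)) / 10  # ms
  sharp <- function(pp) biphasic_trace(n, fs, peak_ms = 15, pp = pp,
                                       width_ms = 4)
  # six handcrafted traces: 39 uV biphasic, 41 uV sharp biphasic, a slow
  # drift-like sine (pp ~50 uV but < 3 uV change within 3 ms of its peak),
  # sharp 100 uV biphasic, all-zero, constant 100 uV offset
  traces <- corridor_of(list(
    sharp(39),
    sharp(41),
    40 + 25 * sin(2 * pi * t / 40),
    sharp(100),
    rep(0, n),
    rep(100, n)), fs)
  meas <- fwavekit:::measure_fwaves(traces)
  meas <- apply_filters(meas, traces)
  expect_equal(meas$status,
               c("low_amplitude", "ok", "noise", "ok",
                 "low_amplitude", "low_amplitude"))
  expect_equal(sum(meas$status == "ok"), 2)
})

test_that("the 40 uV acceptance is strictly greater-than", {
  fs <- 10000
  traces <- corridor_of(list(biphasic_trace(300, fs, 15, 40, 4),
                             biphasic_trace(300, fs, 15, 40.01, 4)), fs)
  meas <- apply_filters(fwavekit:::measure_fwaves(traces), traces)
  expect_equal(meas$status, c("low_amplitude", "ok"))
})

test_that("pair similarity descriptors follow their definitions", {
  fs <- 10000
  a <- biphasic_trace(300, fs, 15, 100, 5)
  ma <- measure_fwave(a, 1, fs)

  # identical traces
  ps <- pair_similarity(a, a, ma, measure_fwave(a, 2, fs), fs, "fmax")
  expect_equal(ps$amp_ratio, 1)
  expect_equal(ps$pow_ratio, 1)
  expect_equal(ps$corr, 1)
  expect_equal(ps$sim_coeff, 0)
  expect_equal(ps$dmax_ms, 0)

  # half-amplitude copy: power scales with the square
  b <- 0.5 * a
  ps2 <- pair_similarity(a, b, ma, measure_fwave(b, 2, fs), fs, "fmax")
  expect_equal(ps2$amp_ratio, 0.5)
  expect_equal(ps2$pow_ratio, 0.25)
  expect_equal(ps2$corr, 1)
  expect_equal(ps2$sim_coeff, 1.25)

  # 1 ms shifted copy: location difference 1 ms, alignment restores corr
  k <- fs / 1000
  c_ <- c(rep(0, k), a[seq_len(300 - k)])
  ps3 <- pair_similarity(a, c_, ma, measure_fwave(c_, 2, fs), fs, "fmax")
  expect_equal(ps3$dmax_ms, 1)
  expect_gt(ps3$corr, 0.99)
})

test_that("two-pass repeater detection confirms planted repeats only", {
  fs <- 10000
  n <- 300
  mk <- function(peak_ms, pp, width) biphasic_trace(n, fs, peak_ms, pp, width)
  planted <- mk(15, 120, 5)
  distinct <- list(mk(12, 60, 4), mk(14, 260, 7), mk(16, 90, 3),
                   mk(18, 450, 6), mk(13, 200, 5.5), mk(17, 330, 4.5),
                   mk(19, 75, 6.5), mk(11, 150, 3.5))
  traces <- corridor_of(c(list(planted, planted), distinct), fs)
  meas <- apply_filters(fwavekit:::measure_fwaves(traces), traces)
  pairs <- detect_repeaters(meas, traces)
  expect_equal(nrow(pairs), 1)
  expect_setequal(c(pairs$id_a, pairs$id_b), c(1, 2))
  expect_true(pairs$most_similar)

  # all-distinct control: no confirmed pairs
  tr2 <- corridor_of(distinct, fs)
  meas2 <- apply_filters(fwavekit:::measure_fwaves(tr2), tr2)
  pairs2 <- detect_repeaters(meas2, tr2)
  expect_equal(nrow(pairs2), 0)
  expect_gt(attr(pairs2, "n_evaluated"), 0)
})

test_that("a decorrelated twin fails pass one on correlation but is
           recovered by the stricter second pass", {
  fs <- 10000
  n <- 300
  t <- (0:(n - 1)) / 10
  # both traces share a sharp biphasic core (identical extrema, so
  # identical pp, dmax = dmin = 0) plus equal-energy orthogonal tail
  # oscillations: the amplitude and power ratios stay ~1 while the
  # correlation drops to the core's share of the total energy (~0.85)
  core <- biphasic_trace(n, fs, 15, 100, 4)
  tail_on <- t >= 20 & t < 28   # 8 full 1 ms periods: sin and cos orthogonal
  e_core <- sum(core^2)
  r_tail <- 0.15 / 0.85         # tail / core energy ratio -> corr ~ 0.85
  amp <- sqrt(r_tail * e_core / (0.5 * sum(tail_on)))
  a <- core + amp * sin(2 * pi * t) * tail_on
  b <- core + amp * cos(2 * pi * t) * tail_on
  traces <- corridor_of(list(a, b), fs)
  meas <- apply_filters(fwavekit:::measure_fwaves(traces), traces)
  ps <- pair_similarity(a, b, meas[1, ], meas[2, ], fs, "fmax")
  expect_lt(ps$corr, 0.9)
  expect_gt(ps$corr, 0.8)
  expect_gt(ps$amp_ratio, 0.95)
  expect_gt(ps$pow_ratio, 0.9)

  pairs <- detect_repeaters(meas, traces)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$pass, 2L)  # rejected in pass 1, confirmed in pass 2

  # pass-2 ratios out of reach (strict > 1 is unattainable): unconfirmed
  cfg_strict <- analysis_config(amp_ratio_2 = 1, pow_ratio_2 = 1)
  pairs_strict <- detect_repeaters(meas, traces, cfg_strict)
  expect_equal(nrow(pairs_strict), 0)
})

test_that("grouping merges linked pairs like a union-find oracle", {
  fs <- 10000
  traces <- corridor_of(lapply(1:6, function(i)
    biphasic_trace(120, fs, 6, 100, 4)), fs)
  meas <- fwavekit:::measure_fwaves(traces)
  mk_pairs <- function(m) {
    data.frame(id_a = m[, 1], id_b = m[, 2], pass = 1L, dmax_ms = 0,
               dmin_ms = 0, amp_ratio = 1, pow_ratio = 1, corr = 1,
               sim_coeff = 0, most_similar = FALSE)
  }
  g1 <- group_repeaters(mk_pairs(rbind(c(1, 2), c(2, 3))), meas, traces)
  expect_equal(nrow(g1), 1)
  expect_equal(g1$members[[1]], c(1, 2, 3))

  g2 <- group_repeaters(mk_pairs(rbind(c(1, 2), c(3, 4))), meas, traces)
  expect_equal(nrow(g2), 2)

  set.seed(9)
  for (rep in 1:5) {
    edges <- unique(t(apply(matrix(sample(1:6, 8, TRUE), ncol = 2), 1, sort)))
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    if (!nrow(edges)) next
    p <- mk_pairs(edges)
    got <- canon_groups(group_repeaters(p, meas, traces)$members)
    want <- canon_groups(Filter(function(g) length(g) >= 2,
                                union_find_groups(p)))
    expect_equal(got, want)
  }
})

test_that("M-response measures come from the mean trace over the M window", {
  fs <- 50000
  n <- 1000  # 20 ms
  m <- biphasic_trace(n, fs, peak_ms = 5, pp = 2000, width_ms = 8)
  traces <- trace_set(rbind(m, m, m), fs)
  r <- measure_m_response(traces)
  expect_equal(r$m_pp_amp, 2000, tolerance = 1)
  # positive-phase area plus negative-phase area equals total area
  idx <- seq_len(16 * fs / 1000)
  neg_area <- sum(pmax(-m[idx], 0)) * 1000 / fs
  expect_equal(r$m_pos_area + neg_area, r$m_total_area, tolerance = 1e-9)

  z <- measure_m_response(trace_set(matrix(0, 2, n), fs))
  expect_equal(unlist(z), c(m_pp_amp = 0, m_pos_area = 0, m_total_area = 0))
})

test_that("feature arithmetic matches the MUNE definitions", {
  groups <- data.frame(group_id = 1:2, size = c(2L, 3L),
                       smup_pp_amp = c(100, 100),
                       smup_pos_area = c(50, 50),
                       smup_total_area = c(100, 100))
  groups$members <- list(c(1L, 2L), c(3L, 4L, 5L))
  meas <- data.frame(trace_id = 1:300,
                     status = rep(c("ok", "low_amplitude"), times = c(150, 150)))
  m_meas <- list(m_pp_amp = 1000, m_pos_area = 500, m_total_area = 1000)
  f <- compute_features(groups, meas, m_meas, 300)
  expect_equal(f$mune1, 10)
  expect_equal(f$mune2, 10)
  expect_equal(f$mune3, 10)
  expect_equal(f$persistence, 0.5)
  expect_equal(f$n_repeater_fwaves, 5L)
  expect_equal(f$n_repeater_neurons, 2L)

  # one group whose sMUP equals the M-response: MUNE of one
  g1 <- groups[1, ]; g1$smup_pp_amp <- 1000
  g1$members <- list(c(1L, 2L))
  expect_equal(compute_features(g1, meas, m_meas, 300)$mune1, 1)

  # no groups: MUNE missing with a reason
  f0 <- compute_features(groups[0, ], meas, m_meas, 300)
  expect_true(is.na(f0$mune1))
  expect_match(f0$mune_reason, "no repeater groups")
})
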