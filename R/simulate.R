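# Synthetic EMG recording generator with ground truth.
#
# Each trace carries a high-amplitude M-response at a fixed early latency
# and, when at least one motor unit of the pool backfires, an F-wave built
# as the sum of the fired units' surface potentials. Unit templates are
# peak-aligned when planted, so a trace's F latency is the location of its
# F-wave peak. Structure (fired sets, latencies, repeats) and nuisance
# (noise, baseline drift) are drawn from two independent random streams,
# so changing the noise level leaves the planted truth unchanged.

#' Simulation configuration
#'
#' @param n_traces Number of consecutive traces (default 300, a full
#'   recording session).
#' @param sampling_rate Hz (default 50000).
#' @param duration_ms Trace duration (default 100 ms).
#' @param m_latency_ms M-response peak latency (default 5 ms; must stay
#'   inside the 7.5 ms M search window).
#' @param m_amplitude_uv M-response peak-to-peak amplitude (default
#'   2000 uV; recordings require at least 1 mV).
#' @param n_units Motor-unit pool size (default 20).
#' @param unit_amp_range_uv Peak-to-peak amplitude range the unit surface
#'   potentials are drawn from (default 50-150 uV).
#' @param unit_fire_prob Per-trace backfire probability of each unit
#'   (default 0.05; expected persistence `1 - (1-p)^n_units` ~ 0.64).
#' @param f_latency_ms F-wave peak latency (default 28 ms; F-waves of the
#'   median/ulnar nerves appear after 20 ms).
#' @param jitter_ms Trace-to-trace latency jitter bound (truncated
#'   Gaussian, sd `jitter_ms / 2`, bounded at `+-jitter_ms`; default 1 ms).
#' @param unit_latency_spread_ms Half-width of the fixed per-unit latency
#'   offsets (uniform), reflecting that each motor neuron has its own
#'   conduction latency. Default 0: all units share `f_latency_ms`, so
#'   the F-peak population stays at `f_latency_ms +- jitter_ms`.
#' @param repeater_frac Fraction of F-wave-bearing traces forced to repeat
#'   an earlier trace's exact unit combination (default 0.2).
#' @param noise_sd_uv Additive Gaussian noise SD (default 10 uV).
#' @param baseline `"none"`, `"linear"` or `"sigmoid"` drift.
#' @param baseline_mag_uv Maximum drift magnitude (default 100, capped at
#'   200 uV).
#' @param seed Integer seed; the nuisance stream uses `seed + 77777`.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_traces = 300L,
                       sampling_rate = 50000,
                       duration_ms = 100,
                       m_latency_ms = 5,
                       m_amplitude_uv = 2000,
                       n_units = 20L,
                       unit_amp_range_uv = c(50, 150),
                       unit_fire_prob = 0.05,
                       f_latency_ms = 28,
                       jitter_ms = 1,
                       unit_latency_spread_ms = 0,
                       repeater_frac = 0.2,
                       noise_sd_uv = 10,
                       baseline = c("none", "linear", "sigmoid"),
                       baseline_mag_uv = 100,
                       seed = 1L) {
  baseline <- match.arg(baseline)
  if (f_latency_ms <= 20)
    stop("f_latency_ms must exceed 20 ms (F-waves are not elicited earlier)",
         call. = FALSE)
  if (m_latency_ms >= 7.5)
    stop("m_latency_ms must be below 7.5 ms", call. = FALSE)
  if (m_amplitude_uv < 1000)
    stop("m_amplitude_uv must be at least 1000 uV (1 mV criterion)",
         call. = FALSE)
  if (noise_sd_uv < 0 || jitter_ms < 0 || baseline_mag_uv < 0 ||
      unit_latency_spread_ms < 0)
    stop("spreads must be non-negative", call. = FALSE)
  if (unit_fire_prob < 0 || unit_fire_prob > 1 ||
      repeater_frac < 0 || repeater_frac > 1)
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (baseline_mag_uv > 200)
    stop("baseline_mag_uv is capped at 200 uV", call. = FALSE)
  structure(list(n_traces = as.integer(n_traces),
                 sampling_rate = sampling_rate,
                 duration_ms = duration_ms,
                 m_latency_ms = m_latency_ms,
                 m_amplitude_uv = m_amplitude_uv,
                 n_units = as.integer(n_units),
                 unit_amp_range_uv = unit_amp_range_uv,
                 unit_fire_prob = unit_fire_prob,
                 f_latency_ms = f_latency_ms,
                 jitter_ms = jitter_ms,
                 unit_latency_spread_ms = unit_latency_spread_ms,
                 repeater_frac = repeater_frac,
                 noise_sd_uv = noise_sd_uv,
                 baseline = baseline,
                 baseline_mag_uv = baseline_mag_uv,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Smooth zero-mean biphasic/triphasic waveform sampled at fs; pp amplitude
# `pp_uv`, support `support_ms`, `phases` half-cycles, asymmetry `skew`,
# second-harmonic admixture `h2` (shape diversity across the pool). The
# returned vector's attribute "peak" is the index of its maximum.
unit_waveform <- function(pp_uv, support_ms, phases, skew, sampling_rate,
                          h2 = 0) {
  n <- max(4L, as.integer(round(support_ms * sampling_rate / 1000)))
  u <- seq(0, 1, length.out = n)
  w <- u^skew / (u^skew + (1 - u)^skew)        # warped time, skews lobes
  taper <- sin(pi * u)^2                       # zero at both ends
  x <- (sin(pi * phases * w) + h2 * sin(2 * pi * phases * w)) * taper
  x <- x - (mean(x) / mean(taper)) * taper     # exact zero mean, kept taper
  x <- x * pp_uv / (max(x) - min(x))
  attr(x, "peak") <- which.max(x)
  x
}

#' Generate the motor-unit template pool
#'
#' Each template is a smooth zero-mean biphasic or triphasic wave of
#' 5-15 ms support with peak-to-peak amplitude drawn from
#' `unit_amp_range_uv`; deterministic under the configuration seed.
#'
#' @param cfg A [sim_config()].
#' @return List of waveform vectors (uV), each with a `"peak"` attribute
#'   marking the sample of its maximum.
#' @export
make_unit_templates <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_units < 1) stop("n_units must be >= 1", call. = FALSE)
  withr_seed <- .Random.seed_exists()
  set.seed(cfg$seed)
  on.exit(restore_seed(withr_seed), add = TRUE)
  lapply(seq_len(cfg$n_units), function(i) {
    pp <- stats::runif(1, cfg$unit_amp_range_uv[1], cfg$unit_amp_range_uv[2])
    # stratified support so no two units are near-duplicates
    support <- 5 + 10 * ((i - stats::runif(1)) / cfg$n_units)
    phases <- sample(2:3, 1)
    skew <- stats::runif(1, 0.6, 1.6)
    h2 <- stats::runif(1, -0.4, 0.4)
    # enforce a dominant positive peak and a dominant trough: near-tied
    # lobes would make the extremum locations flip under recording noise,
    # which real motor-unit potentials do not do
    for (try in 1:6) {
      w <- unit_waveform(pp, support, phases, skew, cfg$sampling_rate, h2)
      if (lobe_dominant(w)) break
      # push the asymmetry away from 1 (in its current direction) and
      # fade the harmonic; both changes separate near-tied lobes
      dev <- skew - 1
      skew <- max(0.25, min(4, 1 + sign(dev + 1e-9) * (abs(dev) * 1.4 + 0.12)))
      h2 <- h2 * 0.5
    }
    if (!lobe_dominant(w))  # plain skewed biphasic is always dominant
      w <- unit_waveform(pp, support, 2, 1.3, cfg$sampling_rate, 0)
    w
  })
}

# TRUE when the waveform's largest positive lobe and deepest trough both
# dominate their runners-up by a clear margin.
lobe_dominant <- function(w, margin = 0.85) {
  lm <- local_maxima(as.numeric(w))
  ln <- local_maxima(-as.numeric(w))
  ok_max <- nrow(lm) < 2 ||
    sort(lm$value, decreasing = TRUE)[2] < margin * max(lm$value)
  ok_min <- nrow(ln) < 2 ||
    sort(ln$value, decreasing = TRUE)[2] < margin * max(ln$value)
  ok_max && ok_min
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
restore_seed <- function(saved) {
  if (!is.null(saved)) assign(".Random.seed", saved, envir = globalenv())
}

# Add waveform w to vector x so that w's peak lands at time `peak_ms`;
# clipped at the trace boundaries.
add_at_peak <- function(x, w, peak_ms, sampling_rate) {
  pk <- attr(w, "peak")
  start <- as.integer(round(peak_ms * sampling_rate / 1000)) + 1L - pk + 1L
  idx <- start:(start + length(w) - 1L)
  keep <- idx >= 1L & idx <= length(x)
  x[idx[keep]] <- x[idx[keep]] + w[keep]
  x
}

#' Synthesize a recording with ground truth
#'
#' Builds `n_traces` traces: an M-response template at `m_latency_ms` on
#' every trace, plus, per trace, the peak-aligned sum of the backfiring
#' units' templates at `f_latency_ms` + jitter, plus baseline drift and
#' Gaussian noise. A `repeater_frac` fraction of the F-wave-bearing traces
#' reuse an earlier trace's exact unit set with latency within 0.1 ms.
#'
#' @param cfg A [sim_config()].
#' @param unit_sets Optional list of length `n_traces` giving each trace's
#'   fired-unit index vector explicitly (overrides random firing and
#'   repeater planting; `integer(0)` entries give F-wave-free traces).
#' @param keep_components If `TRUE`, the noiseless F-wave component matrix
#'   is kept in the ground truth (for energy bookkeeping in tests).
#' @return List with `traces` (a [trace_set()]) and `truth` — per trace:
#'   fired unit sets, F peak latency/location/amplitude, `has_fwave`;
#'   global: repeater grouping by identical unit set, true corridor, unit
#'   count.
#' @export
synthesize <- function(cfg, unit_sets = NULL, keep_components = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  fs <- cfg$sampling_rate
  n_samp <- as.integer(round(cfg$duration_ms * fs / 1000))
  if (cfg$f_latency_ms + cfg$jitter_ms + 15 > cfg$duration_ms)
    stop("duration too short for the configured F latency", call. = FALSE)
  templates <- make_unit_templates(cfg)
  m_tpl <- unit_waveform(cfg$m_amplitude_uv, 9, 2, 0.45, fs)

  saved <- .Random.seed_exists()
  on.exit(restore_seed(saved), add = TRUE)

  # ---- structure stream (distinct from the template stream) ----
  set.seed(cfg$seed + 1337L)
  unit_off <- stats::runif(cfg$n_units, -cfg$unit_latency_spread_ms,
                           cfg$unit_latency_spread_ms)
  if (is.null(unit_sets)) {
    fire <- matrix(stats::runif(cfg$n_traces * cfg$n_units) < cfg$unit_fire_prob,
                   cfg$n_traces, cfg$n_units)
    unit_sets <- lapply(seq_len(cfg$n_traces), function(i) which(fire[i, ]))
    # repeater planting: a fraction of F-bearing traces copy an earlier one
    bearing <- which(lengths(unit_sets) > 0)
    if (length(bearing) > 1 && cfg$repeater_frac > 0) {
      later <- bearing[-1]
      is_rep <- stats::runif(length(later)) < cfg$repeater_frac
      for (k in which(is_rep)) {
        src <- sample(bearing[bearing < later[k]], 1)
        unit_sets[[later[k]]] <- unit_sets[[src]]
        attr(unit_sets[[later[k]]], "copy_of") <- src
      }
    }
  } else {
    stopifnot(length(unit_sets) == cfg$n_traces)
  }
  # truncated-Gaussian latency jitter: peaked at f_latency_ms, bounded by
  # +- jitter_ms (physiological latency scatter is approximately normal)
  jit <- stats::rnorm(cfg$n_traces, 0, cfg$jitter_ms / 2)
  jit <- pmin(pmax(jit, -cfg$jitter_ms), cfg$jitter_ms)
  lat <- cfg$f_latency_ms + jit +
    vapply(unit_sets, function(s)
      if (length(s)) mean(unit_off[as.integer(s)]) else 0, numeric(1))
  # repeats of an earlier trace's unit combination re-fire within 0.1 ms
  # of it (never more than the configured jitter), whether planted by the
  # repeater draw or arising by chance / given explicitly
  rep_jit <- min(0.1, cfg$jitter_ms)
  set_key <- vapply(unit_sets, function(s)
    paste(sort(as.integer(s)), collapse = "-"), character(1))
  for (i in seq_len(cfg$n_traces)) {
    src <- attr(unit_sets[[i]], "copy_of")
    if (is.null(src) && nzchar(set_key[i]) && i > 1) {
      hit <- which(set_key[seq_len(i - 1)] == set_key[i])
      if (length(hit)) src <- hit[1]
    }
    if (!is.null(src)) lat[i] <- lat[src] + stats::runif(1, -rep_jit, rep_jit)
  }

  # ---- build noiseless components ----
  Fc <- matrix(0, cfg$n_traces, n_samp)
  for (i in seq_len(cfg$n_traces)) {
    if (!length(unit_sets[[i]])) next
    row <- Fc[i, ]
    for (u in unit_sets[[i]])
      row <- add_at_peak(row, templates[[u]], lat[i], fs)
    Fc[i, ] <- row
  }
  m_row <- add_at_peak(numeric(n_samp), m_tpl, cfg$m_latency_ms, fs)
  M <- matrix(m_row, cfg$n_traces, n_samp, byrow = TRUE)

  # ---- nuisance stream: baseline drift + noise ----
  set.seed(cfg$seed + 77777L)
  t_ms <- 1000 * (seq_len(n_samp) - 1) / fs
  B <- matrix(0, cfg$n_traces, n_samp)
  if (cfg$baseline == "linear") {
    off <- stats::runif(cfg$n_traces, -1, 1) * cfg$baseline_mag_uv / 2
    slope <- stats::runif(cfg$n_traces, -1, 1) * cfg$baseline_mag_uv /
      cfg$duration_ms
    B <- off + outer(slope, t_ms)
  } else if (cfg$baseline == "sigmoid") {
    mag <- stats::runif(cfg$n_traces, -1, 1) * cfg$baseline_mag_uv
    ctr <- stats::runif(cfg$n_traces, 0.3, 0.7) * cfg$duration_ms
    wid <- stats::runif(cfg$n_traces, 5, 20)
    for (i in seq_len(cfg$n_traces))
      B[i, ] <- mag[i] * stats::plogis((t_ms - ctr[i]) / wid[i])
  }
  Z <- matrix(stats::rnorm(cfg$n_traces * n_samp), cfg$n_traces, n_samp)
  X <- M + Fc + B + cfg$noise_sd_uv * Z

  # ---- ground truth ----
  has_f <- lengths(unit_sets) > 0
  peak_loc <- rep(NA_real_, cfg$n_traces)
  pp <- rep(NA_real_, cfg$n_traces)
  onset <- rep(NA_real_, cfg$n_traces)
  offset <- rep(NA_real_, cfg$n_traces)
  for (i in which(has_f)) {
    x <- Fc[i, ]
    peak_loc[i] <- (which.max(x) - 1) * 1000 / fs
    pp[i] <- max(x) - min(x)
    nz <- which(abs(x) > 1e-9)
    onset[i] <- (nz[1] - 1) * 1000 / fs
    offset[i] <- (nz[length(nz)] - 1) * 1000 / fs
  }
  key <- vapply(unit_sets, function(s)
    paste(sort(as.integer(s)), collapse = "-"), character(1))
  key[!has_f] <- NA_character_
  grouping <- split(which(has_f), key[has_f])
  margin <- 1
  corridor <- if (any(has_f))
    c(min(onset, na.rm = TRUE) - margin, max(offset, na.rm = TRUE) + margin)
  else c(NA_real_, NA_real_)
  truth <- list(unit_sets = lapply(unit_sets, as.integer),
                has_fwave = has_f,
                f_latency_ms = ifelse(has_f, lat, NA_real_),
                f_peak_loc_ms = peak_loc,
                f_pp_amp_uv = pp,
                f_onset_ms = onset, f_offset_ms = offset,
                grouping = unname(grouping[order(vapply(grouping, min, 1))]),
                corridor_ms = corridor,
                n_units = cfg$n_units)
  if (keep_components) truth$f_component <- Fc
  list(traces = trace_set(X, fs, t0_offset = 0,
                          meta = list(synthetic = TRUE, seed = cfg$seed)),
       truth = truth)
}

#' Write simulation ground truth as JSON
#'
#' @param truth The `truth` element of a [synthesize()] result.
#' @param path Output JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  truth$f_component <- NULL
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
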