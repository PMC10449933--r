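# Corridor location: sum signal, autocorrelation, candidate-peak
# validation rules and the 30 ms cutting window.
#
# All locations in this file are in post-trim time: milliseconds measured
# from the first sample of the (artifact-trimmed) traces. Raw-recording
# time is post-trim time plus the artifact trim (2 ms by default).

#' Sum signal of all traces
#'
#' Column-wise sum of all traces. Because every trace carries the
#' M-response at the same latency, the M-response dominates the sum, while
#' F-waves, clustered around a common latency, build a smaller late bump.
#'
#' @param traces A [trace_set()] (denoised and artifact-trimmed).
#' @return An object of class `sum_signal`: list with `values` (uV),
#'   `sampling_rate` and `n_traces_summed`.
#' @export
sum_traces <- function(traces) {
  stopifnot(inherits(traces, "trace_set"))
  structure(list(values = colSums(traces$samples),
                 sampling_rate = traces$sampling_rate,
                 n_traces_summed = n_traces(traces)),
            class = "sum_signal")
}

#' Raw autocorrelation of the sum signal
#'
#' Unnormalized autocorrelation `acf[k] = sum_i s[i] * s[i+k]` for lags
#' `k = 0 .. n-1` (zero-padded shift, non-negative half). Computed by FFT;
#' equal to the O(n^2) direct sum to floating-point accuracy. The lag-0
#' value is always the global maximum.
#'
#' @param s A `sum_signal` or numeric vector.
#' @return Numeric vector of length `n`: autocorrelation at lags 0..n-1.
#' @export
autocorrelation <- function(s) {
  v <- if (inherits(s, "sum_signal")) s$values else as.numeric(s)
  n <- length(v)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  N <- stats::nextn(2L * n, 2)
  V <- stats::fft(c(v, rep(0, N - n)))
  r <- Re(stats::fft(V * Conj(V), inverse = TRUE)) / N
  r[seq_len(n)]
}

# Local maxima of v (strict neighbours; plateaus resolved to the earliest
# sample) with their prominences. Prominence of a peak is its height above
# the higher of the two lowest valleys separating it from higher terrain.
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(data.frame(index = integer(0), value = numeric(0),
                               prominence = numeric(0)))
  d <- diff(v)
  # rising-then-falling, treating flats as continuation of the last move
  s <- sign(d)
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  idx <- which(diff(s) < 0) + 1L
  idx <- idx[idx > 1 & idx < n]
  if (!length(idx)) return(data.frame(index = integer(0), value = numeric(0),
                                      prominence = numeric(0)))
  prom <- vapply(idx, function(i) {
    h <- v[i]
    left <- v[seq_len(i - 1)]
    hi_l <- which(left > h)
    base_l <- if (length(hi_l)) min(left[(max(hi_l) + 1):(i - 1)]) else min(left)
    right <- v[(i + 1):n]
    hi_r <- which(right > h)
    base_r <- if (length(hi_r)) min(right[seq_len(min(hi_r) - 1)]) else min(right)
    h - max(base_l, base_r)
  }, numeric(1))
  data.frame(index = idx, value = v[idx], prominence = prom)
}

#' Candidate peaks of the autocorrelation function
#'
#' Lag 0 (the global maximum of any autocorrelation) is always the first
#' entry; subsequent entries are local maxima with prominence at least
#' `prominence_frac * acf[0]`, ordered by lag.
#'
#' @param acf Autocorrelation values for lags 0..n-1 (see
#'   [autocorrelation()]).
#' @param sampling_rate Sampling rate in Hz (to express lags in ms).
#' @param prominence_frac Minimum peak prominence as a fraction of the
#'   lag-0 value.
#' @return Object of class `acf_peaks`: list with `acf`, `peak_lags_ms`
#'   (strictly increasing, first entry 0) and `sampling_rate`.
#' @export
find_ac_peaks <- function(acf, sampling_rate, prominence_frac = 1e-3) {
  lm <- local_maxima(acf)
  lm <- lm[lm$prominence >= prominence_frac * acf[1], , drop = FALSE]
  lags_ms <- c(0, 1000 * (lm$index - 1) / sampling_rate)
  structure(list(acf = acf, peak_lags_ms = lags_ms,
                 sampling_rate = sampling_rate),
            class = "acf_peaks")
}

#' Location of the M-response peak on the sum signal
#'
#' Argmax of the sum signal over the first `m_search_ms` (default 7.5 ms)
#' of post-trim time; ties resolve to the earliest sample.
#'
#' @param s A `sum_signal`.
#' @param m_search_ms Search window length in ms.
#' @return Location in ms (post-trim).
#' @export
locate_m_peak <- function(s, m_search_ms = 7.5) {
  stopifnot(inherits(s, "sum_signal"))
  if (1000 * length(s$values) / s$sampling_rate <= m_search_ms)
    stop("signal shorter than the M search window", call. = FALSE)
  idx <- window_indices(0, m_search_ms, 0, s$sampling_rate, length(s$values))
  i <- idx[which.max(s$values[idx])]
  index_to_ms(i, 0, s$sampling_rate)
}

#' Slope of a segment in display degrees
#'
#' Least-squares slope of the segment (uV/ms) mapped to the instrument
#' display angle: `atan(slope / scale)` in degrees, signed, where `scale`
#' is the uV/ms slope drawn at 45 degrees on the screen.
#'
#' @param segment Numeric amplitude vector (uV).
#' @param sampling_rate Sampling rate in Hz.
#' @param scale uV/ms corresponding to 45 degrees.
#' @return Signed angle in degrees.
#' @export
slope_angle <- function(segment, sampling_rate, scale = 50) {
  n <- length(segment)
  if (n < 2) stop("segment needs at least 2 samples", call. = FALSE)
  t <- 1000 * (seq_len(n) - 1) / sampling_rate   # ms
  tc <- t - mean(t)
  b <- sum(tc * (segment - mean(segment))) / sum(tc^2)  # uV/ms
  atan(b / scale) * 180 / pi
}

# Positive local maxima (value > 0) of the full signal v that fall inside
# the index window `idx`. Maxima are of v itself, so a monotone stretch at
# the window edge never counts as a peak.
positive_peaks_in <- function(v, idx) {
  if (!length(idx)) return(integer(0))
  lm <- local_maxima(v)
  keep <- lm$index[lm$index %in% idx & lm$value > 0]
  keep
}

#' Locate the F-wave maximum-amplitude position
#'
#' Iterates over candidate autocorrelation peaks in lag order and applies
#' the validation rules. For each candidate lag `L`, the approximate
#' F-maximum location is `m_loc + L`; the refined location is the highest
#' positive local maximum of the sum signal inside the window
#' `[approx - window_back_ms, approx + window_fwd_ms)`. A candidate is
#' rejected and the next tried when:
#' \describe{
#'   \item{`spacing<12ms`}{lag closer than `min_ac_peak_spacing_ms` to lag
#'     zero — an artificial peak from M-response fluctuation;}
#'   \item{`no_positive_peak`}{no positive local maximum in the window;}
#'   \item{`amplitude_floor`}{sum-signal value at the refined location
#'     below `floor_sum_uv` (near the M-response global minimum);}
#'   \item{`latency<16ms`}{refined location earlier than
#'     `min_f_latency_ms` post-trim (18 ms raw — F-waves of the
#'     median/ulnar nerves are not elicited before 20 ms);}
#'   \item{`slope>16deg`}{the 15 ms segment centred on the refined
#'     location slopes more steeply than `slope_limit_deg`, meaning the
#'     left part belongs to the M-response. This rule may advance the
#'     candidate at most once per run; a second hit aborts the search.}
#' }
#'
#' @param s A `sum_signal`.
#' @param peaks An `acf_peaks` object.
#' @param cfg An [analysis_config()].
#' @return List with `fmax_loc_ms` (post-trim), `selected_ac_peak_lag_ms`
#'   and `attempts` (data.frame of candidate lags and outcomes; exactly
#'   one row is `accepted` on success).
#' @export
find_f_location <- function(s, peaks, cfg = analysis_config()) {
  stopifnot(inherits(s, "sum_signal"), inherits(peaks, "acf_peaks"))
  v <- s$values
  fs <- s$sampling_rate
  n <- length(v)
  cand_lags <- peaks$peak_lags_ms[-1]
  if (!length(cand_lags))
    stop("no-corridor: autocorrelation has no peak beyond lag 0; ",
         "use manual cut locations", call. = FALSE)
  m_loc <- locate_m_peak(s, cfg$m_search_ms)
  sum_scale <- cfg$slope_scale_uv_per_ms_45deg * s$n_traces_summed
  attempts <- data.frame(ac_peak_lag_ms = numeric(0),
                         rejection_reason = character(0))
  log_attempt <- function(lag, reason) {
    attempts[nrow(attempts) + 1L, ] <<- list(lag, reason)
  }
  r5_used <- FALSE
  tried <- 0L
  for (lag in cand_lags) {
    if (tried >= cfg$max_ac_attempts) break
    tried <- tried + 1L
    if (lag < cfg$min_ac_peak_spacing_ms) {           # R1
      log_attempt(lag, "spacing<12ms"); next
    }
    approx <- m_loc + lag
    win <- window_indices(approx - cfg$window_back_ms,
                          approx + cfg$window_fwd_ms, 0, fs, n)
    pk <- positive_peaks_in(v, win)
    if (!length(pk)) {                                # R2
      log_attempt(lag, "no_positive_peak"); next
    }
    refined_i <- pk[which.max(v[pk])]
    refined <- index_to_ms(refined_i, 0, fs)
    if (v[refined_i] < cfg$floor_sum_uv) {            # R3
      log_attempt(lag, "amplitude_floor"); next
    }
    if (refined < cfg$min_f_latency_ms) {             # R4
      log_attempt(lag, "latency<16ms"); next
    }
    seg <- window_indices(refined - cfg$window_back_ms,
                          refined + cfg$window_back_ms, 0, fs, n)
    ang <- slope_angle(v[seg], fs, sum_scale)
    if (ang > cfg$slope_limit_deg) {                  # R5
      log_attempt(lag, "slope>16deg")
      if (r5_used) {
        err <- structure(
          class = c("fwave_no_corridor", "error", "condition"),
          list(message = "no-corridor: slope rule rejected a second candidate; use manual cut locations",
               call = NULL, attempts = attempts))
        stop(err)
      }
      r5_used <- TRUE
      next
    }
    log_attempt(lag, "accepted")
    return(list(fmax_loc_ms = refined, selected_ac_peak_lag_ms = lag,
                m_loc_ms = m_loc, attempts = attempts))
  }
  err <- structure(
    class = c("fwave_no_corridor", "error", "condition"),
    list(message = "no-corridor: autocorrelation candidates exhausted; use manual cut locations",
         call = NULL, attempts = attempts))
  stop(err)
}

#' Cut the F-wave corridor from all traces
#'
#' Places the cutting window `[fmax - cut_back_ms, fmax + cut_fwd_ms)`
#' (default 10 ms back, 20 ms forward) on the sum signal, then repeatedly
#' drops the leftmost `trim_piece_ms` (0.25 ms) piece while its slope
#' exceeds `slope_limit_deg` — steep left pieces belong to the M-response
#' tail. The final `[left_cut, right_cut)` window is applied identically
#' to every trace.
#'
#' In manual mode (`manual_cuts` given, post-trim ms) the window is used
#' verbatim and no trimming is performed.
#'
#' @param traces The denoised, artifact-trimmed [trace_set()].
#' @param s The matching `sum_signal`.
#' @param fmax_loc F-maximum location in post-trim ms (ignored in manual
#'   mode, where it is set to the window midpoint if `NULL`).
#' @param cfg An [analysis_config()].
#' @param attempts Attempt log from [find_f_location()] (for the result).
#' @param selected_lag_ms Selected autocorrelation lag (for the result).
#' @param manual_cuts Optional `c(left, right)` post-trim ms.
#' @return List with `corridor` (an `fwave_corridor` result object) and
#'   `traces` (the cut [trace_set()]).
#' @export
extract_corridor <- function(traces, s, fmax_loc, cfg = analysis_config(),
                             attempts = NULL, selected_lag_ms = NA_real_,
                             manual_cuts = NULL) {
  stopifnot(inherits(traces, "trace_set"), inherits(s, "sum_signal"))
  fs <- traces$sampling_rate
  n <- n_samples(traces)
  dur <- 1000 * n / fs
  degenerate <- FALSE
  if (!is.null(manual_cuts)) {
    if (length(manual_cuts) != 2 || manual_cuts[1] < 0 ||
        manual_cuts[2] <= manual_cuts[1] || manual_cuts[2] > dur)
      stop("manual cuts must satisfy 0 <= L < R <= duration", call. = FALSE)
    left <- manual_cuts[1]; right <- manual_cuts[2]
    if (is.null(fmax_loc)) {
      idx <- window_indices(left, right, 0, fs, n)
      fmax_loc <- index_to_ms(idx[which.max(s$values[idx])], 0, fs)
    }
    mode <- "manual"
  } else {
    left <- fmax_loc - cfg$cut_back_ms
    right <- fmax_loc + cfg$cut_fwd_ms
    if (left < 0 || right > dur) {
      warning("cutting window clipped at trace boundary")
      left <- max(left, 0); right <- min(right, dur)
    }
    sum_scale <- cfg$slope_scale_uv_per_ms_45deg * s$n_traces_summed
    # trim steep 0.25 ms pieces off the left edge (M-response tail)
    repeat {
      if (left + cfg$trim_piece_ms >= fmax_loc - 0.5) {
        left <- fmax_loc - 0.5
        degenerate <- TRUE
        warning("left trimming consumed the pre-peak region; degenerate corridor")
        break
      }
      piece <- window_indices(left, left + cfg$trim_piece_ms, 0, fs, n)
      if (length(piece) < 2) break
      if (slope_angle(s$values[piece], fs, sum_scale) > cfg$slope_limit_deg)
        left <- left + cfg$trim_piece_ms
      else break
    }
    mode <- "auto"
  }
  idx <- window_indices(left, right, 0, fs, n)
  cut <- trace_set(traces$samples[, idx, drop = FALSE], fs,
                   t0_offset = traces$t0_offset + index_to_ms(idx[1], 0, fs),
                   meta = traces$meta)
  corridor <- structure(list(
    fmax_loc_ms = fmax_loc,
    fmax_loc_raw_ms = fmax_loc + cfg$artifact_trim_ms,
    left_cut_ms = index_to_ms(idx[1], 0, fs),
    right_cut_ms = index_to_ms(idx[length(idx)] + 1L, 0, fs),
    left_cut_raw_ms = index_to_ms(idx[1], 0, fs) + cfg$artifact_trim_ms,
    right_cut_raw_ms = index_to_ms(idx[length(idx)] + 1L, 0, fs) +
      cfg$artifact_trim_ms,
    duration_ms = 1000 * length(idx) / fs,
    selected_ac_peak_lag_ms = selected_lag_ms,
    attempts = attempts,
    degenerate = degenerate,
    mode = mode), class = "fwave_corridor")
  list(corridor = corridor, traces = cut)
}

#' @export
print.fwave_corridor <- function(x, ...) {
  cat(sprintf("F-wave corridor (%s): [%.2f, %.2f) ms post-trim (raw [%.2f, %.2f)), Fmax at %.2f ms (raw %.2f), duration %.2f ms\n",
              x$mode, x$left_cut_ms, x$right_cut_ms, x$left_cut_raw_ms,
              x$right_cut_raw_ms, x$fmax_loc_ms, x$fmax_loc_raw_ms,
              x$duration_ms))
  if (!is.null(x$attempts)) {
    cat("  autocorrelation attempts:\n")
    for (i in seq_len(nrow(x$attempts)))
      cat(sprintf("    lag %.2f ms: %s\n", x$attempts$ac_peak_lag_ms[i],
                  x$attempts$rejection_reason[i]))
  }
  invisible(x)
}
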