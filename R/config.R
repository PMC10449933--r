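#' Analysis configuration
#'
#' Collects every tunable constant of the F-wave extraction and analysis
#' pipeline with its default value. Durations are in milliseconds,
#' amplitudes in microvolt (uV), ratios dimensionless in (0, 1].
#'
#' @param artifact_trim_ms Stimulus-artifact prefix discarded from every
#'   trace (default 2 ms). All downstream locations are reported in
#'   post-trim time; add `artifact_trim_ms` to recover raw-recording time.
#' @param m_search_ms The M-response (CMAP) global maximum is searched in
#'   the first `m_search_ms` of the sum signal (default 7.5 ms).
#' @param min_ac_peak_spacing_ms Autocorrelation peaks closer than this to
#'   lag zero are treated as M-response fluctuation artifacts and skipped
#'   (default 12 ms).
#' @param window_back_ms,window_fwd_ms Search window around the approximate
#'   F-maximum location: back 7.5 ms, forward 15 ms (22.5 ms total).
#' @param floor_sum_uv Amplitude floor on the sum signal at the refined
#'   F-maximum location; locations below it (near the M-response global
#'   minimum) are rejected. Default -100000 uV (-100 mV on the sum of all
#'   traces); scales with the number of traces summed.
#' @param min_f_latency_ms Earliest admissible F-maximum location in
#'   post-trim time (default 16 ms, i.e. 18 ms in raw time): F-waves of the
#'   median/ulnar nerves are not elicited before 20 ms.
#' @param slope_limit_deg Slope threshold in display degrees used both for
#'   M-tail rejection and corridor left-trimming (default 16).
#' @param slope_scale_uv_per_ms_45deg Display geometry mapping: the uV/ms
#'   slope of a single trace that corresponds to a 45-degree line on the
#'   instrument screen (500 uV gain, 10 ms/division), default 50. For the
#'   sum signal the scale is multiplied by the number of traces summed.
#' @param cut_back_ms,cut_fwd_ms Corridor cutting window around the
#'   F-maximum location: 10 ms back, 20 ms forward (30 ms total).
#' @param trim_piece_ms Width of the left-edge pieces trimmed from the
#'   corridor while their slope exceeds `slope_limit_deg` (default 0.25 ms).
#' @param min_fwave_pp_uv Minimum accepted F-wave peak-to-peak amplitude;
#'   only amplitudes strictly greater than this survive (default 40 uV).
#' @param noise_window_ms A trace whose amplitude changes by less than
#'   `min_fwave_pp_uv` within this window on both sides of its peak is
#'   classified as noise (default 3 ms).
#' @param loc_tol_ms Maximum Fmax/Fmin location difference for repeater
#'   candidacy (default 0.5 ms).
#' @param amp_ratio_1,pow_ratio_1,corr_min,sim_max First-pass repeater
#'   criteria: amplitude ratio > 0.9, power ratio > 0.8, correlation > 0.9,
#'   similarity coefficient < 0.6.
#' @param amp_ratio_2,pow_ratio_2 Stricter second-pass ratios (0.95, 0.9).
#' @param ac_prominence_frac Minimum prominence of an autocorrelation peak,
#'   as a fraction of the lag-zero value, for it to be listed as a
#'   candidate (default 1e-3; the F-wave echo is small relative to the
#'   M-response energy at lag zero).
#' @param max_ac_attempts Maximum number of autocorrelation candidate peaks
#'   tried before giving up with a no-corridor error (default 10).
#' @param min_overlap_frac Minimum post-alignment overlap between two
#'   corridor traces, as a fraction of corridor length, for a pair to be
#'   comparable (default 0.5).
#' @param random_seed Seed recorded in reports for reproducibility.
#'
#' @return An object of class `fwave_config` (a named list).
#' @examples
#' cfg <- analysis_config()
#' cfg$min_fwave_pp_uv
#' @export
analysis_config <- function(artifact_trim_ms = 2,
                            m_search_ms = 7.5,
                            min_ac_peak_spacing_ms = 12,
                            window_back_ms = 7.5,
                            window_fwd_ms = 15,
                            floor_sum_uv = -100000,
                            min_f_latency_ms = 16,
                            slope_limit_deg = 16,
                            slope_scale_uv_per_ms_45deg = 50,
                            cut_back_ms = 10,
                            cut_fwd_ms = 20,
                            trim_piece_ms = 0.25,
                            min_fwave_pp_uv = 40,
                            noise_window_ms = 3,
                            loc_tol_ms = 0.5,
                            amp_ratio_1 = 0.9,
                            pow_ratio_1 = 0.8,
                            corr_min = 0.9,
                            sim_max = 0.6,
                            amp_ratio_2 = 0.95,
                            pow_ratio_2 = 0.9,
                            ac_prominence_frac = 1e-3,
                            max_ac_attempts = 10,
                            min_overlap_frac = 0.5,
                            random_seed = 1L) {
  cfg <- list(
    artifact_trim_ms = artifact_trim_ms,
    m_search_ms = m_search_ms,
    min_ac_peak_spacing_ms = min_ac_peak_spacing_ms,
    window_back_ms = window_back_ms,
    window_fwd_ms = window_fwd_ms,
    floor_sum_uv = floor_sum_uv,
    min_f_latency_ms = min_f_latency_ms,
    slope_limit_deg = slope_limit_deg,
    slope_scale_uv_per_ms_45deg = slope_scale_uv_per_ms_45deg,
    cut_back_ms = cut_back_ms,
    cut_fwd_ms = cut_fwd_ms,
    trim_piece_ms = trim_piece_ms,
    min_fwave_pp_uv = min_fwave_pp_uv,
    noise_window_ms = noise_window_ms,
    loc_tol_ms = loc_tol_ms,
    amp_ratio_1 = amp_ratio_1,
    pow_ratio_1 = pow_ratio_1,
    corr_min = corr_min,
    sim_max = sim_max,
    amp_ratio_2 = amp_ratio_2,
    pow_ratio_2 = pow_ratio_2,
    ac_prominence_frac = ac_prominence_frac,
    max_ac_attempts = max_ac_attempts,
    min_overlap_frac = min_overlap_frac,
    random_seed = as.integer(random_seed)
  )
  validate_config(cfg)
  structure(cfg, class = "fwave_config")
}

validate_config <- function(cfg) {
  durations <- c("artifact_trim_ms", "m_search_ms", "min_ac_peak_spacing_ms",
                 "window_back_ms", "window_fwd_ms", "min_f_latency_ms",
                 "cut_back_ms", "cut_fwd_ms", "trim_piece_ms",
                 "noise_window_ms", "loc_tol_ms")
  for (d in durations) {
    if (!is.numeric(cfg[[d]]) || length(cfg[[d]]) != 1L || cfg[[d]] <= 0)
      stop(sprintf("config field '%s' must be a positive duration (ms)", d),
           call. = FALSE)
  }
  ratios <- c("amp_ratio_1", "pow_ratio_1", "corr_min",
              "amp_ratio_2", "pow_ratio_2", "min_overlap_frac")
  for (r in ratios) {
    if (!is.numeric(cfg[[r]]) || cfg[[r]] <= 0 || cfg[[r]] > 1)
      stop(sprintf("config field '%s' must be a ratio in (0, 1]", r),
           call. = FALSE)
  }
  if (cfg$min_fwave_pp_uv <= 0) stop("min_fwave_pp_uv must be positive",
                                     call. = FALSE)
  if (cfg$sim_max <= 0) stop("sim_max must be positive", call. = FALSE)
  if (cfg$max_ac_attempts < 1) stop("max_ac_attempts must be >= 1",
                                    call. = FALSE)
  invisible(cfg)
}

#' @export
print.fwave_config <- function(x, ...) {
  cat("F-wave analysis configuration\n")
  for (nm in names(x)) cat(sprintf("  %-28s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Merge user overrides (e.g. parsed from a JSON config file) into defaults.
#' Build a configuration from a named list of overrides
#'
#' @param overrides Named list; names must be `analysis_config()` arguments.
#' @return An `fwave_config` object.
#' @export
config_from_list <- function(overrides = list()) {
  known <- names(formals(analysis_config))
  bad <- setdiff(names(overrides), known)
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(analysis_config, overrides)
}
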