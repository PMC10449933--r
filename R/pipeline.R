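# End-to-end pipeline: denoise -> trim -> corridor -> cut -> baseline ->
# measure -> filter -> detect -> group -> features -> report.

#' Run the full F-wave analysis pipeline
#'
#' Executes the complete analysis on a raw [trace_set()]: wavelet
#' denoising, stimulus-artifact trimming, corridor location (automatic
#' sum-signal/autocorrelation search, or manual cut locations), corridor
#' cutting, per-trace linear baseline correction, F-wave measurement and
#' filtering, two-pass repeater detection, grouping, and feature / MUNE
#' computation.
#'
#' @param traces A raw [trace_set()] (`t0_offset = 0`).
#' @param cfg An [analysis_config()].
#' @param manual_cuts Optional `c(left, right)` cut locations in post-trim
#'   ms; skips the automatic corridor search.
#' @param denoise_traces Apply wavelet denoising first (default `TRUE`).
#' @return Object of class `fwave_result`: list with `corridor`,
#'   `measurements` (per-trace table), `pairs`, `groups`, `m_response`,
#'   `features`, `config`, `manifest`.
#' @examples
#' \donttest{
#' sim <- synthesize(sim_config(n_traces = 60, seed = 1))
#' res <- run_pipeline(sim$traces)
#' res$features
#' }
#' @export
run_pipeline <- function(traces, cfg = analysis_config(),
                         manual_cuts = NULL, denoise_traces = TRUE) {
  stopifnot(inherits(traces, "trace_set"))
  t_start <- proc.time()[["elapsed"]]
  input_hash <- digest_matrix(traces$samples)

  work <- if (denoise_traces) denoise(traces) else traces
  work <- trim_stimulus_artifact(work, cfg$artifact_trim_ms)
  s <- sum_traces(work)

  if (is.null(manual_cuts)) {
    acf <- autocorrelation(s)
    peaks <- find_ac_peaks(acf, s$sampling_rate, cfg$ac_prominence_frac)
    loc <- find_f_location(s, peaks, cfg)
    ext <- extract_corridor(work, s, loc$fmax_loc_ms, cfg,
                            attempts = loc$attempts,
                            selected_lag_ms = loc$selected_ac_peak_lag_ms)
  } else {
    ext <- extract_corridor(work, s, NULL, cfg, manual_cuts = manual_cuts)
  }
  corridor <- ext$corridor
  cut <- correct_baseline_traces(ext$traces)

  meas <- measure_fwaves(cut, t_offset_ms = corridor$left_cut_ms)
  meas <- apply_filters(meas, cut, cfg, t_offset_ms = corridor$left_cut_ms)
  pairs <- detect_repeaters(meas, cut, cfg)
  groups <- group_repeaters(pairs, meas, cut)
  m_meas <- measure_m_response(work, cfg)
  features <- compute_features(groups, meas, m_meas, n_traces(traces))

  elapsed <- proc.time()[["elapsed"]] - t_start
  message(sprintf("pipeline completed in %.1f s (%d traces)", elapsed,
                  n_traces(traces)))
  manifest <- list(package_version = as.character(utils::packageVersion("fwavekit")),
                   input_hash = input_hash,
                   n_traces = n_traces(traces),
                   n_samples = n_samples(traces),
                   sampling_rate = traces$sampling_rate,
                   mode = corridor$mode,
                   denoised = denoise_traces,
                   seed = cfg$random_seed)
  structure(list(corridor = corridor, measurements = meas, pairs = pairs,
                 groups = groups, m_response = m_meas, features = features,
                 config = cfg, manifest = manifest),
            class = "fwave_result")
}

# Deterministic content hash of the input matrix (no external digest
# package): sums of byte-chunked products with fixed primes.
digest_matrix <- function(m) {
  v <- as.numeric(m)
  s1 <- sum(v * rep_len(c(1, 3, 7, 13), length(v)))
  sprintf("%dx%d-%.10e-%.10e", nrow(m), ncol(m), sum(v), s1)
}

#' @export
print.fwave_result <- function(x, ...) {
  print(x$corridor)
  print(x$features)
  invisible(x)
}

#' Write the analysis report
#'
#' Writes a JSON document containing every feature, the corridor (cut
#' locations in post-trim and raw time), the corridor-search attempt log,
#' the repeater groups and pairs, and a configuration snapshot, plus a
#' companion CSV with the per-trace F-wave table. The JSON contains no
#' timestamps: identical input, configuration and seed give byte-identical
#' reports.
#'
#' @param result An `fwave_result` from [run_pipeline()].
#' @param path Output JSON path; the per-trace table goes to
#'   `<path-sans-ext>_traces.csv`.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path) {
  stopifnot(inherits(result, "fwave_result"))
  f <- result$features
  groups <- result$groups
  doc <- list(
    format_version = "1.0",
    manifest = result$manifest,
    corridor = list(
      mode = result$corridor$mode,
      fmax_loc_ms = result$corridor$fmax_loc_ms,
      fmax_loc_raw_ms = result$corridor$fmax_loc_raw_ms,
      left_cut_ms = result$corridor$left_cut_ms,
      right_cut_ms = result$corridor$right_cut_ms,
      left_cut_raw_ms = result$corridor$left_cut_raw_ms,
      right_cut_raw_ms = result$corridor$right_cut_raw_ms,
      duration_ms = result$corridor$duration_ms,
      selected_ac_peak_lag_ms = result$corridor$selected_ac_peak_lag_ms,
      degenerate = result$corridor$degenerate,
      attempts = result$corridor$attempts),
    features = list(
      n_repeater_fwaves = f$n_repeater_fwaves,
      n_repeater_neurons = f$n_repeater_neurons,
      mean_smup_amp = f$mean_smup_amp,
      persistence = f$persistence,
      n_accepted_fwaves = f$n_accepted_fwaves,
      n_traces_total = f$n_traces_total,
      m_pp_amp = f$m_pp_amp,
      m_pos_area = f$m_pos_area,
      m_total_area = f$m_total_area,
      mune1 = f$mune1, mune2 = f$mune2, mune3 = f$mune3,
      mune_reason = f$mune_reason),
    groups = if (nrow(groups)) lapply(seq_len(nrow(groups)), function(k)
      list(group_id = groups$group_id[k],
           members = groups$members[[k]],
           size = groups$size[k],
           smup_pp_amp = groups$smup_pp_amp[k],
           smup_pos_area = groups$smup_pos_area[k],
           smup_total_area = groups$smup_total_area[k])) else list(),
    pairs = result$pairs,
    config = unclass(result$config))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  csv_path <- sub("\\.json$", "", path)
  csv_path <- paste0(csv_path, "_traces.csv")
  tab <- result$measurements
  tab$group_id <- NA_integer_
  if (nrow(groups))
    for (k in seq_len(nrow(groups)))
      tab$group_id[tab$trace_id %in% groups$members[[k]]] <- groups$group_id[k]
  utils::write.csv(tab, csv_path, row.names = FALSE)
  invisible(path)
}

#' Read back a report written by [write_report()]
#'
#' @param path JSON report path.
#' @return Parsed report list.
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
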