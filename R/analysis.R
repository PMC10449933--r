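# F-wave measurement, filtering, two-pass repeater detection, grouping,
# feature extraction and F-MUNE.

#' Measure one baseline-corrected corridor trace
#'
#' Global maximum and minimum amplitudes with their (earliest-tie)
#' locations, peak-to-peak amplitude and power (mean squared amplitude
#' over the corridor).
#'
#' @param trace Numeric corridor trace (uV), baseline-corrected.
#' @param trace_id Integer trace identifier.
#' @param sampling_rate Sampling rate in Hz.
#' @param t_offset_ms Post-trim time of the first corridor sample (so
#'   reported locations are in post-trim recording time).
#' @return One-row data.frame: `trace_id`, `fmax_amp`, `fmax_loc`,
#'   `fmin_amp`, `fmin_loc`, `pp_amp`, `power`, `status` (`"ok"` until
#'   [apply_filters()] is run).
#' @export
measure_fwave <- function(trace, trace_id, sampling_rate, t_offset_ms = 0) {
  imax <- which.max(trace)
  imin <- which.min(trace)
  data.frame(
    trace_id = as.integer(trace_id),
    fmax_amp = trace[imax],
    fmax_loc = index_to_ms(imax, t_offset_ms, sampling_rate),
    fmin_amp = trace[imin],
    fmin_loc = index_to_ms(imin, t_offset_ms, sampling_rate),
    pp_amp = trace[imax] - trace[imin],
    power = mean(trace^2),
    status = "ok",
    stringsAsFactors = FALSE)
}

# Measure every trace of a corridor TraceSet; t_offset_ms is the
# post-trim time of the corridor's first sample (left cut location).
measure_fwaves <- function(traces, t_offset_ms = 0) {
  stopifnot(inherits(traces, "trace_set"))
  do.call(rbind, lapply(seq_len(n_traces(traces)), function(i)
    measure_fwave(traces$samples[i, ], i, traces$sampling_rate,
                  t_offset_ms)))
}

#' Classify traces as ok / low-amplitude / noise
#'
#' Two acceptance rules are applied to each measured corridor trace:
#' \itemize{
#'   \item `low_amplitude` — the peak-to-peak amplitude is not strictly
#'     greater than `min_fwave_pp_uv` (40 uV);
#'   \item `noise` — the amplitude changes by less than `min_fwave_pp_uv`
#'     within `noise_window_ms` (3 ms) of the peak location on BOTH sides
#'     (windows clipped at the corridor edges): a genuine F-wave falls by
#'     more than 40 uV within 3 ms of its peak.
#' }
#' Traces passing both are `ok`.
#'
#' @param measurements Data.frame from [measure_fwaves()].
#' @param traces The corridor [trace_set()] the measurements came from.
#' @param cfg An [analysis_config()].
#' @param t_offset_ms Post-trim time of the first corridor sample.
#' @return `measurements` with the `status` column filled in.
#' @export
apply_filters <- function(measurements, traces, cfg = analysis_config(),
                          t_offset_ms = 0) {
  fs <- traces$sampling_rate
  n <- n_samples(traces)
  for (k in seq_len(nrow(measurements))) {
    m <- measurements[k, ]
    if (!(m$pp_amp > cfg$min_fwave_pp_uv)) {
      measurements$status[k] <- "low_amplitude"
      next
    }
    x <- traces$samples[m$trace_id, ]
    ipk <- ms_to_index(m$fmax_loc, t_offset_ms, fs)
    lw <- window_indices(m$fmax_loc - cfg$noise_window_ms, m$fmax_loc,
                         t_offset_ms, fs, n)
    rw <- window_indices(m$fmax_loc, m$fmax_loc + cfg$noise_window_ms +
                           1000 / fs, t_offset_ms, fs, n)
    drop_l <- if (length(lw)) max(abs(x[ipk] - x[lw])) else 0
    drop_r <- if (length(rw)) max(abs(x[ipk] - x[rw])) else 0
    if (drop_l < cfg$min_fwave_pp_uv && drop_r < cfg$min_fwave_pp_uv)
      measurements$status[k] <- "noise"
  }
  measurements
}

#' Similarity descriptors of one trace pair
#'
#' Location differences are taken on the corridor-relative peak locations
#' before alignment. The traces are then shifted so that the chosen peak
#' (`fmax` in pass one, `fmin` in pass two) coincides; Pearson correlation
#' and the power ratio are computed on the overlapping region. The
#' amplitude ratio is `min(pp)/max(pp)`, the power ratio
#' `min(power)/max(power)`, and the similarity coefficient
#' `(1 - amp_ratio) + (1 - pow_ratio)` (smaller = more similar).
#'
#' @param trace_a,trace_b Baseline-corrected corridor traces (uV).
#' @param meas_a,meas_b Their [measure_fwave()] rows.
#' @param sampling_rate Sampling rate in Hz.
#' @param align_by `"fmax"` or `"fmin"`.
#' @param min_overlap_frac Minimum overlap (fraction of corridor length)
#'   for the pair to be comparable.
#' @return One-row data.frame (`dmax_ms`, `dmin_ms`, `amp_ratio`,
#'   `pow_ratio`, `corr`, `sim_coeff`, `valid`).
#' @export
pair_similarity <- function(trace_a, trace_b, meas_a, meas_b, sampling_rate,
                            align_by = c("fmax", "fmin"),
                            min_overlap_frac = 0.5) {
  align_by <- match.arg(align_by)
  n <- length(trace_a)
  dmax <- abs(meas_a$fmax_loc - meas_b$fmax_loc)
  dmin <- abs(meas_a$fmin_loc - meas_b$fmin_loc)
  loc_a <- if (align_by == "fmax") meas_a$fmax_loc else meas_a$fmin_loc
  loc_b <- if (align_by == "fmax") meas_b$fmax_loc else meas_b$fmin_loc
  shift <- as.integer(round((loc_a - loc_b) * sampling_rate / 1000))
  # indices of the overlap after shifting b by `shift` samples
  ia <- max(1L, 1L + shift):min(n, n + shift)
  ib <- ia - shift
  valid <- length(ia) >= min_overlap_frac * n
  if (!valid || stats::sd(trace_a[ia]) == 0 || stats::sd(trace_b[ib]) == 0)
    corr <- NA_real_
  else corr <- stats::cor(trace_a[ia], trace_b[ib])
  pow_a <- mean(trace_a[ia]^2)
  pow_b <- mean(trace_b[ib]^2)
  amp_ratio <- min(meas_a$pp_amp, meas_b$pp_amp) /
    max(meas_a$pp_amp, meas_b$pp_amp)
  pow_ratio <- if (max(pow_a, pow_b) > 0)
    min(pow_a, pow_b) / max(pow_a, pow_b) else NA_real_
  data.frame(dmax_ms = dmax, dmin_ms = dmin, amp_ratio = amp_ratio,
             pow_ratio = pow_ratio, corr = corr,
             sim_coeff = (1 - amp_ratio) + (1 - pow_ratio),
             valid = valid)
}

#' Two-pass repeater F-wave detection
#'
#' Pass one compares every pair of `ok` traces aligned by their maximum
#' amplitude locations; a pair is confirmed when (strict comparisons,
#' default thresholds): both Fmax and Fmin location differences < 0.5 ms,
#' amplitude ratio > 0.9, power ratio > 0.8, correlation > 0.9 and
#' similarity coefficient < 0.6. Pass two re-examines the F-waves not in
#' any confirmed pass-one pair, aligned by their minimum amplitude
#' locations, with stricter ratios (Fmin difference < 0.5 ms, amplitude
#' ratio > 0.95, power ratio > 0.9, similarity coefficient < 0.6; no
#' correlation criterion). The union of confirmed pairs is returned; the
#' minimum-similarity-coefficient pair is flagged most similar.
#'
#' @param measurements Filtered measurements ([apply_filters()]).
#' @param traces The baseline-corrected corridor [trace_set()].
#' @param cfg An [analysis_config()].
#' @return Data.frame of confirmed pairs (`id_a`, `id_b`, `pass`,
#'   similarity columns, `most_similar`) with attribute `n_evaluated`
#'   (number of pairs examined in pass one).
#' @export
detect_repeaters <- function(measurements, traces, cfg = analysis_config()) {
  ok <- measurements[measurements$status == "ok", , drop = FALSE]
  fs <- traces$sampling_rate
  empty <- data.frame(id_a = integer(0), id_b = integer(0),
                      pass = integer(0), dmax_ms = numeric(0),
                      dmin_ms = numeric(0), amp_ratio = numeric(0),
                      pow_ratio = numeric(0), corr = numeric(0),
                      sim_coeff = numeric(0), most_similar = logical(0))
  if (nrow(ok) < 2) return(structure(empty, n_evaluated = 0L))
  rows <- list()
  n_eval <- 0L
  ids <- ok$trace_id
  # pass 1: aligned by Fmax
  for (i in seq_len(length(ids) - 1L)) {
    mi <- ok[i, ]
    for (j in (i + 1L):length(ids)) {
      mj <- ok[j, ]
      n_eval <- n_eval + 1L
      # cheap location gate first
      if (!(abs(mi$fmax_loc - mj$fmax_loc) < cfg$loc_tol_ms &&
            abs(mi$fmin_loc - mj$fmin_loc) < cfg$loc_tol_ms)) next
      ps <- pair_similarity(traces$samples[mi$trace_id, ],
                            traces$samples[mj$trace_id, ], mi, mj, fs,
                            align_by = "fmax",
                            min_overlap_frac = cfg$min_overlap_frac)
      if (!ps$valid || is.na(ps$corr)) next
      if (ps$amp_ratio > cfg$amp_ratio_1 && ps$pow_ratio > cfg$pow_ratio_1 &&
          ps$corr > cfg$corr_min && ps$sim_coeff < cfg$sim_max)
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(id_a = mi$trace_id, id_b = mj$trace_id,
                           pass = 1L), ps[, names(ps) != "valid"])
    }
  }
  in_pair <- unique(unlist(lapply(rows, function(r) c(r$id_a, r$id_b))))
  # pass 2: remaining F-waves, aligned by Fmin, stricter ratios, no corr
  rem <- ok[!(ok$trace_id %in% in_pair), , drop = FALSE]
  if (nrow(rem) >= 2) {
    for (i in seq_len(nrow(rem) - 1L)) {
      mi <- rem[i, ]
      for (j in (i + 1L):nrow(rem)) {
        mj <- rem[j, ]
        if (!(abs(mi$fmin_loc - mj$fmin_loc) < cfg$loc_tol_ms)) next
        ps <- pair_similarity(traces$samples[mi$trace_id, ],
                              traces$samples[mj$trace_id, ], mi, mj, fs,
                              align_by = "fmin",
                              min_overlap_frac = cfg$min_overlap_frac)
        if (!ps$valid) next
        if (ps$amp_ratio > cfg$amp_ratio_2 && ps$pow_ratio > cfg$pow_ratio_2 &&
            ps$sim_coeff < cfg$sim_max)
          rows[[length(rows) + 1L]] <-
            cbind(data.frame(id_a = mi$trace_id, id_b = mj$trace_id,
                             pass = 2L), ps[, names(ps) != "valid"])
      }
    }
  }
  if (!length(rows)) return(structure(empty, n_evaluated = n_eval))
  pairs <- do.call(rbind, rows)
  pairs$most_similar <- seq_len(nrow(pairs)) == which.min(pairs$sim_coeff)
  structure(pairs, n_evaluated = n_eval)
}

#' Merge repeater pairs into groups
#'
#' Pairs sharing a member belong to the same repeater group (connected
#' components of the pair graph). Each group's surface motor unit
#' potential (sMUP) descriptors are the member-wise means of the per-trace
#' peak-to-peak amplitude, positive-peak area and total area.
#'
#' @param pairs Confirmed pairs from [detect_repeaters()].
#' @param measurements Filtered measurements (for per-trace amplitudes).
#' @param traces The baseline-corrected corridor [trace_set()] (for areas).
#' @return Data.frame with one row per group: `group_id`, `members`
#'   (list-column of trace ids), `size`, `smup_pp_amp`, `smup_pos_area`,
#'   `smup_total_area`.
#' @export
group_repeaters <- function(pairs, measurements, traces) {
  if (nrow(pairs) == 0)
    return(data.frame(group_id = integer(0), size = integer(0),
                      smup_pp_amp = numeric(0), smup_pos_area = numeric(0),
                      smup_total_area = numeric(0)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(pairs$id_a),
               to = as.character(pairs$id_b)), directed = FALSE)
  comp <- igraph::components(g)
  dt_ms <- 1000 / traces$sampling_rate
  areas <- function(ids) {
    pos <- vapply(ids, function(i)
      sum(pmax(traces$samples[i, ], 0)) * dt_ms, numeric(1))
    tot <- vapply(ids, function(i)
      sum(abs(traces$samples[i, ])) * dt_ms, numeric(1))
    c(mean(pos), mean(tot))
  }
  out <- lapply(seq_len(comp$no), function(k) {
    ids <- sort(as.integer(names(comp$membership)[comp$membership == k]))
    pp <- measurements$pp_amp[match(ids, measurements$trace_id)]
    ar <- areas(ids)
    data.frame(group_id = k, size = length(ids), smup_pp_amp = mean(pp),
               smup_pos_area = ar[1], smup_total_area = ar[2])
  })
  res <- do.call(rbind, out)
  res$members <- lapply(seq_len(comp$no), function(k)
    sort(as.integer(names(comp$membership)[comp$membership == k])))
  res
}

#' Measure the M-response (CMAP)
#'
#' Computed on the pointwise mean trace over the M-window
#' `[0, min_f_latency_ms)` of post-trim time: peak-to-peak amplitude,
#' positive-peak area (sum of positive amplitudes times the sample
#' spacing) and total rectified area.
#'
#' @param traces The denoised, artifact-trimmed [trace_set()] (before
#'   corridor cutting).
#' @param cfg An [analysis_config()].
#' @return List with `m_pp_amp` (uV), `m_pos_area` and `m_total_area`
#'   (uV*ms).
#' @export
measure_m_response <- function(traces, cfg = analysis_config()) {
  stopifnot(inherits(traces, "trace_set"))
  fs <- traces$sampling_rate
  idx <- window_indices(0, cfg$min_f_latency_ms, 0, fs, n_samples(traces))
  if (!length(idx)) stop("M-response window is empty", call. = FALSE)
  m <- colMeans(traces$samples[, idx, drop = FALSE])
  dt_ms <- 1000 / fs
  list(m_pp_amp = max(m) - min(m),
       m_pos_area = sum(pmax(m, 0)) * dt_ms,
       m_total_area = sum(abs(m)) * dt_ms)
}

#' Recording-level F-wave features and MUNE
#'
#' Counts repeater F-waves (total group membership) and repeater neurons
#' (number of groups), averages the group sMUP amplitudes, computes
#' persistence (accepted F-waves over recorded traces) and the three
#' F-MUNE estimates: M-response size divided by the mean sMUP size, using
#' peak-to-peak amplitude (MUNE1), positive peak area (MUNE2) and total
#' area (MUNE3). With no repeater groups the MUNE values are `NA` with a
#' reason string.
#'
#' @param groups [group_repeaters()] result.
#' @param measurements Filtered measurements.
#' @param m_meas [measure_m_response()] result.
#' @param n_traces_total Number of recorded traces.
#' @return Object of class `fwave_features` (a list).
#' @export
compute_features <- function(groups, measurements, m_meas, n_traces_total) {
  n_ok <- sum(measurements$status == "ok")
  if (nrow(groups) == 0) {
    mune1 <- mune2 <- mune3 <- NA_real_
    reason <- "no repeater groups detected; sMUP size unavailable"
    mean_smup <- NA_real_
  } else if (mean(groups$smup_pp_amp) <= 0) {
    mune1 <- mune2 <- mune3 <- NA_real_
    reason <- "zero mean sMUP amplitude"
    mean_smup <- mean(groups$smup_pp_amp)
  } else {
    mean_smup <- mean(groups$smup_pp_amp)
    mune1 <- m_meas$m_pp_amp / mean_smup
    mune2 <- m_meas$m_pos_area / mean(groups$smup_pos_area)
    mune3 <- m_meas$m_total_area / mean(groups$smup_total_area)
    reason <- NULL
  }
  structure(list(
    n_repeater_fwaves = if (nrow(groups)) sum(groups$size) else 0L,
    n_repeater_neurons = nrow(groups),
    mean_smup_amp = mean_smup,
    persistence = n_ok / n_traces_total,
    n_accepted_fwaves = n_ok,
    n_traces_total = n_traces_total,
    m_pp_amp = m_meas$m_pp_amp,
    m_pos_area = m_meas$m_pos_area,
    m_total_area = m_meas$m_total_area,
    mune1 = mune1, mune2 = mune2, mune3 = mune3,
    mune_reason = reason), class = "fwave_features")
}

#' @export
print.fwave_features <- function(x, ...) {
  cat("F-wave features\n")
  cat(sprintf("  repeater F-waves: %d in %d group(s)\n",
              x$n_repeater_fwaves, x$n_repeater_neurons))
  cat(sprintf("  persistence: %.3f (%d / %d traces)\n", x$persistence,
              x$n_accepted_fwaves, x$n_traces_total))
  cat(sprintf("  mean sMUP amplitude: %s uV\n", format(x$mean_smup_amp)))
  cat(sprintf("  M-response: pp %.1f uV, pos area %.1f, total area %.1f uV*ms\n",
              x$m_pp_amp, x$m_pos_area, x$m_total_area))
  if (is.null(x$mune_reason))
    cat(sprintf("  MUNE1 %.2f  MUNE2 %.2f  MUNE3 %.2f\n",
                x$mune1, x$mune2, x$mune3))
  else cat("  MUNE: not available (", x$mune_reason, ")\n", sep = "")
  invisible(x)
}
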