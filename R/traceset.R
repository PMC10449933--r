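#' Construct a TraceSet
#'
#' A TraceSet holds a block of consecutive EMG traces from one recording
#' session as an `n_traces x n_samples` numeric matrix in microvolt (uV),
#' together with the sampling rate and the amount of time already removed
#' from the start of each trace. The time of (1-based) sample `i` is
#' `t0_offset + 1000 * (i - 1) / sampling_rate` ms; all windows in the
#' package are half-open `[start, stop)`.
#'
#' @param samples Numeric matrix, one trace per row, amplitudes in uV.
#' @param sampling_rate Sampling rate in Hz (e.g. 50000).
#' @param t0_offset Milliseconds already removed from the start of each
#'   trace (0 for raw input; 2 after stimulus-artifact trimming).
#' @param meta Free-form named list of recording metadata (muscle, nerve,
#'   subject label, ...).
#' @return An object of class `trace_set`.
#' @examples
#' ts <- trace_set(matrix(0, 3, 500), sampling_rate = 50000)
#' n_traces(ts); n_samples(ts)
#' @export
trace_set <- function(samples, sampling_rate, t0_offset = 0, meta = list()) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0)
    stop("sampling_rate must be a single positive number (Hz)", call. = FALSE)
  if (nrow(samples) < 1L) stop("need at least one trace", call. = FALSE)
  if (ncol(samples) < 2L) stop("need at least two samples per trace",
                               call. = FALSE)
  if (anyNA(samples)) stop("samples contain NA", call. = FALSE)
  structure(list(samples = samples,
                 sampling_rate = as.numeric(sampling_rate),
                 t0_offset = as.numeric(t0_offset),
                 meta = meta),
            class = "trace_set")
}

#' @rdname trace_set
#' @param x A `trace_set`.
#' @export
n_traces <- function(x) nrow(x$samples)

#' @rdname trace_set
#' @export
n_samples <- function(x) ncol(x$samples)

#' Trace duration in ms (exclusive end of the half-open sample grid)
#' @param x A `trace_set`.
#' @export
duration_ms <- function(x) 1000 * n_samples(x) / x$sampling_rate

# Time axis (ms) of a trace set, sample-exact.
time_axis <- function(x) {
  x$t0_offset + 1000 * (seq_len(n_samples(x)) - 1) / x$sampling_rate
}

# Convert an absolute time (ms, same clock as t0_offset) to the nearest
# 1-based sample index, unclipped.
ms_to_index <- function(t_ms, t0_offset, sampling_rate) {
  as.integer(round((t_ms - t0_offset) * sampling_rate / 1000)) + 1L
}

# 1-based index of a half-open window [a_ms, b_ms); empty -> integer(0).
window_indices <- function(a_ms, b_ms, t0_offset, sampling_rate, n) {
  i0 <- ms_to_index(a_ms, t0_offset, sampling_rate)
  i1 <- ms_to_index(b_ms, t0_offset, sampling_rate) - 1L
  i0 <- max(i0, 1L); i1 <- min(i1, n)
  if (i1 < i0) return(integer(0))
  i0:i1
}

index_to_ms <- function(i, t0_offset, sampling_rate) {
  t0_offset + 1000 * (i - 1) / sampling_rate
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("TraceSet: %d traces x %d samples @ %g kHz, t0 offset %g ms (%.5g ms span)\n",
              n_traces(x), n_samples(x), x$sampling_rate / 1000,
              x$t0_offset, duration_ms(x)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read a trace matrix with its JSON sidecar header
#'
#' The interchange format is a plain CSV/TSV numeric matrix plus a JSON
#' sidecar (`<path>.json` by default) declaring `sampling_rate` (Hz),
#' `orientation` (`"rows"` if one trace per row, `"columns"` otherwise),
#' `units` (`"uV"` or `"mV"`; mV input is scaled to uV) and
#' `format_version`. The returned TraceSet has `t0_offset = 0`.
#'
#' @param path Path to the CSV/TSV matrix file.
#' @param format Either `"csv"` or `"tsv"`.
#' @param sidecar Path to the JSON header; defaults to `<path>.json`.
#' @return A [trace_set()].
#' @export
read_traceset <- function(path, format = c("csv", "tsv"),
                          sidecar = paste0(path, ".json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (!file.exists(sidecar))
    stop("metadata error: missing JSON sidecar ", sidecar, call. = FALSE)
  hdr <- jsonlite::fromJSON(sidecar)
  if (is.null(hdr$sampling_rate))
    stop("metadata error: sidecar lacks 'sampling_rate'", call. = FALSE)
  sep <- if (format == "csv") "," else "\t"
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  cells <- strsplit(lines, sep, fixed = TRUE)
  lens <- lengths(cells)
  if (length(unique(lens)) != 1L)
    stop(sprintf("format error: ragged rows (row lengths %s)",
                 paste(unique(lens), collapse = ", ")), call. = FALSE)
  mat <- matrix(NA_real_, length(cells), lens[1])
  for (i in seq_along(cells)) {
    v <- suppressWarnings(as.numeric(cells[[i]]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      stop(sprintf("parse error: non-numeric cell at row %d, column %d ('%s')",
                   i, j, cells[[i]][j]), call. = FALSE)
    }
    mat[i, ] <- v
  }
  orientation <- if (is.null(hdr$orientation)) "rows" else hdr$orientation
  if (identical(orientation, "columns")) mat <- t(mat)
  units <- if (is.null(hdr$units)) "uV" else hdr$units
  if (identical(units, "mV")) mat <- mat * 1000
  else if (!identical(units, "uV"))
    stop("metadata error: units must be 'uV' or 'mV'", call. = FALSE)
  meta <- hdr$meta
  if (is.null(meta)) meta <- list()
  trace_set(mat, sampling_rate = hdr$sampling_rate, t0_offset = 0,
            meta = meta)
}

#' Write a TraceSet as CSV matrix plus JSON sidecar
#'
#' @param traces A [trace_set()].
#' @param path Output CSV path; the sidecar is written to `<path>.json`.
#' @param format `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_traceset <- function(traces, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  utils::write.table(traces$samples, path, sep = sep, row.names = FALSE,
                     col.names = FALSE)
  hdr <- list(format_version = "1.0",
              sampling_rate = traces$sampling_rate,
              orientation = "rows",
              units = "uV",
              n_traces = n_traces(traces),
              n_samples = n_samples(traces),
              t0_offset_ms = traces$t0_offset,
              meta = traces$meta)
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
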