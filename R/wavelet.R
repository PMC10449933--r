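# Daubechies-12 discrete wavelet transform and soft-threshold shrinkage.
#
# The decomposition low-pass filter coefficients are the standard db12
# (24-tap) extremal-phase values; the quadrature-mirror high-pass and the
# reconstruction filters follow from them. The transform uses symmetric
# (half-point) boundary extension with full convolution, keeping
# floor((n + L - 1)/2) coefficients per level, which makes reconstruction
# after trimming sample-exact for any signal length.

.db12_dec_lo <- c(
  -1.529071758068511e-06, 1.2776952219379767e-05, -2.4241545757030785e-05,
  -8.850410920820432e-05, 0.00038865306282093143, 6.545128212509596e-06,
  -0.0021795036186277603, 0.0022486072409952378, 0.00671149900879551,
  -0.012840825198300683, -0.01221864906974828, 0.04154627749508444,
  0.010849130255822185, -0.09643212009650708, 0.00535956967435215,
  0.18247860592757967, -0.023779257256069726, -0.3161784537527855,
  -0.04476388565377463, 0.5158864784278157, 0.6571987225793071,
  0.37735513521421266, 0.10956627282118515, 0.013112257957229518)

.db12_filters <- local({
  lo <- .db12_dec_lo
  L <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(L))   # quadrature mirror
  list(dec_lo = lo, dec_hi = hi, rec_lo = rev(lo), rec_hi = rev(hi), len = L)
})

# Full (zero-padded) convolution of every column of X with kernel h,
# FFT-based via mvfft. Returns a matrix with nrow(X) + length(h) - 1 rows.
conv_full_cols <- function(X, h) {
  n <- nrow(X); m <- length(h)
  N <- stats::nextn(n + m - 1L, 2)
  Xp <- rbind(X, matrix(0, N - n, ncol(X)))
  H <- stats::fft(c(h, rep(0, N - m)))
  Y <- Re(stats::mvfft(stats::mvfft(Xp) * H, inverse = TRUE)) / N
  Y[seq_len(n + m - 1L), , drop = FALSE]
}

# Symmetric (half-point) extension of each column by e samples both sides.
sym_ext_cols <- function(X, e) {
  n <- nrow(X)
  if (e > n) stop("extension longer than signal", call. = FALSE)
  idx <- c(rev(seq_len(e)), seq_len(n), n + 1L - seq_len(e))
  X[idx, , drop = FALSE]
}

# One analysis level: columns of X -> list(cA, cD) coefficient matrices.
dwt_step <- function(X, f = .db12_filters) {
  e <- f$len - 1L
  ext <- sym_ext_cols(X, e)
  cfA <- conv_full_cols(ext, f$dec_lo)
  cfD <- conv_full_cols(ext, f$dec_hi)
  keep <- f$len:(nrow(ext))              # filter fully inside the extension
  down <- keep[seq(2, length(keep), by = 2)]
  list(cA = cfA[down, , drop = FALSE], cD = cfD[down, , drop = FALSE])
}

# One synthesis level; n_out is the parent-level coefficient length.
idwt_step <- function(cA, cD, n_out, f = .db12_filters) {
  up <- function(M) {
    U <- matrix(0, 2L * nrow(M), ncol(M))
    U[seq(1, nrow(U), by = 2), ] <- M
    U
  }
  Y <- conv_full_cols(up(cA), f$rec_lo) + conv_full_cols(up(cD), f$rec_hi)
  Y <- Y[(f$len - 1L):(nrow(Y) - f$len + 1L), , drop = FALSE]
  Y[seq_len(min(nrow(Y), n_out)), , drop = FALSE]
}

# Multi-level analysis of the columns of X. Returns approximation matrix,
# detail matrices (level 1 = finest) and per-level parent lengths.
wavedec_cols <- function(X, level) {
  details <- vector("list", level)
  lens <- integer(level)
  A <- X
  for (l in seq_len(level)) {
    lens[l] <- nrow(A)
    s <- dwt_step(A)
    details[[l]] <- s$cD
    A <- s$cA
  }
  list(cA = A, details = details, lens = lens)
}

waverec_cols <- function(dec) {
  A <- dec$cA
  for (l in rev(seq_along(dec$details)))
    A <- idwt_step(A, dec$details[[l]], dec$lens[l])
  A
}

# Deepest decomposition level for which every coefficient vector is at
# least as long as the filter (so symmetric extension stays valid).
max_dwt_level <- function(n, flen = .db12_filters$len) {
  lvl <- 0L
  while (n >= flen) {
    n <- (n + flen - 1L) %/% 2L
    lvl <- lvl + 1L
  }
  lvl
}

#' Wavelet shrinkage denoising of EMG traces
#'
#' Per-trace Daubechies-12 wavelet shrinkage: each trace is decomposed to
#' `level` scales (symmetric boundary extension), the detail coefficients
#' are soft-thresholded with the universal threshold
#' `sigma * sqrt(2 log n)` where `sigma` is estimated from the median
#' absolute deviation of the finest-detail coefficients, and the trace is
#' reconstructed. Shape, units and sampling metadata are unchanged; the
#' procedure is deterministic.
#'
#' Traces too short for even one decomposition level are passed through
#' with a warning.
#'
#' @param traces A [trace_set()].
#' @param level Decomposition depth (default 6; reduced automatically when
#'   the trace is too short).
#' @return A denoised [trace_set()].
#' @examples
#' ts <- trace_set(matrix(rnorm(2 * 1000, sd = 10), 2), 50000)
#' dn <- denoise(ts)
#' sd(dn$samples) < sd(ts$samples)
#' @export
denoise <- function(traces, level = 6L) {
  stopifnot(inherits(traces, "trace_set"))
  n <- n_samples(traces)
  lvl <- min(as.integer(level), max_dwt_level(n))
  if (lvl < 1L) {
    warning("trace too short for one wavelet level; returning input unchanged")
    return(traces)
  }
  X <- t(traces$samples)                      # columns = traces
  dec <- wavedec_cols(X, lvl)
  fine <- dec$details[[1]]
  sigma <- apply(fine, 2, function(d) stats::mad(d, center = 0))
  thr <- sigma * sqrt(2 * log(n))
  soft <- function(M, t) {
    Tm <- matrix(t, nrow(M), ncol(M), byrow = TRUE)
    sign(M) * pmax(abs(M) - Tm, 0)
  }
  dec$details <- lapply(dec$details, soft, t = thr)
  Y <- waverec_cols(dec)
  out <- traces
  out$samples <- t(Y)
  out
}

#' Discard the stimulus-artifact prefix of every trace
#'
#' Stimulus artifacts occupy the very beginning of each trace; the first
#' `trim_ms` (default 2 ms) are dropped and `t0_offset` is increased
#' accordingly, so that all subsequent locations are in post-trim time.
#' The operation is a pure slice: remaining samples are bit-identical.
#'
#' @param traces A [trace_set()].
#' @param trim_ms Prefix length to discard, in ms.
#' @return A trimmed [trace_set()].
#' @export
trim_stimulus_artifact <- function(traces, trim_ms = 2) {
  stopifnot(inherits(traces, "trace_set"))
  if (trim_ms < 0) stop("trim_ms must be non-negative", call. = FALSE)
  if (trim_ms == 0) return(traces)
  if (trim_ms >= duration_ms(traces))
    stop("trim_ms must be shorter than the trace duration", call. = FALSE)
  k <- as.integer(round(trim_ms * traces$sampling_rate / 1000))
  out <- traces
  if (k > 0) out$samples <- traces$samples[, -seq_len(k), drop = FALSE]
  out$t0_offset <- traces$t0_offset + trim_ms
  out
}
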