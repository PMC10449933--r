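# Shared fixtures and independent oracles used across the test files.

# A tiny deterministic trace set: `n` traces of a noiseless biphasic wave
# with per-trace amplitude `amps` (pp, uV) peaking at `peak_ms`.
biphasic_trace <- function(n_samples, fs, peak_ms, pp, width_ms = 6) {
  t <- 1000 * (seq_len(n_samples) - 1) / fs
  u <- (t - (peak_ms - width_ms / 4)) / width_ms
  x <- sin(2 * pi * u) * exp(-((t - peak_ms) / (width_ms / 1.5))^2)
  x * pp / (max(x) - min(x))
}

# O(n^2) brute-force raw autocorrelation (lags 0..n-1); the independent
# oracle for the FFT implementation.
acf_brute <- function(s) {
  n <- length(s)
  vapply(0:(n - 1), function(k) sum(s[seq_len(n - k)] * s[(1 + k):n]),
         numeric(1))
}

# Brute-force union-find: independent oracle for graph-based grouping.
union_find_groups <- function(pairs) {
  ids <- sort(unique(c(pairs$id_a, pairs$id_b)))
  parent <- stats::setNames(ids, ids)
  find <- function(x) {
    while (parent[[as.character(x)]] != x) x <- parent[[as.character(x)]]
    x
  }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs$id_a[k]); rb <- find(pairs$id_b[k])
    if (ra != rb) parent[[as.character(ra)]] <- rb
  }
  roots <- vapply(ids, find, numeric(1))
  unname(lapply(split(ids, roots), sort))
}

# Canonical form of a grouping (list of sorted member vectors) for
# order-independent comparison.
canon_groups <- function(gl) {
  gl <- lapply(gl, sort)
  gl[order(vapply(gl, min, numeric(1)))]
}

# Mode of a location sample: kernel-density argmax with a fixed 0.2 ms
# bandwidth (locations are continuous; a binned mode is unstable).
modal_location <- function(x) {
  x <- x[is.finite(x)]
  d <- stats::density(x, bw = 0.2)
  d$x[which.max(d$y)]
}

# Membership vector (one label per trace id) from a grouping list plus
# singleton ids, for adjusted-Rand-index comparisons.
membership_of <- function(groups, all_ids) {
  lab <- stats::setNames(seq_along(all_ids), all_ids)
  nxt <- 0L
  for (g in groups) {
    nxt <- nxt + 1L
    lab[as.character(g)] <- -nxt
  }
  unname(lab[as.character(all_ids)])
}
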