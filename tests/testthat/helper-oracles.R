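# Independent oracles and fixture builders. These deliberately do not share
# code with the package: h2_ref() re-derives the binned piecewise-linear
# regression with base-R grouping, and brute_force_counts() re-runs the
# sliding-window count by explicit window extraction.

# Reference H2: equal-width bins over range(x), knots at per-bin means,
# piecewise-linear interpolation with linear extension of the outer segments.
h2_ref <- function(x, y, bins = 10L) {
  sstot <- sum((y - mean(y))^2)
  if (sstot <= 0 || diff(range(x)) <= 0) return(0)
  width <- diff(range(x)) / bins
  idx <- pmin(floor((x - min(x)) / width) + 1L, bins)
  kx <- as.numeric(tapply(x, idx, mean))
  ky <- as.numeric(tapply(y, idx, mean))
  if (length(kx) < 2L) return(0)
  seg <- pmin(pmax(findInterval(x, kx), 1L), length(kx) - 1L)
  f <- ky[seg] + (ky[seg + 1L] - ky[seg]) * (x - kx[seg]) /
    (kx[seg + 1L] - kx[seg])
  min(max(1 - sum((y - f)^2) / sstot, 0), 1)
}

# Brute-force correlated-pair count: extract every window, call the scalar
# package op pair by pair.
brute_force_counts <- function(signals, pairs, window_len, window_step,
                               s1, bins = 10L) {
  nwin <- (ncol(signals) - window_len) %/% window_step + 1L
  vapply(seq_len(nwin), function(w) {
    idx <- ((w - 1L) * window_step + 1L):((w - 1L) * window_step + window_len)
    sum(vapply(seq_len(nrow(pairs)), function(p) {
      h2_coefficient(signals[pairs[p, 1L], idx],
                     signals[pairs[p, 2L], idx], bins) > s1
    }, logical(1L)))
  }, integer(1L))
}

# A 12-channel fixture whose pair correlations vary over time: independent
# noise everywhere plus a shared band-limited component with a gain that
# ramps across the recording, so counts sweep through low and high values.
mixed_bipolar_fixture <- function(n_samples = 4400L, fs = 200, seed = 42L) {
  set.seed(seed)
  shared <- stats::filter(rnorm(n_samples), rep(1 / 40, 40), sides = 2)
  shared[is.na(shared)] <- 0
  ramp <- seq(0, 3, length.out = n_samples)
  sig <- matrix(rnorm(12L * n_samples, sd = 1), 12L, n_samples)
  gains <- seq(0.5, 1.5, length.out = 12L)
  for (k in 1:12) sig[k, ] <- sig[k, ] + gains[k] * ramp * as.numeric(shared)
  structure(list(signals = sig, sample_rate = fs,
                 position = cbind(bipolar_row = rep(1:3, 4),
                                  col = rep(1:4, each = 3)),
                 labels = paste0("Vb", 1:12)),
            class = "bipolar_set")
}

# Directly assemble a count_curve (for event-detection tests).
make_curve <- function(counts, step_s = 2, window_len_s = 4) {
  structure(list(window_start_s = (seq_along(counts) - 1) * step_s,
                 count = as.integer(counts), n_pairs = 36L,
                 window_len_s = window_len_s),
            class = "count_curve")
}

# Random sorted non-overlapping event list.
random_events <- function(n, horizon = 1000, seed = 1L) {
  set.seed(seed)
  if (n == 0L) return(event_list())
  bounds <- sort(runif(2L * n, 0, horizon))
  event_list(bounds[seq(1L, 2L * n, by = 2L)],
             bounds[seq(2L, 2L * n, by = 2L)])
}

# Small synthetic recording for fast end-to-end tests.
quick_sim <- function(duration_s = 400, n_contractions = 2L, seed = 9L, ...) {
  generate_recording(synthetic_config(
    duration_s = duration_s, n_contractions = n_contractions,
    duration_range = c(40, 60), min_gap_s = 40, seed = seed, ...))
}
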