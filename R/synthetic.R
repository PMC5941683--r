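#' Synthetic EHG generator configuration
#'
#' Describes a simulated 16-channel abdominal EHG recording session.
#' Defaults emulate a 30-minute antepartum monitoring strip: about ten
#' contractions of 40-90 s separated by at least a minute, a burst spectrum
#' concentrated at 0.2-0.8 Hz (inside the 0.1-3 Hz uterine band), strong
#' bursts at 20 dB over background on the unipolar channels, and a handful
#' of brief high-amplitude artifact transients per hour (fetal or maternal
#' movements, electrode-lead motion) that are coherent across the grid but
#' are not contractions.
#'
#' @param duration_s recording length in seconds (default 1800).
#' @param sample_rate sampling rate in Hz (default 200).
#' @param n_contractions number of contractions (default 10).
#' @param duration_range contraction duration bounds in seconds,
#'   default `c(40, 90)`.
#' @param min_gap_s minimal gap between consecutive contractions (default 60).
#' @param burst_band frequency band of the contraction burst, Hz,
#'   default `c(0.2, 0.8)`; must lie inside 0.1-3 Hz.
#' @param snr_db contraction burst-to-background power ratio averaged over
#'   unipolar channels, in dB (default 20: a clean, well-prepared skin
#'   contact recording).
#' @param gain_spread standard deviation of the per-electrode log-normal
#'   gain jitter (default 0.3).
#' @param max_delay_s maximal inter-electrode propagation delay in seconds
#'   (default 0.25); delays increase along the grid diagonal.
#' @param nonlinearity `"saturating"` (default; soft tanh compression of the
#'   shared burst, so inter-channel coupling is nonlinear as the H2
#'   statistic presumes) or `"none"` (purely linear mixing).
#' @param artifact_rate_per_hr mean number of artifact transients per hour
#'   (Poisson arrivals; default 6).
#' @param artifact_duration_range artifact duration bounds in seconds,
#'   default `c(2, 8)`.
#' @param seed RNG seed; every random draw in the generator is derived from
#'   it, so equal configs give byte-identical recordings.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(duration_s = 1800, sample_rate = 200,
                             n_contractions = 10L,
                             duration_range = c(40, 90),
                             min_gap_s = 60,
                             burst_band = c(0.2, 0.8),
                             snr_db = 20,
                             gain_spread = 0.3,
                             max_delay_s = 0.25,
                             nonlinearity = c("saturating", "none"),
                             artifact_rate_per_hr = 6,
                             artifact_duration_range = c(2, 8),
                             seed = 0L) {
  nonlinearity <- match.arg(nonlinearity)
  cfg <- list(duration_s = duration_s, sample_rate = sample_rate,
              n_contractions = as.integer(n_contractions),
              duration_range = as.numeric(duration_range),
              min_gap_s = min_gap_s, burst_band = as.numeric(burst_band),
              snr_db = snr_db, gain_spread = gain_spread,
              max_delay_s = max_delay_s, nonlinearity = nonlinearity,
              artifact_rate_per_hr = artifact_rate_per_hr,
              artifact_duration_range = as.numeric(artifact_duration_range),
              seed = as.integer(seed))
  if (cfg$duration_s <= 0 || cfg$sample_rate <= 0) {
    stop("duration_s and sample_rate must be positive")
  }
  if (cfg$n_contractions < 0L) stop("n_contractions must be >= 0")
  if (length(cfg$duration_range) != 2L ||
      cfg$duration_range[1L] <= 0 ||
      cfg$duration_range[1L] > cfg$duration_range[2L]) {
    stop("duration_range must be (min_s, max_s) with 0 < min <= max")
  }
  if (length(cfg$burst_band) != 2L ||
      cfg$burst_band[1L] < 0.1 || cfg$burst_band[2L] > 3 ||
      cfg$burst_band[1L] >= cfg$burst_band[2L]) {
    stop("burst_band must lie inside the 0.1-3 Hz analysis band")
  }
  n <- cfg$n_contractions
  need <- n * cfg$duration_range[2L] + max(n - 1L, 0L) * cfg$min_gap_s
  if (need > cfg$duration_s) {
    stop("infeasible schedule: ", n, " contractions of up to ",
         cfg$duration_range[2L], " s with ", cfg$min_gap_s,
         " s gaps need ", need, " s but duration_s = ", cfg$duration_s)
  }
  structure(cfg, class = "synthetic_config")
}

# Run expr with the RNG seeded from `seed`, restoring global RNG state.
with_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Gaussian noise with a rectangular amplitude spectrum on [f1, f2] Hz,
# unit variance. FFT-based, so exactly band-limited.
band_noise <- function(n, fs, f1, f2) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)                      # fold to two-sided frequencies
  W[f < f1 | f > f2] <- 0
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

# 1/f-like background: amplitude spectrum ~ f^(-1/2) above a 0.05 Hz knee,
# supported on 0.01-10 Hz; unit variance. Mimics baseline abdominal-surface
# EMG drift plus broadband instrumentation noise.
background_noise <- function(n, fs) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)
  shape <- ifelse(f >= 0.01 & f <= 10, 1 / sqrt(pmax(f, 0.05)), 0)
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Tukey (tapered-cosine) window: flat middle, cosine ramps over alpha/2 of
# each end. Keeps most of a contraction at full strength so detected event
# durations track the annotated ones.
tukey_window <- function(n, alpha = 0.3) {
  if (n == 1L) return(1)
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < alpha / 2
  hi <- t > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (t[hi] - 1) / alpha + 1)))
  w
}

#' Sample a contraction schedule
#'
#' Draws `n_contractions` non-overlapping intervals with durations uniform
#' in `duration_range` and all gaps (including before the first and after
#' the last contraction) of at least `min_gap_s` between events; slack is
#' spread randomly (Dirichlet-uniform) across the gaps. Deterministic given
#' `cfg$seed`.
#'
#' @param cfg a [synthetic_config()].
#' @return An [annotation_set()] labelled "contraction".
#' @export
sample_contraction_schedule <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- cfg$n_contractions
  if (n == 0L) return(annotation_set())
  with_rng(cfg$seed, {
    dur <- stats::runif(n, cfg$duration_range[1L], cfg$duration_range[2L])
    slack <- cfg$duration_s - sum(dur) - (n - 1L) * cfg$min_gap_s
    u <- stats::runif(n + 1L)
    extra <- u / sum(u) * slack
    gaps_between <- if (n > 1L) cfg$min_gap_s + extra[2:n] else numeric(0)
    starts <- cumsum(c(extra[1L], dur[-n] + gaps_between))
    annotation_set(starts, starts + dur, "contraction")
  })
}

#' Generate a synthetic 16-channel EHG recording
#'
#' Each unipolar channel is the sum of (i) independent 1/f-like background
#' noise, (ii) for every scheduled contraction, a shared band-limited burst
#' source with a tapered-cosine envelope, delayed along the grid diagonal,
#' optionally soft-saturated, and scaled by a per-electrode gain, and (iii)
#' brief high-amplitude artifact transients coherent across all channels at
#' Poisson arrival times (excluded from the returned annotations).
#'
#' Electrode gains combine a fixed vertical gradient with log-normal jitter,
#' so vertically adjacent electrodes see the burst at different amplitudes
#' and the bipolar derivation does not cancel it — as in real recordings,
#' where electrodes sit at different distances from the active myometrial
#' region. Burst amplitude is scaled so the mean unipolar burst-to-background
#' power ratio matches `snr_db`.
#'
#' @param cfg a [synthetic_config()].
#' @return `list(recording = ehg_recording, annotations = annotation_set)`;
#'   deterministic given `cfg$seed`.
#' @export
generate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  fs <- cfg$sample_rate
  ns <- as.integer(round(cfg$duration_s * fs))
  schedule <- sample_contraction_schedule(cfg)
  with_rng(cfg$seed + 1L, {
    data <- matrix(0, 16L, ns)
    for (ch in 1:16) data[ch, ] <- background_noise(ns, fs)

    # electrode gains: vertical gradient x log-normal jitter, fixed for the
    # whole recording (anatomy does not change between contractions)
    vgrad <- c(1.6, 1.0, 0.62, 0.38)
    grid_row <- rep(1:4, each = 4)               # row-major electrode order
    grid_col <- rep(1:4, times = 4)
    gains <- vgrad[grid_row] * exp(stats::rnorm(16, 0, cfg$gain_spread))
    delay_smp <- round(cfg$max_delay_s * fs *
                         (grid_row - 1 + grid_col - 1) / 6)
    max_shift <- max(delay_smp)

    nl <- switch(cfg$nonlinearity,
                 none = identity,
                 saturating = function(s) 2 * tanh(s / 2))
    target <- 10^(cfg$snr_db / 10)

    add_coherent <- function(data, i0, i1, src_band, gains_use, amp2) {
      # src spans [i0, i1] plus delay margin; returns updated data
      len <- i1 - i0 + 1L
      src <- band_noise(len + max_shift, fs, src_band[1L], src_band[2L])
      env <- tukey_window(len, 0.3)
      burst <- matrix(0, 16L, len)
      for (ch in 1:16) {
        seg <- src[(max_shift - delay_smp[ch] + 1L):
                     (max_shift - delay_smp[ch] + len)]
        burst[ch, ] <- gains_use[ch] * nl(seg) * env
      }
      p <- mean(burst^2)
      if (p > 0) burst <- burst * sqrt(amp2 / p)
      data[, i0:i1] <- data[, i0:i1] + burst
      data
    }

    for (k in seq_len(nrow(schedule))) {
      i0 <- max(1L, as.integer(floor(schedule$start_s[k] * fs)) + 1L)
      i1 <- min(ns, as.integer(ceiling(schedule$end_s[k] * fs)))
      data <- add_coherent(data, i0, i1, cfg$burst_band, gains, target)
    }

    # artifact transients: coherent, brief, loud (3x burst power), with
    # their own gain jitter per event; broadband within the analysis band
    n_art <- stats::rpois(1L, cfg$artifact_rate_per_hr * cfg$duration_s / 3600)
    if (n_art > 0L) {
      art_start <- stats::runif(n_art, 0, cfg$duration_s -
                                  cfg$artifact_duration_range[2L])
      art_dur <- stats::runif(n_art, cfg$artifact_duration_range[1L],
                              cfg$artifact_duration_range[2L])
      for (k in seq_len(n_art)) {
        i0 <- max(1L, as.integer(floor(art_start[k] * fs)) + 1L)
        i1 <- min(ns, as.integer(ceiling((art_start[k] + art_dur[k]) * fs)))
        g_art <- vgrad[grid_row] * exp(stats::rnorm(16, 0, cfg$gain_spread))
        data <- add_coherent(data, i0, i1, c(0.3, 3), g_art, 3 * target)
      }
    }

    list(recording = ehg_recording(data, fs),
         annotations = schedule)
  })
}
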