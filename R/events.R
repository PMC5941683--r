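#' Threshold the count curve into candidate events
#'
#' Maximal runs of consecutive windows whose correlated-pair count strictly
#' exceeds `s2` become events. An event starts at the first window's start
#' time and ends at the last window's start time plus the window length
#' (each supra-threshold window asserts correlated activity over its full
#' extent, so events are unions of window supports).
#'
#' @param curve a `count_curve` from [sliding_count_curve()].
#' @param s2 count cutoff (integer, 0..n_pairs); strict comparison.
#' @return An `event_list`: data.frame with `start_s`, `end_s`, sorted and
#'   non-overlapping.
#' @export
detect_events <- function(curve, s2 = 10L) {
  stopifnot(inherits(curve, "count_curve"))
  above <- curve$count > s2
  if (!length(above) || !any(above)) return(event_list())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  event_list(curve$window_start_s[starts[keep]],
             curve$window_start_s[ends[keep]] + curve$window_len_s)
}

#' Detected event list
#'
#' @param start_s,end_s numeric vectors of event bounds in seconds; each
#'   `start_s < end_s`; construction sorts by start.
#' @return data.frame of class `event_list` with columns `start_s`, `end_s`.
#' @export
event_list <- function(start_s = numeric(), end_s = numeric()) {
  start_s <- as.numeric(start_s); end_s <- as.numeric(end_s)
  stopifnot(length(start_s) == length(end_s), all(start_s < end_s))
  o <- order(start_s, end_s)
  structure(data.frame(start_s = start_s[o], end_s = end_s[o]),
            class = c("event_list", "data.frame"))
}

#' Fuse events separated by short gaps
#'
#' Consecutive events whose gap (`next start - previous end`) is strictly
#' less than `d1` seconds are merged into one event spanning both, applied
#' left-to-right transitively. Fusion counters oversegmentation, where a
#' single contraction is detected as several shorter events.
#'
#' @param events an `event_list` (sorted).
#' @param d1 fusion gap in seconds (non-negative).
#' @return A fused, sorted, non-overlapping `event_list`. Idempotent:
#'   `fuse_events(fuse_events(e, d1), d1)` equals `fuse_events(e, d1)`.
#' @export
fuse_events <- function(events, d1) {
  if (!is.numeric(d1) || length(d1) != 1L || d1 < 0) {
    stop("d1 must be a non-negative number of seconds")
  }
  n <- nrow(events)
  if (n <= 1L) return(events)
  starts <- events$start_s; ends <- events$end_s
  out_s <- starts[1L]; out_e <- ends[1L]
  for (i in 2:n) {
    j <- length(out_s)
    if (starts[i] - out_e[j] < d1) {
      out_e[j] <- max(out_e[j], ends[i])
    } else {
      out_s <- c(out_s, starts[i]); out_e <- c(out_e, ends[i])
    }
  }
  event_list(out_s, out_e)
}

#' Eliminate brief events
#'
#' Removes events whose duration does not exceed `d2` seconds (survival
#' requires `end - start > d2`, strictly). Brief supra-threshold events are
#' typically fetal/maternal movement or instrumental artifacts rather than
#' contractions; elimination is the main false-alarm reducer.
#'
#' @param events an `event_list`.
#' @param d2 minimal duration in seconds (non-negative).
#' @return The surviving `event_list`, order preserved.
#' @export
eliminate_events <- function(events, d2) {
  if (!is.numeric(d2) || length(d2) != 1L || d2 < 0) {
    stop("d2 must be a non-negative number of seconds")
  }
  keep <- (events$end_s - events$start_s) > d2
  structure(events[keep, , drop = FALSE],
            class = c("event_list", "data.frame"))
}

#' Full contraction-detection pipeline
#'
#' Runs the complete chain on a 16-channel recording: bipolar derivation,
#' band-pass filtering, sliding-window H2 pair counting, count-curve
#' thresholding, fusion of nearby events, and elimination of brief events —
#' in that fixed order. Deterministic for fixed inputs and configuration.
#'
#' @param rec a 16-channel [ehg_recording()].
#' @param cfg a [pipeline_config()].
#' @param grid an [electrode_grid()].
#' @param fuse,eliminate logical switches for the two post-processing steps
#'   (both `TRUE` by default); disabling them exposes the raw detections.
#' @param return_curve if `TRUE`, return `list(events, curve)` instead of
#'   just the events.
#' @return An `event_list` (or a list with the `count_curve` as well).
#' @export
detect_pipeline <- function(rec, cfg = pipeline_config(),
                            grid = electrode_grid(),
                            fuse = TRUE, eliminate = TRUE,
                            return_curve = FALSE) {
  stopifnot(inherits(rec, "ehg_recording"))
  bip <- make_bipolar(rec, grid)
  bip <- bandpass_filter(bip, cfg$band_low, cfg$band_high)
  curve <- sliding_count_curve(bip, cfg$window_len, cfg$window_step,
                               s1 = cfg$s1, bins = cfg$h2_bins)
  ev <- detect_events(curve, cfg$s2)
  if (fuse) ev <- fuse_events(ev, cfg$d1)
  if (eliminate) ev <- eliminate_events(ev, cfg$d2)
  if (return_curve) list(events = ev, curve = curve) else ev
}

#' Write an event list in the annotation TSV dialect
#'
#' @param events an `event_list`.
#' @param path output TSV.
#' @param label label to attach to each event (default "detected").
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, label = "detected") {
  if (nrow(events)) {
    write_annotations(annotation_set(events$start_s, events$end_s, label),
                      path)
  } else {
    write_annotations(annotation_set(), path)
  }
  invisible(path)
}
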