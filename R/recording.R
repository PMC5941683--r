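#' Multichannel EHG recording
#'
#' Container for a multichannel surface-EMG (electrohysterogram) recording:
#' a channels x samples numeric matrix plus its sampling rate and channel
#' labels. Sample `i` (0-based) corresponds to time `i / sample_rate`
#' seconds from recording start, optionally shifted by `start_offset`.
#'
#' @param data numeric matrix, one row per channel, one column per sample.
#' @param sample_rate sampling frequency in Hz (positive scalar).
#' @param channel_labels character vector, one label per channel. Defaults
#'   to `E1..En` (the unipolar electrode naming of a 4x4 abdominal grid).
#' @param start_offset time of the first sample in seconds (default 0).
#'
#' @return An object of class `ehg_recording` with fields `data`,
#'   `sample_rate`, `channel_labels`, `start_offset`.
#' @examples
#' rec <- ehg_recording(matrix(rnorm(32), nrow = 16), sample_rate = 200)
#' n_channels(rec)
#' @export
ehg_recording <- function(data, sample_rate, channel_labels = NULL,
                          start_offset = 0) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric matrix (channels x samples)")
  }
  if (nrow(data) < 1L || ncol(data) < 1L) {
    stop("recording must have at least one channel and one sample")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L ||
      !is.finite(sample_rate) || sample_rate <= 0) {
    stop("`sample_rate` must be a positive scalar (Hz)")
  }
  if (is.null(channel_labels)) {
    channel_labels <- paste0("E", seq_len(nrow(data)))
  }
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data)) {
    stop("`channel_labels` length (", length(channel_labels),
         ") must equal the number of channels (", nrow(data), ")")
  }
  structure(
    list(data = data, sample_rate = as.numeric(sample_rate),
         channel_labels = channel_labels,
         start_offset = as.numeric(start_offset)),
    class = "ehg_recording"
  )
}

#' @rdname ehg_recording
#' @param rec an `ehg_recording`.
#' @export
n_channels <- function(rec) nrow(rec$data)

#' @rdname ehg_recording
#' @export
n_samples <- function(rec) ncol(rec$data)

#' @rdname ehg_recording
#' @export
duration_s <- function(rec) ncol(rec$data) / rec$sample_rate

#' @export
print.ehg_recording <- function(x, ...) {
  cat(sprintf("<ehg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              n_channels(x), n_samples(x), x$sample_rate, duration_s(x)))
  invisible(x)
}

#' Electrode grid geometry
#'
#' Describes the 4x4 abdominal electrode matrix: 16 Ag/AgCl electrodes of
#' 13 mm diameter at 17.5 mm centre-to-centre pitch, placed between pubis
#' and umbilicus. `channel_index[r, c]` maps grid position (row `r` counted
#' from the top, column `c`) to the channel index in the recording. The
#' default is row-major: electrode `Ei` sits at row `ceiling(i/4)`, column
#' `(i - 1) %% 4 + 1`.
#'
#' @param channel_index 4x4 integer matrix, a bijection onto `1:16`.
#' @param electrode_diameter_mm,pitch_mm geometry metadata (mm), not used
#'   by any computation; retained for provenance.
#'
#' @return An object of class `electrode_grid`.
#' @examples
#' g <- electrode_grid()
#' g$channel_index[1, ]  # top row: E1..E4
#' @export
electrode_grid <- function(channel_index = matrix(1:16, nrow = 4, byrow = TRUE),
                           electrode_diameter_mm = 13,
                           pitch_mm = 17.5) {
  channel_index <- as.matrix(channel_index)
  if (!all(dim(channel_index) == c(4L, 4L))) {
    stop("`channel_index` must be a 4x4 matrix")
  }
  if (!setequal(as.integer(channel_index), 1:16)) {
    stop("`channel_index` must be a bijection onto channels 1..16")
  }
  structure(
    list(rows = 4L, cols = 4L,
         channel_index = matrix(as.integer(channel_index), 4L, 4L),
         electrode_diameter_mm = electrode_diameter_mm,
         pitch_mm = pitch_mm),
    class = "electrode_grid"
  )
}

#' Contraction interval annotations
#'
#' A set of labelled time intervals (expert reference contractions or
#' detected events): a data.frame with columns `start_s`, `end_s`, `label`.
#' Construction validates and sorts by start time; intervals must be
#' non-overlapping and each must satisfy `start_s < end_s`.
#'
#' @param start_s,end_s numeric vectors of interval bounds in seconds from
#'   recording start.
#' @param label character vector of labels (recycled).
#'
#' @return A data.frame of class `annotation_set`, sorted by `start_s`.
#' @examples
#' a <- annotation_set(c(300, 100), c(350, 160))
#' a$start_s  # sorted: 100, 300
#' @export
annotation_set <- function(start_s = numeric(), end_s = numeric(),
                           label = "contraction") {
  start_s <- as.numeric(start_s)
  end_s <- as.numeric(end_s)
  if (length(start_s) != length(end_s)) {
    stop("`start_s` and `end_s` must have the same length")
  }
  n <- length(start_s)
  label <- rep_len(as.character(label), n)
  bad <- which(!(start_s < end_s))
  if (length(bad)) {
    stop("interval ", bad[1L], " has start_s >= end_s (",
         start_s[bad[1L]], " >= ", end_s[bad[1L]], ")")
  }
  o <- order(start_s, end_s)
  start_s <- start_s[o]; end_s <- end_s[o]; label <- label[o]
  if (n > 1L) {
    ovl <- which(start_s[-1L] < end_s[-n])
    if (length(ovl)) {
      stop("intervals ", ovl[1L], " and ", ovl[1L] + 1L,
           " overlap after sorting")
    }
  }
  structure(
    data.frame(start_s = start_s, end_s = end_s, label = label,
               stringsAsFactors = FALSE),
    class = c("annotation_set", "data.frame")
  )
}

#' @rdname annotation_set
#' @param x object to coerce: a data.frame with `start_s`, `end_s` and
#'   optionally `label` columns.
#' @export
as_annotation_set <- function(x) {
  if (inherits(x, "annotation_set")) return(x)
  stopifnot(is.data.frame(x), all(c("start_s", "end_s") %in% names(x)))
  lab <- if ("label" %in% names(x) && nrow(x)) x$label else "contraction"
  annotation_set(x$start_s, x$end_s, lab)
}
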