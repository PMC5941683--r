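#' Nonlinear correlation coefficient H2
#'
#' H2 measures the proportion of the variance of `y` explained by a
#' piecewise-linear regression of `y` on `x`: the range of `x` is split into
#' `bins` equal-width bins, a knot is placed at the (mean x, mean y) of each
#' non-empty bin, and the regression curve linearly interpolates the knots
#' (extending the outer segments linearly beyond the outermost knots, so an
#' exact affine relation scores exactly 1). Then
#' `H2 = max(0, 1 - SS_res / SS_tot)`. Unlike the squared Pearson
#' correlation, H2 captures arbitrary (possibly non-monotone) functional
#' dependence, and it is asymmetric: `h2_coefficient(x, y)` regresses y on
#' x, and generally differs from `h2_coefficient(y, x)`.
#'
#' Degenerate inputs return 0: constant `y` (zero variance), constant `x`,
#' or fewer than two non-empty bins.
#'
#' H2 is invariant (to numerical tolerance) under affine transforms of
#' either signal, so raw EHG amplitudes in arbitrary units are acceptable.
#'
#' @param x driver signal (numeric vector).
#' @param y response signal, same length; the variance being explained.
#' @param bins number of equal-width bins over the range of `x`
#'   (default 10). Require `length(x) >= 2 * bins` so bins are populated.
#' @return A scalar in `[0, 1]`; 0 = uncorrelated, 1 = y is an exact
#'   function of x (up to the piecewise-linear approximation).
#' @examples
#' x <- rnorm(800)
#' h2_coefficient(x, 2 * x + 1)   # 1: affine dependence
#' h2_coefficient(x, x^2)         # high: nonlinear but functional
#' @export
h2_coefficient <- function(x, y, bins = 10L) {
  if (length(x) != length(y)) {
    stop("x and y must have the same length (", length(x), " vs ",
         length(y), ")")
  }
  bins <- as.integer(bins)
  if (bins < 2L) stop("bins must be >= 2")
  if (length(x) < 2L * bins) {
    stop("need at least 2 * bins = ", 2L * bins, " samples, got ", length(x))
  }
  h2_pair_cpp(as.numeric(x), as.numeric(y), bins)
}

#' Laterally adjacent bipolar pair topology
#'
#' Enumerates the 36 ordered pairs of bipolar signals used by the
#' correlated-pair count: all pairs sharing a bipolar row across distinct
#' columns (3 rows x choose(4,2) = 18 unordered pairs), each taken in both
#' directions because H2 is asymmetric. With the column-major numbering of
#' [make_bipolar()], `(Vb1, Vb4)`, `(Vb4, Vb7)` and `(Vb2, Vb5)` are all
#' members.
#'
#' @param bip a `bipolar_set` with a 3x4 position layout, or `NULL` for the
#'   default layout.
#' @return A matrix of class `pair_topology`, 36 x 2, columns
#'   `driver`/`response` holding 1-based bipolar channel indices.
#' @export
build_lateral_pairs <- function(bip = NULL) {
  pos <- if (is.null(bip)) {
    cbind(bipolar_row = rep(1:3, 4), col = rep(1:4, each = 3))
  } else {
    stopifnot(!is.null(bip$position))
    bip$position
  }
  if (nrow(pos) != 12L ||
      !identical(sort(paste(pos[, 1L], pos[, 2L])),
                 sort(paste(rep(1:3, 4), rep(1:4, each = 3))))) {
    stop("bipolar layout must cover each (row 1..3, col 1..4) exactly once")
  }
  out <- matrix(0L, 0L, 2L)
  for (r in 1:3) {
    idx <- which(pos[, 1L] == r)
    idx <- idx[order(pos[idx, 2L])]
    for (i in 1:3) for (j in (i + 1L):4L) {
      out <- rbind(out, c(idx[i], idx[j]), c(idx[j], idx[i]))
    }
  }
  colnames(out) <- c("driver", "response")
  structure(out, class = c("pair_topology", class(out)))
}

#' Sliding-window correlated-pair count curve
#'
#' Slides a window of `window_len` samples across the 12 band-passed
#' bipolar signals in steps of `window_step`; at each position computes H2
#' for every ordered pair in the topology and counts how many strictly
#' exceed the cutoff `s1`. During a contraction the myometrial burst is
#' shared across the electrode grid, so many pairs correlate and the count
#' rises; between contractions the channels carry independent noise and the
#' count stays near zero.
#'
#' The number of windows is `floor((n_samples - window_len)/window_step) + 1`;
#' window `w` (0-based) starts at sample `w * window_step`, i.e. time
#' `w * window_step / sample_rate` seconds.
#'
#' @param bip a `bipolar_set` (normally after [bandpass_filter()]).
#' @param window_len window width in samples (default 800 = 4 s at 200 Hz).
#' @param window_step window increment in samples (default 400).
#' @param topo a `pair_topology`; default [build_lateral_pairs()].
#' @param s1 per-pair H2 cutoff in `[0, 1]`.
#' @param bins H2 regression bins.
#' @return An object of class `count_curve`: `window_start_s`, `count`,
#'   `n_pairs`, `window_len_s`.
#' @export
sliding_count_curve <- function(bip, window_len = 800L, window_step = 400L,
                                topo = NULL, s1 = 0.5, bins = 10L) {
  stopifnot(!is.null(bip$signals), !is.null(bip$sample_rate))
  window_len <- as.integer(window_len)
  window_step <- as.integer(window_step)
  if (window_step < 1L || window_step > window_len) {
    stop("require 0 < window_step <= window_len")
  }
  ns <- ncol(bip$signals)
  if (ns < window_len) {
    stop("recording (", ns, " samples) shorter than one window (",
         window_len, " samples)")
  }
  if (is.null(topo)) topo <- build_lateral_pairs(bip)
  counts <- sliding_counts_cpp(bip$signals,
                               matrix(as.integer(topo), ncol = 2L),
                               window_len, window_step, s1, as.integer(bins))
  structure(
    list(window_start_s = (seq_along(counts) - 1L) * window_step /
           bip$sample_rate,
         count = as.integer(counts),
         n_pairs = nrow(topo),
         window_len_s = window_len / bip$sample_rate),
    class = "count_curve"
  )
}

#' @export
print.count_curve <- function(x, ...) {
  cat(sprintf("<count_curve> %d windows of %.3g s, counts 0..%d (max %d)\n",
              length(x$count), x$window_len_s, x$n_pairs, max(x$count, 0L)))
  invisible(x)
}

#' Write a count curve as TSV (columns window_start_s, count)
#'
#' @param curve a `count_curve`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_count_curve <- function(curve, path) {
  utils::write.table(
    data.frame(window_start_s = sprintf("%.3f", curve$window_start_s),
               count = curve$count),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
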