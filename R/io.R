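#' Read a multichannel recording from disk
#'
#' Two interchange formats are supported. `"csv"` is a plain comma-separated
#' table, one column per channel with a header row of channel labels;
#' because delimited text carries no timing metadata the sample rate must be
#' supplied (it is stored in a `# sample_rate_hz: <value>` comment line by
#' [write_recording()], which the reader honours). `"edf"` is the European
#' Data Format (16-bit integer samples with per-channel physical scaling),
#' the conventional clinical container for polygraph-style biosignals.
#'
#' @param path file to read.
#' @param format `"edf"` or `"csv"`; default inferred from the file
#'   extension.
#' @param sample_rate sample rate in Hz for CSV files lacking the metadata
#'   comment line. Ignored for EDF (the header is authoritative).
#' @return An [ehg_recording()].
#' @seealso [write_recording()]
#' @export
read_recording <- function(path, format = c("auto", "edf", "csv"),
                           sample_rate = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (!file.exists(path)) stop("recording file not found: ", path)
  if (format == "edf") read_recording_edf(path) else {
    read_recording_csv(path, sample_rate)
  }
}

read_recording_csv <- function(path, sample_rate = NULL) {
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^#", lines, value = TRUE)
  sr_line <- grep("^#\\s*sample_rate_hz\\s*:", meta, value = TRUE)
  if (length(sr_line)) {
    sample_rate <- as.numeric(sub("^#\\s*sample_rate_hz\\s*:\\s*", "", sr_line[1L]))
  }
  if (is.null(sample_rate) || !is.finite(sample_rate)) {
    stop("CSV recording ", path, ": no sample rate; add a",
         " '# sample_rate_hz: <Hz>' line or pass `sample_rate`")
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (!length(body)) stop("CSV recording ", path, ": no header row")
  header <- strsplit(body[1L], ",", fixed = TRUE)[[1L]]
  nch <- length(header)
  rows <- strsplit(body[-1L], ",", fixed = TRUE)
  nlen <- lengths(rows)
  bad <- which(nlen != nch)
  if (length(bad)) {
    stop("CSV recording ", path, ": line ", bad[1L] + 1L, " has ",
         nlen[bad[1L]], " fields, expected ", nch)
  }
  if (!length(rows)) stop("CSV recording ", path, ": no sample rows")
  vals <- suppressWarnings(as.numeric(unlist(rows, use.names = FALSE)))
  if (anyNA(vals)) {
    bad_row <- which(vapply(rows, function(r) anyNA(suppressWarnings(as.numeric(r))),
                            logical(1L)))[1L]
    stop("CSV recording ", path, ": non-numeric value on line ", bad_row + 1L)
  }
  # rows of the file are samples; recording stores channels x samples
  data <- matrix(vals, nrow = nch, byrow = FALSE)
  ehg_recording(data, sample_rate, channel_labels = trimws(header))
}

#' Write a recording to disk
#'
#' CSV output preserves values to full double precision (17 significant
#' digits). EDF output quantizes each channel to 16-bit integers over its
#' own physical range, so round-trip error is bounded by half a
#' quantization step, i.e. `range / 2^16` per channel.
#'
#' @param rec an [ehg_recording()].
#' @param path output file.
#' @param format `"edf"`, `"csv"`, or `"auto"` (from extension).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "edf", "csv")) {
  stopifnot(inherits(rec, "ehg_recording"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (format == "edf") write_recording_edf(rec, path) else {
    write_recording_csv(rec, path)
  }
  invisible(path)
}

write_recording_csv <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_rate_hz: %.10g", rec$sample_rate), con)
  writeLines(paste(rec$channel_labels, collapse = ","), con)
  # one sample per line, full precision
  txt <- apply(format(t(rec$data), digits = 17, scientific = TRUE,
                      trim = TRUE), 1L, paste, collapse = ",")
  writeLines(txt, con)
}

# ---- Minimal EDF (European Data Format) codec -------------------------------
#
# EDF: 256-byte fixed header + 256 bytes per signal header, then data records
# of little-endian 16-bit integers. One data record per second; the final
# partial record is zero-padded and the true sample count is stashed in the
# reserved header field so round-trips preserve length exactly. No R EDF
# package is available in this environment, so the codec is implemented here;
# it covers the plain-EDF subset this package writes (no EDF+ annotations).

edf_pad <- function(x, n) {
  x <- substr(as.character(x), 1L, n)
  sprintf(paste0("%-", n, "s"), x)
}

write_recording_edf <- function(rec, path) {
  nch <- n_channels(rec); ns <- n_samples(rec)
  fs <- rec$sample_rate
  spr <- as.integer(round(fs))          # samples per 1-s data record
  if (abs(fs - spr) > 1e-9) {
    # non-integer rate: single record holding everything
    spr <- ns
    rec_dur <- ns / fs
  } else rec_dur <- 1
  n_rec <- ceiling(ns / spr)

  phys_min <- apply(rec$data, 1L, min)
  phys_max <- apply(rec$data, 1L, max)
  flat <- phys_max - phys_min <= 0
  phys_min[flat] <- phys_min[flat] - 1
  phys_max[flat] <- phys_max[flat] + 1
  dig_min <- -32768; dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8L),                            # version
    edf_pad("X X X X", 80L),                     # patient id (anonymous)
    edf_pad("Startdate X X X X", 80L),           # recording id
    edf_pad("01.01.00", 8L), edf_pad("00.00.00", 8L),
    edf_pad(256L * (1L + nch), 8L),              # header bytes
    edf_pad(sprintf("NSAMP=%d", ns), 44L),       # reserved: true sample count
    edf_pad(n_rec, 8L),
    edf_pad(format(rec_dur, digits = 7), 8L),
    edf_pad(nch, 4L)
  )
  writeChar(hdr, con, eos = NULL)
  fld <- function(v, w) writeChar(paste0(vapply(v, edf_pad, "", n = w),
                                         collapse = ""), con, eos = NULL)
  fld(rec$channel_labels, 16L)
  fld(rep("", nch), 80L)                         # transducer
  fld(rep("uV", nch), 8L)                        # physical dimension
  fld(sprintf("%.8g", phys_min), 8L)
  fld(sprintf("%.8g", phys_max), 8L)
  fld(rep(dig_min, nch), 8L)
  fld(rep(dig_max, nch), 8L)
  fld(rep("", nch), 80L)                         # prefiltering
  fld(rep(spr, nch), 8L)
  fld(rep("", nch), 32L)                         # per-signal reserved

  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  padded <- matrix(0, nch, n_rec * spr)
  padded[, seq_len(ns)] <- rec$data
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (ch in seq_len(nch)) {
      dig <- round((padded[ch, idx] - phys_min[ch]) * scale[ch]) + dig_min
      writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con,
               size = 2L, endian = "little")
    }
  }
}

read_recording_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8L)                      # version
  rd(160L)                    # patient + recording id
  rd(16L)                     # date + time
  hdr_bytes <- as.integer(rd(8L))
  reserved <- rd(44L)
  n_rec <- as.integer(rd(8L))
  rec_dur <- as.numeric(rd(8L))
  nch <- as.integer(rd(4L))
  if (is.na(nch) || nch < 1L) stop("EDF ", path, ": malformed header")
  rds <- function(w) {
    raw <- rd(nch * w)
    trimws(substring(raw, (0:(nch - 1L)) * w + 1L, (1:nch) * w))
  }
  labels <- rds(16L)
  rds(80L); rds(8L)
  phys_min <- as.numeric(rds(8L))
  phys_max <- as.numeric(rds(8L))
  dig_min <- as.numeric(rds(8L))
  dig_max <- as.numeric(rds(8L))
  rds(80L)
  spr <- as.integer(rds(8L))
  rds(32L)
  if (!all(spr == spr[1L])) {
    stop("EDF ", path, ": heterogeneous sampling rates are not supported")
  }
  spr <- spr[1L]
  fs <- spr / rec_dur
  total <- n_rec * spr
  data <- matrix(0, nch, total)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (ch in seq_len(nch)) {
      dig <- readBin(con, integer(), n = spr, size = 2L, signed = TRUE,
                     endian = "little")
      if (length(dig) < spr) stop("EDF ", path, ": truncated data record ", r)
      data[ch, idx] <- (dig - dig_min[ch]) *
        (phys_max[ch] - phys_min[ch]) / (dig_max[ch] - dig_min[ch]) +
        phys_min[ch]
    }
  }
  m <- regmatches(reserved, regexec("NSAMP=([0-9]+)", reserved))[[1L]]
  if (length(m) == 2L) {
    ns <- as.integer(m[2L])
    if (ns >= 1L && ns <= total) data <- data[, seq_len(ns), drop = FALSE]
  }
  ehg_recording(data, fs, channel_labels = labels)
}

# ---- Annotations ------------------------------------------------------------

#' Read/write interval annotations
#'
#' Annotations travel as tab-separated text with columns `start_s`, `end_s`,
#' `label` (times in seconds from recording start). Reading validates and
#' sorts; writing rounds to 1 ms, which round-trips losslessly at that
#' precision.
#'
#' @param path TSV file.
#' @return [read_annotations()] returns an [annotation_set()];
#'   [write_annotations()] returns `path` invisibly.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("start_s", "end_s")
  if (!all(need %in% names(df))) {
    stop("annotation file ", path, " must have columns start_s, end_s, label")
  }
  if (nrow(df) == 0L) return(annotation_set())
  bad <- which(!(df$start_s < df$end_s))
  if (length(bad)) {
    stop("annotation file ", path, ", row ", bad[1L], ": start_s >= end_s")
  }
  as_annotation_set(df)
}

#' @rdname read_annotations
#' @param ann an [annotation_set()].
#' @export
write_annotations <- function(ann, path) {
  ann <- as_annotation_set(ann)
  df <- data.frame(start_s = sprintf("%.3f", ann$start_s),
                   end_s = sprintf("%.3f", ann$end_s),
                   label = ann$label)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- TOML configuration -----------------------------------------------------

# Minimal TOML subset parser: [section] tables, key = value with integer,
# float, boolean, double-quoted string, and flat numeric arrays; '#'
# comments. Sufficient for the flat config files this package uses; no TOML
# package ships with the environment.
parse_toml <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  section <- NULL
  parse_val <- function(v, lineno) {
    v <- trimws(v)
    if (v %in% c("true", "false")) return(v == "true")
    if (grepl('^".*"$', v)) return(gsub('^"|"$', "", v))
    if (grepl("^\\[.*\\]$", v)) {
      items <- strsplit(gsub("^\\[|\\]$", "", v), ",")[[1L]]
      items <- trimws(items)
      items <- items[nzchar(items)]
      nums <- suppressWarnings(as.numeric(items))
      if (anyNA(nums)) stop("config line ", lineno, ": unsupported array: ", v)
      return(nums)
    }
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) return(num)
    stop("config line ", lineno, ": cannot parse value: ", v)
  }
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[.+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(out[[section]])) out[[section]] <- list()
      next
    }
    kv <- regmatches(ln, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.+)$", ln))[[1L]]
    if (length(kv) != 3L) stop("config line ", i, ": expected key = value: ", ln)
    val <- parse_val(kv[3L], i)
    if (is.null(section)) out[[kv[2L]]] <- val else out[[section]][[kv[2L]]] <- val
  }
  out
}

#' Detection pipeline configuration
#'
#' Bundles every tunable of the detection chain. Defaults marked (*) come
#' from the published method; the rest are this package's own calibration
#' (the study tuned `s1`, `s2`, `d1`, `d2` on its clinical database but did
#' not print the values).
#'
#' \describe{
#'   \item{window_len}{sliding H2 window, samples; 800 (*) = 4 s at 200 Hz.}
#'   \item{window_step}{window increment, samples; 400 (*).}
#'   \item{band_low, band_high}{analysis band, Hz; 0.1-3.0 (*).}
#'   \item{s1}{per-pair H2 cutoff in \[0, 1\] above which a bipolar pair
#'     counts as correlated; default 0.5.}
#'   \item{s2}{cutoff on the correlated-pair count (0-36); windows with
#'     count strictly greater belong to an event; default 10.}
#'   \item{d1}{fusion gap, seconds: consecutive events separated by less
#'     than `d1` are merged; default 15.}
#'   \item{d2}{minimal duration, seconds: events not exceeding `d2` are
#'     eliminated; default 30.}
#'   \item{h2_bins}{number of equal-width bins in the H2 regression;
#'     default 10 (about 80 samples per bin at the default window).}
#'   \item{tolerance}{evaluation margin, seconds, for calling a detection
#'     "full"; default 10.}
#'   \item{seed}{RNG seed for anything stochastic downstream; default 0.}
#' }
#'
#' @param ... overrides of the fields above.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(s1 = 0.5, s2 = 10L, d1 = 15, d2 = 30,
              window_len = 800L, window_step = 400L,
              band_low = 0.1, band_high = 3.0,
              h2_bins = 10L, tolerance = 10, seed = 0L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  for (k in c("s2", "window_len", "window_step", "h2_bins", "seed")) {
    cfg[[k]] <- as.integer(cfg[[k]])
  }
  if (!is.finite(cfg$s1) || cfg$s1 < 0 || cfg$s1 > 1) {
    stop("s1 must lie in [0, 1], got ", cfg$s1)
  }
  if (cfg$s2 < 0L) stop("s2 must be a non-negative count")
  if (cfg$d1 < 0 || cfg$d2 < 0) stop("d1 and d2 must be non-negative seconds")
  if (cfg$window_len < 1L || cfg$window_step < 1L ||
      cfg$window_step > cfg$window_len) {
    stop("require 0 < window_step <= window_len, got step = ",
         cfg$window_step, ", window = ", cfg$window_len)
  }
  if (!(cfg$band_low > 0 && cfg$band_low < cfg$band_high)) {
    stop("require 0 < band_low < band_high, got [", cfg$band_low, ", ",
         cfg$band_high, "]")
  }
  if (cfg$h2_bins < 2L) stop("h2_bins must be >= 2")
  if (cfg$tolerance < 0) stop("tolerance must be non-negative seconds")
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from a TOML file
#'
#' Keys may sit at top level or inside a `[detection]` table; missing keys
#' take the [pipeline_config()] defaults. A `[synthetic]` table, if present,
#' is ignored here (see [synthetic_config_from_toml()]).
#'
#' @param path TOML file. Missing or empty file gives all defaults.
#' @return A `pipeline_config`.
#' @export
load_config <- function(path) {
  raw <- if (file.exists(path)) parse_toml(path) else list()
  if (!is.null(raw$detection)) {
    flat <- raw[!vapply(raw, is.list, logical(1L))]
    raw <- c(raw$detection, flat)
  } else {
    raw <- raw[!vapply(raw, is.list, logical(1L))]
  }
  known <- c("s1", "s2", "d1", "d2", "window_len", "window_step",
             "band_low", "band_high", "h2_bins", "tolerance", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) stop("unknown config key(s) in ", path, ": ",
                            paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}
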