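#' Classify detected events against reference contractions
#'
#' Implements the full / partial / false-alarm taxonomy. Each detected
#' event overlapping at least one reference interval is assigned to the
#' reference with which it shares the greatest overlap (ties broken in
#' favour of the earliest reference). A reference is a **full** detection if
#' some assigned event matches both its boundaries within `tolerance`
#' seconds; **partial** if it has at least one assigned event but none
#' qualifies as full (the event covers only part of the contraction, or
#' spills into baseline); **missed** otherwise. Events assigned to no
#' reference are **false alarms**. Several events on one contraction
#' (oversegmentation) still count that reference once.
#'
#' @param events an `event_list` (sorted).
#' @param refs an [annotation_set()] of reference contractions.
#' @param tolerance acceptable boundary margin in seconds (non-negative);
#'   default 10.
#' @return An object of class `detection_outcome`: `ref_class` (factor
#'   full/partial/missed per reference), `assignment` (reference index per
#'   event, NA for false alarms), `false_alarms` (`event_list`), and counts
#'   `n_full`, `n_partial`, `n_missed`, `n_false_alarms`, `n_refs`.
#' @export
classify_detections <- function(events, refs, tolerance = 10) {
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance < 0) {
    stop("tolerance must be a non-negative number of seconds")
  }
  refs <- as_annotation_set(refs)
  n_ev <- nrow(events); n_ref <- nrow(refs)
  assignment <- rep(NA_integer_, n_ev)
  if (n_ev && n_ref) {
    for (i in seq_len(n_ev)) {
      ovl <- pmin(events$end_s[i], refs$end_s) -
        pmax(events$start_s[i], refs$start_s)
      j <- which.max(ovl)           # earliest index wins ties
      if (ovl[j] > 0) assignment[i] <- j
    }
  }
  ref_class <- rep("missed", n_ref)
  if (n_ref) {
    for (j in seq_len(n_ref)) {
      ev_j <- which(assignment == j)
      if (!length(ev_j)) next
      full <- any(abs(events$start_s[ev_j] - refs$start_s[j]) <= tolerance &
                  abs(events$end_s[ev_j] - refs$end_s[j]) <= tolerance)
      ref_class[j] <- if (full) "full" else "partial"
    }
  }
  fa_idx <- which(is.na(assignment))
  fa <- if (length(fa_idx)) {
    event_list(events$start_s[fa_idx], events$end_s[fa_idx])
  } else event_list()
  structure(
    list(ref_class = factor(ref_class, levels = c("full", "partial", "missed")),
         assignment = assignment,
         false_alarms = fa,
         n_full = sum(ref_class == "full"),
         n_partial = sum(ref_class == "partial"),
         n_missed = sum(ref_class == "missed"),
         n_false_alarms = length(fa_idx),
         n_refs = n_ref),
    class = "detection_outcome"
  )
}

#' Summarize detection performance
#'
#' Computes the four headline percentages relative to the number of
#' reference contractions: full detections, partial detections, total
#' detections (full + partial), and false alarms. The false-alarm rate is
#' expressed per reference contraction and may exceed 100% when detections
#' outnumber contractions.
#'
#' @param outcome a `detection_outcome` from [classify_detections()], or a
#'   list with fields `n_full`, `n_partial`, `n_missed`, `n_false_alarms`
#'   (see [summarize_counts()] for a counts-only entry point).
#' @param n_refs number of reference contractions; defaults to
#'   `outcome$n_refs`. Must be positive (percentages are undefined for an
#'   empty reference set).
#' @return An object of class `evaluation_summary` with the raw counts and
#'   exact (unrounded) percentages `pct_full`, `pct_partial`,
#'   `pct_total_detection`, `pct_false_alarms`.
#' @export
summarize_metrics <- function(outcome, n_refs = outcome$n_refs) {
  if (is.null(n_refs) || !is.finite(n_refs) || n_refs <= 0) {
    stop("percentages are undefined for an empty reference set (n_refs = ",
         if (is.null(n_refs)) 0 else n_refs, ")")
  }
  stopifnot(outcome$n_full + outcome$n_partial + outcome$n_missed == n_refs)
  structure(
    list(n_refs = as.integer(n_refs),
         n_full = outcome$n_full, n_partial = outcome$n_partial,
         n_missed = outcome$n_missed,
         n_false_alarms = outcome$n_false_alarms,
         pct_full = 100 * outcome$n_full / n_refs,
         pct_partial = 100 * outcome$n_partial / n_refs,
         pct_total_detection = 100 * (outcome$n_full + outcome$n_partial) /
           n_refs,
         pct_false_alarms = 100 * outcome$n_false_alarms / n_refs),
    class = "evaluation_summary"
  )
}

#' @rdname summarize_metrics
#' @param n_full,n_partial,n_missed,n_false_alarms raw classification counts.
#' @export
summarize_counts <- function(n_full, n_partial, n_missed, n_false_alarms,
                             n_refs = n_full + n_partial + n_missed) {
  summarize_metrics(list(n_full = n_full, n_partial = n_partial,
                         n_missed = n_missed,
                         n_false_alarms = n_false_alarms),
                    n_refs = n_refs)
}

# Percentage rendering convention of the summary tables: detection rates to
# one decimal place; the false-alarm rate to the nearest integer once it
# reaches 100% (it is quoted per contraction and can far exceed 100%).
format_pct <- function(p, false_alarm = FALSE) {
  if (false_alarm && p >= 100) sprintf("%.0f%%", round(p))
  else sprintf("%.1f%%", round(p, 1L))
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat(format_summary_lines(x), sep = "\n")
  invisible(x)
}

format_summary_lines <- function(x) {
  c(sprintf("Full detections:    %s (%d/%d)",
            format_pct(x$pct_full), x$n_full, x$n_refs),
    sprintf("Partial detections: %s (%d/%d)",
            format_pct(x$pct_partial), x$n_partial, x$n_refs),
    sprintf("Total detections:   %s (%d/%d)",
            format_pct(x$pct_total_detection), x$n_full + x$n_partial,
            x$n_refs),
    sprintf("False alarms:       %s (%d/%d)",
            format_pct(x$pct_false_alarms, TRUE), x$n_false_alarms,
            x$n_refs))
}

#' Write an evaluation report
#'
#' Emits the summary both as a TSV of raw counts and exact percentages and,
#' with `text = TRUE`, a human-readable table alongside (same path with
#' `.txt` appended). Optionally writes a per-event audit trail (CSV:
#' event bounds, matched reference, classification).
#'
#' @param summary an `evaluation_summary`.
#' @param path output TSV path.
#' @param text also write the rendered text table.
#' @param outcome optional `detection_outcome` plus `events` to enable the
#'   audit trail.
#' @param events the `event_list` that produced `outcome`.
#' @param audit_path optional CSV path for the per-event audit trail.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(summary, path, text = TRUE,
                                    outcome = NULL, events = NULL,
                                    audit_path = NULL) {
  df <- data.frame(
    metric = c("full", "partial", "total_detection", "false_alarms"),
    count = c(summary$n_full, summary$n_partial,
              summary$n_full + summary$n_partial, summary$n_false_alarms),
    n_refs = summary$n_refs,
    percent = c(summary$pct_full, summary$pct_partial,
                summary$pct_total_detection, summary$pct_false_alarms))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (text) writeLines(format_summary_lines(summary), paste0(path, ".txt"))
  if (!is.null(outcome) && !is.null(events) && !is.null(audit_path)) {
    cls <- ifelse(is.na(outcome$assignment), "false_alarm",
                  as.character(outcome$ref_class[outcome$assignment]))
    audit <- data.frame(event_start_s = events$start_s,
                        event_end_s = events$end_s,
                        matched_ref = outcome$assignment,
                        ref_classification = cls)
    utils::write.csv(audit, audit_path, row.names = FALSE)
  }
  invisible(path)
}
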