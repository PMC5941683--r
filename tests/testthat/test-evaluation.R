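test_that("classification follows the full/partial/false-alarm rules", {
  refs <- annotation_set(100, 160)

  # boundaries within tolerance on both sides -> full
  out <- classify_detections(event_list(105, 158), refs, tolerance = 10)
  expect_identical(c(out$n_full, out$n_partial, out$n_missed,
                     out$n_false_alarms), c(1L, 0L, 0L, 0L))

  # overlapping but end deviates 40 s -> partial
  out <- classify_detections(event_list(130, 200), refs, tolerance = 10)
  expect_identical(c(out$n_full, out$n_partial, out$n_false_alarms),
                   c(0L, 1L, 0L))

  # disjoint event -> reference missed, event is a false alarm
  out <- classify_detections(event_list(300, 320), refs, tolerance = 10)
  expect_identical(c(out$n_missed, out$n_false_alarms), c(1L, 1L))

  # no events at all
  out <- classify_detections(event_list(), refs)
  expect_identical(out$n_missed, 1L)

  expect_error(classify_detections(event_list(), refs, tolerance = -1),
               "non-negative")
})

test_that("events attach to the reference of maximal overlap, earliest on ties", {
  refs <- annotation_set(c(0, 100), c(50, 150))
  # event overlapping both, more with the second
  out <- classify_detections(event_list(40, 140), refs, tolerance = 5)
  expect_identical(out$assignment, 2L)
  expect_identical(as.character(out$ref_class), c("missed", "partial"))
  # exact tie -> earliest reference
  out <- classify_detections(event_list(40, 110), refs, tolerance = 5)
  expect_identical(out$assignment, 1L)
})

test_that("oversegmentation counts the reference once", {
  refs <- annotation_set(100, 200)
  ev <- event_list(c(100, 150, 180), c(130, 170, 200))
  out <- classify_detections(ev, refs, tolerance = 10)
  expect_identical(out$n_partial, 1L)       # not three
  expect_identical(out$n_false_alarms, 0L)  # extra events are not FAs
  # and if any assigned event matches both bounds, the reference is full
  ev2 <- event_list(c(102, 150), c(195, 170))
  out2 <- classify_detections(ev2, refs, tolerance = 10)
  expect_identical(out2$n_full, 1L)
})

test_that("classification partitions events and references", {
  for (s in 1:6) {
    ev <- random_events(10L, seed = 500L + s)
    rf <- random_events(6L, horizon = 900, seed = 600L + s)
    refs <- annotation_set(rf$start_s, rf$end_s)
    out <- classify_detections(ev, refs, tolerance = 10)
    expect_identical(out$n_full + out$n_partial + out$n_missed, nrow(refs))
    expect_identical(sum(!is.na(out$assignment)) + out$n_false_alarms,
                     nrow(ev))
    # false alarms overlap no reference
    if (nrow(out$false_alarms)) {
      for (i in seq_len(nrow(out$false_alarms))) {
        ovl <- pmin(out$false_alarms$end_s[i], refs$end_s) -
          pmax(out$false_alarms$start_s[i], refs$start_s)
        expect_true(all(ovl <= 0))
      }
    }
  }
})

test_that("summary percentages and rendering match the table conventions", {
  s <- summarize_counts(313, 188, 0, 3918)
  expect_identical(s$n_refs, 501L)
  expect_equal(round(s$pct_full, 1), 62.5)
  expect_equal(round(s$pct_partial, 1), 37.5)
  expect_equal(s$pct_total_detection, 100)
  expect_equal(round(s$pct_false_alarms), 782)
  lines <- ehgdetect:::format_summary_lines(s)
  expect_match(lines[1], "62.5% (313/501)", fixed = TRUE)
  expect_match(lines[4], "782% (3918/501)", fixed = TRUE)

  # perfect detection
  refs <- annotation_set(c(10, 100), c(50, 160))
  out <- classify_detections(event_list(c(10, 100), c(50, 160)), refs, 1)
  s2 <- summarize_metrics(out)
  expect_equal(s2$pct_full, 100)
  expect_equal(s2$pct_false_alarms, 0)

  expect_error(summarize_counts(0, 0, 0, 5, n_refs = 0), "undefined")
})

test_that("evaluation report writes TSV, text, and audit trail", {
  refs <- annotation_set(c(10, 100), c(50, 160))
  ev <- event_list(c(12, 300), c(48, 330))
  out <- classify_detections(ev, refs, tolerance = 5)
  s <- summarize_metrics(out)
  p <- withr::local_tempfile(fileext = ".tsv")
  audit <- withr::local_tempfile(fileext = ".csv")
  write_evaluation_report(s, p, outcome = out, events = ev,
                          audit_path = audit)
  tab <- read.delim(p)
  expect_identical(tab$metric,
                   c("full", "partial", "total_detection", "false_alarms"))
  expect_equal(tab$count, c(1, 0, 1, 1))
  expect_true(file.exists(paste0(p, ".txt")))
  au <- read.csv(audit)
  expect_identical(au$ref_classification, c("full", "false_alarm"))
})

test_that("post-processing does not increase false alarms", {
  # artifact-laden synthetic benchmark: d2 above the artifact duration cap
  sim <- quick_sim(seed = 31L, artifact_rate_per_hr = 30)
  cfg <- pipeline_config()
  curve <- detect_pipeline(sim$recording, cfg, return_curve = TRUE)$curve
  before <- detect_events(curve, cfg$s2)
  after <- eliminate_events(fuse_events(before, cfg$d1), cfg$d2)
  fa <- function(ev) classify_detections(ev, sim$annotations,
                                         cfg$tolerance)$n_false_alarms
  expect_lte(fa(after), fa(before))
})
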