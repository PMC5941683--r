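test_that("detect_events maps supra-threshold runs to events", {
  # worked example: counts [0,0,20,25,18,0,0] at 2 s steps, 4 s windows
  cc <- make_curve(c(0, 0, 20, 25, 18, 0, 0))
  ev <- detect_events(cc, s2 = 10L)
  expect_identical(nrow(ev), 1L)
  expect_equal(c(ev$start_s, ev$end_s), c(4, 12))

  # all counts below: nothing
  expect_identical(nrow(detect_events(make_curve(rep(0, 7)), 10L)), 0L)

  # all above: one event spanning first window start to last window end
  ev <- detect_events(make_curve(rep(36, 7)), 10L)
  expect_equal(c(ev$start_s, ev$end_s), c(0, 16))

  # strict comparison: count == s2 does not trigger
  expect_identical(nrow(detect_events(make_curve(rep(10, 5)), 10L)), 0L)

  # two separate runs -> two events
  ev <- detect_events(make_curve(c(20, 0, 0, 0, 20)), 10L)
  expect_identical(nrow(ev), 2L)
})

test_that("fuse_events merges gaps strictly below d1, transitively", {
  e <- event_list(c(10, 24), c(20, 40))
  expect_equal(fuse_events(e, 5)$start_s, 10)
  expect_equal(fuse_events(e, 5)$end_s, 40)
  expect_equal(nrow(fuse_events(e, 3)), 2L)    # gap 4 >= 3: unchanged
  expect_equal(nrow(fuse_events(e, 4)), 2L)    # strict: gap 4 not < 4

  # transitive chain
  chain <- event_list(c(0, 11, 22), c(10, 21, 32))
  expect_identical(nrow(fuse_events(chain, 2)), 1L)

  expect_identical(nrow(fuse_events(event_list(), 5)), 0L)
  expect_error(fuse_events(e, -1), "non-negative")
})

test_that("fusion is idempotent and preserves interval union", {
  for (s in 1:8) {
    e <- random_events(12L, seed = 400L + s)
    for (d1 in c(1, 10, 50)) {
      f1 <- fuse_events(e, d1)
      expect_identical(fuse_events(f1, d1), f1)
      expect_lte(nrow(f1), nrow(e))
      # sorted, non-overlapping
      if (nrow(f1) > 1L) {
        expect_true(all(diff(f1$start_s) > 0))
        expect_true(all(f1$start_s[-1] >= f1$end_s[-nrow(f1)]))
      }
      # every output event contains at least one input event
      for (i in seq_len(nrow(f1))) {
        expect_true(any(e$start_s >= f1$start_s[i] - 1e-9 &
                        e$end_s <= f1$end_s[i] + 1e-9))
      }
      # union of supports is preserved at a fine grid
      grid <- seq(0, 1000, by = 0.5)
      cover <- function(ev) {
        covered <- rep(FALSE, length(grid))
        for (i in seq_len(nrow(ev))) {
          covered <- covered |
            (grid >= ev$start_s[i] & grid <= ev$end_s[i])
        }
        covered
      }
      # fusion only adds coverage (the bridged gaps), never removes it
      expect_true(all(cover(f1)[cover(e)]))
    }
  }
})

test_that("eliminate_events drops events not exceeding d2", {
  e <- event_list(c(0, 100), c(50, 120))   # durations 50 and 20
  out <- eliminate_events(e, 30)
  expect_identical(nrow(out), 1L)
  expect_equal(out$end_s, 50)

  # strict survival: duration == d2 is eliminated
  expect_identical(nrow(eliminate_events(event_list(0, 30), 30)), 0L)
  # d2 = 0 keeps every positive-duration event
  expect_identical(nrow(eliminate_events(e, 0)), 2L)
  expect_identical(nrow(eliminate_events(event_list(), 10)), 0L)
  expect_error(eliminate_events(e, -2), "non-negative")

  for (s in 1:5) {
    e <- random_events(15L, seed = 430L + s)
    out <- eliminate_events(e, 20)
    expect_lte(nrow(out), nrow(e))
    if (nrow(out)) expect_true(all(out$end_s - out$start_s > 20))
  }
})

test_that("detected event count is monotonically non-increasing in s2", {
  bip <- mixed_bipolar_fixture(n_samples = 8000L)
  cc <- sliding_count_curve(bip)
  n_prev <- Inf
  for (s2 in c(2L, 8L, 14L, 20L, 30L)) {
    n <- nrow(detect_events(cc, s2))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("detect_pipeline recovers synthetic truth and is deterministic", {
  sim <- quick_sim(seed = 12L)
  cfg <- pipeline_config()
  ev1 <- detect_pipeline(sim$recording, cfg)
  ev2 <- detect_pipeline(sim$recording, cfg)
  expect_identical(serialize(ev1, NULL), serialize(ev2, NULL))

  # each true contraction overlapped by a detected event
  out <- classify_detections(ev1, sim$annotations, cfg$tolerance)
  expect_identical(out$n_missed, 0L)

  # raw detections are a superset: at least as many events without
  # fusion/elimination
  raw <- detect_pipeline(sim$recording, cfg, fuse = FALSE, eliminate = FALSE)
  expect_gte(nrow(raw), nrow(ev1))
})

test_that("pure-noise recordings produce no events", {
  sim <- generate_recording(synthetic_config(
    duration_s = 400, n_contractions = 0L, artifact_rate_per_hr = 0,
    seed = 21L))
  ev <- detect_pipeline(sim$recording, pipeline_config())
  expect_identical(nrow(ev), 0L)
})

test_that("events serialize through the annotation dialect", {
  e <- event_list(c(5, 100), c(60, 180))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_events(e, p)
  back <- read_annotations(p)
  expect_equal(back$start_s, e$start_s)
  expect_identical(back$label, rep("detected", 2L))
})
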