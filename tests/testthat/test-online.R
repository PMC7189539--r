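# The small model separates the small cohort's training subjects well enough
# to exercise the event logic; benchmark-grade accuracy is covered by the
# acceptance suite.

nc_trial <- function(subject = "S01", seed = 881) {
  ds <- small_dataset()
  prof <- ds$profiles[[subject]]
  simulate_trial(prof, "back_and_forth", comp_spec("NC", 0, "right"),
                 noise = ds$noise, seed = seed)
}

tlf_trial <- function(subject = "S01", seed = 882, magnitude = 0.9) {
  ds <- small_dataset()
  prof <- ds$profiles[[subject]]
  simulate_trial(prof, "back_and_forth", comp_spec("TLF", magnitude, "right"),
                 noise = ds$noise, seed = seed)
}

test_that("stream_config validates its invariants", {
  expect_error(stream_config(window_len = 0), "window_len")
  expect_error(stream_config(stride = 60, window_len = 50), "stride")
  expect_error(stream_config(smoothing_k = 0), "smoothing_k")
  cfgd <- stream_config()
  expect_equal(cfgd$window_len, 50L)
  expect_equal(cfgd$stride, 10L)
})

test_that("an all-NC stream emits zero events but yields decisions", {
  res <- detect_stream(nc_trial(), small_model())
  expect_length(res$events, 0L)
  expect_gt(nrow(res$decisions), 0L)
  expect_equal(res$decisions$time,
               seq(49, n_frames(nc_trial()) - 1, by = 10) / 50)
})

test_that("a sustained TLF stream after NC opens exactly one TLF event within the latency bound", {
  nc <- nc_trial()$frames
  tlf <- tlf_trial()$frames
  stream <- array(c(nc, tlf), dim = c(32, 32, dim(nc)[3] + dim(tlf)[3]))
  cfg <- stream_config()
  res <- detect_stream(stream, small_model(), cfg)
  tlf_events <- Filter(function(e) e$comp_class == "TLF", res$events)
  expect_length(tlf_events, 1L)
  t_change <- dim(nc)[3] / 50
  lag_bound <- (cfg$window_len +
                  (cfg$debounce_m - 1 + cfg$smoothing_k - 1) * cfg$stride) / 50
  expect_gt(tlf_events[[1]]$onset_time, t_change)
  expect_lte(tlf_events[[1]]$onset_time, t_change + lag_bound + 1e-9)
  expect_true(tlf_events[[1]]$peak_confidence > 0 &&
                tlf_events[[1]]$peak_confidence <= 1)
})

test_that("a single spurious non-NC decision is debounced away", {
  # force the decision series directly through the run logic by streaming a
  # short TLF burst (one window long) inside NC
  nc <- nc_trial()$frames
  burst <- tlf_trial()$frames[, , 1:10]
  stream <- array(c(nc[, , 1:100], burst, nc[, , 111:200]),
                  dim = c(32, 32, 200))
  res <- detect_stream(stream, small_model(), stream_config())
  expect_length(Filter(function(e) e$comp_class != "NC", res$events),
                length(res$events))  # no NC events ever
  expect_length(res$events, 0L)
})

test_that("detect_stream is identical to frame-by-frame detector_step", {
  trial <- tlf_trial()
  cfg <- stream_config(window_len = 30L, stride = 5L, smoothing_k = 3L,
                       debounce_m = 2L, close_m = 2L)
  batch <- detect_stream(trial, small_model(), cfg)
  state <- detector_new(small_model(), cfg, trial$sample_rate,
                        trial$affected_side)
  decs <- list()
  for (t in seq_len(n_frames(trial))) {
    out <- detector_step(state, trial$frames[, , t])
    state <- out$state
    if (!is.null(out$decision)) decs[[length(decs) + 1]] <- out$decision
  }
  manual_events <- seatcomp:::finalize_events(state)
  expect_identical(batch$events, manual_events)
  expect_identical(batch$decisions$raw,
                   vapply(decs, `[[`, character(1), "raw"))
  expect_identical(batch$decisions$smoothed,
                   vapply(decs, `[[`, character(1), "smoothed"))
})

test_that("stride = window_len with no smoothing reduces to batch prediction", {
  trial <- tlf_trial()
  cfg <- stream_config(window_len = 50L, stride = 50L, smoothing_k = 1L,
                       debounce_m = 1L, close_m = 1L)
  res <- detect_stream(trial, small_model(), cfg)
  nwin <- n_frames(trial) %/% 50
  expect_equal(nrow(res$decisions), nwin)
  direct <- vapply(seq_len(nwin), function(w) {
    win <- trial$frames[, , ((w - 1) * 50 + 1):(w * 50), drop = FALSE]
    fv <- extract_features(win, trial$affected_side)
    predict(small_model(), matrix(fv, 1, dimnames = list(NULL, names(fv))))
  }, character(1))
  expect_identical(res$decisions$raw, direct)
  expect_identical(res$decisions$smoothed, res$decisions$raw)
})

test_that("events are non-overlapping, time-ordered, never NC", {
  nc <- nc_trial()$frames
  tlf <- tlf_trial()$frames
  stream <- array(c(nc, tlf, nc, tlf),
                  dim = c(32, 32, 2 * (dim(nc)[3] + dim(tlf)[3])))
  res <- detect_stream(stream, small_model(), stream_config())
  evs <- res$events
  expect_gte(length(evs), 1L)
  for (e in evs) expect_true(e$comp_class %in% c("TR", "TLF", "SE"))
  closed <- Filter(function(e) !is.na(e$offset_time), evs)
  for (e in closed) expect_gt(e$offset_time, e$onset_time)
  if (length(evs) > 1) {
    onsets <- vapply(evs, `[[`, numeric(1), "onset_time")
    expect_true(all(diff(onsets) > 0))
    for (k in seq_len(length(evs) - 1)) {
      expect_lte(evs[[k]]$offset_time, evs[[k + 1]]$onset_time)
    }
  }
})

test_that("sequences shorter than the window are rejected", {
  expect_error(detect_stream(array(1, dim = c(32, 32, 20)), small_model(),
                             stream_config()), "shorter than window_len")
  st <- detector_new(small_model())
  expect_error(detector_step(st, matrix(-1, 32, 32)), "invalid frame")
})

test_that("emit_feedback writes one JSON line per event to any sink", {
  ev <- structure(list(comp_class = "TLF", onset_time = 1.2,
                       offset_time = 3.4, peak_confidence = 0.83),
                  class = "detection_event")
  path <- withr::local_tempfile(fileext = ".ndjson")
  file.create(path)
  emit_feedback(ev, path)
  emit_feedback(ev, path)
  lines <- readLines(path)
  expect_length(lines, 2L)
  parsed <- jsonlite::fromJSON(lines[1])
  expect_equal(parsed, list(class = "TLF", onset = 1.2, offset = 3.4,
                            confidence = 0.83))
  # open event serialises a null offset
  open_ev <- ev
  open_ev$offset_time <- NA_real_
  got <- NULL
  emit_feedback(open_ev, function(line) got <<- line)
  expect_match(got, '"offset":null')
  # failing sink: retried, then error
  calls <- 0L
  bad <- function(line) { calls <<- calls + 1L; stop("socket down") }
  expect_error(emit_feedback(ev, bad, n_retries = 3L), "after 3 attempts")
  expect_equal(calls, 3L)
})
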