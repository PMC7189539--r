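# Online sliding-window detector.
#
# Frames are buffered; every `stride` frames (once `window_len` frames have
# arrived) the trailing window is featurised and classified. Raw decisions
# are majority-smoothed over the last `smoothing_k` decisions (ties broken by
# the fixed class order, which favours NC and therefore no event). An event
# opens when a non-NC smoothed class persists for `debounce_m` consecutive
# decisions (onset = time of the first decision of that run) and closes after
# `close_m` consecutive NC decisions (offset = time of the first NC decision
# of the closing run). Events are never class NC, never overlap, and are
# time-ordered. Decision timestamps are the time of the window's last frame.

#' Streaming detector configuration
#'
#' Defaults bound detection latency to about 1.6 s at 50 Hz while suppressing
#' single-window flicker; all values are in frames/decisions.
#'
#' @param window_len Window length in frames (default 50 = 1 s at 50 Hz).
#' @param stride Frames between decisions (default 10).
#' @param smoothing_k Decisions in the majority vote (default 5).
#' @param debounce_m Consecutive non-NC decisions to open an event (default 3).
#' @param close_m Consecutive NC decisions to close an event (default 3).
#' @return A `stream_config` list.
#' @export
stream_config <- function(window_len = 50L, stride = 10L, smoothing_k = 5L,
                          debounce_m = 3L, close_m = 3L) {
  stopifnot(window_len >= 1, stride >= 1, stride <= window_len,
            smoothing_k >= 1, debounce_m >= 1, close_m >= 1)
  list(window_len = as.integer(window_len), stride = as.integer(stride),
       smoothing_k = as.integer(smoothing_k),
       debounce_m = as.integer(debounce_m), close_m = as.integer(close_m))
}

#' Create a streaming detector state
#'
#' @param model A trained `comp_model`.
#' @param config A [stream_config()].
#' @param sample_rate Stream rate in Hz (default 50).
#' @param affected_side Side passed to feature extraction for canonical
#'   mirroring.
#' @param mirror Canonical mirroring flag.
#' @return A detector state (plain list) for [detector_step()].
#' @export
detector_new <- function(model, config = stream_config(), sample_rate = 50,
                         affected_side = "right", mirror = TRUE) {
  if (!inherits(model, "comp_model")) stopf("a trained comp_model is required")
  list(model = model, config = config, rate = sample_rate,
       affected_side = affected_side, mirror = mirror,
       buffer = array(0, dim = c(GRID_DIM, GRID_DIM, config$window_len)),
       n_seen = 0L, raw = character(), conf = numeric(), times = numeric(),
       smoothed = character(),
       run_class = NA_character_, run_len = 0L, run_start = NA_real_,
       run_peak = 0, open_event = NULL, events = list())
}

majority_vote <- function(labels) {
  counts <- table(factor(labels, levels = comp_classes()))
  names(counts)[which.max(counts)]  # first max: tie-break by class order
}

#' Advance the detector by one frame
#'
#' @param state Detector state from [detector_new()] (or a previous step).
#' @param frame A 32x32 pressure frame.
#' @return List with elements `state` (updated), `decision` (`NULL`, or a
#'   list with `time`, `raw`, `smoothed`, `confidence` when a window was
#'   classified), and `event` (`NULL`, or the newly opened `detection_event`).
#' @export
detector_step <- function(state, frame) {
  if (is.null(state$model)) stopf("detector has no model loaded")
  err <- validate_frame(frame)
  if (length(err)) stopf("invalid frame: %s", err[1])

  w <- state$config$window_len
  state$n_seen <- state$n_seen + 1L
  slot <- ((state$n_seen - 1L) %% w) + 1L
  state$buffer[, , slot] <- frame

  decision <- NULL
  event <- NULL
  due <- state$n_seen >= w && (state$n_seen - w) %% state$config$stride == 0L
  if (due) {
    # chronological order of the ring buffer
    ord <- ((slot + seq_len(w) - 1L) %% w) + 1L
    window <- state$buffer[, , ord, drop = FALSE]
    feats <- extract_features(window, state$affected_side, state$mirror)
    pr <- predict(state$model, matrix(feats, 1,
                                      dimnames = list(NULL, names(feats))),
                  type = "confidence")
    tnow <- (state$n_seen - 1L) / state$rate
    state$raw <- c(state$raw, pr$class)
    state$conf <- c(state$conf, pr$confidence)
    state$times <- c(state$times, tnow)
    k <- state$config$smoothing_k
    sm <- majority_vote(tail(state$raw, k))
    state$smoothed <- c(state$smoothed, sm)

    if (identical(sm, state$run_class)) {
      state$run_len <- state$run_len + 1L
      state$run_peak <- max(state$run_peak, pr$confidence)
    } else {
      state$run_class <- sm
      state$run_len <- 1L
      state$run_start <- tnow
      state$run_peak <- pr$confidence
    }

    if (sm != "NC" && state$run_len == state$config$debounce_m) {
      if (!is.null(state$open_event) &&
          state$open_event$comp_class != sm) {
        # class switch: close the previous episode at the new run's start
        state$open_event$offset_time <- state$run_start
        state$events[[length(state$events) + 1L]] <- state$open_event
        state$open_event <- NULL
      }
      if (is.null(state$open_event)) {
        event <- structure(list(comp_class = sm,
                                onset_time = state$run_start,
                                offset_time = NA_real_,
                                peak_confidence = state$run_peak),
                           class = "detection_event")
        state$open_event <- event
      }
    }
    if (!is.null(state$open_event)) {
      if (sm == state$open_event$comp_class) {
        state$open_event$peak_confidence <-
          max(state$open_event$peak_confidence, pr$confidence)
      }
      if (sm == "NC" && state$run_len == state$config$close_m) {
        state$open_event$offset_time <- state$run_start
        state$events[[length(state$events) + 1L]] <- state$open_event
        state$open_event <- NULL
      }
    }
    decision <- list(time = tnow, raw = pr$class, smoothed = sm,
                     confidence = pr$confidence)
  }
  list(state = state, decision = decision, event = event)
}

finalize_events <- function(state) {
  ev <- state$events
  if (!is.null(state$open_event)) ev[[length(ev) + 1L]] <- state$open_event
  ev
}

#' Run the detector over a recorded frame sequence
#'
#' Literally folds [detector_step()] over the frames, so the result is
#' identical to feeding the stream frame by frame.
#'
#' @param frames A `32 x 32 x T` array, list of frames, or [labeled_trial()].
#' @param model A trained `comp_model`.
#' @param config A [stream_config()].
#' @param sample_rate Stream rate in Hz (taken from a trial input).
#' @param affected_side Side for canonical mirroring (taken from a trial).
#' @param mirror Canonical mirroring flag.
#' @return List with `events` (list of `detection_event`, still-open events
#'   have `offset_time = NA`) and `decisions` (data frame: `time, raw,
#'   smoothed, confidence`, one row per classified window).
#' @export
detect_stream <- function(frames, model, config = stream_config(),
                          sample_rate = 50, affected_side = "right",
                          mirror = TRUE) {
  if (inherits(frames, "labeled_trial")) {
    sample_rate <- frames$sample_rate
    affected_side <- frames$affected_side
    frames <- frames$frames
  }
  if (is.list(frames)) {
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(GRID_DIM, GRID_DIM, length(frames)))
  }
  nT <- dim(frames)[3]
  if (is.null(nT) || nT < config$window_len) {
    stopf("sequence has %d frames, shorter than window_len = %d",
          nT %||% 0L, config$window_len)
  }
  state <- detector_new(model, config, sample_rate, affected_side, mirror)
  decisions <- vector("list", nT)
  t_start <- proc.time()[[3]]
  for (t in seq_len(nT)) {
    res <- detector_step(state, frames[, , t])
    state <- res$state
    decisions[[t]] <- res$decision
  }
  elapsed <- proc.time()[[3]] - t_start
  decisions <- decisions[!vapply(decisions, is.null, logical(1))]
  # real-time budget: one decision must fit in a 20 ms frame slot at 50 Hz
  # (logged, not an error -- the contract is monitoring, not hard real time)
  if (length(decisions) && elapsed / length(decisions) > 0.020) {
    message(sprintf(
      "detect_stream: %.1f ms per decision exceeds the 20 ms frame budget",
      1000 * elapsed / length(decisions)))
  }
  dec_df <- data.frame(
    time = vapply(decisions, `[[`, numeric(1), "time"),
    raw = vapply(decisions, `[[`, character(1), "raw"),
    smoothed = vapply(decisions, `[[`, character(1), "smoothed"),
    confidence = vapply(decisions, `[[`, numeric(1), "confidence"),
    stringsAsFactors = FALSE)
  list(events = finalize_events(state), decisions = dec_df)
}

#' @export
print.detection_event <- function(x, ...) {
  off <- if (is.na(x$offset_time)) "open" else sprintf("%.2f s", x$offset_time)
  cat(sprintf("<detection_event> %s: onset %.2f s, offset %s, confidence %.2f\n",
              x$comp_class, x$onset_time, off, x$peak_confidence))
  invisible(x)
}

#' Emit a detection event to a feedback sink
#'
#' Serialises the event as one newline-delimited JSON message with fields
#' `class`, `onset`, `offset` (null while open) and `confidence`. The sink
#' may be a file path (appended), a writable connection, or a callback
#' function receiving the JSON line. Delivery is retried `n_retries` times
#' before erroring (at-least-once contract).
#'
#' @param event A `detection_event`.
#' @param sink File path, connection, or `function(line)`.
#' @param n_retries Attempts before giving up.
#' @return The JSON line, invisibly.
#' @export
emit_feedback <- function(event, sink, n_retries = 3L) {
  if (!inherits(event, "detection_event")) stopf("not a detection_event")
  line <- as.character(jsonlite::toJSON(list(
    class = event$comp_class, onset = event$onset_time,
    offset = if (is.na(event$offset_time)) NULL else event$offset_time,
    confidence = event$peak_confidence), auto_unbox = TRUE, null = "null",
    digits = NA))
  deliver <- function() {
    if (is.function(sink)) sink(line)
    else if (inherits(sink, "connection")) writeLines(line, sink)
    else if (is.character(sink)) cat(line, "\n", sep = "", file = sink,
                                     append = TRUE)
    else stopf("unsupported sink type")
  }
  last_err <- NULL
  for (a in seq_len(max(1L, n_retries))) {
    ok <- tryCatch({ deliver(); TRUE },
                   error = function(e) { last_err <<- e; FALSE })
    if (ok) return(invisible(line))
  }
  stopf("feedback sink unavailable after %d attempts: %s", n_retries,
        conditionMessage(last_err))
}
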