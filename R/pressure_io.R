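# Plain-text I/O for pressure-mattress frame streams.
#
# The vendor export layout of body-pressure measurement systems is not
# standardised, so the package defines its own documented ASCII dialect:
#
#   subject_id: S1
#   task: back_and_forth
#   label: TLF
#   sample_rate: 50
#   affected_side: right
#   <blank line>
#   <32 rows of 32 whitespace-separated numbers>   # frame 1
#   <blank line>
#   <32 rows ...>                                  # frame 2, ...
#
# Values are written with 17 significant digits so write/read round-trips are
# exact. Timestamps are not stored: acquisition is uniform-rate, so frame t
# (0-based) occurs at t / sample_rate seconds.
#
# Grid convention (inherited by every module): row index 0 is the anterior
# (front) edge of the seat, row 31 posterior; column 0 is at the sitter's
# left, column 31 at the sitter's right.

#' Construct a labeled pressure trial
#'
#' A trial is one reaching repetition: an ordered sequence of 32x32
#' non-negative pressure frames plus metadata. Frames are stored as a
#' `32 x 32 x T` array; timestamps are implicit (`(t-1)/sample_rate`).
#'
#' @param frames A `32 x 32 x T` numeric array, a single 32x32 matrix, or a
#'   list of 32x32 matrices.
#' @param subject_id Opaque subject identifier.
#' @param task One of [reach_tasks()].
#' @param label One of [comp_classes()].
#' @param sample_rate Sampling rate in Hz (default 50).
#' @param affected_side `"left"` or `"right"`.
#' @return An object of class `labeled_trial`.
#' @export
labeled_trial <- function(frames, subject_id, task, label,
                          sample_rate = 50, affected_side = "right") {
  if (is.list(frames)) {
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(GRID_DIM, GRID_DIM, length(frames)))
  } else if (is.matrix(frames)) {
    frames <- array(frames, dim = c(dim(frames), 1L))
  }
  trial <- structure(
    list(frames = frames, subject_id = as.character(subject_id),
         task = task, label = label, sample_rate = sample_rate,
         affected_side = affected_side),
    class = "labeled_trial")
  err <- validate_trial(trial)
  if (length(err)) stopf("invalid trial: %s", paste(err, collapse = "; "))
  trial
}

#' @rdname labeled_trial
#' @param trial A `labeled_trial`.
#' @export
n_frames <- function(trial) dim(trial$frames)[3]

#' @rdname labeled_trial
#' @export
trial_times <- function(trial) (seq_len(n_frames(trial)) - 1) / trial$sample_rate

#' @export
print.labeled_trial <- function(x, ...) {
  cat(sprintf(
    "<labeled_trial> subject %s | task %s | label %s | side %s | %d frames @ %g Hz\n",
    x$subject_id, x$task, x$label, x$affected_side, n_frames(x), x$sample_rate))
  invisible(x)
}

#' Validate a single pressure frame
#'
#' Total function returning a character vector of violations (empty when the
#' frame satisfies all invariants: 32x32 shape, finite, non-negative).
#' Violations name the offending cell as (row, col), 1-based.
#'
#' @param frame Numeric matrix.
#' @return Character vector of violation descriptions (empty if valid).
#' @export
validate_frame <- function(frame) {
  out <- character()
  if (!is.matrix(frame) || !is.numeric(frame)) {
    return("frame is not a numeric matrix")
  }
  if (!identical(dim(frame), c(GRID_DIM, GRID_DIM))) {
    return(sprintf("frame is %d x %d, expected 32 x 32",
                   nrow(frame), ncol(frame)))
  }
  bad <- which(!is.finite(frame), arr.ind = TRUE)
  for (k in seq_len(nrow(bad))) {
    out <- c(out, sprintf("non-finite value at (%d, %d)", bad[k, 1], bad[k, 2]))
  }
  neg <- which(is.finite(frame) & frame < 0, arr.ind = TRUE)
  for (k in seq_len(nrow(neg))) {
    out <- c(out, sprintf("negative value %g at (%d, %d)",
                          frame[neg[k, 1], neg[k, 2]], neg[k, 1], neg[k, 2]))
  }
  out
}

#' @rdname validate_frame
#' @param trial A `labeled_trial`.
#' @export
validate_trial <- function(trial) {
  out <- character()
  f <- trial$frames
  if (!is.array(f) || length(dim(f)) != 3 ||
      dim(f)[1] != GRID_DIM || dim(f)[2] != GRID_DIM) {
    out <- c(out, "frames must be a 32 x 32 x T array")
  } else {
    if (dim(f)[3] < 1) out <- c(out, "trial must contain at least one frame")
    if (anyNA(f) || any(!is.finite(f))) out <- c(out, "non-finite cell values")
    else if (any(f < 0)) out <- c(out, "negative cell values")
  }
  if (!is.numeric(trial$sample_rate) || trial$sample_rate <= 0) {
    out <- c(out, "sample_rate must be > 0")
  }
  if (!trial$label %in% comp_classes()) {
    out <- c(out, sprintf("unknown label '%s'", trial$label))
  }
  if (!trial$task %in% reach_tasks()) {
    out <- c(out, sprintf("unknown task '%s'", trial$task))
  }
  if (!trial$affected_side %in% SIDES) {
    out <- c(out, sprintf("unknown affected_side '%s'", trial$affected_side))
  }
  out
}

HEADER_KEYS <- c("subject_id", "task", "label", "sample_rate", "affected_side")

#' Read a pressure trial from its plain-text file
#'
#' Parses the dialect documented in this file's header. Metadata supplied via
#' `metadata` overrides values found in the file header.
#'
#' @param path Path to a trial file.
#' @param metadata Optional named list overriding header fields
#'   (`subject_id`, `task`, `label`, `sample_rate`, `affected_side`).
#' @return A [labeled_trial()].
#' @export
read_trial <- function(path, metadata = NULL) {
  if (!file.exists(path)) stopf("trial file does not exist: %s", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(trimws(lines) != "")
  if (!length(nonblank)) stopf("empty trial file: %s", path)

  meta <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") { i <- i + 1L; next }
    if (!grepl("^[A-Za-z_]+\\s*:", ln)) break
    kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    if (!key %in% HEADER_KEYS) {
      stopf("%s:%d: unknown header key '%s'", path, i, key)
    }
    meta[[key]] <- trimws(paste(kv[-1], collapse = ":"))
    i <- i + 1L
  }
  if (!is.null(meta$sample_rate)) meta$sample_rate <- as.numeric(meta$sample_rate)
  for (k in names(metadata)) meta[[k]] <- metadata[[k]]
  meta$sample_rate <- meta$sample_rate %||% 50
  meta$affected_side <- meta$affected_side %||% "right"

  frames <- list()
  rows <- list()
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") {
      if (length(rows)) {
        if (length(rows) != GRID_DIM) {
          stopf("%s:%d: frame block has %d rows, expected 32", path, i - 1L,
                length(rows))
        }
        frames[[length(frames) + 1L]] <- do.call(rbind, rows)
        rows <- list()
      }
      i <- i + 1L
      next
    }
    vals <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1]]))
    if (anyNA(vals)) stopf("%s:%d: non-numeric value in frame row", path, i)
    if (length(vals) != GRID_DIM) {
      stopf("%s:%d: frame row has %d values, expected 32", path, i,
            length(vals))
    }
    if (any(vals < 0)) stopf("%s:%d: negative pressure value", path, i)
    rows[[length(rows) + 1L]] <- vals
    i <- i + 1L
  }
  if (length(rows)) {
    if (length(rows) != GRID_DIM) {
      stopf("%s:%d: frame block has %d rows, expected 32", path,
            length(lines), length(rows))
    }
    frames[[length(frames) + 1L]] <- do.call(rbind, rows)
  }
  if (!length(frames)) stopf("no frame blocks found in %s", path)
  for (k in c("subject_id", "task", "label")) {
    if (is.null(meta[[k]])) stopf("missing metadata field '%s' for %s", k, path)
  }
  labeled_trial(frames, meta$subject_id, meta$task, meta$label,
                meta$sample_rate, meta$affected_side)
}

#' Write a pressure trial to a plain-text file
#'
#' Lossless: values are written with 17 significant digits, so
#' `read_trial(write_trial(t))` reproduces `t` cell-for-cell.
#'
#' @param trial A [labeled_trial()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  err <- validate_trial(trial)
  if (length(err)) stopf("refusing to write invalid trial: %s",
                         paste(err, collapse = "; "))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    paste0("subject_id: ", trial$subject_id),
    paste0("task: ", trial$task),
    paste0("label: ", trial$label),
    paste0("sample_rate: ", format(trial$sample_rate, digits = 17)),
    paste0("affected_side: ", trial$affected_side)), con)
  for (t in seq_len(n_frames(trial))) {
    writeLines("", con)
    fr <- trial$frames[, , t]
    writeLines(apply(fr, 1, function(r)
      paste(sprintf("%.17g", r), collapse = " ")), con)
  }
  invisible(path)
}

#' Read or write a dataset manifest
#'
#' A manifest is a CSV describing a set of trial files with columns
#' `path, subject_id, task, label, affected_side` (extra columns such as
#' `magnitude` are preserved).
#'
#' @param path Manifest CSV path.
#' @return `read_manifest`: a data.frame. `write_manifest`: `path` invisibly.
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("path", "subject_id", "task", "label", "affected_side")
  miss <- setdiff(need, names(m))
  if (length(miss)) stopf("manifest %s lacks columns: %s", path,
                          paste(miss, collapse = ", "))
  m
}

#' @rdname read_manifest
#' @param manifest Data frame as above.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
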