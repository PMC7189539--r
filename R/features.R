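# The ten window-level features.
#
# From each pressure frame we take the pressure-weighted centroid (centre of
# pressure, COP) and two half-grid load ratios; over a window (one reaching
# repetition for training, a sliding window online) we report:
#
#   ave_ssv       mean of all cell values over all frames (zeros included)
#   max_sv        maximum cell value in the window
#   ave/sd_ml_cop mean and SD of the medial/lateral (column) COP
#   ave/sd_ap_cop mean and SD of the anterior/posterior (row) COP
#   ave/sd_ml_ratio mean and SD of left-half / right-half load
#   ave/sd_ap_ratio mean and SD of anterior-half / posterior-half load
#
# COP coordinates are 0-based grid units (a point mass at matrix cell
# [6, 8] has COP (ml = 7, ap = 5)). Half-grid splits are at the symmetric
# 16/16 boundary. SDs use the population (N) denominator. Frames from
# left-affected subjects are column-mirrored before extraction (canonical
# mirroring) so "medial/lateral" is pose-invariant across affected sides;
# this can be disabled with `mirror = FALSE`.

#' Centre of pressure of one frame
#'
#' Pressure-weighted centroid in 0-based grid units:
#' `ml = sum(j * p_ij) / sum(p)`, `ap = sum(i * p_ij) / sum(p)`.
#'
#' @param frame 32x32 numeric matrix with positive total load.
#' @return Named vector `c(ml, ap)`, each in `[0, 31]`.
#' @export
frame_cop <- function(frame) {
  tot <- sum(frame)
  if (tot <= 0) stopf("degenerate frame: total pressure is not positive")
  idx <- 0:31
  c(ml = sum(colSums(frame) * idx) / tot,
    ap = sum(rowSums(frame) * idx) / tot)
}

#' Half-grid load ratios of one frame
#'
#' `ml_ratio` = load in columns 1..16 over load in columns 17..32 (after
#' canonical mirroring for left-affected subjects);
#' `ap_ratio` = load in rows 1..16 (anterior) over rows 17..32 (posterior).
#' Denominators are floored at `eps_frac` times the frame's peak value, so
#' the function is total; an all-zero frame returns `c(1, 1)`.
#'
#' @param frame 32x32 numeric matrix.
#' @param affected_side `"left"` or `"right"`.
#' @param eps_frac Denominator floor as a fraction of the frame peak.
#' @param mirror Apply canonical left-right mirroring (default `TRUE`).
#' @return Named vector `c(ml_ratio, ap_ratio)`.
#' @export
frame_ratios <- function(frame, affected_side = "right", eps_frac = 1e-9,
                         mirror = TRUE) {
  if (mirror && affected_side == "left") frame <- frame[, GRID_DIM:1]
  peak <- max(frame)
  if (peak <= 0) return(c(ml_ratio = 1, ap_ratio = 1))
  eps <- eps_frac * peak
  half <- GRID_DIM / 2
  left <- sum(frame[, 1:half]); right <- sum(frame[, (half + 1):GRID_DIM])
  ant <- sum(frame[1:half, ]); post <- sum(frame[(half + 1):GRID_DIM, ])
  c(ml_ratio = left / max(right, eps), ap_ratio = ant / max(post, eps))
}

#' Extract the ten features from a window of frames
#'
#' @param window A `32 x 32 x T` array, list of 32x32 matrices, or a
#'   [labeled_trial()] (whose frames and affected side are used).
#' @param affected_side `"left"` or `"right"`; frames of left-affected
#'   subjects are column-mirrored first (see `mirror`).
#' @param mirror Apply canonical left-right mirroring (default `TRUE`).
#' @return Named numeric vector of the ten features in fixed order
#'   ([feature_names()]).
#' @export
extract_features <- function(window, affected_side = "right", mirror = TRUE) {
  if (inherits(window, "labeled_trial")) {
    affected_side <- window$affected_side
    window <- window$frames
  }
  if (is.list(window)) {
    if (!length(window)) stopf("degenerate window: no frames")
    window <- array(unlist(window, use.names = FALSE),
                    dim = c(GRID_DIM, GRID_DIM, length(window)))
  }
  if (is.matrix(window)) window <- array(window, dim = c(dim(window), 1L))
  nT <- dim(window)[3]
  if (is.null(nT) || nT < 1) stopf("degenerate window: no frames")
  if (mirror && affected_side == "left") {
    window <- window[, GRID_DIM:1, , drop = FALSE]
  }

  m <- matrix(window, nrow = GRID_DIM * GRID_DIM, ncol = nT)
  tot <- colSums(m)
  if (all(tot <= 0)) stopf("degenerate window: every frame has zero load")

  idx <- 0:31
  half <- GRID_DIM / 2
  # per-frame row/column marginals via index grouping on the flat matrix
  colgrp <- rep(idx, each = GRID_DIM)            # column coordinate per cell
  rowgrp <- rep(idx, times = GRID_DIM)           # row coordinate per cell
  ml_num <- colSums(m * colgrp)
  ap_num <- colSums(m * rowgrp)
  left <- colSums(m[colgrp < half, , drop = FALSE])
  right <- colSums(m[colgrp >= half, , drop = FALSE])
  ant <- colSums(m[rowgrp < half, , drop = FALSE])
  post <- colSums(m[rowgrp >= half, , drop = FALSE])

  ok <- tot > 0  # zero-load frames excluded from COP/ratio series
  peak <- apply(m[, ok, drop = FALSE], 2, max)
  eps <- 1e-9 * peak
  ml_cop <- ml_num[ok] / tot[ok]
  ap_cop <- ap_num[ok] / tot[ok]
  ml_ratio <- left[ok] / pmax(right[ok], eps)
  ap_ratio <- ant[ok] / pmax(post[ok], eps)

  sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
  out <- c(mean(m), max(m),
           mean(ml_cop), sd_pop(ml_cop), mean(ap_cop), sd_pop(ap_cop),
           mean(ml_ratio), sd_pop(ml_ratio), mean(ap_ratio), sd_pop(ap_ratio))
  names(out) <- feature_names()
  out
}

#' Feature table for a simulated dataset or a manifest of trial files
#'
#' Computes the ten features for every trial, one row per trial, prefixed by
#' the trial metadata. For datasets simulated with `keep_frames = FALSE`,
#' trials are regenerated one at a time, so memory stays flat.
#'
#' @param ds A `sim_dataset` from [simulate_dataset()], or a manifest
#'   data.frame (with a `path` column) plus `dir`.
#' @param mirror Canonical mirroring flag passed to [extract_features()].
#' @param dir Directory for manifest paths (manifest input only).
#' @return Data frame: `subject_id, task, label, affected_side, magnitude`
#'   (when known) plus the ten feature columns.
#' @export
dataset_features <- function(ds, mirror = TRUE, dir = NULL) {
  if (inherits(ds, "sim_dataset")) {
    man <- ds$manifest
    get_trial <- function(k) dataset_trial(ds, k)
  } else {
    man <- ds
    get_trial <- function(k) {
      read_trial(file.path(dir %||% ".", man$path[k]))
    }
  }
  n <- nrow(man)
  feats <- matrix(NA_real_, n, length(feature_names()),
                  dimnames = list(NULL, feature_names()))
  for (k in seq_len(n)) {
    feats[k, ] <- extract_features(get_trial(k), mirror = mirror)
  }
  keep <- intersect(c("subject_id", "task", "label", "affected_side",
                      "magnitude"), names(man))
  cbind(man[, keep, drop = FALSE], as.data.frame(feats))
}

#' Window-sampled feature table for training an online model
#'
#' The streaming detector classifies sliding windows, whose temporal-SD
#' features differ systematically from whole-trial features (a reach cycle's
#' sway contributes fully to a trial's SD but only partially to a 1 s
#' window). A model meant for streaming should therefore be trained on
#' window-level features: this samples `n_windows` uniformly-placed
#' `window_len`-frame windows per trial (deterministically from `seed`) and
#' extracts the ten features from each.
#'
#' @param ds A `sim_dataset`.
#' @param window_len Window length in frames (default 50, matching
#'   [stream_config()]).
#' @param n_windows Windows sampled per trial.
#' @param seed Integer seed for the window placements.
#' @param subjects Optional subject filter.
#' @param mirror Canonical mirroring flag.
#' @return Data frame like [dataset_features()], one row per sampled window.
#' @export
sample_window_features <- function(ds, window_len = 50L, n_windows = 2L,
                                   seed = 1L, subjects = NULL,
                                   mirror = TRUE) {
  man <- ds$manifest
  rows <- if (is.null(subjects)) seq_len(nrow(man)) else
    which(man$subject_id %in% subjects)
  out <- vector("list", length(rows))
  for (idx in seq_along(rows)) {
    k <- rows[idx]
    trial <- dataset_trial(ds, k)
    nT <- n_frames(trial)
    if (nT < window_len) {
      stopf("trial %d has %d frames, shorter than window_len", k, nT)
    }
    starts <- with_seed(derive_seed(seed, "winoff", k),
                        sample.int(nT - window_len + 1L, n_windows,
                                   replace = TRUE))
    feats <- t(vapply(starts, function(s) {
      extract_features(trial$frames[, , s:(s + window_len - 1L),
                                    drop = FALSE],
                       trial$affected_side, mirror)
    }, numeric(length(feature_names()))))
    keep <- intersect(c("subject_id", "task", "label", "affected_side",
                        "magnitude"), names(man))
    out[[idx]] <- cbind(man[rep(k, n_windows), keep, drop = FALSE],
                        as.data.frame(feats))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a feature table as CSV
#'
#' Columns: metadata first, then the ten features in fixed order.
#'
#' @param features Data frame from [dataset_features()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}
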