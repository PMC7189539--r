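# Synthetic seated-pressure simulator.
#
# A sitter's pressure map is modelled as the sum of four anisotropic Gaussian
# blobs on the 32x32 grid: two ischial-tuberosity lobes (posterior, dominant)
# and two thigh lobes (anterior, lighter). Reaching modulates the blob centres
# with a sinusoidal centre-of-pressure excursion whose axis depends on the
# task; compensatory motion classes superimpose their signatures:
#
#   TLF  all blob centres translate anteriorly and load shifts from the
#        ischial to the thigh lobes;
#   TR   load shifts from the affected-side pair to the opposite pair plus a
#        lateral centre-of-pressure translation toward the unaffected side;
#   SE   the affected-side thigh lobe unloads and the affected-side pair gains
#        frame-to-frame amplitude jitter (raising temporal-SD features).
#
# Every frame is rescaled to the subject's weight (within a small jitter), so
# total load is conserved; sensor noise (multiplicative, additive, dropout) is
# applied last and values are clipped at zero. All parameter defaults live in
# inst/extdata/simulator-config.json, not in code.

#' Default simulator configuration
#'
#' Reads the packaged configuration file and applies optional overrides
#' (recursively, via [utils::modifyList()]).
#'
#' @param overrides Named list of overrides with the same structure.
#' @return Configuration list.
#' @export
default_sim_config <- function(overrides = NULL) {
  path <- system.file("extdata", "simulator-config.json", package = "seatcomp")
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(overrides)) cfg <- utils::modifyList(cfg, overrides)
  cfg
}

#' Compensation and noise specifications
#'
#' `comp_spec` states which motion class a trial exhibits, how strongly
#' (`magnitude` in `[0, 1]`, 0 = indistinguishable from NC), and which arm is
#' paretic. `noise_spec` states sensor-noise levels: a multiplicative
#' fractional SD per cell, an additive SD (absolute sensor units, or as a
#' fraction of the trial's peak value when `additive_sd` is `NULL`), and a
#' per-cell dropout probability.
#'
#' @param comp_class One of [comp_classes()].
#' @param magnitude Scalar in `[0, 1]`.
#' @param affected_side `"left"` or `"right"`.
#' @return A `comp_spec` / `noise_spec` list.
#' @export
comp_spec <- function(comp_class, magnitude = 1, affected_side = "right") {
  if (!comp_class %in% comp_classes()) stopf("unknown class '%s'", comp_class)
  if (!affected_side %in% SIDES) stopf("unknown side '%s'", affected_side)
  if (!is.numeric(magnitude) || magnitude < 0 || magnitude > 1) {
    stopf("magnitude must be in [0, 1]")
  }
  list(comp_class = comp_class, magnitude = magnitude,
       affected_side = affected_side)
}

#' @rdname comp_spec
#' @param multiplicative_sd Fractional SD of per-cell multiplicative noise.
#' @param additive_sd Absolute additive noise SD (sensor units), or `NULL` to
#'   use `additive_sd_frac_peak` times the trial's noise-free peak.
#' @param dropout_prob Per-cell, per-frame probability of a dead reading.
#' @param additive_sd_frac_peak Additive SD as a fraction of trial peak.
#' @export
noise_spec <- function(multiplicative_sd = 0.05, additive_sd = NULL,
                       dropout_prob = 0.005, additive_sd_frac_peak = 0.01) {
  stopifnot(multiplicative_sd >= 0, dropout_prob >= 0, dropout_prob < 1,
            additive_sd_frac_peak >= 0, is.null(additive_sd) || additive_sd >= 0)
  list(multiplicative_sd = multiplicative_sd, additive_sd = additive_sd,
       dropout_prob = dropout_prob,
       additive_sd_frac_peak = additive_sd_frac_peak)
}

#' @rdname comp_spec
#' @export
no_noise <- function() noise_spec(0, 0, 0, 0)

check_range <- function(r, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(r) || length(r) != 2 || anyNA(r) || r[1] > r[2] ||
      r[1] < lo || r[2] > hi) {
    stopf("infeasible range for %s: [%s]", name, paste(r, collapse = ", "))
  }
  r
}

#' Draw a synthetic subject profile
#'
#' Deterministic function of `(population_params, seed)`: draws blob
#' positions, amplitudes, widths and body weight uniformly from the stated
#' population ranges. Blob order is fixed: thigh-left, thigh-right,
#' ischial-left, ischial-right. Left/right pairs are mirror-symmetric about
#' column 15.5 up to a per-blob jitter of at most `col_jitter` columns.
#'
#' @param population_params List of ranges as in
#'   `default_sim_config()$population`.
#' @param seed Integer seed.
#' @param subject_id Identifier stored in the profile.
#' @return A `subject_profile` list.
#' @export
make_subject <- function(population_params, seed, subject_id = "S1") {
  p <- population_params
  check_range(p$ischial_row, "ischial_row", 0, 31)
  check_range(p$thigh_row, "thigh_row", 0, 31)
  check_range(p$ischial_halfwidth, "ischial_halfwidth", 0, 14)
  check_range(p$thigh_halfwidth, "thigh_halfwidth", 0, 14)
  check_range(p$ischial_amplitude, "ischial_amplitude", 1e-12)
  check_range(p$thigh_amplitude, "thigh_amplitude", 1e-12)
  check_range(p$ischial_sigma, "ischial_sigma", 1e-12)
  check_range(p$thigh_sigma, "thigh_sigma", 1e-12)
  check_range(p$weight_scale, "weight_scale", 1e-12)
  jit <- p$col_jitter %||% 1
  if (jit < 0 || max(p$ischial_halfwidth, p$thigh_halfwidth) + jit > 15.5) {
    stopf("halfwidth + col_jitter must keep blob columns inside the grid")
  }

  with_seed(seed, {
    isch_row <- runif(1, p$ischial_row[1], p$ischial_row[2])
    thigh_row <- runif(1, p$thigh_row[1], p$thigh_row[2])
    hw_i <- runif(1, p$ischial_halfwidth[1], p$ischial_halfwidth[2])
    hw_t <- runif(1, p$thigh_halfwidth[1], p$thigh_halfwidth[2])
    cjit <- runif(4, -jit, jit)
    # one mean amplitude per pair plus a small lateral asymmetry: healthy
    # seated load asymmetry is modest, and class signatures (which
    # redistribute load between pairs or sides) must dominate anatomy
    asym <- p$side_asymmetry %||% 0.05
    amp_t0 <- runif(1, p$thigh_amplitude[1], p$thigh_amplitude[2])
    amp_i0 <- runif(1, p$ischial_amplitude[1], p$ischial_amplitude[2])
    asym_t <- runif(1, -asym, asym)
    asym_i <- runif(1, -asym, asym)
    amp_t <- amp_t0 * c(1 + asym_t, 1 - asym_t)
    amp_i <- amp_i0 * c(1 + asym_i, 1 - asym_i)
    sig_t <- runif(1, p$thigh_sigma[1], p$thigh_sigma[2])
    sig_i <- runif(1, p$ischial_sigma[1], p$ischial_sigma[2])
    weight <- runif(1, p$weight_scale[1], p$weight_scale[2])

    centers <- rbind(
      c(thigh_row, 15.5 - hw_t + cjit[1]),  # thigh left
      c(thigh_row, 15.5 + hw_t + cjit[2]),  # thigh right
      c(isch_row, 15.5 - hw_i + cjit[3]),   # ischial left
      c(isch_row, 15.5 + hw_i + cjit[4]))   # ischial right
    dimnames(centers) <- list(
      c("thigh_L", "thigh_R", "isch_L", "isch_R"), c("row", "col"))
    structure(list(
      subject_id = subject_id,
      blob_centers = centers,
      blob_amplitudes = c(amp_t, amp_i),
      blob_widths = c(sig_t, sig_t, sig_i, sig_i),
      blob_types = c("thigh", "thigh", "ischial", "ischial"),
      weight_scale = weight,
      seed = seed), class = "subject_profile")
  })
}

#' Mirror a subject profile left-right
#'
#' Reflects blob columns about the grid midline and swaps the left/right
#' members of each pair, so that simulating the mirrored profile with the
#' opposite `affected_side` (same seeds, no sensor noise) produces exactly the
#' column-reversed frames of the original simulation.
#'
#' @param profile A `subject_profile`.
#' @return The mirrored `subject_profile`.
#' @export
mirror_profile <- function(profile) {
  swap <- c(2L, 1L, 4L, 3L)
  p <- profile
  p$blob_centers <- profile$blob_centers[swap, , drop = FALSE]
  p$blob_centers[, "col"] <- 31 - p$blob_centers[, "col"]
  rownames(p$blob_centers) <- rownames(profile$blob_centers)
  p$blob_amplitudes <- profile$blob_amplitudes[swap]
  p$blob_widths <- profile$blob_widths[swap]
  p
}

# blob side by construction: odd indices left, even indices right
BLOB_SIDE <- c("left", "right", "left", "right")

#' Simulate one labeled reaching trial
#'
#' Generates a 50 Hz frame sequence for one reaching repetition. The
#' class signature is applied noise-free, every frame is rescaled to
#' `weight_scale * (1 + load_jitter * u_t)` (load conservation), then sensor
#' noise is added and values clipped at zero. With `magnitude = 0` and equal
#' seeds, every class reproduces the NC frames exactly.
#'
#' @param profile A `subject_profile` from [make_subject()].
#' @param task One of [reach_tasks()].
#' @param spec A [comp_spec()].
#' @param noise A [noise_spec()]; use [no_noise()] for the noise-free model.
#' @param duration_s Trial duration in seconds (default from config).
#' @param seed Integer seed for the trial's random streams.
#' @param config Simulator configuration ([default_sim_config()]).
#' @return A [labeled_trial()].
#' @export
simulate_trial <- function(profile, task, spec, noise = noise_spec(),
                           duration_s = NULL, seed = 1,
                           config = default_sim_config()) {
  if (!task %in% reach_tasks()) stopf("unknown task '%s'", task)
  if (!spec$comp_class %in% comp_classes()) {
    stopf("unknown class '%s'", spec$comp_class)
  }
  duration_s <- duration_s %||% config$duration_s
  if (duration_s <= 0) stopf("duration_s must be > 0")
  rate <- 50
  nT <- max(1L, as.integer(round(duration_s * rate)))
  tvec <- (seq_len(nT) - 1) / rate
  phase <- 2 * pi * tvec / config$reach$period_s

  side <- spec$affected_side
  mag <- spec$magnitude
  cls <- spec$comp_class
  s_dir <- if (side == "left") 1 else -1  # lateral positive = toward unaffected side
  eff <- config$effects
  exc <- config$reach$excursion[[task]]

  # deterministic per-frame streams, drawn identically for every class so a
  # magnitude-0 trial matches NC frame-for-frame under the same seed
  cyc <- with_seed(derive_seed(seed, "cycle"), {
    list(z = rnorm(nT), u = runif(nT, -1, 1))
  })

  load_fac <- rep(1, 4)
  shift_row <- 0
  shift_col <- 0
  if (cls == "TLF") {
    load_fac <- ifelse(profile$blob_types == "ischial",
                       1 - mag * eff$rho_tlf, 1 + mag * eff$rho_tlf)
    shift_row <- -mag * eff$delta_ap_max  # anterior = toward row 0
  } else if (cls == "TR") {
    load_fac <- ifelse(BLOB_SIDE == side,
                       1 - mag * eff$rho_tr, 1 + mag * eff$rho_tr)
    shift_col <- s_dir * mag * eff$delta_ml_max
  } else if (cls == "SE") {
    load_fac[BLOB_SIDE == side & profile$blob_types == "thigh"] <-
      1 - mag * eff$rho_se
  }
  jit_coef <- if (cls == "SE") mag * eff$sigma_se else 0
  ipsi <- BLOB_SIDE == side

  row_exc <- exc$ap * sin(phase)
  col_exc <- s_dir * exc$ml * sin(phase)
  target <- profile$weight_scale * (1 + config$load_jitter * cyc$u)

  rows31 <- 0:31
  asp <- ifelse(profile$blob_types == "ischial",
                config$blob_aspect$ischial, config$blob_aspect$thigh)
  sig_row <- profile$blob_widths * asp
  sig_col <- profile$blob_widths
  base_amp <- profile$blob_amplitudes * load_fac

  frames <- array(0, dim = c(GRID_DIM, GRID_DIM, nT))
  for (t in seq_len(nT)) {
    r0 <- profile$blob_centers[, "row"] + shift_row + row_exc[t]
    c0 <- profile$blob_centers[, "col"] + shift_col + col_exc[t]
    amp <- base_amp
    if (jit_coef > 0) {
      amp[ipsi] <- amp[ipsi] * max(1 + jit_coef * cyc$z[t], 0.05)
    }
    er <- exp(-sweep(outer(rows31, r0, "-")^2, 2, 2 * sig_row^2, "/"))
    ec <- exp(-sweep(outer(rows31, c0, "-")^2, 2, 2 * sig_col^2, "/"))
    fr <- er %*% (t(ec) * amp)
    frames[, , t] <- fr * (target[t] / sum(fr))
  }

  has_noise <- noise$multiplicative_sd > 0 || noise$dropout_prob > 0 ||
    (!is.null(noise$additive_sd) && noise$additive_sd > 0) ||
    (is.null(noise$additive_sd) && noise$additive_sd_frac_peak > 0)
  if (has_noise) {
    add_sd <- noise$additive_sd %||% (noise$additive_sd_frac_peak * max(frames))
    ncell <- length(frames)
    frames <- with_seed(derive_seed(seed, "noise"), {
      f <- frames * (1 + noise$multiplicative_sd * rnorm(ncell)) +
        add_sd * rnorm(ncell)
      keep <- runif(ncell) >= noise$dropout_prob
      array(pmax(f, 0) * keep, dim = dim(frames))
    })
  }

  labeled_trial(frames, profile$subject_id, task, cls, rate, side)
}

#' Simulate a labeled cohort
#'
#' Generates `n_subjects x 3 tasks x 4 classes x reps_per_cell` trials with
#' per-subject profiles and affected sides, compensation magnitudes drawn
#' uniformly from `config$magnitude_range` for non-NC trials (NC trials have
#' magnitude 0), and fully reproducible sub-seeding from one master seed.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param reps_per_cell Repetitions per subject x task x class cell (>= 1).
#' @param config Simulator configuration.
#' @param seed Master seed.
#' @param noise A [noise_spec()] (default: levels from `config$noise`).
#' @param keep_frames Keep frame arrays in memory (`TRUE`), or store only the
#'   manifest and regenerate trials on demand via [dataset_trial()] (`FALSE`,
#'   recommended for large cohorts).
#' @param out_dir Optional directory: write each trial file plus
#'   `manifest.csv` in the plain-text dialect.
#' @return A `sim_dataset`: list with `manifest` (data.frame), `trials`
#'   (list of [labeled_trial()] or `NULL`), `profiles`, `config`, `noise`,
#'   `seed`.
#' @export
simulate_dataset <- function(n_subjects, reps_per_cell,
                             config = default_sim_config(), seed = 1,
                             noise = NULL, keep_frames = TRUE,
                             out_dir = NULL) {
  if (n_subjects < 2) stopf("n_subjects must be >= 2")
  if (reps_per_cell < 1) stopf("reps_per_cell must be >= 1")
  noise <- noise %||% noise_spec(
    multiplicative_sd = config$noise$multiplicative_sd,
    dropout_prob = config$noise$dropout_prob,
    additive_sd_frac_peak = config$noise$additive_sd_frac_peak)

  ids <- sprintf("S%02d", seq_len(n_subjects))
  profiles <- lapply(seq_len(n_subjects), function(i) {
    make_subject(config$population, derive_seed(seed, "subject", i), ids[i])
  })
  names(profiles) <- ids
  sides <- vapply(seq_len(n_subjects), function(i) {
    with_seed(derive_seed(seed, "side", i), sample(SIDES, 1))
  }, character(1))

  grid <- expand.grid(rep = seq_len(reps_per_cell), label = comp_classes(),
                      task = reach_tasks(), subject = seq_len(n_subjects),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$subject, match(grid$task, reach_tasks()),
                     match(grid$label, comp_classes()), grid$rep), ]
  n <- nrow(grid)
  mags <- numeric(n)
  tseeds <- integer(n)
  for (k in seq_len(n)) {
    g <- grid[k, ]
    tseeds[k] <- derive_seed(seed, "trial", g$subject, g$task, g$label, g$rep)
    mags[k] <- if (g$label == "NC") 0 else {
      with_seed(derive_seed(seed, "mag", g$subject, g$task, g$label, g$rep),
                runif(1, config$magnitude_range[1], config$magnitude_range[2]))
    }
  }
  manifest <- data.frame(
    path = NA_character_, subject_id = ids[grid$subject], task = grid$task,
    label = grid$label, affected_side = sides[grid$subject],
    magnitude = mags, trial_seed = tseeds, rep = grid$rep,
    stringsAsFactors = FALSE)
  rownames(manifest) <- NULL

  ds <- structure(list(manifest = manifest, trials = NULL,
                       profiles = profiles, config = config, noise = noise,
                       seed = seed), class = "sim_dataset")
  if (keep_frames || !is.null(out_dir)) {
    trials <- vector("list", n)
    for (k in seq_len(n)) trials[[k]] <- dataset_trial(ds, k)
    if (keep_frames) ds$trials <- trials
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      for (k in seq_len(n)) {
        fn <- sprintf("%s_%s_%s_r%02d.txt", manifest$subject_id[k],
                      manifest$task[k], manifest$label[k], manifest$rep[k])
        write_trial(trials[[k]], file.path(out_dir, fn))
        ds$manifest$path[k] <- fn
      }
      write_manifest(ds$manifest, file.path(out_dir, "manifest.csv"))
    }
  }
  ds
}

#' Materialise one trial of a simulated dataset
#'
#' Returns trial `k` from memory when frames were kept, otherwise regenerates
#' it deterministically from the manifest's per-trial seed.
#'
#' @param ds A `sim_dataset`.
#' @param k Trial index (manifest row).
#' @return A [labeled_trial()].
#' @export
dataset_trial <- function(ds, k) {
  if (!is.null(ds$trials)) return(ds$trials[[k]])
  m <- ds$manifest[k, ]
  simulate_trial(ds$profiles[[m$subject_id]], m$task,
                 comp_spec(m$label, m$magnitude, m$affected_side),
                 noise = ds$noise, seed = m$trial_seed, config = ds$config)
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d trials, %d subjects, seed %d (frames %s)\n",
              nrow(x$manifest), length(x$profiles), x$seed,
              if (is.null(x$trials)) "on demand" else "in memory"))
  invisible(x)
}
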