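cfg <- default_sim_config()

test_that("make_subject is deterministic and honours degenerate ranges", {
  p1 <- make_subject(cfg$population, seed = 7, subject_id = "A")
  p2 <- make_subject(cfg$population, seed = 7, subject_id = "A")
  expect_identical(p1, p2)

  degen <- cfg$population
  degen$ischial_row <- c(20, 20)
  degen$ischial_halfwidth <- c(5, 5)
  degen$weight_scale <- c(600, 600)
  degen$col_jitter <- 0
  pd <- make_subject(degen, seed = 1)
  expect_equal(unname(pd$blob_centers["isch_L", ]), c(20, 10.5))
  expect_equal(unname(pd$blob_centers["isch_R", ]), c(20, 20.5))
  expect_equal(pd$weight_scale, 600)
})

test_that("distinct seeds give distinct blob centres (cohort diversity)", {
  profiles <- lapply(1:8, function(s) make_subject(cfg$population, seed = s))
  centers <- t(vapply(profiles, function(p) as.vector(p$blob_centers),
                      numeric(8)))
  expect_equal(nrow(unique(centers)), 8L)
  for (p in profiles) {
    cols <- p$blob_centers[, "col"]
    expect_true(all(p$blob_centers >= 0 & p$blob_centers <= 31))
    expect_lt(abs(cols["isch_L"] + cols["isch_R"] - 31), 4)
    expect_true(all(p$blob_amplitudes > 0) && all(p$blob_widths > 0))
  }
})

test_that("infeasible population ranges raise configuration errors", {
  bad <- cfg$population; bad$ischial_row <- c(22, 18)
  expect_error(make_subject(bad, 1), "infeasible")
  bad <- cfg$population; bad$thigh_row <- c(-2, 5)
  expect_error(make_subject(bad, 1), "infeasible")
  bad <- cfg$population; bad$ischial_halfwidth <- c(10, 13); bad$col_jitter <- 3
  expect_error(make_subject(bad, 1), "inside the grid")
})

prof <- make_subject(cfg$population, seed = 42, subject_id = "SIM")

test_that("magnitude 0 reproduces NC exactly, for every class and with noise", {
  for (cls in c("TR", "TLF", "SE")) {
    nc <- simulate_trial(prof, "side_to_side", comp_spec("NC", 0, "right"),
                         seed = 9)
    zz <- simulate_trial(prof, "side_to_side", comp_spec(cls, 0, "right"),
                         seed = 9)
    expect_identical(zz$frames, nc$frames)
  }
})

test_that("noise-free frame loads are conserved within weight_scale * (1 +/- 0.02)", {
  for (cls in comp_classes()) {
    tr <- simulate_trial(prof, "back_and_forth", comp_spec(cls, 0.8, "left"),
                         noise = no_noise(), seed = 3)
    sums <- apply(tr$frames, 3, sum)
    expect_true(all(sums >= prof$weight_scale * 0.98 - 1e-8))
    expect_true(all(sums <= prof$weight_scale * 1.02 + 1e-8))
  }
})

test_that("dose-response is monotone for TLF, TR and SE signatures", {
  mags <- c(0.2, 0.5, 0.8)
  nc <- extract_features(simulate_trial(prof, "up_and_down",
                                        comp_spec("NC", 0, "right"),
                                        noise = no_noise(), seed = 5))
  tlf <- vapply(mags, function(m) {
    extract_features(simulate_trial(prof, "up_and_down",
                                    comp_spec("TLF", m, "right"),
                                    noise = no_noise(), seed = 5))
  }, numeric(10))
  # anterior displacement: ap_cop decreases toward row 0, strictly with dose
  disp <- nc["ave_ap_cop"] - tlf["ave_ap_cop", ]
  expect_true(all(diff(disp) > 0) && all(disp > 0))

  tr <- vapply(mags, function(m) {
    extract_features(simulate_trial(prof, "up_and_down",
                                    comp_spec("TR", m, "right"),
                                    noise = no_noise(), seed = 5))
  }, numeric(10))
  ml_shift <- abs(tr["ave_ml_cop", ] - nc["ave_ml_cop"])
  expect_true(all(diff(ml_shift) > 0) && all(ml_shift > 0))

  # SE: ipsilateral (affected right -> canonical right half) load deficit
  se_ratio <- vapply(mags, function(m) {
    extract_features(simulate_trial(prof, "up_and_down",
                                    comp_spec("SE", m, "right"),
                                    noise = no_noise(), seed = 5))["ave_ml_ratio"]
  }, numeric(1))
  deficit <- se_ratio - nc["ave_ml_ratio"]
  expect_true(all(diff(deficit) > 0) && all(deficit > 0))
})

test_that("mirrored profile + flipped side yields mirrored frames (up to FP rounding)", {
  for (cls in comp_classes()) {
    a <- simulate_trial(prof, "side_to_side", comp_spec(cls, 0.7, "right"),
                        noise = no_noise(), seed = 13)
    b <- simulate_trial(mirror_profile(prof), "side_to_side",
                        comp_spec(cls, 0.7, "left"),
                        noise = no_noise(), seed = 13)
    # column reflection is algebraically exact; 31 - c0 rounds once, so
    # agreement is to floating-point precision, not bit identity
    expect_equal(b$frames, a$frames[, 32:1, , drop = FALSE],
                 tolerance = 1e-12)
  }
})

test_that("unknown class or task is a configuration error", {
  expect_error(comp_spec("XX", 0.5, "right"), "unknown class")
  expect_error(simulate_trial(prof, "diagonal", comp_spec("NC", 0)), "task")
  expect_error(simulate_trial(prof, "up_and_down", comp_spec("NC", 0),
                              duration_s = 0), "duration")
})

test_that("simulate_dataset layout, balance and determinism", {
  ds <- simulate_dataset(2, 1, seed = 77)
  expect_equal(nrow(ds$manifest), 24L)  # 2 x 3 x 4 x 1
  counts <- table(ds$manifest$subject_id, ds$manifest$label)
  expect_true(all(counts == 3L))  # balanced: 3 tasks x 1 rep per class
  expect_true(all(ds$manifest$magnitude[ds$manifest$label == "NC"] == 0))
  ms <- ds$manifest$magnitude[ds$manifest$label != "NC"]
  expect_true(all(ms >= cfg$magnitude_range[1] & ms <= cfg$magnitude_range[2]))

  ds2 <- simulate_dataset(2, 1, seed = 77)
  expect_identical(ds$manifest, ds2$manifest)
  expect_identical(ds$trials[[7]]$frames, ds2$trials[[7]]$frames)
  expect_error(simulate_dataset(1, 1), "n_subjects")
  expect_error(simulate_dataset(2, 0), "reps_per_cell")
})

test_that("on-demand regeneration matches in-memory trials", {
  ds_mem <- simulate_dataset(2, 1, seed = 31, keep_frames = TRUE)
  ds_lazy <- simulate_dataset(2, 1, seed = 31, keep_frames = FALSE)
  expect_null(ds_lazy$trials)
  for (k in c(1L, 10L, 24L)) {
    expect_identical(dataset_trial(ds_lazy, k)$frames, ds_mem$trials[[k]]$frames)
  }
})
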