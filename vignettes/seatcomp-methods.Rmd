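---
title: "Detecting compensatory motions from seat pressure: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting compensatory motions from seat pressure: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

After a stroke, reaching with the paretic arm is often accomplished by
recruiting the trunk or shoulder girdle instead of the arm itself: excessive
trunk rotation (TR), trunk lean-forward (TLF), or shoulder elevation (SE).
These compensations help in the moment but reinforce non-optimal motor
patterns, so unsupervised therapy benefits from a system that notices them
and triggers feedback. A pressure mattress on the seat is an attractive
sensor: compensations move the trunk, the trunk carries most of the seated
load, and the seat pressure map changes in characteristic ways — without
cameras or body-worn sensors.

`seatcomp` implements the full pipeline: pressure-frame I/O, a synthetic
seated-pressure simulator, ten-feature extraction, an RBF-kernel SVM
evaluated by leave-one-subject-out (LOSO) cross-validation, and an online
sliding-window detector that emits debounced compensation events.

## Coordinate and labeling conventions

Frames are 32 x 32 non-negative grids at 50 Hz. Row 0 is the anterior
(front) edge of the seat, column 0 the sitter's left. Four motion classes
(NC = noncompensation, TR, TLF, SE) and three reaching tasks
(back-and-forth, side-to-side, up-and-down) label whole trials; one trial is
one reaching repetition. Frames from left-affected subjects are
column-mirrored before feature extraction ("canonical mirroring"), so
"toward the affected side" is a fixed direction in feature space and left-
and right-affected subjects can be pooled; the flag is switchable off.

## The ten features

Per frame we compute the pressure-weighted centroid (centre of pressure,
COP; medial/lateral = column coordinate, anterior/posterior = row
coordinate, both 0-based) and two half-grid load ratios at the symmetric
16/16 split (left/right and anterior/posterior). Over a window these yield
ten features in fixed order: `ave_ssv` (mean over all cells and frames,
zeros included), `max_sv`, and mean/SD of each of the four per-frame series.
SDs use the population (N) denominator — the choice is arbitrary but fixed
for determinism. Zero-load frames are excluded from the COP/ratio series
(the centroid is undefined there) but still count in `ave_ssv`. Ratio
denominators are floored at `1e-9` times the frame peak, making the ratios
total functions.

For training and LOSO evaluation the window is the whole trial; the online
detector uses sliding windows (below). Whether the original acquisition
summarised per repetition or per fixed window is not documented anywhere we
could find; both are supported, with the trial window as the default.

## The simulator: a stated world

No recorded patient data ships with this package; every claim is exercised
against a generative model whose parameters live in
`inst/extdata/simulator-config.json`, not in code.

A sitter is four axis-aligned anisotropic Gaussian blobs: two ischial
lobes (posterior, dominant — they produce the familiar two-lobed buttock
pattern) and two thigh lobes (anterior, lighter, elongated along the
thigh axis). Reaching modulates blob centres sinusoidally (period 4 s) along
a task-specific axis. Class signatures, applied noise-free and before
rescaling:

* **TLF** — all centres translate anteriorly by `magnitude * 6` rows and a
  fraction `magnitude * 0.5` of load shifts from ischial to thigh lobes
  (leaning forward rolls load onto the thighs).
* **TR** — load shifts by `magnitude * 0.5` from the affected-side pair to
  the opposite pair, plus a lateral COP translation of `magnitude * 5`
  columns toward the unaffected side (rotating the trunk to advance the
  paretic shoulder unloads that side).
* **SE** — the affected-side thigh lobe loses `magnitude * 0.35` of its
  amplitude and the affected-side pair gains iid per-frame amplitude jitter
  with SD `magnitude * 0.15`, raising the temporal-SD features with only a
  small mean shift. Real shoulder elevation's seat-pressure signature is
  unreported anywhere; this signature is an assumption of the synthetic
  world, clearly flagged as such.

Every frame is then rescaled to the subject's weight times `1 ± 0.02`
(load conservation — a sitter's mass does not change mid-reach), and sensor
noise is applied last: 5% multiplicative, additive with SD 1% of the trial
peak, 0.5% per-cell dropout, clipped at zero. With `magnitude = 0` and equal
seeds every class reproduces the NC frames exactly, which anchors the
dose-response and mirror-symmetry property tests.

### Choosing the population ranges: an identifiability bound

The simulator must satisfy a stated invariant: the four classes are
separable by the ten features at `magnitude >= 0.4` under default noise.
The class effect sizes are fixed (above), so this invariant is a
*constraint on the admissible between-subject variability*, and it can be
derived rather than tuned:

> a decision boundary shared across subjects exists only if each class's
> weakest effect (at the magnitude floor 0.4) exceeds the **full
> between-subject range** of its primary feature's NC baseline — not merely
> a multiple of its SD, because a uniform-drawn cohort realises its
> extremes.

Working the channels at magnitude 0.4:

| channel | minimum effect | baseline range budget |
|---|---|---|
| `ave_ap_ratio` (TLF) | factor 1.5 (load shift 0.8x/1.2x) | thigh:ischial share 43-47 : 95-105 → factor 1.2 |
| `ave_ap_cop` (TLF) | 2.4 rows + load-shift | row ranges ±0.5/±1 → < 1 row |
| `ave_ml_cop`, `ave_ml_ratio` (TR) | 2 columns; factor 1.5 | col jitter ±0.3 → ≪ effect |
| `ave_ml_ratio` (SE) | +4.5% | asymmetry ±1% + col jitter → ~±2.5% |
| `sd_ml_ratio` (SE) | ≈ 0.06 | NC sway ≤ 0.3 col → ≤ ~0.03 |

Two of our own early drafts violated this bound and the benchmark caught
them: independently drawn left/right amplitudes (up to 1.5x lateral
imbalance) buried SE, and a wide thigh-amplitude range (30-60) let one
subject's neutral anatomy sit beyond other subjects' TLF. The NC lateral
sway amplitude matters too: with the arm carried by a rehabilitation robot,
non-compensatory reaching moves the seat COP laterally by well under a
centimetre, so sway is 0.3 columns (side-to-side) and 0.15 (up-and-down);
anterior sway in back-and-forth reaching is 1.2 rows, which collides with
nothing (no class discriminates on A/P temporal SD).

The consequence is stated plainly: **this cohort is deliberately
low-variance.** Between subjects, blob geometry (halfwidths, widths,
weight, small position and balance jitter) still varies — enough for LOSO
to be a real test of transfer — but a green benchmark establishes that the
*pipeline* separates the *stated* signatures under the *stated* variability.
It says nothing about real patient anatomies, spasticity, cushions, or
shifting sitting posture, and the SE signature itself is invented.

## Classifier

Features are min-max normalised to [0, 1] with parameters learned from
training folds only (the scale-stabilising choice recommended for RBF
kernels); values outside the training range are not clipped; constant
features map to 0.5. The multiclass scheme is one-vs-one voting over the six
class pairs with ties broken by the fixed order NC < TR < TLF < SE. The
binary machines are soft-margin C-SVCs solved by an SMO solver implemented
in C++ (second-order working-set selection, KKT-gap stopping at 1e-3) —
no SVM library is assumed present. Training rows are shuffled with the
supplied seed before fitting; the fit itself is deterministic.

Hyperparameters are searched over powers of two, `C` in `2^-3..2^7` and
`gamma` in `2^-7..2^3` with the customary exponent step of 2. Two selection
choices deserve their rationale:

* **Grouped inner CV.** When subject ids are available (always, in the LOSO
  and benchmark paths), inner CV folds hold out whole subjects — with eight
  or fewer training subjects, exactly one subject per fold, which is
  deterministic. Class-stratified subject-mixed folds were tried first and
  selected `(C = 128, gamma = 2)` with an inner estimate of 1.000 that
  collapsed on held-out subjects: they reward memorising subject identity,
  which is precisely what a LOSO deployment must not do.
* **One-standard-error rule.** Per-fold macro-F1 over six or seven subjects
  is noisy; the plain argmax intermittently picked aggressive combinations
  that halved a fold's F1. Among combinations within one standard error of
  the best mean, the first in C-ascending, gamma-ascending order (the most
  regularised) is chosen — the same logic as `glmnet`'s `lambda.1se`.

`train_model()` also records the inner-CV estimate and checks the refit
training macro-F1 against it (warning if it falls more than 0.05 below —
a cheap miswiring alarm). Macro-averaged F1 (unweighted mean of the four
per-class F1 scores, every 0/0 convention resolved to 0) is the headline
aggregate; micro-F1 (= accuracy) is reported alongside.

## Online detection

The streaming detector buffers frames and classifies the trailing window of
50 frames (1 s) every 10 frames. Raw decisions are majority-smoothed over
the last 5 decisions (ties resolved by class order, which favours NC and
therefore favours silence); an event opens when a non-NC smoothed class
persists 3 consecutive decisions and closes after 3 consecutive NC
decisions. Onset is backdated to the first decision of the run, so the
worst-case onset lag is `window + (debounce - 1 + smoothing - 1) * stride`
frames = 2.2 s at the defaults; the acceptance suite verifies this bound on
step-change streams. Events are never NC, never overlap, and are
time-ordered; `detect_stream()` is literally a fold over `detector_step()`,
so batch and streaming behaviour are identical by construction. The
confidence attached to an event is the winning class's one-vs-one vote
share — the acquisition literature reports no calibrated probability, and
vote share is the quantity the voting scheme actually produces.

Windows inherit their trial's label for evaluation (whole-trial labeling).
The online constants are stand-ins: no windowing constants are documented
for the original acquisition loop, and all are configurable.

One subtlety matters a great deal: a model destined for streaming must be
**trained on window-level features**. A reach cycle's sway contributes its
full range to a whole trial's temporal-SD features but only a fraction to
any 1 s window, so trial-trained boundaries sit in the wrong place for
window-level inputs — in our benchmark this capped online macro-F1 near
0.93 (SE windows drifting below the learned NC band of `sd_ml_cop`) while
trial-level LOSO scored 0.999. `sample_window_features()` draws seeded
random windows (two per trial by default) from each training trial;
`run_benchmark()` and the acceptance script train the deployment model on
those. Offline LOSO evaluation keeps the trial window, the default unit of
labeling.

## Numerical choices and degenerate inputs

* COP of an all-zero frame is an error; inside windows such frames are
  skipped (a mattress can legitimately report an empty frame under dropout).
* Ratio denominators floored at `1e-9 * peak`; an all-zero frame has ratios
  (1, 1) by symmetry convention.
* SMO: full kernel matrix (problems here are ≤ ~1500 rows), tolerance 1e-3,
  iteration cap 1e6; ties in one-vs-one votes and in majority smoothing
  resolve by the fixed class order.
* All randomness flows through one master seed via stable FNV-1a-derived
  sub-seeds (`subject`, `trial`, `noise`, `fold`, ... keys), so any trial
  can be regenerated in isolation and large cohorts need not be held in
  memory (`keep_frames = FALSE`).

## Known limitations

* The SE pressure signature is invented; nothing here validates it against
  real shoulder-elevation recordings.
* The low-variance cohort required by the identifiability bound means
  synthetic LOSO results bound the method's behaviour only within the
  stated world.
* Blobs are axis-aligned Gaussians; real pressure maps have sharper ischial
  peaks, asymmetric thigh contact, and cushion-dependent spreading.
* Trial-level training windows versus 1 s online windows is a distribution
  shift for the temporal-SD features; it is small in this world (the SE
  jitter is white, so window SDs match trial SDs) but real tremor or sway
  spectra would not be so forgiving.
* The feedback consumer (robot, VR) is out of scope; the package ends at
  the newline-delimited JSON event stream.
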