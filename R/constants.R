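#' Motion classes, reaching tasks, and feature order
#'
#' The four motion classes are noncompensation (NC) and the three compensatory
#' patterns trunk rotation (TR), trunk lean-forward (TLF) and shoulder
#' elevation (SE). Class order is fixed and used for deterministic
#' tie-breaking throughout. The three seated reaching tasks are back-and-forth,
#' side-to-side and up-and-down. The ten features are reported in a fixed
#' order; see [extract_features()].
#'
#' @return Character vector of class, task, or feature names.
#' @export
comp_classes <- function() c("NC", "TR", "TLF", "SE")

#' @rdname comp_classes
#' @export
reach_tasks <- function() c("back_and_forth", "side_to_side", "up_and_down")

#' @rdname comp_classes
#' @export
feature_names <- function() {
  c("ave_ssv", "max_sv",
    "ave_ml_cop", "sd_ml_cop", "ave_ap_cop", "sd_ap_cop",
    "ave_ml_ratio", "sd_ml_ratio", "ave_ap_ratio", "sd_ap_ratio")
}

GRID_DIM <- 32L
SIDES <- c("left", "right")
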