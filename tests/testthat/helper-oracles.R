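# Independent brute-force oracles: explicit double loops, no code shared with
# the package implementation.

oracle_features <- function(frames_list, affected_side = "right",
                            mirror = TRUE) {
  if (mirror && affected_side == "left") {
    frames_list <- lapply(frames_list, function(f) f[, 32:1])
  }
  allv <- numeric()
  maxv <- -Inf
  ml <- ap <- mlr <- apr <- numeric()
  for (f in frames_list) {
    allv <- c(allv, as.vector(f))
    maxv <- max(maxv, max(f))
    tot <- sml <- sap <- left <- right <- ant <- post <- 0
    for (i in 1:32) {
      for (j in 1:32) {
        p <- f[i, j]
        tot <- tot + p
        sml <- sml + (j - 1) * p
        sap <- sap + (i - 1) * p
        if (j <= 16) left <- left + p else right <- right + p
        if (i <= 16) ant <- ant + p else post <- post + p
      }
    }
    if (tot > 0) {
      eps <- 1e-9 * max(f)
      ml <- c(ml, sml / tot)
      ap <- c(ap, sap / tot)
      mlr <- c(mlr, left / max(right, eps))
      apr <- c(apr, ant / max(post, eps))
    }
  }
  sdp <- function(x) sqrt(sum((x - sum(x) / length(x))^2) / length(x))
  out <- c(sum(allv) / length(allv), maxv,
           sum(ml) / length(ml), sdp(ml), sum(ap) / length(ap), sdp(ap),
           sum(mlr) / length(mlr), sdp(mlr), sum(apr) / length(apr), sdp(apr))
  names(out) <- feature_names()
  out
}

# per-example counting implementation of precision/recall/F1
oracle_prf <- function(actual, predicted, cls) {
  tp <- fp <- fn <- 0
  for (k in seq_along(actual)) {
    if (predicted[k] == cls && actual[k] == cls) tp <- tp + 1
    if (predicted[k] == cls && actual[k] != cls) fp <- fp + 1
    if (predicted[k] != cls && actual[k] == cls) fn <- fn + 1
  }
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  c(precision = prec, recall = rec, f1 = f1)
}

random_frame <- function(density = 1) {
  f <- matrix(runif(1024), 32, 32)
  if (density < 1) f[runif(1024) > density] <- 0
  f
}
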