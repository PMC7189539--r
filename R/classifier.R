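# RBF-SVM training and leave-one-subject-out evaluation.
#
# Features are min-max normalised to [0, 1] on the training set only
# (LIBSVM's documented recommendation; keeps the RBF kernel scale-stable).
# The multiclass scheme is one-vs-one voting over the six class pairs, ties
# broken by the fixed class order NC < TR < TLF < SE. Hyperparameters (C,
# gamma) are chosen on an inner stratified 5-fold cross-validation maximising
# macro-F1, first best in grid order winning ties. Training rows are shuffled
# with the supplied seed before fitting, mirroring the usual practice of
# combining normalised features in random order (the fit itself is
# deterministic).

#' Fit a min-max feature normalizer
#'
#' Learns per-feature (min, max) from training data. At transform time
#' features map linearly to `[0, 1]` on the training range (values outside
#' the range map outside `[0, 1]`; no clipping). Constant features map to
#' 0.5.
#'
#' @param x Numeric matrix or data frame of feature vectors (rows = cases).
#' @return A `minmax_norm` object.
#' @export
fit_normalizer <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 1) stopf("cannot fit a normalizer on an empty feature set")
  structure(list(min = apply(x, 2, min), max = apply(x, 2, max),
                 features = colnames(x)),
            class = "minmax_norm")
}

#' @rdname fit_normalizer
#' @param norm A `minmax_norm`.
#' @export
apply_normalizer <- function(norm, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(norm$min)) {
    stopf("feature arity mismatch: %d columns, normalizer has %d",
          ncol(x), length(norm$min))
  }
  rng <- norm$max - norm$min
  out <- sweep(x, 2, norm$min, "-")
  const <- rng == 0
  out[, !const] <- sweep(out[, !const, drop = FALSE], 2, rng[!const], "/")
  out[, const] <- 0.5
  out
}

#' Default hyperparameter grid
#'
#' Powers of two, `C` in `2^-3 .. 2^7` and `gamma` in `2^-7 .. 2^3` with the
#' customary step of 2 in the exponent; search order is C ascending, gamma
#' ascending within C.
#'
#' @param c_exp,gamma_exp Exponent sequences.
#' @return Data frame with columns `C` and `gamma` in search order.
#' @export
default_hyper_grid <- function(c_exp = seq(-3, 7, by = 2),
                               gamma_exp = seq(-7, 3, by = 2)) {
  grid <- expand.grid(gamma = 2^gamma_exp, C = 2^c_exp,
                      KEEP.OUT.ATTRS = FALSE)[, c("C", "gamma")]
  rownames(grid) <- NULL
  grid
}

# ---- one-vs-one multiclass machinery (internal) ----

ovo_fit <- function(x, y, C, gamma, eps = 1e-3) {
  classes <- levels(y)
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  models <- lapply(pairs, function(pr) {
    sel <- y %in% pr
    ybin <- ifelse(y[sel] == pr[1], 1L, -1L)
    fit <- smo_train(x[sel, , drop = FALSE], ybin, C, gamma, eps)
    list(pair = pr, sv = fit$sv, coef = fit$coef, rho = fit$rho)
  })
  list(classes = classes, gamma = gamma, models = models)
}

ovo_votes <- function(ovo, x) {
  n <- nrow(x)
  votes <- matrix(0L, n, length(ovo$classes),
                  dimnames = list(NULL, ovo$classes))
  for (m in ovo$models) {
    f <- rbf_decision(m$sv, m$coef, m$rho, ovo$gamma, x)
    win <- ifelse(f > 0, m$pair[1], m$pair[2])  # f == 0 votes first class
    for (cls in m$pair) votes[, cls] <- votes[, cls] + (win == cls)
  }
  votes
}

ovo_predict <- function(ovo, x) {
  votes <- ovo_votes(ovo, x)
  # which.max takes the first maximum: tie-break by fixed class order
  ovo$classes[apply(votes, 1, which.max)]
}

make_stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in levels(y)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# subject-grouped folds: with few subjects (the usual case here) each inner
# fold holds out exactly one subject, which is deterministic and directly
# measures cross-subject transfer; larger cohorts are assigned round-robin
make_grouped_folds <- function(groups, k, seed) {
  g <- sort(unique(groups))
  k <- min(length(g), max(k, 8L))
  asg <- if (k == length(g)) g else with_seed(seed, sample(g))
  fold_of <- stats::setNames(rep_len(seq_len(k), length(g)), asg)
  unname(fold_of[as.character(groups)])
}

# per-fold inner-CV macro-F1 for one (C, gamma)
cv_macro_f1 <- function(x, y, C, gamma, folds) {
  ids <- sort(unique(folds))
  vapply(ids, function(f) {
    test <- folds == f
    norm <- fit_normalizer(x[!test, , drop = FALSE])
    fit <- ovo_fit(apply_normalizer(norm, x[!test, , drop = FALSE]),
                   droplevels(y[!test]), C, gamma)
    pred <- ovo_predict(fit, apply_normalizer(norm, x[test, , drop = FALSE]))
    macro_f1(confusion_matrix(as.character(y[test]), pred, levels(y)))
  }, numeric(1))
}

as_feature_matrix <- function(x, feature_order = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x[, sapply(x, is.numeric), drop = FALSE])
  if (!is.null(feature_order)) {
    if (!all(feature_order %in% colnames(x)) &&
        ncol(x) != length(feature_order)) {
      stopf("feature arity mismatch: expected %d features",
            length(feature_order))
    }
    if (all(feature_order %in% colnames(x))) {
      x <- x[, feature_order, drop = FALSE]
    }
  }
  x
}

#' Train the multiclass RBF-SVM
#'
#' Fits the normalizer on the training set, selects `(C, gamma)` by inner
#' stratified 5-fold cross-validation on macro-F1 (first best in grid order),
#' then refits on the full training set. Deterministic given `seed`.
#'
#' @param x Feature matrix or data frame (rows = trials). If feature columns
#'   are named they are reordered to [feature_names()] when applicable.
#' @param y Class labels (subset of [comp_classes()], >= 2 classes, >= 5
#'   cases per class present).
#' @param hyper_grid Data frame with columns `C`, `gamma`
#'   ([default_hyper_grid()]).
#' @param seed Integer seed (row shuffle + inner fold assignment).
#' @param inner_folds Number of inner CV folds (default 5).
#' @param groups Optional subject id per row. When supplied, inner CV folds
#'   hold out whole subjects (grouped CV), so the hyperparameter search
#'   measures cross-subject transfer rather than within-subject fit — the
#'   appropriate criterion for leave-one-subject-out deployment. Without
#'   groups, folds are stratified by class.
#' @return A `comp_model`: normalizer, chosen hyperparameters, one-vs-one
#'   binary machines, class list, feature order, inner-CV estimate,
#'   training-set macro-F1 and a training-manifest hash.
#' @export
train_model <- function(x, y, hyper_grid = default_hyper_grid(), seed = 1L,
                        inner_folds = 5L, groups = NULL) {
  x <- as_feature_matrix(x)
  y <- factor(as.character(y), levels = intersect(comp_classes(), unique(y)))
  if (nlevels(y) < 2) stopf("training data must contain at least 2 classes")
  if (min(table(y)) < 5) stopf("every class needs at least 5 training cases")
  if (!is.data.frame(hyper_grid) ||
      !all(c("C", "gamma") %in% names(hyper_grid)) || !nrow(hyper_grid) ||
      any(hyper_grid$C <= 0) || any(hyper_grid$gamma <= 0)) {
    stopf("degenerate hyperparameter grid")
  }

  # seeded shuffle of training rows ("combined in a random order")
  ord <- with_seed(derive_seed(seed, "shuffle"), sample(nrow(x)))
  x <- x[ord, , drop = FALSE]
  y <- y[ord]
  if (!is.null(groups)) {
    groups <- as.character(groups)[ord]
    # grouped CV needs at least two subjects to form folds
    if (length(unique(groups)) < 2) groups <- NULL
  }

  folds <- if (is.null(groups)) {
    make_stratified_folds(y, inner_folds, derive_seed(seed, "folds"))
  } else {
    make_grouped_folds(groups, inner_folds, derive_seed(seed, "folds"))
  }
  k <- length(unique(folds))
  scores <- ses <- numeric(nrow(hyper_grid))
  for (g in seq_len(nrow(hyper_grid))) {
    fold_f1 <- cv_macro_f1(x, y, hyper_grid$C[g], hyper_grid$gamma[g], folds)
    scores[g] <- mean(fold_f1)
    ses[g] <- stats::sd(fold_f1) / sqrt(k)
  }
  # one-standard-error rule: among combos within 1 SE of the best mean,
  # prefer the most regularized (grid is ordered C ascending, then gamma
  # ascending, so the first qualifying combo has the smallest C and the
  # smoothest kernel); cross-validated scores over few subject folds are
  # noisy, and the aggressive argmax combo transfers poorly
  best_mean <- max(scores)
  thr <- best_mean - ses[which.max(scores)]
  best <- which(scores >= thr)[1]

  norm <- fit_normalizer(x)
  xn <- apply_normalizer(norm, x)
  fit <- ovo_fit(xn, y, hyper_grid$C[best], hyper_grid$gamma[best])
  train_pred <- ovo_predict(fit, xn)
  train_f1 <- macro_f1(confusion_matrix(as.character(y), train_pred,
                                        levels(y)))
  if (train_f1 < scores[best] - 0.05) {
    warning(sprintf(
      "training macro-F1 (%.3f) below inner-CV estimate - 0.05 (%.3f)",
      train_f1, scores[best]), call. = FALSE)
  }

  structure(list(
    normalizer = norm, C = hyper_grid$C[best], gamma = hyper_grid$gamma[best],
    classes = levels(y), feature_order = colnames(x), ovo = fit,
    inner_cv_f1 = scores[best], grid_scores = cbind(hyper_grid, f1 = scores),
    train_f1 = train_f1, seed = seed,
    train_hash = object_hash(list(x, as.character(y)))),
    class = "comp_model")
}

#' @export
print.comp_model <- function(x, ...) {
  cat(sprintf(
    "<comp_model> RBF-SVM, C = %g, gamma = %g | classes: %s\n  inner-CV macro-F1 %.3f | train macro-F1 %.3f | hash %s\n",
    x$C, x$gamma, paste(x$classes, collapse = ", "), x$inner_cv_f1,
    x$train_f1, x$train_hash))
  invisible(x)
}

#' Predict motion classes for feature vectors
#'
#' @param object A `comp_model`.
#' @param newdata Feature matrix/data frame in the model's feature order.
#' @param type `"class"` for labels, `"votes"` for the one-vs-one vote
#'   matrix, `"confidence"` for the winning class's vote share in `[0, 1]`.
#' @param ... Unused.
#' @return Character labels, a vote matrix, or a list with both.
#' @export
predict.comp_model <- function(object, newdata,
                               type = c("class", "votes", "confidence"), ...) {
  type <- match.arg(type)
  x <- as_feature_matrix(newdata, object$feature_order)
  if (ncol(x) != length(object$feature_order)) {
    stopf("feature arity mismatch: model expects %d features, got %d",
          length(object$feature_order), ncol(x))
  }
  xn <- apply_normalizer(object$normalizer, x)
  votes <- ovo_votes(object$ovo, xn)
  if (type == "votes") return(votes)
  cls <- object$classes[apply(votes, 1, which.max)]
  if (type == "class") return(cls)
  n_pairs <- length(object$ovo$models)
  list(class = cls, confidence = apply(votes, 1, max) / n_pairs)
}

#' Persist or restore a trained model bundle
#'
#' The bundle is a single file holding the normalizer, hyperparameters,
#' support vectors, class and feature order and the training hash.
#'
#' @param model A `comp_model`.
#' @param path File path.
#' @return `save_model`: `path` invisibly; `load_model`: the `comp_model`.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "comp_model")) stopf("%s is not a comp_model bundle", path)
  m
}

#' Leave-one-subject-out cross-validation
#'
#' One fold per subject. The held-out subject's trials influence neither that
#' fold's normalizer nor its hyperparameter search nor the fitted machines
#' (everything is refit inside the fold by [train_model()]).
#'
#' @param x Feature matrix/data frame.
#' @param y Class labels.
#' @param subjects Subject id per row.
#' @param hyper_grid Hyperparameter grid.
#' @param seed Integer seed.
#' @param inner_folds Inner CV folds for the per-fold grid search.
#' @return A `comp_cv`: per-fold confusion matrices, hyperparameters and
#'   training-subject lists; pooled confusion matrix; per-class
#'   precision/recall/F1; macro- and micro-averaged F1.
#' @export
loso_cv <- function(x, y, subjects, hyper_grid = default_hyper_grid(),
                    seed = 1L, inner_folds = 5L) {
  x <- as_feature_matrix(x)
  y <- as.character(y)
  subjects <- as.character(subjects)
  if (length(y) != nrow(x) || length(subjects) != nrow(x)) {
    stopf("x, y and subjects must have matching lengths")
  }
  subj <- sort(unique(subjects))
  if (length(subj) < 2) stopf("LOSO needs at least 2 subjects")
  classes <- intersect(comp_classes(), unique(y))

  folds <- vector("list", length(subj))
  pooled <- matrix(0L, length(classes), length(classes),
                   dimnames = list(actual = classes, predicted = classes))
  for (i in seq_along(subj)) {
    held <- subjects == subj[i]
    if (!any(held)) stopf("subject %s has no trials", subj[i])
    model <- train_model(x[!held, , drop = FALSE], y[!held], hyper_grid,
                         seed = derive_seed(seed, "fold", subj[i]),
                         inner_folds = inner_folds,
                         groups = subjects[!held])
    pred <- predict(model, x[held, , drop = FALSE])
    cm <- confusion_matrix(y[held], pred, classes)
    pooled <- pooled + cm
    folds[[i]] <- list(subject = subj[i], cm = cm,
                       C = model$C, gamma = model$gamma,
                       inner_cv_f1 = model$inner_cv_f1,
                       train_subjects = sort(unique(subjects[!held])))
  }
  structure(list(folds = folds, pooled = pooled,
                 per_class = class_metrics(pooled),
                 macro_f1 = macro_f1(pooled), micro_f1 = micro_f1(pooled),
                 subjects = subj, seed = seed),
            class = "comp_cv")
}

#' @export
print.comp_cv <- function(x, ...) {
  cat(sprintf("<comp_cv> %d LOSO folds | macro-F1 %.3f | micro-F1 %.3f\n",
              length(x$folds), x$macro_f1, x$micro_f1))
  print(x$per_class, digits = 3)
  invisible(x)
}
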