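sep_features <- function(n_per = 12, seed = 55) {
  # two tight, well-separated synthetic clusters in 10-D
  seatcomp:::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per * 10, 0, 0.1), n_per, 10),
               matrix(rnorm(n_per * 10, 3, 0.1), n_per, 10))
    colnames(x) <- feature_names()
    list(x = x, y = rep(c("NC", "TLF"), each = n_per))
  })
}

test_that("normalizer: constant-feature rule, extremes, no clipping", {
  one <- matrix(rnorm(10), 1, 10, dimnames = list(NULL, feature_names()))
  norm <- fit_normalizer(one)
  expect_true(all(apply_normalizer(norm, one) == 0.5))

  two <- rbind(rep(0, 3), rep(4, 3))
  n2 <- fit_normalizer(two)
  tr <- apply_normalizer(n2, two)
  expect_equal(tr, rbind(rep(0, 3), rep(1, 3)), ignore_attr = TRUE)
  expect_equal(as.vector(apply_normalizer(n2, matrix(8, 1, 3))), rep(2, 3))
  expect_error(fit_normalizer(matrix(numeric(), 0, 3)), "empty")
  expect_error(apply_normalizer(n2, matrix(1, 1, 5)), "arity")
  # applying to its own training data stays in [0, 1]
  x <- matrix(rnorm(60), 12, 5)
  tt <- apply_normalizer(fit_normalizer(x), x)
  expect_true(all(tt >= 0 & tt <= 1))
})

test_that("SMO solution satisfies the KKT conditions", {
  withr::local_seed(6)
  n <- 60
  x <- rbind(matrix(rnorm(n * 2, 0), n, 2), matrix(rnorm(n * 2, 2), n, 2))
  y <- c(rep(1L, n), rep(-1L, n))
  for (C in c(0.5, 8)) {
    gamma <- 0.5
    fit <- seatcomp:::smo_train(x, y, C, gamma)
    expect_true(fit$converged)
    expect_lt(fit$kkt_gap, 1e-3)
    alpha <- abs(fit$coef)
    expect_true(all(alpha >= -1e-12 & alpha <= C + 1e-12))
    # dual equality constraint: sum alpha_i y_i = 0
    expect_equal(sum(fit$coef), 0, tolerance = 1e-9)
    # free SVs sit on the margin: y f(x) = 1 within solver tolerance
    f <- seatcomp:::rbf_decision(fit$sv, fit$coef, fit$rho, gamma, fit$sv)
    free <- alpha > 1e-8 & alpha < C - 1e-8
    if (any(free)) {
      yf <- sign(fit$coef[free]) * f[free]
      expect_true(all(abs(yf - 1) < 2e-3))
    }
  }
})

test_that("separable training reaches accuracy 1.0 and is deterministic", {
  d <- sep_features()
  m1 <- train_model(d$x, d$y, small_grid(), seed = 9)
  m2 <- train_model(d$x, d$y, small_grid(), seed = 9)
  expect_equal(predict(m1, d$x), d$y)
  expect_identical(c(m1$C, m1$gamma), c(m2$C, m2$gamma))
  expect_identical(predict(m1, d$x), predict(m2, d$x))
  expect_gte(m1$train_f1, m1$inner_cv_f1 - 0.05)
  # NC centroid predicts NC
  centroid <- matrix(colMeans(d$x[d$y == "NC", ]), 1,
                     dimnames = list(NULL, feature_names()))
  expect_equal(predict(m1, centroid), "NC")
  # confidence is the winning vote share
  pc <- predict(m1, d$x, type = "confidence")
  expect_true(all(pc$confidence > 0 & pc$confidence <= 1))
})

test_that("training preconditions are enforced", {
  d <- sep_features()
  expect_error(train_model(d$x, rep("NC", nrow(d$x)), small_grid()),
               "2 classes")
  expect_error(train_model(d$x[1:6, ], c(rep("NC", 3), rep("TR", 3)),
                           small_grid()), "at least 5")
  expect_error(train_model(d$x, d$y, data.frame(C = -1, gamma = 1)),
               "degenerate")
  expect_error(predict(small_model(), matrix(1, 2, 4)), "arity")
})

test_that("model bundle round-trips through save_model/load_model", {
  m <- small_model()
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  back <- load_model(path)
  fe <- small_features()
  expect_identical(predict(back, fe[, feature_names()]),
                   predict(m, fe[, feature_names()]))
  other <- withr::local_tempfile(fileext = ".rds")
  saveRDS(1:3, other)
  expect_error(load_model(other), "not a comp_model")
})

test_that("LOSO folds partition subjects; held-out subject never in training", {
  fe <- small_features()
  cv <- loso_cv(fe[, feature_names()], fe$label, fe$subject_id,
                small_grid(), seed = 17)
  expect_length(cv$folds, 3L)
  held <- vapply(cv$folds, `[[`, character(1), "subject")
  expect_setequal(held, unique(fe$subject_id))
  for (f in cv$folds) {
    expect_false(f$subject %in% f$train_subjects)  # disjoint split
    expect_setequal(c(f$subject, f$train_subjects), unique(fe$subject_id))
    expect_equal(sum(f$cm), sum(fe$subject_id == f$subject))
  }
  # pooled = elementwise sum of folds; total = trial count
  expect_equal(Reduce(`+`, lapply(cv$folds, `[[`, "cm")), cv$pooled)
  expect_equal(sum(cv$pooled), nrow(fe))
  expect_equal(cv$macro_f1, macro_f1(cv$pooled))
  expect_error(loso_cv(fe[, feature_names()], fe$label,
                       rep("S01", nrow(fe))), "2 subjects")
})

test_that("2-subject LOSO yields exactly 2 folds covering all trials", {
  fe <- small_features()
  two <- fe$subject_id %in% c("S01", "S02")
  cv <- loso_cv(fe[two, feature_names()], fe$label[two], fe$subject_id[two],
                small_grid(), seed = 23)
  expect_length(cv$folds, 2L)
  expect_equal(sum(cv$pooled), sum(two))
})
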