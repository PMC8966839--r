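# RFECV selection, forest training, and the evaluation metrics (confusion
# scores and trapezoidal ROC AUC vs. a rank-statistic oracle).

sim_informative <- function(n = 200, p = 40, k = 3, seed = 7) {
  set.seed(seed)
  y <- rbinom(n, 1, 0.5) == 1
  x <- matrix(rnorm(n * p), n, p)
  colnames(x) <- sprintf("f%02d", seq_len(p))
  for (j in seq_len(k)) x[, j] <- x[, j] + 2 * y  # signal in f01..f0k
  list(x = as.data.frame(x), y = y)
}

test_that("RFECV keeps exactly the informative columns", {
  d <- sim_informative(n = 200, k = 3, seed = 7)
  sel <- rfecv_select(d$x, d$y, seed = 7)
  expect_true(all(c("f01", "f02", "f03") %in% sel))
})

test_that("RFECV is deterministic and handles the single-feature case", {
  d <- sim_informative(n = 80, k = 2, seed = 3)
  s1 <- rfecv_select(d$x, d$y, seed = 5)
  s2 <- rfecv_select(d$x, d$y, seed = 5)
  expect_identical(as.character(s1), as.character(s2))
  one <- rfecv_select(d$x[, "f01", drop = FALSE], d$y, seed = 1)
  expect_identical(as.character(one), "f01")
  expect_error(rfecv_select(d$x, rep(TRUE, 80), seed = 1), "2 classes")
})

test_that("the forest has capacity for separable data and fixed seeds", {
  set.seed(9)
  x <- data.frame(a = c(rnorm(40, -3), rnorm(40, 3)), b = rnorm(80))
  y <- rep(c(FALSE, TRUE), each = 40)
  m <- train_model(x, y, seed = 2)
  expect_true(all((predict_prob(m, x) >= 0.5) == y))
  m2 <- train_model(x, y, seed = 2)
  expect_identical(predict_prob(m, x), predict_prob(m2, x))
})

test_that("label-permuted training yields chance-level held-out AUC", {
  set.seed(31)
  n <- 90
  x <- data.frame(matrix(rnorm(n * 5), n))
  y <- rbinom(n, 1, 0.5) == 1
  tr <- 1:60; te <- 61:90
  aucs <- sapply(1:20, function(s) {
    set.seed(s)
    yp <- sample(y[tr])
    m <- train_model(x[tr, ], yp, seed = s)
    suppressWarnings(roc_auc(predict_prob(m, x[te, ]), y[te]))
  })
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("confusion-derived metrics follow their definitions", {
  # scores engineered to give confusion tp=7 fp=1 fn=3 tn=4 at 0.5
  y <- c(rep(TRUE, 10), rep(FALSE, 5))
  prob <- c(rep(0.9, 7), rep(0.1, 3), 0.8, rep(0.2, 4))
  rep <- classification_report(prob, y)
  expect_equal(unname(rep$confusion), c(7, 1, 3, 4))
  expect_equal(rep$precision, 0.875)
  expect_equal(rep$recall, 0.7)
  expect_equal(rep$f1, 0.7778, tolerance = 1e-4)
  expect_equal(rep$accuracy, 0.7333, tolerance = 1e-4)
})

test_that("perfect ranking gives AUC 1; single-class labels give NA", {
  y <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), y), 1)
  expect_warning(a <- roc_auc(c(0.5, 0.6), c(TRUE, TRUE)), "one class")
  expect_true(is.na(a))
})

test_that("trapezoidal AUC equals the pair-counting oracle with ties", {
  set.seed(17)
  for (i in 1:50) {
    n <- sample(6:25, 1)
    pos <- rep(FALSE, n)
    pos[sample(n, sample(2:(n - 2), 1))] <- TRUE
    # coarse grid forces plenty of tied scores
    prob <- sample(seq(0, 1, 0.25), n, replace = TRUE)
    expect_equal(roc_auc(prob, pos), oracle_auc(prob, pos),
                 tolerance = 1e-12)
  }
})

test_that("ROC points are monotone and anchored", {
  set.seed(23)
  prob <- runif(30); y <- rbinom(30, 1, 0.5) == 1
  rc <- roc_curve(prob, y)
  expect_equal(rc$fpr[1], 0); expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1); expect_equal(rc$tpr[nrow(rc)], 1)
  expect_true(all(diff(rc$fpr) >= 0))
  expect_true(all(diff(rc$tpr) >= 0))
})

test_that("metrics are invariant to test-row order", {
  d <- sim_informative(n = 60, k = 2, seed = 12)
  m <- train_model(d$x[1:40, ], d$y[1:40], seed = 1)
  ix <- 41:60
  r1 <- evaluate_model(m, d$x[ix, ], d$y[ix])
  set.seed(4); perm <- sample(ix)
  r2 <- evaluate_model(m, d$x[perm, ], d$y[perm])
  expect_equal(r1$auc, r2$auc)
  expect_equal(r1$confusion, r2$confusion)
})

test_that("the four models share one split and conserve the test set", {
  cfg <- run_config(n = 24, seed = 5, slice_heights_mm = c(50, 60))
  reps <- run_cohort_models(cfg)
  expect_named(reps, c("MF", "AH", "TL", "PH"))
  n_test <- sapply(reps, function(r) sum(r$confusion))
  expect_true(all(n_test == round(24 / 3)))
  expect_equal(reps$MF$n_selected_features, 3)
  for (r in reps) {
    expect_true(all(diff(r$roc$fpr) >= 0) && all(diff(r$roc$tpr) >= 0))
    expect_true(r$accuracy >= 0 && r$accuracy <= 1)
  }
})
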