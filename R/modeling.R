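# Region-wise random-forest classifiers of intracranial hypertension with
# recursive feature elimination under stratified cross-validation, and the
# evaluation metrics (confusion-based scores + trapezoidal ROC AUC).

.as_label_factor <- function(y) {
  if (is.logical(y)) y <- ifelse(y, "pos", "neg")
  y <- factor(as.character(y))
  if (nlevels(y) != 2) stop("labels must contain exactly 2 classes")
  if (all(c("neg", "pos") %in% levels(y))) y <- factor(y, c("neg", "pos"))
  y
}

.stratified_fold_ids <- function(y, k) {
  ids <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    ids[idx] <- rep_len(seq_len(k), length(idx))
  }
  ids
}

#' Stratified train/test split
#'
#' @param y Logical or 2-level labels.
#' @param test_fraction Fraction held out (default 1/3).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(y, test_fraction = 1 / 3, seed = 1L) {
  y <- .as_label_factor(y)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  test <- integer(0)
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    n_t <- round(length(idx) * test_fraction)
    test <- c(test, idx[seq_len(n_t)])
  }
  test <- sort(test)
  train <- setdiff(seq_along(y), test)
  if (length(unique(y[train])) < 2 || length(unique(y[test])) < 2)
    stop("split infeasible: a class is missing from a split")
  list(train = train, test = test)
}

.fit_rf <- function(x, y, num_trees, seed, probability = FALSE,
                    importance = "none") {
  ranger::ranger(x = x, y = y, num.trees = num_trees, seed = seed,
                 num.threads = 1, probability = probability,
                 importance = importance,
                 respect.unordered.factors = TRUE)
}

#' Recursive feature elimination with cross-validated size selection
#'
#' Starting from all columns, repeatedly drops the feature with the lowest
#' mean impurity importance (ties: the lexicographically later name is
#' dropped), scoring each candidate feature count by mean stratified k-fold
#' CV accuracy of a random forest. The returned set is the one at the count
#' with the highest mean CV accuracy; ties prefer fewer features.
#' Importances are averaged over the fold fits, so the procedure never sees
#' held-out rows. Deterministic given `seed`.
#'
#' @param x data.frame or matrix of candidate features (named columns).
#' @param y Logical or 2-level labels; both classes required.
#' @param cv_folds Stratified CV folds (default 5).
#' @param num_trees Trees per forest (default 100).
#' @param seed Integer seed.
#' @return Character vector of selected feature names; attributes
#'   `"cv_accuracy"` (named by feature count) and `"elimination_order"`.
#' @export
rfecv_select <- function(x, y, cv_folds = 5, num_trees = 100, seed = 1L) {
  x <- as.data.frame(x)
  y <- .as_label_factor(y)
  if (min(table(y)) < cv_folds)
    stop("need at least cv_folds members per class")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  folds <- .stratified_fold_ids(y, cv_folds)

  current <- colnames(x)
  if (length(current) == 1) return(current)
  sets <- list(); acc <- numeric(0); dropped <- character(0)
  step <- 0L
  while (length(current) >= 1) {
    step <- step + 1L
    imp_sum <- setNames(numeric(length(current)), current)
    correct <- 0L
    for (f in seq_len(cv_folds)) {
      tr <- folds != f
      fit <- .fit_rf(x[tr, current, drop = FALSE], y[tr], num_trees,
                     seed = .derive_seed(seed, step, f),
                     importance = "impurity")
      pred <- predict(fit, data = x[!tr, current, drop = FALSE],
                      num.threads = 1)$predictions
      correct <- correct + sum(pred == y[!tr])
      imp_sum <- imp_sum + fit$variable.importance[current]
    }
    sets[[length(current)]] <- current
    acc[as.character(length(current))] <- correct / length(y)
    if (length(current) == 1) break
    # drop least important; ties -> lexicographically later name
    worst <- min(imp_sum)
    cand <- sort(names(imp_sum)[imp_sum <= worst + 1e-12])
    drop <- cand[length(cand)]
    dropped <- c(dropped, drop)
    current <- setdiff(current, drop)
  }
  sizes <- as.integer(names(acc))
  best_acc <- max(acc)
  best_size <- min(sizes[acc >= best_acc - 1e-12])
  out <- sets[[best_size]]
  attr(out, "cv_accuracy") <- acc[order(sizes)]
  attr(out, "elimination_order") <- dropped
  out
}

#' Fit the random-forest classifier on selected features
#'
#' @param x Training features (data.frame/matrix).
#' @param y Logical or 2-level labels.
#' @param selected Feature names to use (default: all columns).
#' @param num_trees,seed Forest settings.
#' @return An `ic_model`: list with the fitted forest and metadata.
#' @export
train_model <- function(x, y, selected = colnames(as.data.frame(x)),
                        num_trees = 100, seed = 1L) {
  x <- as.data.frame(x)
  y <- .as_label_factor(y)
  fit <- .fit_rf(x[, selected, drop = FALSE], y, num_trees, seed,
                 probability = TRUE)
  structure(list(fit = fit, selected = selected,
                 positive = levels(y)[2]),
            class = "ic_model")
}

#' Predicted probability of intracranial hypertension
#'
#' @param model An `ic_model`.
#' @param x Feature rows.
#' @return Numeric vector of probabilities for the positive class.
#' @export
predict_prob <- function(model, x) {
  x <- as.data.frame(x)
  pr <- predict(model$fit, data = x[, model$selected, drop = FALSE],
                num.threads = 1)$predictions
  pr[, model$positive]
}

#' ROC curve points
#'
#' Probability-ranked ROC: one point per distinct score (ties grouped),
#' anchored at (0,0) and (1,1); monotone nondecreasing in both coordinates.
#'
#' @param prob Scores for the positive class.
#' @param y Logical or 2-level labels.
#' @return data.frame with `fpr`, `tpr`.
#' @export
roc_curve <- function(prob, y) {
  y <- .as_label_factor(y)
  pos <- y == levels(y)[2]
  ord <- order(prob, decreasing = TRUE)
  prob <- prob[ord]; pos <- pos[ord]
  grp <- cumsum(!duplicated(prob))
  tp <- cumsum(pos); fp <- cumsum(!pos)
  last <- !duplicated(grp, fromLast = TRUE)
  data.frame(fpr = c(0, fp[last] / sum(!pos)),
             tpr = c(0, tp[last] / sum(pos)))
}

#' Trapezoidal ROC AUC
#'
#' Integrates the ROC of [roc_curve()] by the trapezoidal rule, which with
#' tie grouping equals the rank-statistic (Mann-Whitney) AUC with half
#' credit for ties.
#'
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`, or `NA` with a warning for single-class `y`.
#' @export
roc_auc <- function(prob, y) {
  yl <- .as_label_factor2(y)
  if (is.null(yl)) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  rc <- roc_curve(prob, yl)
  sum(diff(rc$fpr) * (utils::head(rc$tpr, -1) + utils::tail(rc$tpr, -1)) / 2)
}

# like .as_label_factor but returns NULL instead of erroring on one class
.as_label_factor2 <- function(y) {
  if (is.logical(y)) y <- ifelse(y, "pos", "neg")
  y <- factor(as.character(y))
  if (nlevels(y) != 2) return(NULL)
  if (all(c("neg", "pos") %in% levels(y))) y <- factor(y, c("neg", "pos"))
  y
}

#' Evaluate a fitted model on held-out rows
#'
#' Confusion at the probability threshold, the four confusion-based scores,
#' and the trapezoidal ROC AUC. Precision (and F1) are reported as 0 when no
#' positive predictions (no true positives) exist.
#'
#' @param model An `ic_model`.
#' @param x_test,y_test Held-out rows (disjoint from training).
#' @param threshold Probability threshold, default 0.5.
#' @return A `model_report`: list with `accuracy`, `precision`, `recall`,
#'   `f1`, `auc`, `confusion` (tp, fp, fn, tn), `roc` (points data.frame),
#'   `n_selected_features`, `n_test`.
#' @export
evaluate_model <- function(model, x_test, y_test, threshold = 0.5) {
  prob <- predict_prob(model, x_test)
  rep <- classification_report(prob, y_test, threshold)
  rep$n_selected_features <- length(model$selected)
  rep
}

#' Classification metrics from scores and labels
#'
#' The confusion matrix at a probability threshold, the derived scores, and
#' the trapezoidal ROC AUC — the pure-metrics core behind
#' [evaluate_model()].
#'
#' @param prob Scores for the positive class.
#' @param y Logical or 2-level labels.
#' @param threshold Probability threshold, default 0.5.
#' @return A `model_report` (without `n_selected_features`).
#' @export
classification_report <- function(prob, y, threshold = 0.5) {
  yl <- .as_label_factor2(y)
  pos <- if (is.null(yl)) {
    if (is.logical(y)) y else as.character(y) %in% c("pos", "TRUE")
  } else yl == levels(yl)[2]
  pred <- prob >= threshold
  tp <- sum(pred & pos); fp <- sum(pred & !pos)
  fn <- sum(!pred & pos); tn <- sum(!pred & !pos)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  auc <- if (is.null(yl)) {
    warning("AUC undefined: only one class present")
    NA_real_
  } else roc_auc(prob, yl)
  structure(list(
    accuracy = (tp + tn) / length(pos),
    precision = precision, recall = recall, f1 = f1, auc = auc,
    confusion = c(tp = tp, fp = fp, fn = fn, tn = tn),
    roc = if (is.null(yl)) NULL else roc_curve(prob, yl),
    n_selected_features = NA_integer_,
    n_test = length(pos)), class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf(paste0("model_report: acc %.3f  prec %.3f  rec %.3f  ",
                     "F1 %.3f  AUC %.3f  (%d features, n_test %d)\n"),
              x$accuracy, x$precision, x$recall, x$f1, x$auc,
              x$n_selected_features, x$n_test), ...)
  invisible(x)
}

# wide matrix of standardized variation rates for one region
.region_matrix <- function(vr_std, region, patient_ids) {
  fn <- texture_feature_registry()$name
  sub <- vr_std[vr_std$region == region, , drop = FALSE]
  sub <- sub[match(patient_ids, sub$patient_id), ]
  if (any(is.na(sub$patient_id))) stop("missing patients in region table")
  m <- as.data.frame(sub[, fn])
  rownames(m) <- patient_ids
  m
}

#' Train and evaluate the four region models on one shared split
#'
#' One stratified train/test split is shared by all four models. The three
#' texture models (AH, TL, PH) run RFECV on the training rows of their
#' region's standardized variation rates (min-max fitted on the training
#' split only, applied clipped to the test split); the morphology model (MF)
#' uses its three features without selection.
#'
#' @param vr Raw variation-rate table from [variation_rate_table()].
#' @param morph data.frame with `patient_id`, `hematoma_volume_ml`,
#'   `midline_shift_mm`, `vcr`.
#' @param labels data.frame with `patient_id` and logical `label`.
#' @param split_seed Seed for the shared split and the forests.
#' @param test_fraction Held-out fraction, default 1/3.
#' @param cv_folds,num_trees RFECV / forest settings.
#' @return Named list of `model_report` (MF, AH, TL, PH); attribute
#'   `"selected"` lists the chosen features per texture model.
#' @export
run_four_models <- function(vr, morph, labels, split_seed = 1L,
                            test_fraction = 1 / 3, cv_folds = 5,
                            num_trees = 100) {
  ids <- labels$patient_id
  if (length(ids) < 20) stop("need a cohort of at least 20 patients")
  y <- labels$label
  sp <- stratified_split(y, test_fraction, seed = split_seed)

  vr_tr <- vr[vr$patient_id %in% ids[sp$train], ]
  std_tr <- standardize_variation_rates(vr_tr)
  fitobj <- attr(std_tr, "vr_fit")
  vr_te <- vr[vr$patient_id %in% ids[sp$test], ]
  std_te <- standardize_variation_rates(vr_te, fit = fitobj)

  reports <- list(); selected <- list()
  mm <- morph[match(ids, morph$patient_id),
              c("hematoma_volume_ml", "midline_shift_mm", "vcr")]
  mf_model <- train_model(mm[sp$train, ], y[sp$train],
                          num_trees = num_trees,
                          seed = .derive_seed(split_seed, 1, 1))
  reports$MF <- evaluate_model(mf_model, mm[sp$test, ], y[sp$test])

  for (rg in c("AH", "TL", "PH")) {
    x_tr <- .region_matrix(std_tr, rg, ids[sp$train])
    x_te <- .region_matrix(std_te, rg, ids[sp$test])
    sel <- rfecv_select(x_tr, y[sp$train], cv_folds = cv_folds,
                        num_trees = num_trees,
                        seed = .derive_seed(split_seed, 2, match(rg, c("AH", "TL", "PH"))))
    mod <- train_model(x_tr, y[sp$train], selected = sel,
                       num_trees = num_trees,
                       seed = .derive_seed(split_seed, 3, match(rg, c("AH", "TL", "PH"))))
    reports[[rg]] <- evaluate_model(mod, x_te, y[sp$test])
    selected[[rg]] <- as.character(sel)
  }
  attr(reports, "selected") <- selected
  attr(reports, "split") <- sp
  reports
}
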