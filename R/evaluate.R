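# Evaluation: figures of merit, ROC/AUC, nested patient-wise CV,
# score-significance analysis and prediction overlays.

#' Binary classification metrics
#'
#' Sensitivity, specificity, PPV, NPV, F-score and accuracy from truth and
#' predicted labels, with `positive` naming the positive class.
#'
#' @param truth,pred character/factor vectors.
#' @param positive positive class label.
#' @return named numeric vector including the confusion counts.
#' @export
binary_metrics <- function(truth, pred, positive) {
  tp <- sum(truth == positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  tn <- sum(truth != positive & pred != positive)
  fp <- sum(truth != positive & pred == positive)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  f <- if (is.na(ppv) || is.na(sens) || ppv + sens == 0) NA_real_ else
    2 * ppv * sens / (ppv + sens)
  c(sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
    fscore = f, accuracy = (tp + tn) / length(truth),
    tp = tp, fp = fp, tn = tn, fn = fn)
}

#' ROC curve points
#'
#' False/true positive rates at every distinct score threshold (scores for
#' the positive class, thresholds descending), starting at (0,0) and
#' ending at (1,1).
#'
#' @param truth labels; `positive` the positive class.
#' @param score numeric score for the positive class.
#' @param positive positive class label.
#' @return data frame with `fpr`, `tpr`, `threshold`.
#' @export
roc_points <- function(truth, score, positive) {
  pos <- truth == positive
  np <- sum(pos); nn <- sum(!pos)
  thr <- sort(unique(score), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(score >= t & pos) / np, 0)
  fpr <- vapply(thr, function(t) sum(score >= t & !pos) / nn, 0)
  data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1),
             threshold = c(Inf, thr, -Inf))
}

#' Area under the ROC curve
#'
#' Trapezoidal integration of the score-ranked ROC; equals the
#' Mann-Whitney probability of correct ranking, and is invariant under
#' strictly monotone transforms of the scores.
#'
#' @inheritParams roc_points
#' @return scalar AUC in \[0, 1\].
#' @export
auc <- function(truth, score, positive) {
  r <- roc_points(truth, score, positive)
  sum(diff(r$fpr) * (head(r$tpr, -1) + r$tpr[-1]) / 2)
}

#' Evaluate a fitted model on a test table
#'
#' Computes, for the cascade semantics, (i) artefact-vs-gland metrics over
#' all rows, (ii) benign-vs-grade3 metrics over the rows whose true class
#' is a gland, the per-problem AUC, and the multi-class accuracy.
#'
#' @param model an `svm_cascade` or `mlp_classifier`.
#' @param x normalised feature matrix of the test rows.
#' @param labels true classes of the test rows.
#' @return list of class `fold_report` with `problem_a`, `problem_b`,
#'   `auc_a`, `auc_b`, `accuracy`, `prob`, `pred`, `labels`.
#' @export
evaluate_fold <- function(model, x, labels) {
  if (nrow(x) == 0) stop("empty test set")
  pr <- predict(model, x)
  truth_a <- ifelse(labels == "artefact", "artefact", "gland")
  pred_a <- ifelse(pr$class == "artefact", "artefact", "gland")
  score_gland <- 1 - pr$prob[, "artefact"]
  m_a <- binary_metrics(truth_a, pred_a, positive = "gland")
  a_a <- auc(truth_a, score_gland, positive = "gland")

  gl <- labels != "artefact"
  truth_b <- labels[gl]
  # benign-vs-grade3 over true-gland rows; rows the cascade called
  # artefact count against whichever gland class they were not
  pred_b <- ifelse(pr$prob[gl, "grade3"] > pr$prob[gl, "benign"],
                   "grade3", "benign")
  score_g3 <- pr$prob[gl, "grade3"] /
    pmax(pr$prob[gl, "grade3"] + pr$prob[gl, "benign"], 1e-12)
  m_b <- binary_metrics(truth_b, pred_b, positive = "grade3")
  a_b <- auc(truth_b, score_g3, positive = "grade3")

  structure(list(problem_a = m_a, problem_b = m_b, auc_a = a_a, auc_b = a_b,
                 accuracy = mean(pr$class == labels),
                 prob = pr$prob, pred = pr$class, labels = labels),
            class = "fold_report")
}

#' Patient-wise nested cross-validation
#'
#' Outer folds assign whole patients via [make_fold_plan()]. In each outer
#' iteration, feature selection and z-scoring are refit on the training
#' folds only, the classifier is trained (with inner tuning for the SVM
#' cascade), and the held-out fold is evaluated. Metrics are aggregated as
#' mean and standard deviation over folds; score-significance p-values are
#' averaged over folds.
#'
#' @param tab a `feature_table`.
#' @param classifier "svm" or "mlp".
#' @param k_outer,k_inner outer/inner fold counts.
#' @param alpha,r_thresh selection parameters.
#' @param tuner,budget SVM tuning controls.
#' @param seed integer seed.
#' @param global_selection fit selection once on the whole table (mimics a
#'   one-shot selection) instead of per training split.
#' @return object of class `cv_report`.
#' @export
nested_cv <- function(tab, classifier = c("svm", "mlp"), k_outer = 5,
                      k_inner = 10, alpha = 1e-6, r_thresh = 0.95,
                      tuner = "bo", budget = 30, seed = 1,
                      global_selection = FALSE) {
  classifier <- match.arg(classifier)
  plan <- make_fold_plan(tab$patients, tab$labels, k_outer, seed)
  sel_global <- if (global_selection) {
    select_features(tab, alpha = alpha, r_thresh = r_thresh)
  } else {
    NULL
  }
  folds <- list()
  all_pred <- character(nrow(tab$x))
  all_prob <- matrix(NA_real_, nrow(tab$x), 3,
                     dimnames = list(NULL, c("artefact", "benign", "grade3")))
  sel_sizes <- integer(0)
  for (f in seq_len(k_outer)) {
    te <- plan$fold == f
    train <- subset_table(tab, !te)
    sel <- if (global_selection) sel_global else
      select_features(train, alpha = alpha, r_thresh = r_thresh)
    fz <- zscore_fit(train$x[, sel$selected, drop = FALSE])
    xtr <- fz$x
    xte <- zscore_apply(tab$x[te, sel$selected, drop = FALSE], fz)
    model <- if (classifier == "svm") {
      svm_cascade(xtr, train$labels, k_inner = k_inner, tuner = tuner,
                  budget = budget, seed = seed + f)
    } else {
      mlp_classifier(xtr, train$labels, seed = seed + f)
    }
    rep_f <- evaluate_fold(model, xte, tab$labels[te])
    rep_f$model <- model
    rep_f$selection <- sel
    folds[[f]] <- rep_f
    all_pred[te] <- rep_f$pred
    all_prob[te, ] <- rep_f$prob
    sel_sizes <- c(sel_sizes, length(sel$selected))
  }
  agg <- function(get) {
    v <- vapply(folds, get, 0)
    c(mean = mean(v), sd = sd(v))
  }
  metrics <- list(
    problem_a = sapply(c("sensitivity", "specificity", "ppv", "npv",
                         "fscore", "accuracy"), function(m) {
      agg(function(fr) fr$problem_a[[m]])
    }),
    problem_b = sapply(c("sensitivity", "specificity", "ppv", "npv",
                         "fscore", "accuracy"), function(m) {
      agg(function(fr) fr$problem_b[[m]])
    }),
    auc_a = agg(function(fr) fr$auc_a),
    auc_b = agg(function(fr) fr$auc_b),
    accuracy = agg(function(fr) fr$accuracy))
  sig <- score_significance_folds(folds)
  structure(list(folds = folds, plan = plan, metrics = metrics,
                 multiclass_accuracy = mean(all_pred == tab$labels),
                 score_significance = sig,
                 selected_sizes = sel_sizes,
                 classifier = classifier, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<cv_report %s | %d folds>\n", x$classifier, length(x$folds)))
  cat(sprintf("  artefact vs gland : acc %.3f+-%.3f, AUC %.3f+-%.3f\n",
              m$problem_a["mean", "accuracy"], m$problem_a["sd", "accuracy"],
              m$auc_a["mean"], m$auc_a["sd"]))
  cat(sprintf("  benign vs grade3  : acc %.3f+-%.3f, AUC %.3f+-%.3f\n",
              m$problem_b["mean", "accuracy"], m$problem_b["sd", "accuracy"],
              m$auc_b["mean"], m$auc_b["sd"]))
  cat(sprintf("  multi-class accuracy (pooled): %.3f\n",
              x$multiclass_accuracy))
  invisible(x)
}

#' Score-significance analysis of one score set
#'
#' Treats each class's predicted probability as a variable and tests its
#' dependence on the true class: the scores are z-scored, gated by the KS
#' normality test, then compared across classes with ANOVA (normal) or
#' Kruskal-Wallis (otherwise). Constant score columns report p = 1 with a
#' flag.
#'
#' @param prob n x k matrix of class probabilities.
#' @param labels true classes (length n >= 10).
#' @return named numeric vector of p-values per class, with attribute
#'   `flagged` naming constant columns.
#' @export
score_significance <- function(prob, labels) {
  if (nrow(prob) < 10) stop("need at least 10 rows")
  flagged <- character(0)
  p <- vapply(colnames(prob), function(cl) {
    s <- prob[, cl]
    if (sd(s) == 0) {
      flagged <<- c(flagged, cl)
      return(1)
    }
    z <- (s - mean(s)) / sd(s)
    nt <- normality_test(z)
    class_dependence_test(z, labels, nt$is_normal)$p_value
  }, 0)
  attr(p, "flagged") <- flagged
  p
}

# per-fold score significance averaged over the folds large enough to
# test (the operation requires at least 10 rows)
score_significance_folds <- function(folds) {
  ok <- vapply(folds, function(fr) nrow(fr$prob) >= 10, logical(1))
  if (!any(ok)) {
    return(setNames(rep(NA_real_, 3), colnames(folds[[1]]$prob)))
  }
  ps <- t(vapply(folds[ok], function(fr) {
    as.numeric(score_significance(fr$prob, fr$labels))
  }, numeric(3)))
  colnames(ps) <- colnames(folds[[1]]$prob)
  colMeans(ps)
}

#' Draw prediction overlays on a patch
#'
#' Draws candidate gland contours on the RGB patch: green for candidates
#' predicted benign, red for grade 3; candidates predicted artefact are
#' not drawn.
#'
#' @param rgb HxWx3 array, 0-255.
#' @param candidates list of `gland_candidate` with masks (phantom
#'   candidates, or any candidate with `truth_gland_mask` replaced by a
#'   segmentation mask in bbox coordinates).
#' @param pred character vector of predicted classes per candidate.
#' @param path optional PNG output path.
#' @return the annotated HxWx3 array (invisibly if `path` given).
#' @export
predict_overlay <- function(rgb, candidates, pred, path = NULL) {
  out <- rgb
  stopifnot(length(candidates) == length(pred))
  for (i in seq_along(candidates)) {
    if (pred[i] == "artefact") next
    col <- if (pred[i] == "grade3") c(255, 0, 0) else c(0, 200, 0)
    cd <- candidates[[i]]
    mask <- if (!is.null(cd$truth_gland_mask)) cd$truth_gland_mask else
      cd$gland_mask
    edge <- mask & !erode_disk(mask, 1)
    bb <- cd$bbox
    for (ch in 1:3) {
      sub <- out[bb[1]:bb[3], bb[2]:bb[4], ch]
      sub[edge] <- col[ch]
      out[bb[1]:bb[3], bb[2]:bb[4], ch] <- sub
    }
  }
  if (!is.null(path)) {
    png::writePNG(out / 255, path)
    return(invisible(out))
  }
  out
}
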