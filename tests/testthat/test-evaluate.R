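test_that("binary metrics match hand arithmetic on a stated confusion", {
  # rows = truth, cols = prediction, positive = second class:
  # [[40, 10], [5, 45]]
  truth <- c(rep("neg", 50), rep("pos", 50))
  pred <- c(rep("neg", 40), rep("pos", 10), rep("neg", 5), rep("pos", 45))
  m <- binary_metrics(truth, pred, positive = "pos")
  expect_equal(unname(m["sensitivity"]), 0.9)
  expect_equal(unname(m["specificity"]), 0.8)
  expect_equal(unname(m["ppv"]), 45 / 55)
  expect_equal(unname(m["accuracy"]), 0.85)
  # identities recomputed from the stored confusion counts
  expect_equal(unname(m["accuracy"]),
               unname((m["tp"] + m["tn"]) / sum(m[c("tp", "fp", "tn", "fn")])))
  expect_equal(unname(m["fscore"]),
               unname(2 * m["ppv"] * m["sensitivity"] /
                        (m["ppv"] + m["sensitivity"])))
})

test_that("AUC behaves like the Mann-Whitney statistic", {
  truth <- c(rep("neg", 20), rep("pos", 20))
  perfect <- c(runif(20, 0, 0.4), runif(20, 0.6, 1))
  expect_equal(auc(truth, perfect, "pos"), 1)
  set.seed(8)
  t2 <- sample(c("neg", "pos"), 1000, replace = TRUE)
  s2 <- runif(1000)
  expect_equal(auc(t2, s2, "pos"), 0.5, tolerance = 0.05)
  # invariance under strictly monotone transforms
  expect_equal(auc(t2, s2, "pos"), auc(t2, qlogis(s2 * 0.98 + 0.01), "pos"))
  expect_equal(auc(t2, s2, "pos"), auc(t2, s2^3, "pos"))
  # cross-check against an independent implementation
  skip_if_not_installed("pROC")
  a_ref <- as.numeric(pROC::auc(pROC::roc(t2, s2, levels = c("neg", "pos"),
                                          direction = "<", quiet = TRUE)))
  expect_equal(auc(t2, s2, "pos"), a_ref, tolerance = 1e-9)
})

test_that("fold evaluation applies the cascade semantics", {
  set.seed(9)
  n <- 30
  centers <- list(artefact = c(0, 0), benign = c(6, 0), grade3 = c(0, 6))
  x <- do.call(rbind, lapply(names(centers), function(cl) {
    sweep(matrix(rnorm(2 * n, 0, 0.4), n, 2), 2, centers[[cl]], "+")
  }))
  labs <- rep(names(centers), each = n)
  m <- svm_cascade(x, labs, k_inner = 3, tuner = "grid", budget = 9, seed = 1)
  fr <- evaluate_fold(m, x, labs)
  expect_equal(unname(fr$problem_a["accuracy"]), 1)
  expect_equal(unname(fr$problem_b["accuracy"]), 1)
  expect_equal(fr$auc_a, 1)
  expect_equal(fr$accuracy, 1)
  expect_error(evaluate_fold(m, x[0, , drop = FALSE], character(0)), "empty")
})

test_that("score significance separates informative from null scores", {
  set.seed(10)
  labs <- sample(c("artefact", "benign", "grade3"), 300, replace = TRUE)
  onehot <- outer(labs, c("artefact", "benign", "grade3"), "==") * 1
  colnames(onehot) <- c("artefact", "benign", "grade3")
  p_info <- score_significance(pmin(pmax(
    onehot + matrix(rnorm(900, 0, 0.01), 300), 0), 1), labs)
  expect_true(all(p_info < 1e-10))
  # null scores: p-values approximately uniform across simulations
  ps <- vapply(1:60, function(s) {
    set.seed(s + 500)
    l <- sample(c("artefact", "benign", "grade3"), 200, replace = TRUE)
    pr <- matrix(runif(600), 200, 3,
                 dimnames = list(NULL, c("artefact", "benign", "grade3")))
    score_significance(pr, l)[1]
  }, 0)
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
  # constant columns flagged with p = 1
  pr0 <- matrix(0.5, 50, 3,
                dimnames = list(NULL, c("artefact", "benign", "grade3")))
  l0 <- sample(c("artefact", "benign", "grade3"), 50, replace = TRUE)
  p0 <- score_significance(pr0, l0)
  expect_true(all(p0 == 1))
  expect_length(attr(p0, "flagged"), 3)
  expect_identical(score_significance(pr0, l0), score_significance(pr0, l0))
})

test_that("nested CV audits folds and recovers a null on permuted labels", {
  spec <- phantom_spec(patch_size = 384, candidates_per_patch = 5,
                       patches_per_patient = 2, n_patients = 8, seed = 61)
  co <- generate_cohort(spec)
  tab <- cohort_features(co, maps = "truth")
  rep1 <- nested_cv(tab, "svm", k_outer = 5, k_inner = 3, tuner = "grid",
                    budget = 9, seed = 3)
  # every candidate is tested exactly once
  expect_equal(sort(unique(rep1$plan$fold)), 1:5)
  expect_gte(rep1$multiclass_accuracy, 0.9)
  expect_true(all(rep1$score_significance < 0.05))
})

test_that("overlays colour contours by prediction and keep dimensions", {
  spec <- tiny_spec(seed = 71)
  p <- generate_patch(spec, "P01", seed = 2)
  labs <- vapply(p$candidates, `[[`, "", "label")
  out <- predict_overlay(p$rgb, p$candidates, labs)
  expect_equal(dim(out), dim(p$rgb))
  # no candidates -> unmodified image
  expect_identical(predict_overlay(p$rgb, list(), character(0)), p$rgb)
  # oracle-perfect predictions: benign contours green, grade3 red
  for (i in seq_along(p$candidates)) {
    cd <- p$candidates[[i]]
    if (labs[i] == "artefact") next
    edge <- cd$truth_gland_mask & !erode_disk(cd$truth_gland_mask, 1)
    bb <- cd$bbox
    sub_r <- out[bb[1]:bb[3], bb[2]:bb[4], 1]
    sub_g <- out[bb[1]:bb[3], bb[2]:bb[4], 2]
    if (labs[i] == "grade3") {
      expect_true(all(sub_r[edge] == 255 & sub_g[edge] == 0))
    } else {
      expect_true(all(sub_r[edge] == 0 & sub_g[edge] == 200))
    }
  }
})
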