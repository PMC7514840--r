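test_that("fold plans keep patients together and balance classes", {
  pid <- rep(sprintf("P%02d", 1:5), each = 10)
  labs <- rep(rep(c("artefact", "benign", "grade3"), length.out = 10), 5)
  plan <- make_fold_plan(pid, labs, 5, seed = 1)
  expect_equal(sort(unname(plan$assignment)), 1:5)  # one patient per fold
  pid2 <- rep(sprintf("P%02d", 1:10), each = 6)
  plan2 <- make_fold_plan(pid2, rep("benign", 60), 5, seed = 1)
  expect_true(all(table(plan2$assignment) == 2))
  expect_error(make_fold_plan(rep("P01", 10), rep("benign", 10), 5), "at least")
  # patient-wise integrity on a phantom cohort; class balance within 15%
  spec <- phantom_spec(patch_size = 384, candidates_per_patch = 4,
                       patches_per_patient = 3, n_patients = 15, seed = 41)
  co <- generate_cohort(spec)
  plan3 <- make_fold_plan(co$candidates$patient_id, co$candidates$class,
                          5, seed = 2)
  for (p in unique(co$candidates$patient_id)) {
    expect_length(unique(plan3$fold[co$candidates$patient_id == p]), 1)
  }
  tab <- table(plan3$fold, co$candidates$class)
  glob <- colSums(tab) / 5
  expect_true(all(abs(sweep(tab, 2, glob)) <= pmax(0.15 * glob, 3)))
})

test_that("the quadratic kernel separates XOR where a linear kernel cannot", {
  set.seed(5)
  n <- 200
  x <- cbind(runif(n, -1, 1), runif(n, -1, 1))
  y <- factor(ifelse(x[, 1] * x[, 2] > 0, "a", "b"))
  folds <- rep_len(1:5, n)
  acc_quad <- acc_lin <- 0
  for (f in 1:5) {
    tr <- folds != f
    fq <- e1071::svm(x[tr, ], y[tr], kernel = "polynomial", degree = 2,
                     coef0 = 1, gamma = 1, cost = 10, scale = FALSE)
    fl <- e1071::svm(x[tr, ], y[tr], kernel = "linear", cost = 10,
                     scale = FALSE)
    acc_quad <- acc_quad + mean(predict(fq, x[!tr, ]) == y[!tr]) / 5
    acc_lin <- acc_lin + mean(predict(fl, x[!tr, ]) == y[!tr]) / 5
  }
  expect_gte(acc_quad, 0.95)
  expect_lt(acc_lin, 0.7)
})

test_that("the SVM cascade fits separable data and tunes deterministically", {
  set.seed(6)
  n <- 60
  centers <- list(artefact = c(0, 0), benign = c(6, 0), grade3 = c(0, 6))
  x <- do.call(rbind, lapply(names(centers), function(cl) {
    sweep(matrix(rnorm(2 * n, 0, 0.4), n, 2), 2, centers[[cl]], "+")
  }))
  labs <- rep(names(centers), each = n)
  m1 <- svm_cascade(x, labs, k_inner = 3, tuner = "grid", budget = 9,
                    seed = 3)
  pr <- predict(m1, x)
  expect_gte(mean(pr$class == labs), 0.99)
  expect_equal(rowSums(pr$prob), rep(1, nrow(x)), tolerance = 1e-9)
  m2 <- svm_cascade(x, labs, k_inner = 3, tuner = "grid", budget = 9,
                    seed = 3)
  expect_identical(m1$par_a, m2$par_a)
  expect_identical(m1$par_b, m2$par_b)
  m3 <- svm_cascade(x, labs, k_inner = 3, tuner = "bo", budget = 10, seed = 4)
  m4 <- svm_cascade(x, labs, k_inner = 3, tuner = "bo", budget = 10, seed = 4)
  expect_identical(m3$par_a, m4$par_a)
  expect_error(svm_cascade(x, labs, budget = 3), "budget")
  expect_error(svm_cascade(x, rep("artefact", nrow(x)), budget = 10),
               "stage A")
})

test_that("the MLP learns separated blobs with the adaptive-rate rule", {
  set.seed(7)
  n <- 80
  centers <- list(artefact = c(0, 0), benign = c(10, 0), grade3 = c(0, 10))
  x <- do.call(rbind, lapply(names(centers), function(cl) {
    sweep(matrix(rnorm(2 * n, 0, 1), n, 2), 2, centers[[cl]], "+")
  }))
  labs <- rep(names(centers), each = n)
  m <- mlp_classifier(x, labs, seed = 5)
  pr <- predict(m, x)
  expect_gte(mean(pr$class == labs), 0.99)
  # accepted-loss trace never jumps by more than the 1.04 reject ratio
  tr <- m$loss_trace
  expect_true(all(is.finite(tr)))
  expect_true(all(tr[-1] <= 1.04 * tr[-length(tr)] + 1e-12))
  m2 <- mlp_classifier(x, labs, seed = 5)
  expect_identical(m$W1, m2$W1)
  expect_identical(m$loss_trace, m2$loss_trace)
  expect_error(mlp_classifier(x, rep(c("a", "b"), length.out = nrow(x))),
               "three")
})
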