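test_that("z-scoring centres, scales, flags constants and round-trips", {
  x <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  fz <- zscore_fit(x)
  expect_equal(unname(fz$x[, 1]), c(-1, 0, 1))
  expect_true(all(fz$x[, 2] == 0))
  expect_true(fz$constant[2])
  xt <- cbind(a = c(4, 0), b = c(1, 2))
  expect_equal(zscore_apply(xt, fz)[, 1], c((4 - 2) / 1, (0 - 2) / 1))
  expect_true(all(zscore_apply(xt, fz)[, 2] == 0))
})

test_that("the KS gate accepts normal and rejects uniform data", {
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    normality_test(rnorm(5000))$is_normal
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  set.seed(1)
  u <- runif(5000)
  z <- (u - mean(u)) / sd(u)
  expect_false(normality_test(z)$is_normal)
  expect_error(normality_test(rnorm(5)), "at least 8")
  set.seed(2); x <- rnorm(100)
  expect_identical(normality_test(x), normality_test(x))
})

test_that("class tests separate signal from noise and match t-test", {
  set.seed(3)
  labs <- rep(c("artefact", "benign", "grade3"), each = 300)
  signal <- as.numeric(factor(labs)) + rnorm(900, 0, 0.01)
  expect_lt(class_dependence_test(signal, labs, TRUE)$p_value, 1e-6)
  expect_lt(class_dependence_test(signal, labs, FALSE)$p_value, 1e-6)
  # under the null, p-values rarely dip below the alpha = 1e-6 gate
  ps <- vapply(1:200, function(s) {
    set.seed(s + 1000)
    class_dependence_test(rnorm(900), labs, s %% 2 == 0)$p_value
  }, 0)
  expect_gte(mean(ps > 1e-6), 0.99)
  # two balanced classes: ANOVA F equals t^2, so p-values agree
  set.seed(4)
  y <- rnorm(60); g <- rep(c("a", "b"), each = 30)
  p_aov <- class_dependence_test(y, g, TRUE)$p_value
  p_t <- t.test(y ~ g, var.equal = TRUE)$p.value
  expect_equal(p_aov, p_t, tolerance = 1e-12)
  expect_error(class_dependence_test(y[1:3], c("a", "a", "b"), TRUE),
               "two members")
})

test_that("selection keeps discriminant features and decorrelates", {
  set.seed(5)
  n <- 900
  labs <- rep(c("artefact", "benign", "grade3"), each = n / 3)
  strong <- as.numeric(factor(labs)) * 2 + rnorm(n, 0, 0.3)
  x <- cbind(strong = strong,
             dup = strong,                      # r = 1 duplicate
             weak = rnorm(n),
             noise1 = rnorm(n), noise2 = runif(n))
  tab <- feature_table(x, labs, patients = rep(sprintf("P%02d", 1:9),
                                               length.out = n))
  sel <- select_features(tab)
  expect_true("strong" %in% sel$selected)
  expect_false(all(c("strong", "dup") %in% sel$selected))  # one survives
  expect_false(any(c("weak", "noise1", "noise2") %in% sel$selected))
  expect_true(any(grepl("^correlation\\(", sel$record$dropped_by)))
  # pure-noise tables are fully rejected with an explicit error
  set.seed(6)
  noise_tab <- feature_table(matrix(rnorm(n * 8), n, 8,
                                    dimnames = list(NULL, paste0("f", 1:8))),
                             labs, rep("P01", n))
  expect_error(select_features(noise_tab), "relax alpha")
  # determinism
  expect_identical(select_features(tab), select_features(tab))
})

test_that("shrinking alpha never enlarges the stage-1 survivor set", {
  set.seed(7)
  n <- 300
  labs <- rep(c("artefact", "benign", "grade3"), each = n / 3)
  x <- sapply(1:12, function(j) {
    as.numeric(factor(labs)) * j / 12 + rnorm(n, 0, 1)
  })
  colnames(x) <- paste0("f", 1:12)
  tab <- feature_table(x, labs, rep("P01", n))
  survivors <- function(alpha) {
    sel <- try(select_features(tab, alpha = alpha, r_thresh = 1.01),
               silent = TRUE)
    if (inherits(sel, "try-error")) character(0) else sel$selected
  }
  s1 <- survivors(1e-2)
  s2 <- survivors(1e-4)
  s3 <- survivors(1e-6)
  expect_true(all(s2 %in% s1))
  expect_true(all(s3 %in% s2))
  # the audit covers every feature exactly once
  sel <- select_features(tab, alpha = 1e-2)
  expect_equal(sort(unique(c(sel$selected,
                             sel$record$name[sel$record$dropped_by != "none"]))),
               sort(colnames(x)))
  # no surviving pair violates the correlation rule
  r <- cor(tab$x[, sel$selected])
  diag(r) <- 0
  expect_true(all(abs(r) < 0.95 | is.na(r)))
})
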