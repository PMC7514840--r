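# Two-stage SVM cascade: stage A separates artefacts from glands, stage B
# separates benign from grade-3 among glands. Both stages use a quadratic
# (polynomial degree 2) kernel; the box constraint C and kernel scale gamma
# are tuned on inner cross-validation, by default with a Gaussian-process
# Bayesian optimisation (expected improvement) over log10 space.

# ---- binary quadratic-kernel SVM with Platt-calibrated scores -----------

.fit_binary_svm <- function(x, y, C, gamma) {
  fit <- e1071::svm(x, factor(y), type = "C-classification",
                    kernel = "polynomial", degree = 2, coef0 = 1,
                    gamma = gamma, cost = C, scale = FALSE)
  dv <- attr(predict(fit, x, decision.values = TRUE), "decision.values")[, 1]
  # Platt-style calibration: logistic fit of the labels on decision values
  pos <- levels(factor(y))[2]
  cal <- suppressWarnings(
    glm((y == pos) ~ dv, family = binomial()))
  list(svm = fit, cal = cal, positive = pos)
}

.predict_binary_svm <- function(model, x) {
  dv <- attr(predict(model$svm, x, decision.values = TRUE),
             "decision.values")[, 1]
  p <- suppressWarnings(
    predict(model$cal, newdata = data.frame(dv = dv), type = "response"))
  unname(p)    # probability of the positive (second) level
}

.binary_cv_error <- function(x, y, C, gamma, folds) {
  err <- 0
  n <- 0
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2) next
    fit <- e1071::svm(x[tr, , drop = FALSE], factor(y[tr]),
                      type = "C-classification", kernel = "polynomial",
                      degree = 2, coef0 = 1, gamma = gamma, cost = C,
                      scale = FALSE)
    pred <- predict(fit, x[!tr, , drop = FALSE])
    err <- err + sum(pred != y[!tr])
    n <- n + sum(!tr)
  }
  err / max(n, 1)
}

# ---- hyperparameter search ----------------------------------------------

# maximin-ish Latin hypercube in [0,1]^d, seeded by the caller's RNG state
.lhs <- function(n, d) {
  sapply(seq_len(d), function(j) (sample(n) - runif(n)) / n)
}

# Gaussian-process expected-improvement search over log10(C), log10(gamma)
.tune_bo <- function(obj, lower = c(-2, -2), upper = c(2, 2), budget = 30,
                     n_init = 8) {
  n_init <- min(n_init, budget)
  X <- sweep(sweep(.lhs(n_init, 2), 2, upper - lower, "*"), 2, lower, "+")
  y <- apply(X, 1, obj)
  ell <- 1.0   # kernel length-scale in log10 units
  k_se <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    exp(-0.5 * pmax(d2, 0) / ell^2)
  }
  while (nrow(X) < budget) {
    mu0 <- mean(y)
    sd0 <- max(sd(y), 1e-6)
    ys <- (y - mu0) / sd0
    K <- k_se(X, X) + diag(1e-4, nrow(X))
    Kinv <- solve(K)
    cand <- sweep(sweep(.lhs(256, 2), 2, upper - lower, "*"), 2, lower, "+")
    ks <- k_se(cand, X)
    mu <- as.vector(ks %*% Kinv %*% ys)
    s2 <- pmax(1 - rowSums((ks %*% Kinv) * ks), 1e-9)
    s <- sqrt(s2)
    best <- min(ys)
    imp <- best - mu
    z <- imp / s
    ei <- imp * pnorm(z) + s * dnorm(z)
    xn <- cand[which.max(ei), , drop = FALSE]
    X <- rbind(X, xn)
    y <- c(y, obj(as.vector(xn)))
  }
  X[which.min(y), ]
}

.tune_grid <- function(obj, lower = c(-2, -2), upper = c(2, 2), n_grid = 5) {
  g1 <- seq(lower[1], upper[1], length.out = n_grid)
  g2 <- seq(lower[2], upper[2], length.out = n_grid)
  best <- NULL; best_y <- Inf
  for (a in g1) for (b in g2) {
    v <- obj(c(a, b))
    if (v < best_y) {
      best_y <- v
      best <- c(a, b)
    }
  }
  best
}

.tune_stage <- function(x, y, folds, tuner, budget, seed) {
  set.seed(as.integer(seed))
  obj <- function(par) {
    .binary_cv_error(x, y, C = 10^par[1], gamma = 10^par[2], folds)
  }
  par <- if (tuner == "bo") {
    .tune_bo(obj, budget = budget)
  } else {
    .tune_grid(obj, n_grid = max(3, floor(sqrt(budget))))
  }
  c(C = 10^par[1], gamma = 10^par[2])
}

# ---- cascade fitting -----------------------------------------------------

#' Train the two-stage SVM cascade
#'
#' Stage A is trained on artefact vs gland (benign and grade3 pooled);
#' stage B on benign vs grade3 using the true-gland training rows. Each
#' stage's `(C, gamma)` is tuned in `[1e-2, 1e2]^2` (log10 scale) by
#' minimising stratified inner-CV misclassification, using Bayesian
#' optimisation with an expected-improvement acquisition (default) or a
#' log-grid search, then refit on all training rows. Scores are calibrated
#' to probabilities by a logistic fit on the decision values.
#'
#' @param x numeric matrix of (already normalised) features.
#' @param labels character vector in {artefact, benign, grade3}.
#' @param k_inner inner CV folds (default 10).
#' @param tuner "bo" or "grid".
#' @param budget tuning evaluations per stage (>= 5).
#' @param seed integer seed.
#' @return object of class `svm_cascade` with stages A/B and tuned
#'   hyperparameters.
#' @export
svm_cascade <- function(x, labels, k_inner = 10, tuner = c("bo", "grid"),
                        budget = 30, seed = 1) {
  tuner <- match.arg(tuner)
  if (budget < 5) stop("budget must be at least 5")
  stopifnot(nrow(x) == length(labels))
  y_a <- factor(ifelse(labels == "artefact", "artefact", "gland"),
                levels = c("artefact", "gland"))
  if (length(unique(y_a)) < 2) stop("stage A needs artefacts and glands")
  gl <- labels != "artefact"
  y_b <- factor(labels[gl], levels = c("benign", "grade3"))
  if (length(unique(y_b)) < 2) stop("stage B needs benign and grade3 rows")

  folds_a <- .stratified_folds(as.character(y_a), k_inner, seed)
  par_a <- .tune_stage(x, y_a, folds_a, tuner, budget, seed + 1L)
  stage_a <- .fit_binary_svm(x, y_a, par_a["C"], par_a["gamma"])

  xb <- x[gl, , drop = FALSE]
  folds_b <- .stratified_folds(as.character(y_b), k_inner, seed + 2L)
  par_b <- .tune_stage(xb, y_b, folds_b, tuner, budget, seed + 3L)
  stage_b <- .fit_binary_svm(xb, y_b, par_b["C"], par_b["gamma"])

  structure(list(stage_a = stage_a, stage_b = stage_b,
                 par_a = par_a, par_b = par_b,
                 classes = c("artefact", "benign", "grade3"),
                 tuner = tuner, budget = budget, seed = seed),
            class = "svm_cascade")
}

#' @export
print.svm_cascade <- function(x, ...) {
  cat(sprintf("<svm_cascade quadratic kernel | A: C=%.3g gamma=%.3g | B: C=%.3g gamma=%.3g>\n",
              x$par_a["C"], x$par_a["gamma"], x$par_b["C"], x$par_b["gamma"]))
  invisible(x)
}

#' Predict with the SVM cascade
#'
#' Stage A scores every row as gland-vs-artefact; rows with gland
#' probability >= 0.5 (ties favour glands) are routed to stage B. Class
#' probabilities are composed as `p(artefact) = 1 - pA`,
#' `p(benign) = pA (1 - pB)`, `p(grade3) = pA pB`.
#'
#' @param object an `svm_cascade`.
#' @param newdata numeric feature matrix.
#' @param ... unused.
#' @return list with `class` (character) and `prob` (n x 3 matrix).
#' @export
predict.svm_cascade <- function(object, newdata, ...) {
  p_gland <- .predict_binary_svm(object$stage_a, newdata)
  p_g3 <- .predict_binary_svm(object$stage_b, newdata)
  prob <- cbind(artefact = 1 - p_gland,
                benign = p_gland * (1 - p_g3),
                grade3 = p_gland * p_g3)
  cls <- ifelse(p_gland < 0.5, "artefact",
                ifelse(p_g3 > 0.5, "grade3", "benign"))
  list(class = cls, prob = prob)
}
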