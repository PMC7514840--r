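# Single-hidden-layer perceptron trained by full-batch gradient descent
# with momentum and the classic adaptive learning-rate accept/reject rule.

#' Train the MLP classifier
#'
#' One hidden layer of `hidden` logistic units and a softmax output over
#' the three candidate classes, minimising categorical cross-entropy by
#' full-batch gradient descent with momentum `alpha = 0.9`. The learning
#' rate starts at `eta = 1e-3` and adapts per epoch: if the loss decreases
#' the rate is multiplied by `mu_up = 1.5`; if the new loss exceeds
#' `ratio_max = 1.04` times the previous one, the update is rejected and
#' the rate halved (`mu_down = 0.5`). Training stops when the validation
#' loss has not improved for `patience` epochs or after `max_epochs`.
#'
#' @param x numeric matrix of normalised features.
#' @param labels character vector of classes.
#' @param hidden hidden units (default 15).
#' @param val_fraction fraction of rows held out (stratified) to monitor
#'   early stopping.
#' @param eta,alpha,mu_up,mu_down,ratio_max training-rule constants.
#' @param max_epochs,patience stopping rule.
#' @param seed integer seed (weight initialisation and validation split).
#' @return object of class `mlp_classifier`.
#' @export
mlp_classifier <- function(x, labels, hidden = 15, val_fraction = 0.1,
                           eta = 1e-3, alpha = 0.9, mu_up = 1.5,
                           mu_down = 0.5, ratio_max = 1.04,
                           max_epochs = 1000, patience = 20, seed = 1) {
  classes <- sort(unique(labels))
  if (length(classes) < 3) stop("need the three candidate classes")
  set.seed(as.integer(seed))
  n <- nrow(x)
  val <- .stratified_folds(labels, max(2L, round(1 / val_fraction)), seed) == 1L
  xt <- x[!val, , drop = FALSE]; yt <- labels[!val]
  xv <- x[val, , drop = FALSE]; yv <- labels[val]
  Yt <- outer(yt, classes, "==") * 1
  Yv <- outer(yv, classes, "==") * 1

  d <- ncol(x); k <- length(classes)
  W1 <- matrix(rnorm(d * hidden, 0, 0.1), d, hidden)
  b1 <- rnorm(hidden, 0, 0.01)
  W2 <- matrix(rnorm(hidden * k, 0, 0.1), hidden, k)
  b2 <- rnorm(k, 0, 0.01)

  fwd <- function(X, W1, b1, W2, b2) {
    H <- 1 / (1 + exp(-(X %*% W1 + matrix(b1, nrow(X), hidden, byrow = TRUE))))
    Z <- H %*% W2 + matrix(b2, nrow(X), k, byrow = TRUE)
    Z <- Z - apply(Z, 1, max)
    P <- exp(Z) / rowSums(exp(Z))
    list(H = H, P = P)
  }
  xent <- function(P, Y) -mean(rowSums(Y * log(pmax(P, 1e-12))))

  vel <- list(W1 = W1 * 0, b1 = b1 * 0, W2 = W2 * 0, b2 = b2 * 0)
  f <- fwd(xt, W1, b1, W2, b2)
  loss <- xent(f$P, Yt)
  best_val <- Inf; best <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  stall <- 0L
  trace <- numeric(0)

  for (epoch in seq_len(max_epochs)) {
    # full-batch gradients of the cross-entropy
    G2 <- f$P - Yt
    gW2 <- t(f$H) %*% G2 / nrow(xt)
    gb2 <- colMeans(G2)
    GH <- (G2 %*% t(W2)) * f$H * (1 - f$H)
    gW1 <- t(xt) %*% GH / nrow(xt)
    gb1 <- colMeans(GH)

    nv <- list(W1 = alpha * vel$W1 - eta * gW1,
               b1 = alpha * vel$b1 - eta * gb1,
               W2 = alpha * vel$W2 - eta * gW2,
               b2 = alpha * vel$b2 - eta * gb2)
    cand <- list(W1 = W1 + nv$W1, b1 = b1 + nv$b1,
                 W2 = W2 + nv$W2, b2 = b2 + nv$b2)
    fc <- fwd(xt, cand$W1, cand$b1, cand$W2, cand$b2)
    new_loss <- xent(fc$P, Yt)
    if (!is.finite(new_loss)) stop("training diverged (non-finite loss)")

    if (new_loss > ratio_max * loss) {
      # reject the update, halve the rate, reset momentum
      eta <- eta * mu_down
      vel <- lapply(vel, function(v) v * 0)
    } else {
      if (new_loss < loss) eta <- eta * mu_up
      W1 <- cand$W1; b1 <- cand$b1; W2 <- cand$W2; b2 <- cand$b2
      vel <- nv
      f <- fc
      loss <- new_loss
    }
    trace <- c(trace, loss)

    vloss <- xent(fwd(xv, W1, b1, W2, b2)$P, Yv)
    if (vloss < best_val - 1e-9) {
      best_val <- vloss
      best <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }

  structure(list(W1 = best$W1, b1 = best$b1, W2 = best$W2, b2 = best$b2,
                 classes = classes, hidden = hidden, epochs = length(trace),
                 loss_trace = trace, val_loss = best_val, seed = seed),
            class = "mlp_classifier")
}

#' @export
print.mlp_classifier <- function(x, ...) {
  cat(sprintf("<mlp_classifier %d-%d-%d | %d epochs, val loss %.4f>\n",
              nrow(x$W1), x$hidden, length(x$classes), x$epochs, x$val_loss))
  invisible(x)
}

#' Predict with the MLP classifier
#' @param object an `mlp_classifier`.
#' @param newdata numeric feature matrix.
#' @param ... unused.
#' @return list with `class` and `prob` (n x 3 matrix).
#' @export
predict.mlp_classifier <- function(object, newdata, ...) {
  H <- 1 / (1 + exp(-(newdata %*% object$W1 +
                        matrix(object$b1, nrow(newdata), object$hidden,
                               byrow = TRUE))))
  Z <- H %*% object$W2 + matrix(object$b2, nrow(newdata),
                                length(object$classes), byrow = TRUE)
  Z <- Z - apply(Z, 1, max)
  P <- exp(Z) / rowSums(exp(Z))
  colnames(P) <- object$classes
  list(class = object$classes[max.col(P)], prob = P)
}
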