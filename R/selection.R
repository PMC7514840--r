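# Statistical feature selection: z-score normalisation, a KS normality
# gate deciding between ANOVA and Kruskal-Wallis class tests, and pairwise
# decorrelation of the survivors.

#' Fit and apply z-score normalisation
#'
#' Columns are centred and scaled to unit sample standard deviation.
#' Constant columns become zero and are flagged.
#'
#' @param x numeric matrix (candidates x features).
#' @return list with `x` (normalised matrix), `center`, `scale`, and
#'   `constant` (logical per column).
#' @export
zscore_fit <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  const <- !is.finite(sdv) | sdv == 0
  sc <- ifelse(const, 1, sdv)
  z <- sweep(sweep(x, 2, mu), 2, sc, "/")
  z[, const] <- 0
  list(x = z, center = mu, scale = sc, constant = const)
}

#' Apply stored z-score parameters to new data
#' @param x numeric matrix with the same columns as the fit.
#' @param fit result of [zscore_fit()].
#' @return normalised matrix.
#' @export
zscore_apply <- function(x, fit) {
  z <- sweep(sweep(x, 2, fit$center), 2, fit$scale, "/")
  z[, fit$constant] <- 0
  z
}

#' One-sample Kolmogorov-Smirnov normality test
#'
#' Tests a z-scored column against the standard normal N(0,1). The null
#' hypothesis is normality; `is_normal` is TRUE when the p-value exceeds
#' `alpha`.
#'
#' @param column numeric vector (already z-scored), length >= 8.
#' @param alpha significance level of the gate (default 0.05).
#' @return list with `p_value` and `is_normal`.
#' @export
normality_test <- function(column, alpha = 0.05) {
  if (length(column) < 8) stop("need at least 8 observations")
  p <- suppressWarnings(ks.test(column, "pnorm")$p.value)
  list(p_value = p, is_normal = p > alpha)
}

#' Class-dependence test of one feature
#'
#' One-way ANOVA across classes when the feature passed the normality
#' gate, otherwise Kruskal-Wallis.
#'
#' @param column numeric vector.
#' @param labels factor or character class per observation; at least two
#'   classes with two members each.
#' @param is_normal logical from [normality_test()].
#' @return list with `p_value` and `test` ("anova" or "kruskal").
#' @export
class_dependence_test <- function(column, labels, is_normal) {
  labels <- factor(labels)
  tab <- table(labels)
  if (length(tab) < 2 || any(tab < 2)) {
    stop("need at least two classes with two members each")
  }
  if (is_normal) {
    # suppressed warning: R flags F-tests on near-perfectly separated
    # columns, where p -> 0 is exactly the intended outcome
    fit <- suppressWarnings(lm(column ~ labels))
    p <- suppressWarnings(anova(fit)[["Pr(>F)"]][1])
    list(p_value = p, test = "anova")
  } else {
    p <- kruskal.test(column, labels)$p.value
    list(p_value = p, test = "kruskal")
  }
}

#' Statistical feature selection
#'
#' Stage 1 z-scores every column, gates each with the KS normality test,
#' applies ANOVA (normal) or Kruskal-Wallis (non-normal) against the class
#' labels, and keeps features with `p <= alpha`. Stage 2 computes the
#' Pearson correlation matrix of the survivors with per-pair correlation
#' test p-values and, for every offending pair (`|r| >= r_thresh` and
#' correlation p `<= alpha`), greedily drops the member with the larger
#' class-test p-value (ties drop the later schema column). The procedure
#' is deterministic.
#'
#' @param tab a `feature_table` (or list with `x`, `labels`).
#' @param alpha significance level (default 1e-6).
#' @param r_thresh correlation magnitude threshold (default 0.95).
#' @param ks_alpha significance of the normality gate.
#' @return object of class `selection_result`: `selected` (character),
#'   `record` (per-feature audit data frame), `zscore` (fit parameters),
#'   `alpha`, `r_thresh`.
#' @export
select_features <- function(tab, alpha = 1e-6, r_thresh = 0.95,
                            ks_alpha = 0.05) {
  x <- tab$x
  labels <- tab$labels
  fz <- zscore_fit(x)
  nf <- ncol(x)
  rec <- data.frame(name = colnames(x), mean = fz$center, sd = fz$scale,
                    constant = fz$constant, ks_p = NA_real_,
                    is_normal = NA, test = NA_character_,
                    class_p = NA_real_, dropped_by = "none",
                    stringsAsFactors = FALSE, row.names = NULL)
  for (j in seq_len(nf)) {
    if (fz$constant[j]) {
      rec$dropped_by[j] <- "class_independence"
      rec$class_p[j] <- 1
      next
    }
    nt <- normality_test(fz$x[, j], ks_alpha)
    ct <- class_dependence_test(fz$x[, j], labels, nt$is_normal)
    rec$ks_p[j] <- nt$p_value
    rec$is_normal[j] <- nt$is_normal
    rec$test[j] <- ct$test
    rec$class_p[j] <- ct$p_value
    if (!(ct$p_value <= alpha)) {
      rec$dropped_by[j] <- "class_independence"
    }
  }
  kept <- which(rec$dropped_by == "none")
  if (length(kept) == 0) {
    stop("no feature passes the class-dependence stage; relax alpha")
  }

  # stage 2: pairwise decorrelation of the survivors
  if (length(kept) > 1) {
    r <- cor(fz$x[, kept, drop = FALSE])
    n <- nrow(x)
    tstat <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    pmat <- 2 * pt(tstat, df = n - 2, lower.tail = FALSE)
    viol <- which(abs(r) >= r_thresh & pmat <= alpha & upper.tri(r),
                  arr.ind = TRUE)
    viol <- viol[order(viol[, 1], viol[, 2]), , drop = FALSE]
    active <- rep(TRUE, length(kept))
    # one ordered pass: a feature once dropped never returns, so every
    # offending pair ends with at least one member removed
    for (v in seq_len(nrow(viol))) {
      a <- viol[v, 1]; b <- viol[v, 2]
      if (!active[a] || !active[b]) next
      pa <- rec$class_p[kept[a]]
      pb <- rec$class_p[kept[b]]
      worse <- if (pa > pb) a else b     # tie drops the later schema column
      partner <- if (worse == a) b else a
      active[worse] <- FALSE
      rec$dropped_by[kept[worse]] <-
        paste0("correlation(", rec$name[kept[partner]], ")")
    }
    kept <- kept[active]
  }

  structure(list(selected = rec$name[kept], record = rec, zscore = fz[-1],
                 alpha = alpha, r_thresh = r_thresh, ks_alpha = ks_alpha),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  n_all <- nrow(x$record)
  n_cls <- sum(x$record$dropped_by == "class_independence")
  n_cor <- sum(startsWith(x$record$dropped_by, "correlation"))
  cat(sprintf("<selection_result %d/%d selected (%d class-independent, %d correlated) at alpha=%g>\n",
              length(x$selected), n_all, n_cls, n_cor, x$alpha))
  invisible(x)
}
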