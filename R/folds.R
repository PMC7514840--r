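# Patient-wise fold assignment for cross-validation.

#' Patient-wise fold plan
#'
#' Assigns whole patients to `k_outer` folds by greedy balanced
#' bin-packing: patients are sorted by candidate count (descending, ties
#' broken by a seeded shuffle) and each is assigned to the fold that
#' minimises the resulting class-count imbalance. All candidates of one
#' patient share one fold.
#'
#' @param patient_ids character vector, one entry per candidate.
#' @param labels class per candidate.
#' @param k_outer number of folds (default 5).
#' @param seed integer seed for tie-breaking.
#' @return object of class `fold_plan`: `assignment` (named fold index per
#'   patient), `fold` (per candidate), `k_outer`.
#' @export
make_fold_plan <- function(patient_ids, labels, k_outer = 5, seed = 1) {
  pats <- unique(patient_ids)
  if (length(pats) < k_outer) {
    stop("need at least ", k_outer, " patients for ", k_outer, " folds")
  }
  cls <- sort(unique(labels))
  per_pat <- matrix(vapply(pats, function(p) {
    as.numeric(table(factor(labels[patient_ids == p], levels = cls)))
  }, numeric(length(cls))), nrow = length(pats), ncol = length(cls),
  byrow = TRUE)
  counts <- rowSums(per_pat)
  set.seed(as.integer(seed))
  ord <- order(counts + runif(length(counts)) * 0.5, decreasing = TRUE)

  fold_tot <- matrix(0, k_outer, length(cls))
  fold_n <- integer(k_outer)
  assign_f <- integer(length(pats))
  target <- colSums(per_pat) / k_outer
  for (i in ord) {
    best <- 1L; best_cost <- Inf
    for (f in seq_len(k_outer)) {
      # imbalance if patient i joins fold f, plus a small size-balance term
      cand <- fold_tot
      cand[f, ] <- cand[f, ] + per_pat[i, ]
      cost <- sum((sweep(cand, 2, target))^2) +
        0.01 * var(fold_n + (seq_len(k_outer) == f) * counts[i])
      if (cost < best_cost - 1e-12) {
        best_cost <- cost
        best <- f
      }
    }
    assign_f[i] <- best
    fold_tot[best, ] <- fold_tot[best, ] + per_pat[i, ]
    fold_n[best] <- fold_n[best] + counts[i]
  }
  assignment <- setNames(assign_f, pats)
  structure(list(assignment = assignment,
                 fold = unname(assignment[patient_ids]),
                 k_outer = k_outer, seed = seed),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan %d folds, %d patients>\n", x$k_outer,
              length(x$assignment)))
  print(table(fold = x$fold))
  invisible(x)
}

# stratified record-wise folds for inner CV (hyperparameter tuning)
.stratified_folds <- function(labels, k, seed) {
  set.seed(as.integer(seed))
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}
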