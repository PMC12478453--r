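#' PCA + linear-SVM leave-one-out cross-validation
#'
#' For each held-out sample, PCA (to `n_pcs` components, auto-scaled) and
#' a linear-kernel SVM are fitted on the remaining samples only; the
#' held-out sample is projected into that fold's PCA space and predicted.
#' The cost parameter is chosen from `c_grid` by an inner leave-one-out
#' loop nested inside each training fold (ties go to the smallest cost),
#' so model selection never sees the held-out sample. Set `leaky = TRUE`
#' to instead fit the PCA once on all samples before cross-validating,
#' the optimistic variant some published workflows use.
#'
#' @param x Samples x features matrix or tibble.
#' @param labels Two-class labels, at least 3 samples per class.
#' @param c_grid Candidate SVM costs within \[1, 100\]; the default is a
#'   log-spaced sub-grid. A single value skips the inner selection loop.
#' @param n_pcs Components retained (2, matching the embedding used for
#'   visual comparison of feature sets).
#' @param scale Auto-scale features inside each fold.
#' @param leaky Fit PCA on all samples (not per fold)?
#' @return A `cv_report`: `accuracy`, modal `chosen_C`, per-fold costs and
#'   held-out `predictions`.
#' @export
pca_svm_loocv <- function(x, labels, c_grid = c(1, 2, 5, 10, 20, 50, 100),
                          n_pcs = 2L, scale = TRUE, leaky = FALSE) {
  X <- as_feature_matrix(x)
  y <- factor(as.character(labels))
  n <- nrow(X)
  if (n < 6L) stop("fold error: need at least 6 samples", call. = FALSE)
  if (nlevels(y) != 2L || any(table(y) < 3L))
    stop("fold error: two classes with at least 3 members each required",
         call. = FALSE)
  c_grid <- sort(unique(c_grid))
  if (any(c_grid < 1 | c_grid > 100))
    stop("c_grid values must lie in [1, 100]", call. = FALSE)

  global_pca <- if (leaky) pca_embed(X, k = n_pcs, scale = scale) else NULL
  preds <- character(n)
  fold_C <- numeric(n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]; ytr <- y[-i]
    C <- if (length(c_grid) == 1L) c_grid else
      select_cost(Xtr, ytr, c_grid, n_pcs, scale, global_pca)
    fold_C[i] <- C
    preds[i] <- fit_predict(Xtr, ytr, X[i, , drop = FALSE], C, n_pcs, scale,
                            global_pca)
  }
  acc <- mean(preds == as.character(y))
  tab <- table(fold_C)
  modal <- as.numeric(names(tab)[which.max(tab)])
  structure(list(accuracy = acc, chosen_C = modal, fold_C = fold_C,
                 predictions = tibble(sample = rownames(X) %||%
                                        as.character(seq_len(n)),
                                      truth = as.character(y),
                                      predicted = preds),
                 c_grid = c_grid, leaky = leaky),
            class = "cv_report")
}

# Inner LOOCV over the training fold for each candidate cost; smallest
# cost wins ties.
select_cost <- function(Xtr, ytr, c_grid, n_pcs, scale, global_pca) {
  m <- nrow(Xtr)
  acc <- vapply(c_grid, function(C) {
    hits <- vapply(seq_len(m), function(j) {
      fit_predict(Xtr[-j, , drop = FALSE], ytr[-j],
                  Xtr[j, , drop = FALSE], C, n_pcs, scale, global_pca) ==
        as.character(ytr[j])
    }, logical(1))
    mean(hits)
  }, numeric(1))
  c_grid[which.max(acc)]  # which.max returns the first (smallest) maximizer
}

fit_predict <- function(Xtr, ytr, Xte, C, n_pcs, scale, global_pca) {
  if (is.null(global_pca)) {
    pc <- pca_embed(Xtr, k = n_pcs, scale = scale)
    Str <- pc$coordinates
    Ste <- project_pca(pc, Xte)
  } else {
    Str <- project_pca(global_pca, Xtr)
    Ste <- project_pca(global_pca, Xte)
  }
  fit <- e1071::svm(Str, droplevels(ytr), kernel = "linear", cost = C,
                    scale = FALSE)
  as.character(predict(fit, Ste))
}

project_pca <- function(pc, Xnew) {
  Z <- sweep(Xnew, 2L, pc$center, "-")
  if (!is.null(pc$scale)) Z <- sweep(Z, 2L, pc$scale, "/")
  Z %*% pc$rotation[, seq_len(pc$k), drop = FALSE]
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> LOOCV accuracy %.3f over %d folds (modal C = %g%s)\n",
              x$accuracy, nrow(x$predictions), x$chosen_C,
              if (x$leaky) ", leaky PCA" else ""))
  invisible(x)
}
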