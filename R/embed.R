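#' PCA embedding of a feature table
#'
#' Column-centered (and by default unit-variance auto-scaled) principal
#' component analysis via the singular value decomposition.
#'
#' @param x Samples x features matrix or tibble.
#' @param k Number of components to keep (`<= min(n - 1, p)`).
#' @param scale Auto-scale features to unit variance? Default `TRUE`,
#'   the convention for peak and protein tables whose bands live on very
#'   different intensity scales.
#' @return A `raman_embedding`: `method = "pca"`, `coordinates` (n x k
#'   scores), `explained_variance` (fractions for all components), plus
#'   the rotation/center/scale needed to project new samples.
#' @export
pca_embed <- function(x, k = 2L, scale = TRUE) {
  X <- as_feature_matrix(x)
  kmax <- min(nrow(X) - 1L, ncol(X))
  if (k > kmax)
    stop("rank error: k = ", k, " exceeds min(n - 1, p) = ", kmax,
         call. = FALSE)
  sds <- apply(X, 2L, sd)
  if (scale && any(sds == 0))
    stop("zero-variance feature(s) cannot be auto-scaled: ",
         paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  pc <- prcomp(X, center = TRUE, scale. = scale)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(method = "pca",
                 coordinates = pc$x[, seq_len(k), drop = FALSE],
                 explained_variance = ev,
                 rotation = pc$rotation, center = pc$center,
                 scale = if (isFALSE(pc$scale)) NULL else pc$scale,
                 k = k),
            class = "raman_embedding")
}

#' @export
print.raman_embedding <- function(x, ...) {
  cat(sprintf("<raman_embedding> %s: %d samples x %d dims", x$method,
              nrow(x$coordinates), ncol(x$coordinates)))
  if (!is.null(x$explained_variance))
    cat(sprintf(" (PC1 %.1f%%, PC2 %.1f%%)",
                100 * x$explained_variance[1L],
                100 * x$explained_variance[2L]))
  cat("\n")
  invisible(x)
}

#' PCA-initialized t-SNE embedding
#'
#' Reduces to `n_pcs` principal components, then runs exact
#' (non-approximated) t-SNE to two dimensions. Deterministic for a given
#' seed. Perplexity defaults to `min(30, (n - 1) / 3)`, the feasibility
#' bound for the conditional distributions.
#'
#' @param x Samples x features matrix or tibble (n >= 8).
#' @param n_pcs Principal components fed to t-SNE.
#' @param perplexity Effective neighborhood size.
#' @param seed RNG seed for the random initialization.
#' @param max_iter Gradient-descent iterations.
#' @param scale Auto-scale features before PCA.
#' @return A `raman_embedding` with `method = "pca_tsne"` and the seed
#'   recorded.
#' @export
pca_tsne <- function(x, n_pcs = 10L, perplexity = NULL, seed = 1L,
                     max_iter = 500L, scale = TRUE) {
  X <- as_feature_matrix(x)
  n <- nrow(X)
  if (n < 8L) stop("pca_tsne needs at least 8 samples", call. = FALSE)
  perplexity <- perplexity %||% min(30, (n - 1) / 3)
  if (perplexity < 2 || perplexity > (n - 1) / 3)
    stop("parameter error: perplexity must be in [2, (n - 1) / 3]",
         call. = FALSE)
  n_pcs <- min(n_pcs, n - 1L, ncol(X))
  scores <- pca_embed(X, k = n_pcs, scale = scale)$coordinates
  Y <- with_seed(seed, tsne_exact(scores, perplexity = perplexity,
                                  max_iter = max_iter))
  rownames(Y) <- rownames(X)
  colnames(Y) <- c("TSNE1", "TSNE2")
  structure(list(method = "pca_tsne", coordinates = Y,
                 explained_variance = NULL, seed = seed,
                 perplexity = perplexity, n_pcs = n_pcs),
            class = "raman_embedding")
}

# Exact t-SNE (van der Maaten & Hinton's reference scheme): per-point
# precision calibrated by bisection to the target perplexity, symmetrized
# affinities, early exaggeration, momentum gradient descent. Quadratic in
# n, which is fine at cohort scale (tens to a few hundred samples).
tsne_exact <- function(X, perplexity, max_iter = 500L, eta = 200,
                       exaggeration = 12, exag_iter = 100L) {
  n <- nrow(X)
  D2 <- as.matrix(dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1
    lo <- -Inf; hi <- Inf
    for (it in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      H <- log(sw) + beta * sum(di * w) / sw
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- w / sw
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2L)
  inc <- matrix(0, n, 2L)
  for (iter in seq_len(max_iter)) {
    Pe <- if (iter <= exag_iter) P * exaggeration else P
    num <- 1 / (1 + as.matrix(dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) %*% Y - L %*% Y)
    mom <- if (iter <= 250L) 0.5 else 0.8
    inc <- mom * inc - eta * grad
    Y <- Y + inc
    Y <- sweep(Y, 2L, colMeans(Y), "-")
  }
  Y
}
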