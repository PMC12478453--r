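#' Unpaired two-sided homoscedastic t-test
#'
#' Pooled-variance Student's t with `n_x + n_y - 2` degrees of freedom;
#' the significance engine behind the volcano and rank-metric analyses.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return List with `t_stat`, `p_value`, `df`.
#' @export
ttest_homoscedastic <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L)
    stop("both groups need at least 2 observations", call. = FALSE)
  df <- nx + ny - 2L
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / df
  if (!is.finite(sp2) || sp2 <= 0)
    stop("degenerate error: zero pooled variance", call. = FALSE)
  t_stat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t_stat = t_stat, p_value = 2 * pt(-abs(t_stat), df), df = df)
}

#' Volcano analysis of a feature table
#'
#' Per feature: linear-scale fold change as the ratio of group means
#' (case over reference) and a two-sided homoscedastic t-test p-value.
#' Significance is raw `p < alpha` by default; Benjamini-Hochberg
#' adjustment is available behind `adjust = "BH"`.
#'
#' @param table A `peak_table`, tibble or matrix of samples x features.
#' @param groups Group label per sample (row).
#' @param case,reference Labels of the two groups compared.
#' @param alpha Significance level.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Tibble with `feature`, `fold_change`, `log2_fc`, `t_stat`,
#'   `p_value`, `significant`.
#' @export
volcano <- function(table, groups, case, reference, alpha = 0.05,
                    adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  m <- if (is.matrix(table)) table else peak_matrix(table)
  groups <- as.character(groups)
  if (length(groups) != nrow(m))
    stop("groups must have one label per sample", call. = FALSE)
  for (g in c(case, reference))
    if (sum(groups == g) < 2L)
      stop("label error: group '", g, "' has fewer than 2 samples",
           call. = FALSE)
  xi <- groups == case; yi <- groups == reference
  res <- lapply(seq_len(ncol(m)), function(j) {
    fc <- mean(m[xi, j]) / mean(m[yi, j])
    # constant features (e.g. the ratiometric denominator, identically 1)
    # carry no evidence: t = 0, p = 1 when the means agree
    tt <- tryCatch(ttest_homoscedastic(m[xi, j], m[yi, j]),
                   error = function(e) {
                     if (isTRUE(all.equal(mean(m[xi, j]), mean(m[yi, j]))))
                       list(t_stat = 0, p_value = 1)
                     else list(t_stat = Inf * sign(fc - 1), p_value = 0)
                   })
    c(fc = fc, t = tt$t_stat, p = tt$p_value)
  })
  res <- do.call(rbind, res)
  p <- if (adjust == "BH") stats::p.adjust(res[, "p"], "BH") else res[, "p"]
  tibble(feature = colnames(m),
         fold_change = res[, "fc"],
         log2_fc = log2(res[, "fc"]),
         t_stat = res[, "t"],
         p_value = res[, "p"],
         significant = p < alpha)
}

#' Pairwise Pearson correlation matrix
#'
#' Correlates the columns of `x` with the columns of `y` (or with
#' themselves). Zero-variance features are flagged with a warning and
#' yield `NA` entries.
#'
#' @param x,y Matrices or tibbles of samples x features on the same
#'   samples; `y = NULL` correlates `x` with itself.
#' @return Matrix of Pearson r values.
#' @export
pearson_matrix <- function(x, y = NULL) {
  X <- as_feature_matrix(x)
  Y <- if (is.null(y)) X else as_feature_matrix(y)
  if (nrow(X) != nrow(Y))
    stop("x and y must share their samples", call. = FALSE)
  if (nrow(X) < 3L)
    stop("sample-size error: need at least 3 common samples", call. = FALSE)
  flat <- function(M) colnames(M)[apply(M, 2L, sd) == 0]
  zv <- unique(c(flat(X), flat(Y)))
  if (length(zv))
    warning("zero-variance feature(s): ", paste(zv, collapse = ", "),
            "; correlations set to NA", call. = FALSE)
  r <- suppressWarnings(cor(X, Y))
  r[!is.finite(r)] <- NA_real_
  r
}

as_feature_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.data.frame(x)) {
    if ("sample_id" %in% names(x)) return(peak_matrix(x))
    return(as.matrix(x))
  }
  m <- as.matrix(x)
  if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  m
}

#' Univariate ROC analysis with bootstrap CI
#'
#' AUC by Mann-Whitney pair counting (midranks, so ties are credited one
#' half). The orientation is fixed: the hypothesis is that the positive
#' class scores higher, and the AUC is reported as computed, never
#' auto-flipped. The 95% CI is a stratified percentile bootstrap
#' (positives and negatives resampled separately).
#'
#' @param scores Numeric scores.
#' @param labels Class labels (two classes).
#' @param positive Which label is the positive class; defaults to `TRUE`
#'   for logical labels, else the last sorted level.
#' @param n_boot Bootstrap resamples.
#' @param seed Optional seed for the bootstrap (callers' RNG untouched).
#' @param conf_level Confidence level.
#' @return A `roc_result`: `auc`, `ci_low`, `ci_high`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, positive = NULL, n_boot = 2000L,
                    seed = NULL, conf_level = 0.95) {
  stopifnot(length(scores) == length(labels))
  if (is.logical(labels)) positive <- positive %||% TRUE
  lev <- sort(unique(as.character(labels)))
  if (length(lev) != 2L)
    stop("class error: labels must contain exactly two classes", call. = FALSE)
  positive <- as.character(positive %||% lev[2L])
  pos <- as.character(labels) == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos < 1L || n_neg < 1L)
    stop("class error: both classes must be present", call. = FALSE)
  auc <- auc_rank(scores, pos)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L) {
    ip <- which(pos); ineg <- which(!pos)
    boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
      bi <- c(ip[sample.int(n_pos, n_pos, replace = TRUE)],
              ineg[sample.int(n_neg, n_neg, replace = TRUE)])
      auc_rank(scores[bi], pos[bi])
    }, numeric(1)))
    a <- (1 - conf_level) / 2
    ci <- unname(quantile(boots, c(a, 1 - a)))
  }
  structure(list(auc = auc, ci_low = ci[1L], ci_high = ci[2L],
                 n_pos = n_pos, n_neg = n_neg, n_boot = n_boot,
                 positive = positive),
            class = "roc_result")
}

# Midrank AUC: equals exhaustive counting of (pos, neg) pairs with ties
# worth 1/2.
auc_rank <- function(scores, pos) {
  r <- rank(scores)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f (95%% CI %.3f-%.3f), %d positive / %d negative\n",
              x$auc, x$ci_low, x$ci_high, x$n_pos, x$n_neg))
  invisible(x)
}

#' Neoadjuvant-rectal-score responder strata
#'
#' NAR is a surrogate endpoint of chemoradiation response in rectal
#' cancer; lower is better. Scores below 8 are complete responders, 8-14
#' inclusive partial, above 14 poor.
#'
#' @param nar_score Nonnegative numeric vector; `NA` passes through.
#' @return Character vector in `{"complete", "partial", "poor"}`.
#' @export
stratify_nar <- function(nar_score) {
  if (any(nar_score < 0, na.rm = TRUE))
    stop("domain error: NAR score must be nonnegative", call. = FALSE)
  out <- ifelse(nar_score < 8, "complete",
                ifelse(nar_score <= 14, "partial", "poor"))
  out
}

#' Channel-wise difference of two mean spectra
#'
#' @param mean_a,mean_b Spectra on identical grids (e.g. from
#'   [mean_spectrum()]).
#' @return List with `wavenumbers` and `intensities = a - b`.
#' @export
difference_spectrum <- function(mean_a, mean_b) {
  if (length(mean_a$wavenumbers) != length(mean_b$wavenumbers) ||
      any(mean_a$wavenumbers != mean_b$wavenumbers))
    stop("axis error: spectra are on different grids", call. = FALSE)
  list(wavenumbers = mean_a$wavenumbers,
       intensities = mean_a$intensities - mean_b$intensities)
}
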