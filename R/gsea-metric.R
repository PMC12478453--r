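#' Signed significance rank metric
#'
#' The metric used to order proteins for gene-set enrichment exports:
#' `-log10(p) * sign(log2(FC))`, where p comes from an unpaired two-sided
#' homoscedastic t-test and FC is the linear-scale ratio of group means.
#' A fold change of exactly 1 has sign 0 and metric 0. The metric is
#' monotone decreasing in p for FC > 1 and antisymmetric under
#' `FC -> 1/FC`.
#'
#' @param p_value p-values in (0, 1].
#' @param fold_change Positive fold changes.
#' @return Signed numeric metric (vectorized).
#' @export
rank_metric <- function(p_value, fold_change) {
  if (any(!is.finite(p_value)) || any(p_value <= 0) || any(p_value > 1))
    stop("domain error: p-values must lie in (0, 1]", call. = FALSE)
  if (any(!is.finite(fold_change)) || any(fold_change <= 0))
    stop("domain error: fold changes must be positive", call. = FALSE)
  -log10(p_value) * sign(log2(fold_change))
}

#' Call differential expression at the rank-metric cutoff
#'
#' Computes the rank metric per protein and flags proteins whose absolute
#' metric exceeds the cutoff. The default cutoff is `-log10(0.05)`
#' (printed as 1.30), i.e. the alpha = 0.05 line; the comparison is
#' strict on metrics rounded to 4 decimals, so p = 0.05 exactly is not
#' differential. Output is sorted by descending metric: positive metrics
#' are proteins upregulated in the case group.
#'
#' @param proteins Data frame with columns `protein`, `p_value`,
#'   `fold_change` (case-over-reference ratio of means).
#' @param cutoff Absolute-metric cutoff.
#' @return Tibble with `protein`, `p_value`, `fold_change`, `rank_metric`,
#'   `differential`, sorted by descending metric.
#' @export
call_differential <- function(proteins, cutoff = -log10(0.05)) {
  proteins <- as.data.frame(proteins)
  if (nrow(proteins) == 0L)
    return(tibble(protein = character(), p_value = numeric(),
                  fold_change = numeric(), rank_metric = numeric(),
                  differential = logical()))
  stopifnot(all(c("protein", "p_value", "fold_change") %in% names(proteins)))
  if (anyDuplicated(proteins$protein))
    stop("duplicate error: protein ids must be unique (",
         proteins$protein[duplicated(proteins$protein)][1L], ")",
         call. = FALSE)
  m <- rank_metric(proteins$p_value, proteins$fold_change)
  diff <- round(abs(m), 4L) > round(cutoff, 4L)
  out <- tibble(protein = as.character(proteins$protein),
                p_value = proteins$p_value,
                fold_change = proteins$fold_change,
                rank_metric = m, differential = diff)
  out[order(-out$rank_metric), , drop = FALSE]
}

#' Rank metrics from a protein panel and group labels
#'
#' Per protein: fold change = mean(case) / mean(reference), p-value from
#' [ttest_homoscedastic()], then metric and differential call via
#' [call_differential()].
#'
#' @param panel Protein panel tibble (`sample_id` + analyte columns) or
#'   samples x proteins matrix.
#' @param labels Group label per sample.
#' @param case,reference The two responder groups compared (defaults
#'   complete vs poor, so positive metrics mean higher in complete
#'   responders).
#' @param cutoff Passed to [call_differential()].
#' @return Sorted tibble of ranked proteins.
#' @export
metrics_from_groups <- function(panel, labels, case = "complete",
                                reference = "poor",
                                cutoff = -log10(0.05)) {
  m <- as_feature_matrix(panel)
  labels <- as.character(labels)
  if (length(labels) != nrow(m))
    stop("labels must have one entry per sample", call. = FALSE)
  ci <- labels == case; ri <- labels == reference
  if (sum(ci) < 2L || sum(ri) < 2L)
    stop("both groups need at least 2 samples", call. = FALSE)
  rows <- lapply(seq_len(ncol(m)), function(j) {
    mr <- mean(m[ri, j])
    if (mr == 0)
      stop("degenerate error: zero reference mean for protein ",
           colnames(m)[j], call. = FALSE)
    tt <- ttest_homoscedastic(m[ci, j], m[ri, j])
    data.frame(protein = colnames(m)[j], p_value = tt$p_value,
               fold_change = mean(m[ci, j]) / mr)
  })
  call_differential(do.call(rbind, rows), cutoff = cutoff)
}

#' Write a two-column rank file for external enrichment tools
#'
#' Tab-separated `protein<TAB>metric`, no header, sorted by descending
#' metric — the conventional input for set-level enrichment platforms.
#'
#' @param ranked Output of [call_differential()] or
#'   [metrics_from_groups()].
#' @param path Output path (conventionally `.rnk`).
#' @export
write_rnk <- function(ranked, path) {
  o <- ranked[order(-ranked$rank_metric), , drop = FALSE]
  writeLines(sprintf("%s\t%.6g", o$protein, o$rank_metric), path)
  invisible(path)
}
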