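#' Assemble a pipeline run configuration
#'
#' A run is driven either by a simulation design (`simulate` = a
#' [synthetic_config()]) or by input files (`spectra_csv`,
#' `metadata_csv`, optionally `proteins_csv`). Preprocessing and panel
#' settings ride along; every stochastic stage (bootstrap CIs, t-SNE)
#' derives its stream from the single root `seed`.
#'
#' @param simulate Optional [synthetic_config()].
#' @param spectra_csv,metadata_csv,proteins_csv Input paths (ignored when
#'   `simulate` is given).
#' @param params [preprocess_params()].
#' @param panel [peak_panel()].
#' @param grid Harmonization grid for file inputs.
#' @param seed Root seed; defaults to the simulation seed.
#' @param c_grid SVM cost grid for [run_integration()].
#' @param n_boot Bootstrap resamples for ROC confidence intervals.
#' @return A `run_config` list.
#' @export
run_config <- function(simulate = NULL, spectra_csv = NULL,
                       metadata_csv = NULL, proteins_csv = NULL,
                       params = preprocess_params(), panel = default_panel(),
                       grid = c(600, 1800, 1), seed = NULL,
                       c_grid = c(1, 2, 5, 10, 20, 50, 100),
                       n_boot = 2000L) {
  if (is.null(simulate) && (is.null(spectra_csv) || is.null(metadata_csv)))
    stop("config error: provide either `simulate` or spectra_csv + metadata_csv",
         call. = FALSE)
  seed <- seed %||% (if (!is.null(simulate)) simulate$seed else 1L)
  structure(list(simulate = simulate, spectra_csv = spectra_csv,
                 metadata_csv = metadata_csv, proteins_csv = proteins_csv,
                 params = params, panel = panel, grid = grid,
                 seed = as.integer(seed), c_grid = c_grid,
                 n_boot = as.integer(n_boot)),
            class = "run_config")
}

# Load or simulate the cohort, preprocess every sample, and build the
# ratiometric peak table. The workhorse behind all three run_* fronts.
prepare_cohort <- function(config) {
  if (!is.null(config$simulate)) {
    cohort <- generate_cohort(config$simulate)
    spectra <- cohort$spectra
    metadata <- cohort$metadata
    proteins <- cohort$proteins
    truth <- cohort$truth
  } else {
    spectra <- read_spectra(config$spectra_csv)
    spectra <- lapply(spectra, harmonize_axis, grid = config$grid)
    metadata <- read_cohort_metadata(config$metadata_csv)
    proteins <- if (!is.null(config$proteins_csv))
      read_protein_panel(config$proteins_csv) else NULL
    truth <- NULL
  }
  metadata <- apply_exclusions(metadata, longitudinal = TRUE)
  spectra <- spectra[names(spectra) %in% metadata$sample_id]
  processed <- lapply(spectra, preprocess_sample, params = config$params)
  table <- build_peak_table(processed, config$panel)
  metadata <- metadata[match(table$sample_id, metadata$sample_id), ,
                       drop = FALSE]
  list(processed = processed, table = table, metadata = metadata,
       proteins = proteins, truth = truth)
}

# Peak matrix without the ratiometric denominator column, which is
# identically 1 and carries no information for scaled multivariate
# analyses (it cannot be auto-scaled and would only produce NA
# correlations).
analysis_matrix <- function(table, panel) {
  m <- peak_matrix(table)
  denom <- paste0("peak_", format_wn(panel$denominator_wavenumber))
  m[, setdiff(colnames(m), denom), drop = FALSE]
}

# Mean processed spectrum over the samples of one group.
group_mean_spectrum <- function(processed, sample_ids) {
  ms <- lapply(processed[sample_ids], mean_spectrum)
  list(wavenumbers = ms[[1L]]$wavenumbers,
       intensities = rowMeans(vapply(ms, `[[`, ms[[1L]]$intensities,
                                     "intensities")))
}

roc_table <- function(table, labels, positive, n_boot, seed) {
  m <- peak_matrix(table)
  rows <- lapply(seq_len(ncol(m)), function(j) {
    r <- roc_auc(m[, j], labels, positive = positive, n_boot = n_boot,
                 seed = seed + j)
    data.frame(feature = colnames(m)[j], auc = r$auc, ci_low = r$ci_low,
               ci_high = r$ci_high, n_pos = r$n_pos, n_neg = r$n_neg)
  })
  as_tibble(do.call(rbind, rows))
}

write_manifest <- function(out_dir, config, extra = character()) {
  files <- sort(setdiff(list.files(out_dir), "manifest.txt"))
  md5 <- tools::md5sum(file.path(out_dir, files))
  lines <- c(sprintf("seraman_version=%s",
                     as.character(utils::packageVersion("seraman"))),
             sprintf("seed=%d", config$seed),
             if (!is.null(config$simulate))
               paste0("simulate_", config_lines(config$simulate)),
             extra,
             sprintf("md5_%s=%s", files, unname(md5)))
  writeLines(lines, file.path(out_dir, "manifest.txt"))
}

#' Diagnosis workflow: cancer vs inflammation vs healthy
#'
#' Preprocesses the cohort, builds the peak table, and writes: volcano
#' tables for each disease group against healthy, per-peak ROC for
#' PDAC vs CP (the clinically hard comparison), PCA and PCA-tSNE
#' embeddings, group difference spectra, and a reproducibility manifest.
#'
#' @param config A [run_config()]; the metadata must contain `healthy`
#'   plus `PDAC` and/or `CP`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the peak table, volcano tables, ROC
#'   table, embeddings and output paths.
#' @export
run_diagnosis <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ch <- prepare_cohort(config)
  groups <- ch$metadata$group
  if (!"healthy" %in% groups || !any(c("PDAC", "CP") %in% groups))
    stop("config error: diagnosis needs group 'healthy' plus 'PDAC' and/or 'CP'",
         call. = FALSE)
  write_peak_table(ch$table, file.path(out_dir, "peak_table.csv"))

  cases <- intersect(c("PDAC", "CP"), unique(groups))
  volcanoes <- list()
  for (g in cases) {
    v <- volcano(ch$table, groups, case = g, reference = "healthy")
    volcanoes[[g]] <- v
    write_table_csv(v, file.path(out_dir,
                                 sprintf("volcano_%s_vs_healthy.csv", g)))
    d <- difference_spectrum(
      group_mean_spectrum(ch$processed, ch$table$sample_id[groups == g]),
      group_mean_spectrum(ch$processed,
                          ch$table$sample_id[groups == "healthy"]))
    write_table_csv(tibble(wavenumber_cm1 = d$wavenumbers,
                           difference = d$intensities),
                    file.path(out_dir,
                              sprintf("difference_%s_vs_healthy.csv", g)))
  }
  roc <- NULL
  if (all(c("PDAC", "CP") %in% groups)) {
    v <- volcano(ch$table, groups, case = "PDAC", reference = "CP")
    volcanoes[["PDAC_vs_CP"]] <- v
    write_table_csv(v, file.path(out_dir, "volcano_PDAC_vs_CP.csv"))
    sel <- groups %in% c("PDAC", "CP")
    roc <- roc_table(ch$table[sel, ], groups[sel], positive = "PDAC",
                     n_boot = config$n_boot, seed = config$seed)
    write_table_csv(roc, file.path(out_dir, "roc_PDAC_vs_CP.csv"))
  }

  am <- analysis_matrix(ch$table, config$panel)
  pca <- pca_embed(am, k = 2L)
  emb <- tibble(sample_id = ch$table$sample_id, group = groups,
                PC1 = pca$coordinates[, 1L], PC2 = pca$coordinates[, 2L])
  write_table_csv(emb, file.path(out_dir, "embedding_pca.csv"))
  tsne <- NULL
  if (nrow(ch$table) >= 8L) {
    tsne <- pca_tsne(am, seed = config$seed)
    write_table_csv(tibble(sample_id = ch$table$sample_id, group = groups,
                           TSNE1 = tsne$coordinates[, 1L],
                           TSNE2 = tsne$coordinates[, 2L]),
                    file.path(out_dir, "embedding_pca_tsne.csv"))
  }
  write_manifest(out_dir, config)
  invisible(list(table = ch$table, metadata = ch$metadata,
                 volcano = volcanoes, roc = roc, pca = pca, tsne = tsne,
                 out_dir = out_dir))
}

#' Treatment-response workflow for the rectal-cancer cohort
#'
#' Stratifies LARC samples by NAR score, correlates every panel band
#' with NAR at pre- and post-treatment, compares pre vs post within
#' responder strata (volcano), and runs per-peak ROC for poor vs
#' complete/partial responders at pre-treatment.
#'
#' @param config A [run_config()]; metadata must contain LARC groups
#'   with NAR scores.
#' @param out_dir Output directory.
#' @return Invisibly, peak table, stratified metadata, correlation
#'   tables, volcano tables and the ROC table.
#' @export
run_response <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ch <- prepare_cohort(config)
  md <- ch$metadata
  if (!any(startsWith(md$group, "LARC")))
    stop("config error: response analysis needs LARC groups", call. = FALSE)
  md$responder <- stratify_nar(md$nar_score)
  if (length(unique(stats::na.omit(md$responder))) < 2L)
    warning("all NAR-scored samples fall in one responder stratum",
            call. = FALSE)
  write_peak_table(ch$table, file.path(out_dir, "peak_table.csv"))
  write_table_csv(md, file.path(out_dir, "metadata_stratified.csv"))

  m <- analysis_matrix(ch$table, config$panel)
  cors <- list()
  for (g in intersect(c("LARC_pre", "LARC_post"), unique(md$group))) {
    sel <- md$group == g & !is.na(md$nar_score)
    dropped <- sum(md$group == g) - sum(sel)
    if (dropped > 0)
      warning(dropped, " ", g, " sample(s) without NAR score excluded ",
              "from correlation", call. = FALSE)
    if (sum(sel) >= 3L) {
      r <- pearson_matrix(m[sel, , drop = FALSE],
                          matrix(md$nar_score[sel], ncol = 1L,
                                 dimnames = list(NULL, "nar_score")))
      tab <- tibble(feature = rownames(r), r_nar = r[, 1L])
      cors[[g]] <- tab
      write_table_csv(tab, file.path(out_dir,
                                     sprintf("correlation_nar_%s.csv", g)))
    }
  }

  volcanoes <- list()
  if (all(c("LARC_pre", "LARC_post") %in% md$group)) {
    for (cls in list(poor = "poor", responder = c("complete", "partial"))) {
      nm <- if (length(cls) == 1L) cls else "complete_partial"
      sel <- md$responder %in% cls & !is.na(md$responder)
      if (sum(sel & md$group == "LARC_pre") >= 2L &&
          sum(sel & md$group == "LARC_post") >= 2L) {
        v <- volcano(ch$table[sel, ], md$group[sel], case = "LARC_post",
                     reference = "LARC_pre")
        volcanoes[[nm]] <- v
        write_table_csv(v, file.path(out_dir,
                                     sprintf("volcano_post_vs_pre_%s.csv",
                                             nm)))
      }
    }
  }

  roc <- NULL
  pre <- md$group == "LARC_pre" & !is.na(md$responder)
  if (sum(pre & md$responder == "poor") >= 1L &&
      sum(pre & md$responder != "poor") >= 1L) {
    labels <- ifelse(md$responder[pre] == "poor", "poor", "responder")
    roc <- roc_table(ch$table[pre, ], labels, positive = "poor",
                     n_boot = config$n_boot, seed = config$seed)
    write_table_csv(roc, file.path(out_dir, "roc_poor_vs_responder.csv"))
  }
  write_manifest(out_dir, config)
  invisible(list(table = ch$table, metadata = md, correlations = cors,
                 volcano = volcanoes, roc = roc, out_dir = out_dir))
}

#' Integrated metabolite + protein workflow
#'
#' Correlates panel bands with the protein panel, computes rank metrics
#' and differential calls for complete vs poor responders, and compares
#' feature sets (RS peaks; + cytokines; + DDR markers) by PCA-SVM
#' leave-one-out accuracy.
#'
#' @param config A [run_config()] whose cohort carries a protein panel
#'   and NAR scores.
#' @param out_dir Output directory.
#' @param group Which LARC timepoint to classify (default `LARC_post`,
#'   where proteome differences between responder classes concentrate).
#' @return Invisibly: correlation matrix, ranked proteins, and the
#'   feature-set accuracy table.
#' @export
run_integration <- function(config, out_dir, group = "LARC_post") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ch <- prepare_cohort(config)
  if (is.null(ch$proteins))
    stop("config error: integration needs a protein panel", call. = FALSE)
  md <- ch$metadata
  md$responder <- stratify_nar(md$nar_score)
  common <- intersect(ch$table$sample_id, ch$proteins$sample_id)
  sel <- md$sample_id %in% common & md$group == group &
    md$responder %in% c("complete", "poor")
  if (sum(sel) < 6L)
    stop("config error: need >= 6 aligned samples in two responder classes",
         call. = FALSE)
  ids <- md$sample_id[sel]
  peaks <- ch$table[match(ids, ch$table$sample_id), ]
  prot <- ch$proteins[match(ids, ch$proteins$sample_id), ]
  labels <- md$responder[sel]
  if (any(table(labels) < 3L))
    stop("config error: each responder class needs >= 3 samples",
         call. = FALSE)

  pk <- analysis_matrix(peaks, config$panel)
  r <- pearson_matrix(pk, prot)
  rtab <- dplyr::bind_cols(tibble(feature = rownames(r)), as_tibble(r))
  write_table_csv(rtab, file.path(out_dir, "correlation_peaks_proteins.csv"))

  ranked <- metrics_from_groups(prot, labels, case = "complete",
                                reference = "poor")
  write_table_csv(ranked, file.path(out_dir, "rank_metric_calls.csv"))
  write_rnk(ranked, file.path(out_dir, "proteins.rnk"))

  spec <- if (!is.null(config$simulate)) config$simulate$protein_spec else NULL
  cyto <- intersect(spec$cytokine_analytes %||% character(), names(prot))
  ddr <- intersect(spec$ddr_analytes %||% character(), names(prot))
  pr <- peak_matrix(prot)
  sets <- list(RS = pk)
  if (length(cyto)) sets[["RS_cytokines"]] <- cbind(pk, pr[, cyto, drop = FALSE])
  if (length(cyto) && length(ddr))
    sets[["RS_cytokines_DDR"]] <- cbind(pk, pr[, c(cyto, ddr), drop = FALSE])
  cv <- lapply(sets, function(X)
    pca_svm_loocv(X, labels, c_grid = config$c_grid))
  acc <- tibble(feature_set = names(cv),
                loocv_accuracy = vapply(cv, `[[`, numeric(1), "accuracy"),
                chosen_C = vapply(cv, `[[`, numeric(1), "chosen_C"),
                n = length(labels))
  write_table_csv(acc, file.path(out_dir, "svm_feature_sets.csv"))
  write_manifest(out_dir, config)
  invisible(list(correlation = r, ranked = ranked, cv = cv, accuracy = acc,
                 labels = labels, out_dir = out_dir))
}
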