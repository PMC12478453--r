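test_that("noiseless generation equals the analytic forward model channel-wise", {
  cfg <- synthetic_config(seed = 60, noise_sd = 0, cosmic_rate = 0)
  set.seed(1)
  sp <- generate_point_spectrum(cfg)
  axis <- sp$wavenumbers
  # independent evaluation of the same model: polynomial baseline plus
  # 50/50 gaussian/lorentzian bands of FWHM 8
  t <- 2 * (axis - min(axis)) / diff(range(axis)) - 1
  wn <- as.numeric(names(cfg$base_amplitudes))
  bands <- rep(0, length(axis))
  for (k in seq_along(wn)) {
    d <- axis - wn[k]
    g <- exp(-4 * log(2) * d^2 / 64)
    l <- 1 / (1 + 4 * d^2 / 64)
    bands <- bands + cfg$base_amplitudes[k] * (0.5 * g + 0.5 * l)
  }
  expect_equal(sp$intensities - attr(sp, "clean"), rep(0, length(axis)),
               tolerance = 1e-12)
  expect_equal(attr(sp, "clean") - bands,
               sp$intensities - bands, tolerance = 1e-12)
  # the residual after removing bands must be a smooth positive polynomial
  resid <- sp$intensities - bands
  fit <- lm(resid ~ poly(t, 6))
  expect_lt(max(abs(residuals(fit))), 1e-8)
  expect_true(all(sp$intensities > 0))
})

test_that("generation is reproducible under the seed contract", {
  cfg <- synthetic_config(seed = 61, groups = c(A = 3L, B = 3L),
                          n_points = 2L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(spectra_matrix(a$spectra[[1L]]),
                   spectra_matrix(b$spectra[[1L]]))
  expect_identical(a$truth$amplitudes, b$truth$amplitudes)
  cfg2 <- synthetic_config(seed = 62, groups = c(A = 3L, B = 3L),
                           n_points = 2L)
  c2 <- generate_cohort(cfg2)
  expect_false(identical(spectra_matrix(a$spectra[[1L]]),
                         spectra_matrix(c2$spectra[[1L]])))
})

test_that("empirical channel noise matches the configured sd within 5%", {
  cfg <- synthetic_config(seed = 63, noise_sd = 0.01, cosmic_rate = 0)
  set.seed(63)
  amps <- cfg$base_amplitudes
  coefs <- seraman:::draw_baseline_coefs(cfg, amps[["1448"]])
  reps <- vapply(1:500, function(i)
    generate_point_spectrum(cfg, amps, coefs)$intensities[[700L]],
    numeric(1))
  expect_lt(abs(sd(reps) - 0.01) / 0.01, 0.05)
})

test_that("spike bookkeeping matches what was injected", {
  cfg <- synthetic_config(seed = 64, groups = c(A = 3L, B = 3L),
                          n_points = 5L, cosmic_rate = 0.5)
  co <- generate_cohort(cfg)
  expect_gt(nrow(co$truth$spikes), 0L)
  expect_true(all(co$truth$spikes$width %in% 1:3))
  expect_true(all(co$truth$spikes$amplitude >=
                    20 * co$truth$noise_abs[co$truth$spikes$sample_id] * 0.999))
})

test_that("a null cohort shows only chance-level peak-protein correlation", {
  wn <- names(default_base_amplitudes())
  L <- matrix(0, 5, 40, dimnames = list(paste0("an", 1:5), wn))
  cfg <- synthetic_config(seed = 65, groups = c(A = 10L, B = 10L),
                          n_points = 1L, grid = c(600, 1800, 4),
                          protein_spec = list(loadings = L, noise_sd = 1,
                                              mean = 10))
  co <- generate_cohort(cfg)
  r <- pearson_matrix(co$truth$amplitudes,
                      peak_matrix(co$proteins))
  expect_lt(quantile(abs(r), 0.95), 0.6)
})

test_that("protein correlations converge to the loading-implied values", {
  wn <- names(default_base_amplitudes())
  L <- matrix(0, 3, 40, dimnames = list(c("a1", "a2", "a3"), wn))
  L["a1", "852"] <- 1.2
  L["a2", "898"] <- 0.8
  L["a2", "1155"] <- -0.5
  cfg <- synthetic_config(seed = 66, groups = c(A = 250L, B = 250L),
                          n_points = 1L, grid = c(600, 1800, 4),
                          protein_spec = list(loadings = L, noise_sd = 0.7,
                                              mean = 10))
  co <- generate_cohort(cfg)
  implied <- co$truth$implied_peak_protein_r
  rhat <- pearson_matrix(peak_matrix(co$proteins), co$truth$scores)
  dev <- abs(rhat[, colnames(implied)] - implied)
  loaded <- implied != 0
  expect_lt(max(dev[loaded]), 0.1)
  # null entries: extreme-value bound for ~120 correlations at n = 500
  expect_lt(max(dev[!loaded]), 4 / sqrt(sum(cfg$groups)))
  expect_lt(quantile(dev[!loaded], 0.95), 2 / sqrt(sum(cfg$groups)))
})

test_that("a configured 2-fold group effect survives the full pipeline", {
  cfg <- synthetic_config(seed = 67, groups = c(A = 12L, B = 12L),
                          n_points = 4L, grid = c(600, 1800, 2),
                          group_effects = list(B = c("852" = 2)))
  co <- generate_cohort(cfg)
  proc <- lapply(co$spectra, preprocess_sample)
  pt <- build_peak_table(proc)
  v <- volcano(pt, co$metadata$group, "B", "A")
  fc852 <- v$fold_change[v$feature == "peak_852"]
  expect_lt(abs(fc852 - 2) / 2, 0.2)
  expect_true(v$significant[v$feature == "peak_852"])
})

test_that("NAR scores reproduce the analytic peak correlation", {
  spec <- list(A = list(beta0 = 11, betas = c("898" = 3), sd = 2))
  cfg <- synthetic_config(seed = 68, groups = c(A = 30L, B = 3L),
                          n_points = 1L, grid = c(600, 1800, 4),
                          nar_spec = spec)
  co <- generate_cohort(cfg)
  sel <- co$metadata$group == "A"
  r <- cor(co$truth$amplitudes[sel, "898"], co$metadata$nar_score[sel])
  analytic <- 3 / sqrt(3^2 + 2^2)
  expect_lt(abs(r - analytic), 0.15)
  expect_true(all(co$metadata$nar_score[sel] >= 0))
  expect_true(all(is.na(co$metadata$nar_score[!sel])))
})

test_that("fixtures are byte-stable per seed and log the configured truth", {
  cfg <- synthetic_config(seed = 69, groups = c(A = 3L, B = 3L),
                          n_points = 2L, grid = c(600, 1800, 10),
                          group_effects = list(B = c("852" = 1.5)))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_fixture(cfg, d1)
  p2 <- write_fixture(cfg, d2)
  for (nm in names(p1))
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]),
                     label = nm)
  ge <- utils::read.csv(p1[["truth_group_effects"]])
  expect_equal(ge$factor[ge$group == "B" & ge$wavenumber_cm1 == 852], 1.5)
  back <- read_spectra(p1[["spectra"]])
  expect_length(back, 6L)
})
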