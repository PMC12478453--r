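test_that("parameter invariants are enforced", {
  expect_error(preprocess_params(sg_window = 16L), "odd")
  expect_error(preprocess_params(sg_order = 17L, sg_window = 17L), "odd|greater")
  expect_error(preprocess_params(baseline_tol = 0), "positive")
})

test_that("spike-free replicates pass through the cosmic-ray stage untouched", {
  s <- make_sample(n_points = 5L, noise_sd = 0.5, seed = 3)
  out <- remove_cosmic_rays(s)
  expect_identical(spectra_matrix(out), spectra_matrix(s))
  expect_identical(attr(out, "spikes_replaced"), integer(5))
})

test_that("an injected spike is repaired to within 5x the noise sd", {
  noise_sd <- 0.5
  truth <- make_sample(n_points = 5L, noise_sd = noise_sd, seed = 4)
  m <- spectra_matrix(truth)
  spiked <- m
  spiked[2L, 100L] <- spiked[2L, 100L] + 50 * noise_sd
  s <- seraman:::matrix_to_sample("S1", common_axis(truth), spiked)
  out <- remove_cosmic_rays(s)
  repaired <- spectra_matrix(out)
  expect_equal(sum(attr(out, "spikes_replaced")), 1L)
  expect_lt(abs(repaired[2L, 100L] - m[2L, 100L]), 5 * noise_sd)
  # all untouched channels are bit-identical
  expect_identical(repaired[, -100L], spiked[, -100L])
})

test_that("a zero-amplitude spike triggers no replacement", {
  s <- make_sample(n_points = 5L, noise_sd = 0.5, seed = 5)
  m <- spectra_matrix(s)
  m[1L, 50L] <- m[1L, 50L] + 0
  out <- remove_cosmic_rays(seraman:::matrix_to_sample("S1", common_axis(s), m))
  expect_identical(sum(attr(out, "spikes_replaced")), 0L)
})

test_that("broad excursions wider than cosmic_max_width are preserved", {
  s <- make_sample(n_points = 5L, noise_sd = 0.5, seed = 6)
  m <- spectra_matrix(s)
  m[3L, 80:87] <- m[3L, 80:87] + 100   # 8 channels: real signal, not a ray
  s2 <- seraman:::matrix_to_sample("S1", common_axis(s), m)
  out <- remove_cosmic_rays(s2)
  expect_identical(spectra_matrix(out), m)
})

test_that("cosmic-ray repair is idempotent", {
  set.seed(7)
  s <- make_sample(n_points = 6L, noise_sd = 0.5, seed = 7)
  m <- spectra_matrix(s)
  for (k in 1:4) {
    i <- sample(6, 1); j <- sample(180, 1) + 10
    m[i, j:(j + sample(0:2, 1))] <- m[i, j] + 40
  }
  once <- remove_cosmic_rays(seraman:::matrix_to_sample("S1", common_axis(s), m))
  twice <- remove_cosmic_rays(once)
  expect_identical(spectra_matrix(twice), spectra_matrix(once))
  expect_identical(sum(attr(twice, "spikes_replaced")), 0L)
})

test_that("polynomials up to the filter order pass Savitzky-Golay unchanged", {
  p <- preprocess_params()
  x <- seq_len(301)
  expect_equal(savgol_smooth(rep(7, 301), p), rep(7, 301), tolerance = 1e-12)
  set.seed(8)
  for (deg in c(1L, 3L, 5L)) {
    cf <- rnorm(deg + 1L)
    y <- drop(outer(x / 100, 0:deg, "^") %*% cf)
    sm <- savgol_smooth(y, p)
    interior <- 9:293
    expect_lt(max(abs(sm - y)[interior] / pmax(abs(y[interior]), 1e-8)), 1e-8)
  }
})

test_that("the filter agrees with a direct windowed least-squares oracle", {
  p <- preprocess_params()
  set.seed(9)
  y <- rnorm(101)
  cc <- sg_oracle_coeffs(5L, 17L)
  oracle <- vapply(9:93, function(i) sum(cc * y[(i - 8):(i + 8)]), numeric(1))
  expect_equal(savgol_smooth(y, p)[9:93], oracle, tolerance = 1e-10)
})

test_that("Savitzky-Golay is linear and shrinks white noise by sum(c^2)", {
  p <- preprocess_params()
  set.seed(10)
  x <- rnorm(201); y <- rnorm(201)
  expect_equal(savgol_smooth(2.5 * x - 4 * y, p),
               2.5 * savgol_smooth(x, p) - 4 * savgol_smooth(y, p),
               tolerance = 1e-10)
  # interior variance of filtered white noise ~ sigma^2 * sum(c^2)
  cc <- sg_oracle_coeffs(5L, 17L)
  sm <- matrix(rnorm(2000 * 61), 2000, 61)
  sm <- t(apply(sm, 1L, function(r) savgol_smooth(r, p)))
  expect_equal(var(sm[, 31L]), sum(cc^2), tolerance = 0.1)
})

test_that("modpoly reproduces an in-model baseline and handles zero input", {
  p <- preprocess_params()
  t <- seq(-1, 1, length.out = 400)
  y <- 100 + 20 * t - 7 * t^3 + 3 * t^9
  bl <- modpoly_baseline(y, p)
  expect_lt(max(abs(bl$corrected)), 1e-6 * max(abs(y)))
  expect_true(bl$converged)

  z <- modpoly_baseline(rep(0, 400), p)
  expect_equal(z$baseline, rep(0, 400), tolerance = 1e-12)
  expect_equal(z$corrected, rep(0, 400), tolerance = 1e-12)
})

test_that("the baseline never exceeds the running signal and descends monotonically", {
  p <- preprocess_params(baseline_max_iter = 40L)
  set.seed(11)
  cfg <- synthetic_config(seed = 11, cosmic_rate = 0)
  sp <- generate_point_spectrum(cfg)
  y <- sp$intensities
  # re-run the iteration manually to observe the trajectory
  Q <- seraman:::baseline_basis(length(y), 9L)
  work <- y
  first <- NA_real_
  for (k in 1:40) {
    fit <- drop(Q %*% crossprod(Q, work))
    excess <- max(pmax(work - fit, 0))  # working signal above the fit
    if (k == 1L) first <- excess
    prev_work <- work
    work <- pmin(work, fit)
    # the working signal is clipped monotonically toward the background
    expect_true(all(work <= prev_work + 1e-12))
  }
  # the clipped signal's excess above the fit collapses as the iteration
  # converges to the background (per-iteration descent is only
  # approximate: the polynomial wobbles under freshly clipped peaks)
  expect_lt(excess, 0.05 * first)
  bl <- modpoly_baseline(y, p)
  expect_lte(max(bl$baseline), max(y) + 1e-9)
})

test_that("baseline recovery on synthetic serum spectra beats 2x the noise sd", {
  cfg <- synthetic_config(seed = 12, cosmic_rate = 0)
  p <- preprocess_params()
  pos <- as.numeric(names(cfg$base_amplitudes))
  set.seed(12)
  sq <- c()
  for (i in 1:8) {
    sp <- generate_point_spectrum(cfg)
    truth <- attr(sp, "clean") -
      seraman:::peak_sum(sp$wavenumbers, cfg$base_amplitudes, cfg)
    bl <- modpoly_baseline(savgol_smooth(sp$intensities, p), p)
    free <- vapply(sp$wavenumbers, function(w) min(abs(w - pos)), numeric(1)) >
      3 * cfg$peak_fwhm
    sq <- c(sq, (bl$baseline[free] - truth[free])^2)
  }
  expect_lt(sqrt(mean(sq)) / cfg$noise_sd, 2)
})

test_that("non-convergence is reported in the result, not raised", {
  p <- preprocess_params(baseline_max_iter = 3L)
  set.seed(13)
  cfg <- synthetic_config(seed = 13, cosmic_rate = 0)
  sp <- generate_point_spectrum(cfg)
  expect_no_error(bl <- modpoly_baseline(sp$intensities, p))
  expect_false(bl$converged)
  expect_identical(bl$iterations, 3L)
})

test_that("SNV matches the direct formula and is idempotent on normalized input", {
  set.seed(14)
  x <- rnorm(80, mean = 40, sd = 3)
  out <- snv_normalize(x)
  expect_equal(out, (x - mean(x)) / sd(x), tolerance = 1e-14)
  expect_lt(abs(mean(out)), 1e-12)
  expect_lt(abs(sd(out) - 1), 1e-12)
  expect_equal(snv_normalize(out), out, tolerance = 1e-12)
  expect_error(snv_normalize(rep(3, 50)), "degenerate")
})

test_that("the full chain yields exact SNV units with populated qc", {
  s <- make_sample(n_points = 4L, noise_sd = 0.3, seed = 15)
  pr <- preprocess_sample(s)
  expect_lt(max(abs(rowMeans(pr$intensities))), 1e-9)
  expect_lt(max(abs(apply(pr$intensities, 1L, sd) - 1)), 1e-9)
  expect_length(pr$qc$spikes_replaced, 4L)
  expect_length(pr$qc$baseline_iterations, 4L)
  expect_true(all(pr$qc$baseline_iterations >= 1L))
  expect_true(all(is.finite(pr$baselines)))
})

test_that("preprocessing is invariant under positive affine intensity maps", {
  cfg <- synthetic_config(seed = 16, groups = c(A = 3L, B = 3L),
                          n_points = 4L)
  co <- generate_cohort(cfg)
  s <- co$spectra[[1L]]
  m <- spectra_matrix(s)
  s_aff <- seraman:::matrix_to_sample(s$sample_id, common_axis(s),
                                      3.7 * m + 120)
  a <- preprocess_sample(s)
  b <- preprocess_sample(s_aff)
  expect_lt(max(abs(a$intensities - b$intensities)), 1e-8)
})

test_that("unharmonized or empty input is rejected", {
  ax1 <- seq(600, 650); ax2 <- seq(600, 700, by = 2)
  s <- sample_spectra("u", list(point_spectrum("u", 0, ax1, ax1 * 0 + 1:51),
                                point_spectrum("u", 1, ax2, seq_along(ax2))))
  expect_error(preprocess_sample(s), "axis error")
  expect_error(preprocess_sample(list()), "empty-input")
})
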