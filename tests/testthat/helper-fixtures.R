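# Shared fixtures and independent oracles for the suite.

# Small harmonized sample: deterministic smooth signal + optional noise.
make_sample <- function(sample_id = "S1", n_points = 3L, n_chan = 201L,
                        noise_sd = 0, seed = 1L) {
  set.seed(seed)
  axis <- seq(600, 600 + n_chan - 1)
  pts <- lapply(seq_len(n_points) - 1L, function(i) {
    y <- 100 + 0.05 * (axis - 600) + 10 * exp(-(axis - 700)^2 / 50)
    if (noise_sd > 0) y <- y + rnorm(n_chan, 0, noise_sd)
    point_spectrum(sample_id, i, axis, y)
  })
  sample_spectra(sample_id, pts)
}

# Independent Savitzky-Golay center coefficients by direct least squares
# on the window index (no signal package involved).
sg_oracle_coeffs <- function(order = 5L, window = 17L) {
  half <- (window - 1L) %/% 2L
  X <- outer(seq(-half, half), 0:order, "^")
  H <- solve(crossprod(X), t(X))
  H[1L, ]  # evaluate the fitted polynomial at the window center
}

# Wrap a bare matrix as a processed_sample for peak-quant tests.
fake_processed <- function(sample_id, axis, m) {
  structure(list(sample_id = sample_id, wavenumbers = axis,
                 intensities = m, baselines = m * 0,
                 qc = list(spikes_replaced = integer(nrow(m)),
                           baseline_iterations = integer(nrow(m)),
                           baseline_converged = rep(TRUE, nrow(m)))),
            class = "processed_sample")
}

# Exhaustive-pair AUC oracle with half-credit for ties.
auc_bruteforce <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Analytic composite band height oracle: the generator's peak sum,
# smoothed with independently derived SG coefficients, maximized over the
# extraction window and ratioed against the denominator band.
oracle_peak_ratios <- function(cfg, amplitudes, axis,
                               sg_order = 5L, sg_window = 17L) {
  pk <- seraman:::peak_sum(axis, amplitudes, cfg)
  cc <- sg_oracle_coeffs(sg_order, sg_window)
  half <- (sg_window - 1L) %/% 2L
  sm <- pk
  for (i in (half + 1L):(length(pk) - half))
    sm[i] <- sum(cc * pk[(i - half):(i + half)])
  pos <- as.numeric(names(amplitudes))
  h <- vapply(pos, function(w) max(sm[axis >= w - 5 & axis <= w + 5]),
              numeric(1))
  setNames(h / h[pos == 1448], names(amplitudes))
}
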