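#' Preprocessing parameters
#'
#' Defaults mirror the serum workflow this package implements: degree-5
#' Savitzky-Golay smoothing over a 17-channel frame, a degree-9 iterative
#' modified-polyfit fluorescence baseline, and replicate-consensus
#' cosmic-ray detection at a robust-z threshold of 8 for spikes up to 3
#' channels wide.
#'
#' @param sg_order Savitzky-Golay polynomial order.
#' @param sg_window Savitzky-Golay frame width (odd, `> sg_order`).
#' @param baseline_degree Polynomial degree of the fluorescence baseline.
#' @param baseline_tol Relative-change stopping threshold for the
#'   fit-and-clip iteration.
#' @param baseline_max_iter Iteration cap for the baseline.
#' @param cosmic_threshold Robust z-score above which a channel is called a
#'   cosmic-ray spike.
#' @param cosmic_max_width Maximum spike width in channels; longer
#'   excursions are treated as real signal.
#' @return A `preprocess_params` list.
#' @export
preprocess_params <- function(sg_order = 5L, sg_window = 17L,
                              baseline_degree = 9L, baseline_tol = 1e-6,
                              baseline_max_iter = 100L,
                              cosmic_threshold = 8, cosmic_max_width = 3L) {
  p <- list(sg_order = as.integer(sg_order), sg_window = as.integer(sg_window),
            baseline_degree = as.integer(baseline_degree),
            baseline_tol = baseline_tol,
            baseline_max_iter = as.integer(baseline_max_iter),
            cosmic_threshold = cosmic_threshold,
            cosmic_max_width = as.integer(cosmic_max_width))
  if (p$sg_window %% 2L == 0L || p$sg_window <= p$sg_order)
    stop("parameter error: sg_window must be odd and greater than sg_order",
         call. = FALSE)
  if (p$baseline_degree < 1L) stop("baseline_degree must be >= 1", call. = FALSE)
  if (p$baseline_tol <= 0 || p$cosmic_threshold <= 0)
    stop("thresholds must be positive", call. = FALSE)
  structure(p, class = "preprocess_params")
}

#' Remove cosmic-ray spikes using replicate consensus
#'
#' Cosmic rays hit single detector reads, so they never reproduce across
#' the replicate points of a line map. With >= 3 points on a common axis,
#' each channel is scored against the per-channel median and MAD across
#' points; channels whose robust z exceeds `cosmic_threshold`, in runs of
#' at most `cosmic_max_width` channels, are replaced by the per-channel
#' replicate median, which stays faithful even on sharp band flanks.
#' With fewer than 3 points the detector falls back to a per-spectrum
#' running-median residual with linear-interpolation repair.
#'
#' @param sample A harmonized [sample_spectra()] object.
#' @param params [preprocess_params()].
#' @return The repaired `sample_spectra`; the per-point replacement counts
#'   are attached as attribute `"spikes_replaced"`.
#' @export
remove_cosmic_rays <- function(sample, params = preprocess_params()) {
  m <- spectra_matrix(sample)
  npt <- nrow(m)
  if (npt < 1L) stop("empty-input error: no point spectra", call. = FALSE)
  if (npt >= 3L) {
    med <- apply(m, 2L, median)
    sig <- apply(m, 2L, mad)            # 1.4826 * MAD
    # per-channel MAD from few replicates is noisy; flooring it at the
    # pooled (median-over-channels) MAD stops tiny-denominator false hits
    # while keeping the score affine-equivariant
    floor_ <- pmax(median(sig), 1e-8 * (1 + abs(med)))
    z <- abs(sweep(m, 2L, med, "-")) / rep(pmax(sig, floor_), each = npt)
  } else {
    z <- t(apply(m, 1L, function(x) {
      base <- runmed(x, k = 7L, endrule = "median")
      r <- x - base
      s <- max(mad(r), 1e-8 * (1 + max(abs(x))))
      abs(r) / s
    }))
  }
  flagged <- z > params$cosmic_threshold
  counts <- integer(npt)
  for (i in seq_len(npt)) {
    hits <- which(flagged[i, ])
    if (!length(hits)) next
    runs <- split(hits, cumsum(c(1L, diff(hits) != 1L)))
    for (run in runs) {
      if (length(run) > params$cosmic_max_width) next
      # with replicates, the per-channel median across points is a far
      # better stand-in than interpolation: it stays faithful on sharp
      # band flanks where a linear bridge would not
      if (npt >= 3L) m[i, run] <- med[run]
      else m[i, ] <- repair_run(m[i, ], run)
      counts[i] <- counts[i] + length(run)
    }
  }
  out <- matrix_to_sample(sample$sample_id, common_axis(sample), m,
                          vapply(sample$points, `[[`, integer(1), "point_index"))
  attr(out, "spikes_replaced") <- counts
  out
}

# Linear interpolation across a flagged run; at the spectrum edge the
# nearest clean value is extended instead.
repair_run <- function(x, run) {
  n <- length(x)
  lo <- min(run) - 1L
  hi <- max(run) + 1L
  if (lo < 1L && hi > n) return(x)
  if (lo < 1L) { x[run] <- x[hi]; return(x) }
  if (hi > n) { x[run] <- x[lo]; return(x) }
  x[run] <- x[lo] + (x[hi] - x[lo]) * (run - lo) / (hi - lo)
  x
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing (default degree 5, frame 17).
#' Edges are handled by evaluating the boundary-anchored full-window fit
#' at the edge positions, so no data are fabricated outside the measured
#' range. Any polynomial of degree `<= sg_order` passes through unchanged.
#'
#' @param spectrum A [point_spectrum()] or bare numeric vector on a
#'   uniform grid.
#' @param params [preprocess_params()].
#' @return Same type as the input, smoothed.
#' @export
savgol_smooth <- function(spectrum, params = preprocess_params()) {
  y <- if (inherits(spectrum, "point_spectrum")) spectrum$intensities else spectrum
  if (length(y) < params$sg_window)
    stop("spectrum shorter than the smoothing window", call. = FALSE)
  sm <- as.numeric(signal::sgolayfilt(y, p = params$sg_order,
                                      n = params$sg_window))
  if (inherits(spectrum, "point_spectrum"))
    point_spectrum(spectrum$sample_id, spectrum$point_index,
                   spectrum$wavenumbers, sm)
  else sm
}

#' Modified-polyfit fluorescence baseline
#'
#' Iterative fit-and-clip estimation of the broad fluorescence background
#' under sharp Raman bands: a degree-`baseline_degree` polynomial is
#' least-squares fitted to the working signal, every working value above
#' the fit is clipped down to it, and the loop repeats until the fit's
#' maximum change relative to its own range drops below `baseline_tol`
#' (or `baseline_max_iter` is reached, which is recorded as a
#' non-convergence warning, not an error). The fit uses an orthogonal
#' polynomial basis on a channel axis rescaled to \[-1, 1\]; degree 9 on
#' raw wavenumbers is numerically hostile.
#'
#' @param spectrum A [point_spectrum()] or numeric vector.
#' @param params [preprocess_params()].
#' @return List with `baseline`, `corrected` (input minus baseline),
#'   `iterations`, and `converged`.
#' @export
modpoly_baseline <- function(spectrum, params = preprocess_params()) {
  y <- if (inherits(spectrum, "point_spectrum")) spectrum$intensities else spectrum
  n <- length(y)
  if (n <= params$baseline_degree + 1L)
    stop("spectrum too short for a degree-", params$baseline_degree,
         " baseline", call. = FALSE)
  Q <- baseline_basis(n, params$baseline_degree)
  work <- y
  prev <- NULL
  converged <- FALSE
  iter <- 0L
  while (iter < params$baseline_max_iter) {
    iter <- iter + 1L
    fit <- drop(Q %*% crossprod(Q, work))
    if (!is.null(prev)) {
      scale <- diff(range(prev))
      if (scale == 0) scale <- max(abs(prev), 1)
      if (max(abs(fit - prev)) / scale < params$baseline_tol) {
        converged <- TRUE
        prev <- fit
        break
      }
    }
    work <- pmin(work, fit)
    prev <- fit
  }
  list(baseline = prev, corrected = y - prev, iterations = iter,
       converged = converged)
}

# Orthonormal polynomial basis (intercept + stats::poly) on [-1, 1],
# cached by (n, degree) since it is reused for every point spectrum.
baseline_basis <- local({
  cache <- new.env(parent = emptyenv())
  function(n, degree) {
    key <- paste0(n, "_", degree)
    if (!is.null(cache[[key]])) return(cache[[key]])
    t <- seq(-1, 1, length.out = n)
    B <- cbind(1, poly(t, degree))
    Q <- qr.Q(qr(B))
    cache[[key]] <- Q
    Q
  }
})

#' Standard-normal-variate normalization
#'
#' Per-spectrum mean-variance normalization: `(x - mean(x)) / sd(x)`.
#' Removes additive and multiplicative intensity effects so spectra from
#' different acquisitions are comparable.
#'
#' @param spectrum A [point_spectrum()] or numeric vector.
#' @return Same type, with mean 0 and standard deviation 1.
#' @export
snv_normalize <- function(spectrum) {
  y <- if (inherits(spectrum, "point_spectrum")) spectrum$intensities else spectrum
  s <- sd(y)
  if (!is.finite(s) || s == 0)
    stop("degenerate-spectrum error: constant intensities (sd = 0)",
         call. = FALSE)
  out <- (y - mean(y)) / s
  if (inherits(spectrum, "point_spectrum"))
    point_spectrum(spectrum$sample_id, spectrum$point_index,
                   spectrum$wavenumbers, out)
  else out
}

#' Full preprocessing chain for one sample
#'
#' Applies, in order: replicate-consensus cosmic-ray repair, Savitzky-Golay
#' smoothing, modified-polyfit baseline subtraction (estimated per point
#' spectrum on the smoothed signal), and SNV normalization. The chain is
#' invariant under positive affine transforms of the raw intensities.
#'
#' @param sample A harmonized [sample_spectra()] object.
#' @param params [preprocess_params()].
#' @return A `processed_sample`: `sample_id`, `wavenumbers`, the
#'   point-by-channel `intensities` matrix in SNV units, the estimated
#'   `baselines` matrix (pre-SNV units), and a `qc` record (spikes
#'   replaced, baseline iterations, convergence flags).
#' @export
preprocess_sample <- function(sample, params = preprocess_params()) {
  if (!inherits(sample, "sample_spectra") || length(sample$points) < 1L)
    stop("empty-input error: no point spectra", call. = FALSE)
  axis <- common_axis(sample)
  if (is.null(axis))
    stop("axis error: harmonize_axis() must be applied first", call. = FALSE)
  clean <- remove_cosmic_rays(sample, params)
  m <- spectra_matrix(clean)
  baselines <- matrix(NA_real_, nrow(m), ncol(m))
  iters <- integer(nrow(m))
  conv <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    sm <- savgol_smooth(m[i, ], params)
    bl <- modpoly_baseline(sm, params)
    baselines[i, ] <- bl$baseline
    iters[i] <- bl$iterations
    conv[i] <- bl$converged
    m[i, ] <- snv_normalize(bl$corrected)
  }
  structure(
    list(sample_id = sample$sample_id, wavenumbers = axis, intensities = m,
         baselines = baselines,
         qc = list(spikes_replaced = attr(clean, "spikes_replaced"),
                   baseline_iterations = iters, baseline_converged = conv)),
    class = "processed_sample")
}

#' @export
print.processed_sample <- function(x, ...) {
  cat(sprintf("<processed_sample> %s: %d points x %d channels, %d spike(s) repaired\n",
              x$sample_id, nrow(x$intensities), ncol(x$intensities),
              sum(x$qc$spikes_replaced)))
  invisible(x)
}

#' Mean processed spectrum of a sample
#'
#' @param processed A `processed_sample`.
#' @return List with `wavenumbers` and `intensities` (channel means over
#'   points).
#' @export
mean_spectrum <- function(processed) {
  stopifnot(inherits(processed, "processed_sample"))
  list(sample_id = processed$sample_id, wavenumbers = processed$wavenumbers,
       intensities = colMeans(processed$intensities))
}
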