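#' A single-point Raman spectrum
#'
#' One acquisition point of a serum line map: a strictly increasing
#' wavenumber axis (cm\eqn{^{-1}}) and the matching detector intensities.
#'
#' @param sample_id Sample identifier.
#' @param point_index Zero-based acquisition point index.
#' @param wavenumbers Numeric vector of Raman shifts in cm\eqn{^{-1}},
#'   strictly increasing.
#' @param intensities Numeric vector of intensities (arbitrary detector
#'   units), same length as `wavenumbers`.
#' @return An object of class `point_spectrum`.
#' @export
point_spectrum <- function(sample_id, point_index, wavenumbers, intensities) {
  x <- structure(
    list(sample_id = as.character(sample_id),
         point_index = as.integer(point_index),
         wavenumbers = as.numeric(wavenumbers),
         intensities = as.numeric(intensities)),
    class = "point_spectrum")
  validate_point_spectrum(x)
}

validate_point_spectrum <- function(x) {
  n <- length(x$wavenumbers)
  if (n < 33L)
    stop("point spectrum must have at least 33 channels (one smoothing window), got ",
         n, call. = FALSE)
  if (length(x$intensities) != n)
    stop("wavenumbers and intensities differ in length (", n, " vs ",
         length(x$intensities), ")", call. = FALSE)
  if (anyNA(x$wavenumbers) || anyNA(x$intensities) ||
      !all(is.finite(x$wavenumbers)) || !all(is.finite(x$intensities)))
    stop("spectrum contains missing or non-finite values", call. = FALSE)
  if (any(diff(x$wavenumbers) <= 0))
    stop("axis error: wavenumbers must be strictly increasing", call. = FALSE)
  if (is.na(x$point_index) || x$point_index < 0L)
    stop("point_index must be a nonnegative integer", call. = FALSE)
  x
}

#' @export
print.point_spectrum <- function(x, ...) {
  cat(sprintf("<point_spectrum> %s / point %d: %d channels, %.0f-%.0f cm-1\n",
              x$sample_id, x$point_index, length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers)))
  invisible(x)
}

#' All point spectra of one sample
#'
#' Bundles the (nominally ~100) acquisition points of one serum sample.
#' Downstream stages require all points on a shared grid; use
#' [harmonize_axis()] to get there.
#'
#' @param sample_id Sample identifier.
#' @param points List of [point_spectrum()] objects, all with this
#'   `sample_id`.
#' @return An object of class `sample_spectra`.
#' @export
sample_spectra <- function(sample_id, points) {
  sample_id <- as.character(sample_id)
  if (length(points) < 1L) stop("empty-input error: no point spectra", call. = FALSE)
  ok <- vapply(points, function(p) inherits(p, "point_spectrum"), logical(1))
  if (!all(ok)) stop("all points must be point_spectrum objects", call. = FALSE)
  ids <- vapply(points, `[[`, character(1), "sample_id")
  if (!all(ids == sample_id))
    stop("all points must share sample_id '", sample_id, "'", call. = FALSE)
  idx <- vapply(points, `[[`, integer(1), "point_index")
  points <- points[order(idx)]
  structure(list(sample_id = sample_id, points = points),
            class = "sample_spectra")
}

#' @export
print.sample_spectra <- function(x, ...) {
  ax <- common_axis(x)
  cat(sprintf("<sample_spectra> %s: %d points%s\n", x$sample_id,
              length(x$points),
              if (is.null(ax)) " (unharmonized axes)"
              else sprintf(", common axis %.0f-%.0f cm-1 (%d channels)",
                           min(ax), max(ax), length(ax))))
  invisible(x)
}

#' Shared wavenumber axis of a sample, if any
#'
#' @param x A `sample_spectra` object.
#' @return The common wavenumber vector, or `NULL` when the points do not
#'   share an axis.
#' @export
common_axis <- function(x) {
  stopifnot(inherits(x, "sample_spectra"))
  ax <- x$points[[1L]]$wavenumbers
  for (p in x$points)
    if (length(p$wavenumbers) != length(ax) || any(p$wavenumbers != ax))
      return(NULL)
  ax
}

#' Point-by-channel intensity matrix of a harmonized sample
#'
#' @param x A `sample_spectra` object whose points share one axis.
#' @return Numeric matrix, one row per acquisition point.
#' @export
spectra_matrix <- function(x) {
  ax <- common_axis(x)
  if (is.null(ax))
    stop("axis error: points are not on a common grid; run harmonize_axis() first",
         call. = FALSE)
  m <- do.call(rbind, lapply(x$points, `[[`, "intensities"))
  rownames(m) <- vapply(x$points, function(p) as.character(p$point_index),
                        character(1))
  colnames(m) <- NULL
  m
}

# Rebuild a sample_spectra from a matrix on a shared axis, keeping ids.
matrix_to_sample <- function(sample_id, axis, m, point_indices = NULL) {
  point_indices <- point_indices %||% (seq_len(nrow(m)) - 1L)
  pts <- lapply(seq_len(nrow(m)), function(i)
    point_spectrum(sample_id, point_indices[i], axis, m[i, ]))
  sample_spectra(sample_id, pts)
}
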