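#' Extract one peak value from a spectrum
#'
#' Returns the maximum intensity within `position +/- half_window` on the
#' spectrum's grid. The windowed maximum is robust to the few-cm\eqn{^{-1}}
#' calibration drift typical between acquisitions.
#'
#' @param spectrum Anything with `wavenumbers` and `intensities` (a
#'   [point_spectrum()], a [mean_spectrum()] result, ...).
#' @param position Nominal band position (cm\eqn{^{-1}}).
#' @param half_window Half-window (cm\eqn{^{-1}}).
#' @return The peak intensity (scalar).
#' @export
extract_peak <- function(spectrum, position, half_window = 5) {
  wn <- spectrum$wavenumbers
  if (position - half_window < min(wn) || position + half_window > max(wn))
    stop("range error: window [", position - half_window, ", ",
         position + half_window, "] outside spectrum range", call. = FALSE)
  sel <- wn >= position - half_window & wn <= position + half_window
  max(spectrum$intensities[sel])
}

#' Build the ratiometric samples-by-peaks table
#'
#' For each sample the processed point spectra are averaged on the common
#' grid, every panel band is extracted from the mean spectrum, and all
#' values are divided by the sample's denominator-band value. The
#' resulting dimensionless table is the currency of every downstream
#' comparison; its denominator column is identically 1, and the whole
#' table is invariant to positive rescaling of the processed spectra.
#'
#' @param cohort List of `processed_sample` objects (see
#'   [preprocess_sample()]).
#' @param panel A [peak_panel()].
#' @return A `peak_table` tibble: `sample_id` plus one `peak_<wavenumber>`
#'   column per band, with the panel attached as attribute `"panel"`.
#' @export
build_peak_table <- function(cohort, panel = default_panel()) {
  stopifnot(length(cohort) >= 1L)
  positions <- panel$assignments$wavenumber_cm1
  rows <- lapply(cohort, function(s) {
    ms <- mean_spectrum(s)
    # SNV introduces a constant offset once the baseline is gone (the
    # off-peak floor sits at -mean/sd, not 0); measuring heights above
    # that floor restores proportionality to band amplitudes. A low
    # quantile estimates the floor robustly: with 40 bands of ~8 cm-1
    # width the median already sits inside band tails.
    floor_ <- unname(quantile(ms$intensities, 0.05))
    vals <- vapply(positions, function(p)
      extract_peak(ms, p, panel$half_window), numeric(1)) - floor_
    denom <- extract_peak(ms, panel$denominator_wavenumber,
                          panel$half_window) - floor_
    if (!is.finite(denom) || denom <= 0)
      stop("ratiometric error: denominator band <= 0 for sample ",
           s$sample_id, call. = FALSE)
    c(vals / denom)
  })
  m <- do.call(rbind, rows)
  colnames(m) <- paste0("peak_", format_wn(positions))
  out <- tibble(sample_id = vapply(cohort, `[[`, character(1), "sample_id"))
  out <- dplyr::bind_cols(out, as_tibble(m))
  attr(out, "panel") <- panel
  class(out) <- c("peak_table", class(out))
  out
}

format_wn <- function(x) {
  ifelse(x == round(x), sprintf("%d", as.integer(round(x))), sprintf("%g", x))
}

#' Numeric matrix view of a peak table
#'
#' @param table A `peak_table` (or any tibble with `sample_id` plus
#'   numeric feature columns).
#' @return Matrix with sample ids as row names.
#' @export
peak_matrix <- function(table) {
  m <- as.matrix(table[, setdiff(names(table), "sample_id"), drop = FALSE])
  rownames(m) <- table$sample_id
  m
}

#' Read / write a peak table CSV
#'
#' @param path CSV path.
#' @return A `peak_table` tibble.
#' @export
read_peak_table <- function(path) {
  d <- read.csv(path, check.names = FALSE)
  out <- as_tibble(d)
  class(out) <- c("peak_table", class(out))
  out
}

#' @rdname read_peak_table
#' @param table Peak table.
#' @export
write_peak_table <- function(table, path) {
  write_table_csv(table, path)
}
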