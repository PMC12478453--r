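#' The 40-band serum metabolite peak panel
#'
#' Tentative assignments of the serum fingerprint-region Raman bands used
#' throughout the package, from 621 cm\eqn{^{-1}} (phenylalanine) to 1682
#' cm\eqn{^{-1}} (Amide I). The 1448 cm\eqn{^{-1}} CH\eqn{_2}-deformation
#' band of lipids and proteins serves as the ratiometric denominator; its
#' nominal position is sometimes quoted as 1447 cm\eqn{^{-1}}, a
#' discrepancy the +/- 5 cm\eqn{^{-1}} extraction window absorbs.
#'
#' @return A `peak_panel`: the assignment table plus the denominator
#'   position and extraction half-window.
#' @export
default_panel <- function() {
  a <- panel_assignments()
  peak_panel(a, denominator_wavenumber = 1448, half_window = 5)
}

panel_assignments <- function() {
  tab <- matrix(c(
    "621",  "Phenylalanine", "C-C twisting mode",
    "643",  "Proline", "C-C twisting mode, skeletal stretching vibration",
    "671",  "DNA bases", "C-S stretching mode",
    "701",  "Cholesterol", "Choline group, CH2 rocking, cholesterol ring deformation",
    "719",  "Phosphatidylcholine (PC)/sphingomyelin", "Symmetric stretch vibration of choline group",
    "744",  "Thymine (DNA base)", "Backbone vibrations, deformation of the ring",
    "757",  "Tryptophan", "Symmetric breathing of tryptophan, sigma(ring)",
    "805",  "DNA/RNA", "C'-O-P-O-C'3 phosphodiester stretching",
    "828",  "Tyrosine", "Out-of-plane ring breathing",
    "852",  "Sugars (glucose, glycerol)", "C-O-C skeletal stretching",
    "878",  "Glutamic acid", "COOH deformation",
    "898",  "Glycine", "C-C stretching",
    "938",  "Citric acid, Succinic acid", "v(OH...O) out of plane wagging vibration of hydrogen bonds",
    "957",  "Fatty acid", "C-H bending",
    "992",  "Arginine", "C-N stretching, C-C stretching",
    "1002", "Phenylalanine", "Symmetric in-plane ring breathing",
    "1011", "Carbohydrates", "C-O-C ring, C-O-H bending",
    "1031", "Phenylalanine", "C-H in-plane bending, ring in-plane bending",
    "1051", "Glucose/glycerol", "C-O stretching",
    "1063", "Lipids", "Chain C-C stretching",
    "1082", "Lipids", "Chain C-C stretching",
    "1103", "Mannose", "sigma(CH2) twisting vibrations",
    "1126", "Glucose", "C-C stretching, C-O stretching, C-O-H in-plane bending",
    "1155", "Carotenoids", "C-C stretching, C-H stretching",
    "1172", "Saturated long-chain fatty acids", "C-C stretching",
    "1207", "Amino acids", "NH3 asymmetric rocking",
    "1249", "Amide III", "Asymmetric O-P-O stretching",
    "1257", "Unsaturated lipids, fatty acids", "CH3/CH2 twisting and wagging",
    "1268", "Unsaturated lipids, fatty acids", "CH3/CH2 twisting and wagging",
    "1314", "Histidine", "NH3+ asymmetric rocking, C-C-H stretching",
    "1338", "Threonine", "C-H deformation",
    "1448", "Lipids and proteins", "CH2 and CH2CH3 bending, scissoring, and deformation",
    "1518", "Carotenoids", "C-C stretching and C=C stretching",
    "1552", "Tryptophan", "Indole ring stretching, C=C stretching",
    "1575", "DNA & NADH", "Ring breathing modes",
    "1585", "Phenylalanine", "C-C bending",
    "1605", "Phenylalanine", "C=O stretching, C=C in-plane bending",
    "1615", "Tyrosine", "C=C stretching",
    "1657", "Unsaturated lipids, PC, phosphatidylethanolamine", "C=C stretching",
    "1682", "Amide I", "C=O stretching"),
    ncol = 3L, byrow = TRUE)
  tibble(wavenumber_cm1 = as.numeric(tab[, 1L]),
         metabolite = tab[, 2L],
         vibrational_mode = tab[, 3L])
}

#' Construct a peak panel
#'
#' @param assignments Tibble with columns `wavenumber_cm1`, `metabolite`,
#'   `vibrational_mode`; positions must be unique and within the
#'   fingerprint region.
#' @param denominator_wavenumber Ratiometric reference band (cm\eqn{^{-1}}).
#' @param half_window Extraction half-window (cm\eqn{^{-1}}).
#' @return A `peak_panel` object.
#' @export
peak_panel <- function(assignments, denominator_wavenumber = 1448,
                       half_window = 5) {
  stopifnot(all(c("wavenumber_cm1", "metabolite", "vibrational_mode")
                %in% names(assignments)))
  wn <- assignments$wavenumber_cm1
  if (anyDuplicated(wn))
    stop("panel positions must be unique", call. = FALSE)
  if (half_window <= 0) stop("half_window must be positive", call. = FALSE)
  assignments <- assignments[order(wn), , drop = FALSE]
  structure(list(assignments = as_tibble(assignments),
                 denominator_wavenumber = denominator_wavenumber,
                 half_window = half_window),
            class = "peak_panel")
}

#' @export
print.peak_panel <- function(x, ...) {
  cat(sprintf("<peak_panel> %d bands (%.0f-%.0f cm-1), denominator %.0f cm-1, half-window %.0f cm-1\n",
              nrow(x$assignments), min(x$assignments$wavenumber_cm1),
              max(x$assignments$wavenumber_cm1), x$denominator_wavenumber,
              x$half_window))
  invisible(x)
}

#' Read / write a peak panel CSV
#'
#' CSV columns `wavenumber_cm1,metabolite,vibrational_mode`; the
#' denominator and half-window travel as arguments, not file content.
#'
#' @param path CSV path.
#' @inheritParams peak_panel
#' @return A `peak_panel`.
#' @export
read_peak_panel <- function(path, denominator_wavenumber = 1448,
                            half_window = 5) {
  d <- read.csv(path, colClasses = c("numeric", "character", "character"))
  peak_panel(as_tibble(d), denominator_wavenumber, half_window)
}

#' @rdname read_peak_panel
#' @param panel A `peak_panel`.
#' @export
write_peak_panel <- function(panel, path) {
  write.csv(as.data.frame(panel$assignments), path, row.names = FALSE)
  invisible(path)
}
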