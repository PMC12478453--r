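#' Read point spectra from disk
#'
#' Two dialects are supported. `"long_csv"` is the canonical interchange: a
#' header `sample_id,point_index,wavenumber_cm1,intensity` followed by one
#' row per channel. `"two_column"` reads a directory of per-point text
#' files named `<sample>_<point>.txt`, each holding whitespace- or
#' comma-separated `wavenumber intensity` pairs.
#'
#' @param path CSV file (`long_csv`) or directory of `*.txt` files
#'   (`two_column`).
#' @param dialect One of `"long_csv"`, `"two_column"`.
#' @return A list of [sample_spectra()] objects, one per sample.
#' @export
read_spectra <- function(path, dialect = c("long_csv", "two_column")) {
  dialect <- match.arg(dialect)
  if (dialect == "long_csv") read_spectra_long(path) else read_spectra_dir(path)
}

read_spectra_long <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("sample_id", "point_index", "wavenumber_cm1", "intensity")
  if (!all(need %in% names(raw)))
    stop("parse error: expected columns ", paste(need, collapse = ", "),
         call. = FALSE)
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad))
      stop("parse error: non-numeric value '", raw[[col]][bad[1L]],
           "' in column '", col, "' at data line ", bad[1L] + 1L,
           call. = FALSE)
    v
  }
  pi <- num("point_index"); wn <- num("wavenumber_cm1"); it <- num("intensity")
  key <- paste(raw$sample_id, pi, wn, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate-record error: repeated (sample, point, wavenumber) = (",
         gsub("\r", ", ", d, fixed = TRUE), ")", call. = FALSE)
  }
  out <- list()
  for (sid in unique(raw$sample_id)) {
    sel <- raw$sample_id == sid
    pts <- lapply(sort(unique(pi[sel])), function(p) {
      s <- sel & pi == p
      o <- order(wn[s])
      point_spectrum(sid, p, wn[s][o], it[s][o])
    })
    out[[sid]] <- sample_spectra(sid, pts)
  }
  out
}

read_spectra_dir <- function(path) {
  if (!dir.exists(path)) stop("directory not found: ", path, call. = FALSE)
  files <- list.files(path, pattern = "\\.txt$", full.names = TRUE)
  if (!length(files)) stop("no .txt point files in ", path, call. = FALSE)
  recs <- lapply(files, function(f) {
    base <- sub("\\.txt$", "", basename(f))
    m <- regmatches(base, regexec("^(.*)_([0-9]+)$", base))[[1L]]
    if (length(m) != 3L)
      stop("cannot parse '<sample>_<point>' from filename: ", basename(f),
           call. = FALSE)
    tab <- read.table(f, header = FALSE, sep = "", dec = ".",
                      colClasses = "character")
    if (ncol(tab) == 1L)  # comma-separated fallback
      tab <- read.table(f, header = FALSE, sep = ",", colClasses = "character")
    wn <- suppressWarnings(as.numeric(tab[[1L]]))
    it <- suppressWarnings(as.numeric(tab[[2L]]))
    bad <- which(is.na(wn) | is.na(it))
    if (length(bad))
      stop("parse error in ", basename(f), " at line ", bad[1L], call. = FALSE)
    o <- order(wn)
    point_spectrum(m[2L], as.integer(m[3L]), wn[o], it[o])
  })
  ids <- vapply(recs, `[[`, character(1), "sample_id")
  key <- paste(ids, vapply(recs, `[[`, integer(1), "point_index"))
  if (anyDuplicated(key))
    stop("duplicate-record error: two files map to (sample, point) ",
         key[duplicated(key)][1L], call. = FALSE)
  lapply(split(recs, ids), function(pts) sample_spectra(pts[[1L]]$sample_id, pts))
}

#' Write spectra as long-format CSV
#'
#' Values are written with 17 significant digits so a read/write round trip
#' is lossless for doubles.
#'
#' @param spectra A `sample_spectra` object or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  if (inherits(spectra, "sample_spectra")) spectra <- list(spectra)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("sample_id,point_index,wavenumber_cm1,intensity", con)
  for (s in spectra)
    for (p in s$points)
      writeLines(sprintf("%s,%d,%.17g,%.17g", p$sample_id, p$point_index,
                         p$wavenumbers, p$intensities), con)
  invisible(path)
}

#' Interpolate every point spectrum onto one shared grid
#'
#' Linear interpolation; the requested grid must lie inside the native
#' range of every point (no extrapolation). The default grid, 600 to 1800
#' cm\eqn{^{-1}} at 1 cm\eqn{^{-1}}, covers the whole serum fingerprint
#' panel with margin.
#'
#' @param spectra A `sample_spectra` object.
#' @param grid Numeric `c(start, stop, step)` in cm\eqn{^{-1}}.
#' @return A `sample_spectra` on the common axis.
#' @export
harmonize_axis <- function(spectra, grid = c(600, 1800, 1)) {
  stopifnot(inherits(spectra, "sample_spectra"), length(grid) == 3L)
  axis <- seq(grid[1L], grid[2L], by = grid[3L])
  pts <- lapply(spectra$points, function(p) {
    if (axis[1L] < min(p$wavenumbers) - 1e-9 ||
        axis[length(axis)] > max(p$wavenumbers) + 1e-9)
      stop("extrapolation error: grid [", grid[1L], ", ", grid[2L],
           "] exceeds native range of ", p$sample_id, "/", p$point_index,
           call. = FALSE)
    if (length(p$wavenumbers) == length(axis) &&
        isTRUE(all.equal(p$wavenumbers, axis, tolerance = 0)))
      return(p)
    y <- approx(p$wavenumbers, p$intensities, xout = axis)$y
    point_spectrum(p$sample_id, p$point_index, axis, y)
  })
  sample_spectra(spectra$sample_id, pts)
}

#' Read / write cohort metadata
#'
#' Metadata CSV columns: `sample_id`, `group` (one of healthy, PDAC, CP,
#' LARC_pre, LARC_post), `nar_score` (blank outside the rectal-cancer
#' cohort), `jaundice` (TRUE/FALSE), `matched_pair_id` (blank when the
#' patient has a single timepoint).
#'
#' @param path CSV path.
#' @return A tibble with one row per sample.
#' @export
read_cohort_metadata <- function(path) {
  d <- read.csv(path, colClasses = "character")
  need <- c("sample_id", "group", "nar_score", "jaundice", "matched_pair_id")
  if (!all(need %in% names(d)))
    stop("metadata must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  md <- tibble(
    sample_id = d$sample_id,
    group = d$group,
    nar_score = suppressWarnings(as.numeric(d$nar_score)),
    jaundice = toupper(d$jaundice) %in% c("TRUE", "T", "1", "YES"),
    matched_pair_id = ifelse(d$matched_pair_id == "", NA_character_,
                             d$matched_pair_id))
  validate_metadata(md)
}

validate_metadata <- function(md) {
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample_id in metadata: ",
         md$sample_id[duplicated(md$sample_id)][1L], call. = FALSE)
  bad <- !is.na(md$nar_score) & !startsWith(md$group, "LARC")
  if (any(bad))
    stop("nar_score present for non-LARC sample ", md$sample_id[bad][1L],
         call. = FALSE)
  if (any(md$nar_score < 0, na.rm = TRUE))
    stop("nar_score must be nonnegative", call. = FALSE)
  md
}

#' @rdname read_cohort_metadata
#' @param metadata Metadata tibble.
#' @export
write_cohort_metadata <- function(metadata, path) {
  out <- metadata
  out$nar_score <- ifelse(is.na(out$nar_score), "",
                          sprintf("%.17g", out$nar_score))
  out$matched_pair_id <- ifelse(is.na(out$matched_pair_id), "",
                                out$matched_pair_id)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Apply the cohort exclusion policy
#'
#' Removes samples flagged with jaundice (which biases serum biomarker
#' levels through bilirubin), and, when `longitudinal = TRUE`, keeps only
#' the pre-treatment member of each matched pre/post pair so no patient is
#' counted twice in cross-sectional comparisons.
#'
#' @param metadata Metadata tibble (see [read_cohort_metadata()]).
#' @param longitudinal Apply the matched-pair rule?
#' @return The filtered metadata tibble. Idempotent.
#' @export
apply_exclusions <- function(metadata, longitudinal = FALSE) {
  md <- metadata[!metadata$jaundice, , drop = FALSE]
  if (longitudinal) {
    paired <- !is.na(md$matched_pair_id)
    drop <- paired & md$group != "LARC_pre"
    md <- md[!drop, , drop = FALSE]
  }
  md
}

#' Read / write a wide protein panel
#'
#' Wide CSV: `sample_id` then one nonnegative column per analyte
#' (cytokines, chemokines, DNA-damage-response markers, or label-free
#' abundances).
#'
#' @param path CSV path.
#' @return Tibble, samples in rows.
#' @export
read_protein_panel <- function(path) {
  d <- read.csv(path, check.names = FALSE)
  if (names(d)[1L] != "sample_id")
    stop("protein panel must start with a sample_id column", call. = FALSE)
  vals <- as.matrix(d[, -1L, drop = FALSE])
  if (!is.numeric(vals) || anyNA(vals) || !all(is.finite(vals)))
    stop("protein panel values must be finite numbers", call. = FALSE)
  if (any(vals < 0))
    stop("protein panel values must be nonnegative", call. = FALSE)
  as_tibble(d)
}

#' @rdname read_protein_panel
#' @param panel Protein panel tibble.
#' @export
write_protein_panel <- function(panel, path) {
  write_table_csv(panel, path)
}

# Deterministic CSV writer used for all tabular outputs: doubles at 17
# significant digits, no quoting, no row names.
write_table_csv <- function(df, path) {
  out <- as.data.frame(df)
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
    if (is.logical(out[[j]])) out[[j]] <- ifelse(out[[j]], "TRUE", "FALSE")
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
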