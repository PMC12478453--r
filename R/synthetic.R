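#' Configuration for synthetic serum cohorts
#'
#' Describes a generative model with the statistical structure the
#' analysis pipeline assumes: per-sample fingerprint spectra built as a
#' smooth positive fluorescence baseline (default degree 6, dominating
#' the bands 5-20x) plus narrow pseudo-Voigt peaks at the 40 panel
#' positions, shot-like Gaussian noise, and sporadic cosmic-ray spikes.
#' Group membership acts multiplicatively on selected peak amplitudes;
#' biological variation is lognormal on amplitudes (cv 15% by default).
#' Optional blocks link standardized peak scores to a protein panel
#' through a loading matrix, and to a neoadjuvant-rectal score through a
#' linear model truncated at zero.
#'
#' @param seed Mandatory RNG seed.
#' @param groups Named integer vector: samples per group.
#' @param n_points Acquisition points per sample (25 by default for desk
#'   speed; the full line-map protocol uses 100).
#' @param grid `c(start, stop, step)` wavenumber grid in cm\eqn{^{-1}}.
#' @param peak_shape `"pseudo_voigt"` (default, 50/50), `"gaussian"` or
#'   `"lorentzian"`.
#' @param peak_fwhm Band full width at half maximum (cm\eqn{^{-1}}).
#' @param base_amplitudes Named amplitudes per panel wavenumber; defaults
#'   to a serum-like profile with the 1448 cm\eqn{^{-1}} band strongest.
#' @param group_effects List: group -> named multiplicative factors on
#'   selected wavenumbers.
#' @param baseline_degree Polynomial degree of the true baseline.
#' @param baseline_scale Baseline magnitude as a multiple of the
#'   denominator amplitude.
#' @param noise_sd Channel noise as a fraction of the sample's
#'   denominator amplitude.
#' @param bio_cv Lognormal coefficient of variation of amplitudes across
#'   samples.
#' @param cosmic_rate Expected spikes per point spectrum.
#' @param cosmic_amp Spike amplitude range, in multiples of the noise sd.
#' @param cosmic_width Spike width range in channels.
#' @param protein_spec `NULL`, or `list(loadings, noise_sd, mean,
#'   nar_link, ddr_analytes)`: `loadings` is an analytes x wavenumbers
#'   matrix applied to standardized peak scores; `nar_link` adds
#'   `gamma * (NAR - beta0)` per analyte.
#' @param nar_spec `NULL`, or a list keyed by group:
#'   `list(beta0, betas, sd)` with `betas` named by wavenumber, applied
#'   to standardized log-amplitude scores.
#' @param jaundice_n Named vector: how many samples per group to flag as
#'   jaundiced (default none).
#' @return A `synthetic_config` object.
#' @export
synthetic_config <- function(seed,
                             groups = c(healthy = 20L, PDAC = 20L),
                             n_points = 25L,
                             grid = c(600, 1800, 1),
                             peak_shape = c("pseudo_voigt", "gaussian",
                                            "lorentzian"),
                             peak_fwhm = 8,
                             base_amplitudes = default_base_amplitudes(),
                             group_effects = list(),
                             baseline_degree = 6L,
                             baseline_scale = 10,
                             noise_sd = 0.01,
                             bio_cv = 0.15,
                             cosmic_rate = 0.05,
                             cosmic_amp = c(20, 100),
                             cosmic_width = c(1L, 3L),
                             protein_spec = NULL,
                             nar_spec = NULL,
                             jaundice_n = NULL) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  peak_shape <- match.arg(peak_shape)
  if (peak_fwhm <= 0 || noise_sd < 0 || bio_cv < 0 || baseline_scale <= 0)
    stop("config error: widths, scales and sds must be positive",
         call. = FALSE)
  if (any(base_amplitudes <= 0))
    stop("config error: base amplitudes must be positive", call. = FALSE)
  panel_wn <- names(base_amplitudes)
  for (g in names(group_effects))
    if (!all(names(group_effects[[g]]) %in% panel_wn))
      stop("config error: group_effects keys must be panel wavenumbers",
           call. = FALSE)
  structure(list(seed = as.integer(seed), groups = groups,
                 n_points = as.integer(n_points), grid = grid,
                 peak_shape = peak_shape, peak_fwhm = peak_fwhm,
                 base_amplitudes = base_amplitudes,
                 group_effects = group_effects,
                 baseline_degree = as.integer(baseline_degree),
                 baseline_scale = baseline_scale, noise_sd = noise_sd,
                 bio_cv = bio_cv, cosmic_rate = cosmic_rate,
                 cosmic_amp = cosmic_amp,
                 cosmic_width = as.integer(cosmic_width),
                 protein_spec = protein_spec, nar_spec = nar_spec,
                 jaundice_n = jaundice_n),
            class = "synthetic_config")
}

#' Default serum-like band amplitudes
#'
#' Relative amplitudes over the 40-band panel with the 1448
#' cm\eqn{^{-1}} lipid/protein band as the strongest (1.0) and the
#' 1002 cm\eqn{^{-1}} phenylalanine ring-breathing band next, the
#' familiar look of a dried-serum fingerprint spectrum.
#'
#' @return Named numeric vector keyed by panel wavenumber.
#' @export
default_base_amplitudes <- function() {
  wn <- panel_assignments()$wavenumber_cm1
  amp <- setNames(rep(0.30, length(wn)), format_wn(wn))
  amp[c("1448")] <- 1.00
  amp[c("1002")] <- 0.85
  amp[c("1657", "1249")] <- 0.55
  amp[c("1031", "1063", "1082", "1257", "1268", "1338")] <- 0.45
  amp[c("621", "643", "757", "828", "852", "938", "1126", "1155",
        "1207", "1518", "1552", "1585", "1605", "1615", "1682")] <- 0.35
  amp[c("671", "701", "719", "744", "805", "878", "898", "957", "992",
        "1011", "1051", "1103", "1172", "1314", "1575")] <- 0.25
  amp
}

peak_shape_fn <- function(delta, fwhm, shape, eta = 0.5) {
  g <- exp(-4 * log(2) * delta^2 / fwhm^2)
  l <- 1 / (1 + 4 * delta^2 / fwhm^2)
  switch(shape,
         gaussian = g,
         lorentzian = l,
         pseudo_voigt = eta * g + (1 - eta) * l)
}

# Sum of panel bands at the given per-sample amplitudes.
peak_sum <- function(axis, amplitudes, config) {
  wn <- as.numeric(names(amplitudes))
  out <- numeric(length(axis))
  for (k in seq_along(wn))
    out <- out + amplitudes[k] *
      peak_shape_fn(axis - wn[k], config$peak_fwhm, config$peak_shape)
  out
}

# Baseline polynomial evaluated on the axis; coefs live on t in [-1, 1].
eval_baseline <- function(axis, coefs) {
  t <- 2 * (axis - min(axis)) / (max(axis) - min(axis)) - 1
  out <- numeric(length(axis))
  for (j in seq_along(coefs)) out <- out + coefs[j] * t^(j - 1L)
  out
}

draw_baseline_coefs <- function(config, a_denom) {
  S <- config$baseline_scale * a_denom * runif(1, 0.8, 1.2)
  c(S * runif(1, 0.9, 1.1),
    vapply(seq_len(config$baseline_degree), function(j)
      S * runif(1, -0.08, 0.08) / j, numeric(1)))
}

#' Generate one synthetic point spectrum
#'
#' `intensity = baseline + sum of bands + Gaussian noise + spikes`,
#' drawn from the current RNG state (wrap in `set.seed()` for
#' reproducibility).
#'
#' @param config A [synthetic_config()].
#' @param amplitudes Named per-sample band amplitudes.
#' @param baseline_coefs Baseline polynomial coefficients (constant
#'   first) on the \[-1, 1\] axis; drawn to scale if omitted.
#' @param sample_id,point_index Identifiers for the emitted spectrum.
#' @return A [point_spectrum()]; injected spikes are recorded in
#'   attribute `"spikes"` (`channel`, `width`, `amplitude`).
#' @export
generate_point_spectrum <- function(config, amplitudes = NULL,
                                    baseline_coefs = NULL,
                                    sample_id = "synthetic",
                                    point_index = 0L) {
  axis <- seq(config$grid[1L], config$grid[2L], by = config$grid[3L])
  amplitudes <- amplitudes %||% config$base_amplitudes
  a_denom <- if ("1448" %in% names(amplitudes)) amplitudes[["1448"]]
             else max(amplitudes)
  baseline_coefs <- baseline_coefs %||% draw_baseline_coefs(config, a_denom)
  clean <- eval_baseline(axis, baseline_coefs) +
    peak_sum(axis, amplitudes, config)
  noise_abs <- config$noise_sd * a_denom
  y <- clean
  if (noise_abs > 0) y <- y + rnorm(length(axis), 0, noise_abs)
  spikes <- data.frame(channel = integer(), width = integer(),
                       amplitude = numeric())
  if (config$cosmic_rate > 0) {
    n_sp <- rpois(1L, config$cosmic_rate)
    for (s in seq_len(n_sp)) {
      ch <- sample.int(length(axis), 1L)
      w <- sample(seq(config$cosmic_width[1L], config$cosmic_width[2L]), 1L)
      amp <- runif(1, config$cosmic_amp[1L], config$cosmic_amp[2L]) *
        max(noise_abs, 1e-3 * a_denom)
      idx <- ch:min(ch + w - 1L, length(axis))
      y[idx] <- y[idx] + amp
      spikes <- rbind(spikes, data.frame(channel = ch, width = w,
                                         amplitude = amp))
    }
  }
  out <- point_spectrum(sample_id, point_index, axis, y)
  attr(out, "spikes") <- spikes
  attr(out, "clean") <- clean
  out
}

#' Generate a full synthetic cohort with ground truth
#'
#' Draws per-sample band amplitudes (`base x group factor x lognormal`),
#' per-sample baselines, replicate point spectra with noise and cosmic
#' rays, optional protein panels, and optional NAR scores — and logs
#' everything needed to recompute any expected statistic independently
#' of the analysis pipeline.
#'
#' @param config A [synthetic_config()] with at least 2 groups of at
#'   least 3 samples.
#' @return List with `spectra` (list of harmonized [sample_spectra()]),
#'   `metadata` (tibble), `proteins` (tibble or `NULL`), and `truth`
#'   (amplitudes, standardized scores, baseline coefficients, spike log,
#'   per-sample noise sd, group effects, protein loadings with their
#'   implied peak-analyte correlations, NAR model and latent scores).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (length(config$groups) < 2L || any(config$groups < 3L))
    stop("config error: need >= 2 groups with >= 3 samples each",
         call. = FALSE)
  set.seed(config$seed)
  panel_wn <- names(config$base_amplitudes)
  sdlog <- sqrt(log(1 + config$bio_cv^2))

  group_of <- rep(names(config$groups), config$groups)
  ids <- unlist(lapply(names(config$groups), function(g)
    sprintf("%s_%02d", g, seq_len(config$groups[[g]]))))
  n <- length(ids)

  # Per-sample amplitudes and the exact standard-normal scores behind them
  Z <- matrix(rnorm(n * length(panel_wn)), n, length(panel_wn),
              dimnames = list(ids, panel_wn))
  A <- matrix(NA_real_, n, length(panel_wn), dimnames = list(ids, panel_wn))
  for (i in seq_len(n)) {
    eff <- rep(1, length(panel_wn))
    names(eff) <- panel_wn
    ge <- config$group_effects[[group_of[i]]]
    if (!is.null(ge)) eff[names(ge)] <- ge
    A[i, ] <- config$base_amplitudes * eff * exp(sdlog * Z[i, ])
  }

  # NAR scores from the standardized scores, truncated at zero
  nar <- rep(NA_real_, n)
  nar_latent <- rep(NA_real_, n)
  if (!is.null(config$nar_spec)) {
    for (g in names(config$nar_spec)) {
      sel <- group_of == g
      spec <- config$nar_spec[[g]]
      lin <- rep(spec$beta0, sum(sel))
      for (w in names(spec$betas))
        lin <- lin + spec$betas[[w]] * Z[sel, w]
      lat <- lin + rnorm(sum(sel), 0, spec$sd)
      nar_latent[sel] <- lat
      nar[sel] <- pmax(lat, 0)
    }
  }

  # Protein panel: loadings on standardized scores + optional NAR link
  proteins <- NULL
  implied_r <- NULL
  ps <- config$protein_spec
  if (!is.null(ps)) {
    L <- ps$loadings
    P <- matrix(rep(ps$mean %||% 10, n * nrow(L)), n, nrow(L),
                dimnames = list(ids, rownames(L)))
    P <- P + Z[, colnames(L), drop = FALSE] %*% t(L)
    if (!is.null(ps$nar_link)) {
      centered <- ifelse(is.na(nar_latent), 0, nar_latent)
      for (g in names(config$nar_spec %||% list())) {
        sel <- group_of == g & !is.na(nar_latent)
        centered[sel] <- nar_latent[sel] - config$nar_spec[[g]]$beta0
      }
      for (a in names(ps$nar_link))
        P[, a] <- P[, a] + ps$nar_link[[a]] * centered
    }
    P <- P + matrix(rnorm(length(P), 0, ps$noise_sd), nrow(P))
    P <- pmax(P, 0)
    proteins <- dplyr::bind_cols(tibble(sample_id = ids), as_tibble(P))
    # analytic peak-analyte correlation implied by L (ignoring the NAR
    # link): r = L / sqrt(rowSums(L^2) + noise^2)
    implied_r <- L / sqrt(rowSums(L^2) + ps$noise_sd^2)
  }

  axis <- seq(config$grid[1L], config$grid[2L], by = config$grid[3L])
  coefs <- matrix(NA_real_, n, config$baseline_degree + 1L,
                  dimnames = list(ids, NULL))
  noise_abs <- setNames(config$noise_sd * A[, "1448"], ids)
  spikes <- list()
  spectra <- vector("list", n)
  names(spectra) <- ids
  for (i in seq_len(n)) {
    coefs[i, ] <- draw_baseline_coefs(config, A[i, "1448"])
    pts <- vector("list", config$n_points)
    for (p in seq_len(config$n_points)) {
      sp <- generate_point_spectrum(config, A[i, ], coefs[i, ],
                                    sample_id = ids[i],
                                    point_index = p - 1L)
      sk <- attr(sp, "spikes")
      if (nrow(sk))
        spikes[[length(spikes) + 1L]] <-
          cbind(data.frame(sample_id = ids[i], point_index = p - 1L), sk)
      attr(sp, "spikes") <- NULL
      attr(sp, "clean") <- NULL
      pts[[p]] <- sp
    }
    spectra[[i]] <- sample_spectra(ids[i], pts)
  }
  spikes <- if (length(spikes)) as_tibble(do.call(rbind, spikes))
            else tibble(sample_id = character(), point_index = integer(),
                        channel = integer(), width = integer(),
                        amplitude = numeric())

  jaundice <- rep(FALSE, n)
  if (!is.null(config$jaundice_n))
    for (g in names(config$jaundice_n)) {
      sel <- which(group_of == g)
      jaundice[sample(sel, min(config$jaundice_n[[g]], length(sel)))] <- TRUE
    }

  metadata <- tibble(sample_id = ids, group = group_of, nar_score = nar,
                     jaundice = jaundice,
                     matched_pair_id = NA_character_)

  list(spectra = spectra, metadata = metadata, proteins = proteins,
       truth = list(amplitudes = A, scores = Z, baseline_coefs = coefs,
                    spikes = spikes, noise_abs = noise_abs,
                    group_effects = config$group_effects,
                    protein_loadings = if (is.null(ps)) NULL else ps$loadings,
                    implied_peak_protein_r = implied_r,
                    nar_spec = config$nar_spec, nar_latent = nar_latent,
                    axis = axis, config = config))
}

#' Preset study designs
#'
#' Three ready-made cohort designs:
#' \describe{
#'   \item{`pdac_vs_cp`}{healthy / PDAC / CP diagnosis design. The cancer
#'     group carries elevated sugar and glucose bands (852, 1126, 1011
#'     cm\eqn{^{-1}}), elevated aromatic amino-acid and DNA bands, and
#'     depressed carotenoids (1155, 1518 cm\eqn{^{-1}}); pancreatitis
#'     shares the carotenoid and glucose shifts but not the 852/828/805
#'     cm\eqn{^{-1}} shifts, which are the discriminating bands.}
#'   \item{`larc_response`}{LARC_pre / LARC_post response design with NAR
#'     scores loaded on glycine (898), sugars (852) and carotenoids
#'     (1155, 1518) positively and on amino acids (1207) and saturated
#'     fatty acids (1257) negatively at pre-treatment, and unlinked at
#'     post-treatment; a cytokine + DDR protein panel is linked to peaks
#'     and (inversely, for the DDR markers) to NAR.}
#'   \item{`null`}{two exchangeable groups, no effects, no loadings — for
#'     calibration checks.}
#' }
#'
#' @param preset Preset name.
#' @param seed RNG seed.
#' @param n_per_group Samples per group.
#' @param n_points Points per sample.
#' @param ... Further overrides passed to [synthetic_config()].
#' @return A [synthetic_config()].
#' @export
preset_config <- function(preset = c("pdac_vs_cp", "larc_response", "null"),
                          seed, n_per_group = 20L, n_points = 25L, ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    pdac_vs_cp = list(
      groups = c(healthy = n_per_group, PDAC = n_per_group,
                 CP = n_per_group),
      group_effects = list(
        PDAC = c("852" = 1.6, "1126" = 1.5, "1011" = 1.4, "828" = 1.45,
                 "805" = 1.4, "757" = 1.25, "1031" = 1.2, "1585" = 1.2,
                 "1605" = 1.2, "1615" = 1.2, "1552" = 1.2, "1257" = 1.3,
                 "1268" = 1.3, "1575" = 1.3, "957" = 0.75, "1657" = 0.8,
                 "938" = 0.8, "1155" = 0.65, "1518" = 0.65),
        CP = c("1126" = 1.3, "1011" = 1.2, "1257" = 1.2, "1268" = 1.2,
               "957" = 0.8, "938" = 0.85, "1575" = 1.2, "1155" = 0.65,
               "1518" = 0.65))),
    larc_response = list(
      groups = c(LARC_pre = n_per_group, LARC_post = n_per_group),
      group_effects = list(LARC_pre = c("852" = 1.3, "643" = 1.2)),
      nar_spec = list(
        LARC_pre = list(beta0 = 11,
                        betas = c("852" = 3, "898" = 2.5, "1155" = 1.5,
                                  "1518" = 1.5, "1207" = -2,
                                  "1257" = -1.5),
                        sd = 2),
        LARC_post = list(beta0 = 11, betas = numeric(), sd = 4)),
      protein_spec = larc_protein_spec()),
    null = list(groups = c(A = n_per_group, B = n_per_group)))
  do.call(synthetic_config,
          modifyList(c(list(seed = seed, n_points = n_points), args),
                     list(...)))
}

# Cytokine/chemokine + DDR-marker panel linked to serum bands: immune
# analytes load on amino-acid, arginine and sugar bands; DDR markers on
# DNA-base, NADH, membrane-lipid and fatty-acid bands and inversely on
# the NAR latent score (activated DDR signaling tracks better response).
larc_protein_spec <- function() {
  cyto <- c("IL-2", "IL-4", "IL-6", "IL-8", "IL-13", "IL-17", "IL-1b",
            "IL-1ra", "MCP-1", "MIP-1a", "MIP-1b", "IFN-g", "IP-10",
            "PDGF-bb")
  ddr <- c("ATR", "CHK1_S345", "CHK2_T68", "gH2AX_S139", "p53_S15",
           "MDM2", "p21")
  wn <- names(default_base_amplitudes())
  L <- matrix(0, length(cyto) + length(ddr), length(wn),
              dimnames = list(c(cyto, ddr), wn))
  set_load <- function(analyte, ...) {
    v <- c(...)
    L[analyte, names(v)] <<- v
  }
  set_load("IL-8", "992" = 1.0, "852" = 0.8, "1155" = 0.5)
  set_load("IL-1b", "878" = -0.8, "828" = -0.6, "757" = -0.6, "621" = -0.5)
  set_load("IL-2", "992" = 0.7, "1338" = -0.6, "938" = -0.6)
  set_load("MCP-1", "852" = 0.7, "1082" = 0.6, "1682" = -0.6)
  set_load("IL-1ra", "1002" = 0.6, "828" = 0.6, "757" = 0.5, "805" = 0.5)
  set_load("IL-6", "852" = 0.4, "1126" = 0.4)
  set_load("IL-13", "852" = 0.3, "1126" = 0.3)
  set_load("MDM2", "671" = 0.8, "744" = 0.7, "1575" = 0.7)
  set_load("p53_S15", "671" = 0.7, "744" = 0.7, "1575" = 0.6, "643" = -0.5)
  set_load("ATR", "701" = 0.7, "719" = 0.7, "957" = 0.6)
  set_load("CHK1_S345", "701" = 0.6, "719" = 0.6, "957" = 0.5)
  set_load("CHK2_T68", "701" = 0.6, "719" = 0.5, "957" = 0.5)
  nar_link <- c("IL-17" = -0.30, "IL-2" = -0.25, "IL-4" = -0.20,
                "IL-1ra" = 0.30, "MCP-1" = 0.25,
                ATR = -0.30, CHK1_S345 = -0.30, CHK2_T68 = -0.25,
                gH2AX_S139 = -0.30, p53_S15 = -0.25, MDM2 = -0.20,
                p21 = -0.20)
  list(loadings = L, noise_sd = 1.0, mean = 10, nar_link = nar_link,
       ddr_analytes = ddr, cytokine_analytes = cyto)
}

#' Write a synthetic cohort to disk as plain-text fixtures
#'
#' Emits `spectra.csv` (long format), `metadata.csv`, `proteins.csv`
#' (when configured), the ground-truth tables
#' (`truth_amplitudes.csv`, `truth_spikes.csv`, `truth_group_effects.csv`)
#' and a `config.txt` echo. Byte-stable for a given seed. Intended for
#' small desk-scale configurations; full-size cohorts are better
#' regenerated in code than stored.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Writable output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_fixture <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(config)
  paths <- c(spectra = file.path(out_dir, "spectra.csv"),
             metadata = file.path(out_dir, "metadata.csv"),
             truth_amplitudes = file.path(out_dir, "truth_amplitudes.csv"),
             truth_spikes = file.path(out_dir, "truth_spikes.csv"),
             truth_group_effects = file.path(out_dir,
                                             "truth_group_effects.csv"),
             config = file.path(out_dir, "config.txt"))
  write_spectra(cohort$spectra, paths[["spectra"]])
  write_cohort_metadata(cohort$metadata, paths[["metadata"]])
  amp <- dplyr::bind_cols(tibble(sample_id = rownames(cohort$truth$amplitudes)),
                          as_tibble(cohort$truth$amplitudes))
  write_table_csv(amp, paths[["truth_amplitudes"]])
  write_table_csv(cohort$truth$spikes, paths[["truth_spikes"]])
  ge <- config$group_effects
  ge_tab <- if (length(ge))
    do.call(rbind, lapply(names(ge), function(g)
      data.frame(group = g, wavenumber_cm1 = names(ge[[g]]),
                 factor = unname(ge[[g]]))))
  else data.frame(group = character(), wavenumber_cm1 = character(),
                  factor = numeric())
  write_table_csv(ge_tab, paths[["truth_group_effects"]])
  if (!is.null(cohort$proteins)) {
    paths[["proteins"]] <- file.path(out_dir, "proteins.csv")
    write_protein_panel(cohort$proteins, paths[["proteins"]])
  }
  writeLines(config_lines(config), paths[["config"]])
  invisible(paths)
}

config_lines <- function(config) {
  c(sprintf("seed=%d", config$seed),
    sprintf("groups=%s", paste(sprintf("%s:%d", names(config$groups),
                                       config$groups), collapse = ",")),
    sprintf("n_points=%d", config$n_points),
    sprintf("grid=%g,%g,%g", config$grid[1L], config$grid[2L],
            config$grid[3L]),
    sprintf("peak_shape=%s", config$peak_shape),
    sprintf("peak_fwhm=%g", config$peak_fwhm),
    sprintf("baseline_degree=%d", config$baseline_degree),
    sprintf("baseline_scale=%g", config$baseline_scale),
    sprintf("noise_sd=%g", config$noise_sd),
    sprintf("bio_cv=%g", config$bio_cv),
    sprintf("cosmic_rate=%g", config$cosmic_rate))
}
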