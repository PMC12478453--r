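test_that("the pooled t-test matches its closed form and a quadrature oracle", {
  x <- c(1, 2, 3); y <- c(1, 2, 3)
  r <- ttest_homoscedastic(x, y)
  expect_equal(r$t_stat, 0)
  expect_equal(r$p_value, 1)

  big <- ttest_homoscedastic(c(1, 2, 3), c(1, 2, 3) + 50)
  expect_lt(big$p_value, 1e-4)

  set.seed(30)
  for (i in 1:10) {
    x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1), mean = runif(1))
    r <- ttest_homoscedastic(x, y)
    # oracle: integrate the t density over |t| .. Inf
    q <- 2 * stats::integrate(stats::dt, abs(r$t_stat), Inf, df = r$df,
                              rel.tol = 1e-12)$value
    expect_equal(r$p_value, q, tolerance = 1e-10)
    # and the reference library implementation agrees
    expect_equal(r$p_value,
                 stats::t.test(x, y, var.equal = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  expect_error(ttest_homoscedastic(rep(1, 3), rep(1, 4)), "degenerate")
})

test_that("volcano fold changes and p-values are label-equivariant", {
  set.seed(31)
  m <- matrix(rlnorm(40 * 10), 40, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  g <- rep(c("case", "ref"), each = 20)
  v1 <- volcano(m, g, "case", "ref")
  v2 <- volcano(m, g, "ref", "case")
  expect_equal(v1$fold_change, 1 / v2$fold_change, tolerance = 1e-12)
  expect_equal(v1$p_value, v2$p_value, tolerance = 1e-12)
  expect_identical(v1$significant, v1$p_value < 0.05)
})

test_that("an exchangeable split shows only chance-level significance", {
  set.seed(32)
  m <- matrix(rlnorm(40 * 40, sdlog = 0.15), 40, 40,
              dimnames = list(NULL, paste0("f", 1:40)))
  g <- rep(c("a", "b"), each = 20)
  v <- volcano(m, g, "a", "b")
  expect_lte(sum(v$significant), qbinom(0.999, 40, 0.05))
  expect_lt(max(abs(log2(v$fold_change))), 0.5)
})

test_that("a constant feature (the denominator column) is handled, not fatal", {
  m <- cbind(den = rep(1, 8), f = c(1:4, 6:9))
  g <- rep(c("x", "y"), each = 4)
  v <- volcano(m, g, "x", "y")
  expect_equal(v$p_value[1L], 1)
  expect_equal(v$fold_change[1L], 1)
  expect_false(v$significant[1L])
})

test_that("an injected 2-fold shift is detected with an accurate fold change", {
  set.seed(33)
  hits <- 0L
  for (r in 1:20) {
    m <- matrix(rlnorm(40 * 5, meanlog = 0, sdlog = sqrt(log(1 + 0.15^2))),
                40, 5, dimnames = list(NULL, paste0("f", 1:5)))
    m[1:20, 3L] <- m[1:20, 3L] * 2
    v <- volcano(m, rep(c("case", "ref"), each = 20), "case", "ref")
    ok <- v$significant[3L] && abs(v$fold_change[3L] - 2) / 2 < 0.2 &&
      sum(v$significant[-3L]) <= 2
    hits <- hits + ok
  }
  expect_gte(hits, 19L)
})

test_that("Pearson matrices match the brute-force formula", {
  set.seed(34)
  X <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, letters[1:4]))
  Y <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, LETTERS[1:3]))
  r <- pearson_matrix(X, Y)
  brute <- matrix(NA_real_, 4, 3)
  for (i in 1:4) for (j in 1:3) {
    x <- X[, i]; y <- Y[, j]
    brute[i, j] <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(unname(r), brute, tolerance = 1e-12)

  self <- pearson_matrix(X)
  expect_equal(unname(diag(self)), rep(1, 4))
  expect_equal(self, t(self))
  expect_equal(unname(pearson_matrix(cbind(v = X[, 1L]),
                                     cbind(w = -X[, 1L]))[1L, 1L]), -1)
})

test_that("degenerate correlation inputs are flagged", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  Z <- cbind(flatline = rep(2, 10), ok = rnorm(10))
  expect_warning(r <- pearson_matrix(X, Z), "zero-variance.*flatline")
  expect_true(all(is.na(r[, "flatline"])))
  expect_false(anyNA(r[, "ok"]))
  expect_error(pearson_matrix(X[1:2, ]), "sample-size")
})

test_that("AUC equals exhaustive pair counting, including ties", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), rep(c(FALSE, TRUE), each = 3),
                       n_boot = 0)$auc, 1)
  expect_equal(roc_auc(rep(5, 10), rep(c(TRUE, FALSE), 5), n_boot = 0)$auc,
               0.5)
  set.seed(35)
  for (i in 1:25) {
    n <- sample(6:50, 1)
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(pos) || all(pos)) next
    scores <- sample(round(rnorm(n), 1))  # rounding forces ties
    expect_identical(roc_auc(scores, pos, n_boot = 0)$auc,
                     auc_bruteforce(scores, pos))
  }
})

test_that("the bootstrap CI brackets the AUC and pROC agrees on the point", {
  set.seed(36)
  scores <- c(rnorm(30), rnorm(30, 1.5))
  labs <- rep(c("neg", "pos"), each = 30)
  r <- roc_auc(scores, labs, positive = "pos", seed = 99)
  expect_lte(r$ci_low, r$auc)
  expect_gte(r$ci_high, r$auc)
  expect_equal(r$n_pos, 30L)
  skip_if_not_installed("pROC")
  p <- pROC::roc(labs, scores, levels = c("neg", "pos"),
                 direction = "<", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(p)), tolerance = 1e-12)
})

test_that("single-class labels are rejected", {
  expect_error(roc_auc(1:5, rep("a", 5)), "class error")
})

test_that("NAR strata follow the inclusive 8-14 partial window", {
  expect_identical(stratify_nar(c(0, 7.9, 8, 11, 14, 14.01, 20)),
                   c("complete", "complete", "partial", "partial", "partial",
                     "poor", "poor"))
  expect_identical(stratify_nar(c(5, NA)), c("complete", NA))
  expect_error(stratify_nar(-1), "domain error")
})

test_that("difference spectra are antisymmetric and localized at the true shift", {
  a <- list(wavenumbers = 1:10, intensities = rnorm(10))
  expect_equal(difference_spectrum(a, a)$intensities, rep(0, 10))
  b <- list(wavenumbers = 1:10, intensities = rnorm(10))
  expect_equal(difference_spectrum(a, b)$intensities,
               -difference_spectrum(b, a)$intensities)
  expect_error(difference_spectrum(a, list(wavenumbers = 2:11,
                                           intensities = rnorm(10))),
               "axis error")

  # two groups differing only in the 852 band: the difference peaks there
  cfg <- synthetic_config(seed = 37, groups = c(A = 3L, B = 3L),
                          n_points = 4L, bio_cv = 0, noise_sd = 0.002,
                          cosmic_rate = 0,
                          group_effects = list(B = c("852" = 2)))
  co <- generate_cohort(cfg)
  proc <- lapply(co$spectra, preprocess_sample)
  mean_of <- function(ids) {
    ms <- lapply(proc[ids], mean_spectrum)
    list(wavenumbers = ms[[1L]]$wavenumbers,
         intensities = rowMeans(vapply(ms, `[[`, ms[[1L]]$intensities,
                                       "intensities")))
  }
  d <- difference_spectrum(mean_of(co$metadata$sample_id[4:6]),
                           mean_of(co$metadata$sample_id[1:3]))
  peak_at <- d$wavenumbers[which.max(abs(d$intensities))]
  expect_lte(abs(peak_at - 852), 5)
})
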