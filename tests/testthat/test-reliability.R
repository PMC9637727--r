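test_that("pooled-SD ICC has the right fixed points and mean sensitivity", {
  set.seed(71)
  a <- rnorm(40)
  expect_equal(icc_pooled(a, a), 1)

  b <- a + rnorm(40, sd = 0.5)
  # a constant shift lowers the ICC but leaves Pearson unchanged
  icc0 <- icc_pooled(a, b)
  icc_shift <- icc_pooled(a, b + 2)
  expect_lt(icc_shift, icc0)
  expect_lt(icc_shift, cor(a, b + 2))
  expect_equal(cor(a, b + 2), cor(a, b))
})

test_that("ICC equals the one-way ANOVA variance-decomposition oracle", {
  set.seed(72)
  for (i in 1:30) {
    n <- sample(5:40, 1)
    a <- rnorm(n, sd = runif(1, 0.5, 3))
    b <- a * runif(1, 0.3, 1) + rnorm(n) + runif(1, -2, 2)
    # brute-force oracle: between/within sums of squares of the paired
    # measurements about the grand mean
    m <- mean(c(a, b))
    mi <- (a + b) / 2
    ssb <- 2 * sum((mi - m)^2)
    ssw <- sum((a - mi)^2 + (b - mi)^2)
    expect_equal(icc_pooled(a, b), (ssb - ssw) / (ssb + ssw),
                 tolerance = 1e-10)
  }
})

test_that("even-odd reliability matches the variance-components closed form", {
  # halves = trait + independent noise: expected reliability is
  # var_between / (var_between + var_noise)
  set.seed(73)
  n_sub <- 300
  v_trait <- 2; v_noise <- 0.5
  trait <- rnorm(n_sub, sd = sqrt(v_trait))
  A <- matrix(trait + rnorm(n_sub, sd = sqrt(v_noise)), ncol = 1)
  B <- matrix(trait + rnorm(n_sub, sd = sqrt(v_noise)), ncol = 1)
  r <- even_odd_reliability(A, B)
  expect_equal(r$coefficients, v_trait / (v_trait + v_noise),
               tolerance = 0.12)
  expect_equal(r$type, "even_odd")

  # identical halves across subjects
  r1 <- even_odd_reliability(A, A)
  expect_equal(r1$coefficients, 1)
})

test_that("split-half reliability uses Pearson and ignores common drift", {
  set.seed(74)
  n_sub <- 100
  trait <- rnorm(n_sub)
  A <- matrix(trait + rnorm(n_sub, sd = 0.3), ncol = 1)
  B0 <- trait + rnorm(n_sub, sd = 0.3)
  drift <- 1.5                             # common across subjects
  B <- matrix(B0 + drift, ncol = 1)
  sh <- split_half_reliability(A, B)
  expect_equal(sh$coefficients, cor(A[, 1], B0), tolerance = 1e-12)
  # the ICC on the same drifted data is reduced
  expect_lt(even_odd_reliability(A, B)$coefficients, sh$coefficients)

  # independent halves: near zero; < 3 subjects: missing
  C <- matrix(rnorm(n_sub), ncol = 1)
  expect_lt(abs(split_half_reliability(A, C)$coefficients), 0.3)
  expect_true(is.na(split_half_reliability(A[1:2, , drop = FALSE],
                                           B[1:2, , drop = FALSE])$coefficients))
})

test_that("even-odd halves use every-5th windows whose samples never overlap", {
  sp <- thin_and_split(26, 5)
  idx <- sort(c(sp$a, sp$b))
  expect_equal(idx, seq(1, 26, by = 5))
  # consecutive thinned windows start 5 * 20 = 100 s apart: with 100-s
  # windows their sample ranges are disjoint
  starts <- (idx - 1) * 20
  expect_true(all(diff(starts) >= 100))
  expect_true(length(intersect(sp$a, sp$b)) == 0)
})

test_that("half spectra pipeline is invariant to global signal rescaling", {
  rec <- make_fig_signal(sim_spec(duration = 600, seed = 75))
  ann <- clean_nrem(600)
  eps <- envelope_spectrum(rec, ann$mask, ann$stages, "NREM",
                           bands = demo_bands()["delta"], keep_windows = TRUE)
  fwd <- eps$windows$direction == "forward"
  h1 <- half_spectra(eps$window_psds[[1, 1]][fwd, ], eps$windows[fwd, ],
                     "even_odd")
  # scaling the raw signal scales all densities by a constant; after the
  # log + z post-processing the halves are unchanged
  h2 <- half_spectra(eps$window_psds[[1, 1]][fwd, ] * 7.3,
                     eps$windows[fwd, ], "even_odd")
  expect_equal(h1$a, h2$a, tolerance = 1e-9)
  expect_equal(h1$b, h2$b, tolerance = 1e-9)

  sh <- half_spectra(eps$window_psds[[1, 1]][fwd, ], eps$windows[fwd, ],
                     "split_half")
  expect_equal(length(sh$a), 200)
})

test_that("signal spectrum localizes tones and stays flat for white noise", {
  sw <- signal_psd_welch(tone_recording(12, duration = 120))
  expect_equal(sw$freq[which.max(sw$log_density[, 1])], 12)
  expect_equal(length(sw$freq), 193)    # 0-48 Hz at 0.25 Hz
  expect_equal(max(sw$freq), 48)

  set.seed(76)
  wn <- recording(rnorm(120 * 250), rate = 250)
  swn <- signal_psd_welch(wn)
  expect_lt(diff(range(swn$log_density[swn$freq > 1, 1])), 0.5)

  # demonstration signal: peaks at both component frequencies
  rec <- make_fig_signal(sim_spec(duration = 300, seed = 77))
  sp <- signal_psd_welch(rec)
  ld <- sp$log_density[, 1]
  expect_equal(sp$freq[sp$freq < 8][which.max(ld[sp$freq < 8])], 2)
  expect_equal(sp$freq[sp$freq > 8][which.max(ld[sp$freq > 8])], 12)
})

test_that("signal spectrum respects mask and stages", {
  rec <- tone_recording(12, duration = 120)
  ann <- make_mask_and_stages(120, list(c(0, 60)),
                              list(list(stage = "N2", start = 0, end = 120)))
  sw <- signal_psd_welch(rec, ann$mask, ann$stages, "NREM")
  expect_lt(sw$n_epochs, 31)            # only the clean half contributes
  allart <- make_mask_and_stages(120, list(c(0, 120)), list())
  expect_error(signal_psd_welch(rec, allart$mask, NULL), "no clean")
})

test_that("cross-measure correlations recover shared structure and nulls", {
  set.seed(78)
  n <- 60
  sig <- matrix(rnorm(n * 20), n, 20)
  # duplicated features: unit diagonal
  cm <- cross_measure_correlation(sig, sig)
  expect_equal(diag(cm), rep(1, 20))

  # independent measures: mean |r| consistent with null sampling SD
  env <- matrix(rnorm(n * 15), n, 15)
  cm2 <- cross_measure_correlation(env, sig)
  expect_lt(abs(mean(cm2)), 3 / sqrt(n - 1) / sqrt(length(cm2) / 4))
  expect_lt(mean(abs(cm2)), 2 / sqrt(n - 1))

  # injected common factor produces a positive correlation block
  f <- rnorm(n)
  env2 <- env; env2[, 3] <- f + 0.3 * rnorm(n)
  sig2 <- sig; sig2[, 7] <- f + 0.3 * rnorm(n)
  cm3 <- cross_measure_correlation(env2, sig2)
  expect_gt(cm3[3, 7], 0.7)

  # zero-variance feature: missing cells
  env3 <- env; env3[, 1] <- 5
  expect_true(all(is.na(cross_measure_correlation(env3, sig)[1, ])))
})

test_that("phenotype correlations control FDR and find injected effects", {
  set.seed(79)
  # null cohort: (almost) no rejections
  n <- 120
  X <- matrix(rnorm(n * 50), n, 50)
  phen <- rnorm(n)
  res0 <- phenotype_correlations(X, phen)
  expect_lte(sum(res0$reject), 1)

  # injected effect at one feature rejected, neighbors not
  eff <- list(list(band = "low_sigma", freq_lo = 0.25, freq_hi = 0.25,
                   phenotype = "age", effect = -0.5))
  coh <- make_cohort(cohort_spec(n_subjects = 400, effects = eff, seed = 80))
  feats <- coh$spectra[, "low_sigma", c("0.20", "0.25", "0.30")]
  res <- phenotype_correlations(feats, coh$phenotypes$age)
  expect_true(res$reject[2])
  expect_false(res$reject[1] || res$reject[3])
  expect_lt(res$r[2], -0.3)

  # degenerate inputs
  expect_error(phenotype_correlations(X, rep(1, n)), "constant")
  # feature equal to the phenotype: r = 1
  r1 <- phenotype_correlations(cbind(phen), phen)
  expect_equal(r1$r, 1, tolerance = 1e-12)
})
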