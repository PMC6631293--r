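# HRV metrics: R-peak detection, SDNN, CV, Welch LF/HF.

test_that("SDNN and CV match hand-computed values and their invariances", {
  x <- c(800, 810, 790, 805, 795)
  expect_equal(compute_sdnn(x), 7.905694, tolerance = 1e-6)
  expect_equal(compute_cv(x), 0.009882118, tolerance = 1e-6)
  expect_identical(compute_sdnn(rep(700, 10)), 0)
  expect_identical(compute_cv(rep(700, 10)), 0)
  # translation leaves SDNN unchanged; scaling leaves CV unchanged
  expect_equal(compute_sdnn(x + 100), compute_sdnn(x))
  expect_equal(compute_cv(x * 2), compute_cv(x))
  expect_error(compute_sdnn(800), "at least 2")
})

test_that("SDNN equals a two-pass variance oracle on random series", {
  for (s in 1:20) {
    set.seed(s)
    x <- runif(sample(2:200, 1L), 400, 1200)
    m <- sum(x) / length(x)
    oracle <- sqrt(sum((x - m)^2) / (length(x) - 1L))
    expect_equal(compute_sdnn(x), oracle, tolerance = 1e-10)
  }
})

test_that("R-peak detection recovers generator beat times within one sample", {
  fs <- 250
  rr <- rep(c(800, 820, 790), 3L)
  clean <- simulate_ecg(rr, fs = fs)
  pk <- detect_r_peaks(clean$mv, fs = fs)
  expect_length(pk, length(rr))
  expect_true(all(diff(pk) > 0))
  expect_lt(max(abs(diff(pk) - rr[-1L])), 2 * 1000 / fs + 1e-9)
  expect_lt(max(abs(pk - clean$peak_times_ms)), 1000 / fs + 1e-9)

  noisy <- simulate_ecg(rr, fs = fs, noise_sd = 0.1, seed = 1)
  pk2 <- detect_r_peaks(noisy$mv, fs = fs)
  expect_length(pk2, length(rr))
  expect_lte(max(abs(pk2 - noisy$peak_times_ms)), 1000 / fs)

  expect_warning(out <- detect_r_peaks(rep(0, 1000), fs = fs), "no sample")
  expect_length(out, 0L)
  expect_true(isTRUE(attr(out, "no_peaks")))
})

test_that("detected peaks honour the refractory period", {
  # two bumps 150 ms apart must collapse to one detection
  ecg <- simulate_ecg(c(600, 150, 650, 700), fs = 250)
  pk <- detect_r_peaks(ecg$mv, fs = 250)
  expect_true(all(diff(pk) >= 250))
})

modulated_rr <- function(freqs, amp = 30, mean_rr = 800, n = 400) {
  t <- cumsum(rep(mean_rr / 1000, n))
  mean_rr + rowSums(vapply(freqs, function(f) amp * sin(2 * pi * f * t),
                           numeric(n)))
}

test_that("Welch LF/HF places sinusoidal modulation in the right band", {
  lf_only <- compute_lf_hf(modulated_rr(0.10))
  expect_gte(lf_only$ratio, 5)
  hf_only <- compute_lf_hf(modulated_rr(0.30))
  expect_lte(hf_only$ratio, 0.2)
  both <- compute_lf_hf(modulated_rr(c(0.10, 0.30)))
  expect_gte(both$ratio, 0.5)
  expect_lte(both$ratio, 2)
})

test_that("band powers never exceed the total spectral power in 0.04-0.40 Hz", {
  for (s in 1:10) {
    set.seed(s)
    rr <- 800 + cumsum(rnorm(300, 0, 5))
    rr <- pmin(pmax(rr, 400), 1600)
    sp <- compute_lf_hf(rr)
    df <- sp$freq[2L] - sp$freq[1L]
    total <- sum(sp$psd[sp$freq > 0.04 & sp$freq <= 0.40]) * df
    expect_lte(sp$lf_power + sp$hf_power, total + 1e-9)
  }
})

test_that("short records are rejected for spectral analysis", {
  expect_error(compute_lf_hf(rep(800, 20)), "120 s")
})
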