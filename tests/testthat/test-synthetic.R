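test_that("subject profiles are deterministic and respect class-gain rules", {
  p1 <- generate_subject("AS", 7)
  p2 <- generate_subject("AS", 7)
  expect_identical(p1, p2)

  expect_identical(generate_subject("NON_AS", 7)$class_effect_gain, 0)
  expect_gt(p1$class_effect_gain, 0)
  expect_true(all(p1$class_effect_band_hz > 0 &
                    p1$class_effect_band_hz <= 10))
  expect_true(all(p1$base_freqs_hz > 0 & p1$base_freqs_hz < 25))
  expect_true(all(p1$beat_amplitude > 0))
  expect_gt(p1$noise_sd, 0)

  # co-occurrence classes carry distinct secondary bands
  bands <- lapply(c("AS_MI", "AS_MS", "AS_TR"),
                  function(cl) generate_subject(cl, 1)$secondary_band_hz)
  expect_true(all(vapply(bands, function(b) b[2] <= 25, logical(1))))
  expect_equal(length(unique(vapply(bands, function(b) b[1], numeric(1)))), 3)

  expect_error(generate_subject("ASD", 1), class = "cardiowave_invalid_label")
})

test_that("recordings are deterministic, shaped and labeled correctly", {
  p <- quiet_profile("AS", 3)
  s1 <- generate_recording(p, duration_s = 30, fs_hz = 128)
  s2 <- generate_recording(p, duration_s = 30, fs_hz = 128)
  expect_identical(s1$data, s2$data)
  expect_equal(nrow(s1$data), round(30 * 128))
  expect_identical(s1$channels,
                   c("SCG_X", "SCG_Y", "SCG_Z", "GCG_X", "GCG_Y", "GCG_Z"))
  expect_identical(s1$class_label, "AS")
  expect_error(generate_recording(p, duration_s = -5),
               class = "cardiowave_invalid_argument")
})

test_that("a noiseless profile yields a spectral peak at the first base frequency", {
  p <- quiet_profile("NON_AS", 11)
  p$noise_sd <- 1e-9
  p$baseline_gain <- 0
  fs <- 128
  s <- generate_recording(p, duration_s = 60, fs_hz = fs)
  x <- get_channel(s, "SCG_Z")
  pw <- Mod(fft(x))^2
  f <- (seq_along(x) - 1) * fs / length(x)
  keep <- f > 0.5 & f < fs / 2
  fpeak <- f[keep][which.max(pw[keep])]
  expect_lt(abs(fpeak - p$base_freqs_hz[1]), 0.3)
})

test_that("artifact counts follow the configured Poisson rate", {
  counts <- vapply(1:50, function(s) {
    p <- generate_subject("NON_AS", s)
    p$artifact_rate_per_min <- 6
    sess <- generate_recording(p, duration_s = 300, fs_hz = 64)
    nrow(sess$artifacts)
  }, numeric(1))
  # mean of 50 Poisson(30) draws: sd of the mean ~ 0.77
  expect_gt(mean(counts), 30 - 3 * sqrt(30 / 50))
  expect_lt(mean(counts), 30 + 3 * sqrt(30 / 50))
})

test_that("the noise-only limit has unit variance per channel", {
  p <- quiet_profile("NON_AS", 5)
  p$beat_amplitude[] <- 0
  p$noise_sd <- 1
  s <- generate_recording(p, duration_s = 60, fs_hz = 128)
  for (ch in s$channels) {
    expect_equal(stats::var(get_channel(s, ch)), 1, tolerance = 0.05)
  }
})

test_that("cohorts have the requested composition and are reproducible", {
  coh <- generate_cohort(c(AS = 21, NON_AS = 13), duration_s = 12,
                         fs_hz = 64, seed = 2)
  meta <- cohort_metadata(coh)
  expect_equal(length(coh), 34)
  expect_equal(sum(meta$class_label == "AS"), 21)
  expect_false(anyDuplicated(meta$subject_id) > 0)

  coh2 <- generate_cohort(c(AS = 21, NON_AS = 13), duration_s = 12,
                          fs_hz = 64, seed = 2)
  expect_identical(coh[[5]]$data, coh2[[5]]$data)

  one <- generate_cohort(c(AS = 0, NON_AS = 1), duration_s = 12,
                         fs_hz = 64, seed = 1)
  expect_equal(length(one), 1)

  expect_error(generate_cohort(integer(0)),
               class = "cardiowave_invalid_argument")
})

test_that("AS sessions carry more disease-band power than non-AS sessions", {
  band_power <- function(x, fs, lo, hi) {
    pw <- Mod(fft(x))^2
    f <- (seq_along(x) - 1) * fs / length(x)
    mean(pw[f >= lo & f <= hi])
  }
  pow <- function(cl) {
    vapply(1:20, function(s) {
      p <- quiet_profile(cl, s)
      sess <- generate_recording(p, duration_s = 30, fs_hz = 64)
      band_power(get_channel(sess, "SCG_Z"), 64, 4.5, 8.5)
    }, numeric(1))
  }
  expect_gt(mean(pow("AS")), mean(pow("NON_AS")))
})

test_that("cohort CSV round-trips losslessly", {
  coh <- generate_cohort(c(AS = 1, NON_AS = 1), duration_s = 12,
                         fs_hz = 64, seed = 9)
  dir <- withr::local_tempdir()
  write_cohort_csv(coh, dir)
  back <- read_cohort_csv(dir)
  expect_equal(cohort_metadata(back)$class_label,
               cohort_metadata(coh)$class_label)
  expect_equal(as.data.frame(back[[1]]$data), as.data.frame(coh[[1]]$data))
})
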