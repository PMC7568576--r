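test_that("the frequency grid has the closed-form size and stays in band", {
  g <- build_cwt_grid(256, voices_per_octave = 16)
  expect_equal(length(g$frequencies_hz),
               floor(16 * log2(25.39 / 0.79)) + 1)  # 81
  expect_equal(length(g$frequencies_hz), 81)
  g1 <- build_cwt_grid(256, voices_per_octave = 1)
  expect_equal(length(g1$frequencies_hz), 6)
  for (g_ in list(g, g1)) {
    expect_lte(max(g_$frequencies_hz), 25.39)
    expect_gte(min(g_$frequencies_hz), 0.79)
    expect_true(all(diff(g_$frequencies_hz) < 0))  # descending
  }
  expect_error(build_cwt_grid(50), class = "cardiowave_nyquist_violation")
})

test_that("pure tones localize to within one grid bin across the band", {
  fs <- 128
  g <- build_cwt_grid(fs)
  t <- (0:(10 * fs - 1)) / fs
  test_freqs <- exp(seq(log(1), log(24), length.out = 10))
  step <- log2(g$frequencies_hz[1] / g$frequencies_hz[2])
  for (f0 in test_freqs) {
    sc <- cwt_morse(sin(2 * pi * f0 * t), fs, g)
    ridge <- g$frequencies_hz[which.max(rowMeans(sc$magnitude))]
    expect_lte(abs(log2(ridge / f0)), step + 1e-9)
  }
})

test_that("the Morse CWT is linear, near-unit on ridges, and zero on zero", {
  fs <- 128
  g <- build_cwt_grid(fs)
  t <- (0:(10 * fs - 1)) / fs
  x <- sin(2 * pi * 5 * t)
  sc1 <- cwt_morse(x, fs, g)
  sc3 <- cwt_morse(3 * x, fs, g)
  expect_equal(sc3$magnitude, 3 * sc1$magnitude, tolerance = 1e-10)

  ridge_row <- which.max(rowMeans(sc1$magnitude))
  central <- sc1$magnitude[ridge_row, 300:980]
  expect_true(all(central > 0.9 & central < 1.1))

  z <- cwt_morse(numeric(640), fs, g)
  expect_true(all(z$magnitude == 0))
})

test_that("two tones produce two ridges near their frequencies", {
  fs <- 128
  g <- build_cwt_grid(fs)
  t <- (0:(10 * fs - 1)) / fs
  sc <- cwt_morse(sin(2 * pi * 2 * t) + sin(2 * pi * 15 * t), fs, g)
  prof <- rowMeans(sc$magnitude)
  f <- g$frequencies_hz
  peak_near <- function(f0) {
    local <- which(abs(log2(f / f0)) < 0.3)
    i <- local[which.max(prof[local])]
    prof[i] > 0.7 && abs(log2(f[i] / f0)) < 0.15
  }
  expect_true(peak_near(2))
  expect_true(peak_near(15))
})

test_that("per-frequency statistics match hand-computed values", {
  g <- build_cwt_grid(128, voices_per_octave = 1)
  fake <- structure(list(
    magnitude = rbind(rep(2, 4), c(0, 1, 2, 3),
                      matrix(0, 4, 4)),
    frequencies_hz = g$frequencies_hz,
    times_s = 0:3, grid = g,
    subject_id = "S", channel = "SCG_Z"), class = "scalogram")
  fv <- extract_features(fake)
  expect_equal(nrow(fv), 5 * 6)
  v <- stats::setNames(fv$value, fv$feature)
  f1 <- sprintf("%.2f", g$frequencies_hz[1])
  f2 <- sprintf("%.2f", g$frequencies_hz[2])
  expect_equal(v[[paste0("SCG_Z_MEAN_", f1)]], 2)
  expect_equal(v[[paste0("SCG_Z_STD_", f1)]], 0)
  expect_equal(v[[paste0("SCG_Z_IQR_", f1)]], 0)
  expect_equal(v[[paste0("SCG_Z_MEAN_", f2)]], 1.5)
  expect_equal(v[[paste0("SCG_Z_MED_", f2)]], 1.5)
  expect_equal(v[[paste0("SCG_Z_MAX_", f2)]], 3)
  # population SD and type-7 IQR
  expect_equal(v[[paste0("SCG_Z_STD_", f2)]], sqrt(1.25))
  expect_equal(v[[paste0("SCG_Z_IQR_", f2)]], 1.5)

  expect_error(extract_features(structure(
    list(magnitude = matrix(numeric(0), 0, 0)), class = "scalogram")),
    class = "cardiowave_invalid_argument")
})

test_that("feature names round-trip through the parser", {
  g <- build_cwt_grid(128)
  t <- (0:639) / 128
  sc <- cwt_morse(sin(2 * pi * 5 * t), 128, g, channel = "GCG_Y")
  fv <- extract_features(sc)
  parsed <- parse_feature_names(fv$feature)
  expect_equal(nrow(parsed), 5 * 81)
  expect_true(all(parsed$channel == "GCG_Y"))
  expect_setequal(unique(parsed$statistic),
                  c("MEAN", "MED", "MAX", "STD", "IQR"))
  expect_equal(sort(unique(parsed$freq_hz)),
               sort(round(g$frequencies_hz, 2)))
  expect_error(parse_feature_names("SCGZ_MAX_5"),
               class = "cardiowave_malformed_feature_name")
})

test_that("rendered images honor shape, range and palette contracts", {
  g <- build_cwt_grid(128)
  t <- (0:639) / 128
  sc <- cwt_morse(sin(2 * pi * 5 * t) + 0.1 * rnorm(640), 128, g)

  gray <- render_image(sc, "GRAY_1CH", c(60, 80))
  expect_equal(dim(gray), c(60, 80, 1))
  expect_true(all(gray >= 0 & gray <= 1))

  default_gray <- render_image(sc, "GRAY_1CH")
  expect_equal(dim(default_gray), c(600, 800, 1))

  rgb <- render_image(sc, "PARULA_RGB", c(32, 32))
  expect_equal(dim(rgb), c(32, 32, 3))
  # the minimum cell maps to the first palette entry
  pal <- parula_colors(128)
  idx <- which(rgb[, , 1] == pal[1, 1], arr.ind = TRUE)[1, ]
  expect_equal(c(rgb[idx[1], idx[2], ]), pal[1, ], tolerance = 1e-12)

  flat <- structure(list(magnitude = matrix(5, 4, 4),
                         frequencies_hz = 1:4, times_s = 1:4),
                    class = "scalogram")
  expect_warning(img <- render_image(flat, "GRAY_1CH", c(8, 8)),
                 "constant")
  expect_true(all(img == 0))
})

test_that("parula palette is a valid 128-level ramp", {
  pal <- parula_colors(128)
  expect_equal(dim(pal), c(128, 3))
  expect_true(all(pal >= 0 & pal <= 1))
  # perceptual ramp: blue decreasing overall, red/green increasing
  expect_gt(pal[128, 1], pal[1, 1])
  expect_gt(pal[128, 2], pal[1, 2])
  expect_lt(pal[128, 3], pal[1, 3])
})
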