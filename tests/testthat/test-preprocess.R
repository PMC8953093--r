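test_that("soft thresholding matches its closed form", {
  expect_equal(soft_threshold(3.0, 1.0), 2.0)
  expect_equal(soft_threshold(-3.0, 1.0), -2.0)
  expect_equal(soft_threshold(0.5, 1.0), 0.0)
  x <- c(-2, -0.3, 0, 0.7, 5)
  expect_equal(soft_threshold(x, 0.5), sign(x) * pmax(abs(x) - 0.5, 0))
  expect_error(soft_threshold(1, -0.1), "nonnegative")
})

test_that("universal threshold follows the MAD-based rule", {
  expect_equal(universal_threshold(rep(0, 16)), 0.0)
  expect_equal(universal_threshold(c(5, 5, 5, 5)), 0.0)
  # hand evaluation: median 0, |dev| {1,1,2,2}, MAD 1.5
  expect_equal(universal_threshold(c(1, -1, 2, -2)),
               1.5 / 0.6745 * sqrt(2 * log(4)))
  expect_error(universal_threshold(numeric(0)), "non-empty")
})

test_that("single-level analysis/synthesis matches the reference convention", {
  # frozen values computed with an independent wavelet library
  # (sym8, symmetric extension), seed-0 standard-normal input of length 40
  x <- c(1.6243453636632417, -0.61175641365007538, -0.5281717522634557,
         -1.0729686221561705, 0.86540762932467852, -2.3015386968802827,
         1.74481176421648, -0.76120690089510279, 0.31903909605709857,
         -0.24937037547741009, 1.4621079370449741, -2.060140709497654,
         -0.32241720401350749, -0.38405435466841564, 1.1337694423354374,
         -1.0998912673140309, -0.17242820755043575, -0.87785841792137176,
         0.042213746715592831, 0.58281521371582223, -1.1006191772129212,
         1.1447237098396141, 0.90159072059279555, 0.50249433890186823,
         0.90085594926441181, -0.6837278591743331, -0.12289022551864817,
         -0.93576943425906878, -0.26788807962601591, 0.53035546673818601,
         -0.69166075172530905, -0.39675352685597737, -0.68717270011959941,
         -0.84520564149871957, -0.67124613083681905, -0.01266459891890136,
         -1.1173103486352778, 0.23441569781709215, 1.6598021771098705,
         0.74204416057733558)
  ca_ref <- c(-0.49247283259941438, -0.93587054438127881,
              0.007928763303658071, 1.710474717713909, -1.032563985621529,
              -0.68608565550807465, 0.044368696052508941,
              0.06619792814102915, 0.17289764600024687, -1.2093809307045162,
              0.50609143273023305, -1.1111142823059506, 0.022789899903612208,
              -0.23919892257813652, 1.4153959790348667, 0.58170749513926157,
              -0.86476885454950858, -0.17105182466359814,
              -0.35889716138305039, -1.0385249625028747, -0.75222142965464134,
              -0.87399025555643406, 1.449205143612226, 1.6346954450214366,
              0.35971279212196228, -0.65928109893703901, -1.0716736645512435)
  flt <- ecgdelin:::wavelet_filters("sym8")
  s <- ecgdelin:::dwt_step(x, flt)
  expect_equal(s$ca, ca_ref, tolerance = 1e-12)
  back <- ecgdelin:::idwt_step(s$ca, s$cd, length(x), flt)
  expect_equal(back, x, tolerance = 1e-10)
})

test_that("multilevel reconstruction with untouched coefficients is exact", {
  set.seed(21)
  for (n in c(500, 777)) {
    x <- cumsum(rnorm(n, 0, 0.1))
    for (w in c("sym8", "db4")) {
      dec <- ecgdelin:::wavedec(x, w, 5L)
      y <- ecgdelin:::waverec(dec)
      expect_lt(sqrt(sum((y - x)^2) / sum(x^2)), 1e-8)
    }
  }
})

test_that("denoising preserves length, metadata, and determinism", {
  g <- generate_record(rhythm_spec("NSR", n_beats = 20L, noise_sd = 0.05,
                                   seed = 8L))
  d1 <- dwt_denoise(g$record)
  d2 <- dwt_denoise(g$record)
  expect_length(d1, length(g$record))
  expect_equal(d1$fs, g$record$fs)
  expect_equal(d1$record_id, g$record$record_id)
  expect_identical(d1$samples, d2$samples)
})

test_that("a zero signal stays zero and short records reduce levels", {
  out <- dwt_denoise(ecg_record(numeric(300), 250),
                     denoise_config(levels = 4L))
  expect_equal(out$samples, numeric(300))
  expect_warning(
    dwt_denoise(ecg_record(rnorm(64), 250), denoise_config(levels = 8L)),
    "reducing levels")
})

test_that("baseline wander is strongly attenuated", {
  fs <- 250
  t <- (0:(30 * fs - 1)) / fs
  baseline <- ecg_record(0.5 * sin(2 * pi * 0.25 * t), fs)
  out <- dwt_denoise(baseline, denoise_config(levels = 8L,
                                              remove_baseline = TRUE))
  expect_lt(sum(out$samples^2) / sum(baseline$samples^2), 0.10)
})

test_that("denoising brings a noisy beat closer to its clean version", {
  b <- generate_beat(beat_template(), fs = 250, include_p = TRUE,
                     total_len = 400L)
  set.seed(13)
  noisy <- b$samples + rnorm(400L, 0, 0.05)
  den <- suppressWarnings(  # 400 samples support < 8 levels
    dwt_denoise(ecg_record(noisy, 250),
                denoise_config(remove_baseline = FALSE)))$samples
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  expect_lt(rmse(den, b$samples), rmse(noisy, b$samples))
})
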