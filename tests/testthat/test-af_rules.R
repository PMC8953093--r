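test_that("RR series follows the corrected interval formula", {
  rr <- rr_intervals(c(0L, 250L, 500L), fs = 250)
  expect_equal(rr$rr_ms, c(1000, 1000))
  expect_equal(rr$bpm, c(60, 60))
  rr2 <- rr_intervals(c(0L, 125L), fs = 250)
  expect_equal(rr2$rr_ms, 500)
  expect_equal(rr2$bpm, 120)
  expect_error(rr_intervals(c(10L, 10L), 250), "increasing")
  expect_error(rr_intervals(5L, 250), "two R-peaks")
})

test_that("RR series agrees with a brute-force pairwise oracle", {
  set.seed(71)
  for (i in 1:10) {
    peaks <- sort(sample.int(10000L, sample(5:30, 1L)))
    fs <- sample(c(250, 300, 500), 1L)
    rr <- rr_intervals(peaks, fs)
    brute <- vapply(seq_len(length(peaks) - 1L), function(j)
      (peaks[[j + 1L]] - peaks[[j]]) / fs * 1000, 0)
    expect_equal(rr$rr_ms, brute)
    # telescoping sum
    expect_equal(sum(rr$rr_ms),
                 (peaks[[length(peaks)]] - peaks[[1L]]) / fs * 1000)
  }
})

test_that("ventricular response banding has closed 60/100 boundaries", {
  expect_equal(classify_response(80), "normal")
  expect_equal(classify_response(45), "slow")
  expect_equal(classify_response(120), "rapid")
  expect_equal(classify_response(60), "normal")
  expect_equal(classify_response(100), "normal")
  expect_equal(classify_response(59.999), "slow")
  expect_equal(classify_response(100.001), "rapid")
  expect_error(classify_response(0), "positive")
})

test_that("regularity verdicts follow the median-tolerance rule", {
  mk <- function(rr_ms) rr_intervals(cumsum(c(0, rr_ms)) / 1000 * 250, 250)
  expect_true(assess_regularity(mk(rep(800, 15)))$regular)
  alt <- mk(rep(c(600, 1200), 8L))
  res <- assess_regularity(alt)
  expect_false(res$regular)
  expect_true(all(!res$trace$patterned))
  drift <- mk(seq(800, 840, by = 5))
  expect_true(assess_regularity(drift)$regular)
  expect_error(assess_regularity(mk(rep(800, 3))), "insufficient",
               class = "insufficient_data_error")
  expect_error(assess_regularity(mk(rep(800, 15)), window_beats = 9L),
               "5, 7")
})

test_that("regularity disagrees across response bands even with tight RR", {
  # intervals alternating 590/610 ms straddle the 100 BPM rapid/normal
  # boundary (101.7 vs 98.4 BPM): bands disagree -> unpatterned
  mk <- function(rr_ms) rr_intervals(cumsum(c(0, rr_ms)) / 1000 * 250, 250)
  res <- assess_regularity(mk(rep(c(590, 610), 8L)))
  expect_false(res$regular)
  expect_true(all(!res$trace$bands_agree))
})

test_that("regularity is invariant to uniform time rescaling", {
  set.seed(73)
  rr_ms <- 780 + cumsum(rnorm(20, 0, 8))    # ~75 BPM, stays in-band
  mk <- function(v, fs) rr_intervals(cumsum(c(0, v)) / 1000 * fs, fs)
  r1 <- assess_regularity(mk(rr_ms, 250))
  r2 <- assess_regularity(mk(rr_ms * 1.08, 250))  # still normal band
  expect_equal(r1$regular, r2$regular)
  expect_equal(r1$trace$patterned, r2$trace$patterned)
  expect_equal(r1$trace$max_rel_dev, r2$trace$max_rel_dev)
})

test_that("P presence thresholds on run duration and beat fraction", {
  p_beat <- function(dur_s, fs = 250) {
    n <- round(dur_s * fs)
    c(rep(0L, n), rep(3L, 50L))
  }
  all_p <- replicate(10, p_beat(0.08), simplify = FALSE)
  expect_true(detect_p_presence(all_p, 250)$p_present)
  no_p <- replicate(10, rep(3L, 60L), simplify = FALSE)
  res <- detect_p_presence(no_p, 250)
  expect_false(res$p_present)
  expect_equal(res$fraction_with_p, 0)
  # 4 of 10 beats with 0.07-s runs: 0.4 < 0.5 -> absent
  mix <- c(replicate(4, p_beat(0.07), simplify = FALSE),
           replicate(6, rep(3L, 60L), simplify = FALSE))
  expect_false(detect_p_presence(mix, 250)$p_present)
  # short blips below 0.06 s never count
  blips <- replicate(10, p_beat(0.04), simplify = FALSE)
  expect_false(detect_p_presence(blips, 250)$p_present)
  expect_error(detect_p_presence(list(), 250), "at least one")
})

test_that("the AF rule table is total and driven by regularity", {
  expect_equal(identify_af(TRUE, TRUE)$decision, "NSR")
  expect_equal(identify_af(FALSE, TRUE)$decision, "NSR")
  expect_equal(identify_af(TRUE, FALSE)$decision, "AF")
  expect_equal(identify_af(FALSE, FALSE)$decision, "AF")
  for (p in c(TRUE, FALSE)) for (r in c(TRUE, FALSE))
    expect_equal(identify_af(p, r)$decision == "AF", !r)
})

test_that("ppv/npv match hand counts and flag empty denominators", {
  truth <- rep(c("AF", "NSR"), c(9L, 11L))
  dec <- c(rep("AF", 8L), "NSR", rep("AF", 2L), rep("NSR", 9L))
  res <- ppv_npv(dec, truth)
  expect_equal(res$ppv, 0.8)
  expect_equal(res$npv, 0.9)
  expect_equal(res$counts, c(tp = 8L, fp = 2L, tn = 9L, fn = 1L))
  perfect <- ppv_npv(truth, truth)
  expect_equal(perfect$ppv, 1.0)
  expect_equal(perfect$npv, 1.0)
  expect_equal(perfect$f1, 1.0)
  none <- ppv_npv(rep("NSR", 4L), c("AF", "NSR", "AF", "NSR"))
  expect_true(is.na(none$ppv))
  expect_error(ppv_npv("AF", c("AF", "NSR")), "equal-length")
})

test_that("screening abstains on records with too few beats", {
  m <- build_model(conv_filters = c(2L, 2L), units_per_direction = 4L,
                   seed = 2L)
  m$trained <- TRUE  # tiny stub; abstention happens before prediction
  g <- generate_record(rhythm_spec("NSR", n_beats = 3L, seed = 91L))
  res <- suppressWarnings(screen_record(g$record, m))  # short record: fewer DWT levels
  expect_true(res$abstained)
  expect_true(is.na(res$decision))
  expect_match(res$reason, "beats")
})
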