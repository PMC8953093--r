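test_that("one_hot is the exact indicator encoding and round-trips", {
  m <- rep(3L, 370L)
  oh <- one_hot(m)
  expect_equal(dim(oh), c(370L, 5L))
  expect_true(all(oh[, 4L] == 1L))
  expect_equal(rowSums(oh), rep(1, 370))
  m2 <- c(0:4, sample(0:4, 20, replace = TRUE))
  oh2 <- one_hot(m2)
  expect_equal(oh2[1:5, ], diag(5), ignore_attr = TRUE)
  expect_equal(max.col(oh2, ties.method = "first") - 1L, m2)
  expect_error(one_hot(c(0L, 7L)), "0,1,2,3,4")
})

test_that("beat_window enforces the PAD invariant", {
  s <- numeric(10)
  good <- beat_window(s, c(rep(3L, 6L), rep(4L, 4L)), pad_start = 6L)
  expect_equal(good$pad_start, 6L)
  expect_equal(good$onehot[7L, ], c(0L, 0L, 0L, 0L, 1L))
  expect_error(beat_window(s, c(rep(3L, 6L), rep(4L, 4L)), pad_start = 5L),
               "pad_start")
  expect_error(beat_window(s, c(4L, rep(3L, 9L)), pad_start = 10L),
               "pad_start")
})

test_that("flat or too-short records yield no or an error for R-peaks", {
  flat <- ecg_record(numeric(1000), 250)
  expect_length(detect_rpeaks(flat), 0L)
  expect_error(detect_rpeaks(ecg_record(numeric(100), 250)), "second")
})

test_that("R-peaks are recovered exactly on clean synthetic records", {
  g <- generate_record(rhythm_spec("NSR", n_beats = 20L, noise_sd = 0,
                                   baseline_amp = 0, seed = 31L))
  det <- detect_rpeaks(g$record)
  expect_length(det, 20L)
  expect_true(all(abs(det - g$rpeaks) <= 2L))
  expect_identical(det, detect_rpeaks(g$record))  # deterministic
})

test_that("R-peak sensitivity stays high under noise", {
  hits <- 0L
  total <- 0L
  for (seed in 41:43) {
    g <- generate_record(rhythm_spec("NSR", n_beats = 20L,
                                     noise_sd = 0.05, seed = seed))
    det <- detect_rpeaks(g$record)
    total <- total + length(g$rpeaks)
    hits <- hits + sum(vapply(g$rpeaks, function(r)
      any(abs(det - r) <= 5L), logical(1)))
  }
  expect_gte(hits / total, 0.95)
})

test_that("segmentation pads, clips and maps one window per anchor", {
  g <- generate_record(rhythm_spec("NSR", mean_rr = 1.2, n_beats = 6L,
                                   noise_sd = 0, seed = 51L))
  cfg <- segmentation_config(anchor = "p_onset")
  w <- segment_beats(g$record, g$mask, anchors = g$beat_starts,
                     config = cfg, stops = g$beat_ends)
  expect_length(w, 6L)
  for (i in seq_along(w)) {
    expect_s3_class(w[[i]], "beat_window")
    expect_length(w[[i]]$samples, 370L)
    avail <- min(370L, g$beat_ends[[i]] - g$beat_starts[[i]])
    expect_equal(w[[i]]$pad_start, avail)
    # class-0 run starts at index 0 in p_onset windows
    expect_equal(w[[i]]$mask[[1L]], 0L)
    expect_equal(sum(w[[i]]$mask == 4L), 370L - avail)
    expect_equal(w[[i]]$samples[w[[i]]$mask == 4L],
                 numeric(370L - avail))
  }
  expect_error(segment_beats(g$record, g$mask, anchors = -1L, config = cfg),
               "out of bounds")
  wrong_fs <- ecg_record(g$record$samples, 500)
  expect_error(segment_beats(wrong_fs, NULL, anchors = 0L, config = cfg),
               "resample")
})

test_that("concatenating p_onset windows reproduces the record labels", {
  g <- generate_record(rhythm_spec("NSR", mean_rr = 0.8, n_beats = 8L,
                                   noise_sd = 0, seed = 52L))
  cfg <- segmentation_config(anchor = "p_onset")
  w <- segment_beats(g$record, g$mask, anchors = g$beat_starts,
                     config = cfg, stops = g$beat_ends)
  rebuilt_mask <- unlist(lapply(w, function(x)
    x$mask[seq_len(x$pad_start)]))
  rebuilt_samp <- unlist(lapply(w, function(x)
    x$samples[seq_len(x$pad_start)]))
  span <- (g$beat_starts[[1L]] + 1L):g$beat_ends[[length(w)]]
  expect_equal(rebuilt_mask, g$mask[span])
  expect_equal(rebuilt_samp, g$record$samples[span])
})

test_that("rpeak_offset windows start pre_r before the peak and pad after post_r", {
  g <- generate_record(rhythm_spec("NSR", n_beats = 6L, noise_sd = 0,
                                   seed = 53L))
  cfg <- segmentation_config(anchor = "rpeak_offset", pre_r = 0.2,
                             post_r = 0.45)
  w <- segment_beats(g$record, g$mask, anchors = g$rpeaks, config = cfg)
  expect_length(w, 6L)
  for (i in seq_along(w)) {
    expect_equal(w[[i]]$source$start,
                 max(0L, g$rpeaks[[i]] - round(0.2 * 250)))
    expect_equal(w[[i]]$pad_start,
                 min(370L, g$rpeaks[[i]] + round(0.45 * 250) -
                       w[[i]]$source$start))
  }
  # inference mode: no mask -> class 3 in data, class 4 in padding
  wi <- segment_beats(g$record, NULL, anchors = g$rpeaks, config = cfg)
  expect_true(all(wi[[1L]]$mask %in% c(3L, 4L)))
})

test_that("every produced window satisfies the invariants on random records", {
  for (seed in 61:63) {
    kind <- if (seed %% 2L) "NSR" else "AF"
    g <- generate_record(rhythm_spec(kind, n_beats = 10L, seed = seed))
    cfg <- segmentation_config(anchor = "rpeak_offset")
    for (win in segment_beats(g$record, g$mask, g$rpeaks, cfg)) {
      expect_length(win$mask, 370L)
      expect_true(all(win$mask %in% 0:4))
      is_pad <- win$mask == 4L
      expect_identical(is_pad, seq_len(370L) - 1L >= win$pad_start)
      expect_equal(rowSums(win$onehot), rep(1, 370L))
      expect_equal(max.col(win$onehot, ties.method = "first") - 1L,
                   win$mask)
    }
  }
})
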