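# Beat segmentation: R-peak detection on unannotated records and
# cutting records into fixed-length (default 370-sample) zero-padded
# labelled beat windows.

#' Segmentation configuration
#'
#' @param window_len Window length in samples (default 370, sized to hold
#'   one beat at 250 Hz from P onset to the isoelectric tail).
#' @param anchor `"p_onset"` (training: windows start at each beat's
#'   P onset) or `"rpeak_offset"` (deployment: windows start `pre_r`
#'   seconds before each detected R-peak).
#' @param pre_r,post_r Seconds before / after the R-peak bounding the
#'   beat in `rpeak_offset` mode (defaults 0.2 and 0.45).
#' @param target_fs Sampling frequency the record must carry (default
#'   250 Hz); [segment_beats()] refuses records at any other rate.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(window_len = 370L,
                                anchor = c("rpeak_offset", "p_onset"),
                                pre_r = 0.2, post_r = 0.45,
                                target_fs = 250) {
  anchor <- match.arg(anchor)
  window_len <- as.integer(window_len)
  if (window_len < ceiling((pre_r + post_r) * target_fs))
    stop("segmentation_config: window_len shorter than pre_r + post_r span",
         call. = FALSE)
  structure(list(window_len = window_len, anchor = anchor, pre_r = pre_r,
                 post_r = post_r, target_fs = target_fs),
            class = "segmentation_config")
}

#' Detect R-peaks in a single-lead ECG
#'
#' A Pan-Tompkins-style detector: zero-phase 5-15 Hz Butterworth
#' band-pass, squaring, a centred 0.15 s moving-average energy envelope,
#' an adaptive threshold (running mixture of the signal and noise peak
#' levels), and a 0.3 s refractory period.  Candidate envelope peaks are
#' refined to the local extremum of the absolute band-passed signal
#' within +/- 0.05 s so the returned indices sit on the R apex.
#' Deterministic for a fixed record.
#'
#' @param record An [ecg_record()] of at least one second.
#' @return Strictly increasing 0-based sample indices of detected
#'   R-peaks (possibly empty).
#' @export
detect_rpeaks <- function(record) {
  stopifnot(inherits(record, "ecg_record"))
  fs <- record$fs
  x <- record$samples
  n <- length(x)
  if (n < fs)
    stop("detect_rpeaks: record shorter than one second", call. = FALSE)
  bp <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  xb <- signal::filtfilt(bp, x)
  env <- stats::filter(xb^2, rep(1 / round(0.15 * fs), round(0.15 * fs)),
                       sides = 2)
  env[is.na(env)] <- 0
  env <- as.numeric(env)
  if (max(env) <= 0) return(integer(0))
  # local maxima of the envelope
  cand <- which(diff(sign(diff(env))) < 0) + 1L
  if (!length(cand)) return(integer(0))
  cand <- cand[order(env[cand], decreasing = TRUE)]
  # adaptive threshold: start from the upper peak population, then track
  spki <- stats::quantile(env[cand], 0.95, names = FALSE)
  npki <- stats::quantile(env[cand], 0.50, names = FALSE)
  thr <- npki + 0.25 * (spki - npki)
  cand <- sort(cand[env[cand] >= thr])
  if (!length(cand)) return(integer(0))
  refractory <- round(0.3 * fs)
  keep <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (i - last >= refractory) {
      keep <- c(keep, i)
      last <- i
    } else if (env[[i]] > env[[keep[length(keep)]]]) {
      keep[length(keep)] <- i   # stronger peak inside refractory window
      last <- i
    }
  }
  # refine to the R apex on the band-passed signal
  half <- as.integer(round(0.05 * fs))
  refined <- vapply(keep, function(i) {
    lo <- max(1L, as.integer(i) - half)
    hi <- min(n, as.integer(i) + half)
    lo + which.max(abs(xb[lo:hi])) - 1L
  }, integer(1))
  sort(unique(refined)) - 1L
}

#' One-hot encode a label mask
#'
#' @param mask Integer label mask with values in `{0..4}`.
#' @param n_classes Number of classes (default 5).
#' @return A `length(mask) x n_classes` 0/1 matrix; row `i` indicates
#'   `mask[i]`.
#' @export
one_hot <- function(mask, n_classes = 5L) {
  mask <- validate_mask(mask, what = "one_hot")
  m <- matrix(0L, nrow = length(mask), ncol = n_classes)
  m[cbind(seq_along(mask), mask + 1L)] <- 1L
  m
}

#' Construct a fixed-length beat window
#'
#' @param samples Numeric vector of `window_len` voltages.
#' @param mask Integer label mask of the same length; class 4 (PAD) must
#'   occupy exactly the trailing run starting at `pad_start`.
#' @param pad_start 0-based index where padding begins (`window_len` if
#'   none).
#' @param source Optional `(record_id, start_index)` provenance.
#' @return An object of class `beat_window` with `samples`, `mask`,
#'   `onehot`, `pad_start`, `source`.
#' @export
beat_window <- function(samples, mask, pad_start = length(samples),
                        source = NULL) {
  n <- length(samples)
  mask <- validate_mask(mask, n, what = "beat_window")
  pad_start <- as.integer(pad_start)
  is_pad <- mask == WAVE_CLASSES[["PAD"]]
  if (!identical(is_pad, seq_len(n) - 1L >= pad_start))
    stop("beat_window: PAD class must be exactly the samples at and after pad_start",
         call. = FALSE)
  structure(list(samples = as.numeric(samples), mask = mask,
                 onehot = one_hot(mask), pad_start = pad_start,
                 source = source),
            class = "beat_window")
}

#' @export
print.beat_window <- function(x, ...) {
  cat(sprintf("<beat_window> %d samples, pad at %d, classes: %s\n",
              length(x$samples), x$pad_start,
              paste(WAVE_CLASS_NAMES[sort(unique(x$mask)) + 1L],
                    collapse = "/")))
  invisible(x)
}

#' Cut a record into fixed-length labelled beat windows
#'
#' One window per anchor.  In `p_onset` mode each anchor is a window
#' start (a beat's P onset); in `rpeak_offset` mode each anchor is an
#' R-peak and the window starts `pre_r` seconds earlier (clipped to the
#' record start).  Window content past `stops[i]` (a beat's end, when
#' known) or past the record end is filled with amplitude 0 and class 4
#' (PAD).  Consecutive windows may overlap.  When `mask` is `NULL`
#' (inference), in-data samples are provisionally labelled class 3.
#'
#' @param record An [ecg_record()] already at `config$target_fs`.
#' @param mask Integer label mask for the whole record, or `NULL`.
#' @param anchors 0-based anchor sample indices.
#' @param config A [segmentation_config()].
#' @param stops Optional 0-based half-open end index per anchor (content
#'   from there on is padded); defaults to `anchor + post_r * fs` in
#'   `rpeak_offset` mode and to the record end in `p_onset` mode.
#' @return List of [beat_window()] objects.
#' @export
segment_beats <- function(record, mask = NULL, anchors,
                          config = segmentation_config(), stops = NULL) {
  stopifnot(inherits(record, "ecg_record"),
            inherits(config, "segmentation_config"))
  if (abs(record$fs - config$target_fs) > 1e-9)
    stop(sprintf(
      "segment_beats: record is at %g Hz; resample to target_fs %g first",
      record$fs, config$target_fs), call. = FALSE)
  n <- length(record$samples)
  if (!is.null(mask)) mask <- validate_mask(mask, n, "segment_beats")
  anchors <- as.integer(anchors)
  bad <- which(anchors < 0L | anchors >= n)
  if (length(bad))
    stop(sprintf("segment_beats: anchor %d out of bounds [0, %d)",
                 anchors[[bad[[1L]]]], n), call. = FALSE)
  if (!is.null(stops)) {
    stops <- as.integer(stops)
    stopifnot(length(stops) == length(anchors))
  } else if (config$anchor == "rpeak_offset") {
    # the beat runs post_r seconds past the R-peak; beyond that is PAD
    stops <- anchors + as.integer(round(config$post_r * record$fs))
  }
  W <- config$window_len
  fs <- record$fs
  lapply(seq_along(anchors), function(i) {
    start <- if (config$anchor == "p_onset") anchors[[i]] else
      max(0L, anchors[[i]] - as.integer(round(config$pre_r * fs)))
    stop_i <- min(n, if (is.null(stops)) n else stops[[i]])
    avail <- max(0L, min(W, stop_i - start))
    idx <- if (avail > 0L) start + seq_len(avail) else integer(0)
    samples <- c(record$samples[idx], numeric(W - avail))
    win_mask <- c(
      if (is.null(mask)) rep(WAVE_CLASSES[["NOWAVE"]], avail) else
        mask[idx],
      rep(WAVE_CLASSES[["PAD"]], W - avail))
    beat_window(samples, win_mask, pad_start = avail,
                source = list(record_id = record$record_id,
                              start = start))
  })
}
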