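# Medical-knowledge AF screening stage: RR intervals and instantaneous
# heart rate, ventricular-response banding, rhythm-regularity assessment
# over short sliding windows, P-wave presence from predicted masks, and
# the four-rule AF / NSR decision with PPV / NPV scoring.

#' RR-interval series from R-peak positions
#'
#' `rr_ms[i] = (rpeaks[i+1] - rpeaks[i]) / fs * 1000`, instantaneous
#' rate `bpm = 60000 / rr_ms`.
#'
#' @param rpeaks Strictly increasing 0-based R-peak sample indices
#'   (at least 2).
#' @param fs Sampling frequency in Hz.
#' @return An object of class `rr_series`: list with `rpeaks`, `fs`,
#'   `rr_ms`, `bpm`.
#' @export
rr_intervals <- function(rpeaks, fs) {
  rpeaks <- as.numeric(rpeaks)
  if (length(rpeaks) < 2L)
    stop("rr_intervals: need at least two R-peaks", call. = FALSE)
  if (any(diff(rpeaks) <= 0))
    stop("rr_intervals: rpeaks must be strictly increasing", call. = FALSE)
  if (!is.numeric(fs) || fs <= 0)
    stop("rr_intervals: fs must be positive", call. = FALSE)
  rr_ms <- diff(rpeaks) / fs * 1000
  structure(list(rpeaks = rpeaks, fs = fs, rr_ms = rr_ms,
                 bpm = 60000 / rr_ms),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %d intervals, mean RR %.0f ms (%.0f BPM)\n",
              length(x$rr_ms), mean(x$rr_ms), mean(x$bpm)))
  invisible(x)
}

#' Ventricular response band of a heart rate
#'
#' `normal` for 60-100 BPM (boundaries included), `slow` below 60,
#' `rapid` above 100.
#'
#' @param bpm Heart rate(s) in beats per minute (positive).
#' @return Character vector in `{"slow", "normal", "rapid"}`.
#' @export
classify_response <- function(bpm) {
  if (any(!is.finite(bpm)) || any(bpm <= 0))
    stop("classify_response: bpm must be positive", call. = FALSE)
  ifelse(bpm < 60, "slow", ifelse(bpm > 100, "rapid", "normal"))
}

#' Rhythm regularity over sliding beat windows
#'
#' A window of `window_beats` consecutive RR intervals is "patterned"
#' iff every interval lies within `rel_tol` of the window median and
#' all the intervals fall in the same ventricular-response band.  The
#' record is regular iff at least half of the windows are patterned.
#'
#' @param rr An [rr_intervals()] series with at least `window_beats`
#'   intervals.
#' @param window_beats Sliding window length in intervals (5-7;
#'   default 6).
#' @param rel_tol Relative tolerance around the window median
#'   (default 0.10).
#' @return List with `regular` (flag), `trace` (data frame: one row per
#'   window with its start, median RR, max relative deviation, response
#'   agreement and verdict) and `fraction_patterned`.
#' @export
assess_regularity <- function(rr, window_beats = 6L, rel_tol = 0.10) {
  stopifnot(inherits(rr, "rr_series"))
  if (window_beats < 5L || window_beats > 7L)
    stop("assess_regularity: window_beats must be in [5, 7]", call. = FALSE)
  n <- length(rr$rr_ms)
  if (n < window_beats) {
    cond <- simpleError(sprintf(
      "assess_regularity: %d RR intervals < window of %d (insufficient data)",
      n, window_beats))
    class(cond) <- c("insufficient_data_error", class(cond))
    stop(cond)
  }
  starts <- seq_len(n - window_beats + 1L)
  trace <- do.call(rbind, lapply(starts, function(s) {
    w <- rr$rr_ms[s:(s + window_beats - 1L)]
    med <- median(w)
    dev <- max(abs(w - med)) / med
    bands <- classify_response(60000 / w)
    agree <- length(unique(bands)) == 1L
    data.frame(start = s - 1L, median_rr_ms = med, max_rel_dev = dev,
               bands_agree = agree,
               patterned = dev <= rel_tol && agree)
  }))
  frac <- mean(trace$patterned)
  list(regular = frac >= 0.5, trace = trace, fraction_patterned = frac)
}

#' P-wave presence from per-beat predicted masks
#'
#' A beat carries a P-wave iff its longest class-0 run lasts at least
#' `min_dur` seconds (the lower edge of the 0.06-0.08 s P-duration
#' band); the record is P-positive iff the fraction of P-bearing beats
#' reaches `beat_fraction`.
#'
#' @param masks List of integer label masks, one per beat window.
#' @param fs Sampling frequency in Hz.
#' @param min_dur Minimum credible P duration in seconds.
#' @param beat_fraction Fraction of P-bearing beats required.
#' @return List with `p_present` (flag), `trace` (data frame: per beat
#'   the longest P run in samples/seconds and the verdict) and
#'   `fraction_with_p`.
#' @export
detect_p_presence <- function(masks, fs, min_dur = 0.06,
                              beat_fraction = 0.5) {
  if (!is.list(masks) || length(masks) == 0L)
    stop("detect_p_presence: need at least one beat mask", call. = FALSE)
  trace <- do.call(rbind, lapply(seq_along(masks), function(i) {
    runs <- intervals_from_mask(masks[[i]])
    p_runs <- runs[runs$class == WAVE_CLASSES[["P"]], , drop = FALSE]
    longest <- if (nrow(p_runs)) max(p_runs$end - p_runs$start) else 0L
    data.frame(beat = i, longest_p_samples = longest,
               longest_p_s = longest / fs,
               has_p = longest / fs >= min_dur)
  }))
  frac <- mean(trace$has_p)
  list(p_present = frac >= beat_fraction, trace = trace,
       fraction_with_p = frac)
}

#' The four-rule AF / NSR decision
#'
#' The decision table: a regular rhythm is NSR and an irregular rhythm
#' is AF, whatever the P-wave finding (P-presence is recorded as
#' evidence but never overturns the rhythm verdict).
#'
#' @param p_present Is a P-wave present in the record?
#' @param regular Is the rhythm regular?
#' @return List with `decision` (`"AF"` or `"NSR"`) and `rule` (the
#'   fired rule as text).
#' @export
identify_af <- function(p_present, regular) {
  stopifnot(is.logical(p_present), is.logical(regular),
            length(p_present) == 1L, length(regular) == 1L,
            !is.na(p_present), !is.na(regular))
  rule <- if (p_present && regular)
    "P present + regular rhythm -> normal"
  else if (!p_present && regular)
    "P absent + regular rhythm -> normal"
  else if (p_present && !regular)
    "P present + irregular rhythm -> AF"
  else
    "P absent + irregular rhythm -> AF"
  list(decision = if (regular) "NSR" else "AF", rule = rule)
}

#' Screen one ECG record for atrial fibrillation
#'
#' Full pipeline: wavelet denoising, resampling to 250 Hz, R-peak
#' detection, R-peak-anchored segmentation (0.2 s before to 0.45 s
#' after each peak), per-sample delineation by the model, P-wave
#' presence from the predicted masks, RR intervals from the detected
#' peaks, regularity assessment, and the four-rule decision.
#' Deterministic given the model and record.  Records with fewer than
#' `min_beats` detected beats yield an abstention, not a decision.
#'
#' @param record An [ecg_record()].
#' @param model A trained `delineator_model`.
#' @param denoise A [denoise_config()] or `NULL` to skip denoising.
#' @param seg A [segmentation_config()] (rpeak_offset anchor).
#' @param window_beats,rel_tol Regularity parameters, see
#'   [assess_regularity()].
#' @param min_dur,beat_fraction P-presence parameters, see
#'   [detect_p_presence()].
#' @param min_beats Minimum detected beats required for a decision.
#' @return An object of class `af_assessment`: list with `decision`
#'   (`"AF"`, `"NSR"`, or `NA` on abstention), `abstained`, `reason`,
#'   `rr`, `regularity`, `p_presence`, `rule`, `rpeaks`,
#'   `response_pattern`.
#' @export
screen_record <- function(record, model,
                          denoise = denoise_config(),
                          seg = segmentation_config(anchor = "rpeak_offset"),
                          window_beats = 6L, rel_tol = 0.10,
                          min_dur = 0.06, beat_fraction = 0.5,
                          min_beats = 8L) {
  stopifnot(inherits(record, "ecg_record"),
            inherits(model, "delineator_model"))
  if (!is.null(denoise)) record <- dwt_denoise(record, denoise)
  record <- resample_record(record, seg$target_fs)
  rpeaks <- detect_rpeaks(record)
  abstain <- function(reason)
    structure(list(decision = NA_character_, abstained = TRUE,
                   reason = reason, rpeaks = rpeaks),
              class = "af_assessment")
  if (length(rpeaks) < min_beats)
    return(abstain(sprintf("only %d beats detected (need %d)",
                           length(rpeaks), min_beats)))
  windows <- segment_beats(record, mask = NULL, anchors = rpeaks,
                           config = seg)
  pred <- predict(model, windows)
  masks <- lapply(seq_len(ncol(pred$predicted)),
                  function(i) as.integer(pred$predicted[, i]))
  pp <- detect_p_presence(masks, record$fs, min_dur = min_dur,
                          beat_fraction = beat_fraction)
  rr <- rr_intervals(rpeaks, record$fs)
  reg <- tryCatch(assess_regularity(rr, window_beats, rel_tol),
                  insufficient_data_error = function(e) NULL)
  if (is.null(reg))
    return(abstain("too few RR intervals for a regularity window"))
  dec <- identify_af(pp$p_present, reg$regular)
  structure(list(decision = dec$decision, abstained = FALSE,
                 reason = NULL, rule = dec$rule, rr = rr,
                 regularity = reg, p_presence = pp, rpeaks = rpeaks,
                 response_pattern = classify_response(rr$bpm)),
            class = "af_assessment")
}

#' @export
print.af_assessment <- function(x, ...) {
  if (isTRUE(x$abstained)) {
    cat(sprintf("<af_assessment> abstained: %s\n", x$reason))
  } else {
    cat(sprintf(
      "<af_assessment> %s  (%s)\n  %d beats, mean %.0f BPM, %.0f%% windows patterned, %.0f%% beats with P\n",
      x$decision, x$rule, length(x$rpeaks), mean(x$rr$bpm),
      100 * x$regularity$fraction_patterned,
      100 * x$p_presence$fraction_with_p))
  }
  invisible(x)
}

#' PPV / NPV of AF screening decisions
#'
#' AF is the positive class.  `ppv = TP/(TP+FP)`, `npv = TN/(TN+FN)`,
#' plus the F1 of the positive class; zero-denominator ratios are `NA`.
#'
#' @param decisions,truth Character vectors in `{"AF", "NSR"}` of equal
#'   nonzero length.
#' @return List with `ppv`, `npv`, `f1`, and `counts` (tp, fp, tn, fn).
#' @export
ppv_npv <- function(decisions, truth) {
  if (length(decisions) != length(truth) || length(truth) == 0L)
    stop("ppv_npv: decisions and truth must be equal-length, non-empty",
         call. = FALSE)
  ok <- c("AF", "NSR")
  if (!all(decisions %in% ok) || !all(truth %in% ok))
    stop("ppv_npv: labels must be 'AF' or 'NSR'", call. = FALSE)
  tp <- sum(decisions == "AF" & truth == "AF")
  fp <- sum(decisions == "AF" & truth == "NSR")
  tn <- sum(decisions == "NSR" & truth == "NSR")
  fn <- sum(decisions == "NSR" & truth == "AF")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  ppv <- ratio(tp, tp + fp)
  sens <- ratio(tp, tp + fn)
  f1 <- if (is.na(ppv) || is.na(sens) || ppv + sens == 0) NA_real_ else
    2 * ppv * sens / (ppv + sens)
  list(ppv = ppv, npv = ratio(tn, tn + fn), f1 = f1,
       counts = c(tp = tp, fp = fp, tn = tn, fn = fn))
}
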