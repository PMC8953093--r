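# Labelled synthetic single-lead ECG generator.
#
# Waves are rendered as smooth parametric bumps (raised cosines; a
# triphasic Q-R-S spike) so that every class boundary is known exactly
# and parameter recovery by the delineator is checkable.  Real ECG
# morphology (notched P, biphasic T, ST shifts ...) is deliberately not
# emulated.

#' Beat template: durations and amplitudes of one P-QRS-T complex
#'
#' All durations in seconds, amplitudes in millivolts.  `pr_gap` is the
#' isoelectric gap between P offset and QRS onset; `st_gap` between QRS
#' offset and T onset.  The default P duration (0.08 s) sits in the
#' 0.06-0.08 s band that the AF screening stage uses as its P-presence
#' criterion.
#'
#' @param p_duration,p_amplitude P-wave duration / peak amplitude.
#' @param pr_gap Isoelectric gap after the P-wave.
#' @param qrs_duration,r_amplitude QRS duration / R peak amplitude.
#' @param st_gap Isoelectric gap after the QRS.
#' @param t_duration,t_amplitude T-wave duration / peak amplitude.
#' @return An object of class `beat_template`.
#' @export
beat_template <- function(p_duration = 0.08, p_amplitude = 0.15,
                          pr_gap = 0.05, qrs_duration = 0.10,
                          r_amplitude = 1.0, st_gap = 0.10,
                          t_duration = 0.16, t_amplitude = 0.30) {
  tpl <- list(p_duration = p_duration, p_amplitude = p_amplitude,
              pr_gap = pr_gap, qrs_duration = qrs_duration,
              r_amplitude = r_amplitude, st_gap = st_gap,
              t_duration = t_duration, t_amplitude = t_amplitude)
  durs <- c(p_duration, pr_gap, qrs_duration, st_gap, t_duration)
  if (any(!is.finite(unlist(tpl))))
    stop("beat_template: all fields must be finite", call. = FALSE)
  if (any(durs <= 0))
    stop("beat_template: all durations and gaps must be positive",
         call. = FALSE)
  structure(tpl, class = "beat_template")
}

beat_core_duration <- function(template) {
  template$p_duration + template$pr_gap + template$qrs_duration +
    template$st_gap + template$t_duration
}

# raised-cosine bump of n samples scaled so its grid maximum is `amp`
raised_cosine <- function(n, amp) {
  if (n <= 0L) return(numeric(0))
  u <- (seq_len(n) - 0.5) / n
  y <- 0.5 * (1 - cos(2 * pi * u))
  y / max(y) * amp
}

# triphasic QRS: small Q dip, dominant R, small S dip; R grid max == amp
qrs_shape <- function(n, amp) {
  if (n <= 0L) return(numeric(0))
  nq <- max(1L, round(0.25 * n))
  ns <- max(1L, round(0.25 * n))
  nr <- n - nq - ns
  if (nr < 1L) { nr <- 1L; nq <- max(1L, n - 2L); ns <- n - nq - nr }
  y <- c(raised_cosine(nq, -0.20 * abs(amp)),
         raised_cosine(nr, 1),
         raised_cosine(ns, -0.30 * abs(amp)))
  r <- which.max(y)
  y[y > 0] <- y[y > 0] / y[[r]] * amp
  y
}

#' Render one labelled heartbeat
#'
#' Renders the P / QRS / T bumps of one beat at sampling frequency `fs`
#' and returns the voltage trace together with its per-sample label mask.
#' The mask runs match the rendered wave intervals exactly; samples in
#' the gaps are class 3 (isoelectric).  With `include_p = FALSE` the
#' P interval is rendered flat and labelled class 3.
#'
#' @param template A [beat_template()].
#' @param fs Sampling frequency in Hz (>= 100).
#' @param include_p Render the P-wave?
#' @param total_len Optional total length in samples; the core beat is
#'   followed by isoelectric (class 3) zeros up to this length.
#' @return List with `samples`, `mask`, and `r_index` (0-based index of
#'   the R apex within the beat).
#' @export
generate_beat <- function(template, fs, include_p = TRUE,
                          total_len = NULL) {
  stopifnot(inherits(template, "beat_template"))
  if (!is.numeric(fs) || fs < 100)
    stop("generate_beat: fs must be >= 100 Hz", call. = FALSE)
  np <- round(template$p_duration * fs)
  ng1 <- round(template$pr_gap * fs)
  nq <- round(template$qrs_duration * fs)
  ng2 <- round(template$st_gap * fs)
  nt <- round(template$t_duration * fs)
  if (min(np, ng1, nq, ng2, nt) < 1L)
    stop("generate_beat: a duration rounds to zero samples at this fs",
         call. = FALSE)
  p <- if (include_p) raised_cosine(np, template$p_amplitude) else
    numeric(np)
  q <- qrs_shape(nq, template$r_amplitude)
  tw <- raised_cosine(nt, template$t_amplitude)
  samples <- c(p, numeric(ng1), q, numeric(ng2), tw)
  mask <- c(rep(if (include_p) WAVE_CLASSES[["P"]] else
    WAVE_CLASSES[["NOWAVE"]], np),
    rep(WAVE_CLASSES[["NOWAVE"]], ng1),
    rep(WAVE_CLASSES[["QRS"]], nq),
    rep(WAVE_CLASSES[["NOWAVE"]], ng2),
    rep(WAVE_CLASSES[["T"]], nt))
  r_index <- np + ng1 + which.max(q) - 1L
  if (!is.null(total_len)) {
    total_len <- as.integer(total_len)
    if (total_len < length(samples))
      stop("generate_beat: total_len shorter than the rendered beat",
           call. = FALSE)
    pad <- total_len - length(samples)
    samples <- c(samples, numeric(pad))
    mask <- c(mask, rep(WAVE_CLASSES[["NOWAVE"]], pad))
  }
  list(samples = samples, mask = as.integer(mask), r_index = r_index)
}

#' Rhythm specification for the synthetic generator
#'
#' Defaults encode the two study conditions: normal sinus rhythm (`NSR`)
#' with a near-constant RR series (`rr_cv = 0.02`) and a P-wave on every
#' beat, and an AF-like rhythm (`AF`) with an irregularly irregular RR
#' series (`rr_cv = 0.30`), no P-waves, and an optional low-amplitude
#' 7 Hz fibrillatory oscillation added to the baseline (labelled
#' isoelectric, not as a new class).
#'
#' @param kind `"NSR"` or `"AF"`.
#' @param mean_rr Mean RR interval in seconds (BPM = 60 / `mean_rr`).
#' @param rr_cv Coefficient of variation of the RR intervals.
#' @param p_present_prob Per-beat probability that the P-wave is drawn.
#' @param fs Sampling frequency in Hz.
#' @param n_beats Number of beats.
#' @param noise_sd Additive Gaussian noise SD in mV.
#' @param baseline_amp,baseline_freq Baseline-wander sinusoid (mV, Hz).
#' @param f_wave_amp Fibrillatory 7 Hz oscillation amplitude in mV.
#' @param seed Integer seed; identical seeds give identical records.
#' @return An object of class `rhythm_spec`.
#' @export
rhythm_spec <- function(kind = c("NSR", "AF"),
                        mean_rr = if (kind == "AF") 0.6 else 0.8,
                        rr_cv = if (kind == "AF") 0.30 else 0.02,
                        p_present_prob = if (kind == "AF") 0 else 1,
                        fs = 250, n_beats = 30, noise_sd = 0.02,
                        baseline_amp = 0.05, baseline_freq = 0.25,
                        f_wave_amp = if (kind == "AF") 0.02 else 0,
                        seed = 1L) {
  kind <- match.arg(kind)
  if (mean_rr <= 0 || rr_cv < 0 || fs < 100 || n_beats < 1 ||
      noise_sd < 0 || p_present_prob < 0 || p_present_prob > 1)
    stop("rhythm_spec: invalid field value", call. = FALSE)
  structure(list(kind = kind, mean_rr = mean_rr, rr_cv = rr_cv,
                 p_present_prob = p_present_prob, fs = fs,
                 n_beats = as.integer(n_beats), noise_sd = noise_sd,
                 baseline_amp = baseline_amp,
                 baseline_freq = baseline_freq,
                 f_wave_amp = f_wave_amp, seed = as.integer(seed)),
            class = "rhythm_spec")
}

# evaluate fn with a private RNG stream; caller's RNG state untouched
with_private_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Generate a labelled synthetic ECG record
#'
#' Draws an RR series (i.i.d. truncated normal with mean `mean_rr` and
#' SD `rr_cv * mean_rr`, truncated below at the larger of 0.3 s and the
#' template's rendered beat duration so beats never overlap),
#' concatenates rendered beats, then adds the baseline-wander sinusoid,
#' the fibrillatory oscillation, and Gaussian noise to the samples only
#' -- the label mask and true R-peak list are noise-free ground truth.
#'
#' @param spec A [rhythm_spec()].
#' @param template A [beat_template()].
#' @return List of class `synth_ecg` with elements `record`
#'   ([ecg_record()]), `mask` (integer label mask), `rpeaks` (0-based
#'   true R apex indices), `beat_starts`, `beat_ends` (0-based half-open
#'   beat spans including each beat's isoelectric tail), `rr_s` (the
#'   drawn RR values in seconds) and `p_drawn` (logical per beat).
#' @export
generate_record <- function(spec, template = beat_template()) {
  stopifnot(inherits(spec, "rhythm_spec"), inherits(template, "beat_template"))
  core_s <- beat_core_duration(template)
  if (spec$mean_rr <= core_s)
    stop(sprintf(
      "generate_record: template beat (%.2f s) does not fit mean RR (%.2f s)",
      core_s, spec$mean_rr), call. = FALSE)
  fs <- spec$fs
  rr_floor <- max(0.3, core_s + 2 / fs)
  with_private_seed(spec$seed, function() {
    rr <- rnorm(spec$n_beats, spec$mean_rr, spec$rr_cv * spec$mean_rr)
    rr <- pmax(rr, rr_floor)
    p_drawn <- runif(spec$n_beats) < spec$p_present_prob
    lead_in <- round(0.1 * fs)
    starts <- lead_in + c(0, cumsum(round(rr[-length(rr)] * fs)))
    core_n <- length(generate_beat(template, fs, TRUE)$samples)
    n_total <- starts[[length(starts)]] + core_n + round(0.2 * fs)
    samples <- numeric(n_total)
    mask <- rep(WAVE_CLASSES[["NOWAVE"]], n_total)
    rpeaks <- integer(spec$n_beats)
    for (i in seq_len(spec$n_beats)) {
      b <- generate_beat(template, fs, include_p = p_drawn[[i]])
      idx <- starts[[i]] + seq_along(b$samples)  # starts are 0-based
      samples[idx] <- b$samples
      mask[idx] <- b$mask
      rpeaks[[i]] <- starts[[i]] + b$r_index
    }
    ends <- c(starts[-1L], n_total)
    t <- (seq_len(n_total) - 1L) / fs
    noisy <- samples +
      spec$baseline_amp * sin(2 * pi * spec$baseline_freq * t) +
      spec$f_wave_amp * sin(2 * pi * 7 * t) +
      rnorm(n_total, 0, spec$noise_sd)
    structure(
      list(record = ecg_record(noisy, fs,
                               record_id = sprintf("synth_%s_%d",
                                                   spec$kind, spec$seed)),
           clean = samples,
           mask = as.integer(mask), rpeaks = rpeaks,
           beat_starts = as.integer(starts), beat_ends = as.integer(ends),
           rr_s = rr, p_drawn = p_drawn, spec = spec, template = template),
      class = "synth_ecg")
  })
}

#' @export
print.synth_ecg <- function(x, ...) {
  cat(sprintf("<synth_ecg> %s, %d beats, %d samples @ %g Hz, rr_cv %.2f\n",
              x$spec$kind, length(x$rpeaks), length(x$record$samples),
              x$record$fs, x$spec$rr_cv))
  invisible(x)
}
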