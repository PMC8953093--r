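# Multilevel discrete wavelet denoising: soft thresholding of per-level
# detail coefficients under the universal-threshold rule, plus baseline
# wander removal by zeroing the deepest approximation band.
#
# The DWT uses symmetric signal extension and the decimated pyramid
# convention of the common reference implementations (coefficient length
# floor((n + L - 1) / 2) per level); filter banks are the published
# orthogonal sym8 / db4 coefficients.

.wavelet_banks <- list(
  sym8 = list(dec_lo = c(
    -0.0033824159510061256, -0.00054213233179114812, 0.031695087811492981,
    0.0076074873249176054, -0.14329423835080971, -0.061273359067658524,
    0.48135965125837221, 0.77718575170052351, 0.3644418948353314,
    -0.051945838107709037, -0.027219029917056003, 0.049137179673607506,
    0.0038087520138906151, -0.014952258337048231, -0.0003029205147213668,
    0.0018899503327594609)),
  db4 = list(dec_lo = c(
    -0.010597401785069032, 0.032883011666885197, 0.030841381835560764,
    -0.18703481171909309, -0.027983769416859854, 0.63088076792985892,
    0.71484657055291567, 0.23037781330889651))
)

wavelet_filters <- function(wavelet) {
  bank <- .wavelet_banks[[wavelet]]
  if (is.null(bank))
    stop(sprintf("unknown wavelet '%s' (available: %s)", wavelet,
                 paste(names(.wavelet_banks), collapse = ", ")),
         call. = FALSE)
  lo <- bank$dec_lo
  L <- length(lo)
  # orthogonal QMF relations
  hi <- rev(lo) * (-1)^(seq_len(L))
  list(dec_lo = lo, dec_hi = hi, rec_lo = rev(lo), rec_hi = rev(hi),
       length = L)
}

conv_full <- function(x, h) {
  n <- length(x)
  m <- length(h)
  y <- numeric(n + m - 1L)
  for (j in seq_len(m)) {
    idx <- j:(j + n - 1L)
    y[idx] <- y[idx] + h[[j]] * x
  }
  y
}

# one analysis step with symmetric extension; returns approximation and
# detail coefficients of length floor((n + L - 1) / 2)
dwt_step <- function(x, flt) {
  n <- length(x)
  L <- flt$length
  e <- L - 1L
  if (n < e)
    stop("dwt_step: signal shorter than the filter support", call. = FALSE)
  ext <- c(rev(x[seq_len(e)]), x, rev(x[(n - e + 1L):n]))
  o <- (n + L - 1L) %/% 2L
  pick <- seq(L + 1L, by = 2L, length.out = o)
  list(ca = conv_full(ext, flt$dec_lo)[pick],
       cd = conv_full(ext, flt$dec_hi)[pick])
}

idwt_step <- function(ca, cd, n, flt) {
  L <- flt$length
  up <- function(cc) {
    z <- numeric(2L * length(cc))
    z[seq(1L, by = 2L, length.out = length(cc))] <- cc
    z
  }
  y <- conv_full(up(ca), flt$rec_lo) + conv_full(up(cd), flt$rec_hi)
  y[seq(L - 1L, length.out = n)]
}

# multilevel analysis: list(ca = deepest approximation, cd = list of
# detail vectors deepest-first, lengths = input length per level)
wavedec <- function(x, wavelet, levels) {
  flt <- wavelet_filters(wavelet)
  details <- vector("list", levels)
  lengths <- integer(levels)
  cur <- x
  for (lev in seq_len(levels)) {
    lengths[[lev]] <- length(cur)
    s <- dwt_step(cur, flt)
    details[[lev]] <- s$cd
    cur <- s$ca
  }
  list(ca = cur, cd = rev(details), lengths = rev(lengths),
       wavelet = wavelet, levels = levels)
}

waverec <- function(dec) {
  flt <- wavelet_filters(dec$wavelet)
  cur <- dec$ca
  for (lev in seq_len(dec$levels))
    cur <- idwt_step(cur, dec$cd[[lev]], dec$lengths[[lev]], flt)
  cur
}

max_dwt_level <- function(n, wavelet) {
  L <- wavelet_filters(wavelet)$length
  max(0L, as.integer(floor(log2(n / (L - 1)))))
}

#' Soft thresholding operator
#'
#' Shrinkage `sign(x) * max(|x| - t, 0)` applied elementwise.
#'
#' @param x Numeric vector.
#' @param t Nonnegative threshold.
#' @return Shrunken vector of the same length.
#' @export
soft_threshold <- function(x, t) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("soft_threshold: 't' must be a single nonnegative number",
         call. = FALSE)
  sign(x) * pmax(abs(x) - t, 0)
}

#' Universal threshold of a detail-coefficient band
#'
#' Returns `sigma * sqrt(2 * log(N))` with `N = length(coeffs)` and the
#' robust noise scale `sigma = median(|coeffs - median(coeffs)|) / 0.6745`.
#'
#' @param coeffs Non-empty numeric vector of detail coefficients.
#' @return A single nonnegative threshold.
#' @export
universal_threshold <- function(coeffs) {
  if (length(coeffs) == 0L)
    stop("universal_threshold: 'coeffs' must be non-empty", call. = FALSE)
  sigma <- median(abs(coeffs - median(coeffs))) / 0.6745
  sigma * sqrt(2 * log(length(coeffs)))
}

#' Denoising configuration
#'
#' @param wavelet Wavelet family: `"sym8"` (default; its symmetric,
#'   QRS-like shape limits morphology distortion) or `"db4"`.
#' @param levels Decomposition depth (default 8; at 250 Hz the level-8
#'   approximation holds content below about 0.5 Hz).
#' @param remove_baseline Zero the deepest approximation band before
#'   reconstruction (removes baseline wander)?
#' @return An object of class `denoise_config`.
#' @export
denoise_config <- function(wavelet = "sym8", levels = 8L,
                           remove_baseline = TRUE) {
  wavelet_filters(wavelet)
  if (!is.numeric(levels) || levels < 1L)
    stop("denoise_config: 'levels' must be >= 1", call. = FALSE)
  structure(list(wavelet = wavelet, levels = as.integer(levels),
                 threshold_rule = "universal", mode = "soft",
                 remove_baseline = isTRUE(remove_baseline)),
            class = "denoise_config")
}

#' Wavelet denoising of an ECG record
#'
#' Decomposes the signal to `config$levels` levels (reduced, with a
#' warning, to the deepest level the record length supports), soft
#' thresholds every detail band under the universal rule
#' `t = sigma * sqrt(2 * log(N_band))`, with the noise scale `sigma`
#' estimated once from the finest detail band (the only band where the
#' median absolute deviation reflects noise rather than wave energy;
#' at coarser levels every coefficient overlaps P/QRS/T content, so a
#' per-band scale would shrink the waves themselves), zeroes the
#' deepest approximation if `remove_baseline`, and reconstructs.
#' Output length, sampling frequency and metadata are unchanged.  The
#' whole operation is deterministic.  Symmetric border extension is
#' used, so samples within one filter length of the edges are smoothed
#' against their mirror image.
#'
#' @param record An [ecg_record()].
#' @param config A [denoise_config()].
#' @return The denoised [ecg_record()].
#' @export
dwt_denoise <- function(record, config = denoise_config()) {
  stopifnot(inherits(record, "ecg_record"), inherits(config, "denoise_config"))
  x <- record$samples
  feasible <- max_dwt_level(length(x), config$wavelet)
  levels <- config$levels
  if (feasible < 1L)
    stop("dwt_denoise: record too short for one decomposition level",
         call. = FALSE)
  if (levels > feasible) {
    warning(sprintf(
      "dwt_denoise: reducing levels from %d to %d for a %d-sample record",
      levels, feasible, length(x)))
    levels <- feasible
  }
  dec <- wavedec(x, config$wavelet, levels)
  finest <- dec$cd[[levels]]            # cd is stored deepest-first
  sigma <- median(abs(finest - median(finest))) / 0.6745
  dec$cd <- lapply(dec$cd, function(cd)
    soft_threshold(cd, sigma * sqrt(2 * log(length(cd)))))
  if (config$remove_baseline) dec$ca <- numeric(length(dec$ca))
  y <- waverec(dec)
  ecg_record(y, record$fs, lead = record$lead, record_id = record$record_id)
}
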