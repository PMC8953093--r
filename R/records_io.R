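# Core signal / annotation data model and format input-output.
#
# An ecg_record is a uniformly sampled single-lead voltage trace in
# millivolts with a sampling frequency in Hz.  A label mask is a plain
# integer vector over the classes in WAVE_CLASSES, one value per sample,
# with maximal runs indexed 0-based and half-open [start, end).

#' Construct a single-lead ECG record
#'
#' @param samples Numeric vector of voltages in millivolts; must be
#'   non-empty and finite.
#' @param fs Sampling frequency in Hz; must be positive.
#' @param lead Free-text lead name, e.g. `"II"`.
#' @param record_id Opaque identifier for the record.
#' @return An object of class `ecg_record`: a list with elements
#'   `samples`, `fs`, `lead`, `record_id`.
#' @examples
#' rec <- ecg_record(sin(seq(0, 2 * pi, length.out = 250)), fs = 250)
#' rec
#' @export
ecg_record <- function(samples, fs, lead = "II", record_id = "rec") {
  samples <- as.numeric(samples)
  if (length(samples) == 0L)
    stop("ecg_record: 'samples' must be non-empty", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("ecg_record: all samples must be finite", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("ecg_record: 'fs' must be a single positive number", call. = FALSE)
  structure(
    list(samples = samples, fs = as.numeric(fs),
         lead = as.character(lead), record_id = as.character(record_id)),
    class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record '%s'> lead %s, %d samples @ %g Hz (%.2f s)\n",
              x$record_id, x$lead, length(x$samples), x$fs,
              length(x$samples) / x$fs))
  invisible(x)
}

#' @export
length.ecg_record <- function(x) length(x$samples)

validate_mask <- function(classes, n_samples = NULL, what = "mask") {
  classes <- as.integer(classes)
  if (anyNA(classes) || any(classes < 0L | classes > 4L))
    stop(sprintf("%s: class values must lie in {0,1,2,3,4}", what),
         call. = FALSE)
  if (!is.null(n_samples) && length(classes) != n_samples)
    stop(sprintf("%s: length %d does not match expected %d",
                 what, length(classes), n_samples), call. = FALSE)
  classes
}

#' Read a single-lead ECG record from disk
#'
#' Two formats are supported.  `"csv"` is a plain-text dialect: a header
#' line `# fs=<Hz>`, then `index,amplitude_mV` rows.  `"wfdb"` is a
#' minimal WFDB subset: a `.hea` header naming one format-16 signal and a
#' little-endian 16-bit `.dat` file; the ADC gain and baseline from the
#' header are applied so samples come back in millivolts.
#'
#' @param path For CSV, the file path.  For WFDB, the record path without
#'   extension (or the `.hea` path).
#' @param format `"csv"` or `"wfdb"`.
#' @return An [ecg_record()].
#' @seealso [write_record()]
#' @export
read_record <- function(path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  if (format == "csv") read_record_csv(path) else read_record_wfdb(path)
}

read_record_csv <- function(path) {
  if (!file.exists(path))
    stop(sprintf("read_record: file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L)
    stop("read_record: CSV record needs a header line and data rows",
         call. = FALSE)
  hdr <- lines[[1L]]
  m <- regmatches(hdr, regexec("^#\\s*fs=([0-9.eE+-]+)", hdr))[[1L]]
  if (length(m) != 2L)
    stop(sprintf("read_record: malformed header line 1: '%s' (expected '# fs=<Hz>')",
                 hdr), call. = FALSE)
  fs <- suppressWarnings(as.numeric(m[[2L]]))
  if (is.na(fs))
    stop("read_record: non-numeric fs in header", call. = FALSE)
  if (fs <= 0)
    stop(sprintf("read_record: fs must be positive, got %g", fs),
         call. = FALSE)
  lead <- "II"
  ml <- regmatches(hdr, regexec("lead=([^, ]+)", hdr))[[1L]]
  if (length(ml) == 2L) lead <- ml[[2L]]
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != 2L)
  if (length(bad))
    stop(sprintf("read_record: malformed row at line %d: '%s'",
                 bad[[1L]] + 1L, body[[bad[[1L]]]]), call. = FALSE)
  amp <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(amp)) {
    i <- which(is.na(amp))[[1L]]
    stop(sprintf("read_record: non-numeric amplitude at line %d: '%s'",
                 i + 1L, body[[i]]), call. = FALSE)
  }
  ecg_record(amp, fs, lead = lead,
             record_id = sub("\\.[^.]*$", "", basename(path)))
}

#' Write a single-lead ECG record to disk
#'
#' Inverse of [read_record()].  WFDB output uses signal format 16 with a
#' configurable ADC gain (default 200 adu/mV), so the round trip is exact
#' up to the 1/gain quantization step.
#'
#' @param record An [ecg_record()].
#' @param path Output path (CSV) or record path without extension (WFDB).
#' @param format `"csv"` or `"wfdb"`.
#' @param gain ADC gain in adu/mV for WFDB output.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path, format = c("csv", "wfdb"),
                         gain = 200) {
  format <- match.arg(format)
  stopifnot(inherits(record, "ecg_record"))
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# fs=%.10g,lead=%s", record$fs, record$lead), con)
    writeLines(sprintf("%d,%.10g", seq_along(record$samples) - 1L,
                       record$samples), con)
  } else {
    write_record_wfdb(record, path, gain = gain)
  }
  invisible(path)
}

# --- minimal WFDB format-16 subset ------------------------------------

wfdb_paths <- function(path) {
  base <- sub("\\.hea$", "", path)
  list(base = base, hea = paste0(base, ".hea"), dat = paste0(base, ".dat"))
}

write_record_wfdb <- function(record, path, gain = 200) {
  p <- wfdb_paths(path)
  name <- basename(p$base)
  adc <- as.integer(round(record$samples * gain))
  if (any(adc > 32767L | adc < -32768L))
    stop("write_record: amplitude exceeds 16-bit range at this gain",
         call. = FALSE)
  hea <- c(
    sprintf("%s 1 %.10g %d", name, record$fs, length(adc)),
    sprintf("%s.dat 16 %.10g(0)/mV 16 0 %d 0 0 %s",
            name, gain, adc[[1L]], record$lead))
  writeLines(hea, p$hea)
  con <- file(p$dat, "wb")
  on.exit(close(con))
  writeBin(adc, con, size = 2L, endian = "little")
  invisible(p$base)
}

read_record_wfdb <- function(path) {
  p <- wfdb_paths(path)
  if (!file.exists(p$hea))
    stop(sprintf("read_record: file not found: %s", p$hea), call. = FALSE)
  hea <- readLines(p$hea, warn = FALSE)
  hea <- hea[!grepl("^#", hea)]
  top <- strsplit(trimws(hea[[1L]]), "\\s+")[[1L]]
  if (length(top) < 3L)
    stop("read_record: malformed WFDB header record line", call. = FALSE)
  fs <- suppressWarnings(as.numeric(top[[3L]]))
  n <- if (length(top) >= 4L) as.integer(top[[4L]]) else NA_integer_
  if (is.na(fs))
    stop("read_record: non-numeric fs in WFDB header", call. = FALSE)
  if (fs <= 0)
    stop(sprintf("read_record: fs must be positive, got %g", fs),
         call. = FALSE)
  sig <- strsplit(trimws(hea[[2L]]), "\\s+")[[1L]]
  if (length(sig) < 3L || sig[[2L]] != "16")
    stop("read_record: only single-signal WFDB format 16 is supported",
         call. = FALSE)
  gm <- regmatches(sig[[3L]],
                   regexec("^([0-9.eE+-]+)(\\(([0-9+-]+)\\))?(/mV)?$",
                           sig[[3L]]))[[1L]]
  if (length(gm) == 0L)
    stop(sprintf("read_record: malformed gain field '%s'", sig[[3L]]),
         call. = FALSE)
  gain <- as.numeric(gm[[2L]])
  baseline <- if (nzchar(gm[[4L]])) as.numeric(gm[[4L]]) else 0
  if (is.na(gain) || gain <= 0) gain <- 200
  lead <- if (length(sig) >= 9L) sig[[length(sig)]] else "II"
  con <- file(p$dat, "rb")
  on.exit(close(con))
  size <- file.info(p$dat)$size
  adc <- readBin(con, "integer", n = size %/% 2L, size = 2L,
                 signed = TRUE, endian = "little")
  if (!is.na(n) && n > 0L) {
    if (length(adc) < n)
      stop("read_record: WFDB .dat shorter than header sample count",
           call. = FALSE)
    adc <- adc[seq_len(n)]
  }
  ecg_record((adc - baseline) / gain, fs, lead = lead,
             record_id = basename(p$base))
}

# --- label masks -------------------------------------------------------

#' Convert wave interval annotations to a per-sample label mask
#'
#' Intervals are 0-based, half-open `[start, end)`.  Samples not claimed
#' by any interval become class 3 (isoelectric / no wave).  Overlapping
#' wave intervals are an error: delineation ground truth must partition
#' the record.
#'
#' @param intervals Data frame with columns `class`, `start`, `end`
#'   (may have zero rows).
#' @param n_samples Mask length.
#' @return Integer vector of length `n_samples` with values in `{0..4}`.
#' @export
mask_from_intervals <- function(intervals, n_samples) {
  mask <- rep(WAVE_CLASSES[["NOWAVE"]], n_samples)
  if (is.null(intervals) || nrow(intervals) == 0L) return(mask)
  cls <- validate_mask(intervals$class, what = "mask_from_intervals")
  for (i in seq_len(nrow(intervals))) {
    s <- as.integer(intervals$start[[i]])
    e <- as.integer(intervals$end[[i]])
    if (s < 0L || e > n_samples || s >= e)
      stop(sprintf("mask_from_intervals: bad interval [%d,%d) for n=%d",
                   s, e, n_samples), call. = FALSE)
    idx <- (s + 1L):e
    taken <- which(mask[idx] != WAVE_CLASSES[["NOWAVE"]])
    if (length(taken))
      stop(sprintf(
        "mask_from_intervals: overlapping wave intervals at sample %d",
        s + taken[[1L]] - 1L), call. = FALSE)
    mask[idx] <- cls[[i]]
  }
  mask
}

#' Maximal class runs of a label mask
#'
#' @param mask Integer label mask.
#' @return Data frame with columns `class`, `start`, `end` (0-based,
#'   half-open), one row per maximal run, in order.
#' @export
intervals_from_mask <- function(mask) {
  mask <- validate_mask(mask, what = "intervals_from_mask")
  r <- rle(mask)
  end <- cumsum(r$lengths)
  data.frame(class = r$values, start = end - r$lengths, end = end)
}

#' Read a per-sample label mask
#'
#' Two encodings: `"per_sample"` — one class integer per line;
#' `"intervals"` — a CSV with header `class,start,end` of half-open
#' 0-based wave intervals, converted via [mask_from_intervals()] (samples
#' outside any interval become class 3).
#'
#' @param path File path.
#' @param n_samples Expected mask length.
#' @param format `"per_sample"` or `"intervals"`.
#' @return Integer label mask of length `n_samples`.
#' @export
read_mask <- function(path, n_samples, format = c("per_sample", "intervals")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(sprintf("read_mask: file not found: %s", path), call. = FALSE)
  if (format == "per_sample") {
    vals <- suppressWarnings(as.integer(readLines(path, warn = FALSE)))
    if (anyNA(vals))
      stop("read_mask: non-integer class value", call. = FALSE)
    validate_mask(vals, n_samples, what = "read_mask")
  } else {
    iv <- read.csv(path, stringsAsFactors = FALSE)
    mask_from_intervals(iv, n_samples)
  }
}

#' Write a per-sample label mask (one class integer per line)
#' @param mask Integer label mask.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  mask <- validate_mask(mask, what = "write_mask")
  writeLines(as.character(mask), path)
  invisible(path)
}

#' Resample an ECG record to a new sampling frequency
#'
#' Fourier-method resampling: the spectrum is zero-padded (upsampling) or
#' truncated at the new Nyquist frequency (downsampling), which is
#' inherently anti-aliased for band-limited content.  Output length is
#' `round(n * target_fs / fs)`.
#'
#' @param record An [ecg_record()].
#' @param target_fs Target sampling frequency in Hz.
#' @return A resampled [ecg_record()] with `fs = target_fs`.
#' @export
resample_record <- function(record, target_fs) {
  stopifnot(inherits(record, "ecg_record"))
  if (!is.numeric(target_fs) || length(target_fs) != 1L ||
      !is.finite(target_fs) || target_fs <= 0)
    stop("resample_record: 'target_fs' must be a single positive number",
         call. = FALSE)
  if (isTRUE(all.equal(target_fs, record$fs))) return(record)
  x <- record$samples
  n <- length(x)
  m <- as.integer(round(n * target_fs / record$fs))
  if (m < 1L)
    stop("resample_record: target length would be zero", call. = FALSE)
  y <- fft_resample(x, m)
  ecg_record(y, target_fs, lead = record$lead, record_id = record$record_id)
}

# FFT-domain length change n -> m; unit gain at retained frequencies
# (unnormalized inverse transform divided by the input length n).
fft_resample <- function(x, m) {
  n <- length(x)
  if (m == n) return(x)
  X <- fft(x)
  Y <- complex(m)
  k <- min(n, m)
  npos <- (k + 1L) %/% 2L            # DC + retained positive frequencies
  nneg <- (k - 1L) %/% 2L            # retained negative frequencies
  Y[seq_len(npos)] <- X[seq_len(npos)]
  if (nneg > 0L)
    Y[(m - nneg + 1L):m] <- X[(n - nneg + 1L):n]
  if (m < n && m %% 2L == 0L) {
    # new Nyquist bin must be real for a real output
    Y[[m %/% 2L + 1L]] <- Re(X[[m %/% 2L + 1L]])
  } else if (m > n && n %% 2L == 0L) {
    # split the old Nyquist bin across +/- n/2
    nyq <- X[[n %/% 2L + 1L]]
    Y[[n %/% 2L + 1L]] <- nyq / 2
    Y[[m - n %/% 2L + 1L]] <- Conj(nyq) / 2
  }
  Re(fft(Y, inverse = TRUE)) / n
}
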