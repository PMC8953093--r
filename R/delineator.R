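# The per-sample CNN--Bi-LSTM waveform classifier: model construction,
# training (Adam, categorical cross-entropy), prediction, and
# conversion of predicted masks to fiducial points.
#
# Canonical architecture for a (370, 1) input:
#   conv 3x1/stride 1 ReLU stack 8 -> 16 -> 32 -> 64 filters (length kept),
#   bidirectional LSTM with 512 units per direction (output width 1024),
#   per-timestep affine map to 5 classes with softmax.

#' Build an (untrained) delineator model
#'
#' With the canonical arguments the per-layer output widths are
#' 8, 16, 32, 64 (convolutions), 1024 (Bi-LSTM, 512 per direction) and
#' `n_classes`; every layer preserves the window length.  An empty
#' `conv_filters` yields the Bi-LSTM-only baseline variant.
#'
#' @param conv_filters Integer vector of filters per convolutional layer
#'   (may be empty).
#' @param units_per_direction LSTM units in each direction.
#' @param n_classes Output classes (>= 2).
#' @param window_len Expected input length in samples.
#' @param seed Seed for the weight initialization (fan-in-scaled random
#'   init; recorded in the model).
#' @return An object of class `delineator_model`.
#' @export
build_model <- function(conv_filters = c(8L, 16L, 32L, 64L),
                        units_per_direction = 512L, n_classes = 5L,
                        window_len = 370L, seed = 1L) {
  conv_filters <- as.integer(conv_filters)
  if (any(conv_filters <= 0L))
    stop("build_model: conv filter counts must be positive", call. = FALSE)
  if (units_per_direction < 1L)
    stop("build_model: units_per_direction must be positive", call. = FALSE)
  if (n_classes < 2L)
    stop("build_model: n_classes must be >= 2", call. = FALSE)
  H <- as.integer(units_per_direction)
  K <- as.integer(n_classes)
  params <- with_private_seed(seed, function() {
    chans <- c(1L, conv_filters)
    conv_W <- list()
    conv_b <- list()
    for (l in seq_along(conv_filters)) {
      fan_in <- 3L * chans[[l]]
      conv_W[[l]] <- matrix(rnorm(conv_filters[[l]] * fan_in,
                                  sd = sqrt(2 / fan_in)),
                            nrow = conv_filters[[l]])
      conv_b[[l]] <- matrix(0, nrow = conv_filters[[l]], ncol = 1)
    }
    C <- if (length(conv_filters)) conv_filters[[length(conv_filters)]] else 1L
    k <- 1 / sqrt(H)
    lstm_dir <- function() {
      b <- matrix(0, 4L * H, 1L)
      b[(H + 1L):(2L * H), 1L] <- 1  # forget-gate bias starts open
      list(Wx = matrix(runif(4L * H * C, -k, k), nrow = 4L * H),
           Wh = matrix(runif(4L * H * H, -k, k), nrow = 4L * H),
           b = b)
    }
    f <- lstm_dir()
    bck <- lstm_dir()
    lim <- sqrt(6 / (2 * H + K))
    list(conv_W = conv_W, conv_b = conv_b,
         Wx_f = f$Wx, Wh_f = f$Wh, b_f = f$b,
         Wx_b = bck$Wx, Wh_b = bck$Wh, b_b = bck$b,
         Wd = matrix(runif(K * 2L * H, -lim, lim), nrow = K),
         bd = matrix(0, K, 1L))
  })
  structure(list(conv_filters = conv_filters,
                 units_per_direction = H, n_classes = K,
                 window_len = as.integer(window_len), fitted_fs = 250,
                 init_seed = as.integer(seed), params = params,
                 trained = FALSE, history = NULL, validation = NULL),
            class = "delineator_model")
}

#' Per-layer output shapes of a delineator model
#'
#' @param model A `delineator_model`.
#' @return Data frame with columns `layer` and `width` (per-timestep
#'   feature width); the window length is preserved by every layer.
#' @export
layer_shapes <- function(model) {
  stopifnot(inherits(model, "delineator_model"))
  widths <- c(model$conv_filters, 2L * model$units_per_direction,
              model$n_classes)
  layers <- c(if (length(model$conv_filters))
    paste0("conv", seq_along(model$conv_filters)),
    "bilstm", "softmax")
  data.frame(layer = layers, width = widths)
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 1e-4, the rate used
#'   for full-scale training; reduced-scale runs typically raise it).
#' @param epochs Number of passes over the windows (default 300).
#' @param batch_size Minibatch size (default 32).
#' @param seed Seed controlling shuffling (and any re-initialization).
#' @param validation_fraction Fraction of windows held out for a final
#'   validation measurement (0 disables).
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 300L,
                         batch_size = 32L, seed = 1L,
                         validation_fraction = 0.1) {
  if (learning_rate <= 0) stop("train_config: learning_rate must be > 0",
                               call. = FALSE)
  if (epochs < 1L) stop("train_config: epochs must be >= 1", call. = FALSE)
  structure(list(optimizer = "adam", learning_rate = learning_rate,
                 loss = "categorical_crossentropy",
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed),
                 validation_fraction = validation_fraction),
            class = "train_config")
}

windows_to_matrices <- function(windows, window_len) {
  stopifnot(is.list(windows), length(windows) >= 1L)
  X <- matrix(0, nrow = window_len, ncol = length(windows))
  Y <- matrix(0L, nrow = window_len, ncol = length(windows))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    if (!inherits(w, "beat_window") || length(w$samples) != window_len)
      stop(sprintf("window %d does not match the model window length %d",
                   i, window_len), call. = FALSE)
    X[, i] <- w$samples
    Y[, i] <- w$mask
  }
  list(X = X, Y = Y)
}

#' Train the delineator on labelled beat windows
#'
#' Minimizes per-node categorical cross-entropy (PAD nodes included in
#' the target, per the five-class labelling) with Adam.  With a fixed
#' seed, fixed windows and fixed hardware the run is reproducible.
#'
#' @param model A `delineator_model` from [build_model()].
#' @param windows List of [beat_window()] objects (>= 2).
#' @param config A [train_config()].
#' @return The trained `delineator_model`; `$history` holds per-epoch
#'   training `loss` and `accuracy`, `$validation` the held-out
#'   per-node accuracy if `validation_fraction > 0`.
#' @export
train_delineator <- function(model, windows, config = train_config()) {
  stopifnot(inherits(model, "delineator_model"),
            inherits(config, "train_config"))
  if (length(windows) < 2L)
    stop("train_delineator: need at least two windows", call. = FALSE)
  mats <- windows_to_matrices(windows, model$window_len)
  n <- ncol(mats$X)
  split <- with_private_seed(config$seed, function() {
    perm <- sample.int(n)
    n_val <- floor(config$validation_fraction * n)
    train_idx <- perm[seq_len(n - n_val)]
    val_idx <- if (n_val > 0L) perm[(n - n_val + 1L):n] else integer(0)
    order <- vapply(seq_len(config$epochs),
                    function(e) sample(seq_along(train_idx)),
                    integer(length(train_idx)))
    list(train = train_idx, val = val_idx,
         order = matrix(order, ncol = config$epochs))
  })
  Xtr <- mats$X[, split$train, drop = FALSE]
  Ytr <- mats$Y[, split$train, drop = FALSE]
  fit <- cpp_nn_train(model$params, Xtr, Ytr, split$order - 1L,
                      config$batch_size, config$learning_rate,
                      0.9, 0.999, 1e-8)
  model$params <- fit$params
  model$trained <- TRUE
  model$history <- data.frame(epoch = seq_len(config$epochs),
                              loss = fit$loss, accuracy = fit$accuracy)
  model$train_config <- config
  if (length(split$val)) {
    pv <- predict_mask_matrix(model, mats$X[, split$val, drop = FALSE])
    model$validation <- list(
      n_windows = length(split$val),
      accuracy = mean(pv == mats$Y[, split$val, drop = FALSE]))
  }
  model
}

# probability array (window_len x n_classes x n_windows) for an X matrix
predict_prob_matrix <- function(model, X) {
  arr <- cpp_nn_forward(model$params, X)   # dim (K, N, T)
  aperm(arr, c(3L, 1L, 2L))                # (T, K, N)
}

predict_mask_matrix <- function(model, X) {
  probs <- predict_prob_matrix(model, X)
  apply(probs, 3L, function(p) max.col(p, ties.method = "first") - 1L)
}

#' Predict per-sample waveform classes for beat windows
#'
#' Each output row is a softmax distribution over the five classes; the
#' predicted class is the row argmax with ties broken towards the
#' lowest class index.
#'
#' @param object A `delineator_model`.
#' @param newdata A [beat_window()], a list of them, or a numeric matrix
#'   (`window_len` rows, one column per window).
#' @param type `"class"` for label masks, `"prob"` to also return the
#'   probability array.
#' @param allow_untrained Permit prediction from an untrained model
#'   (random weights); off by default.
#' @param ... Unused.
#' @return For one window: a list with `predicted` (integer mask) and,
#'   for `type = "prob"`, `probabilities` (`window_len x n_classes`).
#'   For several windows the same with a list / array batched over
#'   windows.
#' @export
predict.delineator_model <- function(object, newdata,
                                     type = c("class", "prob"),
                                     allow_untrained = FALSE, ...) {
  type <- match.arg(type)
  if (!object$trained && !allow_untrained)
    stop("model is untrained; pass allow_untrained = TRUE to override",
         call. = FALSE)
  single <- inherits(newdata, "beat_window")
  if (single) newdata <- list(newdata)
  if (is.list(newdata))
    newdata <- windows_to_matrices(newdata, object$window_len)$X
  if (nrow(newdata) != object$window_len)
    stop(sprintf("predict: windows have %d samples, model expects %d",
                 nrow(newdata), object$window_len), call. = FALSE)
  probs <- predict_prob_matrix(object, newdata)
  masks <- apply(probs, 3L, function(p) max.col(p, ties.method = "first") - 1L)
  if (single) {
    out <- list(predicted = as.integer(masks[, 1L]))
    if (type == "prob") out$probabilities <- probs[, , 1L]
  } else {
    out <- list(predicted = masks)
    if (type == "prob") out$probabilities <- probs
  }
  out
}

#' @export
print.delineator_model <- function(x, ...) {
  cat(sprintf(
    "<delineator_model> conv [%s] -> Bi-LSTM %dx2 -> %d classes (%s)\n",
    paste(x$conv_filters, collapse = ","), x$units_per_direction,
    x$n_classes, if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' @export
summary.delineator_model <- function(object, ...) {
  sh <- layer_shapes(object)
  cat("Per-sample ECG waveform classifier\n")
  cat(sprintf("  input: (%d, 1) @ %g Hz\n", object$window_len,
              object$fitted_fs))
  for (i in seq_len(nrow(sh)))
    cat(sprintf("  %-8s (%d, %d)\n", sh$layer[[i]], object$window_len,
                sh$width[[i]]))
  np <- sum(vapply(unlist(object$params, recursive = FALSE),
                   length, 1L))
  cat(sprintf("  parameters: %d (%s)\n", np,
              if (object$trained) "trained" else "untrained"))
  if (!is.null(object$history))
    cat(sprintf("  final training loss %.4f, accuracy %.4f over %d epochs\n",
                tail(object$history$loss, 1L),
                tail(object$history$accuracy, 1L),
                nrow(object$history)))
  if (!is.null(object$validation))
    cat(sprintf("  held-out per-node accuracy %.4f (%d windows)\n",
                object$validation$accuracy, object$validation$n_windows))
  invisible(object)
}

#' @export
coef.delineator_model <- function(object, ...) object$params

#' @export
plot.delineator_model <- function(x, ...) {
  if (is.null(x$history))
    stop("no training history to plot", call. = FALSE)
  graphics::plot(x$history$epoch, x$history$loss, type = "l",
                 xlab = "epoch", ylab = "cross-entropy loss",
                 main = "Training history", ...)
  invisible(x)
}

#' Fiducial points from a label mask
#'
#' One row per maximal run of the wave classes P/QRS/T; runs shorter
#' than `min_dur` seconds are discarded as spurious.  The peak index is
#' the position of the largest absolute amplitude in the run (the R-peak
#' for QRS runs).
#'
#' @param mask Integer label mask.
#' @param samples Voltages aligned with `mask`.
#' @param fs Sampling frequency in Hz.
#' @param min_dur Minimum credible wave duration in seconds.
#' @return Data frame with columns `wave`, `onset`, `offset` (0-based,
#'   half-open), `duration_s`, `peak_index`; zero rows if no wave runs.
#' @export
fiducials_from_mask <- function(mask, samples, fs, min_dur = 0.02) {
  stopifnot(fs > 0, length(mask) == length(samples))
  runs <- intervals_from_mask(mask)
  runs <- runs[runs$class %in% 0:2, , drop = FALSE]
  runs <- runs[(runs$end - runs$start) / fs >= min_dur, , drop = FALSE]
  if (nrow(runs) == 0L)
    return(data.frame(wave = character(0), onset = integer(0),
                      offset = integer(0), duration_s = numeric(0),
                      peak_index = integer(0)))
  peak <- vapply(seq_len(nrow(runs)), function(i) {
    idx <- (runs$start[[i]] + 1L):runs$end[[i]]
    runs$start[[i]] + which.max(abs(samples[idx])) - 1L
  }, integer(1))
  data.frame(wave = WAVE_CLASS_NAMES[runs$class + 1L],
             onset = runs$start, offset = runs$end,
             duration_s = (runs$end - runs$start) / fs,
             peak_index = peak, row.names = NULL)
}

#' Generate labelled training windows from the synthetic generator
#'
#' Draws records with per-record jittered beat templates and rhythm
#' parameters (durations and amplitudes uniform over physiological
#' bands; three quarters of records carry P-waves) and cuts
#' fixed-length windows in both anchoring modes — half the records at
#' the true P onsets (training convention), half anchored 0.2 s before
#' the true R-peaks (deployment convention) — so the trained model sees
#' waves at the offsets it will meet when screening.  With
#' `denoise = TRUE` each record is first wavelet-denoised exactly as
#' [screen_record()] denoises its input; the default is raw windows,
#' because denoising smears wave onsets and makes sample-exact
#' boundaries unrecoverable (it shifts amplitudes too -- see the
#' methods vignette for the trade-off).
#'
#' @param n_windows Number of windows to produce.
#' @param seed Integer seed.
#' @param fs Sampling frequency (default 250 Hz).
#' @param window_len Window length (default 370).
#' @param p_record_frac Fraction of records whose beats carry P-waves.
#' @param noise_sd Additive noise SD in mV.
#' @param denoise Apply the default wavelet denoising to each record
#'   before cutting windows (matches [screen_record()])?
#' @return List with `windows` (list of [beat_window()]) and `meta`
#'   (data frame: one row per window with the record id, anchoring
#'   mode, template P/QRS/T durations in seconds and P presence).
#' @export
synth_training_windows <- function(n_windows, seed = 1L, fs = 250,
                                   window_len = 370L,
                                   p_record_frac = 0.75,
                                   noise_sd = 0.02, denoise = FALSE) {
  draws <- with_private_seed(seed, function() {
    n_rec <- ceiling(n_windows / 10) + 2L
    lapply(seq_len(n_rec), function(i) {
      list(tpl = beat_template(
             p_duration = runif(1, 0.06, 0.09),
             p_amplitude = runif(1, 0.10, 0.20),
             pr_gap = runif(1, 0.04, 0.06),
             qrs_duration = runif(1, 0.08, 0.12),
             r_amplitude = runif(1, 0.7, 1.3),
             st_gap = runif(1, 0.08, 0.12),
             t_duration = runif(1, 0.12, 0.20),
             t_amplitude = runif(1, 0.20, 0.40)),
           with_p = runif(1) < p_record_frac,
           anchor = if (i %% 2L) "p_onset" else "rpeak_offset",
           mean_rr = runif(1, 0.7, 1.0),
           seed = sample.int(.Machine$integer.max, 1L))
    })
  })
  windows <- list()
  meta <- list()
  for (d in draws) {
    if (length(windows) >= n_windows) break
    spec <- rhythm_spec("NSR", mean_rr = d$mean_rr, rr_cv = 0.02,
                        p_present_prob = as.numeric(d$with_p), fs = fs,
                        n_beats = 10L, noise_sd = noise_sd, seed = d$seed)
    g <- generate_record(spec, d$tpl)
    rec <- g$record
    if (denoise) {
      levels <- min(8L, max_dwt_level(length(rec$samples), "sym8"))
      rec <- dwt_denoise(rec, denoise_config(levels = levels))
    }
    cfg <- segmentation_config(window_len = window_len, anchor = d$anchor,
                               target_fs = fs)
    w <- if (d$anchor == "p_onset")
      segment_beats(rec, g$mask, anchors = g$beat_starts, config = cfg,
                    stops = g$beat_ends)
    else
      segment_beats(rec, g$mask, anchors = g$rpeaks, config = cfg)
    windows <- c(windows, w)
    meta <- c(meta, rep(list(data.frame(
      record_id = g$record$record_id, anchor = d$anchor,
      with_p = d$with_p,
      p_duration = d$tpl$p_duration, qrs_duration = d$tpl$qrs_duration,
      t_duration = d$tpl$t_duration)), length(w)))
  }
  windows <- windows[seq_len(n_windows)]
  meta <- do.call(rbind, meta)[seq_len(n_windows), , drop = FALSE]
  rownames(meta) <- NULL
  list(windows = windows, meta = meta)
}
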