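new_epoch_tensor <- function(data, fs, channel_names = NULL) {
  stop_if_not(is.matrix(data) && all(is.finite(data)), "epoch data must be a finite matrix")
  if (is.null(channel_names)) channel_names <- paste0("CH", seq_len(nrow(data)))
  structure(list(data = data, fs = fs, channel_names = channel_names),
            class = "epoch_tensor")
}

#' @export
print.epoch_tensor <- function(x, ...) {
  cat(sprintf("<epoch_tensor> %d ch x %d samples @ %g Hz\n",
              nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

#' Preprocessing configuration
#'
#' Bundles the standard EEG preprocessing recipe: band-pass edges, notch
#' frequency, target sampling rate, window length, channel order, and
#' augmentation settings. Defaults follow common clinical-EEG practice for
#' pretraining corpora (0.1-75 Hz band, 50 Hz notch, 200 Hz, 4 s windows); a
#' 1-40 Hz band is typical for pediatric seizure recordings.
#'
#' @param band Numeric `(low, high)` band-pass edges in Hz.
#' @param notch Notch frequency in Hz (NA disables).
#' @param target_fs Target sampling rate in Hz.
#' @param win_s Epoch window length in seconds.
#' @param channel_order Optional ordered channel-label vector.
#' @param p_reflect Probability of time reflection during augmentation.
#' @param scale_range Numeric `(lo, hi)` uniform scaling range.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(band = c(0.1, 75), notch = 50, target_fs = 200,
                              win_s = 4, channel_order = NULL,
                              p_reflect = 0.5, scale_range = c(0.8, 1.2)) {
  stop_if_not(band[1] >= 0 && band[1] < band[2], "band must satisfy 0 <= low < high")
  stop_if_not(band[2] < target_fs / 2, "band high edge must be below target Nyquist")
  stop_if_not(is.na(notch) || notch < target_fs / 2, "notch must be below target Nyquist")
  stop_if_not(win_s > 0, "win_s must be positive")
  structure(list(band = band, notch = notch, target_fs = target_fs,
                 win_s = win_s, channel_order = channel_order,
                 augment = list(p_reflect = p_reflect, scale_range = scale_range)),
            class = "preprocess_config")
}

#' Select and reorder channels by label
#'
#' @param rec A `raw_recording`.
#' @param channel_order Character vector of labels, all present in `rec`.
#' @return A `raw_recording` with rows in the requested order.
#' @export
select_channels <- function(rec, channel_order) {
  stop_if_not(inherits(rec, "raw_recording"), "rec must be a raw_recording")
  missing <- setdiff(channel_order, rec$channel_names)
  if (length(missing) > 0) {
    stop("channel label(s) not present: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  idx <- match(channel_order, rec$channel_names)
  new_raw_recording(rec$data[idx, , drop = FALSE], rec$fs, rec$channel_names[idx])
}

# RBJ-cookbook notch biquad (band-stop centred at f0, quality factor Q),
# returned as (b, a) coefficient vectors for signal::filtfilt.
notch_biquad <- function(f0, fs, Q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Zero-phase band-pass and notch filtering
#'
#' Applies a 4th-order Butterworth high-pass at `band[1]` (skipped when the
#' low edge is 0), a 4th-order Butterworth low-pass at `band[2]`, and a
#' Q = 30 notch at `notch`, each forward-backward (zero phase, length
#' preserved). The high/low passes are cascaded rather than combined into one
#' band-pass polynomial so very low edges (e.g. 0.1 Hz at 200 Hz) stay
#' numerically stable.
#'
#' @param rec A `raw_recording`.
#' @param band Numeric `(low, high)` in Hz, below Nyquist.
#' @param notch Notch frequency in Hz, below Nyquist; `NA` disables.
#' @return A filtered `raw_recording` of identical shape.
#' @export
bandpass_notch <- function(rec, band = c(0.1, 75), notch = 50) {
  stop_if_not(inherits(rec, "raw_recording"), "rec must be a raw_recording")
  nyq <- rec$fs / 2
  stop_if_not(band[1] < band[2], "band edges inverted")
  stop_if_not(band[2] < nyq, "band high edge must be below Nyquist")
  stop_if_not(is.na(notch) || notch < nyq, "notch must be below Nyquist")
  x <- rec$data
  apply_rows <- function(x, flt) {
    t(apply(x, 1, function(row) signal::filtfilt(flt, row)))
  }
  if (band[1] > 0) {
    # demean first: the high-pass removes DC in steady state, but
    # forward-backward edge transients leak it on finite windows
    x <- x - rowMeans(x)
    hp <- signal::butter(4, band[1] / nyq, type = "high")
    x <- apply_rows(x, hp)
  }
  lp <- signal::butter(4, band[2] / nyq, type = "low")
  x <- apply_rows(x, lp)
  if (!is.na(notch)) {
    nb <- notch_biquad(notch, rec$fs, Q = 30)
    flt <- signal::Arma(b = nb$b, a = nb$a)
    x <- apply_rows(x, flt)
  }
  new_raw_recording(x, rec$fs, rec$channel_names)
}

#' Polyphase resampling to a target sampling rate
#'
#' Rational-factor polyphase resampling with anti-aliasing; the output length
#' is exactly `round(n_in * target_fs / fs_in)`.
#'
#' @param rec A `raw_recording`.
#' @param target_fs Target rate in Hz.
#' @return A `raw_recording` at `target_fs`.
#' @export
resample_recording <- function(rec, target_fs) {
  stop_if_not(inherits(rec, "raw_recording"), "rec must be a raw_recording")
  stop_if_not(target_fs > 0, "target_fs must be positive")
  if (target_fs == rec$fs) return(rec)
  frac <- as.integer(attr(fractions_ratio(target_fs, rec$fs), "pq"))
  p <- frac[1]; q <- frac[2]
  n_out <- round(ncol(rec$data) * target_fs / rec$fs)
  out <- t(apply(rec$data, 1, function(row) {
    y <- signal::resample(row, p, q)
    if (length(y) >= n_out) y[seq_len(n_out)] else c(y, rep(y[length(y)], n_out - length(y)))
  }))
  new_raw_recording(out, target_fs, rec$channel_names)
}

# smallest integer ratio p/q with p/q == a/b (rates are rational in practice)
fractions_ratio <- function(a, b) {
  scale <- 1e6                      # handle non-integer rates to micro-Hz
  p <- round(a * scale); q <- round(b * scale)
  g <- gcd_int(p, q)
  structure(a / b, pq = c(p / g, q / g))
}

gcd_int <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

#' Cut a recording into fixed-length non-overlapping epochs
#'
#' Consecutive windows of `win_s` seconds; a trailing remainder shorter than
#' one window is dropped. A recording shorter than one window yields an empty
#' list.
#'
#' @param rec A `raw_recording`.
#' @param win_s Window length in seconds; `win_s * fs` must be integral.
#' @return List of `epoch_tensor` objects.
#' @export
epoch_recording <- function(rec, win_s) {
  stop_if_not(inherits(rec, "raw_recording"), "rec must be a raw_recording")
  w <- win_s * rec$fs
  stop_if_not(abs(w - round(w)) < 1e-9 && w >= 1, "win_s * fs must be integral")
  w <- as.integer(round(w))
  n_ep <- floor(ncol(rec$data) / w)
  lapply(seq_len(n_ep), function(i) {
    new_epoch_tensor(rec$data[, ((i - 1) * w + 1):(i * w), drop = FALSE],
                     rec$fs, rec$channel_names)
  })
}

#' Random reflection and scaling augmentation
#'
#' With probability `p_reflect` the epoch is time-reversed; the amplitude is
#' scaled by a uniform draw from `scale_range`. Seeded and reproducible.
#'
#' @param ep An `epoch_tensor`.
#' @param p_reflect Reflection probability in `[0, 1]`.
#' @param scale_range Numeric `(lo, hi)` with `0 < lo <= hi`.
#' @param seed Integer seed.
#' @return An augmented `epoch_tensor`.
#' @export
augment_epoch <- function(ep, p_reflect = 0.5, scale_range = c(0.8, 1.2),
                          seed = 1L) {
  stop_if_not(inherits(ep, "epoch_tensor"), "ep must be an epoch_tensor")
  stop_if_not(p_reflect >= 0 && p_reflect <= 1, "p_reflect must be in [0,1]")
  stop_if_not(scale_range[1] > 0 && scale_range[1] <= scale_range[2],
              "scale_range must satisfy 0 < lo <= hi")
  with_seed(seed, {
    reflect <- stats::runif(1) < p_reflect
    s <- stats::runif(1, scale_range[1], scale_range[2])
    x <- ep$data
    if (reflect) x <- x[, rev(seq_len(ncol(x))), drop = FALSE]
    new_epoch_tensor(s * x, ep$fs, ep$channel_names)
  })
}

#' Balance class sizes by subsampling the majority classes
#'
#' Subsamples every class down to `ratio` times the minority-class count
#' (ratio 1 gives a 1:1 balance), keeping epoch order stable. Seeded.
#'
#' @param set A `labeled_epoch_set`.
#' @param ratio Maximum majority:minority ratio (default 1).
#' @param seed Integer seed.
#' @return A balanced `labeled_epoch_set`.
#' @export
balance_classes <- function(set, ratio = 1, seed = 1L) {
  stop_if_not(inherits(set, "labeled_epoch_set"), "set must be a labeled_epoch_set")
  counts <- tabulate(set$labels, nbins = length(set$class_names))
  if (any(counts == 0)) {
    stop("class(es) with no epochs: ",
         paste(set$class_names[counts == 0], collapse = ", "), call. = FALSE)
  }
  target <- round(min(counts) * ratio)
  keep <- with_seed(seed, {
    unlist(lapply(seq_along(counts), function(k) {
      idx <- which(set$labels == k)
      if (length(idx) > target) sort(sample(idx, target)) else idx
    }))
  })
  keep <- sort(keep)
  new_labeled_epoch_set(set$epochs[keep], set$labels[keep], set$class_names)
}

#' Run the full preprocessing recipe on a recording
#'
#' Channel selection (if configured), band-pass + notch filtering, resampling
#' to the target rate, and epoching — in that order.
#'
#' @param rec A `raw_recording`.
#' @param cfg A [preprocess_config()].
#' @return List of `epoch_tensor` objects.
#' @export
run_preprocess <- function(rec, cfg) {
  stop_if_not(inherits(cfg, "preprocess_config"), "cfg must be a preprocess_config")
  if (!is.null(cfg$channel_order)) rec <- select_channels(rec, cfg$channel_order)
  rec <- bandpass_notch(rec, cfg$band, cfg$notch)
  rec <- resample_recording(rec, cfg$target_fs)
  epoch_recording(rec, cfg$win_s)
}
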