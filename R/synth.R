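#' Describe one spectral component of a synthetic EEG signal
#'
#' A component is a band-limited ingredient mixed into selected channels of a
#' generated recording: a pure sinusoid, band-limited Gaussian noise, or a
#' spike-wave burst train (the classic ~3 Hz absence-seizure surrogate).
#'
#' @param center_freq Center frequency in Hz (> 0).
#' @param bandwidth Bandwidth in Hz (ignored for `"sinusoid"`).
#' @param amplitude Component amplitude in microvolts (RMS for noise-like
#'   kinds, peak for sinusoids; >= 0).
#' @param channels Integer indices of the channels carrying the component.
#' @param kind One of `"sinusoid"`, `"band-limited-noise"`, `"spike-wave-burst"`.
#' @return A `component_spec` list.
#' @export
component_spec <- function(center_freq, bandwidth = 1, amplitude = 10,
                           channels = 1L,
                           kind = c("sinusoid", "band-limited-noise",
                                    "spike-wave-burst")) {
  kind <- match.arg(kind)
  stop_if_not(center_freq > 0, "center_freq must be > 0")
  stop_if_not(amplitude >= 0, "amplitude must be >= 0")
  stop_if_not(length(channels) >= 1, "channels must be non-empty")
  structure(list(center_freq = center_freq, bandwidth = bandwidth,
                 amplitude = amplitude, channels = as.integer(channels),
                 kind = kind),
            class = "component_spec")
}

new_raw_recording <- function(data, fs, channel_names = NULL) {
  stop_if_not(is.matrix(data) && nrow(data) >= 1, "data must be a matrix with >= 1 channel")
  stop_if_not(fs > 0, "fs must be > 0")
  stop_if_not(all(is.finite(data)), "data must be finite")
  if (is.null(channel_names)) channel_names <- paste0("CH", seq_len(nrow(data)))
  stop_if_not(length(channel_names) == nrow(data), "one name per channel")
  structure(list(data = data, fs = fs, channel_names = channel_names),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d ch x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

# 1/f^exponent background: shape a white spectrum by f^(-exponent/2) so power
# falls as 1/f^exponent; DC excluded. Output scaled to unit RMS then noise_amp.
pink_noise <- function(n, fs, exponent) {
  w <- stats::rnorm(n)
  if (exponent == 0) return(w)
  f <- c(1, seq_len(n - 1))          # avoid DC blow-up; bin 1 treated as bin 2
  freq <- pmin(f, n - f) * fs / n    # symmetric frequency magnitude
  freq[freq <= 0] <- fs / n
  shape <- freq^(-exponent / 2)
  x <- Re(stats::fft(stats::fft(w) * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

spike_wave_train <- function(tt, freq, phase) {
  # one sharp transient plus a slow half-wave per cycle, unit peak amplitude
  ph <- (tt * freq + phase) %% 1
  spike <- exp(-((ph - 0.15) / 0.03)^2)
  wave <- 0.6 * sin(pmin(pmax((ph - 0.25) / 0.6, 0), 1) * pi)
  spike + wave
}

band_limited_noise <- function(n, fs, lo, hi) {
  w <- stats::rnorm(n)
  fw <- stats::fft(w)
  k <- 0:(n - 1)
  freq <- pmin(k, n - k) * fs / n
  keep <- freq >= lo & freq <= hi
  fw[!keep] <- 0
  x <- Re(stats::fft(fw, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) x else x / s
}

#' Generate a multichannel synthetic EEG recording
#'
#' Mixes a 1/f^`noise_exponent` Gaussian background with the requested spectral
#' components. Fully deterministic for a fixed `seed`; the global RNG state is
#' left untouched.
#'
#' @param specs List of [component_spec()] objects (may be empty).
#' @param n_channels Number of channels.
#' @param duration_s Duration in seconds; `duration_s * fs` must be a positive
#'   integer.
#' @param fs Sampling rate in Hz.
#' @param noise_exponent Spectral exponent of the background (default 1, i.e.
#'   pink noise).
#' @param noise_amp Background RMS amplitude in microvolts (0 disables it).
#' @param seed Integer seed.
#' @return A `raw_recording` with a `(n_channels x duration_s*fs)` data matrix
#'   in microvolts.
#' @export
generate_recording <- function(specs, n_channels, duration_s, fs,
                               noise_exponent = 1, noise_amp = 5, seed = 1L) {
  stop_if_not(fs > 0, "fs must be positive")
  stop_if_not(duration_s > 0, "duration_s must be positive")
  n <- duration_s * fs
  stop_if_not(abs(n - round(n)) < 1e-9 && n >= 1,
              "duration_s * fs must be an integer >= 1")
  n <- as.integer(round(n))
  tt <- (seq_len(n) - 1) / fs
  with_seed(seed, {
    x <- matrix(0, n_channels, n)
    if (noise_amp > 0) {
      for (ch in seq_len(n_channels)) {
        x[ch, ] <- noise_amp * pink_noise(n, fs, noise_exponent)
      }
    }
    for (sp in specs) {
      stop_if_not(inherits(sp, "component_spec"), "specs must be component_spec objects")
      stop_if_not(all(sp$channels >= 1 & sp$channels <= n_channels),
                  "component channels out of range")
      phase <- stats::runif(1)
      comp <- switch(sp$kind,
        "sinusoid" = sin(2 * pi * sp$center_freq * tt + 2 * pi * phase),
        "band-limited-noise" = band_limited_noise(
          n, fs, sp$center_freq - sp$bandwidth / 2, sp$center_freq + sp$bandwidth / 2),
        "spike-wave-burst" = spike_wave_train(tt, sp$center_freq, phase)
      )
      for (ch in sp$channels) x[ch, ] <- x[ch, ] + sp$amplitude * comp
    }
    new_raw_recording(x, fs)
  })
}

#' Inject line interference and artifact bursts into a recording
#'
#' Adds a fixed-frequency power-line sinusoid to every channel and short
#' band-limited artifact bursts (Hann-windowed, e.g. 20-60 Hz muscle-like
#' activity) at a given event rate. Seeded and reproducible.
#'
#' @param rec A `raw_recording`.
#' @param line_freq Line frequency in Hz (must be below Nyquist).
#' @param line_amp Line amplitude in microvolts (0 disables).
#' @param burst_band Numeric `(lo, hi)` band of the bursts in Hz.
#' @param burst_rate Burst events per minute (0 disables).
#' @param burst_amp Burst RMS amplitude in microvolts.
#' @param burst_dur_s Burst duration in seconds.
#' @param seed Integer seed.
#' @return A `raw_recording` of identical shape.
#' @export
inject_artifacts <- function(rec, line_freq = 50, line_amp = 10,
                             burst_band = c(20, 60), burst_rate = 0,
                             burst_amp = 20, burst_dur_s = 0.5, seed = 1L) {
  stop_if_not(inherits(rec, "raw_recording"), "rec must be a raw_recording")
  nyq <- rec$fs / 2
  stop_if_not(line_freq < nyq, "line_freq must be below Nyquist")
  stop_if_not(burst_band[1] < burst_band[2] && burst_band[2] <= nyq,
              "burst_band must lie within (0, Nyquist]")
  x <- rec$data
  n <- ncol(x)
  tt <- (seq_len(n) - 1) / rec$fs
  with_seed(seed, {
    if (line_amp > 0) {
      line <- line_amp * sin(2 * pi * line_freq * tt)
      x <- sweep(x, 2, line, `+`)
    }
    if (burst_rate > 0) {
      n_events <- max(0L, stats::rpois(1, burst_rate * n / rec$fs / 60))
      blen <- max(2L, round(burst_dur_s * rec$fs))
      for (ev in seq_len(n_events)) {
        start <- sample.int(max(1L, n - blen + 1L), 1)
        ch <- sample.int(nrow(x), 1)
        env <- 0.5 * (1 - cos(2 * pi * seq_len(blen) / (blen + 1)))
        noise <- band_limited_noise(blen, rec$fs, burst_band[1], burst_band[2])
        idx <- start:(start + blen - 1L)
        x[ch, idx] <- x[ch, idx] + burst_amp * env * noise
      }
    }
    new_raw_recording(x, rec$fs, rec$channel_names)
  })
}

#' Component presets for a linearly separable two-class dataset
#'
#' Class `"spike_wave"` carries a dominant 3 Hz spike-wave train (seizure-like),
#' class `"alpha"` a dominant 10 Hz oscillation; the two dominant bands are
#' disjoint so a bandpower threshold separates the classes.
#'
#' @param n_channels Number of channels the specs address.
#' @return Named list of per-class `component_spec` lists.
#' @export
separable_class_specs <- function(n_channels = 4) {
  chans <- seq_len(n_channels)
  list(
    spike_wave = list(component_spec(3, amplitude = 40, channels = chans,
                                     kind = "spike-wave-burst")),
    alpha = list(component_spec(10, amplitude = 40, channels = chans,
                                kind = "sinusoid"))
  )
}

#' Generate a labeled epoch dataset
#'
#' Draws `n_per_class` fixed-length epochs for each class in `class_specs`,
#' each generated independently (fresh background noise and phases) with a
#' deterministic per-epoch seed derived from `seed`.
#'
#' @param n_per_class Epochs per class (>= 1).
#' @param class_specs Named list: one list of [component_spec()] per class.
#' @param fs Sampling rate in Hz.
#' @param win_s Epoch length in seconds.
#' @param n_channels Channels per epoch.
#' @param noise_amp Background RMS amplitude in microvolts.
#' @param seed Integer seed.
#' @return A `labeled_epoch_set`: list with `epochs` (list of `epoch_tensor`),
#'   integer `labels` in `1..n_classes`, and `class_names`.
#' @export
generate_labeled_dataset <- function(n_per_class, class_specs, fs = 64,
                                     win_s = 4, n_channels = 4, noise_amp = 5,
                                     seed = 1L) {
  stop_if_not(n_per_class >= 1, "n_per_class must be >= 1")
  stop_if_not(length(class_specs) >= 2, "need at least 2 classes")
  class_names <- names(class_specs)
  stop_if_not(!is.null(class_names) && all(nzchar(class_names)),
              "class_specs must be a named list")
  epochs <- list()
  labels <- integer(0)
  for (k in seq_along(class_specs)) {
    for (i in seq_len(n_per_class)) {
      ep_seed <- (as.integer(seed) + 7919L * k + 104729L * i) %% .Machine$integer.max
      rec <- generate_recording(class_specs[[k]], n_channels, win_s, fs,
                                noise_amp = noise_amp, seed = ep_seed)
      epochs[[length(epochs) + 1L]] <- new_epoch_tensor(rec$data, fs, rec$channel_names)
      labels <- c(labels, k)
    }
  }
  new_labeled_epoch_set(epochs, labels, class_names)
}

new_labeled_epoch_set <- function(epochs, labels, class_names) {
  stop_if_not(length(epochs) == length(labels), "one label per epoch")
  stop_if_not(all(labels >= 1 & labels <= length(class_names)),
              "labels out of declared class range")
  structure(list(epochs = epochs, labels = as.integer(labels),
                 class_names = class_names),
            class = "labeled_epoch_set")
}

#' @export
print.labeled_epoch_set <- function(x, ...) {
  cat(sprintf("<labeled_epoch_set> %d epochs, classes: %s\n",
              length(x$epochs),
              paste(sprintf("%s=%d", x$class_names,
                            tabulate(x$labels, length(x$class_names))),
                    collapse = ", ")))
  invisible(x)
}
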