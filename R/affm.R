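# Adaptive Frequency Filtering Module: FFT along the token axis, learnable
# global/local sigmoid gains per frequency bin, an energy-thresholded adaptive
# mask with learnable threshold, inverse FFT, and a learnable gated fusion with
# the input sequence.

#' Create a filter bank of learnable AFFM parameters
#'
#' Gains are parameterized on a fixed reference grid of `n_bins_ref`
#' non-negative-frequency bins spanning normalized frequency `[0, 0.5]`; at
#' forward time they are linearly interpolated to the actual bin count of the
#' sequence, so one bank serves sequences of any length. The local filter acts
#' only above `local_cutoff` of the Nyquist frequency (identity below); the
#' global filter spans all bins. `alpha` (the fusion gate) is stored as a raw
#' scalar mapped through a sigmoid so it stays in `(0, 1)`.
#'
#' @param n_bins_ref Number of reference frequency bins (default 33).
#' @param local_cutoff Fraction of Nyquist above which the local filter acts
#'   (default 0.5, i.e. the upper half of the spectrum).
#' @param theta_init Initial adaptive-mask threshold on the normalized-energy
#'   scale (default 0.5).
#' @param alpha_init Initial fusion weight in `(0, 1)` (default 0.5).
#' @param lambda Regularization coefficient on `theta^2` (default 1e-4).
#' @param epsilon Stabilizer added to the median power (default 1e-12).
#' @param temperature Soft-mask sigmoid temperature used in training
#'   (default 0.1).
#' @return A `filter_bank` list with fields `W_global`, `W_local`, `theta`,
#'   `alpha_raw` (learnable) and the fixed hyperparameters.
#' @export
filter_bank <- function(n_bins_ref = 33, local_cutoff = 0.5, theta_init = 0.5,
                        alpha_init = 0.5, lambda = 1e-4, epsilon = 1e-12,
                        temperature = 0.1) {
  stop_if_not(n_bins_ref >= 2, "need at least 2 reference bins")
  stop_if_not(alpha_init > 0 && alpha_init < 1, "alpha_init must be in (0,1)")
  stop_if_not(epsilon > 0, "epsilon must be positive")
  structure(list(
    W_global = numeric(n_bins_ref),
    W_local = numeric(n_bins_ref),
    theta = theta_init,
    alpha_raw = stats::qlogis(alpha_init),
    local_cutoff = local_cutoff,
    lambda = lambda,
    epsilon = epsilon,
    temperature = temperature
  ), class = "filter_bank")
}

# linear interpolation matrix from the reference bin grid to n_bins actual
# bins, both spanning normalized frequency [0, 0.5]
interp_matrix <- function(n_bins, n_ref) {
  if (n_bins == n_ref) return(diag(n_ref))
  pos <- seq(0, 1, length.out = n_bins) * (n_ref - 1) + 1
  lo <- pmin(floor(pos), n_ref - 1)
  w <- pos - lo
  R <- matrix(0, n_bins, n_ref)
  for (j in seq_len(n_bins)) {
    R[j, lo[j]] <- 1 - w[j]
    R[j, lo[j] + 1] <- w[j]
  }
  R
}

#' FFT of a real sequence with per-bin power
#'
#' @param x Finite real numeric vector.
#' @return A `spectrum_tensor`: full complex spectrum `F` (length `n`), power
#'   `P = |F|^2` over the `floor(n/2) + 1` non-negative-frequency bins, `n`,
#'   and `n_bins`.
#' @export
forward_fft <- function(x) {
  stop_if_not(is.numeric(x) && all(is.finite(x)), "input must be finite real")
  n <- length(x)
  stop_if_not(n >= 1, "empty input")
  F <- stats::fft(x)
  n_bins <- floor(n / 2) + 1
  structure(list(F = F, P = Mod(F[seq_len(n_bins)])^2, n = n, n_bins = n_bins),
            class = "spectrum_tensor")
}

#' Evaluate the global, local, and combined filter gains
#'
#' `G_global = sigmoid(W_global)` over all bins; `G_local = sigmoid(W_local)`
#' above the local cutoff and exactly 1 below; `G = G_global * G_local`, so
#' every gain lies in `(0, 1)`.
#'
#' @param bank A [filter_bank()].
#' @param n_bins Number of actual non-negative-frequency bins (defaults to the
#'   reference grid size).
#' @return List with `G_global`, `G_local`, `G` (each length `n_bins`).
#' @export
filter_gains <- function(bank, n_bins = length(bank$W_global)) {
  R <- interp_matrix(n_bins, length(bank$W_global))
  g_global <- sigmoid(as.numeric(R %*% bank$W_global))
  g_local <- sigmoid(as.numeric(R %*% bank$W_local))
  nu <- (seq_len(n_bins) - 1) / (2 * max(n_bins - 1, 1))  # in [0, 0.5]
  local_active <- nu >= bank$local_cutoff * 0.5
  g_local[!local_active] <- 1
  list(G_global = g_global, G_local = g_local, G = g_global * g_local,
       local_active = local_active, R = R)
}

#' Energy-thresholded adaptive frequency mask
#'
#' Normalizes the per-bin power by the median power (plus `epsilon`) and
#' compares against the threshold `theta`. Hard mode returns a 0/1 mask
#' (`normalized > theta`); soft mode returns
#' `sigmoid((normalized - theta) / temperature)`, the differentiable
#' relaxation used during training.
#'
#' @param spec A `spectrum_tensor` from [forward_fft()], or a raw numeric
#'   power vector.
#' @param theta Threshold on the normalized-energy scale.
#' @param epsilon Stabilizer added to the median (> 0).
#' @param temperature Soft-mask temperature.
#' @param mode `"hard"` or `"soft"`.
#' @return Numeric mask over the non-negative-frequency bins, values in
#'   `[0, 1]`.
#' @export
adaptive_mask <- function(spec, theta, epsilon = 1e-12, temperature = 0.1,
                          mode = c("hard", "soft")) {
  mode <- match.arg(mode)
  P <- if (inherits(spec, "spectrum_tensor")) spec$P else as.numeric(spec)
  stop_if_not(length(P) >= 1, "empty spectrum")
  stop_if_not(epsilon > 0, "epsilon must be positive")
  r <- P / (stats::median(P) + epsilon)
  if (mode == "hard") as.numeric(r > theta) else sigmoid((r - theta) / temperature)
}

#' Apply mask and gains to a spectrum
#'
#' `F_hat[k] = F[k] * mask[k] * G[k]` elementwise. `mask` and `G` are given on
#' the non-negative-frequency bins and mirrored onto the conjugate-symmetric
#' negative-frequency bins, so the filtered signal stays real.
#'
#' @param spec A `spectrum_tensor`.
#' @param mask Mask over `spec$n_bins` bins, values in `[0, 1]`.
#' @param G Gain vector over `spec$n_bins` bins.
#' @return A `spectrum_tensor` with `F_hat` filled in.
#' @export
apply_filter <- function(spec, mask, G) {
  stop_if_not(inherits(spec, "spectrum_tensor"), "spec must be a spectrum_tensor")
  stop_if_not(length(mask) == spec$n_bins && length(G) == spec$n_bins,
              "mask/G length must equal the number of non-negative bins")
  w <- mirror_bins(mask * G, spec$n)
  spec$F_hat <- spec$F * w
  spec
}

# mirror a non-negative-bin weight vector onto the full DFT index range via
# conjugate symmetry: full[k] = w[k] for k = 1..n_bins, full[n - k + 2] = w[k]
mirror_bins <- function(w, n) {
  n_bins <- floor(n / 2) + 1
  full <- numeric(n)
  full[seq_len(n_bins)] <- w
  if (n_bins > 2 || (n %% 2 == 1 && n_bins == 2)) {
    k <- 2:(if (n %% 2 == 0) n_bins - 1 else n_bins)
    if (length(k) > 0) full[n - k + 2] <- w[k]
  }
  full
}

#' Inverse FFT and gated fusion with the original signal
#'
#' `x_hat = IFFT(F_hat)`; `x_tilde = alpha * x + (1 - alpha) * x_hat`.
#'
#' @param spec A `spectrum_tensor` with `F_hat` (see [apply_filter()]).
#' @param x The original real sequence (length `spec$n`).
#' @param alpha Fusion weight in `[0, 1]`.
#' @return Real numeric vector `x_tilde`.
#' @export
inverse_and_fuse <- function(spec, x, alpha) {
  stop_if_not(!is.null(spec$F_hat), "spec must carry F_hat; call apply_filter()")
  stop_if_not(length(x) == spec$n, "x length must match the spectrum")
  x_hat <- Re(stats::fft(spec$F_hat, inverse = TRUE)) / spec$n
  alpha * x + (1 - alpha) * x_hat
}

#' Adaptive frequency filtering of a token sequence
#'
#' The full module: FFT along the token axis (independently per embedding
#' dimension), energy-thresholded adaptive masking, learnable global/local
#' gains, inverse FFT, and gated fusion with the input. Also returns the
#' per-token attention gate (the mean-normalized energy profile of the
#' filtered signal) and a cache consumed by [affm_backward()].
#'
#' @param H Token matrix (`n_tokens x d_model`).
#' @param bank A [filter_bank()].
#' @param mode `"soft"` (training: sigmoid-relaxed mask) or `"hard"` (0/1
#'   mask).
#' @return List with `out` (same shape as `H`), `gate` (length `n_tokens`),
#'   and `cache`.
#' @export
affm_forward <- function(H, bank, mode = c("soft", "hard")) {
  mode <- match.arg(mode)
  n <- nrow(H)
  if (n < 2) {
    warning("sequence length < 2: AFFM spectrum degenerate, passing through")
    return(list(out = H, gate = rep(1, n), cache = list(passthrough = TRUE, n = n)))
  }
  dm <- ncol(H)
  n_bins <- floor(n / 2) + 1
  F <- stats::mvfft(H)                               # n x dm complex
  P <- Mod(F[seq_len(n_bins), , drop = FALSE])^2     # n_bins x dm
  med <- apply(P, 2, stats::median)
  r <- sweep(P, 2, med + bank$epsilon, `/`)
  m_half <- if (mode == "hard") {
    (r > bank$theta) * 1
  } else {
    sigmoid((r - bank$theta) / bank$temperature)
  }
  gains <- filter_gains(bank, n_bins)
  w_half <- m_half * gains$G                         # vector recycles down rows
  idx_full <- full_bin_index(n)                      # full-spectrum bin -> half bin
  w_full <- w_half[idx_full, , drop = FALSE]
  F_hat <- F * w_full
  x_hat <- Re(stats::mvfft(F_hat, inverse = TRUE)) / n
  alpha <- sigmoid(bank$alpha_raw)
  out <- alpha * H + (1 - alpha) * x_hat
  energy <- rowSums(x_hat^2)
  gate <- if (mean(energy) > 0) energy / mean(energy) else rep(1, n)
  list(out = out, gate = gate,
       cache = list(H = H, F = F, m_half = m_half, gains = gains,
                    w_half = w_half, idx_full = idx_full, x_hat = x_hat,
                    alpha = alpha, r = r, mode = mode, n = n, dm = dm,
                    n_bins = n_bins, bank = bank, passthrough = FALSE))
}

# map each full-spectrum index 1..n to its non-negative-frequency bin index
full_bin_index <- function(n) {
  n_bins <- floor(n / 2) + 1
  k <- seq_len(n)
  ifelse(k <= n_bins, k, n - k + 2)
}

#' Backward pass of [affm_forward()]
#'
#' Exact reverse-mode gradients for the filter-bank parameters and the input
#' sequence. The energy ratio inside the adaptive mask and the attention gate
#' are treated as constants (stop-gradient); `theta` receives gradient through
#' the soft relaxation only.
#'
#' @param dOut Upstream gradient, same shape as the forward output.
#' @param cache Cache returned by [affm_forward()].
#' @return List with `dH` and `grads` (`W_global`, `W_local`, `theta`,
#'   `alpha_raw`).
#' @export
affm_backward <- function(dOut, cache) {
  if (cache$passthrough) {
    return(list(dH = dOut,
                grads = list(W_global = numeric(0), W_local = numeric(0),
                             theta = 0, alpha_raw = 0)))
  }
  n <- cache$n
  bank <- cache$bank
  alpha <- cache$alpha
  # fusion gate
  dalpha <- sum(dOut * (cache$H - cache$x_hat))
  dalpha_raw <- dalpha * alpha * (1 - alpha)
  dx_hat <- (1 - alpha) * dOut
  dH <- alpha * dOut
  # x_hat = Re(IDFT(w_full * DFT(H))) / n; both linear paths below.
  U <- stats::mvfft(dx_hat, inverse = TRUE)          # unnormalized IDFT of grad
  # input path: dH += Re(DFT(w_full * U)) / n
  w_full <- cache$w_half[cache$idx_full, , drop = FALSE]
  dH <- dH + Re(stats::mvfft(w_full * U)) / n
  # weight path: dw_full = Re(F * U) / n, folded onto non-negative bins
  dw_full <- Re(cache$F * U) / n
  dw_half <- rowsum(dw_full, group = cache$idx_full)  # n_bins x dm, fold mirror
  # split into mask and gain factors: w_half = m_half * G
  dG <- rowSums(dw_half * cache$m_half)
  dm_half <- dw_half * cache$gains$G
  # theta gradient (soft mode only; energy ratio r treated as constant)
  dtheta <- if (cache$mode == "soft") {
    s <- cache$m_half
    -sum(dm_half * s * (1 - s)) / bank$temperature
  } else {
    0
  }
  # gains: G = Gg * Gl, each sigmoid of interpolated reference weights
  gg <- cache$gains$G_global
  gl <- cache$gains$G_local
  act <- cache$gains$local_active
  dgg <- dG * gl
  dgl <- dG * gg
  dWg_act <- dgg * gg * (1 - gg)
  dWl_act <- ifelse(act, dgl * gl * (1 - gl), 0)
  Rt <- t(cache$gains$R)
  list(dH = dH,
       grads = list(W_global = as.numeric(Rt %*% dWg_act),
                    W_local = as.numeric(Rt %*% dWl_act),
                    theta = dtheta,
                    alpha_raw = dalpha_raw))
}

# learnable leaves of a filter bank (subtree used by the optimizer)
bank_params <- function(bank) {
  list(W_global = bank$W_global, W_local = bank$W_local,
       theta = bank$theta, alpha_raw = bank$alpha_raw)
}

bank_set_params <- function(bank, p) {
  bank$W_global <- p$W_global
  bank$W_local <- p$W_local
  bank$theta <- p$theta
  bank$alpha_raw <- p$alpha_raw
  bank
}
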