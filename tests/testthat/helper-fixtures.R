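# shared in-code fixtures for the test suite

periodogram_peak_hz <- function(x, fs) {
  n <- length(x)
  p <- Mod(stats::fft(x)[1:(floor(n / 2) + 1)])^2
  p[1] <- 0                        # ignore DC for peak finding
  (which.max(p) - 1) * fs / n
}

psd_at <- function(x, fs, freq) {
  n <- length(x)
  k <- round(freq * n / fs) + 1
  Mod(stats::fft(x)[k])^2 / n
}

tiny_cfg <- function(...) tiny_model_config(n_bins_ref = 9, ...)

random_epoch <- function(C = 4, T = 256, fs = 64, seed = 1) {
  rec <- generate_recording(list(), C, T / fs, fs, noise_amp = 5, seed = seed)
  aftanet:::new_epoch_tensor(rec$data, fs, rec$channel_names)
}

# independently written plain post-attention Transformer block (no AFFM, no
# frequency gate), used as the reduction reference: straightforward loops, no
# shared code with the package internals beyond parameter values.
reference_block <- function(H, p, n_heads) {
  dm <- ncol(H)
  dk <- dm / n_heads
  addb <- function(M, b) sweep(M, 2, b, `+`)
  Q <- addb(H %*% p$attn$Wq, p$attn$bq)
  K <- addb(H %*% p$attn$Wk, p$attn$bk)
  V <- addb(H %*% p$attn$Wv, p$attn$bv)
  O <- matrix(0, nrow(H), dm)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1) * dk + 1):(h * dk)
    S <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dk)
    A <- t(apply(S, 1, function(s) { e <- exp(s - max(s)); e / sum(e) }))
    O[, cols] <- A %*% V[, cols, drop = FALSE]
  }
  H_attn <- addb(O %*% p$attn$Wo, p$attn$bo)
  ln <- function(X, g, b) {
    t(apply(X, 1, function(r) {
      (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-5) * g + b
    }))
  }
  u <- H_attn + H + addb(H_attn %*% p$fc$W, p$fc$b)
  H1 <- ln(u, p$ln1$g, p$ln1$b)
  gelu <- function(x) x * pnorm(x)
  mlp <- addb(gelu(addb(H1 %*% p$mlp$W1, p$mlp$b1)) %*% p$mlp$W2, p$mlp$b2)
  ln(H1 + mlp, p$ln2$g, p$ln2$b)
}

# exhaustive pairwise AUROC oracle
auroc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == max(labels)]
  neg <- scores[labels == min(labels)]
  s <- 0
  for (p in pos) for (n in neg) s <- s + (p > n) + 0.5 * (p == n)
  s / (length(pos) * length(neg))
}
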