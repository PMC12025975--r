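#' Partition an epoch into fixed-size spatiotemporal patches
#'
#' Splits each channel's `T` samples into `T/d` consecutive patches of length
#' `d`. The partition is lossless: concatenating the patches of a channel
#' reproduces the signal exactly.
#'
#' @param ep An `epoch_tensor` (or bare `C x T` matrix).
#' @param d Patch length in samples; must divide `T`.
#' @return A `patch_grid`: array `(C, n_time, d)` plus bookkeeping.
#' @export
partition_patches <- function(ep, d) {
  x <- if (inherits(ep, "epoch_tensor")) ep$data else ep
  stop_if_not(is.matrix(x), "input must be an epoch_tensor or matrix")
  Tn <- ncol(x)
  if (Tn %% d != 0) {
    stop(sprintf("patch length %d does not divide epoch length %d", d, Tn),
         call. = FALSE)
  }
  n_time <- Tn %/% d
  patches <- array(0, dim = c(nrow(x), n_time, d))
  for (j in seq_len(n_time)) {
    patches[, j, ] <- x[, ((j - 1) * d + 1):(j * d), drop = FALSE]
  }
  structure(list(patches = patches, C = nrow(x), n_time = n_time, d = d),
            class = "patch_grid")
}

#' Reassemble an epoch from its patch grid
#' @param grid A `patch_grid`.
#' @return A `C x T` matrix.
#' @export
reassemble_patches <- function(grid) {
  x <- matrix(0, grid$C, grid$n_time * grid$d)
  for (j in seq_len(grid$n_time)) {
    x[, ((j - 1) * grid$d + 1):(j * grid$d)] <- grid$patches[, j, ]
  }
  x
}

#' Sample the dual-ratio spatiotemporal mask
#'
#' Draws `round(time_ratio * n_time)` time columns and
#' `round(channel_ratio * C)` channel rows uniformly at random (round-half-up);
#' a patch `(i, j)` is masked when its channel row or its time column is
#' selected (union rule).
#'
#' @param n_time Number of time patches.
#' @param C Number of channels.
#' @param time_ratio,channel_ratio Masking ratios in `[0, 1]`
#'   (defaults 0.5 and 0.8).
#' @param seed Integer seed.
#' @return A `mask_spec`: `masked_time`, `masked_channels`, logical `C x n_time`
#'   matrix `M`, and index matrices `M_idx` / `M_bar_idx` (columns `i`, `j`).
#' @export
sample_mask <- function(n_time, C, time_ratio = 0.5, channel_ratio = 0.8,
                        seed = 1L) {
  stop_if_not(time_ratio >= 0 && time_ratio <= 1, "time_ratio must be in [0,1]")
  stop_if_not(channel_ratio >= 0 && channel_ratio <= 1, "channel_ratio must be in [0,1]")
  n_mt <- round_half_up(time_ratio * n_time)
  n_mc <- round_half_up(channel_ratio * C)
  with_seed(seed, {
    masked_time <- sort(sample.int(n_time, n_mt))
    masked_channels <- sort(sample.int(C, n_mc))
    M <- matrix(FALSE, C, n_time)
    M[masked_channels, ] <- TRUE
    M[, masked_time] <- TRUE
    idx <- which(M, arr.ind = TRUE)
    idx_bar <- which(!M, arr.ind = TRUE)
    colnames(idx) <- colnames(idx_bar) <- c("i", "j")
    structure(list(masked_time = masked_time, masked_channels = masked_channels,
                   M = M, M_idx = idx, M_bar_idx = idx_bar,
                   C = C, n_time = n_time),
              class = "mask_spec")
  })
}

# grid-slot linear index (channel-major: row (i-1)*n_time + j)
slot_index <- function(i, j, n_time) (i - 1L) * n_time + j

#' Embed a patch grid into the token sequence
#'
#' Unmasked patches become `W_p' p + b_p + zeta_i + pi_j`; masked positions
#' carry only `zeta_i + pi_j + mask_token` (no signal term). The learnable
#' summary tokens are appended after the `C * n_time` patch tokens (without
#' positional encodings).
#'
#' @param grid A `patch_grid`.
#' @param mask A `mask_spec`, or `NULL` to embed every patch with its signal.
#' @param params Embedding parameters: `W_p` (`d x d_model`), `b_p`, `zeta`
#'   (`C x d_model`), `pi` (`n_time x d_model`), `mask_token`, `summary`
#'   (`n_summary x d_model`).
#' @return A `token_sequence`: `tokens` matrix, `roles` data frame (`i`, `j`,
#'   `NA` for summary tokens), and logical `mask_flags`.
#' @export
embed_tokens <- function(grid, mask, params) {
  d <- grid$d
  dm <- ncol(params$W_p)
  stop_if_not(nrow(params$W_p) == d, "W_p rows must equal patch length")
  stop_if_not(nrow(params$zeta) == grid$C, "zeta rows must equal C")
  stop_if_not(nrow(params$pi) == grid$n_time, "pi rows must equal n_time")
  n_patch <- grid$C * grid$n_time
  P <- matrix(0, n_patch, d)        # patch values, row per grid slot
  for (i in seq_len(grid$C)) {
    for (j in seq_len(grid$n_time)) {
      P[slot_index(i, j, grid$n_time), ] <- grid$patches[i, j, ]
    }
  }
  ii <- rep(seq_len(grid$C), each = grid$n_time)
  jj <- rep(seq_len(grid$n_time), times = grid$C)
  masked <- if (is.null(mask)) rep(FALSE, n_patch) else mask$M[cbind(ii, jj)]
  pos <- params$zeta[ii, , drop = FALSE] + params$pi[jj, , drop = FALSE]
  tokens <- pos
  if (any(!masked)) {
    emb <- P[!masked, , drop = FALSE] %*% params$W_p +
      matrix(params$b_p, sum(!masked), dm, byrow = TRUE)
    tokens[!masked, ] <- tokens[!masked, ] + emb
  }
  if (any(masked)) {
    tokens[masked, ] <- tokens[masked, ] +
      matrix(params$mask_token, sum(masked), dm, byrow = TRUE)
  }
  n_summary <- nrow(params$summary)
  tokens <- rbind(tokens, params$summary)
  structure(list(
    tokens = tokens,
    roles = data.frame(i = c(ii, rep(NA, n_summary)),
                       j = c(jj, rep(NA, n_summary))),
    mask_flags = c(masked, rep(FALSE, n_summary)),
    P = P, masked = masked, C = grid$C, n_time = grid$n_time,
    n_summary = n_summary
  ), class = "token_sequence")
}

# gradient of embed_tokens w.r.t. parameters, given d_tokens over the full
# sequence (patch rows then summary rows)
embed_backward <- function(d_tokens, seq) {
  n_patch <- seq$C * seq$n_time
  dpatch <- d_tokens[seq_len(n_patch), , drop = FALSE]
  dsum <- d_tokens[(n_patch + 1):nrow(d_tokens), , drop = FALSE]
  ii <- rep(seq_len(seq$C), each = seq$n_time)
  jj <- rep(seq_len(seq$n_time), times = seq$C)
  dm <- ncol(d_tokens)
  dzeta <- rowsum(dpatch, group = ii)
  dpi <- rowsum(dpatch, group = jj)
  um <- !seq$masked
  dW_p <- if (any(um)) {
    crossprod(seq$P[um, , drop = FALSE], dpatch[um, , drop = FALSE])
  } else {
    matrix(0, ncol(seq$P), dm)
  }
  db_p <- if (any(um)) colSums(dpatch[um, , drop = FALSE]) else numeric(dm)
  dmask_token <- if (any(seq$masked)) {
    colSums(dpatch[seq$masked, , drop = FALSE])
  } else {
    numeric(dm)
  }
  list(W_p = dW_p, b_p = db_p, zeta = dzeta, pi = dpi,
       mask_token = dmask_token, summary = dsum)
}
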