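#' Model configuration for the frequency-time attention Transformer
#'
#' Defaults follow the full-scale training recipe (256-dim tokens, 8 heads,
#' 8 blocks, 200-sample patches, GELU MLPs with ratio 4, dropout 0.3); see
#' [tiny_model_config()] for the small deterministic preset used in tests and
#' examples.
#'
#' @param d_model Token embedding width.
#' @param n_heads Attention heads (`d_model` must be divisible by it).
#' @param n_blocks Encoder depth.
#' @param patch_len Patch length in samples.
#' @param n_summary Number of learnable summary tokens.
#' @param mlp_ratio Hidden width of the MLP as a multiple of `d_model`.
#' @param dropout Dropout rate on MLP hidden units during training.
#' @param n_rec_blocks Depth of the reconstructor (plain blocks).
#' @param time_mask_ratio,channel_mask_ratio Masking ratios of the pretext
#'   task (defaults 0.5 and 0.8).
#' @param n_bins_ref,local_cutoff,mask_temperature,lambda_theta,epsilon,alpha_init
#'   Adaptive-filter hyperparameters; see [filter_bank()].
#' @param hard_mask_eval Use the hard 0/1 adaptive mask at evaluation
#'   (training always uses the soft relaxation).
#' @param use_freq_gate Gate attention values by the per-token frequency
#'   profile (`FALSE` gives plain ungated attention).
#' @param momentum Momentum-encoder EMA coefficient.
#' @return A `model_config` list.
#' @export
model_config <- function(d_model = 256, n_heads = 8, n_blocks = 8,
                         patch_len = 200, n_summary = 4, mlp_ratio = 4,
                         dropout = 0.3, n_rec_blocks = 2,
                         time_mask_ratio = 0.5, channel_mask_ratio = 0.8,
                         n_bins_ref = 17, local_cutoff = 0.5,
                         mask_temperature = 0.1, lambda_theta = 1e-4,
                         epsilon = 1e-12, alpha_init = 0.5,
                         hard_mask_eval = TRUE, use_freq_gate = TRUE,
                         momentum = 0.99) {
  stop_if_not(d_model %% n_heads == 0, "d_model must be divisible by n_heads")
  structure(as.list(environment()), class = "model_config")
}

#' Tiny model preset for fast deterministic runs
#' @param ... Overrides passed to [model_config()].
#' @return A `model_config`.
#' @export
tiny_model_config <- function(...) {
  args <- list(d_model = 64, n_heads = 4, n_blocks = 2, patch_len = 32,
               n_summary = 4, dropout = 0, n_rec_blocks = 2)
  args[names(list(...))] <- list(...)
  do.call(model_config, args)
}

init_block <- function(cfg, with_bank) {
  dm <- cfg$d_model
  p <- list(
    attn = init_attn(dm),
    fc = list(W = init_mat(dm, dm), b = numeric(dm)),
    ln1 = init_ln(dm),
    mlp = init_mlp(dm, dm * cfg$mlp_ratio),
    ln2 = init_ln(dm)
  )
  if (with_bank) {
    bank <- filter_bank(n_bins_ref = cfg$n_bins_ref,
                        local_cutoff = cfg$local_cutoff,
                        alpha_init = cfg$alpha_init,
                        lambda = cfg$lambda_theta,
                        epsilon = cfg$epsilon,
                        temperature = cfg$mask_temperature)
    p$bank <- bank_params(bank)
  }
  p
}

#' Initialize a frequency-time attention model
#'
#' @param cfg A [model_config()].
#' @param C Number of channels.
#' @param n_time Number of time patches per epoch.
#' @param seed Integer seed for weight initialization.
#' @param n_classes Optional: adds a classification head.
#' @param n_outputs Optional: adds a regression head.
#' @return An `afta_model`: config, dimensions, and the parameter tree.
#' @export
init_afta_model <- function(cfg, C, n_time, seed = 1L, n_classes = NULL,
                            n_outputs = NULL) {
  stop_if_not(inherits(cfg, "model_config"), "cfg must be a model_config")
  dm <- cfg$d_model
  d <- cfg$patch_len
  params <- with_seed(seed, {
    p <- list(
      embed = list(W_p = init_mat(d, dm), b_p = numeric(dm),
                   zeta = init_mat(C, dm, sd = 0.02),
                   pi = init_mat(n_time, dm, sd = 0.02),
                   mask_token = stats::rnorm(dm, sd = 0.02),
                   summary = init_mat(cfg$n_summary, dm, sd = 0.02)),
      encoder = lapply(seq_len(cfg$n_blocks), function(b) init_block(cfg, TRUE)),
      predictor = list(attn = init_attn(dm), mlp = init_mlp(dm, dm)),
      reconstructor = list(
        blocks = lapply(seq_len(cfg$n_rec_blocks), function(b) init_block(cfg, FALSE)),
        W_out = init_mat(dm, d), b_out = numeric(d)
      )
    )
    if (!is.null(n_classes)) {
      p$head <- list(W = init_mat(dm, n_classes), b = numeric(n_classes))
    }
    if (!is.null(n_outputs)) {
      p$head <- list(W = init_mat(dm, n_outputs), b = numeric(n_outputs))
    }
    p
  })
  structure(list(cfg = cfg, C = C, n_time = n_time, params = params,
                 n_classes = n_classes, n_outputs = n_outputs),
            class = "afta_model")
}

#' @export
print.afta_model <- function(x, ...) {
  n_par <- tree_sum(length, x$params)
  cat(sprintf(
    "<afta_model> d_model=%d heads=%d blocks=%d patch=%d | %d ch x %d time patches | %s parameters\n",
    x$cfg$d_model, x$cfg$n_heads, x$cfg$n_blocks, x$cfg$patch_len,
    x$C, x$n_time, format(n_par, big.mark = ",")))
  invisible(x)
}

#' Frequency-gated multi-head self-attention
#'
#' Standard scaled dot-product attention whose value rows are scaled by the
#' per-token frequency gate `g` before aggregation:
#' `A = softmax(Q K' / sqrt(d_k))`, `A_f = A diag(g) V`. With `g = 1` this is
#' plain attention.
#'
#' @param H_tilde Token matrix (`n x d_model`).
#' @param gate Per-token gate vector (length `n`), or `NULL` for ungated.
#' @param params Attention parameters (`Wq`, `Wk`, `Wv`, `Wo` + biases).
#' @param n_heads Number of heads.
#' @return List with `out` (`n x d_model`) and `attention` (per-head list of
#'   attention matrices).
#' @export
freq_time_attention <- function(H_tilde, gate, params, n_heads) {
  r <- mha_fwd(H_tilde, H_tilde, params, n_heads, gate = gate)
  list(out = r$out, attention = r$cache$A)
}

# --- AFTA block ---------------------------------------------------------------
# H_tilde = AFFM(H); H_attn = gated-MHA(H_tilde);
# H1 = LayerNorm(H_attn + H_tilde + FC(H_attn)); out = LayerNorm(H1 + MLP(H1)).
# Reconstructor blocks pass bank = NULL: no AFFM, no gate (plain wiring).

afta_block_fwd <- function(H, p, cfg, train = FALSE) {
  if (!is.null(p$bank)) {
    bank <- bank_set_params(filter_bank(
      n_bins_ref = cfg$n_bins_ref, local_cutoff = cfg$local_cutoff,
      lambda = cfg$lambda_theta, epsilon = cfg$epsilon,
      temperature = cfg$mask_temperature), p$bank)
    mode <- if (train || !cfg$hard_mask_eval) "soft" else "hard"
    aff <- affm_forward(H, bank, mode = mode)
    Ht <- aff$out
    gate <- if (isTRUE(cfg$use_freq_gate)) aff$gate else NULL
  } else {
    aff <- NULL
    Ht <- H
    gate <- NULL
  }
  at <- mha_fwd(Ht, Ht, p$attn, cfg$n_heads, gate = gate)
  fc <- linear_fwd(at$out, p$fc$W, p$fc$b)
  u <- at$out + Ht + fc$out
  ln1 <- layernorm_fwd(u, p$ln1$g, p$ln1$b)
  ml <- mlp_fwd(ln1$out, p$mlp, cfg$dropout, train)
  v <- ln1$out + ml$out
  ln2 <- layernorm_fwd(v, p$ln2$g, p$ln2$b)
  list(out = ln2$out,
       cache = list(aff = aff, at = at$cache, fc = fc$cache, ln1 = ln1$cache,
                    ml = ml$cache, ln2 = ln2$cache, has_bank = !is.null(p$bank)))
}

afta_block_bwd <- function(dOut, cache) {
  l2 <- layernorm_bwd(dOut, cache$ln2)
  dv <- l2$dX
  mb <- mlp_bwd(dv, cache$ml)
  dH1 <- dv + mb$dX
  l1 <- layernorm_bwd(dH1, cache$ln1)
  du <- l1$dX
  fb <- linear_bwd(du, cache$fc)
  dat_out <- du + fb$dX
  ab <- mha_bwd(dat_out, cache$at)
  dHt <- du + ab$dXq + ab$dXkv
  grads <- list(attn = ab$grads,
                fc = list(W = fb$dW, b = fb$db),
                ln1 = list(g = l1$dg, b = l1$db),
                mlp = mb$grads,
                ln2 = list(g = l2$dg, b = l2$db))
  if (cache$has_bank) {
    af <- affm_backward(dHt, cache$aff$cache)
    dH <- af$dH
    grads$bank <- af$grads
  } else {
    dH <- dHt
  }
  list(dH = dH, grads = grads)
}

#' Run the encoder stack
#'
#' @param tokens Token matrix (`n x d_model`): unmasked patch tokens plus
#'   summary tokens during pretraining, or the full sequence at fine-tuning.
#' @param model An `afta_model`.
#' @param train Training mode (soft adaptive mask, dropout active).
#' @return List with `out` (`n x d_model`) and internal `caches`.
#' @export
encode <- function(tokens, model, train = FALSE) {
  H <- tokens
  caches <- vector("list", length(model$params$encoder))
  for (b in seq_along(model$params$encoder)) {
    r <- afta_block_fwd(H, model$params$encoder[[b]], model$cfg, train)
    H <- r$out
    caches[[b]] <- r$cache
  }
  list(out = H, caches = caches)
}

encode_bwd <- function(dOut, caches) {
  n_b <- length(caches)
  grads <- vector("list", n_b)
  dH <- dOut
  for (b in rev(seq_len(n_b))) {
    r <- afta_block_bwd(dH, caches[[b]])
    dH <- r$dH
    grads[[b]] <- r$grads
  }
  list(dH = dH, grads = grads)
}

# --- predictor ----------------------------------------------------------------
# One cross-attention read over the encoder output followed by a two-layer MLP,
# both with residual paths. Queries are the positional identities of the
# masked slots (zeta_i + pi_j + mask token).

predict_masked_fwd <- function(queries, enc_out, p, n_heads, cfg) {
  ca <- mha_fwd(queries, enc_out, p$attn, n_heads)
  h <- queries + ca$out
  ml <- mlp_fwd(h, p$mlp)
  list(out = h + ml$out, cache = list(ca = ca$cache, ml = ml$cache))
}

predict_masked_bwd <- function(dOut, cache) {
  mb <- mlp_bwd(dOut, cache$ml)
  dh <- dOut + mb$dX
  ab <- mha_bwd(dh, cache$ca)
  list(dQ = dh + ab$dXq, dEnc = ab$dXkv,
       grads = list(attn = ab$grads, mlp = mb$grads))
}

#' Predict features of the masked patches
#'
#' @param enc Encoder output (`n_enc x d_model`).
#' @param mask A `mask_spec`.
#' @param model An `afta_model`.
#' @return Matrix of `|M|` prediction vectors (`d_model` columns); zero-row
#'   matrix when the mask is empty.
#' @export
predict_masked <- function(enc, mask, model) {
  m_idx <- mask$M_idx
  if (nrow(m_idx) == 0) return(matrix(0, 0, model$cfg$d_model))
  em <- model$params$embed
  queries <- em$zeta[m_idx[, "i"], , drop = FALSE] +
    em$pi[m_idx[, "j"], , drop = FALSE] +
    matrix(em$mask_token, nrow(m_idx), model$cfg$d_model, byrow = TRUE)
  predict_masked_fwd(queries, enc, model$params$predictor,
                     model$cfg$n_heads, model$cfg)$out
}

# --- reconstructor ------------------------------------------------------------
# Z0: full-grid sequence (encoder features at unmasked slots, predictor
# features at masked slots, each plus its positional identity). Two plain
# blocks, then a skip connection from Z0 and a linear projection to patch
# length.

reconstruct_fwd <- function(Z0, p, cfg, train = FALSE) {
  Z <- Z0
  caches <- vector("list", length(p$blocks))
  for (b in seq_along(p$blocks)) {
    r <- afta_block_fwd(Z, p$blocks[[b]], cfg, train)
    Z <- r$out
    caches[[b]] <- r$cache
  }
  lo <- linear_fwd(Z + Z0, p$W_out, p$b_out)
  list(out = lo$out, cache = list(blocks = caches, lo = lo$cache))
}

reconstruct_bwd <- function(dOut, cache) {
  lb <- linear_bwd(dOut, cache$lo)
  dZ <- lb$dX
  dZ0 <- lb$dX                     # skip path
  grads_blocks <- vector("list", length(cache$blocks))
  for (b in rev(seq_along(cache$blocks))) {
    r <- afta_block_bwd(dZ, cache$blocks[[b]])
    dZ <- r$dH
    grads_blocks[[b]] <- r$grads
  }
  dZ0 <- dZ0 + dZ
  list(dZ0 = dZ0,
       grads = list(blocks = grads_blocks, W_out = lb$dW, b_out = lb$db))
}

#' Reconstruct masked patches from encoder and predictor features
#'
#' @param enc Encoder output over unmasked patch tokens plus summary tokens.
#' @param pred Predictor output (`|M| x d_model`).
#' @param mask A `mask_spec`.
#' @param model An `afta_model`.
#' @return Matrix of reconstructed patches (`|M| x patch_len`) in the row
#'   order of `mask$M_idx`.
#' @export
reconstruct <- function(enc, pred, mask, model) {
  z <- assemble_rec_input(enc, pred, mask, model)
  r <- reconstruct_fwd(z$Z0, model$params$reconstructor, model$cfg)
  r$out[z$masked_rows, , drop = FALSE]
}

assemble_rec_input <- function(enc, pred, mask, model) {
  em <- model$params$embed
  n_time <- mask$n_time
  C <- mask$C
  dm <- model$cfg$d_model
  n_patch <- C * n_time
  Z0 <- matrix(0, n_patch, dm)
  ii <- rep(seq_len(C), each = n_time)
  jj <- rep(seq_len(n_time), times = C)
  pos <- em$zeta[ii, , drop = FALSE] + em$pi[jj, , drop = FALSE]
  masked_rows <- slot_index(mask$M_idx[, "i"], mask$M_idx[, "j"], n_time)
  unmasked_rows <- slot_index(mask$M_bar_idx[, "i"], mask$M_bar_idx[, "j"], n_time)
  # encoder rows 1..n_unmasked correspond to unmasked slots in M_bar_idx order
  if (length(unmasked_rows) > 0) {
    Z0[unmasked_rows, ] <- enc[seq_along(unmasked_rows), , drop = FALSE]
  }
  if (length(masked_rows) > 0) {
    Z0[masked_rows, ] <- pred
  }
  Z0 <- Z0 + pos
  list(Z0 = Z0, masked_rows = masked_rows, unmasked_rows = unmasked_rows,
       ii = ii, jj = jj, pos = pos)
}

# --- heads ---------------------------------------------------------------------

#' Classification head on the summary-token features
#'
#' Mean of the summary-token encoder features, linear map, softmax.
#'
#' @param enc_summary Summary-token features (`n_summary x d_model`).
#' @param head Head parameters (`W`, `b`).
#' @return Probability vector on the simplex.
#' @export
classify_head <- function(enc_summary, head) {
  feat <- colMeans(enc_summary)
  z <- as.numeric(feat %*% head$W + head$b)
  e <- exp(z - max(z))
  e / sum(e)
}

#' Regression head on the summary-token features
#' @param enc_summary Summary-token features (`n_summary x d_model`).
#' @param head Head parameters (`W`, `b`).
#' @return Unconstrained real vector.
#' @export
regress_head <- function(enc_summary, head) {
  as.numeric(colMeans(enc_summary) %*% head$W + head$b)
}

#' Exponential-moving-average update of the momentum encoder
#'
#' `momentum <- m * momentum + (1 - m) * online`, leafwise over two parameter
#' trees of identical structure. Momentum parameters never carry gradients.
#'
#' @param online_params,momentum_params Parameter trees of identical shape.
#' @param m EMA coefficient in `[0, 1]`.
#' @return Updated momentum parameter tree.
#' @export
momentum_update <- function(online_params, momentum_params, m) {
  stop_if_not(m >= 0 && m <= 1, "m must be in [0,1]")
  tree_map2(function(new, old) m * old + (1 - m) * new,
            online_params, momentum_params)
}
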