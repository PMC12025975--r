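test_that("frequency-gated attention reduces to plain attention at unit gate", {
  set.seed(1)
  dm <- 8
  p <- aftanet:::init_attn(dm)
  H <- matrix(rnorm(5 * dm), 5, dm)
  gated <- freq_time_attention(H, rep(1, 5), p, n_heads = 2)
  plain <- freq_time_attention(H, NULL, p, n_heads = 2)
  expect_equal(gated$out, plain$out, tolerance = 1e-12)

  # attention rows sum to 1
  for (A in gated$attention) expect_equal(rowSums(A), rep(1, 5), tolerance = 1e-6)

  # single token: softmax weight exactly 1, output = gated value vector
  H1 <- matrix(rnorm(dm), 1, dm)
  g1 <- freq_time_attention(H1, 2, p, n_heads = 2)
  v <- (H1 %*% p$Wv + p$bv) * 2
  expect_equal(g1$out, v %*% p$Wo + matrix(p$bo, 1), tolerance = 1e-12)

  expect_error(aftanet:::mha_fwd(H, H, p, n_heads = 3), "divisible")
})

test_that("the AFTA block preserves shape and is deterministic at eval", {
  cfg <- tiny_cfg(d_model = 16, n_heads = 2, patch_len = 8, mlp_ratio = 2)
  set.seed(2)
  p <- aftanet:::init_block(cfg, TRUE)
  for (n in c(2, 5, 9)) {
    H <- matrix(rnorm(n * 16), n, 16)
    o1 <- aftanet:::afta_block_fwd(H, p, cfg, train = FALSE)$out
    o2 <- aftanet:::afta_block_fwd(H, p, cfg, train = FALSE)$out
    expect_identical(o1, o2)
    expect_equal(dim(o1), c(n, 16L))
  }
})

test_that("every learnable block tensor receives gradient from a scalar loss", {
  cfg <- tiny_cfg(d_model = 8, n_heads = 2, patch_len = 4, mlp_ratio = 2,
                  use_freq_gate = FALSE, hard_mask_eval = TRUE)
  set.seed(3)
  p <- aftanet:::init_block(cfg, TRUE)
  X <- matrix(rnorm(3 * 8), 3, 8)
  Tgt <- matrix(rnorm(3 * 8), 3, 8)
  r <- aftanet:::afta_block_fwd(X, p, cfg, train = FALSE)
  bw <- aftanet:::afta_block_bwd(2 * (r$out - Tgt), r$cache)
  nonzero <- aftanet:::tree_map(function(g) any(abs(g) > 0), bw$grads)
  expect_true(all(unlist(nonzero[c("attn", "fc", "ln1", "mlp", "ln2")])))
  expect_true(any(abs(bw$grads$bank$W_global) > 0))

  # finite-difference spot check on a 3-token instance
  lf <- function(pp) {
    sum((aftanet:::afta_block_fwd(X, pp, cfg, FALSE)$out - Tgt)^2)
  }
  h <- 1e-6
  for (probe in list(c("attn", "Wk"), c("mlp", "W2"), c("ln1", "g"))) {
    p2 <- p
    p2[[probe[1]]][[probe[2]]][1] <- p2[[probe[1]]][[probe[2]]][1] + h
    expect_equal((lf(p2) - lf(p)) / h, bw$grads[[probe[1]]][[probe[2]]][1],
                 tolerance = 1e-3)
  }
})

test_that("with AFFM bypassed and gate off the encoder equals a plain reference", {
  cfg <- tiny_cfg(d_model = 8, n_heads = 2, patch_len = 4, mlp_ratio = 2,
                  n_blocks = 2, use_freq_gate = FALSE)
  model <- init_afta_model(cfg, C = 2, n_time = 2, seed = 4)
  for (b in seq_along(model$params$encoder)) {
    model$params$encoder[[b]]$bank$alpha_raw <- 40   # alpha -> 1: AFFM identity
  }
  H <- matrix(rnorm(3 * 8), 3, 8)
  out <- encode(H, model, train = FALSE)$out
  ref <- H
  for (b in seq_along(model$params$encoder)) {
    ref <- reference_block(ref, model$params$encoder[[b]], cfg$n_heads)
  }
  expect_equal(out, ref, tolerance = 1e-6)

  # n_blocks = 0 -> identity
  m0 <- model
  m0$params$encoder <- list()
  expect_identical(encode(H, m0)$out, H)
})

test_that("momentum update follows the EMA contract and stops gradients", {
  old <- list(a = matrix(1, 2, 2), b = list(c = rep(1, 3)))
  new <- list(a = matrix(0, 2, 2), b = list(c = rep(0, 3)))
  expect_identical(momentum_update(new, old, 1), old)
  expect_identical(momentum_update(new, old, 0), new)
  up <- momentum_update(new, old, 0.9)
  expect_equal(up$a[1, 1], 0.9)
  expect_error(momentum_update(new, list(a = matrix(1, 2, 2)), 0.5), "mismatched")

  # momentum branch carries no gradient: the pretraining gradient tree has no
  # momentum leaves at all (targets enter only as constants)
  ds <- generate_labeled_dataset(2, separable_class_specs(2), fs = 32,
                                 win_s = 2, n_channels = 2, seed = 1)
  cfg <- tiny_cfg(d_model = 8, n_heads = 2, patch_len = 16, n_blocks = 1)
  g <- partition_patches(ds$epochs[[1]], 16)
  model <- init_afta_model(cfg, 2, g$n_time, seed = 1)
  mp <- list(embed = model$params$embed, encoder = model$params$encoder)
  mask <- sample_mask(g$n_time, 2, 0.5, 0.5, seed = 1)
  r <- aftanet:::pretrain_step_sample(g, mask, model$params, mp, cfg, 1)
  expect_named(r$grads, names(model$params))
})

test_that("predictor and reconstructor meet their shape and sensitivity contracts", {
  cfg <- tiny_cfg(d_model = 8, n_heads = 2, patch_len = 4, n_blocks = 1)
  C <- 3; n_t <- 4
  model <- init_afta_model(cfg, C, n_t, seed = 5)
  x <- matrix(rnorm(C * n_t * 4), C, n_t * 4)
  grid <- partition_patches(x, 4)
  mask <- sample_mask(n_t, C, 0.5, 0.8, seed = 6)
  seqf <- embed_tokens(grid, mask, model$params$embed)
  u_rows <- aftanet:::slot_index(mask$M_bar_idx[, "i"], mask$M_bar_idx[, "j"], n_t)
  enc_in <- seqf$tokens[c(u_rows, (C * n_t + 1):(C * n_t + cfg$n_summary)), ]
  enc <- encode(enc_in, model)$out

  pred <- predict_masked(enc, mask, model)
  expect_equal(dim(pred), c(nrow(mask$M_idx), cfg$d_model))
  empty <- sample_mask(n_t, C, 0, 0, seed = 1)
  expect_equal(nrow(predict_masked(enc, empty, model)), 0)

  rec <- reconstruct(enc, pred, mask, model)
  expect_equal(dim(rec), c(nrow(mask$M_idx), cfg$patch_len))
  # reconstructions depend on pred
  rec2 <- reconstruct(enc, pred + 0.5, mask, model)
  expect_false(isTRUE(all.equal(rec, rec2)))
})

test_that("task heads satisfy simplex and determinism contracts", {
  set.seed(7)
  head4 <- list(W = matrix(rnorm(8 * 4), 8, 4), b = rnorm(4))
  feats <- matrix(rnorm(4 * 8), 4, 8)
  pr <- classify_head(feats, head4)
  expect_length(pr, 4)
  expect_equal(sum(pr), 1, tolerance = 1e-6)
  expect_true(all(pr > 0))
  expect_identical(classify_head(feats, head4), pr)

  headr <- list(W = matrix(rnorm(8 * 2), 8, 2), b = rnorm(2))
  expect_length(regress_head(feats, headr), 2)
})
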