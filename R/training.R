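# Losses, the learning-rate schedule, the self-supervised pretraining loop, and
# fine-tuning for classification/prediction.

#' Masked-patch reconstruction loss
#'
#' `L_R = (1/|M|) * sum over masked patches of ||rec - p||^2`, the squared
#' Euclidean norm summed over the `d` samples of each patch and averaged over
#' patches.
#'
#' @param rec Reconstructed patches (`|M| x d`).
#' @param targets True masked patches, same shape.
#' @param normalize_by_d Also divide by the patch length (default `FALSE`,
#'   plain per-patch squared norm).
#' @return Non-negative scalar; 0 with a warning when the mask is empty.
#' @export
loss_reconstruction <- function(rec, targets, normalize_by_d = FALSE) {
  stop_if_not(all(dim(rec) == dim(targets)), "rec and targets must share shape")
  if (nrow(rec) == 0) {
    warning("empty masked set: reconstruction loss defined as 0")
    return(0)
  }
  l <- mean(rowSums((rec - targets)^2))
  if (normalize_by_d) l / ncol(rec) else l
}

#' Feature alignment loss against momentum-encoder targets
#'
#' `L_A = (1/N) * sum_j ||pred_j - LN(menc_j)||^2` with parameter-free layer
#' normalization of the (gradient-stopped) momentum features.
#'
#' @param pred Predictor features (`N x d_model`).
#' @param menc Momentum-encoder features, same shape.
#' @return Non-negative scalar; 0 with a warning when `N = 0`.
#' @export
loss_alignment <- function(pred, menc) {
  stop_if_not(all(dim(pred) == dim(menc)), "pred and menc must share shape")
  if (nrow(pred) == 0) {
    warning("no prediction targets: alignment loss defined as 0")
    return(0)
  }
  mean(rowSums((pred - layernorm_plain(menc))^2))
}

#' Cross-entropy classification loss
#'
#' @param y One-hot vector, or a single integer class index.
#' @param y_hat Predicted probabilities on the simplex.
#' @param eps Floor applied to probabilities before the log.
#' @return Non-negative scalar.
#' @export
loss_classification <- function(y, y_hat, eps = 1e-12) {
  if (length(y) == 1 && y == round(y)) {
    yy <- numeric(length(y_hat))
    yy[y] <- 1
    y <- yy
  }
  stop_if_not(length(y) == length(y_hat), "y and y_hat must align")
  -sum(y * log(pmax(y_hat, eps)))
}

#' Mean squared prediction loss
#' @param y True values.
#' @param y_hat Predicted values, same length.
#' @return Non-negative scalar.
#' @export
loss_prediction <- function(y, y_hat) {
  stop_if_not(length(y) == length(y_hat), "y and y_hat must align")
  mean((y - y_hat)^2)
}

#' Task loss with the adaptive-threshold regularizer
#'
#' `L_adaptive = L_task + lambda * sum(theta^2)`.
#'
#' @param L_task Task loss.
#' @param theta Threshold scalar (or vector over blocks).
#' @param lambda Regularization coefficient (>= 0).
#' @return Scalar.
#' @export
loss_adaptive <- function(L_task, theta, lambda) {
  stop_if_not(lambda >= 0, "lambda must be >= 0")
  L_task + lambda * sum(theta^2)
}

#' Optimizer schedule configuration
#'
#' Defaults follow the full-scale recipe: AdamW, peak learning rate 5e-4
#' reached after a 15-epoch linear warm-up, cosine decay to 0 afterwards,
#' layer-wise decay factor 0.65, weight decay 0.05, batch size 120, at most
#' 100 epochs, dropout 0.3, mask ratios (0.5, 0.8).
#'
#' @param peak_lr Peak learning rate.
#' @param warmup_epochs Linear warm-up length in epochs.
#' @param layer_decay Per-layer multiplier applied from the top down.
#' @param weight_decay Decoupled weight decay.
#' @param batch_size Batch size.
#' @param max_epochs Maximum epochs.
#' @param dropout Dropout rate.
#' @param mask_ratios Numeric `(time_ratio, channel_ratio)`.
#' @param seed Integer seed.
#' @return A `schedule_config` list.
#' @export
schedule_config <- function(peak_lr = 5e-4, warmup_epochs = 15,
                            layer_decay = 0.65, weight_decay = 0.05,
                            batch_size = 120, max_epochs = 100, dropout = 0.3,
                            mask_ratios = c(0.5, 0.8), seed = 1L) {
  stop_if_not(peak_lr > 0, "peak_lr must be positive")
  stop_if_not(layer_decay > 0 && layer_decay <= 1, "layer_decay must be in (0,1]")
  stop_if_not(warmup_epochs <= max_epochs, "warmup_epochs must be <= max_epochs")
  structure(as.list(environment()), class = "schedule_config")
}

#' Tiny schedule preset for fast deterministic runs
#' @param ... Overrides passed to [schedule_config()].
#' @return A `schedule_config`.
#' @export
tiny_schedule_config <- function(...) {
  args <- list(peak_lr = 1e-3, warmup_epochs = 3, batch_size = 8,
               max_epochs = 30, dropout = 0)
  args[names(list(...))] <- list(...)
  do.call(schedule_config, args)
}

#' Learning rate at a given epoch and layer depth
#'
#' Linear warm-up from 0 to `peak_lr` over `warmup_epochs`, cosine decay to 0
#' afterwards; a layer `layer_index` levels below the output is scaled by
#' `layer_decay^layer_index`.
#'
#' @param epoch Epoch (may be fractional), `0 <= epoch < max_epochs`.
#' @param layer_index Depth from the top (0 = output layer).
#' @param cfg A [schedule_config()].
#' @return Learning rate.
#' @export
lr_at <- function(epoch, layer_index, cfg) {
  stop_if_not(epoch >= 0 && epoch <= cfg$max_epochs, "epoch out of range")
  base <- if (epoch < cfg$warmup_epochs) {
    cfg$peak_lr * epoch / cfg$warmup_epochs
  } else if (cfg$max_epochs == cfg$warmup_epochs) {
    cfg$peak_lr
  } else {
    t <- (epoch - cfg$warmup_epochs) / (cfg$max_epochs - cfg$warmup_epochs)
    cfg$peak_lr * 0.5 * (1 + cos(pi * t))
  }
  base * cfg$layer_decay^layer_index
}

# encode with an explicit (embed, encoder) parameter pair — used for the
# momentum branch, which shares the architecture but not the parameter objects
encode_with <- function(tokens, enc_blocks, cfg) {
  H <- tokens
  for (b in seq_along(enc_blocks)) {
    H <- afta_block_fwd(H, enc_blocks[[b]], cfg, train = FALSE)$out
  }
  H
}

# --- one pretraining forward/backward pass over a single epoch ----------------

pretrain_step_sample <- function(grid, mask, params, mparams, cfg, step_seed) {
  dm <- cfg$d_model
  seqf <- embed_tokens(grid, mask, params$embed)
  n_patch <- grid$C * grid$n_time
  n_sum <- cfg$n_summary
  unmasked_rows <- slot_index(mask$M_bar_idx[, "i"], mask$M_bar_idx[, "j"],
                              grid$n_time)
  masked_rows <- slot_index(mask$M_idx[, "i"], mask$M_idx[, "j"], grid$n_time)
  sum_rows <- (n_patch + 1):(n_patch + n_sum)
  enc_in <- seqf$tokens[c(unmasked_rows, sum_rows), , drop = FALSE]

  caches <- vector("list", length(params$encoder))
  H <- enc_in
  for (b in seq_along(params$encoder)) {
    r <- afta_block_fwd(H, params$encoder[[b]], cfg, train = TRUE)
    H <- r$out
    caches[[b]] <- r$cache
  }
  enc_out <- H
  n_unm <- length(unmasked_rows)

  grads <- tree_zeros_like(params)
  n_mask <- nrow(mask$M_idx)
  if (n_mask == 0) {
    return(list(L_R = 0, L_A = 0, grads = grads))
  }

  # predictor queries: positional identity of each masked slot
  em <- params$embed
  queries <- em$zeta[mask$M_idx[, "i"], , drop = FALSE] +
    em$pi[mask$M_idx[, "j"], , drop = FALSE] +
    matrix(em$mask_token, n_mask, dm, byrow = TRUE)
  predr <- predict_masked_fwd(queries, enc_out, params$predictor, cfg$n_heads, cfg)
  pred <- predr$out

  # momentum targets: full unmasked embedding through the momentum branch
  seqm <- embed_tokens(grid, NULL, mparams$embed)
  menc_full <- encode_with(seqm$tokens, mparams$encoder, cfg)
  tgt <- layernorm_plain(menc_full[masked_rows, , drop = FALSE])
  resid_a <- pred - tgt
  L_A <- mean(rowSums(resid_a^2))

  # reconstructor over the full grid
  model_like <- list(cfg = cfg, params = params)
  z <- assemble_rec_input(enc_out, pred, mask, model_like)
  recr <- reconstruct_fwd(z$Z0, params$reconstructor, cfg, train = TRUE)
  rec <- recr$out[z$masked_rows, , drop = FALSE]
  p_true <- seqf$P[z$masked_rows, , drop = FALSE]
  resid_r <- rec - p_true
  L_R <- mean(rowSums(resid_r^2))

  # ---- backward ----
  dRec_full <- matrix(0, n_patch, grid$d)
  dRec_full[z$masked_rows, ] <- 2 * resid_r / n_mask
  rb <- reconstruct_bwd(dRec_full, recr$cache)
  grads$reconstructor <- rb$grads

  dZ0 <- rb$dZ0
  # positional identities in Z0: zeta_i + pi_j over all grid slots
  grads$embed$zeta <- grads$embed$zeta + rowsum(dZ0, group = z$ii)
  grads$embed$pi <- grads$embed$pi + rowsum_by_j(dZ0, z$jj, grid$n_time)
  dPred <- dZ0[z$masked_rows, , drop = FALSE] + 2 * resid_a / n_mask
  dEnc <- matrix(0, nrow(enc_out), dm)
  if (n_unm > 0) {
    dEnc[seq_len(n_unm), ] <- dZ0[z$unmasked_rows, , drop = FALSE]
  }

  pb <- predict_masked_bwd(dPred, predr$cache)
  grads$predictor <- pb$grads
  dEnc <- dEnc + pb$dEnc
  # query gradients flow to zeta, pi, mask_token
  grads$embed$zeta <- grads$embed$zeta +
    rowsum_by_j(pb$dQ, mask$M_idx[, "i"], grid$C)
  grads$embed$pi <- grads$embed$pi +
    rowsum_by_j(pb$dQ, mask$M_idx[, "j"], grid$n_time)
  grads$embed$mask_token <- grads$embed$mask_token + colSums(pb$dQ)

  ebk <- encode_bwd(dEnc, caches)
  grads$encoder <- ebk$grads
  dfull <- matrix(0, n_patch + n_sum, dm)
  dfull[c(unmasked_rows, sum_rows), ] <- ebk$dH
  embg <- embed_backward(dfull, seqf)
  grads$embed <- tree_map2(`+`, grads$embed, embg)

  # threshold regularizer lambda * theta^2 per block
  for (b in seq_along(params$encoder)) {
    grads$encoder[[b]]$bank$theta <- grads$encoder[[b]]$bank$theta +
      2 * cfg$lambda_theta * params$encoder[[b]]$bank$theta
  }
  list(L_R = L_R, L_A = L_A, grads = grads)
}

# rowsum with guaranteed output rows 1..n_groups (rowsum drops absent groups)
rowsum_by_j <- function(x, groups, n_groups) {
  out <- matrix(0, n_groups, ncol(x))
  rs <- rowsum(x, group = groups)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

#' Self-supervised masked-reconstruction pretraining
#'
#' Per step: sample a dual-ratio mask, embed, encode the unmasked tokens,
#' predict masked-slot features, compute momentum-encoder targets, reconstruct
#' masked patches, minimize `L = L_A + L_R` (plus the threshold regularizer)
#' with AdamW under the warm-up/cosine schedule, then update the momentum
#' encoder. Fully deterministic for a fixed seed.
#'
#' @param dataset A `labeled_epoch_set` or list of `epoch_tensor` objects.
#' @param model_cfg A [model_config()].
#' @param sched_cfg A [schedule_config()].
#' @param n_steps Number of optimizer steps.
#' @param seed Integer seed.
#' @return List with the trained `model`, momentum parameters, and a `trace`
#'   data frame of per-step `L_R`, `L_A`, `L`, and learning rate.
#' @export
pretrain <- function(dataset, model_cfg, sched_cfg, n_steps = 300, seed = 1L) {
  epochs <- if (inherits(dataset, "labeled_epoch_set")) dataset$epochs else dataset
  stop_if_not(length(epochs) >= 1, "dataset must contain epochs")
  d <- model_cfg$patch_len
  grids <- lapply(epochs, partition_patches, d = d)
  C <- grids[[1]]$C
  n_time <- grids[[1]]$n_time
  model <- init_afta_model(model_cfg, C, n_time, seed = seed)
  trainable <- model$params
  mparams <- list(embed = trainable$embed, encoder = trainable$encoder)
  opt <- adam_init(trainable)
  trace <- data.frame(step = seq_len(n_steps), L_R = NA_real_, L_A = NA_real_,
                      L = NA_real_, lr = NA_real_)
  tr <- sched_cfg$mask_ratios[1]
  cr <- sched_cfg$mask_ratios[2]
  with_seed(seed, {
    for (step in seq_len(n_steps)) {
      idx <- sample.int(length(grids), min(sched_cfg$batch_size, length(grids)))
      acc <- NULL
      L_R <- 0
      L_A <- 0
      for (s in idx) {
        mask <- sample_mask(n_time, C, tr, cr,
                            seed = sample.int(.Machine$integer.max, 1))
        r <- pretrain_step_sample(grids[[s]], mask, trainable, mparams,
                                  model_cfg, step)
        L_R <- L_R + r$L_R / length(idx)
        L_A <- L_A + r$L_A / length(idx)
        acc <- if (is.null(acc)) r$grads else tree_map2(`+`, acc, r$grads)
      }
      acc <- tree_map(function(g) g / length(idx), acc)
      epoch_equiv <- (step - 1) / n_steps * sched_cfg$max_epochs
      lr <- lr_at(epoch_equiv, 0, sched_cfg)
      st <- adam_step(trainable, acc, opt, lr,
                      weight_decay = sched_cfg$weight_decay)
      trainable <- st$params
      opt <- st$state
      mparams <- momentum_update(list(embed = trainable$embed,
                                      encoder = trainable$encoder),
                                 mparams, model_cfg$momentum)
      L <- L_A + L_R
      if (!is.finite(L)) {
        stop(sprintf("loss diverged (NaN/Inf) at step %d", step), call. = FALSE)
      }
      trace$L_R[step] <- L_R
      trace$L_A[step] <- L_A
      trace$L[step] <- L
      trace$lr[step] <- lr
    }
  })
  model$params <- trainable
  list(model = model, momentum_params = mparams, trace = trace)
}

# forward pass for classification fine-tuning: full unmasked sequence ->
# encoder -> mean summary features -> linear head -> softmax
classify_forward <- function(grid, params, cfg, train = FALSE) {
  seqf <- embed_tokens(grid, NULL, params$embed)
  caches <- vector("list", length(params$encoder))
  H <- seqf$tokens
  for (b in seq_along(params$encoder)) {
    r <- afta_block_fwd(H, params$encoder[[b]], cfg, train)
    H <- r$out
    caches[[b]] <- r$cache
  }
  n_patch <- grid$C * grid$n_time
  sum_rows <- (n_patch + 1):(n_patch + cfg$n_summary)
  feat <- colMeans(H[sum_rows, , drop = FALSE])
  z <- as.numeric(feat %*% params$head$W + params$head$b)
  e <- exp(z - max(z))
  probs <- e / sum(e)
  list(probs = probs, feat = feat, seqf = seqf, caches = caches,
       sum_rows = sum_rows, n_tokens = nrow(H))
}

classify_backward <- function(fw, y_true, params, cfg, freeze_encoder) {
  dlogits <- fw$probs
  dlogits[y_true] <- dlogits[y_true] - 1
  grads <- tree_zeros_like(params)
  grads$head$W <- outer(fw$feat, dlogits)
  grads$head$b <- dlogits
  if (!freeze_encoder) {
    dfeat <- as.numeric(params$head$W %*% dlogits)
    dH <- matrix(0, fw$n_tokens, cfg$d_model)
    dH[fw$sum_rows, ] <- matrix(dfeat / length(fw$sum_rows),
                                length(fw$sum_rows), cfg$d_model, byrow = TRUE)
    ebk <- encode_bwd(dH, fw$caches)
    grads$encoder <- ebk$grads
    embg <- embed_backward(ebk$dH, fw$seqf)
    grads$embed <- embg
    for (b in seq_along(params$encoder)) {
      grads$encoder[[b]]$bank$theta <- grads$encoder[[b]]$bank$theta +
        2 * cfg$lambda_theta * params$encoder[[b]]$bank$theta
    }
  }
  grads
}

#' Fine-tune a pretrained model on a labeled epoch set
#'
#' Splits the data into stratified train/held-out parts, attaches a
#' classification (cross-entropy, plus the adaptive-threshold regularizer) or
#' prediction (MSE) head, trains with AdamW under layer-wise learning-rate
#' decay, and reports held-out metrics.
#'
#' @param model A pretrained `afta_model` (e.g. from [pretrain()]).
#' @param labeled A `labeled_epoch_set` (integer labels for `"classify"`,
#'   numeric targets allowed for `"predict"`).
#' @param task `"classify"` or `"predict"`.
#' @param sched_cfg A [schedule_config()].
#' @param n_epochs Training epochs over the labeled set.
#' @param val_frac Held-out fraction (stratified for classification).
#' @param freeze_encoder Train only the head.
#' @param seed Integer seed.
#' @return List with the fine-tuned `model`, a `metrics_report` (classification)
#'   or held-out MSE (prediction), held-out indices/scores, and the loss
#'   history.
#' @export
finetune <- function(model, labeled, task = c("classify", "predict"),
                     sched_cfg = tiny_schedule_config(), n_epochs = 5,
                     val_frac = 0.25, freeze_encoder = FALSE, seed = 1L) {
  task <- match.arg(task)
  stop_if_not(inherits(labeled, "labeled_epoch_set"),
              "labeled must be a labeled_epoch_set")
  grids <- lapply(labeled$epochs, partition_patches, d = model$cfg$patch_len)
  stop_if_not(grids[[1]]$C == model$C && grids[[1]]$n_time == model$n_time,
              "labeled data shape incompatible with the model checkpoint")
  labels <- labeled$labels
  n_classes <- length(labeled$class_names)
  if (task == "classify") {
    stop_if_not(all(labels == round(labels)) && all(labels >= 1),
                "classification requires integer class labels")
  }
  cfg <- model$cfg
  params <- model$params
  # attach a fresh head
  params$head <- with_seed(seed + 1L, {
    n_out <- if (task == "classify") n_classes else 1L
    list(W = init_mat(cfg$d_model, n_out), b = numeric(n_out))
  })

  # stratified split
  split <- with_seed(seed + 2L, {
    val <- integer(0)
    if (task == "classify") {
      for (k in unique(labels)) {
        idx <- which(labels == k)
        val <- c(val, sample(idx, max(1, round(val_frac * length(idx)))))
      }
    } else {
      val <- sample(seq_along(labels), max(1, round(val_frac * length(labels))))
    }
    sort(val)
  })
  train_idx <- setdiff(seq_along(labels), split)

  opt <- adam_init(params)
  history <- numeric(0)
  n_layers <- length(params$encoder)
  # depth-from-top multipliers: head 0, top block 1, ..., embedding deepest
  group_depth <- list(head = 0,
                      encoder = seq(n_layers, 1),
                      embed = n_layers + 1)
  with_seed(seed, {
    for (ep in seq_len(n_epochs)) {
      order_idx <- sample(train_idx)
      batches <- split(order_idx,
                       ceiling(seq_along(order_idx) / sched_cfg$batch_size))
      for (bt in batches) {
        acc <- NULL
        loss <- 0
        for (s in bt) {
          fw <- classify_forward(grids[[s]], params, cfg,
                                 train = !freeze_encoder)
          if (task == "classify") {
            loss <- loss + loss_classification(labels[s], fw$probs) / length(bt)
            g <- classify_backward(fw, labels[s], params, cfg, freeze_encoder)
          } else {
            yhat <- sum(fw$feat * params$head$W[, 1]) + params$head$b[1]
            r <- yhat - labels[s]
            loss <- loss + r^2 / length(bt)
            g <- tree_zeros_like(params)
            g$head$W[, 1] <- 2 * r * fw$feat
            g$head$b[1] <- 2 * r
          }
          acc <- if (is.null(acc)) g else tree_map2(`+`, acc, g)
        }
        acc <- tree_map(function(x) x / length(bt), acc)
        epoch_equiv <- (ep - 1) * sched_cfg$max_epochs / n_epochs
        # per-group layer-decayed learning rates
        for (grp in c("head", "embed")) {
          lr <- lr_at(min(epoch_equiv + 1, sched_cfg$max_epochs),
                      group_depth[[grp]], sched_cfg)
          if (grp != "head" && freeze_encoder) next
          st <- adam_step(params[[grp]], acc[[grp]], sub_state(opt, grp), lr,
                          weight_decay = sched_cfg$weight_decay)
          params[[grp]] <- st$params
          opt <- set_sub_state(opt, grp, st$state)
        }
        if (!freeze_encoder) {
          for (b in seq_len(n_layers)) {
            lr <- lr_at(min(epoch_equiv + 1, sched_cfg$max_epochs),
                        group_depth$encoder[b], sched_cfg)
            st <- adam_step(params$encoder[[b]], acc$encoder[[b]],
                            sub_state2(opt, "encoder", b), lr,
                            weight_decay = sched_cfg$weight_decay)
            params$encoder[[b]] <- st$params
            opt <- set_sub_state2(opt, "encoder", b, st$state)
          }
        }
        history <- c(history, loss)
      }
    }
  })
  model$params <- params
  model$n_classes <- if (task == "classify") n_classes else NULL

  # held-out evaluation
  if (task == "classify") {
    probs <- t(vapply(split, function(s) {
      classify_forward(grids[[s]], params, cfg, train = FALSE)$probs
    }, numeric(n_classes)))
    preds <- max.col(probs)
    scores <- if (n_classes == 2) probs[, 2] else NULL
    report <- metrics_report(labels[split], preds, n_classes, scores = scores)
    list(model = model, report = report, val_idx = split, scores = scores,
         probs = probs, history = history)
  } else {
    yhat <- vapply(split, function(s) {
      fw <- classify_forward(grids[[s]], params, cfg, train = FALSE)
      sum(fw$feat * params$head$W[, 1]) + params$head$b[1]
    }, numeric(1))
    list(model = model, val_mse = mean((labels[split] - yhat)^2),
         val_idx = split, history = history)
  }
}

# optimizer-state subsetting helpers (state trees mirror the parameter tree)
sub_state <- function(opt, grp) {
  list(m = opt$m[[grp]], v = opt$v[[grp]], t = opt$t)
}
set_sub_state <- function(opt, grp, st) {
  opt$m[[grp]] <- st$m; opt$v[[grp]] <- st$v; opt$t <- st$t
  opt
}
sub_state2 <- function(opt, grp, b) {
  list(m = opt$m[[grp]][[b]], v = opt$v[[grp]][[b]], t = opt$t)
}
set_sub_state2 <- function(opt, grp, b, st) {
  opt$m[[grp]][[b]] <- st$m; opt$v[[grp]][[b]] <- st$v; opt$t <- st$t
  opt
}

#' Evaluate a fine-tuned classification model on a labeled set
#'
#' @param model A fine-tuned `afta_model` with a classification head.
#' @param labeled A `labeled_epoch_set`.
#' @return A `metrics_report`.
#' @export
evaluate_model <- function(model, labeled) {
  stop_if_not(!is.null(model$params$head), "model has no task head")
  grids <- lapply(labeled$epochs, partition_patches, d = model$cfg$patch_len)
  n_classes <- length(labeled$class_names)
  probs <- t(vapply(grids, function(g) {
    classify_forward(g, model$params, model$cfg, train = FALSE)$probs
  }, numeric(n_classes)))
  preds <- max.col(probs)
  scores <- if (n_classes == 2) probs[, 2] else NULL
  metrics_report(labeled$labels, preds, n_classes, scores = scores)
}

#' Evaluate masked-patch reconstruction against a predict-the-mean baseline
#'
#' Draws a seeded mask per epoch, runs the eval-mode encode/predict/reconstruct
#' path, and returns the per-patch reconstruction loss alongside the loss of
#' predicting the global mean of the masked patch values (i.e. their variance
#' times the patch length).
#'
#' @param model A pretrained `afta_model`.
#' @param epochs List of `epoch_tensor` objects.
#' @param seed0 Base seed; epoch `i` uses mask seed `seed0 + i`.
#' @return Named vector with `L_R` and `baseline` (both mean per-patch squared
#'   norms).
#' @export
eval_reconstruction <- function(model, epochs, seed0 = 1000L) {
  cfg <- model$cfg
  tot <- 0
  base <- 0
  m <- 0
  for (i in seq_along(epochs)) {
    g <- partition_patches(epochs[[i]], cfg$patch_len)
    mask <- sample_mask(g$n_time, g$C, cfg$time_mask_ratio,
                        cfg$channel_mask_ratio, seed = seed0 + i)
    if (nrow(mask$M_idx) == 0) next
    seqf <- embed_tokens(g, mask, model$params$embed)
    u <- slot_index(mask$M_bar_idx[, "i"], mask$M_bar_idx[, "j"], g$n_time)
    sr <- (g$C * g$n_time + 1):(g$C * g$n_time + cfg$n_summary)
    enc <- encode(seqf$tokens[c(u, sr), , drop = FALSE], model)$out
    pred <- predict_masked(enc, mask, model)
    rec <- reconstruct(enc, pred, mask, model)
    mrows <- slot_index(mask$M_idx[, "i"], mask$M_idx[, "j"], g$n_time)
    p_true <- seqf$P[mrows, , drop = FALSE]
    tot <- tot + sum((rec - p_true)^2)
    base <- base + sum((p_true - mean(p_true))^2)
    m <- m + nrow(p_true)
  }
  c(L_R = tot / m, baseline = base / m)
}

#' Save / load a model checkpoint
#'
#' Single-file checkpoint holding the parameter tree, a config echo, and an
#' epoch/step counter.
#'
#' @param model An `afta_model`.
#' @param path Checkpoint path.
#' @param extra Optional named list stored alongside (e.g. trace, counters).
#' @return `path` invisibly / the restored `afta_model`.
#' @export
save_checkpoint <- function(model, path, extra = list()) {
  saveRDS(list(model = model, extra = extra, version = 1L), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  ck$model
}
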