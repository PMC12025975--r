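test_that("forward FFT satisfies the Fourier contracts", {
  const <- forward_fft(rep(3, 16))
  expect_equal(const$P[1], (3 * 16)^2)
  expect_true(all(const$P[-1] < 1e-20))

  # pure bin-k cosine concentrates at bin k (+ its conjugate)
  n <- 32; k <- 5
  x <- cos(2 * pi * k * (0:(n - 1)) / n)
  sp <- forward_fft(x)
  expect_equal(which.max(sp$P), k + 1)

  # Parseval: sum |x|^2 = (1/N) sum |F|^2
  set.seed(1)
  y <- rnorm(64)
  spy <- forward_fft(y)
  expect_equal(sum(y^2), sum(Mod(spy$F)^2) / 64, tolerance = 1e-8)

  expect_error(forward_fft(c(1, NA, 2)), "finite")
})

test_that("filter gains are sigmoid products in (0,1), monotone in weights", {
  bk <- filter_bank(n_bins_ref = 9, local_cutoff = 0)
  g0 <- filter_gains(bk, 9)
  expect_equal(g0$G, rep(0.25, 9))           # sigma(0)^2 everywhere

  bk$W_global <- rep(30, 9); bk$W_local <- rep(30, 9)
  expect_equal(filter_gains(bk, 9)$G, rep(1, 9), tolerance = 1e-10)

  # monotone non-decreasing in each weight
  bk2 <- filter_bank(n_bins_ref = 5, local_cutoff = 0)
  g_lo <- filter_gains(bk2, 5)$G
  bk2$W_global[3] <- 1
  g_hi <- filter_gains(bk2, 5)$G
  expect_true(all(g_hi >= g_lo))

  # local filter is identity below the cutoff
  bk3 <- filter_bank(n_bins_ref = 9, local_cutoff = 0.5)
  bk3$W_local <- rep(-5, 9)
  gl <- filter_gains(bk3, 9)$G_local
  expect_true(all(gl[1:4] == 1))
  expect_true(all(gl[5:9] < 0.01))
})

test_that("adaptive mask matches the direct arithmetic oracle", {
  expect_equal(adaptive_mask(c(0, 4, 1, 1), theta = 2, epsilon = 1e-12),
               c(0, 1, 0, 0))
  expect_equal(adaptive_mask(c(1, 1, 1, 1), theta = 0.5), rep(1, 4))
  expect_equal(adaptive_mask(runif(8) + 1, theta = -1), rep(1, 8))

  # soft mode is the sigmoid relaxation
  P <- c(0, 4, 1, 1)
  soft <- adaptive_mask(P, theta = 2, temperature = 0.1, mode = "soft")
  r <- P / (median(P) + 1e-12)
  expect_equal(soft, 1 / (1 + exp(-(r - 2) / 0.1)))
  expect_error(adaptive_mask(numeric(0), 1), "empty")
})

test_that("apply_filter is the elementwise masked product and linear in F", {
  set.seed(2)
  x <- rnorm(24)
  sp <- forward_fft(x)
  ident <- apply_filter(sp, rep(1, sp$n_bins), rep(1, sp$n_bins))
  expect_equal(ident$F_hat, sp$F)
  zero <- apply_filter(sp, rep(0, sp$n_bins), rep(1, sp$n_bins))
  expect_true(all(Mod(zero$F_hat) == 0))

  m <- runif(sp$n_bins); g <- runif(sp$n_bins)
  y <- rnorm(24)
  spy <- forward_fft(y)
  spxy <- forward_fft(2 * x + 3 * y)
  lhs <- apply_filter(spxy, m, g)$F_hat
  rhs <- 2 * apply_filter(sp, m, g)$F_hat + 3 * apply_filter(spy, m, g)$F_hat
  expect_equal(lhs, rhs, tolerance = 1e-10)
  expect_error(apply_filter(sp, m[-1], g), "length")
})

test_that("inverse and fuse: identity at alpha 1, round trip at unit filter", {
  set.seed(3)
  x <- rnorm(40)
  sp <- apply_filter(forward_fft(x), rep(1, 21), rep(1, 21))
  expect_identical(inverse_and_fuse(sp, x, 1), x)
  expect_equal(inverse_and_fuse(sp, x, 0), x, tolerance = 1e-8)

  # IFFT(FFT(x)) = x for random x
  for (n in c(7, 16, 33)) {
    z <- rnorm(n)
    spz <- forward_fft(z)
    expect_equal(Re(fft(spz$F, inverse = TRUE)) / n, z, tolerance = 1e-8)
  }
})

test_that("affm_forward: shape, bypass, linearity, energy non-expansion", {
  set.seed(4)
  H <- matrix(rnorm(20 * 6), 20, 6)
  bk <- filter_bank(n_bins_ref = 6)
  bk$W_global <- rnorm(6); bk$W_local <- rnorm(6)

  out <- affm_forward(H, bk, mode = "soft")
  expect_equal(dim(out$out), dim(H))
  expect_length(out$gate, 20)

  # bypass: alpha -> 1 gives identity
  bk1 <- bk; bk1$alpha_raw <- 40
  expect_equal(affm_forward(H, bk1, mode = "soft")$out, H, tolerance = 1e-12)

  # with the data-dependent mask disabled (theta < 0 hard mask = all ones) and
  # fixed gains, the operator is linear
  bk2 <- bk; bk2$theta <- -1
  f <- function(M) affm_forward(M, bk2, mode = "hard")$out
  expect_equal(f(2.5 * H), 2.5 * f(H), tolerance = 1e-9)

  # energy non-expansion of the filtered signal (gains, mask in [0,1])
  alpha <- aftanet:::sigmoid(bk$alpha_raw)
  x_hat <- (affm_forward(H, bk, mode = "hard")$out - alpha * H) / (1 - alpha)
  expect_lte(sum(x_hat^2), sum(H^2) + 1e-9)

  expect_warning(affm_forward(matrix(1, 1, 3), bk), "degenerate")
})

test_that("all AFFM parameters receive exact gradients (finite differences)", {
  set.seed(5)
  n <- 10; dm <- 4
  H <- matrix(rnorm(n * dm), n, dm)
  Tgt <- matrix(rnorm(n * dm), n, dm)
  bk <- filter_bank(n_bins_ref = 5, temperature = 0.5)
  bk$W_global <- rnorm(5, sd = 0.3)
  bk$W_local <- rnorm(5, sd = 0.3)
  bk$theta <- 0.7
  bk$alpha_raw <- 0.2
  lossf <- function(bank) sum((affm_forward(H, bank, mode = "soft")$out - Tgt)^2)
  fw <- affm_forward(H, bk, mode = "soft")
  bw <- affm_backward(2 * (fw$out - Tgt), fw$cache)
  h <- 1e-6
  for (k in 1:5) {
    b2 <- bk; b2$W_global[k] <- b2$W_global[k] + h
    expect_equal((lossf(b2) - lossf(bk)) / h, bw$grads$W_global[k], tolerance = 1e-4)
    b2 <- bk; b2$W_local[k] <- b2$W_local[k] + h
    expect_equal((lossf(b2) - lossf(bk)) / h, bw$grads$W_local[k], tolerance = 1e-4)
  }
  b2 <- bk; b2$theta <- b2$theta + h
  expect_equal((lossf(b2) - lossf(bk)) / h, bw$grads$theta, tolerance = 1e-4)
  b2 <- bk; b2$alpha_raw <- b2$alpha_raw + h
  expect_equal((lossf(b2) - lossf(bk)) / h, bw$grads$alpha_raw, tolerance = 1e-4)
  expect_true(abs(bw$grads$theta) > 0)
  expect_true(any(abs(bw$grads$W_global) > 0))
  expect_true(any(abs(bw$grads$W_local) > 0))
  expect_true(abs(bw$grads$alpha_raw) > 0)

  # input gradient is exact under the hard mask (mask locally constant)
  fwh <- affm_forward(H, bk, mode = "hard")
  bwh <- affm_backward(2 * (fwh$out - Tgt), fwh$cache)
  lossh <- function(M) sum((affm_forward(M, bk, mode = "hard")$out - Tgt)^2)
  for (probe in list(c(1, 1), c(4, 2), c(10, 4))) {
    H2 <- H; H2[probe[1], probe[2]] <- H2[probe[1], probe[2]] + h
    expect_equal((lossh(H2) - lossh(H)) / h, bwh$dH[probe[1], probe[2]],
                 tolerance = 1e-4)
  }
})
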