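test_that("channel selection reorders rows and rejects missing labels", {
  rec <- generate_recording(list(), 4, 1, 64, noise_amp = 2, seed = 1)
  same <- select_channels(rec, rec$channel_names)
  expect_identical(same$data, rec$data)

  rev_order <- rev(rec$channel_names)
  rv <- select_channels(rec, rev_order)
  expect_identical(rv$data, rec$data[4:1, ])
  expect_identical(rv$channel_names, rev_order)

  sub <- select_channels(rec, c("CH3", "CH1"))
  expect_identical(sub$data, rec$data[c(3, 1), ])

  expect_error(select_channels(rec, c("CH1", "NOPE")), "NOPE")
})

test_that("notch attenuates 50 Hz by >= 20 dB and passband is preserved", {
  fs <- 200
  tt <- (0:(fs * 8 - 1)) / fs
  x50 <- sin(2 * pi * 50 * tt)
  x10 <- sin(2 * pi * 10 * tt)
  rec <- aftanet:::new_raw_recording(rbind(x50 + x10), fs)
  out <- bandpass_notch(rec, c(0.1, 75), 50)
  att_db <- 10 * log10(psd_at(rec$data[1, ], fs, 50) / psd_at(out$data[1, ], fs, 50))
  expect_gte(att_db, 20)
  # 10 Hz passband amplitude preserved within 10% (interior, away from edges)
  mid <- 200:1400
  expect_equal(max(abs(out$data[1, mid])), 1, tolerance = 0.1)

  # DC rejected by the 0.1 Hz high-pass
  dc <- aftanet:::new_raw_recording(matrix(5, 1, fs * 30), fs)
  dout <- bandpass_notch(dc, c(0.1, 75), 50)
  expect_lt(mean(abs(dout$data)), 0.05)

  expect_error(bandpass_notch(rec, c(75, 0.1), 50), "inverted")
})

test_that("filtering is linear and length-preserving", {
  fs <- 200
  set.seed(3)
  x <- matrix(rnorm(fs * 4), 1)
  y <- matrix(rnorm(fs * 4), 1)
  f <- function(m) bandpass_notch(aftanet:::new_raw_recording(m, fs),
                                  c(1, 40), 50)$data
  lhs <- f(2 * x + 3 * y)
  rhs <- 2 * f(x) + 3 * f(y)
  expect_equal(lhs, rhs, tolerance = 1e-6)
  expect_equal(ncol(lhs), fs * 4)
})

test_that("resampling meets the exact sample-count contract", {
  rec <- generate_recording(list(component_spec(10, amplitude = 10, channels = 1)),
                            1, 4, 256, noise_amp = 0, seed = 1)
  out <- resample_recording(rec, 200)
  expect_equal(ncol(out$data), 800L)     # 1024 * 200 / 256
  expect_equal(out$fs, 200)
  expect_equal(periodogram_peak_hz(out$data[1, ], 200), 10, tolerance = 0.25)

  ident <- resample_recording(rec, 256)
  expect_equal(ident$data, rec$data, tolerance = 1e-8)
})

test_that("epoching count, shape, and boundary behavior", {
  rec <- generate_recording(list(), 2, 60, 200, noise_amp = 1, seed = 1)
  eps <- epoch_recording(rec, 4)
  expect_length(eps, 15)
  expect_true(all(vapply(eps, function(e) all(dim(e$data) == c(2, 800)), logical(1))))

  short <- aftanet:::new_raw_recording(matrix(0, 2, 780), 200)
  expect_length(epoch_recording(short, 4), 0)

  # epoch count = floor(n / (win*fs)) exactly, and selection/epoching commute
  rec2 <- generate_recording(list(), 3, 10.5, 64, noise_amp = 2, seed = 5)
  eps2 <- epoch_recording(rec2, 2)
  expect_length(eps2, floor(ncol(rec2$data) / 128))
  sel_then_ep <- epoch_recording(select_channels(rec2, c("CH2", "CH1")), 2)
  ep_then_sel <- lapply(epoch_recording(rec2, 2), function(e) e$data[c(2, 1), ])
  for (i in seq_along(sel_then_ep)) {
    expect_identical(sel_then_ep[[i]]$data, ep_then_sel[[i]])
  }
})

test_that("augmentation is an identity at degenerate settings and seeded", {
  ep <- random_epoch(seed = 8)
  same <- augment_epoch(ep, p_reflect = 0, scale_range = c(1, 1), seed = 1)
  expect_identical(same$data, ep$data)

  a <- augment_epoch(ep, 0.5, c(0.8, 1.2), seed = 33)
  b <- augment_epoch(ep, 0.5, c(0.8, 1.2), seed = 33)
  expect_identical(a$data, b$data)

  # reflection is an involution
  refl <- augment_epoch(ep, 1, c(1, 1), seed = 1)
  refl2 <- augment_epoch(refl, 1, c(1, 1), seed = 1)
  expect_equal(refl2$data, ep$data)
})

test_that("class balancing subsamples the majority to the requested ratio", {
  specs <- separable_class_specs(2)
  ds <- generate_labeled_dataset(10, specs, fs = 64, win_s = 1, n_channels = 2,
                                 seed = 4)
  ds_imb <- aftanet:::new_labeled_epoch_set(ds$epochs[c(1:10, 11:12)],
                                            ds$labels[c(1:10, 11:12)],
                                            ds$class_names)
  bal <- balance_classes(ds_imb, ratio = 1, seed = 2)
  expect_equal(unname(tabulate(bal$labels, 2)), c(2L, 2L))

  # already balanced -> unchanged membership
  bal2 <- balance_classes(ds, ratio = 1, seed = 2)
  expect_identical(bal2$labels, ds$labels)

  b1 <- balance_classes(ds_imb, 1, seed = 9)
  b2 <- balance_classes(ds_imb, 1, seed = 9)
  expect_identical(b1$labels, b2$labels)

  empty <- aftanet:::new_labeled_epoch_set(ds$epochs[1:5], rep(1L, 5),
                                           ds$class_names)
  expect_error(balance_classes(empty), "no epochs")
})

test_that("the full preprocessing recipe composes", {
  rec <- generate_recording(list(component_spec(10, amplitude = 20, channels = 1)),
                            4, 12, 256, noise_amp = 3, seed = 6)
  rec <- inject_artifacts(rec, 50, 10, seed = 7)
  cfg <- preprocess_config(band = c(1, 40), notch = 50, target_fs = 200, win_s = 4)
  eps <- run_preprocess(rec, cfg)
  expect_length(eps, 3)
  expect_equal(dim(eps[[1]]$data), c(4L, 800L))
  expect_equal(eps[[1]]$fs, 200)
})
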