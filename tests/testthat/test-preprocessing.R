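test_that("register_rigid recovers known integer shifts exactly", {
  cfg <- regime_config(n_neurons = 3, duration_s = 5, seed = 11)
  tm <- spikes_to_traces(generate_spikes(cfg), gcamp_kernel(), cfg)
  nt <- ncol(tm)
  set.seed(7)
  shifts <- cbind(sample(-5:5, nt, TRUE), sample(-5:5, nt, TRUE))
  shifts[1, ] <- 0L
  mv <- render_movie(tm, canvas = c(48, 64), shifts = shifts)
  reg <- register_rigid(mv$movie, reference = 1)
  expect_identical(unname(reg$shifts), unname(shifts))
  expect_identical(unname(reg$correction), unname(-shifts))
  # already-aligned movie: all shifts zero
  mv0 <- render_movie(tm, canvas = c(48, 64))
  reg0 <- register_rigid(mv0$movie, reference = 1)
  expect_true(all(reg0$shifts == 0))
  # constant movie cannot be registered
  flat <- array(1, dim = c(3, 8, 8))
  expect_error(register_rigid(flat), "zero variance")
})

test_that("registration improves trace recovery on a drifting movie", {
  cfg <- regime_config(n_neurons = 4, duration_s = 10, seed = 21)
  tm <- spikes_to_traces(generate_spikes(cfg), gcamp_kernel(), cfg)
  nt <- ncol(tm)
  set.seed(3)
  shifts <- cbind(sample(-5:5, nt, TRUE), sample(-5:5, nt, TRUE))
  mv <- render_movie(tm, canvas = c(48, 64), shifts = shifts,
                     image_noise_sd = 1)
  reg <- register_rigid(mv$movie)
  r_reg <- mean(vapply(1:4, function(i)
    cor(extract_traces(reg, mv$label_mask, 7.8)[i, ], tm[i, ]), numeric(1)))
  r_raw <- mean(vapply(1:4, function(i)
    cor(extract_traces(mv$movie, mv$label_mask, 7.8)[i, ], tm[i, ]),
    numeric(1)))
  expect_gt(r_reg, r_raw)
  expect_gt(r_reg, 0.95)
})

test_that("extract_traces averages masks and validates labels", {
  # one ROI covering the whole frame -> frame means
  arr <- array(seq_len(3 * 4 * 5), dim = c(3, 4, 5))
  mask_all <- matrix(1L, 4, 5)
  tr <- extract_traces(arr, mask_all, frame_rate_hz = 1)
  expect_equal(as.numeric(tr[1, ]),
               vapply(1:3, function(t) mean(arr[t, , ]), numeric(1)))
  # two disjoint constant ROIs keep their values
  arr2 <- array(0, dim = c(2, 4, 4))
  arr2[, 1:2, ] <- 10; arr2[, 3:4, ] <- 20
  mask <- matrix(0L, 4, 4); mask[1, 1] <- 1L; mask[4, 1] <- 2L
  tr2 <- extract_traces(arr2, mask, frame_rate_hz = 1)
  expect_equal(unname(tr2[, 1]), c(10, 20))
  # a label with no pixels is an input error naming the label
  mask_gap <- matrix(0L, 4, 4); mask_gap[1, 1] <- 1L; mask_gap[2, 2] <- 3L
  expect_error(extract_traces(arr2, mask_gap, frame_rate_hz = 1), "2")
  # permutation equivariance in labels
  mask_b <- mask; mask_b[mask == 1L] <- 2L; mask_b[mask == 2L] <- 1L
  tr_b <- extract_traces(arr2, mask_b, frame_rate_hz = 1)
  expect_equal(unname(tr_b[, 1]), c(20, 10))
})

test_that("round trip movie -> traces preserves signals", {
  cfg <- regime_config(n_neurons = 5, duration_s = 15, seed = 31)
  tm <- spikes_to_traces(generate_spikes(cfg), gcamp_kernel(), cfg)
  mv <- render_movie(tm, canvas = c(48, 96))
  tr <- extract_traces(mv)
  for (i in 1:5) expect_gt(cor(tr[i, ], tm[i, ]), 0.999)
  # all-zero traces -> every frame identical
  tm0 <- trace_matrix(matrix(0, 2, 10), 7.8, scale = "dff")
  mv0 <- render_movie(tm0, canvas = c(32, 48))
  expect_equal(mv0$movie[1, , ], mv0$movie[10, , ])
  # too-close ROI centers are a configuration error
  geom <- data.frame(x = c(10, 12), y = c(10, 10), radius = 3)
  expect_error(render_movie(tm0, canvas = c(32, 48), roi_geometry = geom),
               "min_separation")
})

test_that("compute_dff identities and scale invariance hold", {
  fr <- 7.8
  const <- trace_matrix(matrix(100, 1, 80), fr, scale = "raw")
  expect_true(all(compute_dff(const, "global_median") == 0))

  x <- rep(100, 80); x[40] <- 150
  tm <- trace_matrix(matrix(x, 1), fr, scale = "raw")
  d <- compute_dff(tm, "global_median")
  expect_equal(as.numeric(d[1, 40]), 0.5)
  expect_equal(as.numeric(d[1, 1]), 0)

  # invariance to positive rescaling of the raw trace
  set.seed(4)
  raw <- matrix(100 + abs(rnorm(200)) * 10, 2, 100)
  t1 <- compute_dff(trace_matrix(raw, fr, scale = "raw"))
  t2 <- compute_dff(trace_matrix(raw * 3.7, fr, scale = "raw"))
  expect_equal(as.numeric(t1), as.numeric(t2), tolerance = 1e-12)

  # non-positive baseline is a numeric error naming the ROI
  bad <- trace_matrix(matrix(c(-5, rep(-5, 79)), 1), fr, scale = "raw",
                      roi_ids = "roi_9")
  expect_error(compute_dff(bad, "global_median"), "roi_9")
})

test_that("dff recovers generated peak amplitudes within 10%", {
  cfg <- regime_config(n_neurons = 4, duration_s = 30, noise_sd = 0,
                       amplitude_sd = 0, amplitude_mean = 1.5, seed = 8)
  gt <- generate_spikes(cfg)
  tm <- spikes_to_traces(gt, gcamp_kernel(), cfg)
  # raw fluorescence with known baseline F0, then invert with compute_dff
  f0 <- 200
  raw <- trace_matrix(f0 * (1 + unclass(as.matrix(tm))), frame_rate(tm),
                      scale = "raw")
  rec <- compute_dff(raw, "global_median")
  for (i in 1:4) {
    if (max(tm[i, ]) < 0.5) next    # skip ROIs without events
    expect_lt(abs(max(rec[i, ]) - max(tm[i, ])) / max(tm[i, ]), 0.1)
    expect_gt(cor(rec[i, ], tm[i, ]), 0.999)
  }
})

test_that("OIS response map applies the ratio-and-threshold rule", {
  base <- matrix(1, 4, 4)
  # uniform response: every pixel equals the max -> all pass
  m <- ois_response_map(list(matrix(2, 4, 4)), list(base))
  expect_true(all(m$binary))
  # values {2,1}: threshold 1.0 -> all pass; {3,1}: threshold 1.5 -> one
  r21 <- matrix(1, 4, 4); r21[2, 2] <- 2
  m21 <- ois_response_map(list(r21), list(base), threshold_frac = 0.5)
  expect_true(all(m21$binary))
  r31 <- matrix(1, 4, 4); r31[2, 2] <- 3
  m31 <- ois_response_map(list(r31), list(base), threshold_frac = 0.5)
  expect_identical(sum(m31$binary), 1L)
  expect_true(m31$binary[2, 2])
  # Gaussian spot: binary map = brute-force pixelwise threshold, and it is
  # the connected superlevel set around the peak
  g <- outer(dnorm(seq(-2, 2, length = 9)), dnorm(seq(-2, 2, length = 9)))
  mg <- ois_response_map(list(g + 1), list(matrix(1, 9, 9)))
  expect_identical(mg$binary, mg$continuous >= 0.5 * max(mg$continuous))
  expect_true(mg$binary[5, 5])
  # trials sum: two identical trials double the continuous map
  m2 <- ois_response_map(list(r31, r31), list(base, base))
  expect_equal(m2$continuous, 2 * m31$continuous)
  # zero baseline pixel is a numeric error
  b0 <- base; b0[1, 1] <- 0
  expect_error(ois_response_map(list(r31), list(b0)), "zero baseline")
})
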