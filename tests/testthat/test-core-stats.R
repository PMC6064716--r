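test_that("quietest period matches the exhaustive oracle", {
  # frame-count rule: 7.8 Hz, 10 s -> 78 frames
  x <- rnorm(200)
  qp <- find_quietest_period(x, 7.8, 10)
  expect_identical(qp$quiet_len, 78L)

  # constant trace: earliest window wins, sd 0
  qp0 <- find_quietest_period(rep(5, 50), 2, 10)
  expect_identical(qp0$quiet_start, 0L)
  expect_equal(qp0$sd, 0)

  # planted quiet segment is found and agrees with the brute-force scan
  set.seed(10)
  for (rep in 1:25) {
    x <- rnorm(400, sd = 1)
    x[200:300] <- rnorm(101, sd = 0.1)
    qp <- find_quietest_period(x, 7.8, 10)
    orc <- oracle_quietest(x, 78L)
    expect_identical(qp$quiet_start, orc$start0)
    expect_gte(qp$quiet_start, 199 - 1)
    expect_lte(qp$quiet_start + qp$quiet_len, 302)
  }
  expect_error(find_quietest_period(rnorm(10), 7.8, 10), "shorter than")
})

test_that("modified z-score standardizes the quiet window and is affine-invariant", {
  cfg <- regime_config(n_neurons = 6, seed = 13)
  tm <- spikes_to_traces(generate_spikes(cfg), gcamp_kernel(), cfg)
  z <- modified_zscore(tm)
  b <- attr(z, "baseline")
  for (i in seq_len(nrow(z))) {
    w <- z[i, (b$quiet_start[i] + 1):(b$quiet_start[i] + b$quiet_len[i])]
    expect_lt(abs(mean(w)), 1e-9)
    expect_lt(abs(sd(w) - 1), 1e-9)
  }
  # positive affine transform of the input leaves z unchanged
  tm2 <- trace_matrix(2.5 * unclass(as.matrix(tm)) + 0.7, frame_rate(tm),
                      scale = "dff")
  z2 <- modified_zscore(tm2)
  expect_equal(unclass(as.matrix(z)), unclass(as.matrix(z2)),
               tolerance = 1e-9)
})

test_that("modified z-score matches a hand computation on a toy trace", {
  # 8-frame trace; 3-frame quiet window chosen by hand: frames 3..5
  x <- c(5, 9, 2.0, 2.1, 2.2, 8, 1, 7)
  tm <- trace_matrix(matrix(x, 1), frame_rate_hz = 1, scale = "dff")
  z <- modified_zscore(tm, window_s = 3)
  m <- mean(c(2.0, 2.1, 2.2)); s <- sd(c(2.0, 2.1, 2.2))
  expect_equal(as.numeric(z[1, ]), (x - m) / s, tolerance = 1e-12)
  b <- attr(z, "baseline")
  expect_identical(b$quiet_start, 2L)
  expect_identical(b$quiet_len, 3L)
})

test_that("degenerate traces are dropped with a warning or raise", {
  x <- rbind(roi_1 = rnorm(100), roi_2 = rep(1, 100))
  tm <- trace_matrix(x, 7.8, scale = "dff")
  expect_warning(z <- modified_zscore(tm, window_s = 2), "roi_2")
  expect_identical(rownames(z), "roi_1")
  expect_error(modified_zscore(tm, window_s = 2, on_degenerate = "error"),
               "roi_2")
})

test_that("detect_epochs matches the run-length oracle", {
  # hand example: epochs [1,3) and [4,6)
  ep <- detect_epochs(c(0, 4, 5, 2, 3, 3, 1), threshold = 3)
  expect_equal(ep$start, c(1L, 4L))
  expect_equal(ep$end, c(3L, 6L))
  expect_equal(ep$peak_z, c(5, 3))
  expect_equal(ep$duration_frames, c(2L, 2L))

  # no crossings and all-crossings cases
  expect_identical(nrow(detect_epochs(c(0, 1, 2), threshold = 3)), 0L)
  ep_all <- detect_epochs(c(0, 1, 2), threshold = -Inf)
  expect_equal(nrow(ep_all), 1L)
  expect_equal(c(ep_all$start, ep_all$end), c(0L, 3L))

  # random traces vs the frame-by-frame oracle, incl. boundary maximality
  set.seed(20)
  for (rep in 1:200) {
    z <- rnorm(80, mean = 1.5, sd = 1.5)
    ep <- detect_epochs(z, threshold = 3)
    orc <- oracle_epochs(z, 3)
    expect_identical(nrow(ep), if (is.null(orc)) 0L else nrow(orc))
    if (nrow(ep)) {
      expect_identical(cbind(ep$start, ep$end), matrix(as.integer(orc), ncol = 2))
      for (j in seq_len(nrow(ep))) {
        expect_true(all(z[(ep$start[j] + 1):ep$end[j]] >= 3))
        if (ep$start[j] > 0) expect_lt(z[ep$start[j]], 3)
        if (ep$end[j] < length(z)) expect_lt(z[ep$end[j] + 1], 3)
      }
    }
  }
  # minimum duration filter
  z <- c(0, 4, 0, 4, 4, 0)
  expect_identical(nrow(detect_epochs(z, 3, min_duration_frames = 2)), 1L)
})

test_that("mean_z_in_range computes half-open means", {
  z <- trace_matrix(rbind(roi_1 = rep(2, 10), roi_2 = 1:10 * 1.0), 1,
                    scale = "zscore")
  expect_equal(unname(mean_z_in_range(z, c(0, 10))), c(2, 5.5))
  expect_equal(unname(mean_z_in_range(z, c(2, 4))["roi_2"]), 3.5)
  expect_error(mean_z_in_range(z, c(4, 4)), "empty")
  expect_error(mean_z_in_range(z, c(5, 12)), "outside")
})

test_that("evoked sessions show higher in-stimulus mean z for responders", {
  cfg <- quiet_cfg(77, n_neurons = 4)
  ev <- generate_evoked_session(cfg, responsive_set = 1:2,
                                response_prob = 1, seed = 77)
  z <- modified_zscore(ev$traces)
  stim <- stimulus_vector(ev$protocol, ncol(z), frame_rate(z))
  m_in <- rowMeans(z[, stim == 1, drop = FALSE])
  m_out <- rowMeans(z[, stim == 0, drop = FALSE])
  expect_true(all(m_in[c("roi_1", "roi_2")] > m_out[c("roi_1", "roi_2")]))
})

test_that("filter_active keeps exactly the ROIs with epochs at all stages", {
  ds <- generate_developmental_dataset(seed = 6, n_neurons = 10)
  # silence two known ROIs at the P30 stage
  silenced <- c("roi_4", "roi_9")
  p30 <- ds$stages$P30$spontaneous
  flat <- unclass(as.matrix(p30))
  set.seed(1)
  # bounded noise keeps z well below the epoch threshold for these ROIs
  flat[silenced, ] <- runif(2 * ncol(p30), -0.05, 0.05)
  ds$stages$P30$spontaneous <- trace_matrix(flat, frame_rate(p30),
                                            scale = "dff")
  active <- filter_active_across_sessions(ds)
  expect_false(any(silenced %in% active))
  # every retained ROI really has >= 1 epoch at every stage
  for (st in ds$stages) {
    ep <- detect_epochs(modified_zscore(st$spontaneous))
    expect_true(all(active %in% ep$roi_id))
  }
  # mismatched ROI spaces are an input error
  tabs <- lapply(ds$stages, function(st)
    detect_epochs(modified_zscore(st$spontaneous)))
  tabs[[1]]$roi_id[1] <- "alien_roi"
  expect_error(filter_active_across_sessions(tabs, roi_ids = ds$roi_ids),
               "mismatched")
})

test_that("AR(1) deconvolution inverts a matching exponential decay", {
  fr <- 7.8; tau <- 1.5
  g <- exp(-1 / (tau * fr))
  x <- numeric(100)
  x[20:100] <- 5 * g^(0:80)          # unit jump at frame 20 (1-based)
  d <- deconvolve(x, decay_tau_s = tau, frame_rate_hz = fr)
  expect_equal(d[20], 5, tolerance = 1e-12)
  expect_lt(max(d[-20]), 1e-10)
  expect_true(all(deconvolve(numeric(50), 1.5, fr) == 0))
  expect_true(all(d >= 0))
  expect_error(deconvolve(c(1, NA, 3), 1.5, fr), "non-finite")
})

test_that("deconvolution concentrates mass near events even with wrong tau", {
  cfg <- regime_config(n_neurons = 5, duration_s = 60, seed = 14)
  gt <- generate_spikes(cfg)
  tm <- spikes_to_traces(gt, gcamp_kernel(), cfg)
  z <- modified_zscore(tm)
  d <- deconvolve(z, decay_tau_s = 3.0)   # 2x the true decay
  hits <- 0; total <- 0
  for (i in seq_len(nrow(z))) {
    ev <- gt$event_frames[[rownames(z)[i]]]
    # only strong, well-separated events are scoreable
    ev <- ev[vapply(ev, function(f) max(z[i, min(f + 1:3, ncol(z))]) >= 5,
                    logical(1))]
    thr <- quantile(d[i, ], 0.9)
    for (f in ev) {
      total <- total + 1
      idx <- pmin(pmax(f + 0:3, 1), ncol(z))
      hits <- hits + (max(d[i, idx]) > thr)
    }
  }
  expect_gt(hits / total, 0.9)
})
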