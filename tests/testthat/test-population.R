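test_that("pairwise correlations match hand-computed values", {
  x <- rbind(a = c(1, 2, 3, 4, 5),
             b = c(2, 1, 4, 3, 6),
             c = c(5, 4, 3, 2, 1))
  pc <- pairwise_correlations(trace_matrix(x, 1, scale = "deconvolved"))
  expect_equal(pc$matrix["a", "b"], cor(x["a", ], x["b", ]), tolerance = 1e-12)
  expect_equal(pc$matrix["a", "c"], -1, tolerance = 1e-12)
  expect_equal(pc$n_pairs, 3L)
  expect_equal(pc$mean_pairwise,
               mean(c(cor(x[1, ], x[2, ]), cor(x[1, ], x[3, ]),
                      cor(x[2, ], x[3, ]))), tolerance = 1e-12)
  # symmetry and unit diagonal
  expect_equal(pc$matrix, t(pc$matrix))
  expect_equal(unname(diag(pc$matrix)), rep(1, 3))
})

test_that("synchronized and independent populations hit the correlation limits", {
  # identical nonconstant traces: all off-diagonal r exactly 1
  base <- sin(seq(0, 10, length.out = 200))
  sync <- trace_matrix(matrix(rep(base, 5), 5, byrow = TRUE), 1,
                       scale = "deconvolved")
  pc <- pairwise_correlations(sync)
  expect_equal(pc$mean_pairwise, 1, tolerance = 1e-12)
  # long independent noise traces: mean pairwise near zero
  set.seed(30)
  noise <- trace_matrix(matrix(rnorm(20 * 10000), 20), 1,
                        scale = "deconvolved")
  pcn <- pairwise_correlations(noise)
  expect_lt(abs(pcn$mean_pairwise), 0.02)
  # constant traces are dropped with a warning; error when < 2 remain
  bad <- trace_matrix(rbind(a = base, b = base * 2, c = rep(1, 200)), 1,
                      scale = "deconvolved")
  expect_warning(pcb <- pairwise_correlations(bad), "c")
  expect_identical(pcb$roi_ids, c("a", "b"))
  expect_error(suppressWarnings(
    pairwise_correlations(trace_matrix(rbind(a = base, b = rep(1, 200)), 1,
                                       scale = "deconvolved"))),
    "at least 2")
})

test_that("development summary is ordered and invariant to ROI relabeling", {
  ds <- generate_developmental_dataset(seed = 4, n_neurons = 12)
  s1 <- summarize_development(ds, n_scrambles = 50, seed = 2)
  expect_identical(s1$stage, c("P11", "P15", "P30"))
  expect_identical(names(s1), c("stage", "n_rois", "mean_pairwise",
                                "mean_spont_z", "mean_evoked_z",
                                "responsive_fraction"))
  expect_true(s1$mean_pairwise[1] > s1$mean_pairwise[2])
  expect_true(s1$mean_pairwise[2] > s1$mean_pairwise[3])

  # permuting ROI rows in every session leaves the summary unchanged
  ds2 <- ds
  set.seed(8)
  perm <- sample(length(ds$roi_ids))
  for (st in names(ds2$stages)) {
    for (kind in c("spontaneous", "evoked")) {
      tm <- ds2$stages[[st]][[kind]]
      ds2$stages[[st]][[kind]] <-
        trace_matrix(unclass(as.matrix(tm))[perm, ], frame_rate(tm),
                     scale = trace_scale(tm))
    }
  }
  s2 <- summarize_development(ds2, n_scrambles = 50, seed = 2)
  for (col in c("mean_pairwise", "mean_spont_z", "mean_evoked_z"))
    expect_equal(s2[[col]], s1[[col]], tolerance = 1e-9)
})

test_that("analyze_development returns a coherent fitted object", {
  ds <- generate_developmental_dataset(seed = 3, n_neurons = 10)
  fit <- analyze_development(ds, n_scrambles = 50, seed = 5)
  expect_s3_class(fit, "ca_development")
  expect_identical(names(coef(fit)), c("P11", "P15", "P30"))
  expect_equal(unname(coef(fit)), fit$summary$mean_pairwise)
  expect_s3_class(fit$friedman, "friedman_posthoc")
  expect_identical(nrow(fit$friedman$posthoc), 3L)
  expect_output(print(fit), "Developmental")
  f <- tempfile(fileext = ".png")
  grDevices::png(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f))
})

test_that("friedman omnibus agrees with stats::friedman.test and handles ties", {
  set.seed(40)
  m <- matrix(rnorm(18), 6, 3) + rep(c(0, 0.5, 1), each = 6)
  f <- friedman_with_posthoc(m)
  expect_equal(f$statistic, unname(friedman.test(m)$statistic),
               tolerance = 1e-12)
  # identical columns: statistic 0, p 1
  f0 <- friedman_with_posthoc(matrix(rep(1:5, 3), 5, 3))
  expect_equal(f0$statistic, 0)
  expect_equal(f0$p_value, 1)
  # Bonferroni: each pairwise p multiplied by 3 and capped at 1
  expect_equal(f$posthoc$p_adj, pmin(1, f$posthoc$p_raw * 3))
  expect_error(friedman_with_posthoc(matrix(c(1, NA, 2, 3, 4, 5), 3, 2)),
               "missing")
  expect_error(friedman_with_posthoc(matrix(1:3, 3, 1)), ">= 2")
})

test_that("exact friedman p matches an independent permutation enumeration", {
  # independent oracle: enumerate all within-row rank permutations directly
  oracle_exact_p <- function(m) {
    n <- nrow(m); k <- ncol(m)
    rk <- t(apply(m, 1, rank))
    A <- sum(rk^2); C <- n * k * (k + 1)^2 / 4
    stat_fn <- function(R) (k - 1) * sum((colSums(R) - n * (k + 1) / 2)^2) / (A - C)
    obs <- stat_fn(rk)
    perm3 <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                  c(3, 1, 2), c(3, 2, 1))
    idx <- as.matrix(expand.grid(rep(list(1:6), n)))
    stats_all <- apply(idx, 1, function(ch) {
      R <- t(vapply(seq_len(n), function(i) rk[i, perm3[[ch[i]]]],
                    numeric(k)))
      stat_fn(R)
    })
    mean(stats_all >= obs - 1e-9)
  }
  set.seed(41)
  for (rep in 1:3) {
    m <- matrix(rnorm(18), 6, 3) + rep(c(0, 0.4, 0.8), each = 6)
    f <- friedman_with_posthoc(m)
    expect_identical(f$method, "exact")
    expect_lt(abs(f$p_value - oracle_exact_p(m)), 0.01)
  }
})

test_that("rank bootstrap separates shifted groups and accepts identical ones", {
  set.seed(50)
  x <- rnorm(6)
  same <- rank_bootstrap_test(x, x, n_resamples = 2000, seed = 7)
  expect_gt(same$p_value, 0.9)
  # strongly shifted groups are detected across seeds
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    a <- rnorm(6); b <- rnorm(6, 3)
    p <- rank_bootstrap_test(a, b, n_resamples = 2000, seed = s)$p_value
    hits <- hits + (p < 0.01)
  }
  expect_gte(hits / 20, 0.95)
  expect_error(rank_bootstrap_test(1, c(1, 2)), "at least 2")
  # determinism given the seed
  a <- rnorm(6); b <- rnorm(6)
  r1 <- rank_bootstrap_test(a, b, seed = 3, n_resamples = 500)
  r2 <- rank_bootstrap_test(a, b, seed = 3, n_resamples = 500)
  expect_identical(r1$p_value, r2$p_value)
})
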