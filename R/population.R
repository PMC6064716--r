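#' Pairwise Pearson correlations of a population
#'
#' Full Pearson correlation matrix over ROIs (intended for deconvolved
#' traces) and its mean over the strict upper triangle, the package's
#' scalar measure of network synchrony.
#'
#' Constant traces have no defined correlation; by default they are dropped
#' with a warning (set `drop_constant = FALSE` to make them an error).
#'
#' @param traces a [trace_matrix()] (any scale; deconvolved spontaneous
#'   traces for the synchrony analysis) or numeric matrix roi x frame.
#' @param drop_constant drop zero-variance traces with a warning instead of
#'   erroring.
#' @return list of class `correlation_result`: `matrix` (symmetric, unit
#'   diagonal), `roi_ids`, `mean_pairwise`, `n_pairs`.
#' @export
pairwise_correlations <- function(traces, drop_constant = TRUE) {
  x <- unclass(traces)
  attr(x, "frame_rate_hz") <- NULL; attr(x, "scale") <- NULL
  if (!is.matrix(x)) stop("need a matrix of traces", call. = FALSE)
  sds <- apply(x, 1, stats::sd)
  if (any(sds < 1e-12)) {
    bad <- rownames(x)[sds < 1e-12] %||% which(sds < 1e-12)
    if (!drop_constant)
      stop("constant trace(s): ", paste(bad, collapse = ", "), call. = FALSE)
    warning("dropping constant trace(s): ", paste(bad, collapse = ", "),
            call. = FALSE)
    x <- x[sds >= 1e-12, , drop = FALSE]
  }
  if (nrow(x) < 2)
    stop("need at least 2 non-constant ROIs", call. = FALSE)
  m <- stats::cor(t(x))
  ut <- m[upper.tri(m)]
  structure(list(matrix = m,
                 roi_ids = rownames(x) %||% paste0("roi_", seq_len(nrow(x))),
                 mean_pairwise = mean(ut),
                 n_pairs = length(ut)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %d ROIs, %d pairs, mean pairwise r = %.4f\n",
              nrow(x$matrix), x$n_pairs, x$mean_pairwise))
  invisible(x)
}

#' Per-stage developmental summary
#'
#' For each stage of a longitudinal session set, restricted to the ROIs
#' active at every stage ([filter_active_across_sessions()]): mean pairwise
#' correlation of deconvolved spontaneous traces, mean spontaneous Z, mean
#' evoked Z within stimulation epochs, and the epoch-scramble bootstrap
#' responsive fraction.
#'
#' @param session_set a `session_set`.
#' @param window_s,threshold quietest-window and epoch parameters.
#' @param decay_tau_s deconvolution decay constant.
#' @param n_scrambles,alpha bootstrap parameters.
#' @param seed seed for the responsiveness bootstrap.
#' @param active_rois override the active-ROI subset (default: computed).
#' @return data frame of class `development_summary`, one row per stage,
#'   columns `stage`, `n_rois`, `mean_pairwise`, `mean_spont_z`,
#'   `mean_evoked_z`, `responsive_fraction`.
#' @export
summarize_development <- function(session_set, window_s = 10, threshold = 3,
                                  decay_tau_s = 1.5, n_scrambles = 1000,
                                  alpha = 0.05, seed = 1,
                                  active_rois = NULL) {
  stopifnot(inherits(session_set, "session_set"))
  active <- active_rois %||%
    filter_active_across_sessions(session_set, window_s = window_s,
                                  threshold = threshold)
  if (length(active) == 0)
    stop("no ROI is active at every stage", call. = FALSE)
  stages <- session_set$stages
  rows <- vector("list", length(stages))
  resp_tabs <- vector("list", length(stages))
  corr_res <- vector("list", length(stages))
  for (s in seq_along(stages)) {
    st <- stages[[s]]
    z_sp <- modified_zscore(st$spontaneous, window_s = window_s,
                            threshold = threshold)
    z_sp <- z_sp[rownames(z_sp) %in% active, , drop = FALSE]
    z_sp <- trace_matrix(z_sp, frame_rate(st$spontaneous), scale = "zscore")
    dec <- deconvolve(z_sp, decay_tau_s = decay_tau_s)
    pc <- pairwise_correlations(dec)

    z_ev_full <- modified_zscore(st$evoked, window_s = window_s,
                                 threshold = threshold)
    keep <- rownames(z_ev_full) %in% active
    z_ev <- trace_matrix(z_ev_full[keep, , drop = FALSE],
                         frame_rate(st$evoked), scale = "zscore")
    attr(z_ev, "threshold") <- threshold
    stim <- stimulus_vector(st$protocol, ncol(z_ev), frame_rate(st$evoked))
    stim_frames <- which(stim == 1L)
    mean_ev <- mean(rowMeans(z_ev[, stim_frames, drop = FALSE]))
    resp <- bootstrap_responsiveness(z_ev, st$protocol,
                                     n_scrambles = n_scrambles,
                                     alpha = alpha,
                                     seed = split_seed(seed, s))
    rows[[s]] <- data.frame(
      stage = names(stages)[s],
      n_rois = nrow(z_sp),
      mean_pairwise = pc$mean_pairwise,
      mean_spont_z = mean(rowMeans(z_sp)),
      mean_evoked_z = mean_ev,
      responsive_fraction = responsive_fraction(resp),
      stringsAsFactors = FALSE)
    resp_tabs[[s]] <- resp
    corr_res[[s]] <- pc
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("development_summary", "data.frame")
  attr(out, "active_rois") <- active
  attr(out, "responsiveness") <- stats::setNames(resp_tabs, names(stages))
  attr(out, "correlations") <- stats::setNames(corr_res, names(stages))
  out
}

#' @export
print.development_summary <- function(x, ...) {
  cat(sprintf("<development_summary> %d stages, %d shared active ROIs\n",
              nrow(x), length(attr(x, "active_rois"))))
  print.data.frame(as.data.frame(x), digits = 3)
  invisible(x)
}

#' Fit the full developmental desynchronization analysis
#'
#' The package's main entry point: runs Z-scoring, epoch detection, the
#' active-ROI filter, deconvolved pairwise correlations, the epoch-scramble
#' responsiveness bootstrap and the Friedman omnibus over per-ROI mean
#' correlations, on a longitudinal session set.
#'
#' @inheritParams summarize_development
#' @return object of class `ca_development` with components `summary` (the
#'   [summarize_development()] table), `correlations`, `responsiveness`,
#'   `active_rois`, `friedman` (omnibus + post-hoc over per-ROI mean
#'   pairwise correlations, when >= 2 stages and >= 2 ROIs), `params`,
#'   `call`. Has `print`, `summary`, `coef` and `plot` methods; `coef`
#'   returns the per-stage mean pairwise correlations.
#' @examples
#' \donttest{
#' ds <- generate_developmental_dataset(seed = 1, n_neurons = 12)
#' fit <- analyze_development(ds, n_scrambles = 100)
#' fit
#' coef(fit)
#' }
#' @export
analyze_development <- function(session_set, window_s = 10, threshold = 3,
                                decay_tau_s = 1.5, n_scrambles = 1000,
                                alpha = 0.05, seed = 1) {
  summ <- summarize_development(session_set, window_s = window_s,
                                threshold = threshold,
                                decay_tau_s = decay_tau_s,
                                n_scrambles = n_scrambles, alpha = alpha,
                                seed = seed)
  corr <- attr(summ, "correlations")
  # per-ROI mean correlation with the rest of the population, per stage:
  # the related-samples matrix for the Friedman omnibus
  active <- attr(summ, "active_rois")
  fr_mat <- NULL; fried <- NULL
  if (length(corr) >= 2 && length(active) >= 2) {
    fr_mat <- vapply(corr, function(pc) {
      m <- pc$matrix; diag(m) <- NA
      rowMeans(m, na.rm = TRUE)[active]
    }, numeric(length(active)))
    fried <- friedman_with_posthoc(fr_mat)
  }
  structure(list(summary = summ, correlations = corr,
                 responsiveness = attr(summ, "responsiveness"),
                 active_rois = active,
                 friedman = fried, roi_correlation_matrix = fr_mat,
                 params = list(window_s = window_s, threshold = threshold,
                               decay_tau_s = decay_tau_s,
                               n_scrambles = n_scrambles, alpha = alpha,
                               seed = seed),
                 call = match.call()),
            class = "ca_development")
}

#' @export
print.ca_development <- function(x, ...) {
  cat("Developmental desynchronization analysis\n\n")
  print.data.frame(as.data.frame(x$summary), digits = 3)
  if (!is.null(x$friedman))
    cat(sprintf("\nFriedman omnibus on per-ROI mean correlations: chi2 = %.3f, p = %.3g\n",
                x$friedman$statistic, x$friedman$p_value))
  invisible(x)
}

#' @export
summary.ca_development <- function(object, ...) {
  print(object)
  if (!is.null(object$friedman) && nrow(object$friedman$posthoc)) {
    cat("\nPost-hoc pairwise comparisons (Wilcoxon signed-rank, Bonferroni):\n")
    print.data.frame(object$friedman$posthoc, digits = 3)
  }
  invisible(object)
}

#' @export
coef.ca_development <- function(object, ...) {
  stats::setNames(object$summary$mean_pairwise, object$summary$stage)
}

#' @export
plot.ca_development <- function(x, ...) {
  s <- x$summary
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::plot(seq_len(nrow(s)), s$mean_pairwise, type = "b", pch = 19,
                 xaxt = "n", xlab = "stage", ylab = "mean pairwise r",
                 main = "Network synchrony", ...)
  graphics::axis(1, at = seq_len(nrow(s)), labels = s$stage)
  graphics::plot(seq_len(nrow(s)), s$responsive_fraction, type = "b",
                 pch = 19, xaxt = "n", ylim = c(0, 1), xlab = "stage",
                 ylab = "responsive fraction",
                 main = "Whisker responsiveness", ...)
  graphics::axis(1, at = seq_len(nrow(s)), labels = s$stage)
  invisible(x)
}

#' Friedman omnibus with Bonferroni-adjusted post-hoc tests
#'
#' Friedman's two-way analysis of variance by ranks for related samples
#' (rows = subjects/ROIs, columns = stages), with post-hoc pairwise
#' Wilcoxon signed-rank tests whose p-values are Bonferroni-multiplied by
#' the number of stage pairs and capped at 1.
#'
#' The omnibus p-value is computed by exact enumeration of all within-row
#' rank permutations whenever that is feasible (`(k!)^n` up to `max_exact`),
#' and by the tie-corrected chi-square approximation from
#' [stats::friedman.test()] otherwise. If every row is completely tied the
#' statistic is 0 and p = 1.
#'
#' @param values numeric matrix, rows = related subjects, columns = stages;
#'   no missing cells.
#' @param exact `TRUE`, `FALSE` or `NULL` (auto: exact when feasible).
#' @param max_exact largest number of enumerated permutations for the exact
#'   path.
#' @return list of class `friedman_posthoc`: `statistic` (tie-corrected
#'   Friedman chi-square), `p_value`, `method` (`"exact"` or
#'   `"asymptotic"`), `posthoc` (data frame: pair, p_raw, p_adj),
#'   `n_subjects`, `n_stages`.
#' @export
friedman_with_posthoc <- function(values, exact = NULL, max_exact = 1e5) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("missing cells not allowed in a related-samples design",
                          call. = FALSE)
  n <- nrow(values); k <- ncol(values)
  if (n < 2 || k < 2) stop("need >= 2 rows and >= 2 columns", call. = FALSE)
  rk <- t(apply(values, 1, rank))
  stat_of <- function(R) {
    # tie-corrected Friedman statistic from within-row ranks R (n x k)
    A <- sum(R^2)
    C <- n * k * (k + 1)^2 / 4
    if (A - C < 1e-12) return(0)
    Rj <- colSums(R)
    (k - 1) * sum((Rj - n * (k + 1) / 2)^2) / (A - C)
  }
  stat <- stat_of(rk)
  n_perm <- factorial(k)^n
  do_exact <- if (is.null(exact)) n_perm <= max_exact else exact
  if (do_exact && n_perm > 1e7)
    stop("exact enumeration infeasible for this design size", call. = FALSE)
  if (stat == 0) {
    p <- 1; method <- "degenerate"
  } else if (do_exact) {
    p <- .friedman_exact_p(rk, stat, stat_of)
    method <- "exact"
  } else {
    p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
    method <- "asymptotic"
  }
  pairs <- utils::combn(k, 2)
  n_pairs <- ncol(pairs)
  cn <- colnames(values) %||% paste0("stage_", seq_len(k))
  ph <- data.frame(pair = character(n_pairs), p_raw = numeric(n_pairs),
                   p_adj = numeric(n_pairs), stringsAsFactors = FALSE)
  for (j in seq_len(n_pairs)) {
    a <- pairs[1, j]; b <- pairs[2, j]
    pr <- if (all(values[, a] == values[, b])) 1
    else suppressWarnings(stats::wilcox.test(values[, a], values[, b],
                                             paired = TRUE)$p.value)
    ph$pair[j] <- paste(cn[a], cn[b], sep = " vs ")
    ph$p_raw[j] <- pr
    ph$p_adj[j] <- min(1, pr * n_pairs)
  }
  structure(list(statistic = stat, p_value = p, method = method,
                 posthoc = ph, n_subjects = n, n_stages = k),
            class = "friedman_posthoc")
}

# exact permutation p: enumerate all within-row permutations of the ranks
.friedman_exact_p <- function(rk, stat_obs, stat_of) {
  n <- nrow(rk); k <- ncol(rk)
  perms <- .all_permutations(k)              # k! x k index matrix
  np <- nrow(perms)
  # column-sum distribution built row by row: states = all achievable
  # column-sum vectors; with n small this product space is enumerable
  combos <- 1L
  Rj <- matrix(0, 1, k)
  for (i in seq_len(n)) {
    ri <- rk[i, ]
    add <- matrix(ri[t(perms)], nrow = np, byrow = TRUE)  # np x k
    Rj <- Rj[rep(seq_len(nrow(Rj)), each = np), , drop = FALSE] +
      add[rep(seq_len(np), times = combos), , drop = FALSE]
    combos <- combos * np
  }
  A <- sum(rk^2); C <- n * k * (k + 1)^2 / 4
  stats_all <- (k - 1) * rowSums((Rj - n * (k + 1) / 2)^2) / (A - C)
  mean(stats_all >= stat_obs - 1e-9)
}

.all_permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- .all_permutations(k - 1)
  out <- matrix(0L, 0, k)
  for (pos in seq_len(k)) {
    block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], k,
                   sub[, seq(pos, k - 1)[seq_len(k - pos)], drop = FALSE])
    out <- rbind(out, block)
  }
  out
}

#' @export
print.friedman_posthoc <- function(x, ...) {
  cat(sprintf("Friedman chi-square = %.4f (%d subjects x %d stages), p = %.4g [%s]\n",
              x$statistic, x$n_subjects, x$n_stages, x$p_value, x$method))
  print.data.frame(x$posthoc, digits = 4)
  invisible(x)
}

#' Unpaired rank-based bootstrap comparison
#'
#' Two-sample comparison for small unpaired groups: the statistic is the
#' difference in mean pooled ranks between the groups; the null
#' distribution is formed by drawing both groups with replacement from the
#' pooled data (`n_resamples` times, default 10,000) and re-ranking. The
#' two-sided add-one p-value is
#' \eqn{(1 + \#\{|T_{null}| \ge |T_{obs}|\}) / (n_{resamples} + 1)}.
#'
#' @param group_a,group_b numeric vectors (each length >= 2).
#' @param n_resamples bootstrap resamples.
#' @param seed RNG seed.
#' @param statistic `"mean_rank_diff"` (default) or `"median_diff"`.
#' @return list of class `rank_bootstrap`: `statistic` (observed),
#'   `p_value`, `n_resamples`, `seed`, `statistic_name`.
#' @export
rank_bootstrap_test <- function(group_a, group_b, n_resamples = 10000,
                                seed = 1,
                                statistic = c("mean_rank_diff",
                                              "median_diff")) {
  statistic <- match.arg(statistic)
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values", call. = FALSE)
  na <- length(a); nb <- length(b); m <- na + nb
  pooled <- c(a, b)
  obs <- .rank_stat(matrix(pooled, 1), na, nb, statistic)
  set.seed(seed)
  idx <- matrix(sample.int(m, n_resamples * m, replace = TRUE),
                n_resamples, m)
  draws <- matrix(pooled[idx], n_resamples, m)
  null_stats <- .rank_stat(draws, na, nb, statistic)
  p <- (1 + sum(abs(null_stats) >= abs(obs))) / (n_resamples + 1)
  structure(list(statistic = obs, p_value = p, n_resamples = n_resamples,
                 seed = seed, statistic_name = statistic),
            class = "rank_bootstrap")
}

# rowwise statistic on an n_draws x (na+nb) matrix
.rank_stat <- function(M, na, nb, statistic) {
  if (statistic == "median_diff") {
    med_a <- apply(M[, seq_len(na), drop = FALSE], 1, stats::median)
    med_b <- apply(M[, na + seq_len(nb), drop = FALSE], 1, stats::median)
    return(med_a - med_b)
  }
  m <- na + nb
  R <- matrix(0, nrow(M), m)
  for (j in seq_len(m)) {
    Mj <- M[, j]
    R[, j] <- 1 + rowSums(M < Mj) + 0.5 * (rowSums(M == Mj) - 1)
  }
  rowMeans(R[, seq_len(na), drop = FALSE]) -
    rowMeans(R[, na + seq_len(nb), drop = FALSE])
}

#' @export
print.rank_bootstrap <- function(x, ...) {
  cat(sprintf("Rank bootstrap (%s): T = %.4f, two-sided p = %.4g (%d resamples)\n",
              x$statistic_name, x$statistic, x$p_value, x$n_resamples))
  invisible(x)
}
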