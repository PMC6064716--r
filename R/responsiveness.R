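#' Binary per-frame stimulus vector
#'
#' Expands a stimulation protocol into a 0/1 vector over frames: a frame is
#' 1 when its time span `[f/rate, (f+1)/rate)` overlaps any stimulation
#' epoch `[onset, onset + duration)`.
#'
#' @param protocol a [stimulus_protocol()].
#' @param n_frames recording length in frames.
#' @param frame_rate_hz frames per second.
#' @return integer vector of length `n_frames` with values 0/1.
#' @export
stimulus_vector <- function(protocol, n_frames, frame_rate_hz) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  .assert_scalar_num(n_frames, "n_frames", min = 1)
  .assert_scalar_num(frame_rate_hz, "frame_rate_hz", min = 1e-12)
  dur_s <- n_frames / frame_rate_hz
  if (any(protocol$onsets_s >= dur_s))
    stop("stimulus onset beyond the end of the recording", call. = FALSE)
  f <- seq_len(n_frames) - 1
  t0 <- f / frame_rate_hz
  t1 <- (f + 1) / frame_rate_hz
  v <- integer(n_frames)
  for (on in protocol$onsets_s)
    v[t0 < on + protocol$epoch_duration_s & t1 > on] <- 1L
  v
}

#' Indicator-convolved stimulus regressor
#'
#' Convolves the binary stimulus vector with the indicator response kernel,
#' yielding the expected calcium time-course of an ideal responder. This is
#' the default regressor for [bootstrap_responsiveness()]: with a slow
#' indicator most of the evoked fluorescence falls after the 1-s
#' stimulation window, which a raw boxcar regressor misses.
#'
#' @inheritParams stimulus_vector
#' @param kernel a [gcamp_kernel()].
#' @return numeric vector of length `n_frames`.
#' @export
stimulus_regressor <- function(protocol, n_frames, frame_rate_hz,
                               kernel = gcamp_kernel()) {
  s <- stimulus_vector(protocol, n_frames, frame_rate_hz)
  k <- sample_kernel(kernel, frame_rate_hz)
  m <- length(k)
  full <- stats::filter(c(numeric(m - 1), s), k, sides = 1)
  as.numeric(full)[m:(m + n_frames - 1)]
}

#' Scramble the activity epochs of a Z trace
#'
#' Builds one draw from the epoch-scramble null: the epoch segments (values
#' kept verbatim, order shuffled) are reinserted at uniform-random
#' non-overlapping positions, and all remaining frames are filled by
#' sampling with replacement from the trace's non-epoch (baseline) frames.
#' The output has the same length as the input and conserves the multiset
#' of epoch values; only epoch timing is destroyed, which is exactly what
#' the responsiveness null requires.
#'
#' Uses the current RNG state; seed it (or use [bootstrap_responsiveness()],
#' which manages per-ROI substreams) for reproducibility.
#'
#' @param z_trace numeric vector, one ROI's Z trace.
#' @param epochs an `epoch_table` from [detect_epochs()] on this trace (or
#'   its subset for this ROI).
#' @return numeric vector, same length as `z_trace`.
#' @export
scramble_epochs <- function(z_trace, epochs) {
  x <- as.numeric(z_trace)
  n <- length(x)
  if (nrow(epochs) > 0 && (min(epochs$start) < 0 || max(epochs$end) > n))
    stop("epochs outside the trace", call. = FALSE)
  k <- nrow(epochs)
  seg <- lapply(seq_len(k),
                function(j) x[(epochs$start[j] + 1):epochs$end[j]])
  ep_len <- sum(lengths(seg))
  if (ep_len > 0.9 * n)
    stop("epochs occupy more than 90% of frames; scramble infeasible",
         call. = FALSE)
  in_epoch <- rep(FALSE, n)
  for (j in seq_len(k))
    in_epoch[(epochs$start[j] + 1):epochs$end[j]] <- TRUE
  baseline <- x[!in_epoch]
  out <- baseline[sample.int(length(baseline), n, replace = TRUE)]
  if (k > 0) {
    ord <- if (k > 1) sample.int(k) else 1L
    free <- n - ep_len
    # uniform composition of the free frames into k+1 gaps (stars and bars)
    pos <- sort(sample.int(free + k, k))
    gap_starts <- pos - seq_len(k)       # baseline frames before each segment
    offset <- 0L
    for (j in seq_len(k)) {
      s <- seg[[ord[j]]]
      start <- gap_starts[j] + offset    # 0-based start of this segment
      out[(start + 1):(start + length(s))] <- s
      offset <- offset + length(s)
    }
  }
  out
}

#' Epoch-scramble bootstrap test of stimulus responsiveness
#'
#' Classifies a neuron as stimulus-responsive by comparing the Pearson
#' correlation between the binary stimulus time-course and its
#' \eqn{Z_F(t)} trace against the correlations obtained from `n_scrambles`
#' scrambles of all its calcium activity epochs (see [scramble_epochs()]).
#' The one-sided add-one p-value is
#' \eqn{p = (1 + \#\{r_{null} \ge r_{obs}\}) / (n_{scrambles} + 1)} and the
#' neuron is called responsive when `p < alpha`.
#'
#' The correlation is taken against the indicator-convolved stimulus
#' time-course by default ([stimulus_regressor()]); set
#' `regressor = "boxcar"` for the raw binary stimulus vector. The same
#' regressor is used for the observed trace and every scramble, so the
#' null comparison is exchangeable either way.
#'
#' For a matrix input the test runs per ROI on an independent RNG substream
#' (`split_seed(seed, roi_index)`), so results do not depend on ROI order.
#'
#' @param z a zscore-scale [trace_matrix()] or a single numeric Z trace.
#' @param protocol a [stimulus_protocol()].
#' @param n_scrambles number of scrambles forming the null (default 1000).
#' @param alpha significance level (default 0.05).
#' @param seed RNG seed.
#' @param threshold epoch threshold in z-units.
#' @param frame_rate_hz required when `z` is a plain vector.
#' @param regressor `"convolved"` (default) or `"boxcar"`.
#' @param kernel indicator kernel for the convolved regressor.
#' @return For a single trace, a list of class `bootstrap_result` with
#'   `roi_id`, `r_obs`, `null_rs`, `p_value`, `responsive`, `n_scrambles`,
#'   `seed`. For a matrix, a data frame of class `responsiveness_table`
#'   (columns roi_id, r_obs, p_value, responsive) with matching attributes.
#' @export
bootstrap_responsiveness <- function(z, protocol, n_scrambles = 1000,
                                     alpha = 0.05, seed = 1,
                                     threshold = NULL, frame_rate_hz = NULL,
                                     regressor = c("convolved", "boxcar"),
                                     kernel = gcamp_kernel()) {
  threshold <- threshold %||% attr(z, "threshold") %||% 3
  regressor <- match.arg(regressor)
  if (inherits(z, "trace_matrix") || is.matrix(z)) {
    fr <- frame_rate_hz %||% frame_rate(z)
    res <- lapply(seq_len(nrow(z)), function(i)
      .bootstrap_one(as.numeric(z[i, ]), rownames(z)[i], protocol,
                     n_scrambles, alpha, split_seed(seed, i), threshold, fr,
                     regressor, kernel))
    tab <- data.frame(
      roi_id = vapply(res, `[[`, character(1), "roi_id"),
      r_obs = vapply(res, `[[`, numeric(1), "r_obs"),
      p_value = vapply(res, `[[`, numeric(1), "p_value"),
      responsive = vapply(res, `[[`, logical(1), "responsive"),
      stringsAsFactors = FALSE)
    class(tab) <- c("responsiveness_table", "data.frame")
    attr(tab, "alpha") <- alpha
    attr(tab, "n_scrambles") <- n_scrambles
    attr(tab, "seed") <- seed
    attr(tab, "threshold") <- threshold
    attr(tab, "regressor") <- regressor
    return(tab)
  }
  if (is.null(frame_rate_hz))
    stop("frame_rate_hz required for a plain numeric trace", call. = FALSE)
  .bootstrap_one(as.numeric(z), "roi_1", protocol, n_scrambles, alpha,
                 seed, threshold, frame_rate_hz, regressor, kernel)
}

.bootstrap_one <- function(x, roi_id, protocol, n_scrambles, alpha, seed,
                           threshold, frame_rate_hz,
                           regressor = "convolved",
                           kernel = gcamp_kernel()) {
  if (!all(is.finite(x))) stop("non-finite trace: ", roi_id, call. = FALSE)
  if (stats::sd(x) < 1e-12)
    stop("zero-variance trace: ", roi_id, call. = FALSE)
  stim <- if (regressor == "convolved")
    stimulus_regressor(protocol, length(x), frame_rate_hz, kernel)
  else stimulus_vector(protocol, length(x), frame_rate_hz)
  if (stats::sd(stim) < 1e-12)
    stop("constant stimulus vector; correlation undefined", call. = FALSE)
  stim_c <- stim - mean(stim)
  stim_ss <- sqrt(sum(stim_c^2))
  r_of <- function(v) {
    vc <- v - mean(v)
    den <- stim_ss * sqrt(sum(vc^2))
    if (den < 1e-300) return(0)
    sum(stim_c * vc) / den
  }
  r_obs <- r_of(x)
  ep <- detect_epochs(x, threshold = threshold)
  set.seed(seed)
  null_rs <- vapply(seq_len(n_scrambles),
                    function(b) r_of(scramble_epochs(x, ep)), numeric(1))
  p <- (1 + sum(null_rs >= r_obs)) / (n_scrambles + 1)
  structure(list(roi_id = roi_id, r_obs = r_obs, null_rs = null_rs,
                 p_value = p, responsive = p < alpha,
                 n_scrambles = n_scrambles, seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> %s: r_obs = %.3f, p = %.4g (%d scrambles) -> %s\n",
              x$roi_id, x$r_obs, x$p_value, x$n_scrambles,
              if (x$responsive) "responsive" else "not responsive"))
  invisible(x)
}

#' @export
print.responsiveness_table <- function(x, ...) {
  cat(sprintf("<responsiveness_table> %d ROIs, %d (%.1f%%) responsive at alpha = %g\n",
              nrow(x), sum(x$responsive), 100 * mean(x$responsive),
              attr(x, "alpha")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Fraction of responsive neurons
#'
#' @param results a `responsiveness_table`, or a list of `bootstrap_result`
#'   objects.
#' @return fraction in `[0, 1]`.
#' @export
responsive_fraction <- function(results) {
  flags <- if (inherits(results, "responsiveness_table")) results$responsive
  else if (is.list(results) && length(results) &&
           all(vapply(results, inherits, logical(1), "bootstrap_result")))
    vapply(results, `[[`, logical(1), "responsive")
  else stop("unsupported input", call. = FALSE)
  if (length(flags) == 0) stop("no results", call. = FALSE)
  mean(flags)
}
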