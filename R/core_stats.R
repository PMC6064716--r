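#' Find the quietest period of a trace
#'
#' Exhaustive sliding-window search (stride 1 frame) for the window of
#' `window_s` seconds with the lowest \eqn{\Delta F/F} standard deviation.
#' Ties are broken by the earliest start. The window length is
#' `round(window_s * frame_rate_hz)` frames, minimum 2.
#'
#' @param dff_trace numeric vector, one ROI's \eqn{\Delta F/F} trace.
#' @param frame_rate_hz frames per second.
#' @param window_s window length in seconds (default 10).
#' @return list of class `quiet_period`: `quiet_start` (0-based first frame
#'   of the window), `quiet_len` (frames), `mean`, `sd` (moments of the
#'   trace inside the window).
#' @export
find_quietest_period <- function(dff_trace, frame_rate_hz, window_s = 10) {
  x <- as.numeric(dff_trace)
  if (!all(is.finite(x))) stop("trace contains non-finite values", call. = FALSE)
  .assert_scalar_num(frame_rate_hz, "frame_rate_hz", min = 1e-12)
  w <- max(2L, as.integer(round(window_s * frame_rate_hz)))
  n <- length(x)
  if (n < w)
    stop(sprintf("trace (%d frames) shorter than window (%d frames)", n, w),
         call. = FALSE)
  n_win <- n - w + 1L
  sds <- vapply(seq_len(n_win), function(s) stats::sd(x[s:(s + w - 1L)]),
                numeric(1))
  s <- which.min(sds)              # which.min takes the first minimum: earliest
  win <- x[s:(s + w - 1L)]
  structure(list(quiet_start = s - 1L, quiet_len = w,
                 mean = mean(win), sd = stats::sd(win)),
            class = "quiet_period")
}

#' Modified Z-score of \eqn{\Delta F/F} traces
#'
#' Standardizes each ROI's trace by the mean and SD of its own quietest
#' period: \eqn{Z_F(t) = (F(t) - \mathrm{mean}(\mathrm{quietest})) /
#' \mathrm{SD}(\mathrm{quietest})}, where the quietest period is the
#' `window_s`-second window with the lowest SD. All downstream statistics
#' (epochs, responsiveness, aggregate activity) operate on this scale.
#'
#' ROIs whose quiet-period SD falls below `sd_tol` cannot be standardized;
#' they are dropped with a warning (or raise an error if `on_degenerate =
#' "error"`).
#'
#' @param dff a dff-scale [trace_matrix()].
#' @param window_s quietest-window length in seconds.
#' @param threshold epoch threshold in z-units, stored for downstream use.
#' @param sd_tol minimal admissible quiet-period SD.
#' @param on_degenerate `"drop"` (default) or `"error"`.
#' @return a zscore-scale [trace_matrix()] with attributes `baseline` (data
#'   frame: roi_id, quiet_start, quiet_len, baseline_mean, baseline_sd) and
#'   `threshold`.
#' @export
modified_zscore <- function(dff, window_s = 10, threshold = 3,
                            sd_tol = 1e-12, on_degenerate = c("drop", "error")) {
  stopifnot(inherits(dff, "trace_matrix"))
  if (!trace_scale(dff) %in% c("dff", "raw"))
    stop("modified_zscore expects dff-scale traces", call. = FALSE)
  on_degenerate <- match.arg(on_degenerate)
  fr <- frame_rate(dff)
  n_roi <- nrow(dff)
  z <- matrix(NA_real_, n_roi, ncol(dff), dimnames = dimnames(dff))
  qs <- integer(n_roi); ql <- integer(n_roi)
  bm <- numeric(n_roi); bs <- numeric(n_roi)
  keep <- rep(TRUE, n_roi)
  for (i in seq_len(n_roi)) {
    qp <- find_quietest_period(dff[i, ], fr, window_s)
    if (qp$sd < sd_tol) {
      if (on_degenerate == "error")
        stop("degenerate trace (quiet-period SD ~ 0): ", rownames(dff)[i],
             call. = FALSE)
      warning("dropping degenerate trace (quiet-period SD ~ 0): ",
              rownames(dff)[i], call. = FALSE)
      keep[i] <- FALSE
      next
    }
    qs[i] <- qp$quiet_start; ql[i] <- qp$quiet_len
    bm[i] <- qp$mean; bs[i] <- qp$sd
    z[i, ] <- (dff[i, ] - qp$mean) / qp$sd
  }
  if (!any(keep)) stop("all traces degenerate", call. = FALSE)
  z <- z[keep, , drop = FALSE]
  tm <- trace_matrix(z, frame_rate_hz = fr, scale = "zscore")
  attr(tm, "baseline") <- data.frame(
    roi_id = rownames(z),
    quiet_start = qs[keep], quiet_len = ql[keep],
    baseline_mean = bm[keep], baseline_sd = bs[keep],
    stringsAsFactors = FALSE)
  attr(tm, "threshold") <- threshold
  attr(tm, "window_s") <- window_s
  tm
}

#' Detect calcium activity epochs
#'
#' An epoch is a maximal run of consecutive frames with \eqn{Z_F(t) \ge}
#' `threshold`. Epochs shorter than `min_duration_frames` are discarded.
#' Frame indices are 0-based and intervals half-open `[start, end)`.
#'
#' @param z a zscore-scale [trace_matrix()] or a numeric vector (single
#'   trace, treated as roi `"roi_1"`).
#' @param threshold z threshold (default 3, or the threshold carried by the
#'   matrix).
#' @param min_duration_frames minimum epoch length in frames (default 1).
#' @return data frame of class `epoch_table` with columns `roi_id`,
#'   `start`, `end`, `peak_z`, `duration_frames`, sorted by (roi_id, start).
#'   Zero rows when nothing crosses threshold.
#' @export
detect_epochs <- function(z, threshold = NULL, min_duration_frames = 1) {
  if (is.numeric(z) && is.null(dim(z)))
    z <- matrix(z, nrow = 1, dimnames = list("roi_1", NULL))
  threshold <- threshold %||% attr(z, "threshold") %||% 3
  rows <- vector("list", nrow(z))
  for (i in seq_len(nrow(z))) {
    xi <- as.numeric(z[i, ])
    r <- rle(xi >= threshold)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- r$values & r$lengths >= min_duration_frames
    if (!any(sel)) next
    s <- starts[sel]; e <- ends[sel]
    rows[[i]] <- data.frame(
      roi_id = rownames(z)[i],
      start = s - 1L, end = e,          # 0-based half-open
      peak_z = vapply(seq_along(s), function(k) max(xi[s[k]:e[k]]), numeric(1)),
      duration_frames = e - s + 1L,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(roi_id = character(0), start = integer(0),
                      end = integer(0), peak_z = numeric(0),
                      duration_frames = integer(0), stringsAsFactors = FALSE)
  out <- out[order(out$roi_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("epoch_table", "data.frame")
  attr(out, "threshold") <- threshold
  out
}

#' Mean Z within a frame range
#'
#' Aggregate activity: the arithmetic mean of \eqn{Z_F(t)} over a half-open
#' 0-based frame range, per ROI.
#'
#' @param z a zscore-scale [trace_matrix()].
#' @param frame_range `c(start, end)`, 0-based, half-open; must be
#'   non-empty and inside the recording.
#' @return named numeric vector, one value per ROI.
#' @export
mean_z_in_range <- function(z, frame_range) {
  idx <- .range_to_idx(frame_range, ncol(z))
  rowMeans(z[, idx, drop = FALSE])
}

#' Keep ROIs active at every stage
#'
#' Longitudinal inclusion rule: an ROI is analyzed only if it shows at least
#' one calcium activity epoch in the spontaneous recording at every stage of
#' the session set.
#'
#' @param session_set a `session_set` (see
#'   [generate_developmental_dataset()]), or a named list of `epoch_table`s
#'   (one per stage) plus `roi_ids`.
#' @param roi_ids the shared ROI id space; inferred from the session set.
#' @param window_s,threshold passed to [modified_zscore()] /
#'   [detect_epochs()] when epochs must be computed from traces.
#' @return character vector of retained ROI ids (subset of `roi_ids`).
#' @export
filter_active_across_sessions <- function(session_set, roi_ids = NULL,
                                          window_s = 10, threshold = 3) {
  if (inherits(session_set, "session_set")) {
    roi_ids <- roi_ids %||% session_set$roi_ids
    epoch_tables <- lapply(session_set$stages, function(st) {
      z <- modified_zscore(st$spontaneous, window_s = window_s,
                           threshold = threshold)
      detect_epochs(z)
    })
  } else if (is.list(session_set)) {
    epoch_tables <- session_set
    if (is.null(roi_ids)) stop("roi_ids required with raw epoch tables",
                               call. = FALSE)
  } else stop("unsupported session_set", call. = FALSE)
  for (tab in epoch_tables) {
    unknown <- setdiff(unique(tab$roi_id), roi_ids)
    if (length(unknown))
      stop("mismatched ROI id spaces: ", paste(unknown, collapse = ", "),
           call. = FALSE)
  }
  active_each <- lapply(epoch_tables, function(tab) unique(tab$roi_id))
  roi_ids[vapply(roi_ids,
                 function(id) all(vapply(active_each, function(a) id %in% a,
                                         logical(1))),
                 logical(1))]
}

#' AR(1) trace deconvolution
#'
#' Temporal sharpening of calcium traces before correlation analysis:
#' inverts a first-order autoregressive model of the indicator decay,
#' \eqn{d(t) = \max(0, x(t) - \gamma x(t-1))} with
#' \eqn{\gamma = e^{-1/(\tau_d f)}}, and \eqn{d(0) = \max(0, x(0))}.
#' No spike-count calibration is attempted; the output is only meant to
#' concentrate mass near event frames.
#'
#' @param x a [trace_matrix()] (zscore or dff scale) or numeric vector.
#' @param decay_tau_s indicator decay time constant in seconds (default
#'   1.5, matching the simulator's kernel default).
#' @param frame_rate_hz frame rate; taken from the trace matrix when
#'   available.
#' @return deconvolved traces, same shape as the input (a
#'   `trace_matrix` tagged `"deconvolved"` for matrix input).
#' @export
deconvolve <- function(x, decay_tau_s = 1.5, frame_rate_hz = NULL) {
  .assert_scalar_num(decay_tau_s, "decay_tau_s", min = 1e-12)
  if (inherits(x, "trace_matrix")) frame_rate_hz <- frame_rate(x)
  if (is.null(frame_rate_hz)) stop("frame_rate_hz required", call. = FALSE)
  if (!all(is.finite(unclass(x)))) stop("non-finite input", call. = FALSE)
  g <- exp(-1 / (decay_tau_s * frame_rate_hz))
  dec1 <- function(v) {
    d <- v - g * c(0, v[-length(v)])
    d[1] <- v[1]
    pmax(d, 0)
  }
  if (is.numeric(x) && is.null(dim(x))) return(dec1(as.numeric(x)))
  out <- t(apply(x, 1, dec1))
  dimnames(out) <- dimnames(x)
  trace_matrix(out, frame_rate_hz = frame_rate_hz, scale = "deconvolved")
}
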