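#' Rigid (integer-pixel) movie registration
#'
#' Estimates per-frame X-Y drift by the integer argmax of the circular
#' cross-correlation (via FFT) between each frame and a reference image, and
#' removes it by translating each frame by the opposite shift. Pixels
#' shifted in from outside the frame are filled with the frame median.
#' Rigid translation suffices here because all downstream analysis is
#' normalized per ROI.
#'
#' @param movie a `synthetic_movie` or a numeric array `frame x ny x nx`.
#' @param reference `"mean"` (default: mean image over frames) or a frame
#'   index (1-based).
#' @param max_shift_px shifts are searched within \code{[-max_shift_px,
#'   max_shift_px]} in each axis.
#' @return list of class `registered_movie`: `movie` (corrected array),
#'   `shifts` (estimated per-frame drift, columns `dx`, `dy`), `correction`
#'   (the applied translation, `-shifts`), `reference`.
#' @export
register_rigid <- function(movie, reference = "mean", max_shift_px = 10) {
  arr <- if (inherits(movie, "synthetic_movie")) movie$movie else movie
  if (length(dim(arr)) != 3 || dim(arr)[1] < 2)
    stop("movie must be a (frame, y, x) array with >= 2 frames", call. = FALSE)
  nt <- dim(arr)[1]
  ref <- if (identical(reference, "mean")) apply(arr, c(2, 3), mean)
         else arr[reference, , ]
  if (stats::sd(ref) < 1e-12)
    stop("reference image has zero variance; cannot register", call. = FALSE)
  ref_c <- ref - mean(ref)
  fref <- stats::fft(ref_c)
  ny <- nrow(ref); nx <- ncol(ref)
  shifts <- matrix(0L, nt, 2, dimnames = list(NULL, c("dx", "dy")))
  out <- array(0, dim = dim(arr))
  for (t in seq_len(nt)) {
    fr <- arr[t, , ]
    cc <- Re(stats::fft(stats::fft(fr - mean(fr)) * Conj(fref),
                        inverse = TRUE))
    # restrict the circular correlation to plausible shifts
    dys <- ((seq_len(ny) - 1 + ny / 2) %% ny) - ny / 2
    dxs <- ((seq_len(nx) - 1 + nx / 2) %% nx) - nx / 2
    ok <- outer(abs(dys) <= max_shift_px, abs(dxs) <= max_shift_px)
    cc[!ok] <- -Inf
    pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    dy <- as.integer(dys[pk[1]]); dx <- as.integer(dxs[pk[2]])
    shifts[t, ] <- c(dx, dy)
    out[t, , ] <- .shift_image(fr, -dx, -dy, fill = stats::median(fr))
  }
  structure(list(movie = out, shifts = shifts, correction = -shifts,
                 reference = ref),
            class = "registered_movie")
}

#' Extract per-ROI fluorescence traces from a movie
#'
#' Each ROI trace is the mean pixel value over that ROI's mask, per frame.
#' ROIs are ordered by ascending label; labels must form the contiguous set
#' 1..max with at least one pixel each.
#'
#' @param movie a `synthetic_movie`, `registered_movie`, or numeric array
#'   `frame x ny x nx`.
#' @param label_mask integer matrix `ny x nx`; 0 = background, k >= 1 = ROI
#'   k. Defaults to the mask carried by a `synthetic_movie`.
#' @param frame_rate_hz frame rate for the resulting trace matrix; taken
#'   from the movie object when available.
#' @return a raw-scale [trace_matrix()] with roi ids `"roi_<label>"`.
#' @export
extract_traces <- function(movie, label_mask = NULL, frame_rate_hz = NULL) {
  if (inherits(movie, "synthetic_movie")) {
    label_mask <- label_mask %||% movie$label_mask
    frame_rate_hz <- frame_rate_hz %||% movie$frame_rate_hz
    arr <- movie$movie
  } else if (inherits(movie, "registered_movie")) {
    arr <- movie$movie
  } else arr <- movie
  if (is.null(label_mask)) stop("label_mask is required", call. = FALSE)
  frame_rate_hz <- frame_rate_hz %||% 1
  if (!all(dim(arr)[2:3] == dim(label_mask)))
    stop("label mask shape must match movie frames", call. = FALSE)
  labs <- sort(unique(as.integer(label_mask[label_mask > 0])))
  if (length(labs) == 0) stop("label mask contains no ROI pixels", call. = FALSE)
  missing <- setdiff(seq_len(max(labs)), labs)
  if (length(missing))
    stop("label(s) with no pixels: ", paste(missing, collapse = ", "),
         call. = FALSE)
  nt <- dim(arr)[1]
  flat <- matrix(arr, nrow = nt)          # frames x pixels (column-major y,x)
  mask_vec <- as.integer(label_mask)
  x <- matrix(0, length(labs), nt)
  for (i in seq_along(labs)) {
    sel <- mask_vec == labs[i]
    x[i, ] <- rowMeans(flat[, sel, drop = FALSE])
  }
  rownames(x) <- paste0("roi_", labs)
  trace_matrix(x, frame_rate_hz = frame_rate_hz, scale = "raw")
}

#' \eqn{\Delta F/F} normalization
#'
#' Computes \eqn{\Delta F/F(t) = (F(t) - F_0(t)) / F_0(t)}. The default
#' baseline \eqn{F_0} is a running 20th percentile over a 30-s window,
#' which tracks slow drift while ignoring sparse transients; a constant
#' percentile over the whole trace and the global median are selectable.
#'
#' @param traces a raw-scale [trace_matrix()].
#' @param baseline_method `"running_percentile"`, `"constant_percentile"`
#'   or `"global_median"`.
#' @param window_s running-window length in seconds.
#' @param percentile baseline percentile in (0, 1).
#' @return a dff-scale [trace_matrix()].
#' @export
compute_dff <- function(traces,
                        baseline_method = c("running_percentile",
                                            "constant_percentile",
                                            "global_median"),
                        window_s = 30, percentile = 0.2) {
  stopifnot(inherits(traces, "trace_matrix"))
  if (trace_scale(traces) != "raw")
    stop("compute_dff expects raw-scale traces", call. = FALSE)
  baseline_method <- match.arg(baseline_method)
  nt <- ncol(traces)
  w <- max(3L, as.integer(round(window_s * frame_rate(traces))))
  out <- matrix(0, nrow(traces), nt, dimnames = dimnames(traces))
  for (i in seq_len(nrow(traces))) {
    f <- as.numeric(traces[i, ])
    f0 <- switch(baseline_method,
      global_median = rep(stats::median(f), nt),
      constant_percentile = rep(stats::quantile(f, percentile, names = FALSE), nt),
      running_percentile = .running_quantile(f, w, percentile))
    if (any(f0 <= 0))
      stop("non-positive baseline F0 for ", rownames(traces)[i], call. = FALSE)
    out[i, ] <- (f - f0) / f0
  }
  tm <- trace_matrix(out, frame_rate_hz = frame_rate(traces), scale = "dff")
  attr(tm, "baseline_method") <- baseline_method
  tm
}

# centered running quantile, window clipped at the trace ends
.running_quantile <- function(x, w, p) {
  n <- length(x)
  half <- w %/% 2
  vapply(seq_len(n), function(t) {
    i0 <- max(1L, t - half); i1 <- min(n, t + half)
    stats::quantile(x[i0:i1], p, names = FALSE)
  }, numeric(1))
}

#' Optical intrinsic signal response map
#'
#' For each stimulation trial the response image is divided pixelwise by the
#' trial's mean baseline image; the ratios are summed over trials and the
#' binary map keeps pixels at or above `threshold_frac` of the maximum of
#' that summed map.
#'
#' @param trial_responses list of response images (matrices), or a 3-D array
#'   `trial x ny x nx`; a per-trial stack `frame x ny x nx` is averaged over
#'   frames.
#' @param trial_baselines baseline images/stacks, same layout and length.
#' @param threshold_frac fraction of the maximum summed ratio (default 0.5).
#' @return list of class `ois_map`: `continuous` (summed ratio image),
#'   `binary` (logical matrix), `threshold` (absolute cutoff applied).
#' @export
ois_response_map <- function(trial_responses, trial_baselines,
                             threshold_frac = 0.5) {
  resp <- .as_image_list(trial_responses)
  base <- .as_image_list(trial_baselines)
  if (length(resp) < 1) stop("need at least one trial", call. = FALSE)
  if (length(resp) != length(base))
    stop("response and baseline trial counts differ", call. = FALSE)
  .assert_scalar_num(threshold_frac, "threshold_frac", min = 0, max = 1)
  cont <- 0
  for (k in seq_along(resp)) {
    if (any(base[[k]] == 0))
      stop("zero baseline pixel in trial ", k, call. = FALSE)
    cont <- cont + resp[[k]] / base[[k]]
  }
  thr <- threshold_frac * max(cont)
  structure(list(continuous = cont, binary = cont >= thr, threshold = thr),
            class = "ois_map")
}

# normalize images to a list of 2-D matrices, averaging stacks over frames
.as_image_list <- function(x) {
  if (is.list(x)) {
    lapply(x, function(im) {
      if (length(dim(im)) == 3) apply(im, c(2, 3), mean) else as.matrix(im)
    })
  } else if (length(dim(x)) == 3) {
    lapply(seq_len(dim(x)[1]), function(k) x[k, , ])
  } else list(as.matrix(x))
}
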