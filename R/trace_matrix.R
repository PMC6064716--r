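#' Fluorescence trace matrix
#'
#' The pipeline's central container: one fluorescence value per (ROI, frame),
#' together with the acquisition frame rate and a tag recording what scale
#' the values are on (`"raw"` arbitrary fluorescence units, `"dff"`
#' \eqn{\Delta F/F}, `"zscore"` modified Z-scores, or `"deconvolved"`).
#'
#' @param values numeric matrix, rows = ROIs, columns = frames; all finite.
#' @param frame_rate_hz acquisition rate in Hz (> 0).
#' @param scale one of `"raw"`, `"dff"`, `"zscore"`, `"deconvolved"`.
#' @param roi_ids character or integer ROI identifiers, unique, one per row.
#'   Defaults to existing rownames or `"roi_1"`, `"roi_2"`, ...
#' @return an object of class `trace_matrix` (a numeric matrix with
#'   attributes `frame_rate_hz` and `scale`; rownames are the ROI ids).
#' @examples
#' tm <- trace_matrix(matrix(rnorm(20), 2), frame_rate_hz = 7.8, scale = "dff")
#' n_frames(tm)
#' @export
trace_matrix <- function(values, frame_rate_hz,
                         scale = c("raw", "dff", "zscore", "deconvolved"),
                         roi_ids = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (roi x frame)", call. = FALSE)
  if (!all(is.finite(values)))
    stop("trace values must be finite (no missing frames)", call. = FALSE)
  .assert_scalar_num(frame_rate_hz, "frame_rate_hz", min = 1e-12)
  roi_ids <- roi_ids %||% rownames(values) %||%
    paste0("roi_", seq_len(nrow(values)))
  roi_ids <- as.character(roi_ids)
  if (length(roi_ids) != nrow(values) || anyDuplicated(roi_ids))
    stop("roi_ids must be unique, one per row", call. = FALSE)
  rownames(values) <- roi_ids
  structure(values,
            frame_rate_hz = as.numeric(frame_rate_hz),
            scale = scale,
            class = c("trace_matrix", "matrix", "array"))
}

#' @rdname trace_matrix
#' @param x a `trace_matrix`.
#' @export
frame_rate <- function(x) attr(x, "frame_rate_hz")

#' @rdname trace_matrix
#' @export
trace_scale <- function(x) attr(x, "scale")

#' @rdname trace_matrix
#' @export
n_frames <- function(x) ncol(x)

#' @rdname trace_matrix
#' @export
roi_ids <- function(x) rownames(x)

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf("<trace_matrix> %d ROIs x %d frames @ %.3g Hz (%.3g s), scale = %s\n",
              nrow(x), ncol(x), frame_rate(x), ncol(x) / frame_rate(x),
              trace_scale(x)))
  invisible(x)
}

#' @export
as.matrix.trace_matrix <- function(x, ...) {
  attributes(x) <- list(dim = dim(x), dimnames = dimnames(x))
  x
}

# rebuild a trace_matrix with the same metadata but new values/scale
.retag <- function(tm, values, scale = trace_scale(tm)) {
  trace_matrix(values, frame_rate_hz = frame_rate(tm), scale = scale,
               roi_ids = rownames(values) %||% roi_ids(tm))
}
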