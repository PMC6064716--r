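#' @keywords internal
"_PACKAGE"

# Frame/pixel indices are 0-based and intervals half-open [start, end),
# matching the on-disk CSV convention. Internal R code converts with +1.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible substream seed
#'
#' Deterministic splitting rule used throughout the package so that each
#' session, stage or ROI gets its own RNG stream from one master seed.
#' The rule is `(seed * 10007 + index) mod (2^31 - 1)`, which keeps the
#' result a valid 32-bit integer seed.
#'
#' @param seed master seed (integer).
#' @param index non-negative integer identifying the substream.
#' @return an integer seed.
#' @export
split_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed),
            is.numeric(index), length(index) == 1, index >= 0)
  as.integer((as.double(seed) * 10007 + as.double(index)) %% 2147483647)
}

.assert_scalar_num <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min || x > max)
    stop(sprintf("'%s' must be a finite number in [%s, %s]", name,
                 format(min), format(max)), call. = FALSE)
  invisible(x)
}

# Half-open frame range [start, end) in 0-based frames -> 1-based R indices
.range_to_idx <- function(frame_range, n_frames) {
  if (length(frame_range) != 2 || !all(is.finite(frame_range)))
    stop("frame_range must be c(start, end), half-open, 0-based", call. = FALSE)
  start <- frame_range[1]; end <- frame_range[2]
  if (end <= start) stop("empty frame range", call. = FALSE)
  if (start < 0 || end > n_frames)
    stop("frame range outside recording", call. = FALSE)
  seq.int(start + 1, end)
}
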