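#' Read and write trace matrices as CSV with a JSON sidecar
#'
#' Traces go on disk in long form with columns `roi_id`, `frame` (0-based),
#' `value`; acquisition metadata (frame rate, scale, plus any extras such
#' as the stage label, protocol and seed) lives in a JSON sidecar next to
#' the CSV (`<path>.json`).
#'
#' @param traces a [trace_matrix()].
#' @param path CSV file path.
#' @param extra named list merged into the sidecar.
#' @return `write_traces` invisibly returns `path`; `read_traces` returns a
#'   `trace_matrix` with the sidecar stored in attribute `meta`.
#' @export
write_traces <- function(traces, path, extra = list()) {
  stopifnot(inherits(traces, "trace_matrix"))
  long <- data.frame(
    roi_id = rep(rownames(traces), times = ncol(traces)),
    frame = rep(seq_len(ncol(traces)) - 1L, each = nrow(traces)),
    value = as.numeric(traces))
  long <- long[order(long$roi_id, long$frame), ]
  utils::write.csv(long, path, row.names = FALSE)
  meta <- c(list(frame_rate_hz = frame_rate(traces),
                 scale = trace_scale(traces),
                 n_rois = nrow(traces), n_frames = ncol(traces)),
            extra)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("roi_id", "frame", "value")
  if (!all(need %in% names(long)))
    stop("malformed trace CSV (need roi_id, frame, value): ", path,
         call. = FALSE)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list(frame_rate_hz = 1, scale = "raw")
  ids <- unique(long$roi_id)
  frames <- sort(unique(long$frame))
  x <- matrix(NA_real_, length(ids), length(frames),
              dimnames = list(ids, NULL))
  x[cbind(match(long$roi_id, ids), match(long$frame, frames))] <- long$value
  if (anyNA(x)) stop("missing frames in trace CSV: ", path, call. = FALSE)
  tm <- trace_matrix(x, frame_rate_hz = meta$frame_rate_hz,
                     scale = meta$scale %||% "raw")
  attr(tm, "meta") <- meta
  tm
}

#' Write an epoch table as CSV with a JSON sidecar
#'
#' @param epochs an `epoch_table` from [detect_epochs()].
#' @param path CSV path.
#' @param extra named list merged into the sidecar (the epoch threshold,
#'   quiet window and tie-break rule are always recorded).
#' @export
write_epochs <- function(epochs, path, extra = list()) {
  utils::write.csv(as.data.frame(epochs)[, c("roi_id", "start", "end",
                                             "peak_z")],
                   path, row.names = FALSE)
  meta <- c(list(threshold = attr(epochs, "threshold") %||% 3,
                 frame_convention = "0-based, half-open [start, end)",
                 tie_break = "earliest quietest window"),
            extra)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read and write movies as multi-page TIFF
#'
#' Movies are stored as 16-bit multi-page TIFFs, frame-major; pixel counts
#' are mapped linearly from `[0, 65535]` to the `[0, 1]` range the TIFF
#' writer expects. Label masks are stored the same way (one page, integer
#' labels as counts).
#'
#' @param movie numeric array `frame x ny x nx` (counts) or a
#'   `synthetic_movie`.
#' @param path TIFF file path.
#' @return `read_movie_tiff` returns a numeric array `frame x ny x nx` in
#'   counts; `read_label_tiff` an integer matrix.
#' @export
write_movie_tiff <- function(movie, path) {
  arr <- if (inherits(movie, "synthetic_movie")) movie$movie else movie
  frames <- lapply(seq_len(dim(arr)[1]), function(t)
    pmin(pmax(arr[t, , ] / 65535, 0), 1))
  tiff::writeTIFF(frames, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(length(pages), dim(pages[[1]])[1],
                          dim(pages[[1]])[2]))
  for (t in seq_along(pages)) arr[t, , ] <- pages[[t]] * 65535
  arr
}

#' @rdname write_movie_tiff
#' @param label_mask integer matrix of ROI labels (0 = background).
#' @export
write_label_tiff <- function(label_mask, path) {
  tiff::writeTIFF(pmin(label_mask / 65535, 1), path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}
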