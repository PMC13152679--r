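#' Time-lapse fluorescence movie
#'
#' The basic container every pipeline stage consumes or produces: a
#' `T x Y x X` intensity (or \eqn{\Delta F/F}) array together with its
#' acquisition metadata. Frames are 1-based; frame `i` maps to time
#' `t = (i - 1) / frame_rate` seconds.
#'
#' @param data numeric `T x Y x X` array (time, rows, columns).
#' @param frame_rate acquisition rate in Hz.
#' @param pixel_size pixel pitch in micrometres per pixel (metadata only;
#'   the pipeline never infers it).
#' @param channel label for the spectral channel (e.g. `"nir"`, `"vis"`).
#' @param stim_frames optional strictly increasing 1-based stimulus frame
#'   indices.
#' @param units `"counts"` for raw intensities, `"dff"` after
#'   [compute_dff()].
#' @return An object of class `movie_stack`.
#' @seealso [read_movie()], [write_movie()], [movie_trace()]
#' @export
movie_stack <- function(data, frame_rate, pixel_size = NA_real_,
                        channel = "unknown", stim_frames = integer(),
                        units = "counts") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("'data' must be a 3-d (T x Y x X) array")
  if (dim(data)[1L] < 2L) stopf("movie must have at least 2 frames")
  check_number(frame_rate, "frame_rate")
  stim_frames <- check_frames(stim_frames, dim(data)[1L], "stim_frames")
  structure(
    list(data = data, frame_rate = frame_rate, pixel_size = pixel_size,
         channel = channel, stim_frames = stim_frames, units = units),
    class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<movie_stack> %d frames x %d x %d px, %.3g Hz, channel '%s' [%s]\n",
              d[1L], d[2L], d[3L], x$frame_rate, x$channel, x$units))
  if (length(x$stim_frames))
    cat("  stim frames:", paste(x$stim_frames, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.movie_stack <- function(x) dim(x$data)

#' Single fluorescence time series
#'
#' @param values numeric vector of length T (finite).
#' @param frame_rate sampling rate in Hz.
#' @param t0_frame 1-based frame index that time zero refers to (stimulus
#'   frame for evoked traces; 1 otherwise).
#' @return An object of class `fluor_trace`.
#' @export
fluor_trace <- function(values, frame_rate, t0_frame = 1L) {
  values <- as.numeric(values)
  if (!all(is.finite(values))) stopf("trace values must all be finite")
  check_number(frame_rate, "frame_rate")
  t0_frame <- as.integer(t0_frame)
  structure(list(values = values, frame_rate = frame_rate,
                 t0_frame = t0_frame),
            class = "fluor_trace")
}

#' @export
print.fluor_trace <- function(x, ...) {
  cat(sprintf("<fluor_trace> %d samples @ %.3g Hz (%.1f s), t0 frame %d\n",
              length(x$values), x$frame_rate,
              length(x$values) / x$frame_rate, x$t0_frame))
  invisible(x)
}

#' @export
length.fluor_trace <- function(x) length(x$values)

# Time axis (seconds from trace start) of a trace or movie.
#' Time axis of a trace or movie
#' @param x a `fluor_trace` or `movie_stack`.
#' @return numeric vector, seconds from the first frame.
#' @export
time_axis <- function(x) {
  n <- if (inherits(x, "movie_stack")) dim(x$data)[1L] else length(x$values)
  (seq_len(n) - 1) / x$frame_rate
}

#' Spatial-mean trace of a movie
#'
#' Averages every pixel per frame, yielding the whole-field trace used by
#' the integrated-response and retinal analyses.
#'
#' @param movie a `movie_stack`.
#' @return a `fluor_trace` (t0 at the first stimulus frame if any).
#' @export
movie_trace <- function(movie) {
  stopifnot(inherits(movie, "movie_stack"))
  v <- apply(movie$data, 1L, mean)
  t0 <- if (length(movie$stim_frames)) movie$stim_frames[1L] else 1L
  fluor_trace(v, movie$frame_rate, t0)
}

#' Write a movie as multi-page 16-bit TIFF with JSON sidecar
#'
#' One grayscale page per frame; intensities are clipped to `[0, 65535]`
#' and rounded. The sidecar (`<path>.json`, or `path` with its extension
#' replaced) records frame rate, pixel size, channel, stimulus frames
#' (1-based) and an optional seed.
#'
#' @param movie a `movie_stack` in count units.
#' @param path output TIFF path (`.tif`/`.tiff`).
#' @param seed optional integer recorded in the sidecar for provenance.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path, seed = NULL) {
  stopifnot(inherits(movie, "movie_stack"))
  d <- movie$data
  d[d < 0] <- 0; d[d > 65535] <- 65535
  pages <- lapply(seq_len(dim(d)[1L]), function(i) round(d[i, , ]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  side <- list(frame_rate_hz = movie$frame_rate,
               pixel_size_um = movie$pixel_size,
               channel = movie$channel,
               stim_frames = I(movie$stim_frames),
               frame_indexing = "1-based",
               units = movie$units)
  if (!is.null(seed)) side$seed <- seed
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Read a multi-page TIFF movie and its JSON sidecar
#'
#' @param path TIFF path written by [write_movie()] (or any multi-page
#'   grayscale TIFF).
#' @param sidecar sidecar path; defaults to `path` with a `.json`
#'   extension. The sidecar is required: it carries the frame rate.
#' @return a `movie_stack`.
#' @export
read_movie <- function(path, sidecar = sidecar_path(path)) {
  if (!file.exists(path)) stopf("TIFF file not found: %s", path)
  if (!file.exists(sidecar))
    stopf("metadata sidecar not found: %s (required for frame rate)", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1L]])
  arr <- array(0, dim = c(length(pages), d[1L], d[2L]))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  movie_stack(arr,
              frame_rate = meta$frame_rate_hz,
              pixel_size = if (is.null(meta$pixel_size_um)) NA_real_ else meta$pixel_size_um,
              channel = if (is.null(meta$channel)) "unknown" else meta$channel,
              stim_frames = if (is.null(meta$stim_frames)) integer() else meta$stim_frames,
              units = if (is.null(meta$units)) "counts" else meta$units)
}

#' Write a trace as CSV (frame, time_s, value)
#' @param trace a `fluor_trace`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(frame = seq_along(trace$values),
                   time_s = time_axis(trace),
                   value = trace$values)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
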