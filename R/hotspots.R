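#' Tile a movie with a square grid mask and extract per-square traces
#'
#' Non-overlapping squares anchored at the top-left pixel; each square's
#' trace is the spatial mean of its pixels per frame. Trailing rows or
#' columns that do not fill a whole square are discarded (their count is
#' recorded), so every square has identical area.
#'
#' @param dff a `movie_stack` (normally in dFF units).
#' @param square_px square side length in pixels (default 8).
#' @return An object of class `grid_traces`: list with `traces`
#'   (`n_squares x T` matrix, row order row-major over the grid), `mask`
#'   (data.frame: square, row, col, y0, y1, x0, x1), `frame_rate`,
#'   `square_px`, `pixel_size`, `stim_frames`, `n_discarded_px`.
#' @export
apply_grid <- function(dff, square_px = 8L) {
  stopifnot(inherits(dff, "movie_stack"))
  square_px <- as.integer(square_px)
  d <- dim(dff$data)
  if (square_px < 1L || d[2L] < square_px || d[3L] < square_px)
    stopf("square_px = %d does not fit a %d x %d frame", square_px, d[2L], d[3L])
  nr <- d[2L] %/% square_px
  nc <- d[3L] %/% square_px
  crop <- dff$data[, seq_len(nr * square_px), seq_len(nc * square_px), drop = FALSE]
  # reinterpret Y as (within-square, grid-row) and X as (within-square,
  # grid-col), then average the within-square axes
  dim(crop) <- c(d[1L], square_px, nr, square_px, nc)
  sq <- apply(crop, c(1L, 3L, 5L), mean)       # T x nr x nc
  traces <- matrix(aperm(sq, c(2L, 3L, 1L)), nrow = nr * nc, ncol = d[1L])
  grid <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  mask <- data.frame(square = seq_len(nr * nc), row = grid$row, col = grid$col,
                     y0 = (grid$row - 1L) * square_px + 1L,
                     y1 = grid$row * square_px,
                     x0 = (grid$col - 1L) * square_px + 1L,
                     x1 = grid$col * square_px)
  structure(list(traces = traces, mask = mask, frame_rate = dff$frame_rate,
                 square_px = square_px, pixel_size = dff$pixel_size,
                 stim_frames = dff$stim_frames,
                 n_discarded_px = as.integer(d[2L] * d[3L] - nr * nc * square_px^2)),
            class = "grid_traces")
}

#' @export
print.grid_traces <- function(x, ...) {
  cat(sprintf("<grid_traces> %d squares (%d px side) x %d frames; %d edge px discarded\n",
              nrow(x$traces), x$square_px, ncol(x$traces), x$n_discarded_px))
  invisible(x)
}

default_response_window <- function(stim_frame, frame_rate, n_frames,
                                    response_s = 30) {
  c(stim_frame, min(n_frames, stim_frame + round(response_s * frame_rate)))
}

#' Detect active grid squares (ROIs) by the k-SD criterion
#'
#' Per square, the baseline mean and sample SD are computed over the
#' frames before the stimulus, the peak is the maximum dFF inside the
#' response window, and the square is an active ROI when
#' `peak > baseline mean + k * SD` (strict). With several repeated
#' stimulations, per-trial peaks are averaged per square before
#' thresholding, and baseline statistics are averaged across trials.
#' Squares with zero baseline SD are flagged for QC (a constant square
#' can never activate; a noiseless responding square still can, since the
#' rule is a strict comparison, not a z-score — no division occurs).
#'
#' @param grid a `grid_traces` object, or a list of them (one per trial,
#'   identical geometry and stimulus frame).
#' @param stim_frame 1-based stimulus frame; must leave >= 3 baseline
#'   frames. Defaults to the first stimulus frame carried by `grid`.
#' @param k threshold in baseline SDs (default 2).
#' @param response_window length-2 frame range searched for the peak;
#'   default `[stim_frame, stim_frame + 30 s]`.
#' @return An object of class `grid_response_map`: data.frame with one
#'   row per square (`square, row, col, baseline_mean, baseline_sd, peak,
#'   active, flagged`) plus attributes `stim_frame`, `response_window`,
#'   `k`, `mask`, `mean_traces` (per-square traces averaged over trials),
#'   `frame_rate`, `n_trials`.
#' @export
detect_active_rois <- function(grid, stim_frame = NULL, k = 2,
                               response_window = NULL) {
  trials <- if (inherits(grid, "grid_traces")) list(grid) else grid
  if (!length(trials) || !all(vapply(trials, inherits, logical(1), "grid_traces")))
    stopf("'grid' must be a grid_traces object or a list of them")
  g1 <- trials[[1L]]
  for (g in trials[-1L])
    if (!identical(dim(g$traces), dim(g1$traces)) ||
        !identical(g$mask, g1$mask))
      stopf("all trials must share the same grid geometry")
  if (is.null(stim_frame)) {
    if (!length(g1$stim_frames)) stopf("no stimulus frame available")
    stim_frame <- g1$stim_frames[1L]
  }
  nT <- ncol(g1$traces)
  if (stim_frame < 4L || stim_frame > nT)
    stopf("stim_frame must leave >= 3 baseline frames (got %d)", stim_frame)
  if (is.null(response_window))
    response_window <- default_response_window(stim_frame, g1$frame_rate, nT)
  response_window <- as.integer(response_window)
  if (response_window[1L] < stim_frame || response_window[2L] > nT ||
      response_window[1L] > response_window[2L])
    stopf("response window [%d, %d] must lie in [stim_frame, %d]",
          response_window[1L], response_window[2L], nT)

  base_idx <- seq_len(stim_frame - 1L)
  win_idx <- seq(response_window[1L], response_window[2L])
  n_sq <- nrow(g1$traces)
  bmean <- bsd <- peak <- matrix(0, n_sq, length(trials))
  for (j in seq_along(trials)) {
    tr <- trials[[j]]$traces
    bmean[, j] <- rowMeans(tr[, base_idx, drop = FALSE])
    bsd[, j] <- apply(tr[, base_idx, drop = FALSE], 1L, stats::sd)
    peak[, j] <- apply(tr[, win_idx, drop = FALSE], 1L, max)
  }
  bm <- rowMeans(bmean); bs <- rowMeans(bsd); pk <- rowMeans(peak)
  active <- pk > bm + k * bs
  flagged <- bs == 0
  res <- data.frame(square = g1$mask$square, row = g1$mask$row,
                    col = g1$mask$col, baseline_mean = bm, baseline_sd = bs,
                    peak = pk, active = active, flagged = flagged)
  mean_traces <- Reduce(`+`, lapply(trials, `[[`, "traces")) / length(trials)
  structure(res, class = c("grid_response_map", "data.frame"),
            stim_frame = stim_frame, response_window = response_window,
            k = k, mask = g1$mask, mean_traces = mean_traces,
            frame_rate = g1$frame_rate, n_trials = length(trials))
}

#' @export
print.grid_response_map <- function(x, ...) {
  cat(sprintf("<grid_response_map> %d/%d squares active (k = %g, stim frame %d, window [%d, %d], %d trial(s))\n",
              sum(x$active), nrow(x), attr(x, "k"), attr(x, "stim_frame"),
              attr(x, "response_window")[1L], attr(x, "response_window")[2L],
              attr(x, "n_trials")))
  if (any(x$flagged))
    cat(sprintf("  %d squares flagged (zero baseline SD)\n", sum(x$flagged)))
  invisible(x)
}

#' Whole-field integrated response
#'
#' Spatial mean over the full field per frame, and its peak within a
#' frame window.
#'
#' @param dff a `movie_stack` in dFF units.
#' @param window length-2 frame range for the peak; default the movie's
#'   default response window after its first stimulus, or the full movie
#'   when it carries no stimulus.
#' @return list with `trace` (a `fluor_trace`) and `peak` (scalar).
#' @export
integrated_response <- function(dff, window = NULL) {
  stopifnot(inherits(dff, "movie_stack"))
  tr <- movie_trace(dff)
  nT <- length(tr$values)
  if (is.null(window)) {
    window <- if (length(dff$stim_frames))
      default_response_window(dff$stim_frames[1L], dff$frame_rate, nT)
    else c(1L, nT)
  }
  window <- as.integer(window)
  if (window[1L] < 1L || window[2L] > nT || window[1L] > window[2L])
    stopf("window [%d, %d] outside movie of %d frames", window[1L], window[2L], nT)
  list(trace = tr, peak = max(tr$values[seq(window[1L], window[2L])]))
}

#' Compare two pharmacological conditions square by square
#'
#' Pairs squares by grid index and reports, per condition, the
#' active-ROI percentage and the integrated peak dFF (peak of the
#' across-squares mean trace inside the response window), plus the
#' fractional change in each. Percent change is `(after - before) /
#' before`; swapping the conditions maps a change `d` to `1/(1+d) - 1`.
#'
#' @param before,after `grid_response_map`s with identical grid geometry
#'   and response windows.
#' @return An object of class `condition_comparison` (a list).
#' @export
compare_conditions <- function(before, after) {
  stopifnot(inherits(before, "grid_response_map"),
            inherits(after, "grid_response_map"))
  if (!identical(attr(before, "mask"), attr(after, "mask")))
    stopf("conditions were analysed on different grids; cannot pair squares")
  if (!identical(attr(before, "response_window"), attr(after, "response_window")) ||
      !identical(attr(before, "stim_frame"), attr(after, "stim_frame")))
    stopf("conditions use different stimulus/response windows")
  win <- attr(before, "response_window")
  widx <- seq(win[1L], win[2L])
  field_peak <- function(m) max(colMeans(attr(m, "mean_traces"))[widx])
  pct <- function(m) 100 * mean(m$active)
  out <- list(
    active_pct = c(before = pct(before), after = pct(after)),
    n_active = c(before = sum(before$active), after = sum(after$active)),
    n_squares = nrow(before),
    integrated_peak = c(before = field_peak(before), after = field_peak(after)))
  out$delta_active <- unname(
    if (out$active_pct[1L] == 0) NA_real_
    else (out$active_pct[2L] - out$active_pct[1L]) / out$active_pct[1L])
  out$delta_integrated <- unname(
    if (out$integrated_peak[1L] == 0) NA_real_
    else (out$integrated_peak[2L] - out$integrated_peak[1L]) / out$integrated_peak[1L])
  structure(out, class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("<condition_comparison> active ROIs %.1f%% -> %.1f%% (change %.1f%%); integrated peak %.4g -> %.4g (change %.1f%%)\n",
              x$active_pct[1L], x$active_pct[2L], 100 * x$delta_active,
              x$integrated_peak[1L], x$integrated_peak[2L],
              100 * x$delta_integrated))
  invisible(x)
}

#' Per-square response heat map
#'
#' Returns the peak (or baseline-subtracted peak) response arranged on
#' the grid, optionally rendered with [graphics::image()].
#'
#' @param map a `grid_response_map`.
#' @param value `"peak"` or `"peak_minus_baseline"`.
#' @param plot draw the heat map?
#' @return numeric matrix (grid rows x grid cols), invisibly when
#'   `plot = TRUE`.
#' @export
roi_heatmap <- function(map, value = c("peak", "peak_minus_baseline"),
                        plot = FALSE) {
  stopifnot(inherits(map, "grid_response_map"))
  value <- match.arg(value)
  v <- if (value == "peak") map$peak else map$peak - map$baseline_mean
  m <- matrix(NA_real_, max(map$row), max(map$col))
  m[cbind(map$row, map$col)] <- v
  if (plot) {
    graphics::image(t(m)[, nrow(m):1, drop = FALSE], axes = FALSE,
                    main = sprintf("%s (%d/%d active)", value,
                                   sum(map$active), nrow(map)))
    return(invisible(m))
  }
  m
}

#' Export a grid response map as CSV
#' @param map a `grid_response_map`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(map, path) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE)
  invisible(path)
}
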