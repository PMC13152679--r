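#' Detect spontaneous waves by z-scored peak finding
#'
#' The trace (already preprocessed: bleach-corrected, low-pass filtered,
#' dFF) is z-scored against its full-trace mean and sample SD. Candidate
#' events are local maxima whose z-score strictly exceeds `z`; candidates
#' closer together than `min_sep` seconds are resolved by keeping the
#' larger peak (ties keep the earlier frame).
#'
#' @param trace a `fluor_trace`.
#' @param z threshold in SD units (default 3).
#' @param min_sep minimum separation between retained events, seconds
#'   (default 10).
#' @param kind event label stored on the catalog (`"wave"` or `"puff"`).
#' @return An object of class `event_catalog`: data.frame with columns
#'   `frame`, `time_s`, `z_value`, plus attributes `kind`, `z_threshold`,
#'   `min_separation_s`, `frame_rate`, `n_frames`.
#' @export
detect_waves <- function(trace, z = 3, min_sep = 10, kind = c("wave", "puff")) {
  stopifnot(inherits(trace, "fluor_trace"))
  kind <- match.arg(kind)
  v <- trace$values
  n <- length(v)
  mu <- mean(v)
  s <- stats::sd(v)
  empty <- data.frame(frame = integer(), time_s = numeric(), z_value = numeric())
  mk <- function(df) structure(df, class = c("event_catalog", "data.frame"),
                               kind = kind, z_threshold = z,
                               min_separation_s = min_sep,
                               frame_rate = trace$frame_rate, n_frames = n)
  if (s == 0) {
    warning("trace has zero SD; no events detectable")
    return(mk(empty))
  }
  zs <- (v - mu) / s
  # local maxima: strictly above the left neighbour, at least the right
  # (so a flat-topped peak is reported at its first frame)
  i <- 2:(n - 1L)
  cand <- i[v[i] > v[i - 1L] & v[i] >= v[i + 1L] & zs[i] > z]
  if (!length(cand)) return(mk(empty))
  # greedy suppression: take candidates by decreasing height (earlier
  # frame on ties), drop any within min_sep of an accepted event
  ord <- cand[order(-zs[cand], cand)]
  keep <- integer()
  for (f in ord) {
    if (!length(keep) || all(abs(f - keep) / trace$frame_rate >= min_sep))
      keep <- c(keep, f)
  }
  keep <- sort(keep)
  mk(data.frame(frame = keep, time_s = (keep - 1) / trace$frame_rate,
                z_value = zs[keep]))
}

#' @export
print.event_catalog <- function(x, ...) {
  cat(sprintf("<event_catalog> %d %s event(s) (z > %g, separation >= %g s)\n",
              nrow(x), attr(x, "kind"), attr(x, "z_threshold"),
              attr(x, "min_separation_s")))
  invisible(x)
}

#' Event-triggered average of one or more channels
#'
#' Each event contributes the trace segment centred on the frame before
#' its peak (`trigger = event frame - 1`), spanning `window/2` seconds on
#' each side. Events whose full window would cross a trace boundary are
#' dropped and counted. All channels use identical trigger frames, so a
#' catalog detected on a high-SNR channel can read out the coupled
#' response of a low-SNR one.
#'
#' @param traces a `fluor_trace` or a named list of them (equal length
#'   and frame rate).
#' @param events an `event_catalog` (non-empty).
#' @param window total window span in seconds (default 60).
#' @return For one channel an object of class `triggered_average`: list
#'   with `time_s` (offsets relative to the trigger), `segments` (matrix,
#'   one column per surviving event), `mean`, `sd`, `n_events_used`,
#'   `n_events_dropped`, `frame_rate`, `window_s`. For a list input, a
#'   named list of such objects.
#' @export
triggered_average <- function(traces, events, window = 60) {
  stopifnot(inherits(events, "event_catalog"))
  if (!nrow(events)) stopf("event catalog is empty")
  single <- inherits(traces, "fluor_trace")
  lst <- if (single) list(trace = traces) else traces
  if (!all(vapply(lst, inherits, logical(1), "fluor_trace")))
    stopf("'traces' must be fluor_trace objects")
  n <- unique(vapply(lst, function(x) length(x$values), integer(1)))
  fr <- unique(vapply(lst, `[[`, numeric(1), "frame_rate"))
  if (length(n) != 1L || length(fr) != 1L)
    stopf("all channels must share length and frame rate")
  half <- round(window / 2 * fr)
  trig <- events$frame - 1L
  ok <- trig - half >= 1L & trig + half <= n
  if (!any(ok))
    stopf("all %d events dropped: %g s window does not fit the trace",
          nrow(events), window)
  used <- trig[ok]
  res <- lapply(lst, function(x) {
    seg <- vapply(used, function(f) x$values[(f - half):(f + half)],
                  numeric(2L * half + 1L))
    seg <- matrix(seg, nrow = 2L * half + 1L)
    structure(list(time_s = (-half:half) / fr,
                   segments = seg,
                   mean = rowMeans(seg),
                   sd = if (ncol(seg) > 1L) apply(seg, 1L, stats::sd)
                        else rep(0, nrow(seg)),
                   n_events_used = length(used),
                   n_events_dropped = sum(!ok),
                   frame_rate = fr, window_s = window),
              class = "triggered_average")
  })
  if (single) res[[1L]] else res
}

#' @export
print.triggered_average <- function(x, ...) {
  cat(sprintf("<triggered_average> %g s window @ %g Hz; %d event(s) used, %d dropped\n",
              x$window_s, x$frame_rate, x$n_events_used, x$n_events_dropped))
  invisible(x)
}

#' Quantify the event-locked response of a triggered average
#'
#' On the mean trace, the peak frame is found inside the `flank_win`
#' seconds before the trigger and inside the `flank_win` seconds after
#' it; each peak value is replaced by the mean over a `peak_win`-second
#' window centred on it (clipped to its flank window, with clipping
#' counted); the response is the after-value minus the before-value.
#'
#' @param ta a `triggered_average`.
#' @param peak_win peak-averaging window, seconds (default 3).
#' @param flank_win pre/post search window, seconds (default 10).
#' @return list with `response`, `before`, `after`, `before_peak_s`,
#'   `after_peak_s`, `n_clipped` (0-2 windows clipped at a flank edge).
#' @export
quantify_response <- function(ta, peak_win = 3, flank_win = 10) {
  stopifnot(inherits(ta, "triggered_average"))
  if (ta$window_s < 2 * flank_win)
    stopf("triggered-average window (%g s) shorter than two %g s flanks",
          ta$window_s, flank_win)
  tsec <- ta$time_s
  m <- ta$mean
  clipped <- 0L
  # the trigger sample itself belongs to neither flank
  flank_value <- function(in_flank) {
    idx <- which(in_flank)
    if (!length(idx)) stopf("flank window outside the triggered average")
    pk <- idx[which.max(m[idx])]
    w0 <- tsec[pk] - peak_win / 2
    w1 <- tsec[pk] + peak_win / 2
    widx <- idx[tsec[idx] >= w0 & tsec[idx] <= w1]
    if (tsec[min(idx)] > w0 || tsec[max(idx)] < w1) clipped <<- clipped + 1L
    list(value = mean(m[widx]), peak_s = tsec[pk])
  }
  before <- flank_value(tsec >= -flank_win & tsec < 0)
  after <- flank_value(tsec > 0 & tsec <= flank_win)
  list(response = after$value - before$value,
       before = before$value, after = after$value,
       before_peak_s = before$peak_s, after_peak_s = after$peak_s,
       n_clipped = clipped)
}

#' Export an event catalog as CSV
#' @param events an `event_catalog`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' Export a triggered average as CSV
#'
#' One row per time offset; columns: `time_s`, one column per event
#' segment, `mean`, `sd`.
#' @param ta a `triggered_average`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_triggered_csv <- function(ta, path) {
  seg <- as.data.frame(ta$segments)
  names(seg) <- sprintf("event_%d", seq_len(ncol(seg)))
  df <- cbind(data.frame(time_s = ta$time_s), seg,
              data.frame(mean = ta$mean, sd = ta$sd))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
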