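# Independent brute-force reference implementations used to cross-check
# the vectorised package code. Deliberately written as plain loops over
# squares/frames/assignments, sharing no code with the implementation.

# ROI detection: loop over every square and frame of raw per-trial dFF
# grid traces.
oracle_detect_rois <- function(trials, stim_frame, k, window) {
  if (inherits(trials, "grid_traces")) trials <- list(trials)
  n_sq <- nrow(trials[[1L]]$traces)
  out <- data.frame(square = seq_len(n_sq), baseline_mean = NA_real_,
                    baseline_sd = NA_real_, peak = NA_real_, active = NA)
  for (s in seq_len(n_sq)) {
    bms <- bsds <- pks <- numeric(length(trials))
    for (j in seq_along(trials)) {
      tr <- trials[[j]]$traces[s, ]
      base <- tr[1:(stim_frame - 1)]
      bms[j] <- sum(base) / length(base)
      bsds[j] <- sqrt(sum((base - bms[j])^2) / (length(base) - 1))
      pk <- -Inf
      for (f in window[1]:window[2]) if (tr[f] > pk) pk <- tr[f]
      pks[j] <- pk
    }
    out$baseline_mean[s] <- mean(bms)
    out$baseline_sd[s] <- mean(bsds)
    out$peak[s] <- mean(pks)
    out$active[s] <- out$peak[s] > out$baseline_mean[s] + k * out$baseline_sd[s]
  }
  out
}

# Mann-Whitney upper/lower tail probabilities from the exact null
# distribution of U provided by base R (dwilcox), independent of the
# package's combn enumeration.
oracle_mw_tail <- function(u, nx, ny) {
  support <- 0:(nx * ny)
  d <- stats::dwilcox(support, nx, ny)
  list(p_greater = sum(d[support >= u]), p_less = sum(d[support <= u]))
}

# Triggered-response quantification by explicit window scans.
oracle_quantify <- function(time_s, mean_trace, peak_win = 3, flank_win = 10) {
  win_value <- function(sel) {
    idx <- which(sel)
    best <- idx[1]
    for (i in idx) if (mean_trace[i] > mean_trace[best]) best <- i
    w <- idx[time_s[idx] >= time_s[best] - peak_win / 2 &
             time_s[idx] <= time_s[best] + peak_win / 2]
    mean(mean_trace[w])
  }
  win_value(time_s > 0 & time_s <= flank_win) -
    win_value(time_s >= -flank_win & time_s < 0)
}

# Wave detection oracle: enumerate local maxima above threshold by a
# plain loop, then apply the keep-the-larger rule recursively — the
# tallest candidate (earliest frame on ties) is always kept and all
# candidates within min_sep of it are discarded.
oracle_detect_waves <- function(values, frame_rate, z = 3, min_sep = 10) {
  mu <- mean(values); s <- stats::sd(values)
  if (s == 0) return(integer())
  zs <- (values - mu) / s
  n <- length(values)
  cand <- integer()
  for (i in 2:(n - 1))
    if (values[i] > values[i - 1] && values[i] >= values[i + 1] && zs[i] > z)
      cand <- c(cand, i)
  resolve <- function(cand) {
    if (length(cand) <= 1) return(cand)
    best <- cand[1]
    for (f in cand) if (zs[f] > zs[best]) best <- f
    rest <- cand[abs(cand - best) / frame_rate >= min_sep]
    sort(c(best, resolve(rest)))
  }
  resolve(cand)
}
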