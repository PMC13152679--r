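test_that("wave detection finds injected transients at their sampled peaks", {
  fr <- 2; nT <- 200L
  t <- (0:(nT - 1)) / fr
  mk <- function(onsets, amps = 1) {
    v <- rep(0, nT)
    amps <- rep_len(amps, length(onsets))
    for (i in seq_along(onsets))
      v <- v + amps[i] * rise_decay_kernel(t - t[onsets[i]], 0.8, 3)
    fluor_trace(v, fr)
  }
  # 3 transients spaced 20 s apart: exactly 3 events at the sampled peaks
  tr <- mk(c(30L, 70L, 110L))
  ev <- detect_waves(tr, z = 1.5, min_sep = 10)   # sparse signal, low z floor
  kern <- rise_decay_kernel(t, 0.8, 3)
  off <- which.max(kern) - 1L
  expect_identical(ev$frame, c(30L, 70L, 110L) + off)

  # flat trace: empty catalog with a warning
  expect_warning(e0 <- detect_waves(fluor_trace(rep(1, 50), fr)), "zero SD")
  expect_identical(nrow(e0), 0L)

  # two transients 5 s apart with unequal heights: one event, the larger
  # (fast kinetics so the first transient's tail does not move the peak)
  v2 <- 0.6 * rise_decay_kernel(t - t[50], 0.5, 1) +
    1.0 * rise_decay_kernel(t - t[60], 0.5, 1)
  ev2 <- detect_waves(fluor_trace(v2, fr), z = 0.5, min_sep = 10)
  off2 <- which.max(rise_decay_kernel(t, 0.5, 1)) - 1L
  expect_identical(nrow(ev2), 1L)
  expect_identical(ev2$frame, 60L + off2)
})

test_that("wave detection matches the recursive keep-the-larger oracle", {
  set.seed(55)
  fr <- 2
  for (case in 1:60) {
    nT <- 150L
    t <- (0:(nT - 1)) / fr
    v <- rnorm(nT, 0, 0.2)
    for (o in sample(5:(nT - 10), sample(2:6, 1)))
      v <- v + runif(1, 0.5, 3) * rise_decay_kernel(t - t[o], 0.5, 2)
    z <- runif(1, 1, 3); ms <- runif(1, 2, 12)
    tr <- fluor_trace(v, fr)
    expect_identical(detect_waves(tr, z = z, min_sep = ms)$frame,
                     as.integer(oracle_detect_waves(v, fr, z = z, min_sep = ms)))
  }
})

test_that("event count is non-increasing in the threshold and the separation", {
  set.seed(14)
  fr <- 2; nT <- 300L
  t <- (0:(nT - 1)) / fr
  v <- rnorm(nT, 0, 0.1)
  for (o in c(20, 60, 90, 150, 210, 260))
    v <- v + runif(1, 0.5, 2) * rise_decay_kernel(t - t[o], 0.5, 2)
  tr <- fluor_trace(v, fr)
  n_by_z <- vapply(c(0.5, 1, 2, 3, 4),
                   function(z) nrow(detect_waves(tr, z = z, min_sep = 5)),
                   integer(1))
  expect_true(all(diff(n_by_z) <= 0))
  n_by_sep <- vapply(c(2, 5, 10, 20, 40),
                     function(ms) nrow(detect_waves(tr, z = 1, min_sep = ms)),
                     integer(1))
  expect_true(all(diff(n_by_sep) <= 0))
})

test_that("triggered averaging centres on the pre-peak frame and drops boundary events", {
  fr <- 1; nT <- 300L
  v <- rnorm(nT, 0, 0.01)
  v[100] <- 5; v[200] <- 5
  tr <- fluor_trace(v, fr)
  ev <- detect_waves(tr, z = 3, min_sep = 10)
  expect_identical(ev$frame, c(100L, 200L))

  ta <- triggered_average(tr, ev, window = 60)
  half <- 30L
  expect_identical(ta$n_events_used, 2L)
  expect_equal(ta$time_s, (-half:half) / fr)
  # segments are centred on the frame before each peak
  expect_equal(ta$segments[, 1], v[(99 - half):(99 + half)])
  expect_equal(ta$mean, rowMeans(ta$segments))

  # identical injected transients: per-event SD is ~ the noise, peak aligned
  expect_identical(which.max(ta$segments[, 1]), which.max(ta$segments[, 2]))

  # an event too close to the start is dropped and counted
  v2 <- v; v2[2] <- 7
  tr2 <- fluor_trace(v2, fr)
  ev2 <- detect_waves(tr2, z = 3, min_sep = 10)
  ta2 <- triggered_average(tr2, ev2, window = 60)
  expect_identical(ta2$n_events_dropped, 1L)
  expect_identical(ta2$n_events_used, 2L)

  # all events dropped: refuse with detail
  short <- fluor_trace(v[1:110], fr)
  ev3 <- detect_waves(short, z = 3, min_sep = 10)
  expect_error(triggered_average(short, ev3, window = 400), "dropped")
})

test_that("triggered averaging is shift equivariant and shares triggers across channels", {
  fr <- 2; nT <- 400L
  set.seed(9)
  base <- rnorm(nT, 0, 0.05)
  t <- (0:(nT - 1)) / fr
  sig <- function(onsets) {
    v <- base
    for (o in onsets) v <- v + 2 * rise_decay_kernel(t - t[o], 0.5, 2)
    v
  }
  shift <- 40L
  v1 <- sig(c(120L, 240L))
  v2 <- c(rep(0, shift), v1)[1:nT]           # same trace, delayed
  ev1 <- detect_waves(fluor_trace(v1, fr), z = 2)
  ev2 <- detect_waves(fluor_trace(v2, fr), z = 2)
  ta1 <- triggered_average(fluor_trace(v1, fr), ev1, window = 30)
  ta2 <- triggered_average(fluor_trace(v2, fr), ev2, window = 30)
  expect_equal(ta2$mean, ta1$mean, tolerance = 0.05)

  # second channel is cut at the first channel's triggers
  ch2 <- fluor_trace(0.1 * v1 + 0.5, fr)
  both <- triggered_average(list(ca = fluor_trace(v1, fr), nir = ch2), ev1,
                            window = 30)
  expect_equal(both$nir$mean, 0.1 * ta1$mean + 0.5, tolerance = 1e-12)
})

test_that("response quantification handles steps, offsets, scaling, and matches the oracle", {
  fr <- 2; half <- 60L
  mk_ta <- function(mean_trace) {
    structure(list(time_s = (-half:half) / fr, segments = cbind(mean_trace),
                   mean = mean_trace, sd = rep(0, 2 * half + 1),
                   n_events_used = 1L, n_events_dropped = 0L,
                   frame_rate = fr, window_s = 2 * half / fr),
              class = "triggered_average")
  }
  # zero trace: zero response
  expect_equal(quantify_response(mk_ta(rep(0, 2 * half + 1)))$response, 0)

  # step of height h at the trigger: response = h
  step <- c(rep(0, half), rep(2.5, half + 1))
  expect_equal(quantify_response(mk_ta(step))$response, 2.5)

  # invariance to constant offsets, linearity in scale
  set.seed(77)
  tt <- (-half:half) / fr
  v <- rise_decay_kernel(tt - 1, 0.8, 3) + rnorm(length(tt), 0, 0.05)
  q <- quantify_response(mk_ta(v))
  expect_equal(quantify_response(mk_ta(v + 11))$response, q$response,
               tolerance = 1e-12)
  expect_equal(quantify_response(mk_ta(3 * v))$response, 3 * q$response,
               tolerance = 1e-12)

  # brute-force window oracle on random traces
  for (case in 1:50) {
    v <- rnorm(2 * half + 1)
    expect_equal(quantify_response(mk_ta(v))$response,
                 oracle_quantify(tt, v), tolerance = 1e-12)
  }

  # flanks wider than the average span are rejected
  expect_error(quantify_response(mk_ta(step), flank_win = 40), "flank")
})
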