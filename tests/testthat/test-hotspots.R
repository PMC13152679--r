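test_that("grid tiling has the right square count, traces, and edge handling", {
  # 256 x 256 at 8 px: 32 x 32 = 1024 squares
  m <- movie_stack(array(1, dim = c(2, 256, 256)), 1.47)
  g <- apply_grid(m, 8L)
  expect_identical(nrow(g$traces), 1024L)
  expect_identical(g$n_discarded_px, 0L)

  # uniform movie: every square trace equals the global mean trace
  set.seed(3)
  v <- 5 + cumsum(rnorm(12))
  um <- uniform_movie(v, 16L, 16L)
  gu <- apply_grid(um, 8L)
  for (s in seq_len(nrow(gu$traces))) expect_equal(unname(gu$traces[s, ]), v)

  # one bright grid-aligned 8x8 block dominates every frame
  arr <- array(1, dim = c(5, 24, 24))
  arr[, 9:16, 17:24] <- 9
  gb <- apply_grid(movie_stack(arr, 2), 8L)
  bright <- which(gb$mask$row == 2 & gb$mask$col == 3)
  for (f in 1:5)
    expect_identical(which.max(gb$traces[, f]), bright)

  # trailing partial squares are discarded and counted
  gp <- apply_grid(movie_stack(array(0, dim = c(2, 20, 19)), 2), 8L)
  expect_identical(nrow(gp$traces), 4L)
  expect_identical(gp$n_discarded_px, 20L * 19L - 4L * 64L)
})

test_that("ROI detection agrees square-by-square with the brute-force oracle", {
  set.seed(101)
  for (case in 1:200) {
    nT <- sample(25:40, 1)
    stim <- sample(8:12, 1)
    n_trials <- sample(1:3, 1)
    win <- c(stim, min(nT, stim + sample(3:10, 1)))
    trials <- lapply(seq_len(n_trials), function(j) {
      arr <- array(rnorm(nT * 12 * 12), dim = c(nT, 12, 12))
      # sprinkle a few responding blocks
      for (b in seq_len(sample(0:3, 1))) {
        r <- sample(1:3, 1); cc <- sample(1:3, 1)
        arr[win[1]:win[2], (r*4-3):(r*4), (cc*4-3):(cc*4)] <-
          arr[win[1]:win[2], (r*4-3):(r*4), (cc*4-3):(cc*4)] + runif(1, 0, 4)
      }
      apply_grid(movie_stack(arr, 2, units = "dff"), 4L)
    })
    got <- detect_active_rois(trials, stim, k = 2, response_window = win)
    want <- oracle_detect_rois(trials, stim, 2, win)
    expect_equal(got$baseline_mean, want$baseline_mean, tolerance = 1e-12)
    expect_equal(got$baseline_sd, want$baseline_sd, tolerance = 1e-12)
    expect_equal(got$peak, want$peak, tolerance = 1e-12)
    expect_identical(got$active, want$active)
  }
})

test_that("raising the threshold never adds ROIs and zero-SD squares are flagged", {
  set.seed(7)
  arr <- array(rnorm(30 * 8 * 8), dim = c(30, 8, 8))
  arr[, 1:4, 1:4] <- 3   # constant block: zero baseline SD
  arr[20:25, 5:8, 5:8] <- arr[20:25, 5:8, 5:8] + 5
  g <- apply_grid(movie_stack(arr, 2, units = "dff"), 4L)
  counts <- vapply(c(0.5, 1, 2, 3, 5),
                   function(k) sum(detect_active_rois(g, 10L, k = k,
                                     response_window = c(18L, 28L))$active),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  m <- detect_active_rois(g, 10L, k = 2, response_window = c(18L, 28L))
  expect_true(m$flagged[m$row == 1 & m$col == 1])
  expect_false(m$active[m$row == 1 & m$col == 1])   # constant square never fires

  # all-constant movie: zero active squares
  m0 <- detect_active_rois(apply_grid(uniform_movie(rep(2, 30)), 4L),
                           10L, response_window = c(12L, 20L))
  expect_identical(sum(m0$active), 0L)
})

test_that("the active set is invariant to affine rescaling of raw intensity", {
  fx <- generate_striatal_fixture(test_striatal_config(seed = 2L))
  win <- fx$truth$response_window
  m1 <- analyse_trials(fx$nir, fx$truth$stim_frame, win)
  scaled <- lapply(fx$nir, function(m) { m$data <- m$data * 3.7; m })
  m2 <- analyse_trials(scaled, fx$truth$stim_frame, win)
  expect_identical(m1$active, m2$active)
})

test_that("integrated response reduces to areal means and peaks", {
  # uniform transient of peak 0.2
  v <- c(0, 0, 0.2, 0.1, 0)
  um <- uniform_movie(v, 8L, 8L); um$units <- "dff"
  ir <- integrated_response(um, c(1L, 5L))
  expect_equal(ir$peak, 0.2)
  expect_equal(ir$trace$values, v)

  # two disjoint blocks, each area fraction f with peak a: field peak 2 f a
  arr <- array(0, dim = c(4, 16, 16))
  arr[2, 1:4, 1:4] <- 0.8; arr[2, 9:12, 9:12] <- 0.8
  m <- movie_stack(arr, 2, units = "dff")
  expect_equal(integrated_response(m, c(1L, 4L))$peak, 2 * (16 / 256) * 0.8)

  # mean of per-square traces equals the full-field trace on an exact tiling
  set.seed(8)
  arr2 <- array(rnorm(5 * 16 * 16), dim = c(5, 16, 16))
  mm <- movie_stack(arr2, 2, units = "dff")
  g <- apply_grid(mm, 4L)
  expect_equal(colMeans(g$traces), movie_trace(mm)$values, tolerance = 1e-12)

  expect_error(integrated_response(um, c(2L, 9L)), "outside")
})

test_that("condition comparison pairs grids, reports deltas, and is antisymmetric", {
  fx <- generate_striatal_fixture(test_striatal_config())
  win <- fx$truth$response_window
  before <- analyse_trials(fx$nir, fx$truth$stim_frame, win)

  same <- compare_conditions(before, before)
  expect_equal(same$delta_active, 0)
  expect_equal(same$delta_integrated, 0)

  fq <- generate_striatal_fixture(test_striatal_config(), amplitude_scale = 0.4)
  after <- analyse_trials(fq$nir, fq$truth$stim_frame, win)
  fwd <- compare_conditions(before, after)
  rev <- compare_conditions(after, before)
  # percent changes compose to identity under swapping
  expect_equal((1 + fwd$delta_active) * (1 + rev$delta_active), 1,
               tolerance = 1e-12)
  expect_equal((1 + fwd$delta_integrated) * (1 + rev$delta_integrated), 1,
               tolerance = 1e-12)

  # suppressing all release: every ROI disappears
  f0 <- generate_striatal_fixture(test_striatal_config(), amplitude_scale = 0)
  none <- analyse_trials(f0$nir, f0$truth$stim_frame, win)
  gone <- compare_conditions(before, none)
  expect_equal(gone$delta_active, -1)

  # different grids cannot be paired
  g1 <- analyse_trials(fx$nir, fx$truth$stim_frame, win, square_px = 16L)
  expect_error(compare_conditions(before, g1), "different grids")
})

test_that("heat map arranges per-square peaks on the grid", {
  fx <- generate_striatal_fixture(test_striatal_config())
  m <- analyse_trials(fx$nir, fx$truth$stim_frame, fx$truth$response_window)
  h <- roi_heatmap(m)
  expect_identical(dim(h), c(8L, 8L))
  expect_equal(h[cbind(m$row, m$col)], m$peak)
})
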