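test_that("Hill sensor response matches its defining algebra", {
  m <- sensor_model("s", kd = 4, hill_n = 1, dff_max = 0.8,
                    tau_on = 1, tau_off = 5)
  conc <- uniform_movie(c(0, 4, 40, 4e6), 2L, 2L)
  conc$units <- "uM"
  r <- sensor_response(conc, m)
  expect_equal(r$data[1, 1, 1], 0)                       # zero ligand
  expect_equal(r$data[2, 1, 1], 0.4)                     # half-saturation at Kd
  expect_equal(r$data[3, 1, 1], 0.8 * 10 / 11)           # C = 10 Kd, n = 1
  expect_lt(max(r$data), 0.8 + 1e-12)                    # bounded by dff_max
  conc$data[1, 1, 1] <- -1
  expect_error(sensor_response(conc, m), "concentrations")
})

test_that("sensor response is monotone in concentration for any Hill slope", {
  for (n_h in c(0.5, 1, 2.4)) {
    m <- sensor_model("s", kd = 7, hill_n = n_h, dff_max = 1.2,
                      tau_on = 1, tau_off = 2)
    cv <- sort(runif(50, 0, 100))
    conc <- movie_stack(array(cv, dim = c(50, 1, 1)), 1, units = "uM")
    r <- sensor_response(conc, m)
    expect_true(all(diff(r$data[, 1, 1]) >= 0))
  }
})

test_that("concentration movies superpose and peak at the analytic kernel time", {
  model <- sensor_model("s", kd = 1, dff_max = 1, tau_on = 1, tau_off = 5)
  cfg <- synthetic_config(n_frames = 400L, height = 8L, width = 8L,
                          frame_rate = 20, pixel_size = 1, f0_mean = 100,
                          noise_sd = 0, seed = 1L)
  # centre on a pixel centre so the peak value is attained exactly
  field <- hotspot_field(centers = rbind(c(3.5, 3.5)), sigma = 1.2,
                         amplitudes = 10, background = 0)
  # one event: maximum at the hotspot-centre pixel sits at the analytic
  # kernel peak t_event + tau_on log(1 + tau_off/tau_on)
  p1 <- stimulus_protocol(40L)
  m1 <- simulate_concentration(field, p1, model, cfg)
  ctr <- m1$data[, 4, 4]
  t_peak <- (which.max(ctr) - 1) / 20
  t_expect <- (40 - 1) / 20 + rise_decay_peak_time(1, 5)
  expect_lt(abs(t_peak - t_expect), 0.5 / 20 + 1e-9)     # within half a frame
  expect_equal(max(ctr), 10, tolerance = 1e-3)           # normalised kernel
  expect_true(all(m1$data[1:39, , ] == 0))               # silent before event

  # superposition: disjoint event sets add to their union
  p2 <- stimulus_protocol(200L)
  p12 <- stimulus_protocol(c(40L, 200L))
  m2 <- simulate_concentration(field, p2, model, cfg)
  m12 <- simulate_concentration(field, p12, model, cfg)
  expect_equal(m12$data, m1$data + m2$data, tolerance = 1e-12)

  # two non-overlapping hotspots add linearly; movie max tracks the larger
  f2 <- hotspot_field(centers = rbind(c(1.5, 1.5), c(5.5, 5.5)), sigma = 0.5,
                      amplitudes = c(3, 8), background = 0.5)
  mm <- simulate_concentration(f2, p1, model, cfg)
  expect_equal(max(mm$data), 8 + 0.5, tolerance = 1e-2)

  expect_error(simulate_concentration(field, stimulus_protocol(500L), model, cfg),
               "within")
  # empty hotspot list: background-only movie
  f0 <- hotspot_field(matrix(numeric(), 0, 2), sigma = 1, amplitudes = numeric(),
                      background = 0.7)
  m0 <- simulate_concentration(f0, p1, model, cfg)
  expect_true(all(m0$data == 0.7))
})

test_that("no events and zero background give an all-zero movie", {
  model <- nircat_model()
  cfg <- synthetic_config(n_frames = 10L, height = 4L, width = 4L,
                          frame_rate = 2, pixel_size = 1, noise_sd = 0)
  field <- hotspot_field(rbind(c(2, 2)), sigma = 1, amplitudes = 5,
                         background = 0)
  m <- simulate_concentration(field, stimulus_protocol(integer()), model, cfg)
  expect_true(all(m$data == 0))
})

test_that("rendering is deterministic, respects noiseless limits, and clips loudly", {
  dff <- uniform_movie(rep(0, 20), 4L, 4L)
  dff$units <- "dff"
  cfg <- synthetic_config(n_frames = 20L, height = 4L, width = 4L,
                          frame_rate = 2, f0_mean = 1000, noise_sd = 0,
                          bleach = c(1, 1e12, 0.0001, 1e12), seed = 7L)
  m <- render_movie(dff, cfg)
  expect_true(all(m$data == 1000))                       # constant at f0

  cfg$noise_sd <- 25
  m1 <- render_movie(dff, cfg)
  m2 <- render_movie(dff, cfg)
  expect_identical(m1$data, m2$data)                     # same seed, same bits
  cfg$seed <- 8L
  expect_false(identical(render_movie(dff, cfg)$data, m1$data))

  cfg_hot <- cfg
  cfg_hot$f0_mean <- 65000; cfg_hot$noise_sd <- 5000
  expect_warning(render_movie(dff, cfg_hot), "clipped")

  cfg_p <- cfg; cfg_p$noise_model <- "poisson"
  expect_identical(render_movie(dff, cfg_p)$data, render_movie(dff, cfg_p)$data)
})

test_that("pure double-exponential bleach round-trips through the corrector", {
  dff <- uniform_movie(rep(0, 600), 2L, 2L, frame_rate = 2)
  dff$units <- "dff"
  cfg <- synthetic_config(n_frames = 600L, height = 2L, width = 2L,
                          frame_rate = 2, f0_mean = 20000, noise_sd = 0,
                          bleach = c(0.6, 20, 0.4, 200), seed = 1L)
  m <- render_movie(dff, cfg)
  tr <- fluor_trace(m$data[, 1, 1], 2)
  fit <- correct_bleach(tr)
  expect_true(fit$converged)
  # recover (a1, tau1, a2, tau2) of the generator within 1 %
  ord <- order(c(fit$pars[["tau1"]], fit$pars[["tau2"]]))
  taus <- c(fit$pars[["tau1"]], fit$pars[["tau2"]])[ord]
  amps <- c(fit$pars[["A1"]], fit$pars[["A2"]])[ord]
  expect_equal(taus, c(20, 200), tolerance = 0.01)
  expect_equal(amps, 20000 * c(0.6, 0.4), tolerance = 0.01)
})

test_that("affinity contrast puts the linear-regime nIR response three orders below the high-affinity channel", {
  g <- grab_da3m_model(); n <- nircat_model()
  ratio <- (n$dff_max / n$kd) / (g$dff_max / g$kd)
  expect_equal(ratio, 1e-3, tolerance = 1e-9)
  # realised on a weak (linear-regime for both) concentration step
  conc <- uniform_movie(c(0, 0.002), 2L, 2L); conc$units <- "uM"
  rg <- sensor_response(conc, g)$data[2, 1, 1]
  rn <- sensor_response(conc, n)$data[2, 1, 1]
  expect_equal(rn / rg, 1e-3, tolerance = 0.1)
})

test_that("wave fixture honours its separation contract and noiseless recovery", {
  cfg <- synthetic_config(n_frames = 400L, height = 4L, width = 4L,
                          frame_rate = 2, f0_mean = 2000, noise_sd = 0,
                          bleach = c(1, 1e12, 0.0001, 1e12), seed = 3L)
  expect_error(generate_wave_fixture(cfg, wave_frames = c(50L, 60L),
                                     nir_noise_sd = 0),
               "separated")
  fx <- generate_wave_fixture(cfg, wave_frames = c(60L, 180L, 300L),
                              nir_noise_sd = 0)
  tr <- compute_dff(movie_trace(fx$ca), baseline_spec("trial_median"))
  ev <- detect_waves(tr, z = 3, min_sep = 10)
  expect_identical(ev$frame, as.integer(fx$truth$peak_frames))

  # no waves: baseline only, detector returns an empty catalog
  fx0 <- generate_wave_fixture(cfg, wave_frames = integer(), nir_noise_sd = 0)
  tr0 <- movie_trace(fx0$ca)
  expect_warning(ev0 <- detect_waves(tr0, z = 3), "zero SD")
  expect_identical(nrow(ev0), 0L)
})
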