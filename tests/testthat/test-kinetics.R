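# Kinetics: normalisation, patterned-system mask, traces, derivative,
# responders, depth profiles, washout fits.

test_that("first-frame normalisation is exact and invertible", {
  s <- small_sim()
  off <- 0.01
  nrm <- normalize_to_first_frame(s$stack, offset = off)
  expect_true(all(abs(nrm$data[1, 1, 1, , ] - 1) < 1e-12))
  # inverse: output x (frame1 + offset) - offset reproduces the input
  ref <- s$stack$data[1, 1, 1, , ] + off
  for (k in c(5, 20)) {
    back <- nrm$data[k, 1, 1, , ] * ref - off
    expect_lt(max(abs(back - s$stack$data[k, 1, 1, , ])), 1e-9)
  }
  # a c-scaled static stack normalises to c (up to the guard offset)
  st <- matrix(runif(64, 1, 2), 8, 8)
  arr <- array(0, c(3, 1, 1, 8, 8))
  for (k in 1:3) arr[k, 1, 1, , ] <- 2.5 * st
  stk <- papt_stack(arr, 1, 1, axes = "TZCYX")
  nr2 <- normalize_to_first_frame(stk, offset = 1e-9)
  expect_equal(as.vector(nr2$data[3, 1, 1, , ]), rep(1, 64),
               tolerance = 1e-6)
})

test_that("patterned-system mask is cumulative and covers the puncta", {
  geom <- generate_islet_geometry(9, 192, seed = 51)
  prot <- stimulus_protocol(0, 1200, "c", 1)
  rates <- simulate_rates(prot, geom$cell_types, baseline_rate = 2e-3,
                          heterogeneity_cv = 0, seed = 51)
  sim <- render_movie(geom, rates, n_frames = 40, photon_scale = Inf,
                      read_noise_sd = 0, puncta_min_sep_px = 6, seed = 51)
  det <- detect_stack(sim$stack, scale_space_params(),
                      border_mask = sim$truth$border_mask,
                      cell_label_map = sim$truth$label_map)
  mask <- build_papt_mask(sim$stack, det, scale_space_params(),
                          cell_mask = sim$truth$label_map > 0)
  # cumulative: mask(t) subset of mask(t+1)
  for (t in 1:39) expect_equal(sum(mask[, , t] & !mask[, , t + 1]), 0L)
  # covers bright punctum pixels (> half max) at the final frame
  tp <- sim$truth$puncta
  skip_if(nrow(tp) < 5)
  clean <- matrix(0, 192, 192)
  for (j in seq_len(nrow(tp))) {
    clean <- paptkit:::stamp_punctum(clean, tp$y[j], tp$x[j], 1, 1)
  }
  bright <- clean > 0.5 & sim$truth$label_map > 0
  expect_gte(sum(mask[, , 40] & bright) / sum(bright), 0.95)
  # stays off the empty background: few interior pixels far from puncta
  bg <- sim$truth$label_map > 0 & !(clean > 0.02)
  expect_lt(sum(mask[, , 40] & bg) / sum(bg), 0.05)
  # no detections + infinite network threshold -> empty masks
  m0 <- build_papt_mask(sim$stack, det[0, ], scale_space_params(),
                        network_threshold = Inf)
  expect_equal(sum(m0), 0L)
})

test_that("papt traces conserve punctum brightness and stay non-negative", {
  geom <- generate_islet_geometry(1, 128, cell_diameter = 16, seed = 52)
  prot <- stimulus_protocol(0, 2400, "c", 1)
  rates <- simulate_rates(prot, geom$cell_types, baseline_rate = 4e-3,
                          heterogeneity_cv = 0, seed = 52)
  # unit *integrated* brightness: peak = 1 / (2 pi sigma^2)
  sim <- render_movie(geom, rates, chamber_kinetics(0, 1e-6), 30, 80,
                      photon_scale = Inf, read_noise_sd = 0,
                      haze_fraction = 0, tracer_amplitude = 0,
                      bleach_tau_s = Inf, psf_sigma = 1,
                      puncta_peak = 1 / (2 * pi), puncta_min_sep_px = 5,
                      seed = 52)
  n_born <- nrow(sim$truth$puncta)
  skip_if(n_born < 3)
  det <- detect_stack(sim$stack, scale_space_params(),
                      cell_label_map = sim$truth$label_map)
  # disks of 4 PSF sigma capture >99.9% of each spot's flux; the network
  # term is disabled so the conservation bookkeeping is exact
  mask <- build_papt_mask(sim$stack, det, scale_space_params(),
                          cell_mask = sim$truth$label_map > 0,
                          dilation_radius = 4, network_threshold = Inf)
  tr <- cell_trace(sim$stack, sim$truth$label_map, mask)
  plateau <- tr$papt[tr$frame == 80]
  expect_equal(plateau, n_born, tolerance = 0.02)
  expect_true(all(tr$papt >= 0))
  # noise-free cumulative masks give non-decreasing traces
  expect_true(all(diff(tr$papt) > -1e-9))
})

test_that("zero-rate movies give near-zero traces", {
  geom <- generate_islet_geometry(9, 192, seed = 53)
  prot <- stimulus_protocol(0, 1200, "c", 1)
  rates <- simulate_rates(prot, geom$cell_types, baseline_rate = 0, seed = 53)
  sim <- render_movie(geom, rates, n_frames = 30, seed = 53)
  ana <- papt_analyze(sim$stack, scale_space_params(), sim$truth$label_map,
                      border_mask = sim$truth$border_mask)
  # PAPT stays within a few noise standard errors of zero
  area <- pmax(ana$traces$mask_area_px, 1)
  noise_se <- 0.2 * sqrt(area)
  expect_gt(mean(ana$traces$papt < 3 * noise_se + 1e-9), 0.95)
})

test_that("the smoothed derivative is exact on polynomials and linear", {
  expect_equal(trace_derivative(rep(4, 20), 30), rep(0, 20))
  ramp <- 0.25 * (0:19)
  d <- trace_derivative(ramp, dt = 2, smooth_window = 5)
  expect_equal(d, rep(0.125, 20), tolerance = 1e-9)
  set.seed(5)
  x <- rnorm(40); y <- rnorm(40)
  expect_equal(trace_derivative(2 * x + 3 * y, 1),
               2 * trace_derivative(x, 1) + 3 * trace_derivative(y, 1),
               tolerance = 1e-12)
})

test_that("orchestrated analysis equals the modular mask + trace path", {
  geom <- generate_islet_geometry(9, 192, seed = 54)
  prot <- stimulus_protocol(0, 1200, "c", 1)
  rates <- simulate_rates(prot, geom$cell_types, baseline_rate = 2e-3,
                          heterogeneity_cv = 0, seed = 54)
  sim <- render_movie(geom, rates, n_frames = 25, seed = 54)
  ana <- papt_analyze(sim$stack, scale_space_params(), sim$truth$label_map,
                      border_mask = sim$truth$border_mask)
  det <- detect_stack(sim$stack, scale_space_params(),
                      border_mask = sim$truth$border_mask,
                      cell_label_map = sim$truth$label_map)
  mask <- build_papt_mask(sim$stack, det, scale_space_params(),
                          cell_mask = sim$truth$label_map > 0)
  tr <- cell_trace(sim$stack, sim$truth$label_map, mask)
  expect_equal(ana$detections$y, det$y)
  expect_equal(ana$traces$papt, tr$papt, tolerance = 1e-12)
})

test_that("responder classification recovers programmed activity patterns", {
  # all strongly active -> fraction 1; synthetic small islet
  geom <- generate_islet_geometry(9, 192, seed = 55)
  prot <- stimulus_protocol(c(0, 900), c(900, 1500), c("off", "on"), c(0, 12))
  rates <- simulate_rates(prot, geom$cell_types, baseline_rate = 3e-3,
                          heterogeneity_cv = 0, seed = 55)
  sim <- render_movie(geom, rates, n_frames = 50, photon_scale = 160,
                      read_noise_sd = 0.05, seed = 55)
  ana <- papt_analyze(sim$stack, scale_space_params(), sim$truth$label_map,
                      border_mask = sim$truth$border_mask)
  # baseline after wash-in completes (~520 s), stimulus from the step on
  res <- classify_responders(ana$traces, baseline_frames = 19:30,
                             stimulus_frames = 31:50)
  expect_equal(res$active_fraction, 1.0)
  expect_true(res$ci95["lower"] <= 1 && res$ci95["upper"] == 1)
  expect_error(classify_responders(ana$traces, 10:30, 25:50), "precede")
})

test_that("depth profiles bin cells into layers and conserve counts", {
  s <- small_sim()
  ana <- papt_analyze(s$stack, scale_space_params(), s$truth$label_map,
                      border_mask = s$truth$border_mask)
  depths <- compute_depth(s$truth$label_map, s$truth$hull, 0.4)
  prof <- depth_profile(ana$traces, depths, layer_width = 10)
  expect_equal(sum(tapply(prof$n_cells, prof$layer, unique)),
               length(unique(ana$traces$cell_label)))
  # single wide layer equals the islet mean
  prof1 <- depth_profile(ana$traces, depths, layer_width = 1000)
  isl <- attr(ana$traces, "islet")
  expect_equal(prof1$mean_papt, isl$papt, tolerance = 1e-9)
})

test_that("washout fits recover programmed chamber kinetics", {
  tt <- seq(0, 1195, 5)                  # the 5-s chamber characterisation
  y <- ifelse(tt < 138, 0, 1 - exp(-(tt - 138) / 126))
  f <- fit_washout(y, tt)
  expect_equal(f$lag_time, 138, tolerance = 138 * 0.01)
  expect_equal(f$clearance_tau, 126, tolerance = 126 * 0.01)
  # washout phase, mirrored
  yw <- ifelse(tt < 100, 1, exp(-(tt - 100) / 126))
  fw <- fit_washout(yw, tt, phase = "washout")
  expect_equal(fw$clearance_tau, 126, tolerance = 126 * 0.02)
  # tau -> 0 limit: a step is fitted with the lag at the step time
  ys <- as.numeric(tt >= 300)
  fs <- fit_washout(ys, tt)
  expect_lt(abs(fs$lag_time - 300), 5)
  expect_error(fit_washout(rep(0, 100), seq_len(100)), "no signal")
})

test_that("noisy washout recovery is within 5% (median over 100 traces)", {
  tt <- seq(0, 1195, 5)
  y <- ifelse(tt < 138, 0, 1 - exp(-(tt - 138) / 126))
  set.seed(19)
  errs <- vapply(1:100, function(i) {
    fn <- fit_washout(y + rnorm(length(y), 0, 0.05), tt)
    c(abs(fn$lag_time - 138) / 138, abs(fn$clearance_tau - 126) / 126)
  }, numeric(2))
  expect_lt(median(errs[1, ]), 0.05)
  expect_lt(median(errs[2, ]), 0.05)
})
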