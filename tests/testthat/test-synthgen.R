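# Synthetic generator: geometry, rates, rendering, and its ground truth.

test_that("islet geometry is reproducible, labelled and bordered", {
  g <- generate_islet_geometry(64, 512, seed = 1)
  g2 <- generate_islet_geometry(64, 512, seed = 1)
  expect_identical(g$label_map, g2$label_map)
  expect_setequal(unique(as.vector(g$label_map)), 0:64)
  # cells are pairwise disjoint by construction; each separated from its
  # neighbours by border pixels: no two 4-adjacent pixels carry different
  # positive labels
  lab <- g$label_map
  h <- lab[, -1] > 0 & lab[, -ncol(lab)] > 0 & lab[, -1] != lab[, -ncol(lab)]
  v <- lab[-1, ] > 0 & lab[-nrow(lab), ] > 0 & lab[-1, ] != lab[-nrow(lab), ]
  expect_equal(sum(h) + sum(v), 0L)
  # border mask is the in-hull complement of the cells
  expect_true(all((g$hull & g$label_map == 0L) == g$border_mask))
})

test_that("single-cell geometry and forced endothelial counts", {
  g1 <- generate_islet_geometry(1, 64, seed = 2)
  expect_equal(max(g1$label_map), 1L)
  expect_true(all(g1$border_mask == (g1$hull & g1$label_map == 0L)))
  g5 <- generate_islet_geometry(50, 512, endothelial_fraction = 0.1, seed = 3)
  expect_equal(sum(g5$cell_types == "endothelial"), 5L)
  expect_error(generate_islet_geometry(500, 64), "infeasible")
})

test_that("simulate_rates honours CV, inactive fraction and protocol", {
  prot <- default_protocol()
  types <- rep("alpha", 100)
  r0 <- simulate_rates(prot, types, heterogeneity_cv = 0,
                       inactive_fraction = 0, seed = 1)
  expect_true(all(apply(r0$lambda, 2, function(col) length(unique(col)) == 1)))
  r1 <- simulate_rates(prot, types, inactive_fraction = 0.66, seed = 1)
  expect_equal(sum(rowSums(r1$lambda) == 0), 66L)
  # protocol passthrough: a 0 -> 10 multiplier step raises every active rate
  prot2 <- stimulus_protocol(c(0, 600), c(600, 1200), c("off", "on"), c(0, 10))
  r2 <- simulate_rates(prot2, rep("beta", 20), seed = 2)
  expect_true(all(r2$lambda[, 1] == 0))
  expect_true(all(r2$lambda[, 2] > 0))
  expect_error(stimulus_protocol(c(0, 500), c(600, 1200), c("a", "b"),
                                 c(1, 1)), "contiguous")
  expect_error(stimulus_protocol(0, 600, "a", -1), "finite")
})

test_that("noise-free rendering is the deterministic wash-in plus puncta", {
  geom <- generate_islet_geometry(4, 128, seed = 5)
  prot <- stimulus_protocol(0, 900, "c", 1)
  rates <- simulate_rates(prot, geom$cell_types, baseline_rate = 0,
                          heterogeneity_cv = 0, seed = 5)
  ch <- chamber_kinetics(120, 120)   # lag + tau = 240 s falls on frame 9
  sim <- render_movie(geom, rates, ch, 30, 40, photon_scale = Inf,
                      read_noise_sd = 0, haze_fraction = 0,
                      bleach_tau_s = Inf, seed = 5)
  expect_equal(nrow(sim$truth$puncta), 0L)
  # every pixel scales with the wash-in curve; at t = lag + tau the scale
  # is exactly (1 - 1/e) of the plateau amplitude
  last <- get_frame(sim$stack, 40)
  p <- which.max(last)
  w_last <- 1 - exp(-((40 - 1) * 30 - 120) / 120)
  curve <- vapply(seq_len(40), function(k) get_frame(sim$stack, k)[p],
                  numeric(1))
  expect_equal(curve[9] / curve[40], (1 - exp(-1)) / w_last,
               tolerance = 1e-9)
  expect_true(all(diff(curve) >= -1e-12))           # monotone wash-in
  expect_true(all(curve[sim$stack$time < 120] == 0))  # dead time
})

test_that("puncta persist and conserve integrated intensity without noise", {
  geom <- generate_islet_geometry(4, 128, seed = 6)
  prot <- stimulus_protocol(0, 1200, "c", 1)
  rates <- simulate_rates(prot, geom$cell_types, baseline_rate = 2e-3,
                          heterogeneity_cv = 0, seed = 6)
  sim <- render_movie(geom, rates, chamber_kinetics(0, 1e-6), 30, 40,
                      photon_scale = Inf, read_noise_sd = 0,
                      haze_fraction = 0, tracer_amplitude = 0,
                      bleach_tau_s = Inf, psf_sigma = 1, seed = 6)
  tp <- sim$truth$puncta
  skip_if(nrow(tp) < 3)
  # with borders/haze off, total intensity = (# born <= t) x spot integral
  spot_integral <- 2 * pi * 1^2
  for (k in c(15, 30, 40)) {
    n_born <- sum(tp$birth_time_s <= (k - 1) * 30)
    expect_equal(sum(get_frame(sim$stack, k)), n_born * spot_integral,
                 tolerance = 0.02)
  }
})

test_that("punctum births follow the programmed Poisson process", {
  # constant rate c over duration T: mean count over seeds within 3 SE of cT
  geom <- generate_islet_geometry(1, 64, cell_diameter = 8, seed = 7)
  prot <- stimulus_protocol(0, 3000, "c", 1)
  rates <- simulate_rates(prot, geom$cell_types, baseline_rate = 4e-3,
                          heterogeneity_cv = 0, seed = 7)
  counts <- vapply(1:200, function(s) {
    sim <- render_movie(geom, rates, chamber_kinetics(0, 1e-6),
                        frame_interval_s = 300, n_frames = 11,
                        photon_scale = Inf, read_noise_sd = 0, seed = s)
    nrow(sim$truth$puncta)
  }, numeric(1))
  expected <- 4e-3 * 3000
  se <- sqrt(expected / 200)
  expect_lt(abs(mean(counts) - expected), 3 * se)
  # dispersion consistent with Poisson (variance/mean near 1)
  expect_gt(var(counts) / mean(counts), 0.7)
  expect_lt(var(counts) / mean(counts), 1.4)
})

test_that("rendering is bit-reproducible for a fixed seed", {
  s <- small_sim()
  geom <- s$geom; rates <- s$rates
  sim2 <- render_movie(geom, rates, n_frames = 40, seed = 21)
  expect_identical(s$stack$data, sim2$stack$data)
  expect_identical(s$truth$puncta, sim2$truth$puncta)
  expect_error(render_movie(geom, rates, n_frames = 40, psf_sigma = NA),
               "non-finite|psf_sigma")
})
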