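# Detection module: classification logic and full-stack orchestration.

test_that("classification follows the blob/ridge/bulk/extracellular rules", {
  p <- scale_space_params()
  bm <- matrix(FALSE, 20, 20); bm[10, ] <- TRUE
  # blob eigenvalues off-border, fine scale dominant -> punctate
  expect_equal(classify_maximum(cbind(-4, -3.8), cbind(3, 3), bm,
                                dog_small = 1, dog_bulk = 0.5, p), "punctate")
  # ridge eigenvalues -> membrane_ridge
  expect_equal(classify_maximum(cbind(-4, -0.05), cbind(3, 3), bm,
                                dog_small = 1, dog_bulk = 0.5, p),
               "membrane_ridge")
  # positive curvature in any direction -> not a blob
  expect_equal(classify_maximum(cbind(-4, 0.2), cbind(3, 3), bm,
                                dog_small = 1, dog_bulk = 0.5, p),
               "membrane_ridge")
  # coarse scale dominant -> bulk
  expect_equal(classify_maximum(cbind(-4, -3.8), cbind(3, 3), bm,
                                dog_small = 0.1, dog_bulk = 1, p), "bulk")
  # on the (dilated) border -> extracellular, regardless of shape
  expect_equal(classify_maximum(cbind(-4, -3.8), cbind(11, 5), bm,
                                dog_small = 1, dog_bulk = 0.5, p),
               "extracellular")
})

test_that("noise-free movie with resolvable puncta gives perfect detection", {
  geom <- generate_islet_geometry(16, 256, seed = 31)
  prot <- stimulus_protocol(0, 1200, "c", 1)
  rates <- simulate_rates(prot, geom$cell_types, baseline_rate = 2.5e-3,
                          heterogeneity_cv = 0, seed = 31)
  sim <- render_movie(geom, rates, n_frames = 40, photon_scale = Inf,
                      read_noise_sd = 0, puncta_min_sep_px = 6, seed = 31)
  expect_gt(nrow(sim$truth$puncta), 20)
  det <- detect_stack(sim$stack, scale_space_params(),
                      border_mask = sim$truth$border_mask,
                      cell_label_map = sim$truth$label_map)
  ev <- evaluate_detection(det, sim$truth, radius = 2)
  expect_equal(ev$precision, 1.0)
  expect_equal(ev$recall, 1.0)
  # class counts partition the maxima
  expect_equal(sum(table(det$class)), nrow(det))
  expect_true(all(det$class %in% c("punctate", "membrane_ridge", "bulk",
                                   "extracellular")))
})

test_that("zero-rate movies yield no punctate detections inside cells", {
  geom <- generate_islet_geometry(9, 192, seed = 32)
  prot <- stimulus_protocol(0, 1200, "c", 1)
  rates <- simulate_rates(prot, geom$cell_types, baseline_rate = 0, seed = 32)
  sim <- render_movie(geom, rates, n_frames = 20, photon_scale = Inf,
                      read_noise_sd = 0, seed = 32)
  det <- detect_stack(sim$stack, scale_space_params(),
                      border_mask = sim$truth$border_mask,
                      cell_label_map = sim$truth$label_map)
  expect_equal(sum(det$class == "punctate" & det$cell_label > 0), 0L)
})

test_that("intensity scaling leaves class labels unchanged", {
  s <- small_sim()
  det1 <- detect_stack(s$stack, scale_space_params(),
                       border_mask = s$truth$border_mask,
                       cell_label_map = s$truth$label_map)
  s2 <- s$stack
  s2$data <- s2$data * 3.7
  det2 <- detect_stack(s2, scale_space_params(),
                       border_mask = s$truth$border_mask,
                       cell_label_map = s$truth$label_map)
  expect_equal(nrow(det1), nrow(det2))
  expect_equal(det1$class, det2$class)
  expect_equal(det1$y, det2$y)
  expect_equal(det2$dog_response, det1$dog_response * 3.7)
})

test_that("bulk uptake regions are classified bulk, puncta punctate", {
  # one endothelial-like uniform-uptake cell among secretory cells
  geom <- generate_islet_geometry(9, 192, endothelial_fraction = 1 / 9,
                                  seed = 33)
  prot <- stimulus_protocol(0, 1200, "c", 1)
  rates <- simulate_rates(prot, geom$cell_types, baseline_rate = 2e-3,
                          heterogeneity_cv = 0,
                          endothelial_uptake = 2e-3, seed = 33)
  sim <- render_movie(geom, rates, n_frames = 40, photon_scale = Inf,
                      read_noise_sd = 0, puncta_min_sep_px = 6, seed = 33)
  det <- detect_stack(sim$stack, scale_space_params(),
                      border_mask = sim$truth$border_mask,
                      cell_label_map = sim$truth$label_map)
  endo <- which(geom$cell_types == "endothelial")
  in_endo <- det[det$cell_label %in% endo, ]
  in_secr <- det[det$cell_label > 0 & !det$cell_label %in% endo, ]
  expect_false(any(in_endo$class == "punctate"))
  expect_gt(sum(in_secr$class == "punctate"), 0)
})

test_that("shape mismatches are rejected", {
  s <- small_sim()
  expect_error(detect_stack(s$stack, scale_space_params(),
                            border_mask = matrix(FALSE, 10, 10)),
               "spatial shape")
})
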