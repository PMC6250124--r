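# Segmentation: border mask, cell partition, viability flags, depth.

test_that("border mask is accurate and avoids cell interiors (noise-free)", {
  geom <- generate_islet_geometry(36, 400, seed = 41)
  prot <- stimulus_protocol(0, 1500, "c", 1)
  rates <- simulate_rates(prot, geom$cell_types, baseline_rate = 1e-3,
                          heterogeneity_cv = 0, seed = 41)
  # puncta kept 3 px clear of the membrane: a punctum overlapping a border
  # junction is optically part of the membrane signal and unresolvable
  sim <- render_movie(geom, rates, n_frames = 20, photon_scale = Inf,
                      read_noise_sd = 0, puncta_margin_px = 3, seed = 41)
  ref <- get_frame(sim$stack, 18)
  bm <- extract_border_mask(ref)
  expect_gte(mask_iou(bm, sim$truth$border_mask), 0.8)
  # never intrudes into cell interiors eroded by 2 px
  inner <- EBImage::erode(matrix(as.numeric(sim$truth$label_map > 0), 400, 400),
                          EBImage::makeBrush(5, "diamond")) > 0
  expect_equal(sum(bm & inner), 0L)
  expect_error(extract_border_mask(matrix(0, 64, 64)), "dark")
})

test_that("cells are recovered as a disjoint partition bounded by borders", {
  geom <- generate_islet_geometry(36, 400, seed = 41)
  prot <- stimulus_protocol(0, 1500, "c", 1)
  rates <- simulate_rates(prot, geom$cell_types, baseline_rate = 1e-3,
                          heterogeneity_cv = 0, seed = 41)
  sim <- render_movie(geom, rates, n_frames = 20, seed = 41)
  ref <- get_frame(sim$stack, 18)
  lab <- segment_cells(ref)
  m <- match_segmentation(lab, sim$truth$label_map)
  expect_gte(m$recovered, 0.9)
  expect_lte(m$oversegmentation, 1.2)
  # labels never overlap the border mask; labels are 1..K
  expect_equal(sum(lab > 0 & attr(lab, "border_mask")), 0L)
  expect_setequal(unique(as.vector(lab)), 0:max(lab))
  # determinism and label-count invariance under intensity scaling
  expect_identical(lab, segment_cells(ref))
  expect_equal(max(segment_cells(ref * 5)), max(lab))
})

test_that("single-cell geometry segments to exactly one label", {
  geom <- generate_islet_geometry(1, 96, cell_diameter = 12, seed = 42)
  prot <- stimulus_protocol(0, 900, "c", 1)
  rates <- simulate_rates(prot, geom$cell_types, baseline_rate = 0, seed = 42)
  sim <- render_movie(geom, rates, n_frames = 18, photon_scale = Inf,
                      read_noise_sd = 0, seed = 42)
  lab <- segment_cells(get_frame(sim$stack, 18), min_area = 40)
  expect_equal(max(lab), 1L)
})

test_that("uniform high-uptake cells are flagged, punctate ones are not", {
  geom <- generate_islet_geometry(50, 512, endothelial_fraction = 0.1,
                                  seed = 43)
  true_endo <- which(geom$cell_types == "endothelial")
  rates <- simulate_rates(default_protocol(), geom$cell_types, seed = 43)
  sim <- render_movie(geom, rates, n_frames = 40, seed = 43)
  fl <- flag_nonviable(sim$stack, sim$truth$label_map, frames = 18:24)
  expect_setequal(fl$label[fl$endothelial_like], true_endo)
  expect_true(all(fl$viable[!fl$endothelial_like]))
  # all-secretory islet: no flags
  s <- small_sim()
  fl2 <- flag_nonviable(s$stack, s$truth$label_map, frames = 18:24)
  expect_equal(sum(fl2$endothelial_like), 0L)
  # empty label map: empty flag table
  fl3 <- flag_nonviable(s$stack, matrix(0L, 256, 256), frames = 18:24)
  expect_equal(nrow(fl3), 0L)
})

test_that("depth is the distance transform at the centroid, in um", {
  # one cell centred in a disk of radius 50 um (125 px at 0.4 um/px)
  n <- 260
  yy <- matrix(seq_len(n), n, n); xx <- t(yy)
  hull <- (yy - 130)^2 + (xx - 130)^2 <= 125^2
  lab <- matrix(0L, n, n)
  lab[(yy - 130)^2 + (xx - 130)^2 <= 10^2] <- 1L
  d <- compute_depth(lab, hull, pixel_size = 0.4)
  expect_equal(d$depth_um, 50, tolerance = 1)
  # boundary-touching cell is shallower than one cell diameter
  lab2 <- matrix(0L, n, n)
  lab2[(yy - 130)^2 + (xx - 13)^2 <= 10^2] <- 1L
  d2 <- compute_depth(lab2, hull, pixel_size = 0.4)
  expect_lt(d2$depth_um, 10 * 2 * 0.4 + 1)
  # depth ordering follows the distance transform ordering
  lab3 <- matrix(0L, n, n)
  lab3[(yy - 130)^2 + (xx - 40)^2 <= 8^2] <- 1L
  lab3[(yy - 130)^2 + (xx - 90)^2 <= 8^2] <- 2L
  lab3[(yy - 130)^2 + (xx - 130)^2 <= 8^2] <- 3L
  d3 <- compute_depth(lab3, hull, pixel_size = 0.4)
  expect_true(all(diff(d3$depth_um) > 0))
})
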