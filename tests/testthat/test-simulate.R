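test_that("static parameters give identical frames and an empty event log", {
  p <- sim_params(n_cells = 2, duration_s = 100, bleb_rate_per_min = 0,
                  migration_speed_um_min = 0, seed = 7)
  sim <- simulate_blebbing_movie(p)
  expect_equal(nrow(sim$ground_truth$bleb_events), 0)
  for (f in sim$movie$frames) expect_identical(f, sim$movie$frames[[1]])
  expect_setequal(sim$ground_truth$phenotypes$phenotype, "flagellate")
})

test_that("identical seeds give bit-identical movies and logs", {
  p <- sim_params(n_cells = 3, duration_s = 200, seed = 7)
  a <- simulate_blebbing_movie(p)
  b <- simulate_blebbing_movie(p)
  expect_identical(a$movie$frames, b$movie$frames)
  expect_identical(a$ground_truth$bleb_events, b$ground_truth$bleb_events)
  expect_identical(a$ground_truth$true_tracks, b$ground_truth$true_tracks)
})

test_that("bleb nucleation counts follow the programmed Poisson law", {
  # 20 cells x 10 min x 1 per min: count ~ Poisson(200)
  p <- sim_params(image_size_px = c(640L, 640L), n_cells = 20,
                  duration_s = 600, bleb_rate_per_min = 1,
                  frame_interval_s = 20, seed = 123)
  sim <- simulate_blebbing_movie(p)
  n <- nrow(sim$ground_truth$bleb_events)
  ci <- qpois(c(0.005, 0.995), 200)
  expect_gte(n, ci[1])
  expect_lte(n, ci[2])
  expect_true(all(sim$ground_truth$bleb_events$time_s <= 600))
})

test_that("body area is conserved over time within rasterization tolerance", {
  p <- sim_params(n_cells = 1, duration_s = 300, bleb_rate_per_min = 0,
                  frame_interval_s = 20, seed = 11) # body r = 15.4 px
  sim <- simulate_blebbing_movie(p)
  areas <- vapply(sim$movie$frames, function(f) sum(f == 1L), numeric(1))
  expect_true(all(abs(areas / mean(areas) - 1) < 0.02))
})

test_that("every connected protrusion corresponds to an active logged bleb", {
  p <- sim_params(n_cells = 2, duration_s = 400, bleb_rate_per_min = 2,
                  frame_interval_s = 20, seed = 21)
  sim <- simulate_blebbing_movie(p)
  gt <- sim$ground_truth
  dims <- dim(sim$movie$frames[[1]])
  s <- p$pixel_spacing_um
  for (k in c(8, 15, 21)) {
    t <- sim$movie$timestamps_s[k]
    for (id in 1:2) {
      tt <- gt$true_tracks[gt$true_tracks$cell_id == id & gt$true_tracks$time_s == t, ]
      body <- blebquant:::disc_px(c(tt$x_um, tt$y_um), p$body_radius_um, s, dims)
      cellpx <- which(sim$movie$frames[[k]] == id)
      protr <- setdiff(cellpx, body)
      comps <- blebquant:::label_components8(protr, dims)
      comps <- comps[lengths(comps) > 2] # ignore 1-2 px rasterization slivers
      ev <- gt$bleb_events[gt$bleb_events$cell_id == id, ]
      active <- which(blebquant:::bleb_radius_at(t, ev$time_s, p$bleb_max_radius_um,
                                                 p$bleb_expand_s, p$bleb_retract_s) > 0)
      active_px <- unlist(lapply(active, function(m) {
        anchor <- c(tt$x_um, tt$y_um) + p$body_radius_um *
          c(cos(ev$angle_rad[m]), sin(ev$angle_rad[m]))
        rb <- blebquant:::bleb_radius_at(t, ev$time_s[m], p$bleb_max_radius_um,
                                         p$bleb_expand_s, p$bleb_retract_s)
        blebquant:::disc_px(anchor, rb, s, dims)
      }))
      for (comp in comps) {
        expect_gt(length(intersect(comp, active_px)), 0)
      }
    }
  }
})

test_that("cells are placed without overlap or an informative error is raised", {
  expect_error(sim_params(image_size_px = c(32L, 32L), n_cells = 2),
               "image too small")
  p <- sim_params(image_size_px = c(96L, 96L), n_cells = 4, duration_s = 0,
                  migration_speed_um_min = 0, seed = 5)
  expect_error(simulate_blebbing_movie(p), "could not place")
})

test_that("escape simulator programs a radial crossing with elongation", {
  es <- simulate_escape_movie(start_dist_um = 3)
  gt <- es$ground_truth
  expect_true(gt$escape$escaped)
  expect_lte(gt$escape$t_front_s, gt$escape$t_complete_s)
  # programmed crawl is radial: true-track displacement is along +x only
  tt <- gt$true_tracks
  expect_true(all(diff(tt$y_um) == 0))
  expect_true(all(diff(tt$x_um) >= 0))
  expect_gt(max(tt$aspect_ratio), 1.5)
  expect_equal(tt$aspect_ratio[1], 1)
  expect_equal(tt$aspect_ratio[nrow(tt)], 1)
})

test_that("escape beyond the programmed reach logs no crossing", {
  es <- simulate_escape_movie(start_dist_um = 14, crawl_speed_um_min = 0.3)
  expect_false(es$ground_truth$escape$escaped)
  expect_true(is.na(es$ground_truth$escape$t_complete_s))
})

test_that("a start distance beyond the boundary radius is rejected", {
  b <- confinement_boundary(c(26, 26), 10)
  expect_error(simulate_escape_movie(boundary = b, start_dist_um = 12),
               "exceeds the boundary radius")
})

test_that("cortex render paints a ratio-1, noise-free cell uniformly", {
  p <- sim_params(n_cells = 1, duration_s = 0, bleb_rate_per_min = 0,
                  migration_speed_um_min = 0, seed = 3,
                  image_size_px = c(96L, 96L))
  sim <- simulate_blebbing_movie(p)
  fl <- render_intensity_movie(sim$movie, "cortex_fluor", noise_sd = 0,
                               cortex_to_cytoplasm_ratio = 1)
  f <- fl$frames[[1]]
  inside <- sim$movie$frames[[1]] == 1L
  expect_true(all(f[inside] == 100))
  expect_true(all(f[!inside] == 0))
})

test_that("render is deterministic per seed and rejects over-wide bands", {
  p <- sim_params(n_cells = 1, duration_s = 0, bleb_rate_per_min = 0,
                  migration_speed_um_min = 0, seed = 3,
                  image_size_px = c(96L, 96L))
  sim <- simulate_blebbing_movie(p)
  a <- render_intensity_movie(sim$movie, "cortex_fluor", noise_sd = 0.05, seed = 9)
  b <- render_intensity_movie(sim$movie, "cortex_fluor", noise_sd = 0.05, seed = 9)
  expect_identical(a$frames, b$frames)
  expect_error(render_intensity_movie(sim$movie, "cortex_fluor",
                                      cortex_width_um = 3),
               "cell radius")
})

test_that("movies and ground truth survive a TIFF/JSON round trip", {
  p <- sim_params(n_cells = 2, duration_s = 60, seed = 13,
                  image_size_px = c(128L, 128L))
  sim <- simulate_blebbing_movie(p)
  tdir <- withr::local_tempdir()
  path <- file.path(tdir, "movie.tif")
  write_movie_tiff(sim$movie, path)
  back <- read_movie_tiff(path)
  expect_identical(back$frames, sim$movie$frames)
  expect_equal(back$pixel_spacing_um, sim$movie$pixel_spacing_um)
  expect_equal(back$timestamps_s, sim$movie$timestamps_s)
  gt_path <- file.path(tdir, "gt.json")
  write_ground_truth(sim$ground_truth, gt_path)
  gt2 <- read_ground_truth(gt_path)
  expect_equal(nrow(gt2$bleb_events), nrow(sim$ground_truth$bleb_events))
  expect_equal(gt2$bleb_events$time_s, sim$ground_truth$bleb_events$time_s)
  expect_equal(gt2$phenotypes$phenotype, sim$ground_truth$phenotypes$phenotype)
})
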