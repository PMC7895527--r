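test_that("shape difference matches the brute-force pixel-set oracle", {
  body <- disc_mask(81, c(41, 41), 20)
  # new bleb: r = 5 disc centred on the body boundary
  bleb <- disc_mask(81, c(41, 61), 5)
  now <- body | bleb
  d <- shape_difference(now, body)
  o <- oracle_diff(now, body)
  expect_equal(sort(d$gained), sort(o$gained))
  expect_equal(d$gained_area_px, o$gained_area)
  expect_equal(d$lost_area_px, 0)
  expect_length(d$lost, 0)
  # identical masks
  d0 <- shape_difference(body, body)
  expect_equal(d0$gained_area_px + d0$lost_area_px, 0)
  # swapped arguments exchange gained and lost exactly
  dsw <- shape_difference(body, now)
  expect_equal(dsw$gained, d$lost)
  expect_equal(dsw$lost, d$gained)
  # symmetric difference identity
  expect_equal(d$gained_area_px + d$lost_area_px, sum(xor(now, body)))
  expect_error(shape_difference(body, disc_mask(41, c(21, 21), 5)), "grids")
})

test_that("activity of a static track is zero and equals the oracle elsewhere", {
  static <- tracks_from_masks(rep(list(disc_mask(61, c(31, 31), 14)), 13),
                              seq(0, 240, by = 20))
  expect_equal(blebbing_activity(static)$activity, 0)
  p <- sim_params(n_cells = 2, duration_s = 240, frame_interval_s = 20,
                  image_size_px = c(256L, 256L), bleb_rate_per_min = 1.5, seed = 8)
  sim <- simulate_blebbing_movie(p)
  tr <- tracks_from_labels(sim$movie)
  for (id in 1:2) {
    trk <- one_track(tr, id)
    res <- blebbing_activity(trk)
    masks <- lapply(trk$pixels, blebquant:::mask_from_px, attr(trk, "dim_px"))
    expect_equal(res$activity, oracle_activity(masks, trk$area_px),
                 tolerance = 1e-12)
    expect_equal(res$n_steps, nrow(trk) - 1)
    expect_equal(res$activity, mean(res$per_step$normalized_diff))
  }
  expect_error(blebbing_activity(tracks_from_masks(list(disc_mask(21, c(11, 11), 4)), 0)),
               "fewer than 2")
})

test_that("activity is unchanged by global drift once registration is applied", {
  p <- sim_params(n_cells = 1, duration_s = 240, frame_interval_s = 20,
                  image_size_px = c(200L, 200L), bleb_rate_per_min = 1,
                  migration_speed_um_min = 0, seed = 14)
  sim <- simulate_blebbing_movie(p)
  act0 <- blebbing_activity(tracks_from_labels(sim$movie))$activity
  drifted <- sim$movie
  for (k in seq_along(drifted$frames)) {
    drifted$frames[[k]] <- blebquant:::shift_frame(drifted$frames[[k]],
                                                   2 * (k - 1), -(k - 1))
  }
  rereg <- register_movie(drifted)$movie
  act1 <- blebbing_activity(tracks_from_labels(rereg))$activity
  expect_equal(act1, act0, tolerance = 1e-12)
})

test_that("protrusion extraction classifies gained and lost components", {
  base <- disc_mask(81, c(41, 41), 20)
  gained_blob <- disc_mask(81, c(41, 64), 6) & !base
  lost_blob <- disc_mask(81, c(28, 41), 4) & base
  now <- (base | gained_blob) & !lost_blob
  d <- shape_difference(now, base)
  ev <- extract_protrusions(d, time_s = 20, spacing_um = 0.2,
                            min_protrusion_px = 20L)
  expect_equal(sum(ev$class == "expanding"), 1)
  expect_equal(sum(ev$class == "retracting"), 1)
  gx <- ev[ev$class == "expanding", ]
  expect_equal(gx$area_px, sum(gained_blob))
  expect_equal(gx$area_um2, sum(gained_blob) * 0.2^2)
  # everything below the minimum size disappears
  ev2 <- extract_protrusions(d, min_protrusion_px = 10000L)
  expect_equal(nrow(ev2), 0)
})

test_that("detected onset counts track the programmed nucleation counts", {
  n_true <- 0; n_det <- 0
  for (m in 1:2) {
    p <- sim_params(image_size_px = c(512L, 512L), frame_interval_s = 20,
                    duration_s = 600, n_cells = 6, bleb_rate_per_min = 1,
                    seed = 600 + m)
    sim <- simulate_blebbing_movie(p)
    tr <- tracks_from_labels(sim$movie)
    n_true <- n_true + nrow(sim$ground_truth$bleb_events)
    for (id in unique(tr$track_id)) {
      n_det <- n_det + nrow(count_bleb_onsets(one_track(tr, id)))
    }
  }
  expect_lt(abs(n_det - n_true) / n_true, 0.25)
})

test_that("populations simulated at different bleb rates separate in activity", {
  acts <- list()
  for (rate in c(0, 1)) {
    p <- sim_params(image_size_px = c(640L, 640L), frame_interval_s = 20,
                    duration_s = 240, n_cells = 20, bleb_rate_per_min = rate,
                    seed = 900 + 10 * rate)
    sim <- simulate_blebbing_movie(p)
    acts[[as.character(rate)]] <-
      blebbing_activity_all(tracks_from_labels(sim$movie))$activity
  }
  expect_gt(mean(acts[["1"]]), mean(acts[["0"]]))
  w <- mannwhitney_u(acts[["1"]], acts[["0"]])
  expect_lt(w$p_value, 0.01)
})

test_that("phenotype calls use an inclusive threshold", {
  expect_equal(classify_phenotype(0, activity_threshold = 0.05), "flagellate")
  expect_equal(classify_phenotype(0.05, activity_threshold = 0.05), "amoeboid")
  expect_equal(classify_phenotype(c(0.01, 0.2), 0.05),
               c("flagellate", "amoeboid"))
})
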