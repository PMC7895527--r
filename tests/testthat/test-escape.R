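test_that("boundary distances match the brute-force per-pixel oracle", {
  b <- confinement_boundary(c(10, 10), 6)
  # single-pixel cell 3 um inside the border: px at (row 1, col 1)*... choose
  # a pixel whose centre sits at distance 3 inside: radius 6, so 3 from centre
  m <- matrix(FALSE, 41, 41)
  m[cbind(21, 27)] <- TRUE # (x, y) = (13, 10) at spacing 0.5 -> r = 3, d = 3
  d <- boundary_distances(m, b, spacing_um = 0.5)
  expect_equal(d$front_um, 3)
  expect_equal(d$rear_um, 3)
  expect_equal(d$centroid_um_dist, 3)
  # horizontal segment straddling the border symmetrically: front ~ 0
  seg <- matrix(FALSE, 41, 41)
  seg[cbind(21, 28:38)] <- TRUE # x from 13.5 to 18.5 um crosses r = 16
  b2 <- confinement_boundary(c(0, 10), 16)
  d2 <- boundary_distances(seg, b2, spacing_um = 0.5)
  expect_lte(d2$front_um, 0.25) # within half a pixel of the border
  # random blobs: exact agreement with the explicit enumeration
  set.seed(42)
  for (i in 1:5) {
    blob <- disc_mask(41, c(sample(10:30, 1), sample(10:30, 1)), sample(3:8, 1))
    o <- oracle_boundary(blob, c(10, 10), 6, 0.5)
    d3 <- boundary_distances(blob, b, spacing_um = 0.5)
    expect_identical(d3$front_um, o$front)
    expect_identical(d3$rear_um, o$rear)
    expect_identical(d3$frac_outside, o$frac_outside)
  }
})

test_that("escape detection matches the simulator log within one frame", {
  es <- simulate_escape_movie(start_dist_um = 3)
  gt <- es$ground_truth
  tr <- add_shape_descriptors(tracks_from_labels(es$movie))
  rec <- detect_escape(tr, gt$boundary)
  expect_true(rec$escaped)
  expect_lte(abs(rec$t_complete_s - gt$escape$t_complete_s),
             es$movie$frame_interval_s)
  expect_lte(abs(rec$t_front_s - gt$escape$t_front_s),
             es$movie$frame_interval_s)
  expect_true(all(rec$per_frame$front_um <= rec$per_frame$rear_um))
})

test_that("a cell that never reaches the border does not escape", {
  es <- simulate_escape_movie(start_dist_um = 14, crawl_speed_um_min = 0.3)
  tr <- add_shape_descriptors(tracks_from_labels(es$movie))
  rec <- detect_escape(tr, es$ground_truth$boundary)
  expect_false(rec$escaped)
  expect_true(is.na(rec$t_front_s))
  expect_true(is.na(rec$t_complete_s))
})

test_that("a cell straddling the border at t = 0 has t_front = 0", {
  b <- confinement_boundary(c(10, 10), 5)
  masks <- rep(list(disc_mask(81, c(41, 57), 10)), 3) # centre (x=14,y=10)*0.25
  tr <- tracks_from_masks(masks, c(0, 20, 40), spacing = 0.25)
  rec <- detect_escape(tr, b)
  expect_equal(rec$t_front_s, 0)
})

test_that("an unconfined starting cell is rejected", {
  b <- confinement_boundary(c(2, 2), 1.5)
  masks <- rep(list(disc_mask(41, c(30, 30), 5)), 2)
  tr <- tracks_from_masks(masks, c(0, 20), spacing = 0.5)
  expect_error(detect_escape(tr, b), "not confined")
})

test_that("escape angles read 0 for radial, 90 for tangential motion", {
  b <- confinement_boundary(c(0, 0), 50)
  radial <- tibble::tibble(time_s = seq(0, 200, 20),
                           x_um = seq(5, 25, 2), y_um = 0)
  a_rad <- escape_angle_series(radial, b)
  expect_true(all(abs(a_rad$angle_deg) < 5))
  th <- seq(0, 1, 0.1)
  tangential <- tibble::tibble(time_s = seq(0, 200, 20),
                               x_um = 10 * cos(th), y_um = 10 * sin(th))
  a_tan <- escape_angle_series(tangential, b)
  expect_true(all(abs(a_tan$angle_deg - 90) < 5))
})

test_that("random-walk angles are uniform on [0, 180]", {
  set.seed(5)
  n <- 220
  steps <- matrix(rnorm(2 * n, sd = 2), ncol = 2)
  pos <- apply(steps, 2, cumsum)
  walk <- tibble::tibble(time_s = seq_len(n) * 20,
                         x_um = 400 + pos[, 1], y_um = 400 + pos[, 2])
  b <- confinement_boundary(c(0, 0), 1000)
  a <- escape_angle_series(walk, b)
  expect_gt(nrow(a), 150)
  ks <- stats::ks.test(a$angle_deg, "punif", 0, 180)
  expect_gt(ks$p.value, 0.01)
})

test_that("speed and persistence obey their closed forms", {
  # straight line at 0.3 um/min on a 20 s grid
  straight <- tibble::tibble(time_s = seq(0, 240, 20),
                             x_um = 0.3 / 60 * seq(0, 240, 20), y_um = 0)
  mr <- speed_and_persistence(straight, window_s = 120)
  expect_equal(mr$speed_um_min, rep(0.3, nrow(mr)))
  expect_equal(mr$persistence, rep(1, nrow(mr)))
  mrc <- speed_and_persistence(straight, window_s = 120, definition = "conventional")
  expect_equal(mrc$persistence, rep(1, nrow(mrc)))
  # square-wave zigzag: total path 8, Euclidean displacement 4, ratio 2
  zig <- tibble::tibble(time_s = seq(0, 120, 20),
                        x_um = c(0, 2, 2, 2, 4, 4, 4),
                        y_um = c(0, 0, 1, 0, 0, 1, 0))
  zp <- speed_and_persistence(zig, window_s = 120)
  expect_equal(zp$persistence, 2)
  zc <- speed_and_persistence(zig, window_s = 120, definition = "conventional")
  expect_equal(zc$persistence, 0.5)
  expect_equal(zc$persistence, 1 / zp$persistence)
  # static cell: zero speed, undefined persistence
  static <- tibble::tibble(time_s = seq(0, 120, 20), x_um = 1, y_um = 1)
  sp <- speed_and_persistence(static, window_s = 120)
  expect_equal(sp$speed_um_min, 0)
  expect_true(is.na(sp$persistence))
})

test_that("paper-literal persistence is >= 1 and reciprocal to conventional", {
  set.seed(9)
  pos <- apply(matrix(rnorm(60, sd = 0.5), ncol = 2), 2, cumsum)
  walk <- tibble::tibble(time_s = seq_len(30) * 20, x_um = pos[, 1], y_um = pos[, 2])
  pl <- speed_and_persistence(walk, 120, "paper_literal")
  cv <- speed_and_persistence(walk, 120, "conventional")
  ok <- !is.na(pl$persistence)
  expect_true(all(pl$persistence[ok] >= 1))
  expect_equal(cv$persistence[ok], 1 / pl$persistence[ok])
})

test_that("event alignment reproduces single-track values and cohort elongation", {
  es <- simulate_escape_movie(start_dist_um = 3)
  tr <- add_shape_descriptors(tracks_from_labels(es$movie))
  rec <- detect_escape(tr, es$ground_truth$boundary)
  al <- align_to_event(tr, tibble::tibble(track_id = 1L,
                                          t_event_s = rec$t_complete_s))
  expect_equal(al$n, rep(1L, nrow(al)))
  expect_true(all(al$sd_aspect_ratio == 0))
  expect_equal(sort(al$rel_time_s), sort(tr$time_s - rec$t_complete_s))
  # mean aspect ratio peaks near crossing and relaxes after
  peak_bin <- al$rel_time_s[which.max(al$mean_aspect_ratio)]
  expect_lt(peak_bin, 0)
  expect_lt(al$mean_aspect_ratio[al$rel_time_s == max(al$rel_time_s)], 1.1)
  # empty aggregate when no tracks have events
  empty <- align_to_event(tr, tibble::tibble(track_id = 99L, t_event_s = 0))
  expect_equal(nrow(empty), 0)
})
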