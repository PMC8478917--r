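# Segmentation, edge-normal velocity mapping, cone speed, stability and
# protrusion run-length metrics, plus the geometric invariants.

test_that("segmentation recovers the synthetic disc and is scale invariant", {
  em <- synth_edge_movie(arc_protruding = 90, radius_um = 15,
                         shape = c(140L, 140L), n_frames = 3L)
  seg <- preprocess_and_segment(em$movie, blur_sigma = 1)
  for (t in 1:3) {
    a <- seg$mask[, , t]; b <- em$mask[, , t]
    expect_gte(sum(a & b) / sum(a | b), 0.98)     # Jaccard overlap
  }
  # doubling intensities leaves masks unchanged (per-frame normalisation)
  doubled <- movie_stack(em$movie * 2, 0.25, 30)
  seg2 <- preprocess_and_segment(doubled, blur_sigma = 1)
  expect_identical(as.vector(seg$mask), as.vector(seg2$mask))
  # blank movie: empty-foreground error
  blank <- movie_stack(array(0.3, c(20, 20, 2)), 0.25, 30)
  expect_error(preprocess_and_segment(blank), "empty foreground")
  # mask override skips segmentation
  ovr <- preprocess_and_segment(em$movie, masks = em$mask)
  expect_identical(as.vector(ovr$mask), as.vector(array(em$mask,
                                                        dim(em$mask))))
})

test_that("edge velocity matches radial growth on a disc", {
  # disc expanding 2 px/frame = 1 um/min at 0.25 um px, 30 s frames
  dm <- disc_movie(c(40, 42, 44))
  prof <- edge_velocity(dm)
  v <- prof$frames[[1]]$velocity
  expect_equal(mean(v), 1, tolerance = 0.12)       # 1 px-equivalent scale
  expect_true(all(v > 0))
  # identical consecutive masks: velocity 0
  still <- disc_movie(c(40, 40))
  expect_equal(unique(edge_velocity(still)$frames[[1]]$velocity), 0)
  # sector movie: positive velocities confined to the protruding sector
  em <- synth_edge_movie(arc_protruding = 90, n_frames = 3L)
  pr <- edge_velocity(em$mask)
  fr <- pr$frames[[1]]
  cy <- (200 + 1) / 2 * 0.25
  ang <- abs(atan2(fr$y_um - cy, fr$x_um - cy)) * 180 / pi
  expect_true(all(ang[fr$velocity > 0] <= 45 + 3))  # sector half-angle + slack
  expect_true(all(fr$velocity[ang > 60] <= 0))
})

test_that("boundary velocity integrates to the area change", {
  dm <- disc_movie(c(50, 51.5), h = 200L, w = 200L)
  prof <- edge_velocity(dm)
  fr <- prof$frames[[1]]
  predicted <- sum(fr$velocity * fr$seg_um) * 0.5   # um/min * um * min
  actual <- (sum(dm[, , 2]) - sum(dm[, , 1])) * 0.25^2
  expect_equal(predicted, actual, tolerance = 0.05)
})

test_that("cone speed follows the migration-facing sector", {
  # uniformly expanding disc drifting slightly: cone speed = radial speed
  h <- 140L
  m <- array(FALSE, c(h, h, 4))
  for (t in 1:4) m[, , t] <- disc_mask(h, h, 70.5, 60.5 + 2 * (t - 1),
                                       40 + 2 * (t - 1))
  cs <- cone_speed(edge_velocity(movie_stack(m, 0.25, 30)))
  # boundary advances by drift + growth toward migration (+x): 4 px/frame
  expect_equal(mean(cs$cone_speed), 2, tolerance = 0.25)
  # sector facing the migration direction: cone speed = edge_speed
  em <- synth_edge_movie(arc_protruding = 120, edge_speed = 1,
                         retraction_speed = 0.5, n_frames = 4L)
  cs2 <- cone_speed(edge_velocity(em$mask))
  expect_equal(mean(cs2$cone_speed), 1, tolerance = 0.12)
  # stationary centroid: frames flagged and skipped
  still <- disc_movie(c(40, 40, 40))
  expect_error(cone_speed(edge_velocity(still)), "undefined")
})

test_that("protrusion stability measures speed fluctuation", {
  # constant uniform expansion: S.D. = 0 exactly on a continuum profile
  const <- synthetic_profile(list(1.5, 1.5, 1.5, 1.5))
  expect_equal(protrusion_stability(const), 0)
  # alternating expand/pause, 50/50 duty: pooled S.D. = half peak-to-peak
  alt <- synthetic_profile(list(2, 0, 2, 0, 2, 0, 2, 0))
  # half the peak-to-peak speed, up to the n-1 sample-sd correction
  expect_equal(protrusion_stability(alt), 1, tolerance = 0.01)
  expect_equal(protrusion_stability(alt, mode = "per_frame"),
               sd(c(2, 0, 2, 0, 2, 0, 2, 0)), tolerance = 1e-9)
  # i.i.d. velocity jitter of sd sigma on a constant protrusion: S.D. ~ sigma
  set.seed(42)
  sigma <- 0.4
  jit <- synthetic_profile(lapply(1:12, function(i)
    1.5 + rnorm(360, sd = sigma)))
  expect_equal(protrusion_stability(jit), sigma, tolerance = 0.05)
  # pixelated integration check: constant growth with a drifting centre
  # keeps the cone defined; pooled S.D. stays small
  grow <- drift_disc_movie(seq(40, 48, by = 2))
  expect_lt(protrusion_stability(edge_velocity(grow)), 0.3)
  expect_error(protrusion_stability(synthetic_profile(list(1))[-1]),
               class = "error")
})

test_that("longest uninterrupted run matches circle geometry", {
  em <- synth_edge_movie(arc_protruding = 90, radius_um = 20, n_frames = 4L)
  run <- longest_uninterrupted_run(edge_velocity(em$mask))
  truth <- mean(ground_truth(em)$protruding_arc_um[1:3])
  expect_equal(run$track_mean, truth, tolerance = 0.05)
  # fully retracting cell: run 0
  shrink <- disc_movie(c(50, 48, 46))
  expect_equal(longest_uninterrupted_run(edge_velocity(shrink))$track_mean, 0)
  # two disjoint sectors 40 and 80 degrees: run = the 80-degree arc
  two <- two_sector_movie(arcs_deg = c(40, 80), centres_deg = c(0, 180),
                          r_px = 60)
  run2 <- longest_uninterrupted_run(edge_velocity(two))
  expect_equal(run2$per_frame$longest_run[1], 80 / 180 * pi * 60 * 0.25,
               tolerance = 0.08)
  expect_equal(run2$per_frame$n_runs[1], 2L)
  # monotone in the protruding arc
  runs <- vapply(c(30, 90, 180, 360), function(a) {
    e <- synth_edge_movie(arc_protruding = a, n_frames = 2L)
    longest_uninterrupted_run(edge_velocity(e$mask))$track_mean
  }, numeric(1))
  expect_true(all(diff(runs) > 0))
  # length distribution: single sector gives one run per frame
  dist1 <- protrusion_length_distribution(edge_velocity(em$mask))
  expect_length(dist1, 3L)
  expect_lt(stats::sd(dist1) / mean(dist1), 0.1)
  expect_length(protrusion_length_distribution(edge_velocity(shrink)), 0L)
})

test_that("metrics are translation invariant and scale correctly", {
  base <- two_sector_movie(r_px = 40, h = 140L, w = 140L)
  shifted <- movie_stack(base[c(11:140, 1:10), , , drop = FALSE], 0.25, 30)
  r1 <- longest_uninterrupted_run(edge_velocity(base))
  r2 <- longest_uninterrupted_run(edge_velocity(shifted))
  expect_equal(r1$track_mean, r2$track_mean, tolerance = 1e-9)
  # doubling pixel size doubles lengths and velocities
  double_ps <- movie_stack(array(base, dim(base)), 0.5, 30)
  r3 <- longest_uninterrupted_run(edge_velocity(double_ps))
  expect_equal(r3$track_mean, 2 * r1$track_mean, tolerance = 1e-9)
})

test_that("curve length follows constructed shapes", {
  # straight 3-px bar, 50 px long at 1 um/px
  bar <- matrix(FALSE, 60, 60); bar[30:32, 6:55] <- TRUE
  expect_equal(curve_length(bar, 1), 50, tolerance = 1 / 50)
  # semicircular annulus, mid-radius 20: pi * r within 2%
  yy <- matrix(1:60, 60, 60) - 30.5; xx <- t(yy)
  rr <- sqrt(xx^2 + yy^2)
  ann <- rr >= 18 & rr <= 22 & yy <= 0
  expect_equal(curve_length(ann, 1), pi * 20, tolerance = 0.02)
  # degenerate circle: documented behaviour, ~diameter (ties broken
  # lexicographically; averaging opposite arcs collapses to the diameter)
  disc <- rr <= 20
  expect_equal(curve_length(disc, 1), 40, tolerance = 0.06)
  expect_error(curve_length(matrix(c(TRUE, rep(FALSE, 8)), 3, 3), 1),
               "boundary points")
})

test_that("lamellipodium morphometrics measure a rectangular band", {
  band <- matrix(FALSE, 60, 80); band[20:24, 11:70] <- TRUE
  cell <- matrix(FALSE, 60, 80); cell[10:50, 5:75] <- TRUE
  inten <- matrix(3, 60, 80)
  m <- lamellipodium_morphometrics(cell, band, inten, pixel_size = 0.5)
  expect_equal(m$length_um, 60 * 0.5, tolerance = 0.02)
  expect_equal(m$width_um, 5 * 0.5, tolerance = 0.1)
  expect_equal(m$lamellipodium_area_um2, 300 * 0.25)
  expect_equal(m$intensity_per_area, 3 / 0.25)     # uniform I per um^2
  expect_equal(m$length_per_area, m$length_um / (sum(cell) * 0.25))
  expect_error(lamellipodium_morphometrics(cell, cell & FALSE, inten, 0.5),
               "empty")
  expect_error(lamellipodium_morphometrics(band, cell, inten, 0.5),
               "outside")
  # control normalisation maps the control mean to 1 exactly
  vals <- c(2, 4, 3, 9)
  grp <- c("ctrl", "ctrl", "ko", "ko")
  norm <- normalise_to_control(vals, grp, "ctrl")
  expect_equal(mean(norm[grp == "ctrl"]), 1)
})
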