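# Track statistics: displacement sampling, MTS/MTP, usable time interval,
# profile, MSD, DR over time, direction autocorrelation, plus the rigid-
# motion and subsampling invariants.

test_that("interval displacements decimate, not slide", {
  tr <- straight_track(n = 10L, fi = 5, speed = 1)
  # 10 frames, k = 3: exactly 3 displacements, frame 10 unused
  d <- interval_displacements(tr, 15)
  expect_length(d, 3L)
  expect_equal(d, rep(15, 3))
  expect_error(interval_displacements(tr, 7), "integer multiple")
  # closed loops: zig-zag returning to start every k frames
  oab <- out_and_back_track(n_cycles = 3L, fi = 5)
  expect_equal(interval_displacements(oab, 10), rep(0, 3))
  # too short: flagged empty
  short <- straight_track(n = 3L, fi = 5)
  res <- interval_displacements(short, 20)
  expect_length(res, 0L)
  expect_true(attr(res, "too_short"))
})

test_that("MTS is mean displacement over delta_t", {
  expect_equal(mean_track_speed(straight_track(speed = 1), 15), 1)
  expect_equal(mean_track_speed(stationary_track(), 15), 0)
  expect_error(mean_track_speed(straight_track(n = 3L, fi = 5), 30),
               "no complete interval")
})

test_that("directionality ratio matches hand geometry", {
  expect_equal(directionality_ratio(straight_track(n = 13L), 15), 1)
  oab <- out_and_back_track(n_cycles = 1L, fi = 5)
  expect_equal(directionality_ratio(oab, 5), 0)
  # right-angle two-interval window with equal d: sqrt(2)/2
  zz <- zigzag_track(n_steps = 2L, fi = 5, step = 3)
  expect_equal(directionality_ratio(zz, 5), sqrt(2) / 2)
  # stationary window: defined as 1 by convention
  expect_equal(directionality_ratio(stationary_track(n = 5L), 5), 1)
  expect_error(directionality_ratio(straight_track(n = 12L), 15),
               "whole number")
})

test_that("MTP scores straight paths 1 and is monotone in kappa", {
  pp <- persistence_params(delta_t = 15, TR = 4L)
  tr <- straight_track(n = 48L, fi = 5, speed = 1, angle = 0.7)
  expect_equal(as.numeric(mean_track_persistence(tr, pp)), 1)
  ppa <- persistence_params(delta_t = 15, TR = 4L, alpha_mode = "affine_rw",
                            mc_reps = 50L, seed = 3L)
  expect_equal(as.numeric(mean_track_persistence(tr, ppa)), 1)
  # out-and-back per window: raw MTP = 0
  oab <- out_and_back_track(n_cycles = 6L, fi = 5)
  expect_equal(as.numeric(mean_track_persistence(
    oab, persistence_params(delta_t = 5, TR = 4L))), 0)
  # simulation-ordering oracle over kappa
  mtp_pop <- function(kappa, seed0) mean(vapply(
    simulate_population(200L, seed0, n_frames = 48L, frame_interval = 5,
                        speed_mean = 0.5, speed_sd = 0.1, kappa = kappa,
                        noise_sd = 0),
    function(t) as.numeric(mean_track_persistence(t, pp)), numeric(1)))
  m0 <- mtp_pop(0, 1000); m1 <- mtp_pop(1, 2000); m8 <- mtp_pop(8, 3000)
  expect_lt(m0, m1)
  expect_lt(m1, m8)
})

test_that("track statistics are invariant under rigid motion and scale", {
  tr <- simulate_crw(crw_params(n_frames = 40L, frame_interval = 5,
                                speed_mean = 0.5, speed_sd = 0.2, kappa = 2,
                                noise_sd = 0.2, seed = 17))
  pp <- persistence_params(delta_t = 15, TR = 2L)
  th <- 0.83
  rot <- track(tr$cell_id, tr$times,
               cos(th) * tr$x - sin(th) * tr$y + 11,
               sin(th) * tr$x + cos(th) * tr$y - 4)
  scl <- track(tr$cell_id, tr$times, 3 * tr$x, 3 * tr$y)
  expect_equal(as.numeric(mean_track_persistence(rot, pp)),
               as.numeric(mean_track_persistence(tr, pp)))
  expect_equal(as.numeric(mean_track_persistence(scl, pp)),
               as.numeric(mean_track_persistence(tr, pp)))
  expect_equal(mean_track_speed(rot, 15), mean_track_speed(tr, 15))
  expect_equal(direction_autocorrelation(list(rot), 15)$autocorrelation,
               direction_autocorrelation(list(tr), 15)$autocorrelation)
  expect_equal(directionality_ratio_over_time(list(scl))$mean_ratio,
               directionality_ratio_over_time(list(tr))$mean_ratio)
  # path shortening under subsampling: MTS at k*fi <= MTS at fi
  for (k in c(2, 3, 4))
    expect_lte(mean_track_speed(tr, k * 5), mean_track_speed(tr, 5) + 1e-12)
})

test_that("usable time interval selects the smallest passing multiple", {
  truth <- ground_truth(simulate_crw(crw_params(
    n_frames = 121L, frame_interval = 5, speed_mean = 0.4, speed_sd = 0.1,
    kappa = 50, noise_sd = 0, seed = 5)))$true_track
  # noiseless replicates: ratio 0 everywhere, k = 1
  expect_equal(usable_time_interval(
    replicate_observations(truth, 0, 3, seed = 1))$k, 1L)
  # fixed noise on a directed track: ratio non-increasing in k
  reps <- replicate_observations(truth, 1.2, 10, seed = 2)
  u <- usable_time_interval(reps)
  expect_gt(u$k, 1L)
  expect_true(all(diff(u$table$ratio) <= 1e-9))
  # noise so large no candidate passes
  bad <- replicate_observations(truth, 60, 5, seed = 3)
  expect_error(usable_time_interval(bad), "no candidate")
})

test_that("MTP at the usable interval beats MTP at the frame interval", {
  truth <- ground_truth(simulate_crw(crw_params(
    n_frames = 121L, frame_interval = 5, speed_mean = 0.4, speed_sd = 0.1,
    kappa = 50, noise_sd = 0, seed = 5)))$true_track
  reps <- replicate_observations(truth, 1.2, 10, seed = 2)
  u <- usable_time_interval(reps)
  pp <- function(k) persistence_params(delta_t = k * 5, TR = 4L)
  err <- function(k) mean(vapply(reps, function(r)
    abs(as.numeric(mean_track_persistence(r, pp(k))) -
          as.numeric(mean_track_persistence(truth, pp(k)))), numeric(1)))
  expect_lt(err(u$k), err(1))
})

test_that("persistence profile reflects noise-speed interplay", {
  straight_pop <- lapply(1:5, function(i)
    straight_track(n = 40L, fi = 5, angle = i, id = paste0("s", i)))
  prof <- persistence_profile(straight_pop, TR = 4L, multiples = 1:4)
  expect_equal(prof$mean_mtp, rep(1, 4))
  # random walks stay below the straight-line value
  rw <- simulate_population(30L, 500, n_frames = 60L, frame_interval = 5,
                            speed_mean = 0.5, speed_sd = 0.1, kappa = 0,
                            noise_sd = 0)
  prw <- persistence_profile(rw, TR = 4L, multiples = 1:3)
  expect_true(all(prw$mean_mtp < 1))
  # noisy persistent walkers: profile rises to an interior peak then falls,
  # and the peak moves right as tracking noise grows
  pop <- function(noise, seed0) simulate_population(
    60L, seed0, n_frames = 60L, frame_interval = 5, speed_mean = 0.5,
    speed_sd = 0.1, kappa = 8, noise_sd = noise)
  p_lo <- persistence_profile(pop(0.5, 100), TR = 4L, multiples = 1:8)
  p_hi <- persistence_profile(pop(2.0, 300), TR = 4L, multiples = 1:8)
  pk_lo <- which.max(p_lo$mean_mtp); pk_hi <- which.max(p_hi$mean_mtp)
  expect_gt(p_hi$mean_mtp[pk_hi], p_hi$mean_mtp[1])       # rises to a peak
  expect_gt(p_hi$mean_mtp[pk_hi], p_hi$mean_mtp[8])       # then falls off
  expect_gt(pk_hi, pk_lo)                                  # peak shifts right
})

test_that("MSD is ballistic for straight and flat for stationary tracks", {
  tr <- straight_track(n = 30L, fi = 5, speed = 0.5)
  m <- mean_square_displacement(list(tr), max_lag = 8L)
  expect_equal(m$msd, (0.5 * m$lag_minutes)^2)
  expect_equal(m$slope, 2, tolerance = 1e-9)
  expect_equal(mean_square_displacement(list(stationary_track()),
                                        max_lag = 5L)$msd, rep(0, 5))
  expect_error(mean_square_displacement(list(straight_track(n = 5L)),
                                        max_lag = 5L), "max_lag")
})

test_that("directionality ratio over time is bounded and monotone for walks", {
  st <- lapply(1:3, function(i) straight_track(n = 20L, angle = i,
                                               id = paste0("s", i)))
  d <- directionality_ratio_over_time(st)
  expect_equal(d$mean_ratio, rep(1, 19))
  # two-frame track: first step ratio 1
  two <- track("two", c(0, 5), c(0, 1), c(0, 2))
  expect_equal(directionality_ratio_over_time(list(two))$mean_ratio, 1)
  rw <- simulate_population(40L, 900, n_frames = 50L, frame_interval = 5,
                            speed_mean = 0.5, speed_sd = 0.1, kappa = 0,
                            noise_sd = 0)
  dr <- directionality_ratio_over_time(rw)
  expect_true(all(dr$mean_ratio <= 1 + 1e-12))
  expect_true(all(diff(dr$mean_ratio) < 0.03))  # non-increasing up to MC noise
})

test_that("direction autocorrelation separates straight, random and zig-zag", {
  expect_equal(direction_autocorrelation(
    list(straight_track(n = 25L)), 15)$autocorrelation |> unique(), 1)
  tr <- ground_truth(simulate_crw(crw_params(
    n_frames = 10001L, frame_interval = 5, speed_mean = 0.5, speed_sd = 0.1,
    kappa = 0, noise_sd = 0, seed = 21)))$true_track
  ac <- direction_autocorrelation(list(tr), 5, max_lag = 3L)
  expect_true(all(abs(ac$autocorrelation) < 0.05))
  # constructed geometry: +/- 90 degree zig-zag alternates 0, 1
  zz <- zigzag_track(n_steps = 8L, fi = 5)
  acz <- direction_autocorrelation(list(zz), 5, max_lag = 4L)
  expect_equal(acz$autocorrelation, c(0, 1, 0, 1), tolerance = 1e-12)
  expect_error(direction_autocorrelation(list(stationary_track()), 5),
               "zero length")
})

test_that("tracking CSV round-trips and rejects malformed input", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("track_id,frame,x_px,y_px", "a,0,10,4", "a,1,12,4"), tmp)
  trs <- read_tracks(tmp, frame_interval = 5, pixel_size = 0.5)
  expect_equal(trs[[1]]$x, c(5, 6))     # px * 0.5
  # duplicate (track, frame)
  writeLines(c("track_id,frame,x_px,y_px", "a,0,1,1", "a,0,2,2"), tmp)
  expect_error(read_tracks(tmp, 5, 0.5), "duplicate")
  # missing frame within a track
  writeLines(c("track_id,frame,x_px,y_px", "a,0,1,1", "a,2,2,2"), tmp)
  expect_error(read_tracks(tmp, 5, 0.5), "missing frames")
  # non-numeric cell names the row
  writeLines(c("track_id,frame,x_px,y_px", "a,0,oops,1"), tmp)
  expect_error(read_tracks(tmp, 5, 0.5), "non-numeric")
  # Fiji Manual Tracking shim: leading index, 1-based slices
  writeLines(c(" ,Track n°,Slice n°,X,Y", "1,7,1,3,4", "2,7,2,5,6"),
             tmp)
  fi <- read_tracks(tmp, 5, 1)
  expect_equal(fi[[1]]$times, c(0, 5))
  expect_equal(fi[[1]]$x, c(3, 5))
  # write/read round trip on values
  pop <- simulate_population(3L, 40, n_frames = 12L, frame_interval = 5,
                             speed_mean = 0.5, speed_sd = 0.1, kappa = 1,
                             noise_sd = 0.1)
  out <- withr::local_tempfile(fileext = ".csv")
  write_tracks(pop, out, pixel_size = 0.65)
  back <- read_tracks(out, frame_interval = 5, pixel_size = 0.65)
  for (i in 1:3) {
    j <- which(vapply(back, `[[`, "", "cell_id") == pop[[i]]$cell_id)
    expect_equal(back[[j]]$x, pop[[i]]$x, tolerance = 1e-6)
    expect_equal(back[[j]]$y, pop[[i]]$y, tolerance = 1e-6)
  }
})
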