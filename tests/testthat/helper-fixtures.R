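# Shared fixtures built in code: canonical tracks and masks with known
# geometry, used across the module tests.

straight_track <- function(n = 48L, fi = 5, speed = 1, angle = 0,
                           id = "straight") {
  t <- (seq_len(n) - 1) * fi
  track(id, t, t * speed * cos(angle), t * speed * sin(angle))
}

stationary_track <- function(n = 20L, fi = 5) {
  track("still", (seq_len(n) - 1) * fi, rep(1.5, n), rep(-2, n))
}

# out-and-back every k intervals: net displacement zero per window
out_and_back_track <- function(n_cycles = 4L, fi = 5, step = 2) {
  x <- c(0, rep(c(step, 0), n_cycles))
  track("oab", (seq_along(x) - 1) * fi, x, rep(0, length(x)))
}

# right-angle zig-zag: alternating +x and +y displacements of equal length
zigzag_track <- function(n_steps = 12L, fi = 5, step = 3) {
  dx <- rep(c(step, 0), length.out = n_steps)
  dy <- rep(c(0, step), length.out = n_steps)
  track("zig", (0:n_steps) * fi, c(0, cumsum(dx)), c(0, cumsum(dy)))
}

disc_mask <- function(h, w, cy, cx, r_px) {
  yy <- matrix(seq_len(h), h, w) - cy
  xx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  sqrt(xx^2 + yy^2) <= r_px
}

# disc movie whose radius follows radii_px, as a movie_stack
disc_movie <- function(radii_px, h = 120L, w = 120L, pixel_size = 0.25,
                       frame_interval = 30) {
  m <- array(FALSE, c(h, w, length(radii_px)))
  for (t in seq_along(radii_px))
    m[, , t] <- disc_mask(h, w, (h + 1) / 2, (w + 1) / 2, radii_px[t])
  movie_stack(m, pixel_size, frame_interval)
}

# disc with two disjoint protruding sectors (given in degrees, centred at
# the given directions), grown by grow_px in the sectors between frames
two_sector_movie <- function(arcs_deg = c(40, 80), centres_deg = c(0, 180),
                             r_px = 60, grow_px = 2, h = 160L, w = 160L,
                             pixel_size = 0.25, frame_interval = 30) {
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- matrix(seq_len(h), h, w) - cy
  xx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  rr <- sqrt(xx^2 + yy^2)
  ang <- atan2(yy, xx) * 180 / pi
  in_sector <- matrix(FALSE, h, w)
  for (i in seq_along(arcs_deg)) {
    d <- (ang - centres_deg[i] + 180) %% 360 - 180
    in_sector <- in_sector | abs(d) <= arcs_deg[i] / 2
  }
  m <- array(FALSE, c(h, w, 2))
  m[, , 1] <- rr <= r_px
  m[, , 2] <- (in_sector & rr <= r_px + grow_px) | (!in_sector & rr <= r_px)
  movie_stack(m, pixel_size, frame_interval)
}

# drifting disc: radius follows radii_px while the centre moves +drift_px
# per frame along x, so the migration direction (hence the cone) is defined
drift_disc_movie <- function(radii_px, drift_px = 1, h = 180L,
                             pixel_size = 0.25, frame_interval = 30) {
  m <- array(FALSE, c(h, h, length(radii_px)))
  for (t in seq_along(radii_px))
    m[, , t] <- disc_mask(h, h, (h + 1) / 2,
                          (h + 1) / 2 + drift_px * (t - 1), radii_px[t])
  movie_stack(m, pixel_size, frame_interval)
}

# hand-built edge profile on a continuum circle: one velocity vector per
# frame (recycled around the boundary), centroid fixed at the origin,
# migration direction +x; exercises the cone statistics without pixelation
synthetic_profile <- function(velocity_frames, radius_um = 10,
                              n_points = 360L) {
  th <- seq(0, 2 * pi, length.out = n_points + 1L)[-(n_points + 1L)]
  seg <- rep(2 * pi * radius_um / n_points, n_points)
  frames <- lapply(seq_along(velocity_frames), function(t) {
    data.frame(frame = t, row = NA, col = NA,
               x_um = radius_um * cos(th), y_um = radius_um * sin(th),
               arc_um = cumsum(seg) - seg[1], seg_um = seg,
               velocity = rep(velocity_frames[[t]], length.out = n_points))
  })
  structure(list(frames = frames,
                 centroids = matrix(0, length(velocity_frames) + 1L, 2),
                 migration_dir = matrix(rep(c(1, 0),
                                            each = length(velocity_frames)),
                                        ncol = 2),
                 pixel_size = 1, frame_interval_min = 0.5,
                 n_frames = length(velocity_frames) + 1L),
            class = "edge_profile")
}

simulate_population <- function(n, seed0, ...) {
  lapply(seq_len(n), function(i)
    simulate_crw(crw_params(..., seed = seed0 + i),
                 cell_id = sprintf("c%03d", i)))
}
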