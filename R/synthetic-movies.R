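# Synthetic time-lapse generators: a textured lamellipodial band with a
# prescribed uniform retrograde flow (PIV ground truth) and a disc-like cell
# with a protruding angular sector (edge-metric ground truth).

#' Movie container
#'
#' Wraps a `[row, col, frame]` numeric array with the physical calibration
#' every image stage needs. Rows are the image y axis (pointing down).
#'
#' @param arr 3-D numeric array
#' @param pixel_size um per pixel
#' @param frame_interval seconds between frames
#' @export
movie_stack <- function(arr, pixel_size, frame_interval) {
  stopifnot(length(dim(arr)) == 3L)
  check_scalar(pixel_size, "pixel_size", lower = 0, allow_equal_lower = FALSE)
  check_scalar(frame_interval, "frame_interval", lower = 0,
               allow_equal_lower = FALSE)
  structure(arr, pixel_size = pixel_size, frame_interval = frame_interval,
            class = c("movie_stack", "array"))
}

pixel_size_of <- function(m) attr(m, "pixel_size", exact = TRUE)
frame_interval_of <- function(m) attr(m, "frame_interval", exact = TRUE)

um_per_min_to_px_per_frame <- function(v, pixel_size, frame_interval_s) {
  v * frame_interval_s / 60 / pixel_size
}

#' Parameters of the synthetic retrograde-flow movie
#'
#' Defaults follow the acquisition the PIV stage targets: Airyscan frames
#' every 3.22 s, at least 20 frames, pixels of 0.05 um.
#'
#' @param shape image height and width in pixels
#' @param pixel_size um/px
#' @param frame_interval seconds
#' @param n_frames frame count (>= 2)
#' @param flow_speed retrograde flow, um/min, directed into the cell (+y)
#' @param protrusion_speed edge advance, um/min, directed out of the cell (-y)
#' @param texture_grain Gaussian filter scale of the speckle texture, px
#' @param texture_contrast amplitude of the texture relative to mean level
#' @param noise_sd per-frame additive Gaussian intensity noise
#' @param band_depth lamellipodium band depth, um
#' @param seed integer RNG seed
#' @export
flow_movie_params <- function(shape = c(128L, 128L), pixel_size = 0.05,
                              frame_interval = 3.22, n_frames = 20L,
                              flow_speed = 1.5, protrusion_speed = 0,
                              texture_grain = 2, texture_contrast = 0.4,
                              noise_sd = 0.02, band_depth = 3, seed = 1L) {
  stopifnot(length(shape) == 2L, all(shape >= 16))
  check_scalar(flow_speed, "flow_speed", lower = 0)
  check_scalar(protrusion_speed, "protrusion_speed", lower = 0)
  check_scalar(texture_grain, "texture_grain", lower = 1)
  check_scalar(band_depth, "band_depth", lower = 0, allow_equal_lower = FALSE)
  check_scalar(n_frames, "n_frames", lower = 2, integer = TRUE)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(seed, "seed", integer = TRUE)
  structure(list(shape = as.integer(shape), pixel_size = pixel_size,
                 frame_interval = frame_interval, n_frames = as.integer(n_frames),
                 flow_speed = flow_speed, protrusion_speed = protrusion_speed,
                 texture_grain = texture_grain, texture_contrast = texture_contrast,
                 noise_sd = noise_sd, band_depth = band_depth,
                 seed = as.integer(seed)), class = "flow_movie_params")
}

#' Synthesize a lamellipodial flow movie with known displacement field
#'
#' A horizontal band of speckle texture occupies the lower part of the frame
#' (the cell, entered from its top edge). The texture translates rigidly
#' downwards (into the cell) at `flow_speed` by Fourier shifting a periodic
#' noise canvas — sub-pixel motion without interpolation blur — while the
#' band's outer (top) edge advances upwards at `protrusion_speed`. Per-frame
#' intensity noise is redrawn independently.
#'
#' @param params a [flow_movie_params()]
#' @return list with `movie` and `mask` ([movie_stack()]s); [ground_truth()]
#'   on the returned list records the per-frame true displacement (px and
#'   um), the flow vector in um/min and any PIV-reach warning
#' @export
synth_flow_movie <- function(params) {
  stopifnot(inherits(params, "flow_movie_params"))
  set.seed(params$seed)
  h <- params$shape[1]; w <- params$shape[2]
  dy_px <- um_per_min_to_px_per_frame(params$flow_speed, params$pixel_size,
                                      params$frame_interval)
  prot_px <- um_per_min_to_px_per_frame(params$protrusion_speed,
                                        params$pixel_size, params$frame_interval)
  depth_px <- params$band_depth / params$pixel_size
  canvas <- gaussian_blur_periodic(matrix(stats::rnorm(h * w), h, w),
                                   params$texture_grain)
  canvas <- tanh(canvas / stats::sd(canvas))   # soft threshold, range (-1, 1)
  edge0 <- h - depth_px - 2                    # top edge row of the band
  if (edge0 < 2 + prot_px * (params$n_frames - 1))
    stop_bad("band leaves the field of view: reduce n_frames or speeds")
  mov <- array(0, c(h, w, params$n_frames))
  msk <- array(FALSE, c(h, w, params$n_frames))
  rows <- seq_len(h)
  for (t in seq_len(params$n_frames)) {
    tex <- fourier_shift(canvas, dy = (t - 1) * dy_px, dx = 0)
    top <- edge0 - (t - 1) * prot_px
    inb <- rows >= top & rows <= min(top + depth_px, h)
    frame <- matrix(0.05, h, w)
    frame[inb, ] <- 0.5 + params$texture_contrast * tex[inb, ]
    if (params$noise_sd > 0)
      frame <- frame + stats::rnorm(h * w, sd = params$noise_sd)
    mov[, , t] <- frame
    msk[, , t] <- inb
  }
  reach_um <- 0.5 / 2                          # default PIV search reach
  warn <- if (dy_px * params$pixel_size > reach_um)
    sprintf("per-frame displacement %.3g um exceeds default PIV reach %.3g um",
            dy_px * params$pixel_size, reach_um) else NULL
  out <- list(movie = movie_stack(mov, params$pixel_size, params$frame_interval),
              mask = movie_stack(msk, params$pixel_size, params$frame_interval))
  set_ground_truth(out, "synth_flow_movie", params,
                   displacement_px = c(dy = dy_px, dx = 0),
                   displacement_um = c(dy = dy_px * params$pixel_size, dx = 0),
                   flow_vector_um_min = c(vx = 0, vy = params$flow_speed),
                   protrusion_speed = params$protrusion_speed,
                   warning = warn)
}

#' Synthesize a disc cell with a protruding angular sector
#'
#' A disc of radius `radius_um` whose boundary advances at `edge_speed`
#' inside a contiguous sector of `arc_protruding` degrees centred on the +x
#' direction, and retracts at `retraction_speed` elsewhere. The ground truth
#' records the protruding arc length per frame.
#'
#' @param arc_protruding sector size, degrees in (0, 360]
#' @param edge_speed protrusion speed inside the sector, um/min
#' @param retraction_speed retraction speed outside the sector, um/min (>= 0)
#' @param radius_um initial disc radius, um
#' @param shape image height and width, px
#' @param pixel_size um/px
#' @param frame_interval seconds
#' @param n_frames frame count
#' @param noise_sd intensity noise on the rendered movie
#' @param seed integer RNG seed
#' @return list with `mask` (logical [movie_stack()]) and `movie` (an
#'   intensity rendering: foreground 0.85, background 0.05, plus noise);
#'   [ground_truth()] holds the per-frame protruding arc length and radii
#' @export
synth_edge_movie <- function(arc_protruding = 90, edge_speed = 1,
                             retraction_speed = 0.5, radius_um = 20,
                             shape = c(200L, 200L), pixel_size = 0.25,
                             frame_interval = 30, n_frames = 6L,
                             noise_sd = 0, seed = 1L) {
  if (!(arc_protruding > 0 && arc_protruding <= 360))
    stop_bad("arc_protruding must be in (0, 360], got %g", arc_protruding)
  check_scalar(edge_speed, "edge_speed")
  check_scalar(retraction_speed, "retraction_speed", lower = 0)
  check_scalar(n_frames, "n_frames", lower = 2, integer = TRUE)
  set.seed(as.integer(seed))
  h <- shape[1]; w <- shape[2]
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  half <- arc_protruding / 2 * pi / 180
  yy <- matrix(seq_len(h) - cy, h, w)
  xx <- matrix(seq_len(w) - cx, h, w, byrow = TRUE)
  rr <- sqrt(xx^2 + yy^2) * pixel_size
  ang <- atan2(yy, xx)
  msk <- array(FALSE, c(h, w, n_frames))
  mov <- array(0, c(h, w, n_frames))
  r_sec <- r_out <- arc_len <- numeric(n_frames)
  for (t in seq_len(n_frames)) {
    dt_min <- (t - 1) * frame_interval / 60
    r_sec[t] <- radius_um + edge_speed * dt_min
    r_out[t] <- radius_um - retraction_speed * dt_min
    if (r_out[t] <= 2 * pixel_size || r_sec[t] <= 2 * pixel_size)
      stop_bad("cell boundary self-intersects at frame %d", t)
    if (r_sec[t] >= min(cx, cy) * pixel_size - pixel_size)
      stop_bad("cell leaves the field of view at frame %d", t)
    in_sector <- abs(wrap_angle(ang)) <= half
    m <- (in_sector & rr <= r_sec[t]) | (!in_sector & rr <= r_out[t])
    msk[, , t] <- m
    frame <- ifelse(m, 0.85, 0.05)
    if (noise_sd > 0) frame <- frame + stats::rnorm(h * w, sd = noise_sd)
    mov[, , t] <- frame
    arc_len[t] <- if (arc_protruding >= 360) 2 * pi * r_sec[t] else
      2 * half * r_sec[t]
  }
  out <- list(mask = movie_stack(msk, pixel_size, frame_interval),
              movie = movie_stack(mov, pixel_size, frame_interval))
  set_ground_truth(out, "synth_edge_movie",
                   list(arc_protruding = arc_protruding,
                        edge_speed = edge_speed,
                        retraction_speed = retraction_speed,
                        radius_um = radius_um, shape = shape,
                        pixel_size = pixel_size,
                        frame_interval = frame_interval,
                        n_frames = n_frames, noise_sd = noise_sd, seed = seed),
                   protruding_arc_um = arc_len,
                   sector_radius_um = r_sec, other_radius_um = r_out,
                   sector_direction = c(x = 1, y = 0))
}
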