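# Cross-correlation particle image velocimetry of F-actin retrograde flow:
# zero-normalised template matching on a grid, correlation thresholding,
# optional three-point Gaussian sub-pixel peak refinement, and
# normalised-convolution interpolation to a dense spatiotemporal field.

#' PIV parameters
#'
#' Defaults are the optimised settings for Airyscan lamellipodium movies:
#' source box 0.3 um searched within 0.5 um on a 0.2 um grid, correlation
#' threshold 0.5; interpolation kernels 3 um (sigma 0.5 um) in space and
#' 15 s (sigma 6 s) in time.
#'
#' @param source_box source (template) box side, um
#' @param search_box search box side, um (must exceed `source_box`)
#' @param grid_step grid spacing, um
#' @param corr_threshold minimum correlation coefficient in (0, 1)
#' @param spatial_kernel_size,spatial_sigma interpolation kernel, um
#' @param temporal_kernel_size,temporal_sigma interpolation kernel, s
#' @param subpixel enable three-point Gaussian peak refinement
#' @export
piv_params <- function(source_box = 0.3, search_box = 0.5, grid_step = 0.2,
                       corr_threshold = 0.5, spatial_kernel_size = 3,
                       spatial_sigma = 0.5, temporal_kernel_size = 15,
                       temporal_sigma = 6, subpixel = TRUE) {
  if (search_box <= source_box)
    stop_bad("search_box (%g) must exceed source_box (%g)", search_box,
             source_box)
  check_scalar(corr_threshold, "corr_threshold", lower = 0, upper = 1,
               allow_equal_lower = FALSE)
  if (spatial_kernel_size < spatial_sigma ||
      temporal_kernel_size < temporal_sigma)
    stop_bad("kernel sizes must be at least their sigmas")
  structure(list(source_box = source_box, search_box = search_box,
                 grid_step = grid_step, corr_threshold = corr_threshold,
                 spatial_kernel_size = spatial_kernel_size,
                 spatial_sigma = spatial_sigma,
                 temporal_kernel_size = temporal_kernel_size,
                 temporal_sigma = temporal_sigma,
                 subpixel = isTRUE(subpixel)), class = "piv_params")
}

# nearest odd pixel count >= 3
odd_px <- function(um, pixel_size) {
  n <- max(3L, as.integer(round(um / pixel_size)))
  if (n %% 2L == 0L) n + 1L else n
}

# three-point peak interpolation along one axis: Gaussian fit on the raw
# correlation values when all three are positive (the usual PIV estimator),
# parabolic fit otherwise
gauss_subpixel <- function(cm, c0, cp) {
  if (cm > 0 && c0 > 0 && cp > 0) {
    lm_ <- log(cm); l0 <- log(c0); lp <- log(cp)
    den <- 2 * (lm_ + lp - 2 * l0)
    if (is.finite(den) && den < 0)
      return(max(min((lm_ - lp) / den, 0.5), -0.5))
  }
  den <- 2 * (cm + cp - 2 * c0)
  if (!is.finite(den) || den >= 0) return(0)
  max(min((cm - cp) / den, 0.5), -0.5)
}

#' PIV on one frame pair
#'
#' For every grid node whose source box lies fully inside `mask_t`, the
#' zero-normalised (Pearson) correlation of the source patch of `frame_t`
#' against every candidate offset inside the search box of `frame_t1` is
#' computed; the best match is kept iff its coefficient reaches
#' `corr_threshold` (ties: smallest displacement, then row-major order).
#' Zero-variance source patches are marked invalid. The grid origin sits at
#' the mask bounding-box corner.
#'
#' @param frame_t,frame_t1 numeric matrices (consecutive frames)
#' @param mask_t logical matrix: analysis region in frame t
#' @param params a [piv_params()]
#' @param pixel_size um/px
#' @param frame_interval s
#' @return data.frame of sparse vectors: `x_um`, `y_um` (node centre),
#'   `dx_px`, `dy_px`, `dx_um`, `dy_um`, `corr`, `valid`
#' @export
piv_frame_pair <- function(frame_t, frame_t1, mask_t, params = piv_params(),
                           pixel_size, frame_interval) {
  stopifnot(identical(dim(frame_t), dim(frame_t1)))
  h <- nrow(frame_t); w <- ncol(frame_t)
  src <- odd_px(params$source_box, pixel_size)
  srch <- odd_px(params$search_box, pixel_size)
  if (srch <= src) srch <- src + 2L
  # candidate centres span the search box: displacements up to search_box/2.
  # (Containing whole candidate boxes would cap measurable flow below the
  # speeds this method is routinely applied to.)
  reach <- (srch - 1L) %/% 2L
  step <- max(1L, as.integer(round(params$grid_step / pixel_size)))
  hs <- (src - 1L) %/% 2L
  idx <- which(mask_t)
  if (!length(idx)) stop_bad("empty PIV mask")
  rr <- ((idx - 1L) %% h) + 1L; cc <- ((idx - 1L) %/% h) + 1L
  rows <- seq(min(rr), max(rr), by = step)
  cols <- seq(min(cc), max(cc), by = step)
  offs <- expand.grid(dy = -reach:reach, dx = -reach:reach)
  offs <- offs[order(offs$dy, offs$dx), ]
  out <- vector("list", length(rows) * length(cols))
  n_out <- 0L
  patch_rows <- -hs:hs
  for (r0 in rows) for (c0 in cols) {
    if (r0 - hs < 1 || r0 + hs > h || c0 - hs < 1 || c0 + hs > w) next
    mrows <- r0 + patch_rows; mcols <- c0 + patch_rows
    if (!all(mask_t[mrows, mcols])) next
    if (r0 - hs - reach < 1 || r0 + hs + reach > h ||
        c0 - hs - reach < 1 || c0 + hs + reach > w) next
    s <- frame_t[mrows, mcols]
    s0 <- s - mean(s)
    sden <- sqrt(sum(s0^2))
    n_out <- n_out + 1L
    if (sden == 0) {
      out[[n_out]] <- data.frame(x_um = c0 * pixel_size, y_um = r0 * pixel_size,
                                 dx_px = NA_real_, dy_px = NA_real_,
                                 dx_um = NA_real_, dy_um = NA_real_,
                                 corr = NA_real_, valid = FALSE)
      next
    }
    cmat <- matrix(NA_real_, 2L * reach + 1L, 2L * reach + 1L)
    for (k in seq_len(nrow(offs))) {
      t2 <- frame_t1[mrows + offs$dy[k], mcols + offs$dx[k]]
      t0 <- t2 - mean(t2)
      tden <- sqrt(sum(t0^2))
      cmat[offs$dy[k] + reach + 1L, offs$dx[k] + reach + 1L] <-
        if (tden == 0) -Inf else sum(s0 * t0) / (sden * tden)
    }
    best <- max(cmat)
    cand <- which(cmat == best, arr.ind = TRUE)
    dmag <- (cand[, 1] - reach - 1)^2 + (cand[, 2] - reach - 1)^2
    cand <- cand[order(dmag, cand[, 1], cand[, 2]), , drop = FALSE]
    dy <- cand[1, 1] - reach - 1L; dx <- cand[1, 2] - reach - 1L
    if (params$subpixel && abs(dy) < reach && abs(dx) < reach &&
        is.finite(best)) {
      iy <- dy + reach + 1L; ix <- dx + reach + 1L
      dy <- dy + gauss_subpixel(cmat[iy - 1L, ix], cmat[iy, ix],
                                cmat[iy + 1L, ix])
      dx <- dx + gauss_subpixel(cmat[iy, ix - 1L], cmat[iy, ix],
                                cmat[iy, ix + 1L])
    }
    out[[n_out]] <- data.frame(x_um = c0 * pixel_size, y_um = r0 * pixel_size,
                               dx_px = dx, dy_px = dy,
                               dx_um = dx * pixel_size, dy_um = dy * pixel_size,
                               corr = best,
                               valid = is.finite(best) &&
                                 best >= params$corr_threshold)
  }
  res <- if (n_out) do.call(rbind, out[seq_len(n_out)]) else
    data.frame(x_um = numeric(0), y_um = numeric(0), dx_px = numeric(0),
               dy_px = numeric(0), dx_um = numeric(0), dy_um = numeric(0),
               corr = numeric(0), valid = logical(0))
  attr(res, "pixel_size") <- pixel_size
  attr(res, "frame_interval") <- frame_interval
  res
}

#' PIV over a whole movie
#'
#' Applies [piv_frame_pair()] to every consecutive pair.
#' @param movie,masks [movie_stack()]s (masks logical)
#' @param params a [piv_params()]
#' @return list of sparse vector tables, one per frame pair, with `frame`
#'   column added
#' @export
piv_movie <- function(movie, masks, params = piv_params()) {
  nt <- dim(movie)[3]
  ps <- pixel_size_of(movie); fi <- frame_interval_of(movie)
  lapply(seq_len(nt - 1L), function(t) {
    v <- piv_frame_pair(movie[, , t], movie[, , t + 1],
                        masks[, , t] == TRUE, params, ps, fi)
    cbind(frame = t, v)
  })
}

# zero-padded separable convolution along rows/cols with an arbitrary kernel
conv2_zero <- function(img, k) {
  r <- (length(k) - 1L) %/% 2L
  axis_mat <- function(n) {
    B <- matrix(0, n, n)
    for (j in seq_along(k)) {
      src <- seq_len(n) + j - r - 1L
      keep <- src >= 1L & src <= n
      B[cbind(which(keep), src[keep])] <- B[cbind(which(keep), src[keep])] + k[j]
    }
    B
  }
  axis_mat(nrow(img)) %*% img %*% t(axis_mat(ncol(img)))
}

#' Interpolate sparse PIV vectors to a dense spatiotemporal field
#'
#' Normalised convolution: every pixel value is the Gaussian-weighted mean
#' of the valid sparse vectors in its spatiotemporal neighbourhood
#' (truncated Gaussians of the stated kernel sizes), which preserves
#' constant fields exactly; pixels receiving zero weight are NA (missing).
#'
#' @param sparse_layers output of [piv_movie()]
#' @param params a [piv_params()]
#' @param dims image dimensions `c(h, w)`
#' @param pixel_size um/px
#' @param frame_interval s
#' @return list `vx`, `vy`: arrays `[h, w, n_pairs]` of velocities in
#'   um/min, plus `weight`
#' @export
interpolate_dense <- function(sparse_layers, params, dims, pixel_size,
                              frame_interval) {
  nt <- length(sparse_layers)
  h <- dims[1]; w <- dims[2]
  num_x <- num_y <- den <- array(0, c(h, w, nt))
  any_valid <- FALSE
  for (t in seq_len(nt)) {
    v <- sparse_layers[[t]]
    v <- v[v$valid %in% TRUE, , drop = FALSE]
    if (!nrow(v)) next
    any_valid <- TRUE
    r <- pmin(pmax(round(v$y_um / pixel_size), 1L), h)
    c0 <- pmin(pmax(round(v$x_um / pixel_size), 1L), w)
    for (i in seq_len(nrow(v))) {
      num_x[r[i], c0[i], t] <- num_x[r[i], c0[i], t] + v$dx_um[i]
      num_y[r[i], c0[i], t] <- num_y[r[i], c0[i], t] + v$dy_um[i]
      den[r[i], c0[i], t] <- den[r[i], c0[i], t] + 1
    }
  }
  if (!any_valid) stop_bad("no valid sparse vectors to interpolate")
  sr <- max(1L, floor(params$spatial_kernel_size / pixel_size / 2))
  ks <- stats::dnorm(-sr:sr, sd = params$spatial_sigma / pixel_size)
  tr_ <- max(0L, floor(params$temporal_kernel_size / frame_interval / 2))
  kt <- stats::dnorm(-tr_:tr_, sd = params$temporal_sigma / frame_interval)
  smooth_st <- function(a) {
    for (t in seq_len(nt)) a[, , t] <- conv2_zero(a[, , t], ks)
    if (length(kt) > 1L) {
      flat <- matrix(a, ncol = nt)
      out <- matrix(0, nrow(flat), nt)
      for (j in seq_along(kt)) {
        t_src <- seq_len(nt) + j - tr_ - 1L
        keep <- t_src >= 1L & t_src <= nt
        out[, keep] <- out[, keep] + kt[j] * flat[, t_src[keep]]
      }
      a <- array(out, c(h, w, nt))
    }
    a
  }
  num_x <- smooth_st(num_x); num_y <- smooth_st(num_y); den <- smooth_st(den)
  scale_ <- 60 / frame_interval            # um/frame -> um/min
  eps <- 1e-12
  vx <- ifelse(den > eps, num_x / den, NA_real_) * scale_
  vy <- ifelse(den > eps, num_y / den, NA_real_) * scale_
  list(vx = array(vx, c(h, w, nt)), vy = array(vy, c(h, w, nt)),
       weight = den)
}

#' Mean retrograde flow speed
#'
#' Per frame, the mean velocity magnitude over masked pixels of the dense
#' field; per cell, the mean over frames.
#'
#' @param dense output of [interpolate_dense()]
#' @param masks logical [movie_stack()] (frames t of each pair)
#' @return list: `per_frame` data.frame, `cell_mean` um/min
#' @export
mean_flow_speed <- function(dense, masks) {
  nt <- dim(dense$vx)[3]
  per <- vapply(seq_len(nt), function(t) {
    m <- masks[, , t] == TRUE
    if (!any(m)) stop_bad("empty mask at frame %d", t)
    sp <- sqrt(dense$vx[, , t]^2 + dense$vy[, , t]^2)[m]
    mean(sp[is.finite(sp)])
  }, numeric(1))
  list(per_frame = data.frame(frame = seq_len(nt), flow_speed = per),
       cell_mean = mean(per, na.rm = TRUE))
}

#' F-actin assembly rate
#'
#' The effective polymerisation speed at the leading edge: the sum of the
#' magnitudes of the retrograde flow speed and the protrusion speed.
#'
#' @param flow_speed um/min
#' @param protrusion_speed um/min
#' @return um/min
#' @export
assembly_rate <- function(flow_speed, protrusion_speed) {
  abs(flow_speed) + abs(protrusion_speed)
}

#' Truncate a movie at quality-loss events
#'
#' Automated surrogate for manual truncation: trailing frames are dropped
#' once the mask area falls below `area_fraction` of its initial value or
#' the mask touches the image border on more than `border_budget` pixels.
#'
#' @param movie,masks [movie_stack()]s
#' @param area_fraction minimum mask area relative to frame 1
#' @param border_budget tolerated border-touching pixels
#' @return list: truncated `movie` and `mask`, `kept` frame count, `log`
#' @export
truncate_movie <- function(movie, masks, area_fraction = 0.5,
                           border_budget = 0L) {
  nt <- dim(masks)[3]
  a1 <- sum(masks[, , 1])
  cut <- nt + 1L
  reason <- NA_character_
  for (t in seq_len(nt)) {
    m <- masks[, , t] == TRUE
    border <- sum(m[1, ]) + sum(m[nrow(m), ]) + sum(m[, 1]) + sum(m[, ncol(m)])
    if (sum(m) < area_fraction * a1) {
      cut <- t; reason <- sprintf("area below %g of initial at frame %d",
                                  area_fraction, t); break
    }
    if (border > border_budget) {
      cut <- t; reason <- sprintf("mask touches border (%d px) at frame %d",
                                  border, t); break
    }
  }
  if (cut == 1L) stop_bad("all frames rejected: %s", reason)
  keep <- seq_len(cut - 1L)
  list(movie = movie_stack(movie[, , keep, drop = FALSE],
                           pixel_size_of(movie), frame_interval_of(movie)),
       mask = movie_stack(masks[, , keep, drop = FALSE],
                          pixel_size_of(masks), frame_interval_of(masks)),
       kept = length(keep),
       log = if (is.na(reason)) "nothing trimmed" else reason)
}
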