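# Low-level raster primitives used by the segmentation, edge and PIV stages.
# Images are numeric matrices indexed [row, col] with the y axis pointing
# down; movies are [row, col, frame] arrays carrying `pixel_size` (um/px) and
# `frame_interval` (s) attributes.

#' Separable Gaussian blur with replicated borders
#'
#' @param img numeric matrix
#' @param sigma kernel standard deviation in pixels; 0 returns `img`
#' @return blurred matrix of the same shape
#' @keywords internal
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  blur_axis <- function(n) {
    B <- matrix(0, n, n)
    for (j in seq_len(2 * r + 1)) {
      idx <- pmin(pmax(seq_len(n) + j - r - 1L, 1L), n)
      B[cbind(seq_len(n), idx)] <- B[cbind(seq_len(n), idx)] + k[j]
    }
    B
  }
  blur_axis(nrow(img)) %*% img %*% t(blur_axis(ncol(img)))
}

# Circular (periodic) Gaussian smoothing via FFT; used for texture synthesis
# where the canvas is treated as a torus so Fourier shifts stay exact.
gaussian_blur_periodic <- function(img, sigma) {
  h <- nrow(img); w <- ncol(img)
  fy <- c(0:(h %/% 2), -((h - h %/% 2 - 1):1)) / h
  fx <- c(0:(w %/% 2), -((w - w %/% 2 - 1):1)) / w
  gk <- exp(-2 * pi^2 * sigma^2 * outer(fy^2, fx^2, `+`))
  Re(stats::fft(stats::fft(img) * gk, inverse = TRUE)) / (h * w)
}

# Subpixel rigid translation by (dy, dx) pixels using the Fourier shift
# theorem (image treated as periodic).
fourier_shift <- function(img, dy, dx) {
  h <- nrow(img); w <- ncol(img)
  fy <- c(0:(h %/% 2), -((h - h %/% 2 - 1):1)) / h
  fx <- c(0:(w %/% 2), -((w - w %/% 2 - 1):1)) / w
  ph <- exp(-2i * pi * (outer(fy * dy, fx * dx, `+`)))
  Re(stats::fft(stats::fft(img) * ph, inverse = TRUE)) / (h * w)
}

#' Otsu threshold of a [0,1]-scaled image
#' @keywords internal
otsu_threshold <- function(img, n_bins = 256L) {
  v <- img[is.finite(img)]
  h <- tabulate(pmin(pmax(floor(v * n_bins) + 1L, 1L), n_bins), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  (which.max(sigma_b)) / n_bins
}

# 8-connected component labelling by vectorised frontier growth.
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  off <- c(-1L, 1L, -h, h, -h - 1L, -h + 1L, h - 1L, h + 1L)
  row_of <- function(i) ((i - 1L) %% h) + 1L
  next_lab <- 0L
  todo <- which(mask & lab == 0L)
  while (length(todo)) {
    seed <- todo[1L]
    next_lab <- next_lab + 1L
    lab[seed] <- next_lab
    frontier <- seed
    while (length(frontier)) {
      cand <- rep(frontier, each = 8L) + off
      src_row <- rep(row_of(frontier), each = 8L)
      keep <- cand >= 1L & cand <= h * w &
        abs(row_of(cand) - src_row) <= 1L
      cand <- unique(cand[keep])
      cand <- cand[mask[cand] & lab[cand] == 0L]
      lab[cand] <- next_lab
      frontier <- cand
    }
    todo <- which(mask & lab == 0L)
  }
  lab
}

largest_component <- function(mask) {
  lab <- label_components(mask)
  if (max(lab) == 0L) return(mask & FALSE)
  lab == which.max(tabulate(lab[lab > 0L]))
}

# Fill interior holes: background components (4-connected) not touching the
# image border become foreground.
fill_holes <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  bg <- !mask
  lab <- matrix(0L, h, w)
  off <- c(-1L, 1L, -h, h)
  row_of <- function(i) ((i - 1L) %% h) + 1L
  next_lab <- 0L
  todo <- which(bg & lab == 0L)
  while (length(todo)) {
    seed <- todo[1L]
    next_lab <- next_lab + 1L
    lab[seed] <- next_lab
    frontier <- seed
    while (length(frontier)) {
      cand <- rep(frontier, each = 4L) + off
      src_row <- rep(row_of(frontier), each = 4L)
      keep <- cand >= 1L & cand <= h * w & abs(row_of(cand) - src_row) <= 1L
      cand <- unique(cand[keep])
      cand <- cand[bg[cand] & lab[cand] == 0L]
      lab[cand] <- next_lab
      frontier <- cand
    }
    todo <- which(bg & lab == 0L)
  }
  border_labs <- unique(c(lab[1, ], lab[h, ], lab[, 1], lab[, w]))
  out <- mask
  out[bg & !(lab %in% border_labs)] <- TRUE
  out
}

#' Ordered closed boundary of a binary mask (Moore-neighbour tracing)
#'
#' Returns an n x 2 matrix of (row, col) pixel coordinates describing the
#' outer boundary as one closed loop. The start point is the boundary pixel
#' nearest the image origin (ties broken lexicographically), which fixes the
#' wrap-around bookkeeping of arc positions deterministically.
#' @keywords internal
trace_boundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(mask)
  if (!length(idx)) stop_bad("empty mask has no boundary")
  rows <- ((idx - 1L) %% h) + 1L
  cols <- ((idx - 1L) %/% h) + 1L
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[cbind(rows + 1L, cols + 1L)] <- TRUE
  is_boundary <- vapply(seq_along(idx), function(i) {
    r <- rows[i] + 1L; c0 <- cols[i] + 1L
    !(pad[r - 1L, c0] && pad[r + 1L, c0] && pad[r, c0 - 1L] && pad[r, c0 + 1L])
  }, logical(1))
  brows <- rows[is_boundary]; bcols <- cols[is_boundary]
  d2 <- (brows - 1)^2 + (bcols - 1)^2
  o <- order(d2, brows, bcols)
  start <- c(brows[o[1]], bcols[o[1]])
  if (sum(mask) == 1L) return(matrix(start, 1, 2,
                                     dimnames = list(NULL, c("row", "col"))))
  # Moore neighbourhood in counter-clockwise order for y-down images
  nb <- matrix(c(0L, -1L, -1L, -1L, -1L, 0L, -1L, 1L, 0L, 1L,
                 1L, 1L, 1L, 0L, 1L, -1L), ncol = 2, byrow = TRUE)
  inside <- function(p) pad[p[1] + 1L, p[2] + 1L]
  # initial scan direction: any background neighbour of the start pixel
  dir <- 0L
  for (k in 0:7) {
    p <- start + nb[k + 1L, ]
    if (!(p[1] >= 1L && p[1] <= h && p[2] >= 1L && p[2] <= w && inside(p))) {
      dir <- k
      break
    }
  }
  path <- matrix(0L, 4L * sum(is_boundary) + 8L, 2L)
  path[1, ] <- start
  np <- 1L
  b <- start
  repeat {
    found <- FALSE
    for (k in 0:7) {
      d <- (dir + k) %% 8L
      p <- b + nb[d + 1L, ]
      if (p[1] >= 1L && p[1] <= h && p[2] >= 1L && p[2] <= w && inside(p)) {
        # next scan starts just behind the direction we arrived from
        dir <- (d + 6L) %% 8L
        b <- p
        found <- TRUE
        break
      }
    }
    if (!found) break                       # isolated pixel
    if (all(b == start)) break              # closed the loop
    if (np >= nrow(path)) break             # safety cap
    np <- np + 1L
    path[np, ] <- b
  }
  out <- path[seq_len(np), , drop = FALSE]
  colnames(out) <- c("row", "col")
  out
}

# Exact histogram specification: remap `img` so its sorted values follow the
# reference frame's sorted values (rank matching; photobleach correction).
match_histogram <- function(img, ref) {
  o <- order(img)
  q <- stats::quantile(ref, probs = (rank(img, ties.method = "first") - 0.5) /
                         length(img), names = FALSE, type = 4)
  matrix(q, nrow(img), ncol(img))
}

percentile_stretch <- function(img, lo = 0.01, hi = 0.99) {
  q <- stats::quantile(img, c(lo, hi), names = FALSE)
  if (q[2] <= q[1]) return(img * 0)
  pmin(pmax((img - q[1]) / (q[2] - q[1]), 0), 1)
}
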