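# Curved-object length: centerline construction from the two boundary arcs
# between the maximally separated boundary points, and the morphometrics
# built on it (lamellipodium length, width, area and intensity ratios).

#' Centerline of an elongated binary object
#'
#' Finds the boundary point pair with the largest separation (the
#' endpoints; ties broken lexicographically by boundary index, which makes
#' the circle's degenerate case deterministic), splits the closed boundary
#' into the left and right arcs connecting them, re-parameterises both by
#' normalised arc length on a common grid and averages them pointwise.
#'
#' @param mask logical matrix with one connected object
#' @param pixel_size um per pixel
#' @param n_samples arc-length grid resolution
#' @return matrix of centerline points (x_um, y_um)
#' @export
centerline_curve <- function(mask, pixel_size = 1, n_samples = 200L) {
  b <- trace_boundary(mask)
  if (nrow(b) < 3L) stop_bad("object has fewer than 3 boundary points")
  d2 <- outer(b[, 1], b[, 1], `-`)^2 + outer(b[, 2], b[, 2], `-`)^2
  hit <- which(d2 == max(d2), arr.ind = TRUE)
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
  i <- min(hit[1, ]); j <- max(hit[1, ])
  n <- nrow(b)
  arc1 <- b[i:j, , drop = FALSE]                       # endpoint A -> B
  arc2 <- b[c(j:n, seq_len(i)), , drop = FALSE]        # B -> A the other way
  arc2 <- arc2[rev(seq_len(nrow(arc2))), , drop = FALSE]  # re-orient A -> B
  resample <- function(arc) {
    if (nrow(arc) == 1L)
      return(matrix(rep(arc, each = n_samples), n_samples, 2))
    s <- c(0, cumsum(sqrt(rowSums(diff(arc)^2))))
    s <- s / max(s[length(s)], .Machine$double.eps)
    grid <- seq(0, 1, length.out = n_samples)
    cbind(stats::approx(s, arc[, 1], grid, ties = "ordered")$y,
          stats::approx(s, arc[, 2], grid, ties = "ordered")$y)
  }
  mid <- (resample(arc1) + resample(arc2)) / 2
  cbind(x_um = mid[, 2] * pixel_size, y_um = mid[, 1] * pixel_size)
}

#' Length of a curved object (centerline arc length)
#'
#' @inheritParams centerline_curve
#' @return centerline length in um
#' @export
curve_length <- function(mask, pixel_size = 1, n_samples = 200L) {
  cl <- centerline_curve(mask, pixel_size, n_samples)
  sum(sqrt(rowSums(diff(cl)^2)))
}

# width of `mask` at a centerline point: extent along the local normal,
# probed in quarter-pixel steps
transect_width <- function(mask, pt_px, normal, max_steps = 4000L) {
  h <- nrow(mask); w <- ncol(mask)
  probe <- function(sgn) {
    s <- 0
    repeat {
      nxt <- s + 0.25
      r <- round(pt_px[1] + sgn * nxt * normal[1])
      c0 <- round(pt_px[2] + sgn * nxt * normal[2])
      if (r < 1 || r > h || c0 < 1 || c0 > w || !mask[r, c0]) break
      s <- nxt
      if (s > max_steps) break
    }
    s
  }
  # quarter-pixel probes stop at the physical mask edge on each side, so the
  # two reaches sum to the full transect extent
  probe(1) + probe(-1)
}

#' Lamellipodium morphometrics
#'
#' Length is the centerline length of the lamellipodium mask; width the mean
#' mask extent along the local centerline normal at ten equally spaced
#' centerline points; area the pixel count times `pixel_size^2`;
#' `intensity_per_area` the summed intensity inside the mask per unit area;
#' `length_per_area` normalises the lamellipodium length to the total cell
#' area.
#'
#' @param cell_mask logical matrix of the whole cell
#' @param lamellipodium_mask logical matrix, subset of `cell_mask`
#' @param intensity optional intensity frame for the intensity/area ratio
#' @param pixel_size um per pixel
#' @return list: length_um, width_um, cell_area_um2, lamellipodium_area_um2,
#'   length_per_area, intensity_per_area
#' @export
lamellipodium_morphometrics <- function(cell_mask, lamellipodium_mask,
                                        intensity = NULL, pixel_size = 1) {
  if (!any(lamellipodium_mask)) stop_bad("empty lamellipodium mask")
  if (any(lamellipodium_mask & !cell_mask))
    stop_bad("lamellipodium mask extends outside the cell mask")
  cl <- centerline_curve(lamellipodium_mask, pixel_size = 1)  # pixel units
  len <- curve_length(lamellipodium_mask, pixel_size)
  s <- c(0, cumsum(sqrt(rowSums(diff(cl)^2))))
  targets <- seq(min(s), max(s), length.out = 12L)[2:11]  # 10 interior points
  widths <- vapply(targets, function(tg) {
    i <- which.min(abs(s - tg))
    i0 <- max(1, i - 3); i1 <- min(nrow(cl), i + 3)
    tang <- c(cl[i1, 2] - cl[i0, 2], cl[i1, 1] - cl[i0, 1])  # (row, col)
    tl <- sqrt(sum(tang^2))
    if (tl == 0) return(NA_real_)
    normal <- c(-tang[2], tang[1]) / tl
    transect_width(lamellipodium_mask, c(cl[i, 2], cl[i, 1]), normal)
  }, numeric(1))
  width_um <- mean(widths, na.rm = TRUE) * pixel_size
  cell_area <- sum(cell_mask) * pixel_size^2
  lam_area <- sum(lamellipodium_mask) * pixel_size^2
  list(length_um = len, width_um = width_um, cell_area_um2 = cell_area,
       lamellipodium_area_um2 = lam_area,
       length_per_area = len / cell_area,
       intensity_per_area = if (is.null(intensity)) NA_real_ else
         sum(intensity[lamellipodium_mask]) / lam_area)
}

#' Normalise per-cell values to the mean of a control group
#'
#' @param values numeric vector, one value per cell
#' @param groups group label per cell
#' @param control label of the control group (its mean maps to 1 exactly)
#' @return normalised values
#' @export
normalise_to_control <- function(values, groups, control) {
  if (!control %in% groups) stop_bad("control group '%s' not present", control)
  m <- mean(values[groups == control])
  if (m == 0) stop_bad("control mean is zero; cannot normalise")
  values / m
}
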