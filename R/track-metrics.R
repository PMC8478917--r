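# Track statistics at the usable time interval: interval displacements d_n,
# Mean Track Speed, windowed directionality ratios and Mean Track
# Persistence, the persistence profile, MSD, directionality ratio over time
# and direction autocorrelation.

#' Persistence-analysis parameters
#'
#' `delta_t` is the usable time interval (an integer multiple of the frame
#' interval) at which displacements `d_n` are sampled; persistence is scored
#' over non-overlapping windows of `Delta_t = TR * delta_t` (`TR` = Time
#' Ratio). `alpha_mode = "raw"` reports the plain mean directionality ratio
#' (which already reaches 1 on a straight path); `"affine_rw"` additionally
#' maps the random-walk baseline to 0, with the baseline either supplied in
#' `[0, 1]` via `rw_baseline` or estimated by Monte Carlo (`"monte_carlo"`):
#' the track's own `d_n` are re-emitted with uniform random headings and the
#' same windowing, `mc_reps` times.
#'
#' @param delta_t usable time interval, minutes
#' @param TR time ratio `Delta_t / delta_t`, integer >= 1
#' @param alpha_mode `"raw"` or `"affine_rw"`
#' @param rw_baseline `"monte_carlo"` or a number in `[0, 1]`
#' @param mc_reps Monte-Carlo repetitions for the baseline
#' @param seed RNG seed for the Monte-Carlo baseline
#' @export
persistence_params <- function(delta_t = 15, TR = 4L, alpha_mode = c("raw", "affine_rw"),
                               rw_baseline = "monte_carlo", mc_reps = 200L,
                               seed = 1L) {
  check_scalar(delta_t, "delta_t", lower = 0, allow_equal_lower = FALSE)
  check_scalar(TR, "TR", lower = 1, integer = TRUE)
  alpha_mode <- match.arg(alpha_mode)
  if (!identical(rw_baseline, "monte_carlo"))
    check_scalar(rw_baseline, "rw_baseline", lower = 0, upper = 1)
  structure(list(delta_t = delta_t, TR = as.integer(TR),
                 alpha_mode = alpha_mode, rw_baseline = rw_baseline,
                 mc_reps = as.integer(mc_reps), seed = as.integer(seed)),
            class = "persistence_params")
}

# number of frames per displacement interval; errors unless delta_t is an
# integer multiple of the track's frame interval
interval_frames <- function(track, delta_t) {
  fi <- frame_interval(track)
  k <- delta_t / fi
  if (abs(k - round(k)) > 1e-8)
    stop_bad("delta_t = %g min is not an integer multiple of the frame interval %g min",
             delta_t, fi)
  as.integer(round(k))
}

#' Non-overlapping interval displacements d_n
#'
#' Samples the track every `delta_t` (a displacement measurement every k
#' frames, anchored at the first frame; trailing remainder frames are
#' discarded) and returns the consecutive displacement magnitudes.
#'
#' @param track a [track()]
#' @param delta_t sampling interval, minutes (integer multiple of the frame
#'   interval)
#' @return numeric vector of displacements in um; empty with attribute
#'   `too_short = TRUE` when no complete interval fits
#' @export
interval_displacements <- function(track, delta_t) {
  k <- interval_frames(track, delta_t)
  idx <- seq(1L, n_frames(track), by = k)
  if (length(idx) < 2L)
    return(structure(numeric(0), too_short = TRUE))
  sqrt(diff(track$x[idx])^2 + diff(track$y[idx])^2)
}

# positions subsampled every k frames (the interval endpoints)
interval_positions <- function(track, delta_t) {
  k <- interval_frames(track, delta_t)
  idx <- seq(1L, n_frames(track), by = k)
  cbind(x = track$x[idx], y = track$y[idx])
}

#' Mean Track Speed
#'
#' MTS is the average of the interval displacements divided by the sampling
#' interval: `mean(d_n) / delta_t`, the average cell speed over the whole
#' track at the usable time interval.
#'
#' @inheritParams interval_displacements
#' @return speed in um/min
#' @export
mean_track_speed <- function(track, delta_t) {
  d <- interval_displacements(track, delta_t)
  if (!length(d))
    stop_bad("track '%s' has no complete interval of %g min", track$cell_id,
             delta_t)
  mean(d) / delta_t
}

#' Directionality ratio of one window
#'
#' Net displacement `D_N` over a window divided by the path length over that
#' window (the sum of its `d_n`). A window in which the cell never moved
#' (`sum(d_n) = 0`) scores 1 by convention: no path, no directional error.
#'
#' @param window a [track()] spanning exactly a whole number of `delta_t`
#'   intervals
#' @param delta_t sampling interval, minutes
#' @return dimensionless ratio in `[0, 1]`
#' @export
directionality_ratio <- function(window, delta_t) {
  k <- interval_frames(window, delta_t)
  if ((n_frames(window) - 1L) %% k != 0L)
    stop_bad("window of %d frames is not a whole number of %d-frame intervals",
             n_frames(window), k)
  d <- interval_displacements(window, delta_t)
  if (!length(d)) stop_bad("window holds no complete interval")
  p <- interval_positions(window, delta_t)
  D_N <- unname(sqrt((p[nrow(p), 1] - p[1, 1])^2 +
                       (p[nrow(p), 2] - p[1, 2])^2))
  s <- sum(d)
  if (s == 0) 1 else D_N / s
}

# directionality ratios of all complete non-overlapping TR-interval windows
window_ratios <- function(track, delta_t, TR) {
  k <- interval_frames(track, delta_t)
  wlen <- TR * k                       # frames advanced per window
  n_win <- (n_frames(track) - 1L) %/% wlen
  if (n_win < 1L) return(numeric(0))
  vapply(seq_len(n_win), function(i) {
    sel <- ((i - 1L) * wlen + 1L):(i * wlen + 1L)
    directionality_ratio(track(track$cell_id, track$times[sel],
                               track$x[sel], track$y[sel]), delta_t)
  }, numeric(1))
}

# Monte-Carlo random-walk baseline: re-emit the track's own d_n with uniform
# random headings (order shuffled) and score the same windowing
mc_rw_baseline <- function(d_n, delta_t, TR, mc_reps, seed) {
  set.seed(seed)
  fi <- delta_t                         # surrogate sampled at delta_t itself
  mean(vapply(seq_len(mc_reps), function(r) {
    d <- sample(d_n)
    th <- stats::runif(length(d), -pi, pi)
    x <- c(0, cumsum(d * cos(th)))
    y <- c(0, cumsum(d * sin(th)))
    tr <- track("rw", (seq_along(x) - 1) * fi, x, y)
    mean(window_ratios(tr, fi, TR))
  }, numeric(1)))
}

#' Mean Track Persistence
#'
#' The average directionality ratio over consecutive non-overlapping windows
#' of `Delta_t = TR * delta_t`, optionally normalised so that a straight
#' path scores 1 and a purely random walk 0 (`alpha_mode = "affine_rw"`).
#'
#' @param track a [track()]
#' @param params a [persistence_params()]
#' @return dimensionless persistence score (attribute `n_windows` reports
#'   how many windows entered the mean, `baseline` the random-walk baseline
#'   used when normalising)
#' @export
#' @examples
#' tr <- track("straight", seq(0, 295, by = 5), x = seq(0, 295, by = 5), y = 0)
#' mean_track_persistence(tr, persistence_params(delta_t = 15, TR = 4))  # 1
mean_track_persistence <- function(track, params = persistence_params()) {
  stopifnot(inherits(params, "persistence_params"))
  ratios <- window_ratios(track, params$delta_t, params$TR)
  if (!length(ratios))
    stop_bad("track '%s' holds no complete window of %g min", track$cell_id,
             params$delta_t * params$TR)
  raw <- mean(ratios)
  if (params$alpha_mode == "raw")
    return(structure(raw, n_windows = length(ratios)))
  b <- if (identical(params$rw_baseline, "monte_carlo")) {
    mc_rw_baseline(interval_displacements(track, params$delta_t),
                   params$delta_t, params$TR, params$mc_reps, params$seed)
  } else params$rw_baseline
  structure((raw - b) / (1 - b), n_windows = length(ratios), baseline = b)
}

#' Full per-track statistics record
#'
#' Bundles the interval displacements, per-window net displacements, MTS and
#' MTP of one track.
#'
#' @inheritParams mean_track_persistence
#' @return list of class `track_stats`
#' @export
track_stats <- function(track, params = persistence_params()) {
  d_n <- interval_displacements(track, params$delta_t)
  p <- interval_positions(track, params$delta_t)
  n_win <- length(d_n) %/% params$TR
  D_N <- if (n_win >= 1) vapply(seq_len(n_win), function(i) {
    a <- (i - 1L) * params$TR + 1L
    b <- i * params$TR + 1L
    sqrt((p[b, 1] - p[a, 1])^2 + (p[b, 2] - p[a, 2])^2)
  }, numeric(1)) else numeric(0)
  structure(list(cell_id = track$cell_id, d_n = d_n, D_N = D_N,
                 MTS = mean(d_n) / params$delta_t,
                 MTP = as.numeric(mean_track_persistence(track, params)),
                 n_intervals = length(d_n), n_windows = n_win,
                 params = params),
            class = "track_stats")
}

#' Usable time interval from replicate observations
#'
#' Estimates the positional error of a displacement measurement from
#' repeated blinded observations of the same cell and returns the smallest
#' integer multiple `k` of the frame interval at which that error falls
#' below `threshold` (10%) of the mean displacement at `delta_t = k *
#' frame_interval`. The error scale is `sqrt(2)` times the per-coordinate
#' RMS replicate deviation: a displacement is a difference of two noisy
#' points, per axis, combined over axes.
#'
#' @param replicates list of >= 2 [track()]s sharing timestamps
#' @param threshold error / displacement ratio to fall below (default 0.10)
#' @param candidate_multiples integer multiples of the frame interval tried,
#'   smallest first (default 1-10, covering the common 3- and 5-frame picks)
#' @return list of class `usable_interval` with `k`, `delta_t` (minutes) and
#'   the diagnostic `table` (k, delta_t, mean displacement, error, ratio)
#' @export
usable_time_interval <- function(replicates, threshold = 0.10,
                                 candidate_multiples = 1:10) {
  if (length(replicates) < 2L)
    stop_bad("need at least 2 replicate tracks, got %d", length(replicates))
  t0 <- replicates[[1]]$times
  for (r in replicates)
    if (!isTRUE(all.equal(r$times, t0)))
      stop_bad("replicates must share timestamps")
  fi <- frame_interval(replicates[[1]])
  X <- sapply(replicates, `[[`, "x")
  Y <- sapply(replicates, `[[`, "y")
  sigma2 <- mean(c(apply(X, 1, stats::var), apply(Y, 1, stats::var)))
  err <- sqrt(2 * sigma2)
  tab <- do.call(rbind, lapply(sort(candidate_multiples), function(k) {
    dt <- k * fi
    d <- unlist(lapply(replicates, function(r) {
      di <- interval_displacements(r, dt)
      if (length(di)) di else NA_real_
    }))
    md <- mean(d, na.rm = TRUE)
    data.frame(k = k, delta_t = dt, mean_displacement = md, error = err,
               ratio = err / md)
  }))
  ok <- which(is.finite(tab$ratio) & tab$ratio < threshold)
  if (!length(ok))
    stop_bad("no candidate multiple meets error/displacement < %g; ratios: %s",
             threshold, paste(sprintf("k=%d:%.3f", tab$k, tab$ratio),
                              collapse = ", "))
  structure(list(k = tab$k[ok[1]], delta_t = tab$delta_t[ok[1]], table = tab,
                 threshold = threshold), class = "usable_interval")
}

#' @export
print.usable_interval <- function(x, ...) {
  cat(sprintf("usable time interval: k = %d (delta_t = %g min, threshold %g)\n",
              x$k, x$delta_t, x$threshold))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Mean persistence profile over a grid of usable time intervals
#'
#' Population-mean MTP for every candidate `delta_t = k * frame_interval`,
#' at fixed TR. Tracks lacking a complete window at some `delta_t` are
#' excluded there and counted.
#'
#' @param tracks list of [track()]s with a common frame interval
#' @param TR time ratio
#' @param multiples integer grid of frame-interval multiples
#' @param alpha_mode,rw_baseline,mc_reps,seed passed to
#'   [persistence_params()]
#' @return data.frame (k, delta_t, mean_mtp, n_tracks, n_excluded)
#' @export
persistence_profile <- function(tracks, TR = 4L, multiples = 1:10,
                                alpha_mode = "raw",
                                rw_baseline = "monte_carlo", mc_reps = 50L,
                                seed = 1L) {
  if (!length(multiples)) stop_bad("empty delta_t grid")
  fi <- frame_interval(tracks[[1]])
  do.call(rbind, lapply(sort(multiples), function(k) {
    pp <- persistence_params(delta_t = k * fi, TR = TR,
                             alpha_mode = alpha_mode,
                             rw_baseline = rw_baseline, mc_reps = mc_reps,
                             seed = seed)
    vals <- vapply(tracks, function(tr) {
      tryCatch(as.numeric(mean_track_persistence(tr, pp)),
               error = function(e) NA_real_)
    }, numeric(1))
    data.frame(k = k, delta_t = k * fi, mean_mtp = mean(vals, na.rm = TRUE),
               n_tracks = sum(is.finite(vals)), n_excluded = sum(!is.finite(vals)))
  }))
}

#' Mean square displacement
#'
#' `MSD(l)` averages `|p(t + l) - p(t)|^2` over all ordered pairs
#' (overlapping), per track and over the population, with the log-log slope
#' fitted over a stated lag range.
#'
#' @param tracks list of [track()]s
#' @param max_lag largest lag in frames (must be below the shortest track)
#' @param slope_lags lag range (frames) for the log-log slope fit
#' @return list of class `msd_result`: `lag_frames`, `lag_minutes`, `msd`
#'   (population mean), `per_track` matrix, `slope`
#' @export
mean_square_displacement <- function(tracks, max_lag = 10L,
                                     slope_lags = 1:10) {
  shortest <- min(vapply(tracks, n_frames, integer(1)))
  if (max_lag >= shortest)
    stop_bad("max_lag = %d not below shortest track length %d", max_lag,
             shortest)
  per <- sapply(tracks, function(tr) {
    vapply(seq_len(max_lag), function(l) {
      dx <- tr$x[-seq_len(l)] - tr$x[seq_len(length(tr$x) - l)]
      dy <- tr$y[-seq_len(l)] - tr$y[seq_len(length(tr$y) - l)]
      mean(dx^2 + dy^2)
    }, numeric(1))
  })
  per <- matrix(per, nrow = max_lag)
  msd <- rowMeans(per)
  sl <- intersect(slope_lags, seq_len(max_lag))
  sl <- sl[msd[sl] > 0]
  slope <- if (length(sl) >= 2)
    unname(stats::coef(stats::lm(log(msd[sl]) ~ log(sl)))[2]) else NA_real_
  structure(list(lag_frames = seq_len(max_lag),
                 lag_minutes = seq_len(max_lag) * frame_interval(tracks[[1]]),
                 msd = msd, per_track = per, slope = slope),
            class = "msd_result")
}

#' Directionality ratio over time
#'
#' For each track and elapsed time: net displacement from the origin divided
#' by the cumulative path length so far; averaged over the population per
#' time point.
#'
#' @param tracks list of [track()]s with a common frame interval
#' @return data.frame (time, mean_ratio, n)
#' @export
directionality_ratio_over_time <- function(tracks) {
  n_max <- max(vapply(tracks, n_frames, integer(1)))
  ratios <- sapply(tracks, function(tr) {
    path <- cumsum(sqrt(diff(tr$x)^2 + diff(tr$y)^2))
    net <- sqrt((tr$x[-1] - tr$x[1])^2 + (tr$y[-1] - tr$y[1])^2)
    r <- ifelse(path == 0, 1, net / path)
    c(r, rep(NA_real_, n_max - 1L - length(r)))
  })
  ratios <- matrix(ratios, nrow = n_max - 1L)
  data.frame(time = seq_len(n_max - 1L) * frame_interval(tracks[[1]]),
             mean_ratio = rowMeans(ratios, na.rm = TRUE),
             n = rowSums(is.finite(ratios)))
}

#' Direction autocorrelation
#'
#' Mean cosine of the angle between displacement unit vectors `l` intervals
#' apart, with displacements sampled at `delta_t` exactly as in
#' [interval_displacements()]. Speed-independent by construction;
#' zero-length displacements are skipped and counted.
#'
#' @param tracks list of [track()]s
#' @param delta_t sampling interval, minutes
#' @param max_lag largest lag in units of `delta_t` (default: longest
#'   available)
#' @return data.frame (lag, autocorrelation, n_pairs) with attribute
#'   `n_skipped`
#' @export
direction_autocorrelation <- function(tracks, delta_t, max_lag = NULL) {
  vecs <- lapply(tracks, function(tr) {
    p <- interval_positions(tr, delta_t)
    if (nrow(p) < 2L) return(NULL)
    cbind(diff(p[, 1]), diff(p[, 2]))
  })
  vecs <- Filter(Negate(is.null), vecs)
  if (!length(vecs)) stop_bad("no displacements available at delta_t = %g",
                              delta_t)
  skipped <- 0L
  units <- lapply(vecs, function(v) {
    len <- sqrt(rowSums(v^2))
    keep <- len > 0
    skipped <<- skipped + sum(!keep)
    u <- v / len
    u[!keep, ] <- NA_real_
    u
  })
  if (all(vapply(units, function(u) all(!is.finite(u)), logical(1))))
    stop_bad("all displacements have zero length")
  if (is.null(max_lag))
    max_lag <- max(vapply(units, nrow, integer(1))) - 1L
  out <- do.call(rbind, lapply(seq_len(max_lag), function(l) {
    dots <- unlist(lapply(units, function(u) {
      n <- nrow(u)
      if (n <= l) return(numeric(0))
      rowSums(u[seq_len(n - l), , drop = FALSE] *
                u[(l + 1):n, , drop = FALSE])
    }))
    dots <- dots[is.finite(dots)]
    data.frame(lag = l, autocorrelation = mean(dots), n_pairs = length(dots))
  }))
  structure(out, n_skipped = skipped)
}
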