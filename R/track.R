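#' Construct a cell track
#'
#' A `track` stores one cell's time-ordered positions in physical units:
#' times in minutes on a uniform grid, positions in micrometres. All track
#' statistics ([mean_track_speed()], [mean_track_persistence()], ...) consume
#' this container; pixel/frame conversion happens only in [read_tracks()].
#'
#' @param cell_id identifier (coerced to character)
#' @param times numeric vector of times in minutes, strictly increasing with
#'   uniform spacing
#' @param x,y coordinates in micrometres
#' @return an object of class `track`
#' @export
#' @examples
#' tr <- track("c1", times = seq(0, 45, by = 5), x = 0:9, y = rep(0, 10))
#' frame_interval(tr)
track <- function(cell_id, times, x, y) {
  if (length(times) < 2L) stop_bad("a track needs at least 2 points")
  if (length(x) != length(times) || length(y) != length(times))
    stop_bad("times, x and y must have equal length")
  if (!all(is.finite(times)) || !all(is.finite(x)) || !all(is.finite(y)))
    stop_bad("track coordinates and times must be finite")
  dt <- diff(times)
  if (any(dt <= 0)) stop_bad("times must be strictly increasing")
  if (max(abs(dt - dt[1])) > 1e-9 * max(abs(dt[1]), 1))
    stop_bad("track '%s' does not have uniform frame spacing", cell_id)
  structure(list(cell_id = as.character(cell_id), times = as.numeric(times),
                 x = as.numeric(x), y = as.numeric(y)),
            class = "track")
}

#' @export
print.track <- function(x, ...) {
  cat(sprintf("<track '%s': %d frames, interval %.4g min, %.4g min total>\n",
              x$cell_id, length(x$times), frame_interval(x),
              diff(range(x$times))))
  invisible(x)
}

#' @export
as.data.frame.track <- function(x, ...) {
  data.frame(cell_id = x$cell_id, time = x$times, x = x$x, y = x$y)
}

#' Frame interval of a track, in minutes
#' @param track a [track()]
#' @export
frame_interval <- function(track) track$times[2] - track$times[1]

n_frames <- function(track) length(track$times)

#' Ground truth attached to a synthetic object
#'
#' Synthetic generators attach the full generating parameter record and the
#' derived true values to their outputs; recovery tests read them back here.
#' @param x an object produced by a `synth_*`/`simulate_*` generator
#' @return a list (generator name, parameters, true values) or NULL
#' @export
ground_truth <- function(x) attr(x, "ground_truth", exact = TRUE)

set_ground_truth <- function(x, generator, params, ...) {
  attr(x, "ground_truth") <- list(generator = generator, params = params, ...)
  x
}

#' Write ground truth as a JSON sidecar
#' @param x object carrying ground truth
#' @param path output file path
#' @export
write_ground_truth <- function(x, path) {
  gt <- ground_truth(x)
  if (is.null(gt)) stop_bad("object carries no ground truth")
  strip <- function(x) {
    if (inherits(x, "track")) return(as.data.frame(x))
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  gt_ser <- strip(gt)
  jsonlite::write_json(gt_ser, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
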