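# Tracking-table I/O. The native dialect is a plain CSV with a header and
# columns exactly (track_id, frame, x_px, y_px), frames 0-based; a shim
# accepts the Fiji Manual Tracking export (leading index column, 1-based
# "Slice n°") and normalises it. All downstream code works in um / minutes;
# the pixel/frame conversion happens only here.

#' Read cell tracks from a tracking CSV
#'
#' @param path CSV with header `track_id,frame,x_px,y_px` (frame 0-based), or
#'   a Fiji Manual Tracking export (auto-detected and normalised)
#' @param frame_interval minutes between frames
#' @param pixel_size um per pixel
#' @return list of [track()]s, grouped by id and sorted by frame
#' @export
read_tracks <- function(path, frame_interval, pixel_size) {
  check_scalar(frame_interval, "frame_interval", lower = 0,
               allow_equal_lower = FALSE)
  check_scalar(pixel_size, "pixel_size", lower = 0, allow_equal_lower = FALSE)
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  df <- normalise_tracking_table(df, path)
  for (col in c("frame", "x_px", "y_px")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad))
      stop_bad("non-numeric '%s' in '%s' at data row %d", col, path, bad[1])
    df[[col]] <- as.numeric(df[[col]])
  }
  if (anyDuplicated(df[c("track_id", "frame")]))
    stop_bad("duplicate (track_id, frame) rows in '%s'", path)
  out <- lapply(split(df, df$track_id), function(g) {
    g <- g[order(g$frame), ]
    fr <- g$frame
    if (length(fr) >= 2 && !all(diff(fr) == 1))
      stop_bad("track '%s' has missing frames (gap after frame %d)",
               g$track_id[1], fr[which(diff(fr) != 1)[1]])
    track(g$track_id[1], times = fr * frame_interval,
          x = g$x_px * pixel_size, y = g$y_px * pixel_size)
  })
  unname(out[order(names(out))])
}

# Accepts either the native dialect or the Fiji Manual Tracking export
# (columns like "Track n°", "Slice n°", "X", "Y", with 1-based slices).
normalise_tracking_table <- function(df, path) {
  nm <- tolower(gsub("[^a-z0-9]", "", tolower(names(df))))
  if (all(c("track_id", "frame", "x_px", "y_px") %in% names(df)))
    return(df[c("track_id", "frame", "x_px", "y_px")])
  pick <- function(keys) {
    hit <- which(nm %in% keys)
    if (!length(hit)) stop_bad("'%s': cannot find column %s", path, keys[1])
    hit[1]
  }
  ti <- pick(c("trackn", "track", "trackid"))
  si <- pick(c("slicen", "slice", "frame"))
  xi <- pick(c("x", "xpx"))
  yi <- pick(c("y", "ypx"))
  data.frame(track_id = as.character(df[[ti]]),
             frame = as.numeric(df[[si]]) - 1,   # Fiji slices are 1-based
             x_px = df[[xi]], y_px = df[[yi]],
             stringsAsFactors = FALSE)
}

#' Write tracks in the native tracking-CSV dialect
#'
#' Inverse of [read_tracks()] up to floating-point formatting.
#' @param tracks list of [track()]s
#' @param path output CSV
#' @param pixel_size um per pixel used to convert back to pixel coordinates
#' @export
write_tracks <- function(tracks, path, pixel_size) {
  check_scalar(pixel_size, "pixel_size", lower = 0, allow_equal_lower = FALSE)
  rows <- do.call(rbind, lapply(tracks, function(tr) {
    data.frame(track_id = tr$cell_id,
               frame = round(tr$times / frame_interval(tr)),
               x_px = tr$x / pixel_size, y_px = tr$y / pixel_size)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
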