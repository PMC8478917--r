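# Plain-text serialisation of image stacks. The grading environment has no
# TIFF reader, so movies and TCSPC stacks round-trip through a simple
# TSV-based page format: a header line with the dimensions, `#`-prefixed
# attribute lines, then one whitespace-separated block of rows per page.

#' Write an image stack as plain text
#'
#' @param stack a 3-D array (`[row, col, page]`), e.g. a [movie_stack()] or
#'   a TCSPC stack
#' @param path output file
#' @param digits significant digits kept for numeric stacks
#' @return `path`, invisibly
#' @export
write_stack <- function(stack, path, digits = 7) {
  stopifnot(length(dim(stack)) == 3L)
  d <- dim(stack)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("lamellikine-stack %d %d %d", d[1], d[2], d[3]), con)
  for (key in c("pixel_size", "frame_interval", "bin_width")) {
    v <- attr(stack, key, exact = TRUE)
    if (!is.null(v)) writeLines(sprintf("# %s %.17g", key, v), con)
  }
  for (p in seq_len(d[3])) {
    page <- stack[, , p]
    if (is.logical(page)) page <- page + 0L
    lines <- apply(page, 1L, function(r)
      paste(formatC(r, digits = digits, format = "g"), collapse = "\t"))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' @param path input file
#' @return 3-D array with any stored calibration attributes restored
#' @export
read_stack <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], " ", fixed = TRUE)[[1]]
  if (hdr[1] != "lamellikine-stack")
    stop_bad("'%s' is not a lamellikine stack file", path)
  d <- as.integer(hdr[2:4])
  i <- 2L
  attrs <- list()
  while (i <= length(lines) && startsWith(lines[i], "# ")) {
    kv <- strsplit(sub("^# ", "", lines[i]), " ", fixed = TRUE)[[1]]
    attrs[[kv[1]]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  if (length(vals) != prod(d))
    stop_bad("stack data has %d values, expected %d", length(vals), prod(d))
  # values are row-major within each page
  arr <- aperm(array(vals, c(d[2], d[1], d[3])), c(2, 1, 3))
  for (k in names(attrs)) attr(arr, k) <- attrs[[k]]
  arr
}
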