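# Optional TIFF-stack I/O for movies (arrays t x y x x). Requires the
# `tiff` package, which stores samples in [0, 1]: intensities are scaled
# by an explicit factor on write and restored on read.

#' Write / read a movie as a multi-page TIFF
#'
#' @param movie numeric array `(t, y, x)`, non-negative intensities.
#' @param path TIFF file path.
#' @param scale intensity corresponding to full scale; defaults to the
#'   movie maximum on write, and must be passed again to [read_movie_tiff()]
#'   to restore original units (1 leaves the stored [0, 1] values).
#' @return `path` (write, invisibly, with the scale as attribute
#'   `"scale"`) or the movie array (read).
#' @export
write_movie_tiff <- function(movie, path, scale = max(movie)) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF movie output", call. = FALSE)
  }
  stopifnot(length(dim(movie)) == 3, scale > 0)
  frames <- lapply(seq_len(dim(movie)[1]), function(t) movie[t, , ] / scale)
  tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  invisible(structure(path, scale = scale))
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path, scale = 1) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF movie input", call. = FALSE)
  }
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  out <- array(0, c(length(frames), nrow(frames[[1]]), ncol(frames[[1]])))
  for (t in seq_along(frames)) out[t, , ] <- frames[[t]] * scale
  out
}
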