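#' Time-lapse image stack
#'
#' The raw substrate of every analysis in the package: `T` grayscale frames
#' with a physical pixel size and a frame interval.  Frames are stored as an
#' `H x W x T` numeric array; frame `[i, j, t]` is row `i` (image y, growing
#' downward), column `j` (image x, growing rightward).
#'
#' @param frames `H x W x T` numeric array, a single `H x W` matrix, or a
#'   list of equally-sized matrices.
#' @param pixel_size physical pixel size (micrometres per pixel).
#' @param frame_interval time between consecutive frames (seconds).
#' @param roi optional record of the crop that produced this stack, a list
#'   with elements `x`, `y`, `w`, `h` (1-based pixel coordinates).
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(frames, pixel_size, frame_interval, roi = NULL) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1) stop("all frames must have the same shape")
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[[1]], length(frames)))
  }
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  if (!is.numeric(pixel_size) || pixel_size <= 0) stop("pixel_size must be > 0")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be > 0")
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval, roi = roi),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("image_stack: %d frames of %d x %d px (%.3g x %.3g um), dt = %g s\n",
              d[3], d[1], d[2], d[1] * x$pixel_size, d[2] * x$pixel_size,
              x$frame_interval))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$frames)

n_frames <- function(stack) dim(stack$frames)[3]

#' Read an image stack from TIFF
#'
#' Accepts a multi-page TIFF or a character vector of single-frame image
#' paths (read in the given order).
#'
#' @param path path to a multi-page TIFF, or vector of frame paths.
#' @inheritParams image_stack
#' @return an [image_stack()].
#' @export
read_image_stack <- function(path, pixel_size, frame_interval) {
  frames <- if (length(path) == 1) {
    f <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (is.matrix(f)) list(f) else f
  } else {
    lapply(path, function(p) tiff::readTIFF(p, as.is = FALSE))
  }
  frames <- lapply(frames, function(f) {
    if (length(dim(f)) == 3) f <- f[, , 1] # drop extra channels
    f
  })
  image_stack(frames, pixel_size, frame_interval)
}

#' Write an image stack as a 16-bit multi-page TIFF
#'
#' Intensities are affinely rescaled to span `[0, 1]` over the whole stack
#' before quantization (constant stacks map to 0).
#'
#' @param stack an [image_stack()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  fr <- stack$frames
  lo <- min(fr); hi <- max(fr)
  scale <- if (hi > lo) 1 / (hi - lo) else 0
  pages <- lapply(seq_len(dim(fr)[3]), function(t) (fr[, , t] - lo) * scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}
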