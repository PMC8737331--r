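#' @include AllClasses.R
NULL

#' Construct an ROI pixel mask
#'
#' @param pixels Integer n x 2 matrix of (row, col) pixel coordinates.
#' @param dims Frame dimensions `c(nrow, ncol)`.
#' @return A [RoiMask-class].
#' @export
roiMask <- function(pixels, dims) {
  methods::new("RoiMask", pixels = matrix(as.integer(pixels), ncol = 2L),
               dims = as.integer(dims))
}

#' Rectangular ROI mask helper
#' @param rows,cols Integer ranges of pixel rows/columns.
#' @param dims Frame dimensions.
#' @return A [RoiMask-class].
#' @export
rectMask <- function(rows, cols, dims) {
  roiMask(as.matrix(expand.grid(rows, cols)), dims)
}

#' Render a synthetic imaging movie from ROI fluorescence
#'
#' Each frame is the sum of the ROI footprints scaled by that ROI's raw
#' fluorescence for the frame, plus optional i.i.d. Gaussian pixel noise.
#' Overlapping masks are allowed (their contributions add) but produce a
#' warning since extracted traces then become mixtures.
#'
#' @param recording A [FluorescenceRecording-class], one mask per ROI.
#' @param masks List of [RoiMask-class], in ROI order.
#' @param frameDims Frame dimensions `c(nrow, ncol)`.
#' @param pixelNoiseSd Gaussian pixel noise s.d. (fluorescence units).
#' @param seed Integer seed for pixel noise.
#' @return 3-d array `[row, col, frame]`.
#' @export
renderMovie <- function(recording, masks, frameDims, pixelNoiseSd = 0,
                        seed = 1) {
  raw <- rawTrace(recording)
  if (length(masks) != nrow(raw))
    .configError("one mask per ROI required")
  lin <- lapply(masks, function(m) {
    methods::validObject(m)
    if (any(m@dims != frameDims))
      .configError("mask dimensions do not match frameDims")
    (m@pixels[, 2L] - 1L) * frameDims[1L] + m@pixels[, 1L]
  })
  allPix <- unlist(lin)
  if (anyDuplicated(allPix))
    warning("overlapping ROI masks: extracted traces will be mixtures")
  nFrames <- ncol(raw)
  movie <- array(0, c(frameDims[1L], frameDims[2L], nFrames))
  frameSize <- prod(frameDims)
  for (f in seq_len(nFrames)) {
    off <- (f - 1L) * frameSize
    for (i in seq_along(lin))
      movie[off + lin[[i]]] <- movie[off + lin[[i]]] + raw[i, f]
  }
  if (pixelNoiseSd > 0) {
    set.seed(as.integer(seed))
    movie <- movie + array(stats::rnorm(length(movie), 0, pixelNoiseSd),
                           dim(movie))
  }
  movie
}

#' Extract mean-pixel ROI fluorescence traces from a movie
#'
#' The fluorescence trace of an ROI is the arithmetic mean pixel value over
#' its mask in each frame.
#'
#' @param movie 3-d array `[row, col, frame]` (or list of frame matrices).
#' @param masks List of [RoiMask-class].
#' @param frameRate Effective frame rate (Hz).
#' @return A [FluorescenceRecording-class].
#' @export
extractRoiTraces <- function(movie, masks, frameRate = 15) {
  if (is.list(movie)) {
    d1 <- dim(movie[[1L]])
    movie <- array(unlist(movie), c(d1, length(movie)))
  }
  d <- dim(movie)
  if (length(d) != 3L) .dataError("movie must be a [row, col, frame] array")
  frameSize <- d[1L] * d[2L]
  traces <- matrix(NA_real_, length(masks), d[3L])
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    methods::validObject(m)
    if (any(m@dims != d[1:2]))
      .dataError("mask dimensions do not match the movie frames")
    lin <- (m@pixels[, 2L] - 1L) * d[1L] + m@pixels[, 1L]
    idx <- outer(lin, (seq_len(d[3L]) - 1L) * frameSize, `+`)
    traces[i, ] <- colMeans(matrix(movie[idx], nrow = length(lin)))
  }
  rownames(traces) <- sprintf("roi%04d", seq_along(masks))
  methods::new("FluorescenceRecording", raw = pmax(traces, 0),
               frameRate = as.numeric(frameRate),
               roiIds = rownames(traces))
}

#' Write / read a movie as a multi-page TIFF stack
#'
#' Frames are stored as 32-bit float TIFF pages in fluorescence units
#' scaled by `scale` (values must map into [0, 1] for the TIFF writer).
#'
#' @param movie 3-d array `[row, col, frame]`.
#' @param path TIFF file path.
#' @param scale Divisor applied before writing (reapplied on read).
#' @return `readTiffStack` returns the array; `writeTiffStack` the path.
#' @export
writeTiffStack <- function(movie, path, scale = max(movie, 1)) {
  frames <- lapply(seq_len(dim(movie)[3L]),
                   function(f) movie[, , f] / scale)
  tiff::writeTIFF(frames, path, bits.per.sample = 32L, reduce = FALSE)
  attr(path, "scale") <- scale
  invisible(path)
}

#' @rdname writeTiffStack
#' @export
readTiffStack <- function(path, scale = 1) {
  frames <- tiff::readTIFF(path, all = TRUE)
  array(unlist(frames), c(dim(frames[[1L]]), length(frames))) * scale
}
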