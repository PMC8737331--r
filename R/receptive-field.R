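#' @include AllClasses.R
NULL

#' Visual-space grid specification
#'
#' Positions in the virtual corridor are abstract coordinates (corridor
#' coordinate x elevation), not degrees of visual angle; the default grid
#' bins the unit square into 20 x 8 cells.
#'
#' @param nx,ny Grid cells along the corridor / elevation axes.
#' @param xlim,ylim Extents covered by the grid.
#' @return List with `nx`, `ny`, `xlim`, `ylim`.
#' @export
rfGrid <- function(nx = 20, ny = 8, xlim = c(0, 1), ylim = c(0, 1)) {
  if (nx < 1 || ny < 1) .configError("grid must have at least one cell")
  list(nx = as.integer(nx), ny = as.integer(ny),
       xlim = as.numeric(xlim), ylim = as.numeric(ylim))
}

#' Map responses as a function of location in visual space
#'
#' Bins per-event windowed responses by stimulus position on a visual-space
#' grid: each cell holds the mean response over events falling in it, with
#' an s.e.m. companion map and event counts. Cells without events are
#' missing (`NA`), not zero. Optionally the mean map is normalized to its
#' peak, with the normalization constant retained.
#'
#' @param resp Per-event windowed responses (numeric vector).
#' @param positions n x 2 matrix / data.frame of event positions (x, y).
#' @param grid A [rfGrid()] specification covering all positions.
#' @param normalize Peak-normalize the mean map.
#' @return A [ReceptiveFieldMap-class].
#' @export
mapVisualSpace <- function(resp, positions, grid = rfGrid(),
                           normalize = FALSE) {
  positions <- as.matrix(positions)
  if (nrow(positions) != length(resp))
    .dataError("one position per event required")
  cellOf <- function(v, lim, n) {
    i <- floor((v - lim[1L]) / diff(lim) * n) + 1L
    # events exactly on the right edge belong to the last cell
    i[abs(v - lim[2L]) < 1e-12] <- n
    i
  }
  ix <- cellOf(positions[, 1L], grid$xlim, grid$nx)
  iy <- cellOf(positions[, 2L], grid$ylim, grid$ny)
  if (any(ix < 1L | ix > grid$nx | iy < 1L | iy > grid$ny))
    .dataError("positions outside the grid extent")
  mMean <- matrix(NA_real_, grid$ny, grid$nx)
  mSem <- matrix(NA_real_, grid$ny, grid$nx)
  mN <- matrix(0, grid$ny, grid$nx)
  for (g in split(seq_along(resp), list(iy, ix), drop = TRUE)) {
    r <- resp[g]
    mMean[iy[g[1L]], ix[g[1L]]] <- mean(r)
    mSem[iy[g[1L]], ix[g[1L]]] <- sem(r)
    mN[iy[g[1L]], ix[g[1L]]] <- length(r)
  }
  map <- methods::new("ReceptiveFieldMap", mean = mMean, sem = mSem, n = mN,
    xCenters = .gridCenters(grid$xlim, grid$nx),
    yCenters = .gridCenters(grid$ylim, grid$ny),
    normConstant = NA_real_)
  if (normalize) map <- normalizeRf(map) else map
}

#' Peak-normalize a receptive-field map
#'
#' Divides the mean map by its maximum so the normalized peak is 1.
#' Idempotent: normalizing an already normalized map leaves it unchanged
#' (its recorded constant then refers to the original scale).
#'
#' @param map A [ReceptiveFieldMap-class].
#' @return The normalized map, with `@normConstant` set.
#' @export
normalizeRf <- function(map) {
  peak <- max(map@mean, na.rm = TRUE)
  if (peak == 0) .dataError("cannot peak-normalize an all-zero map")
  map@sem <- map@sem / peak
  map@mean <- map@mean / peak
  map@normConstant <- if (is.na(map@normConstant)) peak
                      else map@normConstant   # already in normalized units
  map
}

#' Locate the peak of a receptive-field map
#'
#' Argmax over non-missing cells; ties are broken by the lowest grid
#' coordinate (column-major order) with a warning.
#'
#' @param map A [ReceptiveFieldMap-class] with at least one non-missing
#'   cell.
#' @return List: `x`, `y` (cell-centre coordinates), `ix`, `iy` (cell
#'   indices), `value`.
#' @export
peakLocation <- function(map) {
  m <- map@mean
  if (all(is.na(m))) .dataError("all map cells are missing")
  peak <- max(m, na.rm = TRUE)
  hits <- which(m == peak)
  if (length(hits) > 1L)
    warning("tied map maximum; lowest grid coordinate returned")
  iy <- ((hits[1L] - 1L) %% nrow(m)) + 1L
  ix <- ((hits[1L] - 1L) %/% nrow(m)) + 1L
  list(x = map@xCenters[ix], y = map@yCenters[iy], ix = ix, iy = iy,
       value = peak)
}

#' Serialize a receptive-field map to long-format CSV
#'
#' @param map A [ReceptiveFieldMap-class].
#' @param path CSV path; columns x, y, mean, sem, n_events.
#' @return `path`, invisibly.
#' @export
writeRfMap <- function(map, path) {
  long <- expand.grid(y = map@yCenters, x = map@xCenters)
  long <- data.frame(x = long$x, y = long$y,
                     mean = as.vector(map@mean), sem = as.vector(map@sem),
                     n_events = as.vector(map@n))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
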