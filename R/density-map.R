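# Density-grid construction, moving-average smoothing, and point sampling.
#
# Index conventions (the one place they are documented): grids are stored in
# canonical x,y,z order; R indexing is 1-based, and the physical `origin` is
# the Cartesian Angstrom position of the *center* of cell [1,1,1]. The center
# of cell [i,j,k] is therefore origin + (c(i,j,k) - 1) * voxelSize. A point
# maps to the nearest cell by rounding (p - origin)/voxelSize to integers.

#' Construct a DensityGrid
#'
#' @param values 3-D numeric array of map values (canonical x,y,z order).
#' @param voxelSize Angstrom per cell; scalar or numeric(3).
#' @param origin Cartesian Angstrom position of the center of cell [1,1,1].
#' @param smoothed logical; has the grid already been moving-average filtered?
#' @return a [DensityGrid-class].
#' @examples
#' densityGrid(array(0, c(4, 4, 4)), voxelSize = 0.86)
#' @export
densityGrid <- function(values, voxelSize = 1, origin = c(0, 0, 0),
                        smoothed = FALSE) {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  new("DensityGrid", values = values, voxelSize = as.numeric(voxelSize),
      origin = as.numeric(origin), smoothed = smoothed)
}

# truncated running sum along the first dimension of a 3-D array:
# out[i,,] = sum over max(1, i-h) .. min(n, i+h) of a[.,,]
.runsumDim1 <- function(a, h) {
  n <- dim(a)[1]
  cs <- apply(a, c(2, 3), cumsum)
  dim(cs) <- dim(a)            # apply() keeps dim for matrix margins, be safe
  hi <- pmin(seq_len(n) + h, n)
  lo <- pmax(seq_len(n) - h, 1L)
  top <- cs[hi, , , drop = FALSE]
  bottom <- array(0, dim(a))
  has <- lo > 1L
  if (any(has)) bottom[has, , ] <- cs[lo[has] - 1L, , , drop = FALSE]
  top - bottom
}

.runcount1d <- function(n, h) {
  pmin(seq_len(n) + h, n) - pmax(seq_len(n) - h, 1L) + 1L
}

#' Moving-average smoothing of a density grid
#'
#' Replaces each cell with the arithmetic mean of all in-bounds cells of the
#' centered `window` x `window` x `window` cube (the default 5 gives the
#' 125-cell cube). At the grid boundary the mean is truncated to in-bounds
#' cells only, so a constant map stays constant everywhere. Geometry is
#' unchanged; the result carries `smoothed = TRUE`.
#'
#' @param grid a [DensityGrid-class] that has not been smoothed yet.
#' @param window odd integer window edge length (cells), >= 1.
#' @return a smoothed [DensityGrid-class].
#' @examples
#' g <- densityGrid(array(rnorm(7^3), c(7, 7, 7)))
#' s <- smoothMap(g, window = 5)
#' @export
smoothMap <- function(grid, window = 5L) {
  stopifnot(is(grid, "DensityGrid"))
  window <- as.integer(window)
  if (length(window) != 1L || is.na(window) || window < 1L ||
      window %% 2L == 0L) {
    stopf("'window' must be a positive odd integer (got %s)", window)
  }
  if (grid@smoothed) {
    stopf("grid is already smoothed; smoothing twice is not the defined filter")
  }
  h <- window %/% 2L
  v <- grid@values
  d <- dim(v)
  if (h > 0L) {
    # separable truncated box sum: per-axis running sums, then divide by the
    # product of per-axis in-bounds counts
    s <- .runsumDim1(v, h)
    s <- aperm(.runsumDim1(aperm(s, c(2, 1, 3)), h), c(2, 1, 3))
    s <- aperm(.runsumDim1(aperm(s, c(3, 2, 1)), h), c(3, 2, 1))
    cnt <- outer(outer(.runcount1d(d[1], h), .runcount1d(d[2], h)),
                 .runcount1d(d[3], h))
    dim(cnt) <- d
    v <- s / cnt
  }
  densityGrid(v, voxelSize = grid@voxelSize, origin = grid@origin,
              smoothed = TRUE)
}

#' Sample a density grid at Cartesian points
#'
#' Returns map values at arbitrary Angstrom positions. The default mode
#' returns the value of the voxel whose center is nearest to each point;
#' `mode = "trilinear"` interpolates the 8 surrounding voxel centers (offered
#' for sensitivity checks). Points outside the grid return 0.0 and are
#' flagged in the `outOfBounds` attribute of the result so callers can tally
#' them.
#'
#' @param grid a [DensityGrid-class].
#' @param points numeric(3) or an n x 3 matrix of Cartesian Angstrom points.
#' @param mode "nearest" (default) or "trilinear".
#' @return numeric vector of map values, with a logical attribute
#'   `outOfBounds` marking points that fell outside the grid.
#' @examples
#' g <- densityGrid(array(1:8, c(2, 2, 2)))
#' sampleAt(g, c(0, 0, 0))
#' @export
sampleAt <- function(grid, points, mode = c("nearest", "trilinear")) {
  stopifnot(is(grid, "DensityGrid"))
  mode <- match.arg(mode)
  p <- points
  if (is.null(dim(p))) p <- matrix(p, ncol = 3, byrow = TRUE)
  p <- as.matrix(p)
  if (ncol(p) != 3L) stopf("'points' must be length-3 or an n x 3 matrix")
  if (any(!is.finite(p))) stopf("'points' must have finite coordinates")

  d <- dim(grid@values)
  # fractional 1-based index of each point
  fi <- sweep(sweep(p, 2, grid@origin), 2, grid@voxelSize, "/") + 1

  if (mode == "nearest") {
    idx <- round(fi)
    inb <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
           idx[, 2] >= 1 & idx[, 2] <= d[2] &
           idx[, 3] >= 1 & idx[, 3] <= d[3]
    out <- numeric(nrow(p))
    if (any(inb)) {
      lin <- (idx[inb, 3] - 1) * d[1] * d[2] + (idx[inb, 2] - 1) * d[1] +
        idx[inb, 1]
      out[inb] <- grid@values[lin]
    }
  } else {
    lo <- floor(fi)
    frac <- fi - lo
    inb <- lo[, 1] >= 1 & lo[, 1] <= d[1] - 1 &
           lo[, 2] >= 1 & lo[, 2] <= d[2] - 1 &
           lo[, 3] >= 1 & lo[, 3] <= d[3] - 1
    out <- numeric(nrow(p))
    if (any(inb)) {
      l <- lo[inb, , drop = FALSE]
      f <- frac[inb, , drop = FALSE]
      acc <- numeric(nrow(l))
      for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
        w <- (if (dx) f[, 1] else 1 - f[, 1]) *
             (if (dy) f[, 2] else 1 - f[, 2]) *
             (if (dz) f[, 3] else 1 - f[, 3])
        lin <- (l[, 3] + dz - 1) * d[1] * d[2] + (l[, 2] + dy - 1) * d[1] +
          l[, 1] + dx
        acc <- acc + w * grid@values[lin]
      }
      out[inb] <- acc
    }
  }
  attr(out, "outOfBounds") <- !inb
  out
}
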