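# MRC/CCP4 2014-format map I/O (mode 2, 32-bit float).
#
# Axis bookkeeping: the file stores data with the fastest axis given by MAPC,
# then MAPR, then MAPS (each 1=x, 2=y, 3=z). Everything in the package works
# on grids in canonical x,y,z order; the reader un-permutes on load and the
# writer can re-permute for interoperability tests. The physical origin is
# taken from the ORIGIN header words when any is non-zero, otherwise from the
# start indices (NXSTART...) times the voxel size. Map values are never
# rescaled: they stay in the units of the file.

#' Read an MRC/CCP4 density map
#'
#' Reads a 2014-format MRC/CCP4 map (mode 2, 32-bit float; modes 0 and 1 are
#' also accepted) into a [DensityGrid-class] in canonical x,y,z axis order,
#' honoring the MAPC/MAPR/MAPS axis permutation and both the ORIGIN and
#' start-index origin conventions. Values are left in the file's units.
#'
#' @param path path to the map file.
#' @return a [DensityGrid-class] with `smoothed = FALSE`.
#' @examples
#' g <- densityGrid(array(rnorm(24), c(2, 3, 4)))
#' f <- tempfile(fileext = ".mrc")
#' writeMRC(g, f)
#' g2 <- readMRC(f)
#' @export
readMRC <- function(path) {
  if (!file.exists(path)) stopf("map file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))

  readHeader <- function(endian) {
    seek(con, 0)
    ints <- readBin(con, "integer", n = 10, size = 4, endian = endian)
    cella <- readBin(con, "numeric", n = 3, size = 4, endian = endian)
    cellb <- readBin(con, "numeric", n = 3, size = 4, endian = endian)
    mapcrs <- readBin(con, "integer", n = 3, size = 4, endian = endian)
    dstats <- readBin(con, "numeric", n = 3, size = 4, endian = endian)
    ispg_nsym <- readBin(con, "integer", n = 2, size = 4, endian = endian)
    readBin(con, "integer", n = 25, size = 4, endian = endian)   # EXTRA
    origin <- readBin(con, "numeric", n = 3, size = 4, endian = endian)
    list(nx = ints[1], ny = ints[2], nz = ints[3], mode = ints[4],
         nstart = ints[5:7], m = ints[8:10], cella = cella,
         mapcrs = mapcrs, nsymbt = ispg_nsym[2], origin = origin)
  }

  endian <- .Platform$endian
  h <- readHeader(endian)
  if (is.na(h$mode) || h$mode < 0 || h$mode > 6) {
    endian <- if (identical(endian, "little")) "big" else "little"
    h <- readHeader(endian)
  }
  if (is.na(h$mode) || !(h$mode %in% c(0L, 1L, 2L))) {
    stopf("unsupported MRC MODE %s in %s (only modes 0/1/2 are read)",
          h$mode, path)
  }
  if (any(h$nx <= 0, h$ny <= 0, h$nz <= 0)) {
    stopf("invalid MRC header: NX/NY/NZ must be positive (got %d %d %d)",
          h$nx, h$ny, h$nz)
  }
  cmap <- h$mapcrs
  if (!setequal(cmap, 1:3)) {
    stopf("invalid MRC header: MAPC/MAPR/MAPS must be a permutation of 1,2,3 (got %s)",
          paste(cmap, collapse = " "))
  }
  if (any(h$m <= 0)) {
    stopf("invalid MRC header: MX/MY/MZ must be positive (got %s)",
          paste(h$m, collapse = " "))
  }
  if (any(h$cella <= 0)) {
    stopf("invalid MRC header: CELLA cell dimensions must be positive (got %s)",
          paste(signif(h$cella, 6), collapse = " "))
  }
  voxel <- h$cella / h$m

  nvals <- h$nx * h$ny * h$nz
  seek(con, 1024 + max(0L, h$nsymbt))
  vals <- switch(as.character(h$mode),
    "0" = as.numeric(readBin(con, "integer", n = nvals, size = 1,
                             signed = TRUE, endian = endian)),
    "1" = as.numeric(readBin(con, "integer", n = nvals, size = 2,
                             signed = TRUE, endian = endian)),
    "2" = readBin(con, "numeric", n = nvals, size = 4, endian = endian))
  if (length(vals) != nvals) {
    stopf("truncated MRC data block in %s: expected %d values, read %d",
          path, nvals, length(vals))
  }

  fileArr <- array(vals, dim = c(h$nx, h$ny, h$nz))
  # canonical[ix,iy,iz]: invert the file-axis permutation
  canon <- aperm(fileArr, match(1:3, cmap))
  # start indices are stored per file axis; map them to cartesian axes
  nstartXYZ <- h$nstart[match(1:3, cmap)]
  origin <- if (any(abs(h$origin) > 0)) {
    as.numeric(h$origin)
  } else {
    nstartXYZ * voxel
  }
  densityGrid(canon, voxelSize = voxel, origin = origin, smoothed = FALSE)
}

#' Write a DensityGrid as an MRC/CCP4 map
#'
#' Writes mode-2 (32-bit float) MRC 2014 format. `axisOrder` selects the
#' file's fast/medium/slow storage axes (MAPC/MAPR/MAPS); the default writes
#' x fastest. [readMRC()] restores canonical order for any `axisOrder`.
#'
#' @param grid a [DensityGrid-class].
#' @param path output file path.
#' @param axisOrder permutation of 1:3 giving the cartesian axis stored
#'   fastest, medium, slowest.
#' @return `path`, invisibly.
#' @export
writeMRC <- function(grid, path, axisOrder = 1:3) {
  stopifnot(is(grid, "DensityGrid"))
  if (!setequal(axisOrder, 1:3)) {
    stopf("'axisOrder' must be a permutation of 1:3")
  }
  canon <- grid@values
  dims <- dim(canon)
  fileArr <- aperm(canon, axisOrder)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(dim(fileArr),       # NX NY NZ
                        2L,                 # MODE 2
                        0L, 0L, 0L,         # NXSTART...
                        dims)),             # MX MY MZ
           con, size = 4)
  writeBin(as.numeric(c(dims * grid@voxelSize,  # CELLA
                        90, 90, 90)),           # CELLB
           con, size = 4)
  writeBin(as.integer(c(axisOrder,          # MAPC MAPR MAPS
                        0L, 0L, 0L)), con, size = 4)  # placeholder DMIN/DMAX/DMEAN
  # rewrite statistics as floats at the correct offset
  seek(con, 76)
  writeBin(as.numeric(c(min(canon), max(canon), mean(canon))), con, size = 4)
  writeBin(as.integer(c(1L, 0L)), con, size = 4)      # ISPG, NSYMBT
  writeBin(integer(25), con, size = 4)                 # EXTRA
  writeBin(as.numeric(grid@origin), con, size = 4)     # ORIGIN
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  machst <- if (identical(.Platform$endian, "little")) {
    as.raw(c(0x44, 0x44, 0x00, 0x00))
  } else {
    as.raw(c(0x11, 0x11, 0x00, 0x00))
  }
  writeBin(machst, con)
  rms <- if (length(canon) > 1) stats::sd(canon) else 0
  writeBin(as.numeric(rms), con, size = 4)                # RMS
  writeBin(0L, con, size = 4)                             # NLABL
  writeBin(raw(800), con)                                 # labels
  writeBin(as.numeric(fileArr), con, size = 4)
  invisible(path)
}
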