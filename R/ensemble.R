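# Ensemble-level analysis: pairwise RMSD matrix, central-structure
# selection (minimum average RMSD to all other members), spread statistics,
# trajectory-frame scoring and 1-D moving-average smoothing of time series.

#' Pairwise C-alpha RMSD matrix of an ensemble
#'
#' Entry (i, j) is [rmsdCalpha()] between members i and j in the common
#' frame; the diagonal is zero.
#'
#' @param members list of [ComplexModel-class] poses (or n x 3 C-alpha
#'   coordinate matrices, all paired row-by-row).
#' @param pairingMode residue-pairing rule for ComplexModel members.
#' @return symmetric n x n numeric matrix (Angstrom).
#' @export
rmsdMatrix <- function(members, pairingMode = c("auto", "resno", "align")) {
  pairingMode <- match.arg(pairingMode)
  n <- length(members)
  if (!n) stopf("empty ensemble")
  m <- matrix(0, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        r <- tryCatch(
          rmsdCalpha(members[[i]], members[[j]], pairingMode = pairingMode),
          error = function(e) {
            stopf("pairing failed between members %d and %d: %s", i, j,
                  conditionMessage(e))
          })
        m[i, j] <- m[j, i] <- r
      }
    }
  }
  m
}

#' Assemble an Ensemble object
#'
#' Computes the pairwise RMSD matrix and the central-structure index for a
#' list of poses sharing one reference frame.
#'
#' @param members list of [ComplexModel-class] poses.
#' @param pairingMode residue-pairing rule.
#' @return an [Ensemble-class].
#' @export
makeEnsembleObject <- function(members,
                               pairingMode = c("auto", "resno", "align")) {
  pairingMode <- match.arg(pairingMode)
  m <- rmsdMatrix(members, pairingMode = pairingMode)
  new("Ensemble", members = members, rmsdMatrix = m,
      centralIndex = centralStructure(m))
}

#' Central structure of an ensemble
#'
#' The member with the minimum average RMSD to all *other* members (the
#' zero self-distance is excluded from the mean, which cannot change the
#' argmin). Ties break to the lowest index, so the choice is deterministic
#' and order-stable. A single-member ensemble returns index 1.
#'
#' @param x an [Ensemble-class], a symmetric RMSD matrix, or a list of
#'   members (matrix computed via [rmsdMatrix()]).
#' @return integer(1), the 1-based index of the central structure.
#' @export
centralStructure <- function(x) {
  m <- if (is(x, "Ensemble")) x@rmsdMatrix
       else if (is.matrix(x)) x
       else rmsdMatrix(x)
  n <- nrow(m)
  if (n < 1L) stopf("empty ensemble")
  if (n == 1L) return(1L)
  avg <- (rowSums(m) - diag(m)) / (n - 1)
  which.min(avg)   # which.min takes the first (lowest-index) minimum
}

#' Ensemble spread statistics
#'
#' @param x an [Ensemble-class] or a symmetric RMSD matrix.
#' @return named numeric(3): `maxPairwiseRMSD`, `maxRMSDToCentral`,
#'   `meanRMSDToCentral` (Angstrom).
#' @export
spreadStats <- function(x) {
  m <- if (is(x, "Ensemble")) x@rmsdMatrix else x
  ci <- if (is(x, "Ensemble")) x@centralIndex else centralStructure(m)
  n <- nrow(m)
  toCentral <- m[ci, -ci]
  if (n == 1L) toCentral <- 0
  c(maxPairwiseRMSD = max(m),
    maxRMSDToCentral = max(toCentral),
    meanRMSDToCentral = mean(toCentral))
}

#' Moving average of a time series
#'
#' Centered truncated-window arithmetic mean per point (the same boundary
#' convention as the 3-D map smoothing: the window shrinks at the ends).
#' Time values are unchanged.
#'
#' @param series data.frame with numeric columns `time` (strictly
#'   increasing) and `value`.
#' @param window window size in samples (>= 1, at most the series length);
#'   e.g. 20 samples for 1-ns-spaced frames and a 20-ns window.
#' @return a data.frame of the same shape with smoothed `value`.
#' @export
movingAverageSeries <- function(series, window) {
  if (!is.data.frame(series) || !all(c("time", "value") %in% names(series))) {
    stopf("'series' must be a data.frame with columns 'time' and 'value'")
  }
  n <- nrow(series)
  if (any(diff(series$time) <= 0)) stopf("'time' must be strictly increasing")
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window > n) {
    stopf("'window' must be an integer in [1, %d]", n)
  }
  h <- window %/% 2L
  hUp <- window - h - 1L      # asymmetric split for even windows
  v <- series$value
  out <- vapply(seq_len(n), function(i) {
    mean(v[max(1L, i - h):min(n, i + hUp)])
  }, numeric(1))
  data.frame(time = series$time, value = out)
}

#' EDC score along a trajectory
#'
#' Aligns each frame into the common reference frame and scores it against
#' the smoothed map, returning an EDC time series. Frames are poses from a
#' multi-model PDB or any ordered list; native MD trajectory formats are
#' not parsed. Times default to (frame index - 1) * `dtNs` nanoseconds.
#'
#' @param frames ordered list of [ComplexModel-class] frames.
#' @param smoothed a smoothed [DensityGrid-class].
#' @param reference a [StructureModel-class] reference frame holder.
#' @param referenceChain heme-protein chain ID in `reference`.
#' @param hemeRadius fit-set radius passed to [alignComplexToReference()].
#' @param dtNs frame spacing in nanoseconds (default 1).
#' @param times optional explicit time vector overriding `dtNs`.
#' @param mode density sampling mode.
#' @return data.frame with columns `time` (ns), `value` (EDC, map units)
#'   and `oobFraction`.
#' @export
scoreTrajectory <- function(frames, smoothed, reference, referenceChain,
                            hemeRadius = 8, dtNs = 1, times = NULL,
                            mode = c("nearest", "trilinear")) {
  mode <- match.arg(mode)
  n <- length(frames)
  if (!n) stopf("no trajectory frames supplied")
  if (is.null(times)) times <- (seq_len(n) - 1) * dtNs
  if (length(times) != n) stopf("'times' must match the number of frames")
  edc <- numeric(n)
  oob <- numeric(n)
  for (i in seq_len(n)) {
    al <- tryCatch(
      alignComplexToReference(frames[[i]], reference, referenceChain,
                              hemeRadius = hemeRadius),
      error = function(e) {
        stopf("frame %d failed alignment: %s", i, conditionMessage(e))
      })
    s <- edcScore(al, smoothed, mode = mode)
    edc[i] <- as.numeric(s)
    oob[i] <- attr(s, "oobFraction")
  }
  data.frame(time = times, value = edc, oobFraction = oob)
}
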