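# Per-pose and pairwise pose metrics: the EDC score, Cu-Fe cofactor
# distance, mobile-protein center-of-mass distance, C-alpha RMSD, and the
# comparison-table builder that assembles them for a set of poses sharing
# one reference frame.
#
# Pairwise RMSDs and CoM distances are deliberately computed in the common
# frame WITHOUT per-pair refitting: with every pose anchored on the same
# reference heme, the triangles measure differences in the mobile protein's
# pose, not internal conformational differences.

#' Electron-density compliance (EDC) score
#'
#' The mean of the smoothed map value sampled at each C-alpha position.
#' Atoms falling outside the map contribute 0.0 to the mean and are tallied
#' in the `oobFraction` attribute so callers can flag meaningless scores.
#' The grid must have been smoothed with [smoothMap()]; scoring a raw grid
#' is refused because the score is defined on the smoothed field.
#'
#' @param calphaCoords n x 3 matrix of C-alpha positions (Angstrom), e.g.
#'   from [selectCalpha()], or a [ComplexModel-class] (its mobile C-alphas
#'   are used).
#' @param smoothed a smoothed [DensityGrid-class].
#' @param mode sampling mode, `"nearest"` (default) or `"trilinear"`.
#' @return numeric(1) EDC score in map units, with attributes `oobFraction`
#'   (fraction of C-alphas outside the map) and `nOutOfBounds`.
#' @examples
#' g <- smoothMap(densityGrid(array(2, c(5, 5, 5))))
#' edcScore(matrix(c(1, 1, 1), 1), g)  # constant map -> 2
#' @export
edcScore <- function(calphaCoords, smoothed, mode = c("nearest", "trilinear")) {
  mode <- match.arg(mode)
  stopifnot(is(smoothed, "DensityGrid"))
  if (!smoothed@smoothed) {
    stopf("the EDC score is defined on a smoothed grid; call smoothMap() first")
  }
  if (is(calphaCoords, "ComplexModel")) {
    calphaCoords <- selectCalpha(mobileModel(calphaCoords))
  }
  m <- as.matrix(calphaCoords)
  if (!nrow(m)) stopf("empty C-alpha coordinate set")
  v <- sampleAt(smoothed, m, mode = mode)
  oob <- attr(v, "outOfBounds")
  out <- mean(v)                     # out-of-bounds samples are 0.0
  attr(out, "oobFraction") <- mean(oob)
  attr(out, "nOutOfBounds") <- sum(oob)
  out
}

#' Cu-Fe cofactor distance
#'
#' Euclidean distance (Angstrom) between the mobile protein's copper and the
#' anchor protein's heme iron — the electron-tunneling proxy (functional
#' complexes sit below roughly 15 Angstrom).
#'
#' @param complex a [ComplexModel-class].
#' @return numeric(1) distance in Angstrom.
#' @export
cofactorDistance <- function(complex) {
  stopifnot(is(complex, "ComplexModel"))
  cu <- as.numeric(cuAtom(complex)[, c("x", "y", "z")])
  fe <- as.numeric(feAtom(complex)[, c("x", "y", "z")])
  sqrt(sum((cu - fe)^2))
}

#' Center-of-mass distance between two mobile proteins
#'
#' Both poses must already sit in the common reference frame; the distance
#' is then a direct measure of how far the mobile protein's position
#' differs between the two poses.
#'
#' @param a,b [ComplexModel-class] poses (their mobile bodies are used) or
#'   [StructureModel-class] atom subsets.
#' @param massWeighted mass-weighted centers (default) or geometric centers.
#' @return numeric(1) distance in Angstrom.
#' @export
comDistance <- function(a, b, massWeighted = TRUE) {
  ma <- if (is(a, "ComplexModel")) mobileModel(a) else a
  mb <- if (is(b, "ComplexModel")) mobileModel(b) else b
  ca <- centerOfMass(ma, massWeighted = massWeighted)
  cb <- centerOfMass(mb, massWeighted = massWeighted)
  sqrt(sum((ca - cb)^2))
}

#' C-alpha RMSD between two poses in the common frame
#'
#' Root-mean-square distance over paired C-alpha atoms, with NO refitting:
#' both structures are assumed to be pre-aligned to the common reference
#' frame, so the value reflects pose difference. Coordinate matrices are
#' used as given (and must pair row-by-row); ComplexModel inputs are paired
#' by the residue-pairing rule (residue numbers when the numbering schemes
#' match, sequence alignment otherwise; unpaired residues are dropped).
#'
#' @param a,b paired n x 3 coordinate matrices, or [ComplexModel-class]
#'   poses whose mobile C-alphas are paired automatically.
#' @param pairingMode `"auto"`, `"resno"` or `"align"` (ComplexModel inputs).
#' @return numeric(1) RMSD in Angstrom.
#' @export
rmsdCalpha <- function(a, b, pairingMode = c("auto", "resno", "align")) {
  pairingMode <- match.arg(pairingMode)
  if (is(a, "ComplexModel") && is(b, "ComplexModel")) {
    pr <- pairCalpha(mobileModel(a), mobileModel(b), mode = pairingMode)
    a <- pr$a
    b <- pr$b
  }
  a <- as.matrix(a)
  b <- as.matrix(b)
  if (nrow(a) != nrow(b)) {
    stopf("paired coordinate lists differ in length: %d vs %d",
          nrow(a), nrow(b))
  }
  if (!nrow(a)) stopf("empty coordinate pairing")
  sqrt(mean(rowSums((a - b)^2)))
}

#' Build the pairwise pose comparison table
#'
#' For an ordered set of poses already aligned to one reference frame:
#' the per-pose diagonal holds the Cu-Fe distance and EDC score, the upper
#' triangle the mobile center-of-mass distances, and the lower triangle the
#' mobile C-alpha RMSDs, for every unordered pose pair. Values are stored at
#' full precision; the writers round at output time only.
#'
#' @param complexes list of aligned [ComplexModel-class] poses.
#' @param smoothed a smoothed [DensityGrid-class].
#' @param pairingMode residue-pairing rule for the RMSD triangle.
#' @param massWeighted mass-weighted centers of mass (default TRUE).
#' @param mode density sampling mode for the EDC score.
#' @return a [ComparisonTable-class].
#' @export
buildComparisonTable <- function(complexes, smoothed,
                                 pairingMode = c("auto", "resno", "align"),
                                 massWeighted = TRUE,
                                 mode = c("nearest", "trilinear")) {
  pairingMode <- match.arg(pairingMode)
  mode <- match.arg(mode)
  if (!length(complexes)) stopf("no poses supplied")
  labels <- vapply(complexes, poseLabel, character(1))
  if (any(!nzchar(labels))) {
    labels[!nzchar(labels)] <- paste0("pose", which(!nzchar(labels)))
  }
  n <- length(complexes)
  edc <- numeric(n)
  oob <- numeric(n)
  cufe <- numeric(n)
  for (i in seq_len(n)) {
    s <- edcScore(complexes[[i]], smoothed, mode = mode)
    edc[i] <- as.numeric(s)
    oob[i] <- attr(s, "oobFraction")
    cufe[i] <- cofactorDistance(complexes[[i]])
  }
  com <- matrix(0, n, n, dimnames = list(labels, labels))
  rms <- matrix(0, n, n, dimnames = list(labels, labels))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        com[i, j] <- com[j, i] <- comDistance(complexes[[i]], complexes[[j]],
                                              massWeighted = massWeighted)
        r <- tryCatch(
          rmsdCalpha(complexes[[i]], complexes[[j]], pairingMode = pairingMode),
          error = function(e) {
            stopf("C-alpha pairing failed between poses '%s' and '%s': %s",
                  labels[i], labels[j], conditionMessage(e))
          })
        rms[i, j] <- rms[j, i] <- r
      }
    }
  }
  new("ComparisonTable", labels = labels, cuFe = cufe, edc = edc,
      oobFraction = oob, comDist = com, rmsd = rms)
}

#' Format a comparison table for display or CSV output
#'
#' Mirrors the familiar layout: diagonal cells "cuFe|edc" with distances to
#' 1 decimal and EDC to 3 decimals, upper triangle CoM distances, lower
#' triangle C-alpha RMSDs (1 decimal each).
#'
#' @param table a [ComparisonTable-class].
#' @return a character matrix with label dimnames.
#' @export
formatComparisonTable <- function(table) {
  stopifnot(is(table, "ComparisonTable"))
  n <- length(table@labels)
  out <- matrix("", n, n, dimnames = list(table@labels, table@labels))
  for (i in seq_len(n)) {
    out[i, i] <- sprintf("%.1f|%.3f", table@cuFe[i], table@edc[i])
    if (i < n) {
      for (j in (i + 1):n) {
        out[i, j] <- sprintf("%.1f", table@comDist[i, j])
        out[j, i] <- sprintf("%.1f", table@rmsd[j, i])
      }
    }
  }
  out
}

#' Write a comparison table as CSV
#'
#' @param table a [ComparisonTable-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeComparisonCSV <- function(table, path) {
  m <- formatComparisonTable(table)
  df <- data.frame(structure = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a comparison table as JSON (full precision)
#'
#' @param table a [ComparisonTable-class].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeComparisonJSON <- function(table, path) {
  stopifnot(is(table, "ComparisonTable"))
  x <- list(
    labels = table@labels,
    cuFeDistance = table@cuFe,
    edcScore = table@edc,
    oobFraction = table@oobFraction,
    comDistance = table@comDist,
    rmsdCalpha = table@rmsd
  )
  jsonlite::write_json(x, path, digits = NA, matrix = "rowmajor")
  invisible(path)
}
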