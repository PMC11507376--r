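# Atomic-model I/O and atom-selection operations.
#
# File parsing goes through bio3d (read.pdb / read.cif); this module turns
# its tables into StructureModel objects, infers elements where the element
# column is absent, and provides the selections the scoring pipeline needs.

.WATER_RESIDUES <- c("HOH", "WAT", "TIP", "TIP3", "TIP4", "SOL", "DOD")
.TWO_LETTER_ELEMENTS <- c("CU", "FE", "ZN", "MG", "MN", "SE", "CL", "BR",
                          "NA", "CA", "NI", "CO", "MO", "CD", "HG")

# element from the element column when present, atom-name heuristics second.
# Atom names like "CA" inside amino-acid residues are carbon; a bare metal
# name in a hetero residue (resid CU / FE / HEM...) is the metal.
.inferElement <- function(elety, resid, elesy = NULL) {
  n <- length(elety)
  out <- character(n)
  if (!is.null(elesy)) {
    e <- toupper(trimws(elesy))
    ok <- !is.na(e) & nzchar(e)
    out[ok] <- e[ok]
  }
  todo <- which(!nzchar(out))
  if (length(todo)) {
    nm <- toupper(trimws(elety[todo]))
    rs <- toupper(trimws(resid[todo]))
    stripped <- gsub("[0-9']", "", nm)
    guess <- substr(stripped, 1, 1)
    # a two-letter candidate counts as a metal only outside amino acids
    # (atom name CA inside GLY is carbon; residue CA / HEM FE is the metal)
    isAA <- suppressWarnings(bio3d::aa321(rs)) != "X"
    metal <- stripped %in% .TWO_LETTER_ELEMENTS & !isAA
    guess[metal] <- stripped[metal]
    out[todo] <- guess
  }
  out
}

.makeStructureModel <- function(atoms, modelIndex, sourceId) {
  atoms$mass <- elementMass(atoms$element)
  rownames(atoms) <- NULL
  new("StructureModel", atoms = atoms, modelIndex = as.integer(modelIndex),
      sourceId = sourceId)
}

#' Read an atomic structure from PDB or mmCIF
#'
#' Parses all models of a (possibly multi-model) PDB or mmCIF file. Hetero
#' atoms (Cu, heme, ...) are retained; waters are excluded by default.
#' Elements are taken from the element column when present and inferred from
#' atom names otherwise.
#'
#' @param path path to a `.pdb` or `.cif` file.
#' @param modelIndex `"all"` (default) to return a list of every model, or a
#'   single 1-based model number.
#' @param removeWaters drop water residues (default TRUE).
#' @return a [StructureModel-class] (single model requested) or a list of
#'   them, ordered by model number.
#' @export
readStructure <- function(path, modelIndex = "all", removeWaters = TRUE) {
  if (!file.exists(path)) stopf("structure file not found: %s", path)
  isCif <- grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)
  pdb <- if (isCif) {
    bio3d::read.cif(path, multi = TRUE, verbose = FALSE)
  } else {
    bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  }
  a <- pdb$atom
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nModels <- nrow(xyz)

  keep <- rep(TRUE, nrow(a))
  if (removeWaters) keep <- !(toupper(a$resid) %in% .WATER_RESIDUES)
  element <- .inferElement(a$elety, a$resid,
                           if ("elesy" %in% names(a)) a$elesy else NULL)
  chain <- ifelse(is.na(a$chain) | !nzchar(a$chain), " ", a$chain)

  buildModel <- function(im) {
    cm <- matrix(xyz[im, ], ncol = 3, byrow = TRUE)
    atoms <- data.frame(
      elety = trimws(a$elety), element = element, resid = toupper(a$resid),
      chain = chain, resno = as.integer(a$resno),
      x = cm[, 1], y = cm[, 2], z = cm[, 3],
      stringsAsFactors = FALSE
    )[keep, , drop = FALSE]
    ok <- is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)
    atoms <- atoms[ok, , drop = FALSE]
    .makeStructureModel(atoms, im, sprintf("%s model %d", basename(path), im))
  }

  if (identical(modelIndex, "all")) {
    models <- lapply(seq_len(nModels), buildModel)
    if (nModels == 1L) return(models[[1L]])
    return(models)
  }
  modelIndex <- as.integer(modelIndex)
  if (is.na(modelIndex) || modelIndex < 1L || modelIndex > nModels) {
    stopf("model %s not found in %s; available models: %s",
          modelIndex, path, paste(seq_len(nModels), collapse = ", "))
  }
  buildModel(modelIndex)
}

#' Write one or more StructureModels as a PDB file
#'
#' A list of models is written as a multi-model file with MODEL/ENDMDL
#' records. Metal and other non-amino-acid atoms are written as HETATM.
#'
#' @param x a [StructureModel-class] or a list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeStructure <- function(x, path) {
  models <- if (is(x, "StructureModel")) list(x) else x
  blocks <- lapply(models, function(m) {
    a <- m@atoms
    isAA <- suppressWarnings(bio3d::aa321(a$resid)) != "X"
    tmp <- tempfile(fileext = ".pdb")
    on.exit(unlink(tmp), add = TRUE)
    bio3d::write.pdb(
      file = tmp,
      xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
      type = ifelse(isAA, "ATOM", "HETATM"),
      resno = a$resno, resid = a$resid, eleno = seq_len(nrow(a)),
      elety = a$elety, chain = ifelse(a$chain == " ", "", a$chain),
      elesy = a$element, end = FALSE
    )
    readLines(tmp)
  })
  lines <- if (length(blocks) == 1L) {
    c(blocks[[1L]], "END")
  } else {
    c(unlist(lapply(seq_along(blocks), function(i) {
      c(sprintf("MODEL     %4d", i), blocks[[i]], "ENDMDL")
    })), "END")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Split a model into a two-body complex
#'
#' Assigns chains to the mobile (copper protein) and anchor (heme protein)
#' roles and resolves the Cu and heme Fe cofactors by element. Ambiguity is
#' an error unless `feSelect = "nearest-cu"`, which picks the Fe nearest to
#' the Cu (the multi-heme anchor case).
#'
#' @param model a [StructureModel-class].
#' @param mobileChains chain IDs of the mobile protein.
#' @param anchorChains chain IDs of the anchor protein.
#' @param label pose label for the resulting complex.
#' @param feSelect `"require-unique"` (default) or `"nearest-cu"`.
#' @return a [ComplexModel-class].
#' @export
splitComplex <- function(model, mobileChains, anchorChains, label = NULL,
                         feSelect = c("require-unique", "nearest-cu")) {
  feSelect <- match.arg(feSelect)
  stopifnot(is(model, "StructureModel"))
  if (!length(mobileChains) || !length(anchorChains)) {
    stopf("both chain sets must be non-empty")
  }
  a <- model@atoms
  for (ch in c(mobileChains, anchorChains)) {
    if (!ch %in% a$chain) stopf("chain '%s' not present in the model", ch)
  }
  mob <- a[a$chain %in% mobileChains, , drop = FALSE]
  anc <- a[a$chain %in% anchorChains, , drop = FALSE]

  cuRows <- which(toupper(mob$element) == "CU")
  if (length(cuRows) != 1L) {
    stopf("expected exactly one Cu in the mobile chains, found %d%s",
          length(cuRows),
          if (length(cuRows)) paste0(": ",
            paste(sprintf("%s %s%d", mob$elety[cuRows], mob$chain[cuRows],
                          mob$resno[cuRows]), collapse = ", ")) else "")
  }
  feRows <- which(toupper(anc$element) == "FE")
  if (length(feRows) == 0L) {
    stopf("no Fe atom found in the anchor chains")
  }
  if (length(feRows) > 1L) {
    if (feSelect == "require-unique") {
      stopf("multiple Fe candidates in the anchor chains: %s",
            paste(sprintf("%s %s%d", anc$elety[feRows], anc$chain[feRows],
                          anc$resno[feRows]), collapse = ", "))
    }
    cuXYZ <- as.numeric(mob[cuRows, c("x", "y", "z")])
    dd <- apply(anc[feRows, c("x", "y", "z")], 1,
                function(p) sum((as.numeric(p) - cuXYZ)^2))
    feRows <- feRows[which.min(dd)]
  }

  new("ComplexModel",
      anchor = .makeStructureModel(anc, model@modelIndex,
                                   paste0(model@sourceId, " anchor")),
      mobile = .makeStructureModel(mob, model@modelIndex,
                                   paste0(model@sourceId, " mobile")),
      cuIdx = as.integer(cuRows), feIdx = as.integer(feRows),
      label = if (is.null(label)) model@sourceId else label,
      meta = list(source = model@sourceId))
}

#' Select C-alpha coordinates
#'
#' One coordinate per amino-acid residue that has a CA atom, ordered by
#' chain then residue number. Residues without a CA atom are skipped.
#'
#' @param x a [StructureModel-class].
#' @return an n x 3 coordinate matrix with a `resno` attribute.
#' @export
selectCalpha <- function(x) {
  stopifnot(is(x, "StructureModel"))
  a <- x@atoms
  isAA <- suppressWarnings(bio3d::aa321(a$resid)) != "X"
  ca <- a[isAA & a$elety == "CA" & toupper(a$element) == "C", , drop = FALSE]
  if (!nrow(ca)) stopf("no C-alpha atoms in the selection")
  ca <- ca[order(ca$chain, ca$resno), , drop = FALSE]
  # one CA per residue: drop alternate duplicates deterministically
  ca <- ca[!duplicated(paste(ca$chain, ca$resno)), , drop = FALSE]
  m <- as.matrix(ca[, c("x", "y", "z")])
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  attr(m, "resno") <- ca$resno
  attr(m, "chain") <- ca$chain
  m
}

#' Select atoms within a radius of a point
#'
#' All atoms passing `atomFilter` whose distance to `center` is at most
#' `radius`, in deterministic (chain, residue, atom-name) order.
#'
#' @param x a [StructureModel-class].
#' @param center Cartesian Angstrom triple.
#' @param radius Angstrom, > 0.
#' @param atomFilter optional predicate on the atom data.frame returning a
#'   logical vector (e.g. heavy atoms only).
#' @return a [StructureModel-class] subset.
#' @export
selectWithinRadius <- function(x, center, radius, atomFilter = NULL) {
  stopifnot(is(x, "StructureModel"))
  if (!is.numeric(radius) || radius <= 0) stopf("'radius' must be > 0")
  a <- x@atoms
  if (!is.null(atomFilter)) a <- a[atomFilter(a), , drop = FALSE]
  if (nrow(a)) {
    d2 <- (a$x - center[1])^2 + (a$y - center[2])^2 + (a$z - center[3])^2
    a <- a[d2 <= radius^2, , drop = FALSE]
  }
  if (!nrow(a)) {
    stopf("no atoms within %.3g A of the given center", radius)
  }
  a <- a[order(a$chain, a$resno, a$elety), , drop = FALSE]
  .makeStructureModel(a, x@modelIndex, paste0(x@sourceId, " radius subset"))
}

#' Center of mass of an atom set
#'
#' Mass-weighted mean coordinate over non-hydrogen atoms (the default), or
#' the unweighted geometric center with `massWeighted = FALSE`.
#'
#' @param x a [StructureModel-class].
#' @param massWeighted logical, default TRUE.
#' @return numeric(3) Cartesian Angstrom position.
#' @export
centerOfMass <- function(x, massWeighted = TRUE) {
  stopifnot(is(x, "StructureModel"))
  a <- x@atoms[toupper(x@atoms$element) != "H", , drop = FALSE]
  if (!nrow(a)) stopf("no non-hydrogen atoms in the selection")
  w <- if (massWeighted) a$mass else rep(1, nrow(a))
  c(sum(a$x * w), sum(a$y * w), sum(a$z * w)) / sum(w)
}

# -- residue pairing ----------------------------------------------------------

# Pair the C-alpha atoms of two mobile proteins. "resno" pairs by residue
# number; "align" pairs by a global pairwise alignment of one-letter
# sequences with identity scoring; "auto" uses residue numbers when the two
# numbering schemes overlap in at least 3 residues and falls back to the
# alignment otherwise. Unpaired residues are dropped.
pairCalpha <- function(a, b, mode = c("auto", "resno", "align")) {
  mode <- match.arg(mode)
  caA <- selectCalpha(a)
  caB <- selectCalpha(b)
  rnA <- attr(caA, "resno")
  rnB <- attr(caB, "resno")
  common <- intersect(rnA, rnB)
  useResno <- switch(mode,
    resno = TRUE,
    align = FALSE,
    auto = length(common) >= 3L)
  if (useResno) {
    if (length(common) < 1L) {
      stopf("no shared residue numbers between '%s' and '%s'",
            a@sourceId, b@sourceId)
    }
    ia <- match(common, rnA)
    ib <- match(common, rnB)
  } else {
    seqA <- .calphaSequence(a)
    seqB <- .calphaSequence(b)
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(seqA), Biostrings::AAString(seqB),
      type = "global",
      substitutionMatrix = .identityMatrix(),
      gapOpening = 5, gapExtension = 1)
    pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    pb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    ia <- integer(0); ib <- integer(0)
    ca <- 0L; cb <- 0L
    for (k in seq_along(pa)) {
      if (pa[k] != "-") ca <- ca + 1L
      if (pb[k] != "-") cb <- cb + 1L
      if (pa[k] != "-" && pb[k] != "-") {
        ia <- c(ia, ca); ib <- c(ib, cb)
      }
    }
    if (!length(ia)) {
      stopf("sequence alignment produced no residue pairs between '%s' and '%s'",
            a@sourceId, b@sourceId)
    }
  }
  list(a = caA[ia, , drop = FALSE], b = caB[ib, , drop = FALSE])
}

.calphaSequence <- function(model) {
  ca <- selectCalpha(model)
  a <- model@atoms
  isAA <- suppressWarnings(bio3d::aa321(a$resid)) != "X"
  caRows <- a[isAA & a$elety == "CA" & toupper(a$element) == "C", , drop = FALSE]
  caRows <- caRows[order(caRows$chain, caRows$resno), , drop = FALSE]
  caRows <- caRows[!duplicated(paste(caRows$chain, caRows$resno)), , drop = FALSE]
  paste(suppressWarnings(bio3d::aa321(caRows$resid)), collapse = "")
}

.identityMatrix <- function() {
  letters20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V", "X")
  m <- matrix(-1, length(letters20), length(letters20),
              dimnames = list(letters20, letters20))
  diag(m) <- 2
  m
}
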