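# Structure I/O, chain splitting, and atom selections.

test_that("write/read round trip preserves a multi-model structure", {
  spec <- syntheticSpec(seed = 3)
  cx <- makeToyComplex(spec)
  m1 <- complexAsModel(cx, "m1")
  m2 <- complexAsModel(perturbPose(cx, 15, 3, seed = 9), "m2")
  f <- tempfile(fileext = ".pdb")
  writeStructure(list(m1, m2), f)

  models <- readStructure(f)
  expect_length(models, 2L)
  expect_equal(models[[2]]@modelIndex, 2L)
  for (pair in list(list(m1, models[[1]]), list(m2, models[[2]]))) {
    a <- atomTable(pair[[1]]); b <- atomTable(pair[[2]])
    expect_equal(nrow(a), nrow(b))
    expect_equal(a$elety, b$elety)
    expect_equal(a$resno, b$resno)
    expect_equal(toupper(a$element), toupper(b$element))
    expect_equal(coords(pair[[2]]), coords(pair[[1]]), tolerance = 1e-3)
  }

  one <- readStructure(f, modelIndex = 2)
  expect_s4_class(one, "StructureModel")
  expect_equal(coords(one), coords(models[[2]]))
  expect_error(readStructure(f, modelIndex = 7), "available models: 1, 2")
})

test_that("waters are dropped and elements inferred from atom names", {
  lines <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00",
    "HETATM    3 CU    CU A   3       1.000   2.000   3.000  1.00  0.00",
    "HETATM    4  O   HOH A   4       9.000   9.000   9.000  1.00  0.00",
    "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  m <- readStructure(f)
  a <- atomTable(m)
  expect_equal(nrow(a), 3L)                       # water gone
  expect_false(any(a$resid == "HOH"))
  expect_equal(toupper(a$element), c("C", "C", "CU"))
  expect_gt(a$mass[3], 60)                        # copper mass, not carbon
})

test_that("splitComplex resolves cofactors and reports ambiguity", {
  cx0 <- makeToyComplex(syntheticSpec(seed = 5))
  m <- complexAsModel(cx0)
  cx <- splitComplex(m, "A", "C")
  expect_equal(toupper(cuAtom(cx)$element), "CU")
  expect_equal(toupper(feAtom(cx)$element), "FE")
  expect_equal(cofactorDistance(cx), cofactorDistance(cx0), tolerance = 1e-9)

  # a second adventitious Fe in the anchor is an error listing candidates...
  a2 <- atomTable(m)
  extra <- a2[a2$elety == "FE", , drop = FALSE]
  extra$x <- extra$x + 30
  extra$resno <- 99L
  dup <- toyModel(rbind(a2, extra))
  expect_error(splitComplex(dup, "A", "C"), "multiple Fe")
  # ...unless nearest-Cu selection is requested (multi-heme anchors)
  cxN <- splitComplex(dup, "A", "C", feSelect = "nearest-cu")
  expect_equal(as.numeric(feAtom(cxN)[, c("x", "y", "z")]),
               as.numeric(feAtom(cx)[, c("x", "y", "z")]))

  expect_error(splitComplex(m, "B", "C"), "chain 'B'")
  noCu <- toyModel(a2[toupper(a2$element) != "CU", ])
  expect_error(splitComplex(noCu, "A", "C"), "one Cu")
})

test_that("selectCalpha returns one ordered coordinate per residue with CA", {
  atoms <- rbind(
    atomRow("N", "N", "ALA", "A", 2, 0, 0, 0),
    atomRow("CA", "C", "ALA", "A", 2, 1, 0, 0),
    atomRow("CA", "C", "GLY", "A", 1, 2, 0, 0),
    atomRow("CA", "C", "SER", "A", 3, 3, 0, 0),
    atomRow("CB", "C", "VAL", "A", 4, 4, 0, 0),   # residue without CA
    atomRow("CU", "CU", "CU", "A", 5, 5, 0, 0))   # cofactor ignored
  ca <- selectCalpha(toyModel(atoms))
  expect_equal(nrow(ca), 3L)                       # VAL 4 skipped
  expect_equal(attr(ca, "resno"), c(1L, 2L, 3L))   # residue-number order
  expect_equal(ca[, 1], c(2, 1, 3))
  expect_error(selectCalpha(toyModel(atoms[c(1, 6), ])), "no C-alpha")
})

test_that("selectWithinRadius matches a brute-force distance loop", {
  set.seed(21)
  n <- 100
  atoms <- do.call(rbind, lapply(seq_len(n), function(i)
    atomRow("CA", "C", "ALA", "A", i, rnorm(1, 0, 8), rnorm(1, 0, 8),
            rnorm(1, 0, 8))))
  m <- toyModel(atoms)
  center <- c(1, -2, 0.5)
  for (r in c(4, 8, 12)) {
    sel <- selectWithinRadius(m, center, r)
    d <- sqrt((atoms$x - center[1])^2 + (atoms$y - center[2])^2 +
              (atoms$z - center[3])^2)
    expect_setequal(atomTable(sel)$resno, atoms$resno[d <= r])
  }
  # monotone in radius
  s1 <- atomTable(selectWithinRadius(m, center, 6))$resno
  s2 <- atomTable(selectWithinRadius(m, center, 9))$resno
  expect_true(all(s1 %in% s2))
  expect_error(selectWithinRadius(m, c(1000, 0, 0), 1), "no atoms within")
  # radius 0.1 around an atom picks exactly that atom
  one <- selectWithinRadius(m, as.numeric(atoms[5, c("x", "y", "z")]), 0.1)
  expect_equal(atomTable(one)$resno, 5L)
})

test_that("center of mass matches the weighted-sum oracle and is equivariant", {
  set.seed(33)
  els <- sample(c("C", "N", "O", "S", "FE"), 20, TRUE)
  atoms <- do.call(rbind, lapply(1:20, function(i)
    atomRow("X", els[i], "UNK", "A", i, rnorm(1), rnorm(1), rnorm(1))))
  m <- toyModel(atoms)
  w <- edcscore:::elementMass(els)
  want <- c(sum(atoms$x * w), sum(atoms$y * w), sum(atoms$z * w)) / sum(w)
  expect_equal(centerOfMass(m), want, tolerance = 1e-12)
  expect_equal(centerOfMass(m, massWeighted = FALSE),
               colMeans(as.matrix(atoms[, c("x", "y", "z")])),
               ignore_attr = TRUE)
  # two equal masses at (0,0,0) and (2,0,0) -> midpoint
  two <- toyModel(rbind(atomRow("C", "C", "UNK", "A", 1, 0, 0, 0),
                        atomRow("C", "C", "UNK", "A", 2, 2, 0, 0)))
  expect_equal(centerOfMass(two), c(1, 0, 0))
  # equivariance under a rigid transform
  tr <- rigidTransform(randomRotation(), c(3, -1, 2))
  expect_equal(centerOfMass(applyTransform(m, tr)),
               as.numeric(applyTransform(matrix(centerOfMass(m), 1), tr)),
               tolerance = 1e-10)
})

test_that("hydrogens are excluded from the center of mass", {
  atoms <- rbind(atomRow("CA", "C", "ALA", "A", 1, 0, 0, 0),
                 atomRow("H", "H", "ALA", "A", 1, 100, 0, 0))
  expect_equal(centerOfMass(toyModel(atoms)), c(0, 0, 0))
})

test_that("C-alpha pairing falls back to sequence alignment across numbering", {
  # same fold, shifted residue numbering and one mutation
  n <- 20
  xyz <- cbind(3.8 * seq_len(n), sin(seq_len(n)), cos(seq_len(n)))
  res3 <- rep(c("ALA", "GLY", "SER", "VAL"), 5)
  a <- do.call(rbind, lapply(seq_len(n), function(i)
    atomRow("CA", "C", res3[i], "A", i, xyz[i, 1], xyz[i, 2], xyz[i, 3])))
  b <- do.call(rbind, lapply(seq_len(n), function(i)
    atomRow("CA", "C", res3[i], "A", i + 500L, xyz[i, 1], xyz[i, 2],
            xyz[i, 3])))
  pr <- edcscore:::pairCalpha(toyModel(a), toyModel(b), mode = "auto")
  expect_equal(nrow(pr$a), n)
  expect_equal(pr$a[, ], pr$b[, ], ignore_attr = TRUE)
  # resno mode on disjoint numbering fails loudly
  expect_error(edcscore:::pairCalpha(toyModel(a), toyModel(b), mode = "resno"),
               "no shared residue numbers")
})
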