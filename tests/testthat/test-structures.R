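test_that("a minimal glycine file parses into one chain of three atoms", {
  s <- readPdb(glycinePdb(), structureId = "gly")
  expect_s4_class(s, "ProteinStructure")
  expect_identical(chainIds(s), "A")
  rt <- residueTable(s)
  expect_identical(nrow(rt), 1L)
  expect_identical(rt$aa, "G")
  expect_identical(rt$n_atoms, 3L)
  a <- atomRecords(s)
  expect_identical(a$element, c("N", "C", "C"))
  expect_equal(a$radius, c(1.55, 1.70, 1.70))
})

test_that("multi-chain toy files report correct per-chain residue counts", {
  pdb <- generateToyStructure(15, c("A", "B"), seed = 7)
  s <- readPdb(pdb, structureId = "toy2")
  rt <- residueTable(s)
  expect_identical(sort(unique(rt$chain)), c("A", "B"))
  expect_identical(sum(rt$chain == "A"), 15L)
  expect_identical(sum(rt$chain == "B"), 15L)
})

test_that("HETATM-only input is an empty-structure error; waters drop", {
  het <- c(pdbAtomLine(1, "O", "HOH", "A", 1, c(0, 0, 0), rec = "HETATM"),
           "END")
  expect_error(readPdb(het, structureId = "het"), "empty structure")
  mixed <- c(glycinePdb()[1:3],
             pdbAtomLine(4, "O", "HOH", "A", 2, c(9, 9, 9), rec = "HETATM"),
             "END")
  s <- readPdb(mixed, structureId = "mix")
  expect_identical(nrow(atomRecords(s)), 3L)
})

test_that("highest-occupancy altloc wins, ties broken by file order", {
  lines <- c(
    pdbAtomLine(1, "CA", "ALA", "A", 1, c(0, 0, 0), occ = 0.4, alt = "A"),
    pdbAtomLine(2, "CA", "ALA", "A", 1, c(5, 0, 0), occ = 0.6, alt = "B"),
    pdbAtomLine(3, "CB", "ALA", "A", 1, c(1, 1, 0), occ = 0.5, alt = "A"),
    pdbAtomLine(4, "CB", "ALA", "A", 1, c(6, 1, 0), occ = 0.5, alt = "B"),
    "END")
  a <- atomRecords(readPdb(lines, structureId = "alt"))
  expect_identical(nrow(a), 2L)
  expect_equal(a$x[a$elety == "CA"], 5)  # occupancy 0.6 conformer
  expect_equal(a$x[a$elety == "CB"], 1)  # tie -> first in file
})

test_that("write/read round-trip preserves coordinates to 3 decimals", {
  s <- readPdb(generateToyStructure(10, "A", seed = 2), structureId = "rt")
  back <- readPdb(writePdb(s), structureId = "rt")
  expect_equal(atomRecords(back)$x, atomRecords(s)$x, tolerance = 1e-9)
  expect_equal(atomRecords(back)$y, atomRecords(s)$y, tolerance = 1e-9)
  expect_equal(atomRecords(back)$z, atomRecords(s)$z, tolerance = 1e-9)
  expect_identical(atomRecords(back)$resno, atomRecords(s)$resno)
})

test_that("nonnative residues outside the native range are stripped", {
  s <- readPdb(generateToyStructure(25, "A", seed = 1), structureId = "tag")
  # pretend residues 1-5 are a purification tag
  kept <- stripNonnative(s, c(6L, 25L))
  expect_identical(nrow(residueTable(kept)), 20L)
  expect_true(all(residueTable(kept)$resno >= 6L))
  empty <- stripNonnative(s, c(1000L, 2000L))
  expect_identical(nrow(atomRecords(empty)), 0L)
  expect_error(stripNonnative(s, c(10L, 5L)), "lo <= hi")
})

test_that("coverage map lists resolving chains per position", {
  ens <- list(rangeChain("s1", "A", 1L, 50L),
              rangeChain("s2", "A", 1L, 50L),
              rangeChain("s3", "A", 10L, 50L))
  cov <- coverageMap(ens)
  expect_identical(nrow(cov[["5"]]), 2L)
  expect_identical(sort(cov[["5"]]$structure_id), c("s1", "s2"))
  expect_identical(nrow(cov[["10"]]), 3L)
  expect_null(cov[["9999"]])
  # cardinalities sum to the total residue count over the ensemble
  expect_identical(sum(vapply(cov, nrow, integer(1))),
                   50L + 50L + 41L)
  # single chain: every resolved position maps to exactly that chain
  solo <- coverageMap(ens[1])
  expect_true(all(vapply(solo, function(d)
    identical(d$structure_id, "s1"), logical(1))))
})

test_that("Kabsch superposition recovers rigid motions exactly", {
  set.seed(11)
  pts <- matrix(rnorm(30, sd = 4), 10, 3)
  expect_equal(kabschSuperpose(pts, pts)$rmsd, 0, tolerance = 1e-12)
  R <- randomRotation(); tr <- c(3, -2, 7)
  moved <- pts %*% R + matrix(tr, 10, 3, byrow = TRUE)
  fit <- kabschSuperpose(moved, pts)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  # symmetry of the optimal RMSD in its arguments
  pert <- pts + matrix(rnorm(30, sd = 0.3), 10, 3)
  expect_equal(kabschSuperpose(pts, pert)$rmsd,
               kabschSuperpose(pert, pts)$rmsd, tolerance = 1e-9)
  # invariance under a joint rigid motion of both sets
  R2 <- randomRotation()
  expect_equal(kabschSuperpose(pts %*% R2, pert %*% R2)$rmsd,
               kabschSuperpose(pts, pert)$rmsd, tolerance = 1e-9)
})

test_that("Kabsch RMSD matches the rotation-grid-search oracle", {
  set.seed(21)
  base <- matrix(c(0, 0, 0, 3, 0, 0, 0, 3, 0, 1, 1, 2), 4, 3, byrow = TRUE)
  pert <- base + matrix(rnorm(12, sd = 0.25), 4, 3)
  fit <- kabschSuperpose(base, pert)
  oracle <- rmsdByGridSearch(base, pert)
  expect_equal(fit$rmsd, oracle, tolerance = 1e-3)
  expect_lte(fit$rmsd, oracle + 1e-9)  # SVD optimum can never be worse
})

test_that("degenerate point sets are rejected", {
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabschSuperpose(line, line + 0.1), "degenerate")
  same <- matrix(1, 4, 3)
  expect_error(kabschSuperpose(same, same), "degenerate")
  expect_error(kabschSuperpose(matrix(0, 2, 3), matrix(0, 2, 3)),
               "at least 3")
})

test_that("C-alpha superposition agrees with an independent implementation", {
  s1 <- readPdb(generateToyStructure(20, "A", seed = 5), structureId = "a")
  a <- atomRecords(s1)
  R <- randomRotation()
  xyz <- as.matrix(a[c("x", "y", "z")]) %*% R
  xyz <- xyz + matrix(rnorm(nrow(xyz) * 3, sd = 0.2), ncol = 3)
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  s2 <- new("ProteinStructure", structureId = "b", atoms = a,
            resolution = NA_real_)
  fit <- superposeCalpha(s2, s1)
  ca1 <- a[a$elety == "CA", ]
  orig <- atomRecords(s1); ca0 <- orig[orig$elety == "CA", ]
  M1 <- as.matrix(ca1[c("x", "y", "z")])
  M0 <- as.matrix(ca0[c("x", "y", "z")])
  ref <- bio3d::rot.lsq(as.vector(t(M1)), as.vector(t(M0)))
  refRmsd <- sqrt(mean(rowSums(
    (matrix(ref, ncol = 3, byrow = TRUE) - M0)^2)))
  expect_equal(fit$rmsd, refRmsd, tolerance = 1e-6)
})
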