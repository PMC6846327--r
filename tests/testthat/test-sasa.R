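test_that("an isolated atom matches the closed-form sphere area", {
  s <- sphereStructure(c(0, 0, 0))
  res <- shrakeRupley(s)
  expect_equal(sum(atomAreas(res)), 4 * pi * (1.7 + 1.4)^2,
               tolerance = 0.01)
  expect_error(shrakeRupley(s, nPoints = 8), ">= 16")
})

test_that("distant atoms do not occlude each other", {
  s <- sphereStructure(rbind(c(0, 0, 0), c(100, 0, 0)))
  areas <- atomAreas(shrakeRupley(s))
  iso <- 4 * pi * (1.7 + 1.4)^2
  expect_equal(areas, c(iso, iso), tolerance = 0.01)
})

test_that("two intersecting carbons match the spherical-cap closed form", {
  for (d in c(2.0, 3.5, 5.0)) {
    s <- sphereStructure(rbind(c(0, 0, 0), c(d, 0, 0)))
    areas <- atomAreas(shrakeRupley(s))
    oracle <- twoSphereCapAreas(1.7, 1.7, d)
    expect_equal(areas, oracle, tolerance = 0.01 * oracle[1])
  }
  # unequal radii (carbon against sulfur-sized sphere)
  s <- sphereStructure(rbind(c(0, 0, 0), c(2.5, 0, 0)))
  a <- atomRecords(s); a$radius <- c(1.7, 1.8)
  s2 <- new("ProteinStructure", structureId = "uneq", atoms = a)
  areas <- atomAreas(shrakeRupley(s2))
  oracle <- twoSphereCapAreas(1.7, 1.8, 2.5)
  expect_equal(areas[1], oracle[1], tolerance = 0.01 * oracle[1])
  expect_equal(areas[2], oracle[2], tolerance = 0.01 * oracle[2])
})

test_that("total SASA is invariant under rigid motion", {
  s <- readPdb(generateToyStructure(15, c("A", "B"), seed = 9),
               structureId = "inv")
  tot <- sum(atomAreas(shrakeRupley(s)))
  a <- atomRecords(s)
  # pure translation: exactly invariant with the fixed quadrature grid
  a2 <- a; a2$x <- a$x + 13.7; a2$y <- a$y - 4.2; a2$z <- a$z + 0.9
  sT <- new("ProteinStructure", structureId = "t", atoms = a2)
  expect_equal(sum(atomAreas(shrakeRupley(sT))), tot,
               tolerance = 1e-9)
  # rotation with a co-rotated quadrature frame: invariant to 1e-6 relative
  set.seed(4); R <- randomRotation()
  xyz <- as.matrix(a[c("x", "y", "z")]) %*% R
  a3 <- a; a3$x <- xyz[, 1]; a3$y <- xyz[, 2]; a3$z <- xyz[, 3]
  sR <- new("ProteinStructure", structureId = "r", atoms = a3)
  totR <- sum(atomAreas(shrakeRupley(sR, orientation = t(R))))
  expect_equal(totR, tot, tolerance = 1e-6)
  # plain re-run under rotation agrees only to quadrature error
  totRplain <- sum(atomAreas(shrakeRupley(sR)))
  expect_equal(totRplain, tot, tolerance = 0.01)
})

test_that("adding an atom can only reduce the area of existing atoms", {
  set.seed(31)
  for (rep in 1:5) {
    xyz <- matrix(rnorm(15, sd = 2.5), 5, 3)
    s5 <- sphereStructure(xyz)
    s6 <- sphereStructure(rbind(xyz, rnorm(3, sd = 2.5)))
    a5 <- atomAreas(shrakeRupley(s5))
    a6 <- atomAreas(shrakeRupley(s6))[1:5]
    expect_true(all(a6 <= a5 + 1e-9))
  }
})

test_that("quadrature converges: 960 vs 3840 points differ by <1%", {
  s <- readPdb(generateToyStructure(12, c("A", "B"), seed = 2),
               structureId = "conv")
  t1 <- sum(atomAreas(shrakeRupley(s, nPoints = 960)))
  t2 <- sum(atomAreas(shrakeRupley(s, nPoints = 3840)))
  expect_equal(t1, t2, tolerance = 0.01)
})

test_that("RSA is mean ASA over structures divided by the Tien maximum", {
  mk <- function(area, aa = "A", id = "x") {
    new("SasaResult", structureId = id, perAtom = area,
        perResidue = data.frame(chain = "A", resno = 10L, aa = aa,
                                area = area, stringsAsFactors = FALSE),
        probeRadius = 1.4, nPoints = 960L)
  }
  p1 <- rsaProfile(list(mk(64.5)))
  expect_equal(rsaTable(p1)$rsa, 64.5 / 129.0)
  # mean first, then normalise
  p2 <- rsaProfile(list(mk(80), mk(120)), scale = c(A = 200))
  expect_equal(rsaTable(p2)$rsa, 0.5)
  expect_identical(rsaTable(p2)$n_structures, 2L)
  expect_error(rsaProfile(list(mk(10, aa = "X"))), "missing from the max-ASA")
})

test_that("a core sphere inside a dense cluster has RSA near zero", {
  # central atom caged by 14 neighbours at 3.5 A: fully occluded
  dirs <- rbind(diag(3), -diag(3),
                cbind(c(1, 1, 1, 1, -1, -1, -1, -1), c(1, 1, -1, -1, 1, 1, -1, -1),
                      c(1, -1, 1, -1, 1, -1, 1, -1)) / sqrt(3))
  xyz <- rbind(c(0, 0, 0), dirs * 3.5)
  s <- sphereStructure(xyz)
  res <- shrakeRupley(s)
  scale <- maxAsaTien()
  rsaCore <- atomAreas(res)[1] / scale[["G"]]
  expect_lt(rsaCore, 0.02)
  # independent fine-grained sampling run agrees that the core is buried
  fine <- shrakeRupley(s, nPoints = 7680)
  expect_lt(atomAreas(fine)[1] / scale[["G"]], 0.02)
})

test_that("burial calls use a strict RSA threshold of 0.2", {
  expect_identical(isBuried(c(0.19, 0.20, 0)), c(TRUE, FALSE, TRUE))
  expect_identical(isBuried(0.25, threshold = 0.3), TRUE)
  expect_error(isBuried(-0.1), ">= 0")
})

test_that("binding can only occlude: dRSA <= 0 against the isolated chain", {
  cpx <- readPdb(generateToyStructure(14, c("A", "B"), seed = 6),
                 structureId = "cpx")
  iso <- new("ProteinStructure", structureId = "iso",
             atoms = subset(atomRecords(cpx), chain == "A"))
  profC <- rsaProfile(list(shrakeRupley(cpx)), chains = "A")
  profI <- rsaProfile(list(shrakeRupley(iso)))
  dr <- deltaRsa(profC, profI)
  expect_true(all(dr$delta_rsa <= 1e-9))
  # the constructed interface occludes at least one residue markedly
  expect_lt(min(dr$delta_rsa), -0.05)
  # identical profiles give all-zero differences
  dr0 <- deltaRsa(profI, profI)
  expect_true(all(dr0$delta_rsa == 0))
})

test_that("RSA TSV output carries the burial column", {
  s <- readPdb(generateToyStructure(10, "A", seed = 8), structureId = "io")
  prof <- rsaProfile(list(shrakeRupley(s)))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeRsaTsv(prof, path)
  back <- read.delim(path)
  expect_identical(names(back),
                   c("position", "aa", "mean_asa_A2", "rsa",
                     "n_structures", "buried"))
  expect_identical(back$buried, rsaTable(prof)$rsa < 0.2)
})
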