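# Independent oracles and small programmatic fixtures.

# Accessible area of each of two intersecting solvent-expanded spheres
# (radii R1, R2 = vdW + probe, centre distance d): full sphere minus the
# spherical cap buried inside the other sphere.
twoSphereCapAreas <- function(r1, r2, d, probe = 1.4) {
  R1 <- r1 + probe; R2 <- r2 + probe
  if (d >= R1 + R2) return(c(4 * pi * R1^2, 4 * pi * R2^2))
  x1 <- (d^2 + R1^2 - R2^2) / (2 * d)   # plane of intersection from centre 1
  h1 <- R1 - x1
  h2 <- R2 - (d - x1)
  c(4 * pi * R1^2 - 2 * pi * R1 * h1,
    4 * pi * R2^2 - 2 * pi * R2 * h2)
}

# Mann-Whitney pair concordance with ties counted 1/2, by exhaustive
# enumeration of all (positive, negative) pairs.
aucByPairEnumeration <- function(values, labels) {
  pos <- values[labels == "pathogenic"]
  neg <- values[labels == "benign"]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Brute-force confusion counts by scanning every item.
confusionByScan <- function(values, labels, threshold) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(values)) {
    call <- values[i] > threshold
    if (labels[i] == "pathogenic") {
      if (call) tp <- tp + 1L else fn <- fn + 1L
    } else {
      if (call) fp <- fp + 1L else tn <- tn + 1L
    }
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

# Best-fit RMSD by multi-stage grid search over Euler angles (independent
# of the SVD route). Translation handled by centroid alignment.
rmsdByGridSearch <- function(mobile, reference, stages = 5L) {
  Mc <- sweep(mobile, 2, colMeans(mobile))
  Rc <- sweep(reference, 2, colMeans(reference))
  rotZ <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0,
                               0, 0, 1), 3, 3)
  rotY <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0,
                               sin(a), 0, cos(a)), 3, 3)
  rmsdAt <- function(a, b, g) {
    R <- rotZ(a) %*% rotY(b) %*% rotZ(g)
    sqrt(mean(rowSums((Mc %*% R - Rc)^2)))
  }
  ctr <- c(pi, pi / 2, pi)
  span <- c(pi, pi / 2, pi)
  best <- c(ctr, rmsdAt(ctr[1], ctr[2], ctr[3]))
  for (s in seq_len(stages)) {
    as_ <- seq(ctr[1] - span[1], ctr[1] + span[1], length.out = 13)
    bs <- seq(max(0, ctr[2] - span[2]), min(pi, ctr[2] + span[2]),
              length.out = 13)
    gs <- seq(ctr[3] - span[3], ctr[3] + span[3], length.out = 13)
    for (a in as_) for (b in bs) for (g in gs) {
      r <- rmsdAt(a, b, g)
      if (r < best[4]) best <- c(a, b, g, r)
    }
    ctr <- best[1:3]
    span <- span / 5
  }
  best[4]
}

# A random proper rotation matrix.
randomRotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# Minimal hand-written PDB fixtures ---------------------------------------

pdbAtomLine <- function(serial, name, resn, chain, resno, xyz,
                        occ = 1, rec = "ATOM  ", alt = " ", elem = NULL) {
  if (is.null(elem)) elem <- substr(name, 1, 1)
  name4 <- if (nchar(name) < 4L) sprintf(" %-3s", name)
           else sprintf("%-4s", name)
  sprintf("%s%5d %s%s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, name4, alt, resn, chain, resno,
          xyz[1], xyz[2], xyz[3], occ, 0, elem)
}

glycinePdb <- function() {
  c(pdbAtomLine(1, "N", "GLY", "A", 1, c(0.000, 0.000, 0.000)),
    pdbAtomLine(2, "CA", "GLY", "A", 1, c(1.458, 0.000, 0.000)),
    pdbAtomLine(3, "C", "GLY", "A", 1, c(2.009, 1.420, 0.000)),
    "END")
}

# Structure holding arbitrary carbon spheres at given coordinates, one
# residue per atom.
sphereStructure <- function(xyz, radius = 1.7, id = "spheres") {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  new("ProteinStructure", structureId = id, atoms = data.frame(
    chain = "A", resno = seq_len(n), insert = "", resid = "GLY",
    aa = "G", elety = "CA", element = "C",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, radius = radius, stringsAsFactors = FALSE))
}

# Range-covering helix chains for coverage-map fixtures.
rangeChain <- function(id, chain, from, to) {
  s <- readPdb(generateToyStructure(to - from + 1L, "A", seed = 1),
               structureId = id)
  a <- atomRecords(s)
  a$resno <- a$resno + from - 1L
  a$chain <- chain
  list(structure = new("ProteinStructure", structureId = id, atoms = a,
                       resolution = NA_real_),
       chain = chain)
}
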