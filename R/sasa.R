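#' Quasi-uniform unit-sphere point set (golden spiral)
#'
#' Deterministic spherical Fibonacci lattice used as the quadrature grid of
#' the Shrake-Rupley calculation.
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
goldenSpiralPoints <- function(n) {
  stopifnot(n >= 1L)
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Solvent-accessible surface area by Shrake-Rupley sampling
#'
#' For every atom, a fixed quasi-uniform point set is placed on its
#' solvent-expanded sphere (radius `r + probeRadius`); a test point is
#' exposed iff it lies outside the solvent-expanded sphere of every other
#' atom, and the atom's area is the exposed fraction times the full sphere
#' area `4 pi (r + probe)^2`. Per-residue areas are the sums over the
#' residue's atoms.
#'
#' Because the quadrature grid is fixed in space, the estimator is exactly
#' invariant under translation but only approximately (to quadrature error)
#' under rotation of the input; passing the same rotation as `orientation`
#' co-rotates the grid and restores exact invariance.
#'
#' @param s a [ProteinStructure-class].
#' @param probeRadius solvent probe radius in Angstrom (default 1.4, water).
#' @param nPoints quadrature points per atom (default 960; minimum 16).
#' @param ignoreH drop hydrogen atoms before the calculation (default
#'   `TRUE`; crystal structures generally lack them).
#' @param orientation optional 3 x 3 rotation applied to the quadrature
#'   grid (see above).
#' @return a [SasaResult-class].
#' @export
#' @examples
#' # a single carbon atom: area = 4*pi*(1.7+1.4)^2
#' s <- new("ProteinStructure", structureId = "one", atoms = data.frame(
#'   chain = "A", resno = 1L, insert = "", resid = "GLY", aa = "G",
#'   elety = "CA", element = "C", x = 0, y = 0, z = 0,
#'   occupancy = 1, radius = 1.7))
#' sum(atomAreas(shrakeRupley(s)))
shrakeRupley <- function(s, probeRadius = 1.4, nPoints = 960L,
                         ignoreH = TRUE, orientation = NULL) {
  stopifnot(is(s, "ProteinStructure"))
  if (nPoints < 16L) stop("nPoints must be >= 16")
  a <- atomRecords(s)
  if (ignoreH) a <- a[a$element != "H", , drop = FALSE]
  if (nrow(a) == 0L) stop("structure has no atoms to analyse")
  pts <- goldenSpiralPoints(as.integer(nPoints))
  if (!is.null(orientation)) {
    orientation <- as.matrix(orientation)
    stopifnot(all(dim(orientation) == c(3L, 3L)))
    pts <- pts %*% t(orientation)
  }
  xyz <- as.matrix(a[c("x", "y", "z")])
  expanded <- a$radius + probeRadius
  nAtoms <- nrow(a)
  areas <- numeric(nAtoms)
  for (i in seq_len(nAtoms)) {
    ri <- expanded[i]
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (ri + expanded)^2 & seq_len(nAtoms) != i)
    if (length(nb) == 0L) {
      areas[i] <- 4 * pi * ri^2
      next
    }
    p <- pts * ri
    p[, 1] <- p[, 1] + xyz[i, 1]
    p[, 2] <- p[, 2] + xyz[i, 2]
    p[, 3] <- p[, 3] + xyz[i, 3]
    exposed <- rep(TRUE, nPoints)
    # nearest occluders first: most points are decided early
    nb <- nb[order(d2[nb])]
    for (j in nb) {
      if (!any(exposed)) break
      rj2 <- expanded[j]^2
      idx <- which(exposed)
      dj2 <- (p[idx, 1] - xyz[j, 1])^2 + (p[idx, 2] - xyz[j, 2])^2 +
        (p[idx, 3] - xyz[j, 3])^2
      exposed[idx[dj2 < rj2]] <- FALSE
    }
    areas[i] <- sum(exposed) / nPoints * 4 * pi * ri^2
  }
  key <- paste(a$chain, a$resno, a$insert, sep = "\r")
  first <- !duplicated(key)
  perRes <- data.frame(chain = a$chain[first], resno = a$resno[first],
                       aa = a$aa[first],
                       area = as.vector(tapply(areas, key, sum)[key[first]]),
                       stringsAsFactors = FALSE)
  perRes <- perRes[order(perRes$chain, perRes$resno), , drop = FALSE]
  rownames(perRes) <- NULL
  new("SasaResult", structureId = structureId(s), perAtom = areas,
      perResidue = perRes, probeRadius = probeRadius,
      nPoints = as.integer(nPoints))
}

#' Relative solvent accessibility across representative structures
#'
#' For each residue position, the absolute per-residue ASA is averaged over
#' the structures resolving that position, then divided by the
#' residue-type theoretical maximum ASA (Tien scale) to give RSA. RSA may
#' exceed 1 and is reported uncapped.
#'
#' @param results list of [SasaResult-class] objects (one per
#'   representative structure/chain); positions are pooled by residue
#'   number across all chains present.
#' @param scale named numeric vector mapping one-letter residue codes to
#'   maximum ASA (default [maxAsaTien()]).
#' @param chains optional chain filter applied to every result.
#' @param buriedThreshold RSA threshold recorded in the profile
#'   (default 0.2).
#' @return an [RsaProfile-class].
#' @export
rsaProfile <- function(results, scale = maxAsaTien(), chains = NULL,
                       buriedThreshold = 0.2) {
  stopifnot(is.list(results), length(results) >= 1L,
            all(vapply(results, is, logical(1), "SasaResult")))
  recs <- lapply(results, function(r) {
    pr <- residueAreas(r)
    if (!is.null(chains)) pr <- pr[pr$chain %in% chains, , drop = FALSE]
    pr
  })
  long <- do.call(rbind, recs)
  if (nrow(long) == 0L) stop("no residues selected for the RSA profile")
  unknown <- setdiff(unique(long$aa), names(scale))
  if (length(unknown) > 0L)
    stop("residue type(s) missing from the max-ASA scale: ",
         paste(unknown, collapse = ", "))
  agg <- aggregate(long["area"], by = long[c("resno", "aa")], FUN = mean)
  cnt <- aggregate(list(n = long$area), by = long[c("resno", "aa")],
                   FUN = length)
  agg <- merge(agg, cnt, by = c("resno", "aa"))
  agg <- agg[order(agg$resno), , drop = FALSE]
  prof <- data.frame(position = as.integer(agg$resno), aa = agg$aa,
                     mean_asa = agg$area,
                     rsa = agg$area / unname(scale[agg$aa]),
                     n_structures = as.integer(agg$n),
                     stringsAsFactors = FALSE)
  rownames(prof) <- NULL
  new("RsaProfile", profile = prof, buriedThreshold = buriedThreshold)
}

#' Classify burial from relative solvent accessibility
#'
#' A residue is buried (solvent-inaccessible) when its RSA falls strictly
#' below the threshold, 0.2 by default.
#'
#' @param rsa numeric vector of RSA values (>= 0).
#' @param threshold burial threshold (default 0.2).
#' @return logical vector.
#' @export
#' @examples
#' isBuried(c(0.19, 0.2))  # TRUE FALSE
isBuried <- function(rsa, threshold = 0.2) {
  if (any(rsa < 0, na.rm = TRUE)) stop("RSA values must be >= 0")
  rsa < threshold
}

#' Per-position RSA difference between complexed and isolated chains
#'
#' `dRSA = RSA(complex) - RSA(isolated)`; interface residues occluded by a
#' binding partner show negative values. Positions absent from either
#' profile are dropped.
#'
#' @param complexProfile,isolatedProfile [RsaProfile-class] objects sharing
#'   one residue numbering.
#' @return data.frame with columns `position`, `rsa_complex`,
#'   `rsa_isolated`, `delta_rsa`.
#' @export
deltaRsa <- function(complexProfile, isolatedProfile) {
  stopifnot(is(complexProfile, "RsaProfile"),
            is(isolatedProfile, "RsaProfile"))
  pc <- rsaTable(complexProfile)
  pi_ <- rsaTable(isolatedProfile)
  m <- merge(pc[c("position", "rsa")], pi_[c("position", "rsa")],
             by = "position", suffixes = c("_complex", "_isolated"))
  out <- data.frame(position = m$position,
                    rsa_complex = m$rsa_complex,
                    rsa_isolated = m$rsa_isolated,
                    delta_rsa = m$rsa_complex - m$rsa_isolated)
  out[order(out$position), , drop = FALSE]
}

#' Write an RSA profile as TSV
#'
#' Columns: `position, aa, mean_asa_A2, rsa, n_structures, buried`.
#'
#' @param profile an [RsaProfile-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeRsaTsv <- function(profile, path) {
  stopifnot(is(profile, "RsaProfile"))
  p <- rsaTable(profile)
  out <- data.frame(position = p$position, aa = p$aa,
                    mean_asa_A2 = p$mean_asa, rsa = p$rsa,
                    n_structures = p$n_structures,
                    buried = isBuried(p$rsa, profile@buriedThreshold))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
  invisible(path)
}
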