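#' ProteinStructure: atoms of a parsed structure
#'
#' Container for one structure parsed from a PDB file. Atoms are stored as a
#' flat data.frame (one row per atom) with columns `chain`, `resno`, `insert`,
#' `resid` (three-letter), `aa` (one-letter, `X` for nonstandard), `elety`
#' (atom name), `element`, `x`, `y`, `z` (Angstrom), `occupancy` and `radius`
#' (van der Waals, Angstrom).
#'
#' @slot structureId PDB-style identifier.
#' @slot atoms data.frame of atom records as described above.
#' @slot resolution numeric, crystallographic resolution in Angstrom
#'   (`NA_real_` when unknown).
#' @export
setClass("ProteinStructure",
         representation(structureId = "character",
                        atoms = "data.frame",
                        resolution = "numeric"),
         prototype(structureId = "unknown",
                   atoms = data.frame(),
                   resolution = NA_real_))

setValidity("ProteinStructure", function(object) {
  need <- c("chain", "resno", "insert", "resid", "aa", "elety",
            "element", "x", "y", "z", "occupancy", "radius")
  a <- object@atoms
  # zero-atom structures are representable (e.g. after stripping every
  # residue); parsers are responsible for rejecting empty input
  if (nrow(a) == 0L) return(TRUE)
  miss <- setdiff(need, names(a))
  if (length(miss) > 0L)
    return(paste("atoms table missing columns:", paste(miss, collapse = ", ")))
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("atom coordinates must be finite")
  if (!all(a$radius > 0)) return("atom radii must be positive")
  TRUE
})

#' SasaResult: solvent-accessible surface areas for one structure
#'
#' @slot structureId identifier of the structure the areas belong to.
#' @slot perAtom numeric vector of per-atom areas (Angstrom^2), parallel to
#'   the atoms table used in the calculation.
#' @slot perResidue data.frame with columns `chain`, `resno`, `aa`, `area`.
#' @slot probeRadius solvent probe radius (Angstrom).
#' @slot nPoints number of quadrature points per atom.
#' @export
setClass("SasaResult",
         representation(structureId = "character",
                        perAtom = "numeric",
                        perResidue = "data.frame",
                        probeRadius = "numeric",
                        nPoints = "integer"))

setValidity("SasaResult", function(object) {
  if (any(object@perAtom < -1e-9)) return("per-atom areas must be >= 0")
  if (any(object@perResidue$area < -1e-9)) return("per-residue areas must be >= 0")
  if (object@probeRadius < 0) return("probe radius must be >= 0")
  TRUE
})

#' RsaProfile: relative solvent accessibility per residue position
#'
#' Mean absolute ASA across the structures resolving each position, divided
#' by the residue-type theoretical maximum (Tien scale). RSA may exceed 1
#' and is reported uncapped.
#'
#' @slot profile data.frame with columns `position`, `aa`, `mean_asa`,
#'   `rsa`, `n_structures`.
#' @slot buriedThreshold RSA below which a residue is called buried
#'   (default 0.2, strict inequality).
#' @export
setClass("RsaProfile",
         representation(profile = "data.frame",
                        buriedThreshold = "numeric"),
         prototype(buriedThreshold = 0.2))

setValidity("RsaProfile", function(object) {
  p <- object@profile
  need <- c("position", "aa", "mean_asa", "rsa", "n_structures")
  miss <- setdiff(need, names(p))
  if (length(miss) > 0L)
    return(paste("profile missing columns:", paste(miss, collapse = ", ")))
  if (nrow(p) > 0L && any(p$n_structures < 1L))
    return("every reported position needs n_structures >= 1")
  if (nrow(p) > 0L && any(p$rsa < 0)) return("rsa must be >= 0")
  TRUE
})

#' ConfusionCounts: 2x2 classification counts
#'
#' @slot tp,fp,tn,fn non-negative integer counts.
#' @export
setClass("ConfusionCounts",
         representation(tp = "integer", fp = "integer",
                        tn = "integer", fn = "integer"))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@fp, object@tn, object@fn)
  if (any(is.na(v)) || any(v < 0L)) return("counts must be non-negative integers")
  TRUE
})

#' RocCurve: receiver operating characteristic curve with AUC
#'
#' @slot points data.frame with columns `threshold`, `fpr`, `tpr`; rows
#'   ordered from (0,0) to (1,1), both coordinates nondecreasing. Tied
#'   scores are grouped, producing diagonal segments.
#' @slot auc area under the curve by trapezoidal integration, in `[0,1]`;
#'   equals the Mann-Whitney pair-concordance probability with ties
#'   counted 1/2.
#' @export
setClass("RocCurve",
         representation(points = "data.frame", auc = "numeric"))

setValidity("RocCurve", function(object) {
  p <- object@points
  if (!all(c("threshold", "fpr", "tpr") %in% names(p)))
    return("points needs columns threshold, fpr, tpr")
  if (object@auc < -1e-12 || object@auc > 1 + 1e-12) return("auc must lie in [0,1]")
  if (nrow(p) > 0L) {
    if (is.unsorted(p$fpr) || is.unsorted(p$tpr))
      return("fpr and tpr must be nondecreasing")
    if (abs(p$fpr[1]) > 1e-12 || abs(p$tpr[1]) > 1e-12)
      return("curve must start at (0,0)")
    n <- nrow(p)
    if (abs(p$fpr[n] - 1) > 1e-12 || abs(p$tpr[n] - 1) > 1e-12)
      return("curve must end at (1,1)")
  }
  TRUE
})

#' SyntheticConfig: parameters of the synthetic cohort generator
#'
#' Defaults encode the study conditions the generator emulates: two
#' Gaussian ddG groups (pathogenic mean 5.06, SD 4.25; benign mean 1.13,
#' SD 1.46 kcal/mol) of 161 variants each, per-structure observation noise
#' of SD 0.8 kcal/mol, an ensemble of 31 chains with 95% of variants
#' resolved in all chains and the remainder in one, a buried-RSA mixture
#' for pathogenic variants (Beta(2,8) with probability 0.863, else
#' uniform), and REVEL-like scores increasing in the latent ddG.
#'
#' @slot nPathogenic,nBenign cohort sizes.
#' @slot ddgMeanPath,ddgSdPath,ddgMeanBenign,ddgSdBenign group ddG
#'   distribution parameters (kcal/mol).
#' @slot buriedFractionPath probability a pathogenic variant draws its RSA
#'   from the buried Beta(2,8) component.
#' @slot nStructures ensemble size (chains).
#' @slot fullCoverageFraction fraction of variants resolved in every chain;
#'   the rest are resolved in a single chain.
#' @slot perStructureNoiseSd SD of per-structure observation noise (kcal/mol).
#' @slot revelNoiseSd SD of the additive noise on the logistic REVEL model.
#' @slot proteinLength number of residue positions available (610).
#' @slot seed integer RNG seed; the generator is deterministic given it.
#' @export
setClass("SyntheticConfig",
         representation(nPathogenic = "integer",
                        nBenign = "integer",
                        ddgMeanPath = "numeric",
                        ddgSdPath = "numeric",
                        ddgMeanBenign = "numeric",
                        ddgSdBenign = "numeric",
                        buriedFractionPath = "numeric",
                        nStructures = "integer",
                        fullCoverageFraction = "numeric",
                        perStructureNoiseSd = "numeric",
                        revelNoiseSd = "numeric",
                        proteinLength = "integer",
                        seed = "integer"),
         prototype(nPathogenic = 161L,
                   nBenign = 161L,
                   ddgMeanPath = 5.06,
                   ddgSdPath = 4.25,
                   ddgMeanBenign = 1.13,
                   ddgSdBenign = 1.46,
                   buriedFractionPath = 0.863,
                   nStructures = 31L,
                   fullCoverageFraction = 0.95,
                   perStructureNoiseSd = 0.8,
                   revelNoiseSd = 0.15,
                   proteinLength = 610L,
                   seed = 1L))

setValidity("SyntheticConfig", function(object) {
  if (object@nPathogenic < 0L || object@nBenign < 0L)
    return("group sizes must be >= 0")
  if (object@ddgSdPath <= 0 || object@ddgSdBenign <= 0)
    return("group SDs must be > 0")
  if (object@buriedFractionPath < 0 || object@buriedFractionPath > 1)
    return("buriedFractionPath must lie in [0,1]")
  if (object@fullCoverageFraction < 0 || object@fullCoverageFraction > 1)
    return("fullCoverageFraction must lie in [0,1]")
  if (object@perStructureNoiseSd < 0) return("perStructureNoiseSd must be >= 0")
  if (object@nStructures < 1L) return("nStructures must be >= 1")
  TRUE
})
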