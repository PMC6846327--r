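#' @describeIn ProteinStructure-class identifier of the structure.
#' @export
setMethod("structureId", "ProteinStructure", function(object) object@structureId)

#' @describeIn ProteinStructure-class the flat atom table (one row per atom).
#' @export
setMethod("atomRecords", "ProteinStructure", function(object) object@atoms)

#' @describeIn ProteinStructure-class chain identifiers present.
#' @export
setMethod("chainIds", "ProteinStructure",
          function(object) sort(unique(object@atoms$chain)))

#' @describeIn ProteinStructure-class one row per residue: `chain`, `resno`,
#'   `insert`, `aa`, `n_atoms`.
#' @export
setMethod("residueTable", "ProteinStructure", function(object) {
  a <- object@atoms
  key <- paste(a$chain, a$resno, a$insert, sep = "\r")
  first <- !duplicated(key)
  out <- data.frame(chain = a$chain[first],
                    resno = a$resno[first],
                    insert = a$insert[first],
                    aa = a$aa[first],
                    n_atoms = as.vector(table(key)[key[first]]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chain, out$resno, out$insert), , drop = FALSE]
  rownames(out) <- NULL
  out
})

setMethod("show", "ProteinStructure", function(object) {
  rt <- residueTable(object)
  cat("ProteinStructure '", object@structureId, "': ",
      nrow(object@atoms), " atoms, ", nrow(rt), " residues, chains ",
      paste(chainIds(object), collapse = ","), "\n", sep = "")
  if (!is.na(object@resolution))
    cat("  resolution: ", object@resolution, " A\n", sep = "")
})

#' @describeIn SasaResult-class per-residue areas (`chain`, `resno`, `aa`,
#'   `area` in Angstrom^2).
#' @export
setMethod("residueAreas", "SasaResult", function(object) object@perResidue)

#' @describeIn SasaResult-class per-atom areas (Angstrom^2).
#' @export
setMethod("atomAreas", "SasaResult", function(object) object@perAtom)

setMethod("show", "SasaResult", function(object) {
  cat("SasaResult for '", object@structureId, "': total ",
      round(sum(object@perAtom), 1), " A^2 over ", length(object@perAtom),
      " atoms (probe ", object@probeRadius, " A, ", object@nPoints,
      " points)\n", sep = "")
})

#' @describeIn RsaProfile-class the per-position profile data.frame.
#' @export
setMethod("rsaTable", "RsaProfile", function(object) object@profile)

setMethod("show", "RsaProfile", function(object) {
  p <- object@profile
  cat("RsaProfile: ", nrow(p), " positions, ",
      sum(p$rsa < object@buriedThreshold), " buried (RSA < ",
      object@buriedThreshold, ")\n", sep = "")
})

#' @describeIn RocCurve-class the (threshold, fpr, tpr) table.
#' @export
setMethod("rocPoints", "RocCurve", function(object) object@points)

#' @describeIn RocCurve-class area under the curve.
#' @export
setMethod("aucValue", "RocCurve", function(object) object@auc)

setMethod("show", "RocCurve", function(object) {
  cat("RocCurve: ", nrow(object@points), " points, AUC = ",
      format(object@auc, digits = 4), "\n", sep = "")
})

setMethod("show", "ConfusionCounts", function(object) {
  cat("ConfusionCounts: TP=", object@tp, " FP=", object@fp,
      " TN=", object@tn, " FN=", object@fn, "\n", sep = "")
})

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig: ", object@nPathogenic, " pathogenic / ",
      object@nBenign, " benign variants, ", object@nStructures,
      " chains, seed ", object@seed, "\n", sep = "")
  cat("  ddG pathogenic ~ N(", object@ddgMeanPath, ", ",
      object@ddgSdPath, "^2), benign ~ N(", object@ddgMeanBenign, ", ",
      object@ddgSdBenign, "^2) kcal/mol\n", sep = "")
})
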