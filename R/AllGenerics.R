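#' @rdname ProteinStructure-class
#' @param object a package object.
#' @export
setGeneric("structureId", function(object) standardGeneric("structureId"))

#' @rdname ProteinStructure-class
#' @export
setGeneric("atomRecords", function(object) standardGeneric("atomRecords"))

#' @rdname ProteinStructure-class
#' @export
setGeneric("chainIds", function(object) standardGeneric("chainIds"))

#' @rdname ProteinStructure-class
#' @export
setGeneric("residueTable", function(object) standardGeneric("residueTable"))

#' @rdname SasaResult-class
#' @param object a package object.
#' @export
setGeneric("residueAreas", function(object) standardGeneric("residueAreas"))

#' @rdname SasaResult-class
#' @export
setGeneric("atomAreas", function(object) standardGeneric("atomAreas"))

#' @rdname RsaProfile-class
#' @param object a package object.
#' @export
setGeneric("rsaTable", function(object) standardGeneric("rsaTable"))

#' @rdname RocCurve-class
#' @param object a package object.
#' @export
setGeneric("rocPoints", function(object) standardGeneric("rocPoints"))

#' @rdname RocCurve-class
#' @export
setGeneric("aucValue", function(object) standardGeneric("aucValue"))

#' @rdname ConfusionCounts-class
#' @param object a package object.
#' @export
setGeneric("classificationMetrics",
           function(object) standardGeneric("classificationMetrics"))
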