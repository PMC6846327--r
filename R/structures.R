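#' Read a protein structure from a PDB file
#'
#' Parses fixed-width `ATOM` records (via \pkg{bio3d}) into a
#' [ProteinStructure-class] object. `HETATM` records and waters are
#' excluded; for alternate locations the highest-occupancy conformer is
#' kept (ties broken by file order); only the first `MODEL` of multi-model
#' files is read. Element symbols are taken from the element column when
#' present and inferred from the atom name otherwise; van der Waals radii
#' are attached per element from `radii`.
#'
#' @param input a file path, or a character vector of PDB-format lines.
#' @param structureId identifier to record; defaults to the file base name.
#' @param radii named numeric vector of van der Waals radii by element
#'   (default [defaultVdwRadii()]); unknown elements get 1.70 A with a
#'   warning.
#' @return a [ProteinStructure-class].
#' @export
readPdb <- function(input, structureId = NULL, radii = defaultVdwRadii()) {
  if (length(input) > 1L || grepl("\n", input[1], fixed = TRUE) ||
      grepl("^(ATOM|HETATM|MODEL|REMARK|HEADER)", input[1])) {
    lines <- unlist(strsplit(input, "\n", fixed = TRUE))
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(lines, path)
    if (is.null(structureId)) structureId <- "inline"
  } else {
    path <- input
    lines <- readLines(path, warn = FALSE)
    if (is.null(structureId))
      structureId <- sub("\\.(pdb|ent)$", "", basename(path))
  }
  # keep only the first model of multi-model files
  mdl <- grep("^MODEL", lines)
  if (length(mdl) > 1L) {
    endmdl <- grep("^ENDMDL", lines)
    if (length(endmdl) >= 1L) lines <- lines[seq_len(endmdl[1])]
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(lines, path)
  }
  if (!any(grepl("^ATOM  ", lines)))
    stop("empty structure: no ATOM records in '", structureId, "'")
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE,
                                          rm.alt = FALSE, hex = FALSE,
                                          verbose = FALSE))
  a <- pdb$atom
  a <- a[a$type == "ATOM", , drop = FALSE]
  a <- a[!(a$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (nrow(a) == 0L)
    stop("empty structure: no ATOM records in '", structureId, "'")
  if (any(!is.finite(a$x) | !is.finite(a$y) | !is.finite(a$z)))
    stop("malformed PDB: non-numeric coordinates in '", structureId, "'")
  a$insert[is.na(a$insert)] <- ""
  a$alt[is.na(a$alt)] <- ""
  a$o[is.na(a$o)] <- 1.0
  # altloc policy: highest occupancy, tie broken by file order
  if (any(a$alt != "")) {
    key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "\r")
    ord <- order(-a$o, seq_len(nrow(a)))
    keep <- ord[!duplicated(key[ord])]
    a <- a[sort(keep), , drop = FALSE]
  }
  element <- a$elesy
  if (is.null(element)) element <- rep(NA_character_, nrow(a))
  element <- toupper(trimws(element))
  blank <- is.na(element) | element == ""
  element[blank] <- inferElement(a$elety[blank])
  radius <- unname(radii[element])
  if (any(is.na(radius))) {
    warning("unknown element(s) ",
            paste(unique(element[is.na(radius)]), collapse = ", "),
            "; using radius 1.70 A")
    radius[is.na(radius)] <- 1.70
  }
  aa <- AA3TO1[a$resid]
  aa[is.na(aa)] <- "X"
  atoms <- data.frame(chain = a$chain, resno = as.integer(a$resno),
                      insert = a$insert, resid = a$resid, aa = unname(aa),
                      elety = a$elety, element = element,
                      x = a$x, y = a$y, z = a$z,
                      occupancy = a$o, radius = radius,
                      stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  res <- parseResolution(lines)
  new("ProteinStructure", structureId = structureId, atoms = atoms,
      resolution = res)
}

parseResolution <- function(lines) {
  rl <- grep("^REMARK   2 RESOLUTION\\.", lines, value = TRUE)
  if (length(rl) == 0L) return(NA_real_)
  m <- regmatches(rl[1], regexpr("[0-9]+\\.[0-9]+", rl[1]))
  if (length(m) == 0L) NA_real_ else as.numeric(m)
}

#' Write a ProteinStructure as fixed-width PDB text
#'
#' @param s a [ProteinStructure-class].
#' @param path optional output file; when `NULL` the lines are returned.
#' @return character vector of PDB lines (invisibly when `path` is given).
#' @export
writePdb <- function(s, path = NULL) {
  stopifnot(is(s, "ProteinStructure"))
  a <- atomRecords(s)
  name4 <- ifelse(nchar(a$elety) < 4L,
                  sprintf(" %-3s", a$elety), sprintf("%-4s", a$elety))
  lines <- sprintf(
    "ATOM  %5d %s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)), name4, a$resid,
    a$chain, a$resno, ifelse(a$insert == "", " ", a$insert),
    a$x, a$y, a$z, a$occupancy, 0, a$element)
  lines <- c(lines, "END")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Remove nonnative residues from a structure
#'
#' Crystal constructs often contain residues that are not part of the
#' native sequence (affinity purification tags, cloning artifacts);
#' residues with author numbering outside `nativeRange` are removed before
#' analysis. Chains left empty are dropped.
#'
#' @param s a [ProteinStructure-class].
#' @param nativeRange integer vector `c(lo, hi)` of native residue numbers.
#' @return a [ProteinStructure-class] (possibly with zero atoms).
#' @export
stripNonnative <- function(s, nativeRange) {
  stopifnot(is(s, "ProteinStructure"), length(nativeRange) == 2L)
  lo <- nativeRange[1]; hi <- nativeRange[2]
  if (lo > hi) stop("nativeRange must satisfy lo <= hi")
  a <- atomRecords(s)
  a <- a[a$resno >= lo & a$resno <= hi, , drop = FALSE]
  rownames(a) <- NULL
  new("ProteinStructure", structureId = structureId(s), atoms = a,
      resolution = s@resolution)
}

#' Residue coverage across a structure ensemble
#'
#' For each residue position, lists the ensemble members (structure chain
#' pairs) in which that position is resolved. All chains must share one
#' numbering; insertion codes are rejected to keep position keys integral.
#'
#' @param ensemble a list whose elements are lists with components
#'   `structure` (a [ProteinStructure-class]) and `chain` (chain id; all
#'   chains of the structure when omitted).
#' @return named list: for each resolved position (name = position), a
#'   data.frame with columns `structure_id`, `chain_id`. Positions resolved
#'   nowhere are absent.
#' @export
coverageMap <- function(ensemble) {
  stopifnot(is.list(ensemble), length(ensemble) >= 1L)
  recs <- lapply(ensemble, function(e) {
    stopifnot(is.list(e), is(e$structure, "ProteinStructure"))
    rt <- residueTable(e$structure)
    if (!is.null(e$chain)) rt <- rt[rt$chain %in% e$chain, , drop = FALSE]
    if (any(rt$insert != ""))
      stop("coverageMap does not support insertion codes (structure '",
           structureId(e$structure), "')")
    if (nrow(rt) == 0L) return(NULL)
    data.frame(position = rt$resno,
               structure_id = structureId(e$structure),
               chain_id = rt$chain, stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, recs)
  if (is.null(long) || nrow(long) == 0L) return(list())
  long <- unique(long)
  split(long[c("structure_id", "chain_id")],
        factor(long$position, levels = sort(unique(long$position))))
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation (det = +1) and translation minimising the
#' root-mean-square deviation between paired point sets, via singular value
#' decomposition of the covariance matrix.
#'
#' @param mobile,reference numeric n x 3 matrices of paired coordinates
#'   (n >= 3, non-degenerate).
#' @return list with `rotation` (3 x 3, applied on the right to row-vector
#'   coordinates), `translation` (length-3), and `rmsd` (Angstrom), such
#'   that `mobile %*% rotation + translation` best fits `reference`.
#' @export
#' @examples
#' pts <- matrix(rnorm(12), 4, 3)
#' kabschSuperpose(pts, pts)$rmsd  # 0
kabschSuperpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (ncol(mobile) != 3L || ncol(reference) != 3L)
    stop("point sets must be n x 3 matrices")
  n <- nrow(mobile)
  if (nrow(reference) != n) stop("point sets must have equal length")
  if (n < 3L) stop("need at least 3 paired points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  M <- sweep(mobile, 2, cm); R <- sweep(reference, 2, cr)
  H <- crossprod(M, R)
  sv <- svd(H)
  scale <- max(sqrt(rowSums(M^2)))
  if (scale == 0 || sv$d[2] / max(sv$d[1], .Machine$double.eps) < 1e-8)
    stop("degenerate point set (coincident or collinear points)")
  d <- sign(det(sv$u %*% t(sv$v)))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- M %*% rot
  rmsd <- sqrt(mean(rowSums((fitted - R)^2)))
  list(rotation = rot, translation = as.vector(cr - cm %*% rot), rmsd = rmsd)
}

#' Superpose two structures on shared C-alpha atoms
#'
#' Pairs residues by number intersection within the given chains, extracts
#' C-alpha coordinates and calls [kabschSuperpose()].
#'
#' @param mobile,reference [ProteinStructure-class] objects.
#' @param chainMobile,chainReference chain ids (first chain by default).
#' @return as [kabschSuperpose()], plus `n_atoms` used.
#' @export
superposeCalpha <- function(mobile, reference,
                            chainMobile = NULL, chainReference = NULL) {
  getCa <- function(s, chain) {
    a <- atomRecords(s)
    if (is.null(chain)) chain <- chainIds(s)[1]
    a <- a[a$chain == chain & a$elety == "CA", , drop = FALSE]
    a[!duplicated(a$resno), , drop = FALSE]
  }
  am <- getCa(mobile, chainMobile)
  ar <- getCa(reference, chainReference)
  shared <- intersect(am$resno, ar$resno)
  if (length(shared) < 3L)
    stop("fewer than 3 shared C-alpha positions between the structures")
  am <- am[match(shared, am$resno), ]
  ar <- ar[match(shared, ar$resno), ]
  fit <- kabschSuperpose(as.matrix(am[c("x", "y", "z")]),
                         as.matrix(ar[c("x", "y", "z")]))
  fit$n_atoms <- length(shared)
  fit
}
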