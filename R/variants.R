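#' Assign a variant group from database membership
#'
#' Implements the grouping rule for inherited missense variants:
#' *pathogenic* = disease-mutation (DM) class in HGMD but absent from both
#' population databases (gnomAD, SGCD); *benign* = present in a population
#' database but not DM class; *uncertain* = DM class and present in a
#' population database; *unlabeled* = reported nowhere. The *novel* label is
#' reserved for variants supplied explicitly as novel and is never produced
#' by this rule.
#'
#' @param inHgmdDm logical, DM-class record in HGMD.
#' @param inGnomad logical, present in gnomAD.
#' @param inSgcd logical, present in SGCD.
#' @return character vector over
#'   `{"pathogenic","benign","uncertain","unlabeled"}`; vectorised,
#'   inputs recycled to common length.
#' @export
#' @examples
#' assignGroup(TRUE, FALSE, FALSE)   # pathogenic
#' assignGroup(FALSE, TRUE, TRUE)    # benign
assignGroup <- function(inHgmdDm, inGnomad, inSgcd) {
  n <- max(length(inHgmdDm), length(inGnomad), length(inSgcd))
  inHgmdDm <- rep_len(as.logical(inHgmdDm), n)
  inGnomad <- rep_len(as.logical(inGnomad), n)
  inSgcd <- rep_len(as.logical(inSgcd), n)
  inPop <- inGnomad | inSgcd
  out <- rep("unlabeled", n)
  out[inHgmdDm & !inPop] <- "pathogenic"
  out[!inHgmdDm & inPop] <- "benign"
  out[inHgmdDm & inPop] <- "uncertain"
  out
}

#' Valid variant group labels
#' @return character vector of the five labels.
#' @export
variantGroups <- function() {
  c("pathogenic", "benign", "uncertain", "novel", "unlabeled")
}

#' Renumber residue positions from the 615- to the 610-residue isoform
#'
#' The minor 615-residue isoform of menin carries five extra residues
#' inserted at the end of exon 1, after amino acid 148 of the major
#' 610-residue isoform. Positions at or before the insertion point are
#' unchanged; positions after it are shifted down by five; positions inside
#' the inserted block have no equivalent in the short isoform and raise an
#' error.
#'
#' @param position615 integer vector of 1-based positions in 615 numbering.
#' @param insertionStart first inserted position (default 149; the inserted
#'   block is `insertionStart .. insertionStart+4`).
#' @return integer vector of positions in 610 numbering.
#' @export
#' @examples
#' renumber615To610(c(100, 200))  # 100, 195
renumber615To610 <- function(position615, insertionStart = 149L) {
  position615 <- as.integer(position615)
  if (any(is.na(position615)) || any(position615 < 1L) ||
      any(position615 > 615L))
    stop("position out of range for the 615-residue isoform [1, 615]")
  insEnd <- insertionStart + 4L
  inInsert <- position615 >= insertionStart & position615 <= insEnd
  if (any(inInsert))
    stop("no equivalent in the 610-residue isoform: position(s) ",
         paste(position615[inInsert], collapse = ", "),
         " fall inside the 5-residue insertion (",
         insertionStart, "-", insEnd, ")")
  ifelse(position615 > insEnd, position615 - 5L, position615)
}

#' Parse a protein-level HGVS missense notation
#'
#' Accepts `p.(His46Pro)`, `p.His46Pro` or the bare one-letter form `H46P`.
#' Non-missense notations (frameshift, stop, deletion, synonymous) are
#' rejected.
#'
#' @param text a single notation string.
#' @return named list with `ref_aa`, `position`, `alt_aa` (one-letter codes).
#' @export
#' @examples
#' parseProteinHgvs("p.(His46Pro)")
#' parseProteinHgvs("G419D")
parseProteinHgvs <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- trimws(text)
  if (grepl("(fs|del|dup|ins|ext|Ter|\\*|=)", txt))
    stop("not a missense substitution: '", text, "'")
  m3 <- regmatches(txt, regexec(
    "^p\\.\\(?([A-Z][a-z]{2})([0-9]+)([A-Z][a-z]{2})\\)?$", txt))[[1]]
  if (length(m3) == 4L) {
    ref <- AA3_TITLE[m3[2]]
    alt <- AA3_TITLE[m3[4]]
    if (is.na(ref) || is.na(alt))
      stop("unknown amino-acid code in '", text, "'")
    return(list(ref_aa = unname(ref), position = as.integer(m3[3]),
                alt_aa = unname(alt)))
  }
  m1 <- regmatches(txt, regexec("^([A-Z])([0-9]+)([A-Z])$", txt))[[1]]
  if (length(m1) == 4L) {
    if (!isCanonicalAa(m1[2]) || !isCanonicalAa(m1[4]))
      stop("unknown amino-acid code in '", text, "'")
    return(list(ref_aa = m1[2], position = as.integer(m1[3]), alt_aa = m1[4]))
  }
  stop("cannot parse protein HGVS notation: '", text, "'")
}

#' Collapse nucleotide-level records to unique protein substitutions
#'
#' Different nucleotide substitutions producing the same coding change are
#' treated as a single missense substitution: records sharing
#' `(position, ref_aa, alt_aa)` are merged. The allele frequency of a merged
#' record is the total over all contributing alleles; the REVEL score is the
#' arithmetic mean over the individual nucleotide variants. Database
#' membership flags are combined by logical OR and the group label
#' reassigned from the merged flags (explicit `novel` labels are kept).
#'
#' @param variants data.frame in the variant-table layout (see
#'   [readVariantTsv()]).
#' @return data.frame with one row per protein substitution; idempotent.
#' @export
dedupeProteinVariants <- function(variants) {
  stopifnot(is.data.frame(variants),
            all(c("position", "ref_aa", "alt_aa") %in% names(variants)))
  v <- variants
  # records at one position must agree on the reference residue
  byPos <- split(v$ref_aa, v$position)
  bad <- names(byPos)[vapply(byPos, function(r) length(unique(r)) > 1L,
                             logical(1))]
  if (length(bad) > 0L)
    stop("conflicting ref_aa at position(s): ", paste(bad, collapse = ", "))
  key <- paste(v$position, v$ref_aa, v$alt_aa, sep = ":")
  idx <- split(seq_len(nrow(v)), key)
  # preserve input order of first occurrence
  idx <- idx[order(vapply(idx, min, integer(1)))]
  rows <- lapply(idx, function(i) {
    r <- v[i[1], , drop = FALSE]
    if (length(i) > 1L) {
      if ("allele_frequency" %in% names(v)) {
        af <- v$allele_frequency[i]
        r$allele_frequency <- if (all(is.na(af))) NA_real_ else
          sum(af, na.rm = TRUE)
      }
      if ("revel" %in% names(v)) {
        rv <- v$revel[i]
        r$revel <- if (all(is.na(rv))) NA_real_ else mean(rv, na.rm = TRUE)
      }
      for (fl in c("in_hgmd_dm", "in_gnomad", "in_sgcd"))
        if (fl %in% names(v)) r[[fl]] <- any(v[[fl]][i], na.rm = TRUE)
      if ("cdna_notation" %in% names(v)) {
        cn <- unique(v$cdna_notation[i])
        cn <- cn[!is.na(cn)]
        r$cdna_notation <- if (length(cn) > 0L)
          paste(cn, collapse = ";") else NA_character_
      }
      if (all(c("group", "in_hgmd_dm", "in_gnomad", "in_sgcd") %in% names(v)) &&
          !identical(r$group, "novel")) {
        r$group <- assignGroup(r$in_hgmd_dm, r$in_gnomad, r$in_sgcd)
      }
    }
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a variant table (TSV)
#'
#' Expected columns: `id, position, ref_aa, alt_aa, in_hgmd_dm, in_gnomad,
#' in_sgcd, allele_frequency, revel, cdna_notation` (header required, `.`
#' for missing, 1-based positions, UTF-8). A `group` column is derived from
#' the membership flags when absent. Variants annotated against the
#' 615-residue isoform are renumbered to 610; variants inside the insertion
#' region are dropped with a warning since they have no equivalent.
#'
#' @param path file path (or connection) of the TSV.
#' @param numbering `"610"` (default) or `"615"`; output is always 610
#'   numbering.
#' @param insertionStart passed to [renumber615To610()].
#' @return data.frame of validated variants.
#' @export
readVariantTsv <- function(path, numbering = c("610", "615"),
                           insertionStart = 149L) {
  numbering <- match.arg(numbering)
  v <- read.delim(path, na.strings = c(".", "NA", ""), sep = "\t",
                  stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("id", "position", "ref_aa", "alt_aa")
  miss <- setdiff(need, names(v))
  if (length(miss) > 0L)
    stop("variant table missing columns: ", paste(miss, collapse = ", "))
  v$position <- as.integer(v$position)
  for (fl in c("in_hgmd_dm", "in_gnomad", "in_sgcd"))
    if (fl %in% names(v)) v[[fl]] <- parseBoolColumn(v[[fl]], fl)
  validateVariants(v)
  if (numbering == "615") {
    insEnd <- insertionStart + 4L
    inIns <- v$position >= insertionStart & v$position <= insEnd
    if (any(inIns)) {
      warning(sum(inIns), " variant(s) inside the 5-residue insertion ",
              "have no 610-isoform equivalent and were dropped")
      v <- v[!inIns, , drop = FALSE]
    }
    v$position <- renumber615To610(v$position, insertionStart)
  }
  if (!"group" %in% names(v) &&
      all(c("in_hgmd_dm", "in_gnomad", "in_sgcd") %in% names(v)))
    v$group <- assignGroup(v$in_hgmd_dm, v$in_gnomad, v$in_sgcd)
  rownames(v) <- NULL
  v
}

#' Write a variant table (TSV)
#'
#' Inverse of [readVariantTsv()]; missing values are written as `.`.
#'
#' @param variants data.frame of variants.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeVariantTsv <- function(variants, path) {
  write.table(variants, path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = ".")
  invisible(path)
}

parseBoolColumn <- function(x, name) {
  if (is.logical(x)) return(x)
  up <- toupper(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[up %in% c("TRUE", "T", "1", "YES", "Y")] <- TRUE
  out[up %in% c("FALSE", "F", "0", "NO", "N")] <- FALSE
  if (any(is.na(out) & !is.na(x)))
    stop("column '", name, "' contains values not interpretable as logical")
  out
}

validateVariants <- function(v) {
  if (any(is.na(v$position)) || any(v$position < 1L))
    stop("positions must be integers >= 1")
  if (!all(isCanonicalAa(v$ref_aa)) || !all(isCanonicalAa(v$alt_aa)))
    stop("ref_aa/alt_aa must be canonical one-letter amino-acid codes")
  if (any(v$ref_aa == v$alt_aa))
    stop("ref_aa and alt_aa must differ (missense)")
  if ("allele_frequency" %in% names(v)) {
    af <- v$allele_frequency
    if (any(!is.na(af) & (af < 0 | af > 1)))
      stop("allele_frequency must lie in [0,1]")
  }
  if ("revel" %in% names(v)) {
    rv <- v$revel
    if (any(!is.na(rv) & (rv < 0 | rv > 1)))
      stop("revel must lie in [0,1]")
  }
  if ("group" %in% names(v) && !all(v$group %in% variantGroups()))
    stop("group labels must be one of: ",
         paste(variantGroups(), collapse = ", "))
  invisible(v)
}
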