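#' Read a per-structure ddG table (TSV)
#'
#' Expected header: `structure_id, chain_id, position, ref_aa, alt_aa,
#' ddg_kcal_mol`. Blank lines and `#` comments are skipped; malformed rows
#' are reported with their line number.
#'
#' @param input file path or character vector of lines.
#' @return data.frame of ddG records (one row per structure-chain
#'   observation of a substitution).
#' @export
parseDdgTsv <- function(input) {
  lines <- if (length(input) == 1L && !grepl("\n", input, fixed = TRUE) &&
               file.exists(input)) readLines(input, warn = FALSE)
           else unlist(strsplit(input, "\n", fixed = TRUE))
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L)
    return(emptyDdgTable())
  header <- strsplit(lines[keep[1]], "\t", fixed = TRUE)[[1]]
  need <- c("structure_id", "chain_id", "position", "ref_aa", "alt_aa",
            "ddg_kcal_mol")
  if (!identical(trimws(header), need))
    stop("ddG table header must be: ", paste(need, collapse = ", "))
  body <- keep[-1]
  if (length(body) == 0L) return(emptyDdgTable())
  rows <- lapply(body, function(ln) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) != 6L)
      stop("line ", ln, ": expected 6 tab-separated fields, got ", length(f))
    pos <- suppressWarnings(as.integer(f[3]))
    ddg <- suppressWarnings(as.numeric(f[6]))
    if (is.na(pos)) stop("line ", ln, ": non-integer position '", f[3], "'")
    if (is.na(ddg)) stop("line ", ln, ": non-numeric ddg '", f[6], "'")
    if (!isCanonicalAa(f[4]) || !isCanonicalAa(f[5]))
      stop("line ", ln, ": non-canonical amino acid")
    data.frame(structure_id = f[1], chain_id = f[2], position = pos,
               ref_aa = f[4], alt_aa = f[5], ddg = ddg,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

emptyDdgTable <- function() {
  data.frame(structure_id = character(), chain_id = character(),
             position = integer(), ref_aa = character(),
             alt_aa = character(), ddg = numeric(),
             stringsAsFactors = FALSE)
}

#' Adapter for FoldX BuildModel "Dif" output
#'
#' Reads the tabular energy-difference file written by the external FoldX
#' BuildModel command: one data row per mutant, in the order the mutants
#' were requested, whose first numeric column is the total energy
#' difference (ddG, kcal/mol). Header/banner lines without a numeric second
#' field are skipped.
#'
#' @param input file path or character vector of lines.
#' @param structureId structure the run was performed on.
#' @param mutantOrder character vector of substitutions (`"R123G"` one-letter
#'   form) in request order.
#' @param chainId chain the substitutions were applied to (default `"A"`).
#' @return data.frame of ddG records, as [parseDdgTsv()].
#' @export
parseFoldxDif <- function(input, structureId, mutantOrder, chainId = "A") {
  lines <- if (length(input) == 1L && !grepl("\n", input, fixed = TRUE) &&
               file.exists(input)) readLines(input, warn = FALSE)
           else unlist(strsplit(input, "\n", fixed = TRUE))
  lines <- lines[!grepl("^\\s*$", lines)]
  vals <- numeric(0)
  for (ln in lines) {
    f <- strsplit(trimws(ln), "[\t ]+")[[1]]
    if (length(f) < 2L) next
    num <- suppressWarnings(as.numeric(f))
    firstNum <- which(!is.na(num))
    # data rows lead with the model name; first numeric column is total ddG
    if (length(firstNum) == 0L || firstNum[1] == 1L) next
    vals <- c(vals, num[firstNum[1]])
  }
  if (length(vals) == 0L) stop("no energy rows found in FoldX output")
  if (length(vals) != length(mutantOrder))
    stop("FoldX output has ", length(vals), " rows but ",
         length(mutantOrder), " mutants were expected")
  subs <- lapply(mutantOrder, parseProteinHgvs)
  data.frame(structure_id = structureId, chain_id = chainId,
             position = vapply(subs, `[[`, integer(1), "position"),
             ref_aa = vapply(subs, `[[`, character(1), "ref_aa"),
             alt_aa = vapply(subs, `[[`, character(1), "alt_aa"),
             ddg = vals, stringsAsFactors = FALSE)
}

#' Aggregate per-structure ddG records per variant
#'
#' Each unique substitution `(position, ref_aa, alt_aa)` receives the mean
#' (or median) and SD of its ddG observations over all structure chains
#' resolving the position, with `n_structures` the number of observations.
#' Variants with no records are necessarily absent: only variants covered
#' by at least one structure can be assessed.
#'
#' @param records ddG record data.frame ([parseDdgTsv()] layout).
#' @param statistic `"mean"` (default) or `"median"`.
#' @return data.frame with columns `position, ref_aa, alt_aa, mean_ddg,
#'   sd_ddg, n_structures` (`sd_ddg` is `NA` for single observations).
#' @export
aggregateDdg <- function(records, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L)
    return(data.frame(position = integer(), ref_aa = character(),
                      alt_aa = character(), mean_ddg = numeric(),
                      sd_ddg = numeric(), n_structures = integer(),
                      stringsAsFactors = FALSE))
  if (any(!is.finite(records$ddg))) stop("ddg values must be finite")
  byPos <- split(records$ref_aa, records$position)
  bad <- names(byPos)[vapply(byPos, function(r) length(unique(r)) > 1L,
                             logical(1))]
  if (length(bad) > 0L)
    stop("records disagree on ref_aa at position(s): ",
         paste(bad, collapse = ", "))
  key <- paste(records$position, records$ref_aa, records$alt_aa, sep = ":")
  idx <- split(seq_len(nrow(records)), key)
  idx <- idx[order(vapply(idx, function(i) records$position[i[1]],
                          integer(1)))]
  stat <- if (statistic == "mean") mean else median
  rows <- lapply(idx, function(i) {
    d <- records$ddg[i]
    data.frame(position = records$position[i[1]],
               ref_aa = records$ref_aa[i[1]],
               alt_aa = records$alt_aa[i[1]],
               mean_ddg = stat(d),
               sd_ddg = if (length(d) > 1L) sd(d) else NA_real_,
               n_structures = length(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Destabilisation call at a ddG threshold
#'
#' A variant is called (strongly) destabilising when its mean ddG exceeds
#' the threshold, strictly: values equal to the threshold are not called.
#' Boundary cases (exact ties) are reported via a message.
#'
#' @param meanDdg numeric vector of mean ddG values (kcal/mol).
#' @param threshold positive threshold in kcal/mol (commonly 3, with 4 as a
#'   conservative alternative).
#' @return logical vector.
#' @export
#' @examples
#' classifyStability(c(5.06, 3, -0.5), threshold = 3)  # TRUE FALSE FALSE
classifyStability <- function(meanDdg, threshold = 3) {
  if (threshold <= 0) stop("threshold must be > 0")
  ties <- which(!is.na(meanDdg) & meanDdg == threshold)
  if (length(ties) > 0L)
    message(length(ties), " value(s) exactly at the ", threshold,
            " kcal/mol threshold; strict '>' leaves them uncalled")
  meanDdg > threshold
}

#' Interface effect: ddG difference between complexed and isolated chains
#'
#' `dddG = ddG(complex) - ddG(isolated)` per variant; a large magnitude
#' indicates the substitution acts at a protein-protein interface rather
#' than on the fold itself. Variants present on only one side are skipped
#' with a message.
#'
#' @param ddgComplex,ddgIsolated data.frames with columns `position,
#'   ref_aa, alt_aa, mean_ddg` (e.g. from [aggregateDdg()] on the
#'   complexed and isolated runs).
#' @param flagThreshold variants with `|dddG| >= flagThreshold` are flagged
#'   (default 3 kcal/mol).
#' @return data.frame `position, ref_aa, alt_aa, ddg_complex, ddg_isolated,
#'   dddg, flagged`.
#' @export
interfaceShift <- function(ddgComplex, ddgIsolated, flagThreshold = 3) {
  need <- c("position", "ref_aa", "alt_aa", "mean_ddg")
  stopifnot(all(need %in% names(ddgComplex)),
            all(need %in% names(ddgIsolated)))
  m <- merge(ddgComplex[need], ddgIsolated[need],
             by = c("position", "ref_aa", "alt_aa"),
             suffixes = c("_complex", "_isolated"))
  if (nrow(m) == 0L)
    stop("no shared variants between complexed and isolated inputs")
  skipped <- (nrow(ddgComplex) - nrow(m)) + (nrow(ddgIsolated) - nrow(m))
  if (skipped > 0L)
    message(skipped, " variant(s) present on only one side were skipped")
  out <- data.frame(position = m$position, ref_aa = m$ref_aa,
                    alt_aa = m$alt_aa,
                    ddg_complex = m$mean_ddg_complex,
                    ddg_isolated = m$mean_ddg_isolated,
                    dddg = m$mean_ddg_complex - m$mean_ddg_isolated)
  out$flagged <- abs(out$dddg) >= flagThreshold
  out[order(out$position), , drop = FALSE]
}

#' Write a ddG record table as TSV
#'
#' @param records ddG record data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeDdgTsv <- function(records, path) {
  out <- records
  names(out)[names(out) == "ddg"] <- "ddg_kcal_mol"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
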