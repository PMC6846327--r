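#' End-to-end variant assessment
#'
#' Joins a variant table with aggregated per-structure ddG records and an
#' optional RSA profile, producing per-variant assessments (mean ddG, SD,
#' number of structures, mean RSA, burial, destabilisation calls at two
#' thresholds and the combined ddG+REVEL call) together with cohort-level
#' evaluation: confusion metrics at both thresholds, ROC curves for ddG
#' and (when present) REVEL, group summaries with t-test p values, the
#' population-frequency table and the multiallelic-site comparison.
#'
#' Variants not covered by any structure are excluded from assessment (and
#' reported in `uncovered`). The quoted uncertainty of the external
#' stability predictor (about +/-0.8 kcal/mol per calculation) is carried
#' as the `ddg_error_note` annotation, not propagated statistically.
#'
#' @param variants variant data.frame ([readVariantTsv()] layout; deduped
#'   internally).
#' @param ddgRecords ddG record data.frame ([parseDdgTsv()] layout).
#' @param rsa optional [RsaProfile-class] (or data.frame with `position`
#'   and `rsa` columns) supplying per-position mean RSA.
#' @param ddgThresholds two ddG thresholds in kcal/mol (default `c(3, 4)`).
#' @param rsaThreshold burial threshold (default 0.2).
#' @param revelThreshold REVEL cutoff for the combined rule (default 0.7).
#' @param combineMode `"and"` (default) or `"or"` for the combined rule.
#' @param outDir optional directory; when given, writes
#'   `assessments.tsv`, `metrics.json` and `roc_<scorer>.tsv`.
#' @return list with `assessments`, `metrics`, `roc` (list of
#'   [RocCurve-class]), `group_summary`, `frequency_table`,
#'   `multiallelic`, `uncovered`, `ddg_error_note`.
#' @export
runAssess <- function(variants, ddgRecords, rsa = NULL,
                      ddgThresholds = c(3, 4), rsaThreshold = 0.2,
                      revelThreshold = 0.7, combineMode = c("and", "or"),
                      outDir = NULL) {
  combineMode <- match.arg(combineMode)
  stopifnot(length(ddgThresholds) == 2L, all(ddgThresholds > 0))
  ddgThresholds <- sort(ddgThresholds)
  v <- dedupeProteinVariants(variants)
  if (!"group" %in% names(v) &&
      all(c("in_hgmd_dm", "in_gnomad", "in_sgcd") %in% names(v)))
    v$group <- assignGroup(v$in_hgmd_dm, v$in_gnomad, v$in_sgcd)
  if (!"group" %in% names(v))
    stop("variants need a 'group' column or the database membership flags")
  agg <- aggregateDdg(ddgRecords)
  m <- merge(v, agg, by = c("position", "ref_aa", "alt_aa"))
  uncovered <- v[!paste(v$position, v$ref_aa, v$alt_aa) %in%
                   paste(agg$position, agg$ref_aa, agg$alt_aa), ,
                 drop = FALSE]
  if (nrow(m) == 0L) stop("no variant is covered by any ddG record")
  if (!is.null(rsa)) {
    rt <- if (is(rsa, "RsaProfile")) rsaTable(rsa) else rsa
    stopifnot(all(c("position", "rsa") %in% names(rt)))
    m$mean_rsa <- rt$rsa[match(m$position, rt$position)]
    m$buried <- ifelse(is.na(m$mean_rsa), NA,
                       isBuried(pmax(m$mean_rsa, 0), rsaThreshold))
  } else {
    m$mean_rsa <- NA_real_
    m$buried <- NA
  }
  m$destabilizing_lo <- classifyStability(m$mean_ddg, ddgThresholds[1])
  m$destabilizing_hi <- classifyStability(m$mean_ddg, ddgThresholds[2])
  hasRevel <- "revel" %in% names(m) && any(!is.na(m$revel))
  m$combined_call <- if (hasRevel)
    suppressWarnings(combinedRule(m$mean_ddg, m$revel, ddgThresholds[1],
                                  revelThreshold, combineMode))
  else m$destabilizing_lo
  m <- m[order(m$position, m$alt_aa), , drop = FALSE]
  rownames(m) <- NULL

  lab <- m$group
  eval_ <- m[lab %in% c("pathogenic", "benign"), , drop = FALSE]
  metrics <- list()
  rocs <- list()
  groupSum <- NULL
  multi <- NULL
  if (nrow(eval_) > 0L &&
      all(c("pathogenic", "benign") %in% eval_$group)) {
    for (thr in ddgThresholds) {
      cc <- confusionCounts(eval_$mean_ddg, eval_$group, thr)
      metrics[[paste0("ddg_gt_", thr)]] <-
        c(classificationMetrics(cc),
          list(tp = cc@tp, fp = cc@fp, tn = cc@tn, fn = cc@fn))
    }
    rocs$ddg <- rocCurve(eval_$mean_ddg, eval_$group)
    if (hasRevel) {
      er <- eval_[!is.na(eval_$revel), , drop = FALSE]
      if (all(c("pathogenic", "benign") %in% er$group))
        rocs$revel <- rocCurve(er$revel, er$group)
      ccComb <- new("ConfusionCounts",
                    tp = sum(eval_$combined_call &
                               eval_$group == "pathogenic"),
                    fp = sum(eval_$combined_call & eval_$group == "benign"),
                    tn = sum(!eval_$combined_call &
                               eval_$group == "benign"),
                    fn = sum(!eval_$combined_call &
                               eval_$group == "pathogenic"))
      metrics[[paste0("combined_", combineMode)]] <-
        classificationMetrics(ccComb)
    }
    groupSum <- groupSummary(eval_$mean_ddg,
                             factor(eval_$group,
                                    levels = c("pathogenic", "benign")))
    multi <- multiallelicComparison(eval_)
  } else {
    stop("evaluation requires both pathogenic and benign variants ",
         "covered by structures")
  }
  freqTable <- NULL
  if ("allele_frequency" %in% names(m) && any(!is.na(m$allele_frequency))) {
    f <- m[!is.na(m$allele_frequency),
           c("position", "ref_aa", "alt_aa", "group",
             "allele_frequency", "mean_ddg"), drop = FALSE]
    freqTable <- f[order(-f$allele_frequency), , drop = FALSE]
    rownames(freqTable) <- NULL
  }
  res <- list(assessments = m, metrics = metrics, roc = rocs,
              group_summary = groupSum, frequency_table = freqTable,
              multiallelic = multi, uncovered = uncovered,
              ddg_error_note = paste("predictor uncertainty approximately",
                                     "+/-0.8 kcal/mol per calculation"))
  if (!is.null(outDir)) writeAssessOutputs(res, outDir, ddgThresholds)
  res
}

# per shared position: mean ddG of co-occurring benign vs pathogenic
# variants, plus a group-level t test over those per-variant means
multiallelicComparison <- function(eval_) {
  byPos <- split(eval_, eval_$position)
  shared <- byPos[vapply(byPos, function(d)
    all(c("pathogenic", "benign") %in% d$group), logical(1))]
  if (length(shared) == 0L) return(NULL)
  rows <- lapply(shared, function(d) {
    data.frame(position = d$position[1],
               n_pathogenic = sum(d$group == "pathogenic"),
               n_benign = sum(d$group == "benign"),
               mean_ddg_pathogenic =
                 mean(d$mean_ddg[d$group == "pathogenic"]),
               mean_ddg_benign = mean(d$mean_ddg[d$group == "benign"]))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  pooled <- do.call(rbind, shared)
  p <- if (sum(pooled$group == "pathogenic") >= 2L &&
           sum(pooled$group == "benign") >= 2L)
    tTestTwoSample(pooled$mean_ddg[pooled$group == "pathogenic"],
                   pooled$mean_ddg[pooled$group == "benign"])$p
  else NA_real_
  list(table = tab, p_value = p)
}

writeAssessOutputs <- function(res, outDir, ddgThresholds) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  a <- res$assessments
  out <- data.frame(position = a$position, ref_aa = a$ref_aa,
                    alt_aa = a$alt_aa, group = a$group,
                    mean_ddg = a$mean_ddg, sd_ddg = a$sd_ddg,
                    n_structures = a$n_structures, mean_rsa = a$mean_rsa,
                    buried = a$buried,
                    stringsAsFactors = FALSE)
  out[[paste0("destabilizing_", ddgThresholds[1])]] <- a$destabilizing_lo
  out[[paste0("destabilizing_", ddgThresholds[2])]] <- a$destabilizing_hi
  out$combined_call <- a$combined_call
  write.table(out, file.path(outDir, "assessments.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = ".")
  meta <- res$metrics
  meta$auc <- lapply(res$roc, aucValue)
  jsonlite::write_json(meta, file.path(outDir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  for (nm in names(res$roc))
    writeRocTsv(res$roc[[nm]], file.path(outDir, paste0("roc_", nm, ".tsv")))
  invisible(outDir)
}

#' Interface analysis: dRSA and dddG between complexed and isolated chains
#'
#' Compares per-variant mean ddG and per-position RSA computed on a
#' protein complex against the same chain(s) in isolation. Variants with
#' `|dddG| >= flagThreshold` are flagged as interface-acting.
#'
#' @param ddgComplex,ddgIsolated aggregated ddG tables ([aggregateDdg()]
#'   layout) from the complexed and isolated runs.
#' @param rsaComplex,rsaIsolated optional [RsaProfile-class] pair for the
#'   same chains.
#' @param flagThreshold dddG flag threshold (default 3 kcal/mol).
#' @param outDir optional output directory (`interface.tsv`).
#' @return data.frame with `position, ref_aa, alt_aa, ddg_complex,
#'   ddg_isolated, dddg, flagged` and, when RSA profiles are given,
#'   `delta_rsa`.
#' @export
runInterface <- function(ddgComplex, ddgIsolated,
                         rsaComplex = NULL, rsaIsolated = NULL,
                         flagThreshold = 3, outDir = NULL) {
  shift <- interfaceShift(ddgComplex, ddgIsolated, flagThreshold)
  if (!is.null(rsaComplex) && !is.null(rsaIsolated)) {
    dr <- deltaRsa(rsaComplex, rsaIsolated)
    shift$delta_rsa <- dr$delta_rsa[match(shift$position, dr$position)]
  }
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    write.table(shift, file.path(outDir, "interface.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, na = ".")
  }
  shift
}
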