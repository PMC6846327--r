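#' Confusion counts at a score threshold
#'
#' Counts true/false positives/negatives for a binary pathogenic/benign
#' labelling at a score threshold. With `direction = "greater"` (default) a
#' score strictly above the threshold predicts pathogenic; with `"less"`,
#' strictly below.
#'
#' @param values numeric scores (e.g. mean ddG).
#' @param labels character/factor labels, `"pathogenic"` or `"benign"`.
#' @param threshold score threshold.
#' @param direction `"greater"` (default) or `"less"`.
#' @return a [ConfusionCounts-class].
#' @export
#' @examples
#' confusionCounts(c(5, 1), c("pathogenic", "benign"), 3)
confusionCounts <- function(values, labels,
                            threshold, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  labels <- as.character(labels)
  stopifnot(length(values) == length(labels),
            all(labels %in% c("pathogenic", "benign")))
  pos <- labels == "pathogenic"
  if (!any(pos)) stop("no pathogenic (positive-class) observations")
  if (all(pos)) stop("no benign (negative-class) observations")
  called <- if (direction == "greater") values > threshold
            else values < threshold
  new("ConfusionCounts",
      tp = sum(pos & called), fp = sum(!pos & called),
      tn = sum(!pos & !called), fn = sum(pos & !called))
}

#' Construct ConfusionCounts from raw counts
#' @param tp,fp,tn,fn non-negative integer counts.
#' @return a [ConfusionCounts-class].
#' @export
makeConfusionCounts <- function(tp, fp, tn, fn) {
  new("ConfusionCounts", tp = as.integer(tp), fp = as.integer(fp),
      tn = as.integer(tn), fn = as.integer(fn))
}

#' @describeIn ConfusionCounts-class sensitivity `tp/(tp+fn)`, specificity
#'   `tn/(tn+fp)`, positive predictive value `tp/(tp+fp)` and negative
#'   predictive value `tn/(tn+fn)`, as fractions; a metric whose
#'   denominator is zero is `NA` (undefined).
#' @export
setMethod("classificationMetrics", "ConfusionCounts", function(object) {
  frac <- function(num, den) if (den == 0L) NA_real_ else num / den
  with_ <- list(tp = object@tp, fp = object@fp, tn = object@tn,
                fn = object@fn)
  list(sensitivity = frac(with_$tp, with_$tp + with_$fn),
       specificity = frac(with_$tn, with_$tn + with_$fp),
       ppv = frac(with_$tp, with_$tp + with_$fp),
       npv = frac(with_$tn, with_$tn + with_$fn))
})

#' Receiver operating characteristic curve with trapezoidal AUC
#'
#' Sweeps all distinct score values as thresholds (predict pathogenic when
#' score >= threshold), grouping tied scores so ties produce diagonal
#' segments; the curve runs from (0,0) to (1,1) and the AUC (trapezoidal
#' rule) equals the Mann-Whitney pair-concordance probability with ties
#' counted 1/2. Higher scores must indicate the positive (pathogenic)
#' class; invert inverse scorers before calling.
#'
#' @param values numeric scores.
#' @param labels `"pathogenic"`/`"benign"` labels.
#' @return a [RocCurve-class].
#' @export
rocCurve <- function(values, labels) {
  labels <- as.character(labels)
  stopifnot(length(values) == length(labels),
            all(labels %in% c("pathogenic", "benign")),
            all(is.finite(values)))
  pos <- labels == "pathogenic"
  nP <- sum(pos); nN <- sum(!pos)
  if (nP == 0L || nN == 0L)
    stop("both classes must be non-empty for a ROC curve")
  ord <- order(values, decreasing = TRUE)
  v <- values[ord]; p <- pos[ord]
  lastOfGroup <- c(v[-1] != v[-length(v)], TRUE)
  cumTp <- cumsum(p)[lastOfGroup]
  cumFp <- cumsum(!p)[lastOfGroup]
  points <- data.frame(threshold = c(Inf, v[lastOfGroup]),
                       fpr = c(0, cumFp / nN),
                       tpr = c(0, cumTp / nP))
  rownames(points) <- NULL
  auc <- sum(diff(points$fpr) *
               (points$tpr[-1] + points$tpr[-nrow(points)]) / 2)
  new("RocCurve", points = points, auc = auc)
}

#' Combine a ddG threshold with a REVEL cutoff
#'
#' Conjunctive mode (default) calls a variant when ddG strictly exceeds its
#' threshold AND the REVEL score is at or above its cutoff; disjunctive
#' mode uses OR. Variants without a REVEL score fall back to the ddG-only
#' call, with a warning.
#'
#' @param ddg numeric mean ddG values (kcal/mol).
#' @param revel numeric REVEL scores in `[0,1]` (`NA` allowed).
#' @param ddgThreshold ddG threshold (kcal/mol).
#' @param revelThreshold REVEL cutoff (default 0.7).
#' @param mode `"and"` (default) or `"or"`.
#' @return logical vector of calls.
#' @export
combinedRule <- function(ddg, revel, ddgThreshold = 3,
                         revelThreshold = 0.7, mode = c("and", "or")) {
  mode <- match.arg(mode)
  if (any(!is.na(revel) & (revel < 0 | revel > 1)))
    stop("revel scores must lie in [0,1]")
  n <- max(length(ddg), length(revel))
  ddg <- rep_len(ddg, n); revel <- rep_len(revel, n)
  ddgCall <- ddg > ddgThreshold
  revelCall <- revel >= revelThreshold
  out <- if (mode == "and") ddgCall & revelCall else ddgCall | revelCall
  if (any(is.na(revel))) {
    warning(sum(is.na(revel)),
            " variant(s) without REVEL score fall back to the ddG-only call")
    out[is.na(revel)] <- ddgCall[is.na(revel)]
  }
  out
}

#' Two-sample t test (Student or Welch)
#'
#' Student's test pools the variances (df = n_a + n_b - 2); Welch's uses
#' the Satterthwaite degrees of freedom. Two-sided p values. When both
#' groups have zero variance, the p value is 1 for equal means and 0
#' otherwise, by convention.
#'
#' @param a,b numeric vectors (length >= 2 each).
#' @param variant `"student"` (default) or `"welch"`.
#' @return list with `t`, `df`, `p`.
#' @export
tTestTwoSample <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 observations")
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p = 0))
  }
  ht <- t.test(a, b, var.equal = (variant == "student"))
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Per-group summary statistics with a two-group comparison
#'
#' Mean, sample SD (n-1), median and quartiles (linear-interpolation
#' convention, R quantile type 7) per group, plus the two-sided t-test
#' p value between the two groups (Student by default).
#'
#' @param values numeric vector.
#' @param groups group labels, exactly two distinct values for the
#'   comparison (more are summarised, with `p_value` computed between the
#'   first two levels).
#' @param variant t-test flavour, see [tTestTwoSample()].
#' @return list with `stats` (data.frame: group, n, mean, sd, median, q1,
#'   q3) and `p_value`.
#' @export
groupSummary <- function(values, groups, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups)[keep]
  lv <- unique(groups)
  if (length(lv) < 1L) stop("no non-missing groups")
  rows <- lapply(lv, function(g) {
    x <- values[groups == g]
    q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(group = g, n = length(x), mean = mean(x),
               sd = if (length(x) > 1L) sd(x) else NA_real_,
               median = q[2], q1 = q[1], q3 = q[3],
               stringsAsFactors = FALSE)
  })
  stats <- do.call(rbind, rows)
  p <- if (length(lv) >= 2L &&
           sum(groups == lv[1]) >= 2L && sum(groups == lv[2]) >= 2L)
    tTestTwoSample(values[groups == lv[1]], values[groups == lv[2]],
                   variant)$p
  else NA_real_
  list(stats = stats, p_value = p)
}

#' Write a ROC curve as TSV
#'
#' Columns: `threshold, fpr, tpr`.
#'
#' @param roc a [RocCurve-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeRocTsv <- function(roc, path) {
  stopifnot(is(roc, "RocCurve"))
  write.table(rocPoints(roc), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
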