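test_that("confusion counts match a brute-force scan", {
  cc <- confusionCounts(c(5, 1), c("pathogenic", "benign"), 3)
  expect_identical(c(cc@tp, cc@tn, cc@fp, cc@fn), c(1L, 1L, 0L, 0L))
  low <- confusionCounts(c(1, 2, 0.5), c("pathogenic", "benign", "benign"), 3)
  expect_identical(c(low@tp, low@fp), c(0L, 0L))
  set.seed(41)
  vals <- round(rnorm(200, 3, 2), 2)
  labs <- sample(c("pathogenic", "benign"), 200, replace = TRUE)
  cc2 <- confusionCounts(vals, labs, 3)
  oracle <- confusionByScan(vals, labs, 3)
  expect_identical(c(tp = cc2@tp, fp = cc2@fp, tn = cc2@tn, fn = cc2@fn),
                   oracle)
  expect_error(confusionCounts(1:3, rep("benign", 3), 2),
               "no pathogenic")
  expect_error(confusionCounts(1:3, rep("pathogenic", 3), 2),
               "no benign")
})

test_that("metrics follow their defining ratios, undefined as NA", {
  m <- classificationMetrics(makeConfusionCounts(108, 17, 144, 53))
  expect_equal(m$sensitivity, 108 / 161)
  expect_equal(m$specificity, 144 / 161)
  expect_equal(m$ppv, 108 / 125)
  expect_equal(m$npv, 144 / 197)
  allOne <- classificationMetrics(makeConfusionCounts(1, 1, 1, 1))
  expect_true(all(unlist(allOne) == 0.5))
  noCalls <- classificationMetrics(makeConfusionCounts(0, 0, 10, 5))
  expect_true(is.na(noCalls$ppv))
  expect_equal(noCalls$specificity, 1)
  # complement identity: sensitivity + miss rate = 1
  expect_equal(m$sensitivity + 53 / 161, 1)
})

test_that("ROC handles separation, constancy and ties", {
  sep <- rocCurve(c(5, 6, 1, 2), c("pathogenic", "pathogenic",
                                   "benign", "benign"))
  expect_equal(aucValue(sep), 1.0)
  flat <- rocCurve(rep(2, 6), rep(c("pathogenic", "benign"), 3))
  expect_equal(aucValue(flat), 0.5)
  # tied scores produce a diagonal segment, not a step
  pts <- rocPoints(flat)
  expect_identical(nrow(pts), 2L)
})

test_that("AUC equals exhaustive pair concordance on random fixtures", {
  set.seed(77)
  for (rep in 1:100) {
    n <- sample(4:15, 1)
    vals <- sample(round(rnorm(n, 0, 1.5), 1))  # rounding induces ties
    labs <- c("pathogenic", "benign",
              sample(c("pathogenic", "benign"), n - 2, replace = TRUE))
    roc <- rocCurve(vals, labs)
    expect_equal(aucValue(roc), aucByPairEnumeration(vals, labs),
                 tolerance = 1e-12)
  }
})

test_that("ROC is invariant under strictly monotone score transforms", {
  set.seed(78)
  vals <- rnorm(60); labs <- sample(c("pathogenic", "benign"), 60,
                                    replace = TRUE, prob = c(.4, .6))
  a1 <- aucValue(rocCurve(vals, labs))
  expect_equal(aucValue(rocCurve(exp(vals), labs)), a1, tolerance = 1e-12)
  expect_equal(aucValue(rocCurve(5 * vals - 2, labs)), a1,
               tolerance = 1e-12)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(79)
  vals <- round(rnorm(80, 2, 2), 1)
  labs <- sample(c("pathogenic", "benign"), 80, replace = TRUE)
  ours <- aucValue(rocCurve(vals, labs))
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labs, predictor = vals, levels = c("benign", "pathogenic"),
    direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("the combined ddG+REVEL rule behaves conjunctively", {
  expect_true(combinedRule(5.0, 0.9, ddgThreshold = 3))
  expect_false(combinedRule(5.0, 0.5, ddgThreshold = 3))
  expect_false(combinedRule(2.0, 0.9, ddgThreshold = 3))
  expect_true(combinedRule(2.0, 0.9, ddgThreshold = 3, mode = "or"))
  # REVEL exactly at the cutoff counts (>=)
  expect_true(combinedRule(5.0, 0.7, ddgThreshold = 3))
  expect_warning(out <- combinedRule(c(5, 5), c(0.9, NA), 3),
                 "fall back")
  expect_identical(out, c(TRUE, TRUE))
  expect_error(combinedRule(5, 1.2, 3), "\\[0,1\\]")
})

test_that("conjunctive filtering cannot lower PPV on the synthetic cohort", {
  coh <- generateCohort(syntheticConfig(seed = 9L))
  agg <- aggregateDdg(coh$ddg)
  m <- merge(coh$truth, agg, by = c("position", "ref_aa", "alt_aa"))
  m <- merge(m, coh$variants[c("id", "revel")], by = "id")
  ddgOnly <- m$mean_ddg > 3
  comb <- suppressWarnings(combinedRule(m$mean_ddg, m$revel, 3))
  ppv <- function(call) sum(call & m$group == "pathogenic") / sum(call)
  expect_gte(ppv(comb), ppv(ddgOnly))
})

test_that("t tests match a numerical-integration oracle of the t tail", {
  a <- c(2.1, 2.5, 1.9, 2.4); b <- c(3.0, 3.4, 2.9)
  res <- tTestTwoSample(a, b, "student")
  # two-sided tail mass of the t density, integrated numerically
  dens <- function(x, df) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  tail <- integrate(dens, abs(res$t), Inf, df = res$df,
                    rel.tol = 1e-10)$value
  expect_equal(res$p, 2 * tail, tolerance = 1e-6)
  expect_identical(res$df, 5)
  welch <- tTestTwoSample(a, b, "welch")
  expect_lt(welch$df, 5)  # Satterthwaite df below pooled df here
  tailW <- integrate(dens, abs(welch$t), Inf, df = welch$df,
                     rel.tol = 1e-10)$value
  expect_equal(welch$p, 2 * tailW, tolerance = 1e-6)
})

test_that("degenerate t-test inputs follow the stated conventions", {
  x <- c(1, 2, 3)
  same <- tTestTwoSample(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  shifted <- tTestTwoSample(x, x + 10)
  expect_lt(shifted$p, 0.01)
  expect_equal(tTestTwoSample(c(2, 2), c(2, 2))$p, 1)
  expect_equal(tTestTwoSample(c(2, 2), c(3, 3))$p, 0)
  expect_error(tTestTwoSample(1, c(1, 2)), "at least 2")
})

test_that("group summaries use type-7 quartiles and sample SD", {
  gs <- groupSummary(c(1, 2, 3, 4, 11, 12, 13, 14),
                     rep(c("a", "b"), each = 4))
  a <- gs$stats[gs$stats$group == "a", ]
  expect_equal(a$median, 2.5)
  expect_equal(a$q1, 1.75)
  expect_equal(a$q3, 3.25)
  expect_equal(a$sd, sd(1:4))
  expect_lt(gs$p_value, 0.001)
  single <- groupSummary(c(5, 1, 2), c("x", "y", "y"))
  xrow <- single$stats[single$stats$group == "x", ]
  expect_true(all(c(xrow$median, xrow$q1, xrow$q3) == 5))
})

test_that("large synthetic groups recover the configured mean", {
  cfg <- syntheticConfig(nPathogenic = 10000L, nBenign = 100L,
                         nStructures = 1L, seed = 3L)
  truth <- generateCohort(cfg)$truth
  m <- mean(truth$latent_ddg[truth$group == "pathogenic"])
  expect_lt(abs(m - 5.06), 0.2)
})
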