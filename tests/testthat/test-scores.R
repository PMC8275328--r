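# Brute-force oracle: unalikeability as the fraction of unequal ordered
# pairs (self-pairs included).
pairwiseUnalike <- function(v) {
  v <- v[!is.na(v)]
  mean(outer(v, v, FUN = "!="))
}

test_that("modvr hits its closed-form values", {
  expect_identical(modvr(c("A", "A", "A")), 0)
  expect_identical(modvr(c("A", "B", "C", "D")), 1)
  expect_equal(modvr(c("A", "A", "B", "C")), 0.75)  # 3*(4-2)/(4*2)
  expect_true(is.na(modvr(c("A", NA))))
  expect_true(is.na(modvr(character(0))))
})

test_that("modvr is 0 iff constant and 1 iff exactly uniform", {
  set.seed(21)
  for (i in 1:50) {
    K <- sample(2:5, 1)
    v <- sample(LETTERS[1:K], sample(3:40, 1), TRUE)
    m <- modvr(v)
    expect_gte(m, 0)
    expect_lte(m, 1)
    tab <- table(v)
    expect_identical(m == 0, length(tab) == 1L)
    expect_identical(m == 1,
                     length(tab) >= 2 && length(unique(as.integer(tab))) == 1)
  }
})

test_that("unalikeability equals the ordered-pair counting oracle", {
  expect_identical(unalikeability(rep("A", 4)), 0)
  expect_equal(unalikeability(c("A", "A", "B", "B")), 0.5)
  expect_equal(unalikeability(c("A", "A", "B", "C")), 0.625)
  set.seed(33)
  for (i in 1:200) {
    v <- sample(LETTERS[1:sample(2:6, 1)], sample(2:50, 1), TRUE)
    expect_equal(unalikeability(v), pairwiseUnalike(v), tolerance = 1e-12)
    expect_lt(unalikeability(v), 1)
    expect_lte(unalikeability(v), 1 - 1 / length(unique(v)))
  }
})

test_that("coefficient of variation and variance match direct evaluation", {
  expect_identical(coefficientOfVariation(c(5, 5, 5)), 0)
  expect_equal(as.numeric(coefficientOfVariation(c(2, 4, 6))), 0.5)
  expect_warning(out <- coefficientOfVariation(c(0, 0, 0)), "zero mean")
  expect_true(is.na(out))
  neg <- coefficientOfVariation(c(-2, -4, -6))
  expect_equal(as.numeric(neg), 0.5)
  expect_true(isTRUE(attr(neg, "negativeMean")))
  expect_identical(varianceScore(c(1, 1)), 0)
  expect_equal(varianceScore(c(2, 4, 6)), 4)  # (4+0+4)/2
  expect_true(is.na(varianceScore(3)))
})

test_that("rate of change counts changed transitions, excluding gapped pairs", {
  expect_equal(rateOfChangeCategorical(c("II", "II", "IV")), 0.5)
  expect_identical(rateOfChangeCategorical(rep("A", 4)), 0)
  expect_equal(rateOfChangeCategorical(c("A", "B", "A")), 1)
  expect_true(is.na(rateOfChangeCategorical(c("A", NA, "A"))))
  expect_equal(rateOfChangeCategorical(c("A", "B", NA, "C", "C")), 0.5)

  expect_equal(rateOfChangeContinuous(c(0, 5, 10), 10), 0.5)
  expect_identical(rateOfChangeContinuous(c(7, 7, 7), 0), 0)
  expect_equal(rateOfChangeContinuous(c(0, 10), 10), 1)
  set.seed(5)
  for (i in 1:30) {
    v <- runif(sample(2:8, 1), 0, 100)
    expect_gte(rateOfChangeContinuous(v, diff(range(v)) + 1e-9), 0)
    expect_lte(rateOfChangeContinuous(v, max(diff(range(v)), 1e-9)), 1)
    cv <- sample(LETTERS[1:3], 6, TRUE)
    expect_gte(rateOfChangeCategorical(cv), 0)
    expect_lte(rateOfChangeCategorical(cv), 1)
  }
})

test_that("row scores aggregate per block; column scores per patient", {
  # block 0 values A,A,B,C over 4 patients; block 1 constant
  m <- rbind(c("A", "A", "B", "C"),
             c("D", "D", "D", "D"))
  co <- gridCohort(m, domain = LETTERS[1:4])
  g <- deriveBlocks(co, "x")
  sMax <- scoreFeature(co, g, "x", "modvr", "max")
  expect_equal(as.numeric(sMax), 0.75)
  expect_equal(unname(attr(sMax, "perUnit")), c(0.75, 0))
  sMean <- scoreFeature(co, g, "x", "modvr", "mean")
  expect_equal(as.numeric(sMean), 0.375)
  expect_error(scoreFeature(tinyCohort(),
                            deriveBlocks(tinyCohort(), "mutation_count"),
                            "mutation_count", "modvr", "mean"),
               "not applicable")
  # constant feature scores 0 under every score/aggregation
  cm <- matrix("A", 3, 5)
  cco <- gridCohort(cm, domain = "A")
  cg <- deriveBlocks(cco, "x")
  for (agg in c("min", "max", "mean")) {
    expect_identical(as.numeric(scoreFeature(cco, cg, "x", "modvr", agg)), 0)
    expect_identical(as.numeric(scoreFeature(cco, cg, "x", "roc", agg)), 0)
  }
})

test_that("row scores are invariant under patient reordering", {
  m <- rbind(c("A", "B", "B", "C", "A"),
             c("B", "B", "A", "C", "C"))
  co <- gridCohort(m, domain = LETTERS[1:3])
  g <- deriveBlocks(co, "x")
  s1 <- as.numeric(scoreFeature(co, g, "x", "modvr", "mean"))
  # same cohort, reversed patient order
  co2 <- buildCohort(sampleTable(co), list(getFeature(co, "x")),
                     patientOrder = rev(patientIds(co)))
  g2 <- deriveBlocks(co2, "x")
  expect_equal(as.numeric(scoreFeature(co2, g2, "x", "modvr", "mean")), s1)
  expect_equal(as.numeric(scoreFeature(co2, g2, "x", "roc", "mean")),
               as.numeric(scoreFeature(co, g, "x", "roc", "mean")))
})

test_that("orthogonal variability patterns separate row and column scores", {
  # high within-timepoint, zero across: per-patient constant values,
  # uniform over 4 categories within every block
  nPer <- 25
  vals <- rep(LETTERS[1:4], each = nPer)
  m <- matrix(rep(vals, each = 3), nrow = 3, byrow = FALSE)
  co <- gridCohort(m, domain = LETTERS[1:4])
  g <- deriveBlocks(co, "x")
  expect_identical(as.numeric(scoreFeature(co, g, "x", "modvr", "mean")), 1)
  expect_identical(as.numeric(scoreFeature(co, g, "x", "roc", "mean")), 0)
  # transposed pattern: constant within each block, changing every step
  m2 <- matrix(rep(c("A", "B", "A"), 100), nrow = 3)
  co2 <- gridCohort(m2, domain = c("A", "B"))
  g2 <- deriveBlocks(co2, "x")
  expect_identical(as.numeric(scoreFeature(co2, g2, "x", "modvr", "mean")),
                   0)
  expect_identical(as.numeric(scoreFeature(co2, g2, "x", "roc", "mean")),
                   1)
})

test_that("Markov switch probability is recovered by the mean rate of change", {
  for (p in c(0, 0.25, 0.5)) {
    cfg <- syntheticCohortConfig(
      nPatients = 200,
      timepointWeights = c(`2` = 0, `3` = 0, `4` = 1),
      categoricalFeatures = list(list(
        id = "state", name = "State", categories = LETTERS[1:3],
        initWeights = c(1, 1, 1), switchProb = p)),
      eventSpec = list(eventType = "TREATMENT", attributes = NULL,
                       prob = 0),
      seed = 101)
    res <- generateSyntheticCohort(cfg)
    g <- deriveBlocks(res$cohort, "state")
    est <- as.numeric(scoreFeature(res$cohort, g, "state", "roc", "mean"))
    se <- sqrt(p * (1 - p) / (200 * 3))
    expect_lte(abs(est - p), max(3 * se, 1e-12))
  }
})

test_that("features rank by descending variability with missing scores last", {
  # x dominates y at every timepoint
  mx <- rbind(c("A", "B", "C", "A"), c("B", "C", "A", "B"))
  my <- rbind(c("A", "A", "A", "B"), c("C", "C", "C", "C"))
  co <- gridCohort(mx, domain = LETTERS[1:3])
  sids <- names(featureValues(getFeature(co, "x")))
  co <- addFeature(co, makeFeature("y", "categorical",
    stats::setNames(as.vector(my), sids), domain = LETTERS[1:3]))
  co <- addFeature(co, makeFeature("z", "continuous",
    stats::setNames(seq_along(sids), sids)))
  g <- deriveBlocks(co, c("x", "y", "z"))
  for (agg in c("min", "max", "mean")) {
    tab <- rankFeatures(co, g, list(list(score = "modvr",
                                         aggregation = agg)))
    col <- paste0("rank_modvr_", agg)
    expect_identical(tab[[col]][tab$feature_id == "x"], 1L)
    # modvr inapplicable to continuous z -> ranked after scored features
    expect_identical(tab[[col]][tab$feature_id == "z"], 3L)
    expect_true(is.na(tab[[paste0("modvr_", agg)]][tab$feature_id == "z"]))
  }
  single <- rankFeatures(co, g, list(list(score = "roc",
                                          aggregation = "mean")),
                         featureIds = "x")
  expect_identical(single$rank_roc_mean, 1L)
  expect_true(all(c("datatype", "source", "range_or_categories")
                  %in% names(single)))
  expect_error(rankFeatures(co, g, list()), "at least one")
})
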