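test_that("binning sends values at the threshold to the upper bin", {
  co <- flatCohort(c(100, 149, 150, 200))
  co <- binFeature(co, "x", 150, c("low", "high"), newId = "xb")
  expect_identical(unname(featureValues(getFeature(co, "xb"))),
                   c("low", "low", "high", "high"))
  expect_identical(getFeature(co, "xb")@datatype, "ordinal")
  expect_identical(getFeature(co, "xb")@domain, c("low", "high"))

  co2 <- flatCohort(c(5, 10, 15, 20, 25))
  co2 <- binFeature(co2, "x", c(10, 20), c("b0", "b1", "b2"), newId = "xb")
  expect_identical(unname(featureValues(getFeature(co2, "xb"))),
                   c("b0", "b1", "b1", "b2", "b2"))

  expect_error(binFeature(flatCohort(1:3), "x", numeric(0), "a"),
               "non-empty")
  expect_error(binFeature(flatCohort(1:3), "x", c(5, 5), c("a", "b", "c")),
               "strictly increasing")
})

test_that("every non-missing value lands in exactly one bin", {
  set.seed(11)
  for (i in 1:20) {
    v <- c(rnorm(40, 50, 30), NA)
    edges <- sort(sample(1:100, sample(1:4, 1)))
    labels <- paste0("b", seq_len(length(edges) + 1))
    co <- binFeature(flatCohort(v), "x", edges, labels, newId = "xb")
    out <- featureValues(getFeature(co, "xb"))
    expect_identical(sum(!is.na(out)), sum(!is.na(v)))
    expect_true(all(out[!is.na(out)] %in% labels))
  }
})

test_that("log transform evaluates correctly and rejects nonpositive values", {
  co <- logFeature(flatCohort(c(1, 10, 100)), "x", newId = "xl")
  expect_equal(unname(featureValues(getFeature(co, "xl"))), c(0, 1, 2))
  expect_error(logFeature(flatCohort(c(1, 0, 3)), "x"), "S2")
  co2 <- logFeature(flatCohort(3), "x", pseudocount = 1, newId = "xl")
  expect_equal(unname(featureValues(getFeature(co2, "xl"))), log10(4),
               tolerance = 1e-12)
  # monotone: ordering preserved
  v <- c(3, 1, 7, 2, 9)
  co3 <- logFeature(flatCohort(v), "x", newId = "xl")
  expect_identical(order(featureValues(getFeature(co3, "xl"))), order(v))
})

binTriple <- function(a, b, c) {
  sids <- paste0("S", seq_along(a))
  samples <- data.frame(patient_id = "P1", sample_id = sids,
                        date = seq_along(a) - 1L, stringsAsFactors = FALSE)
  buildCohort(samples, list(
    makeFeature("MLH1", "binary", stats::setNames(a, sids)),
    makeFeature("MSH6", "binary", stats::setNames(b, sids)),
    makeFeature("MSH3", "binary", stats::setNames(c, sids))))
}

test_that("Boolean combination folds non-missing inputs with missing propagation", {
  co <- binTriple(c(1, 0, 1, NA), c(0, 0, NA, NA), c(0, 0, NA, NA))
  co <- combineFeatures(co, c("MLH1", "MSH6", "MSH3"), "OR", "mmr")
  # pathway track: any mutated gene -> 1; all-0 -> 0; OR(1,NA,NA) -> 1
  expect_identical(unname(featureValues(getFeature(co, "mmr"))),
                   c(1L, 0L, 1L, NA_integer_))
  co2 <- binTriple(c(1, 0, 1, 1), c(1, 0, NA, 0), c(1, 1, NA, NA))
  co2 <- combineFeatures(co2, c("MLH1", "MSH6", "MSH3"), "AND", "all3")
  # AND decidable from an observed 0; undecidable (1, NA) -> missing
  expect_identical(unname(featureValues(getFeature(co2, "all3"))),
                   c(1L, 0L, NA_integer_, 0L))
  expect_error(combineFeatures(tinyCohort(), c("grade", "MGMT"), "OR", "z"),
               "binary")
})

test_that("OR is monotone in its inputs", {
  set.seed(4)
  for (i in 1:25) {
    a <- sample(c(0L, 1L, NA), 6, TRUE)
    b <- sample(c(0L, 1L, NA), 6, TRUE)
    co <- binTriple(a, b, rep(0L, 6))  # only first 4 used
    co <- combineFeatures(co, c("MLH1", "MSH6"), "OR", "or0")
    base <- featureValues(getFeature(co, "or0"))
    # flip one observed 0 to 1
    j <- which(!is.na(a) & a == 0)
    if (!length(j)) next
    a2 <- a
    a2[j[1]] <- 1L
    co2 <- binTriple(a2, b, rep(0L, 6))
    co2 <- combineFeatures(co2, c("MLH1", "MSH6"), "OR", "or0")
    up <- featureValues(getFeature(co2, "or0"))
    ok <- !is.na(base) & base == 1
    expect_true(all(is.na(up[ok]) | up[ok] == 1))
  }
})

test_that("mean combination averages available values", {
  sids <- c("S1", "S2", "S3")
  samples <- data.frame(patient_id = "P1", sample_id = sids, date = 0:2)
  co <- buildCohort(samples, list(
    makeFeature("g1", "continuous", stats::setNames(c(2, 5, NA), sids)),
    makeFeature("g2", "continuous", stats::setNames(c(4, NA, NA), sids))))
  co <- combineFeatures(co, c("g1", "g2"), "MEAN", "gs")
  expect_equal(unname(featureValues(getFeature(co, "gs"))), c(3, 5, NA))
  expect_error(combineFeatures(co, "g1", "MEAN", "z"), "at least 2")
})

test_that("binary inversion is an involution preserving missingness", {
  sids <- c("S1", "S2", "S3")
  samples <- data.frame(patient_id = "P1", sample_id = sids, date = 0:2)
  co <- buildCohort(samples, list(
    makeFeature("b", "binary", stats::setNames(c(1L, 0L, NA), sids))))
  co <- invertFeature(co, "b", newId = "bi")
  expect_identical(unname(featureValues(getFeature(co, "bi"))),
                   c(0L, 1L, NA_integer_))
  co <- invertFeature(co, "bi", newId = "bii")
  expect_identical(featureValues(getFeature(co, "bii")),
                   featureValues(getFeature(co, "b")))
  expect_error(invertFeature(tinyCohort(), "grade"), "binary")
})

test_that("ordinal conversion needs a full permutation and round-trips", {
  co <- tinyCohort()
  co <- toCategorical(toOrdinal(co, "grade", c("II", "III", "IV")), "grade")
  co <- toOrdinal(co, "grade", c("II", "III", "IV"))
  f <- getFeature(co, "grade")
  expect_identical(f@datatype, "ordinal")
  expect_identical(f@domain, c("II", "III", "IV"))
  expect_identical(featureValues(f), featureValues(getFeature(tinyCohort(),
                                                              "grade")))
  expect_error(toOrdinal(tinyCohort(), "grade", c("II", "III")),
               "permutation.*IV")
})

test_that("feature rows reorder stably by attribute or explicit list", {
  co <- tinyCohort()
  g <- deriveBlocks(co, c("mutation_count", "MGMT", "grade"))
  gn <- reorderFeatures(g, co, "name")
  # display names: Mutation Count, MGMT, Neoplasm Histologic Grade
  expect_identical(gn@displayedFeatures, c("MGMT", "mutation_count",
                                           "grade"))
  expect_identical(blocks(gn)[[1]]@rows, gn@displayedFeatures)
  ge <- reorderFeatures(g, co, explicit = c("grade", "MGMT",
                                            "mutation_count"))
  expect_identical(ge@displayedFeatures, c("grade", "MGMT",
                                           "mutation_count"))
  expect_error(reorderFeatures(g, co, explicit = c("grade", "MGMT")),
               "permutation")
  # identity explicit order leaves everything unchanged
  gid <- reorderFeatures(g, co, explicit = g@displayedFeatures)
  expect_equal(gid, g)
  # stable sort by datatype keeps prior relative order within ties
  gd <- reorderFeatures(g, co, "datatype")
  expect_identical(gd@displayedFeatures, c("MGMT", "grade",
                                           "mutation_count"))
})

test_that("each transform appends exactly one op-log record", {
  co <- tinyCohort()
  expect_length(opLog(co), 0)
  co <- binFeature(co, "mutation_count", 150, c("low", "high"))
  expect_length(opLog(co), 1)
  co <- renameFeature(co, "MGMT", "MGMT methylation")
  expect_length(opLog(co), 2)
  expect_identical(opLog(co)[[2]]$op, "rename")
  expect_identical(opLog(co)[[2]]$stamp, 2L)
})
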