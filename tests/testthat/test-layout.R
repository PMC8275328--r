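# 4 patients x 2 timepoints with hand-set values for sorting/grouping.
sortFixture <- function() {
  m <- rbind(c("III", "II", "II", "IV"),
             c("II", "II", "III", "IV"))
  co <- gridCohort(m, domain = c("II", "III", "IV"), id = "grade")
  sids <- names(featureValues(getFeature(co, "grade")))
  co <- addFeature(co, makeFeature("score", "continuous",
    stats::setNames(c(5, 5, 9, 9, 3, 3, 1, 1), sids)))
  co
}

test_that("single-key sorting is stable with missing and gap values last", {
  co <- sortFixture()
  g <- deriveBlocks(co, c("grade", "score"))
  g1 <- sortBlock(g, 1, "grade")
  # ties (P002, P003 both II) keep prior relative order
  expect_identical(blocks(g1)[[1]]@order,
                   c("P002", "P003", "P001", "P004"))
  expect_identical(blocks(g1)[[1]]@primaryFeature, "grade")
  # idempotent under re-sorting by the same key
  expect_identical(blocks(sortBlock(g1, 1, "grade"))[[1]]@order,
                   blocks(g1)[[1]]@order)
  # descending
  g2 <- sortBlock(g, 1, "grade", "desc")
  expect_identical(blocks(g2)[[1]]@order,
                   c("P004", "P001", "P002", "P003"))
  expect_error(sortBlock(g, 1, "nope"), "not displayed")

  # an all-missing key leaves the order unchanged
  sids <- names(featureValues(getFeature(co, "grade")))
  co2 <- addFeature(co, makeFeature("allNA", "continuous",
    stats::setNames(rep(NA_real_, 8), sids)))
  gm <- deriveBlocks(co2, c("grade", "allNA"))
  expect_identical(blocks(sortBlock(gm, 1, "allNA"))[[1]]@order,
                   blocks(gm)[[1]]@order)

  # gaps sort last: tiny cohort block 3 has gaps for P1 and P4
  tg <- deriveBlocks(tinyCohort(), "grade")
  ts <- sortBlock(tg, 3, "grade")
  expect_identical(blocks(ts)[[3]]@order[3:4], c("P1", "P4"))
})

test_that("multidimensional sorting equals the lexicographic oracle", {
  co <- sortFixture()
  g <- deriveBlocks(co, c("grade", "score"))
  g1 <- sortBlockMulti(g, 1, c("grade", "score"), c("asc", "asc"))
  # keys (grade, score): P2(II,5) P3(II,3) -> score breaks tie
  expect_identical(blocks(g1)[[1]]@order,
                   c("P003", "P002", "P001", "P004"))
  # single-feature call reduces to sortBlock
  expect_identical(blocks(sortBlockMulti(g, 1, "grade"))[[1]]@order,
                   blocks(sortBlock(g, 1, "grade"))[[1]]@order)
  # constant secondary key degenerates to the primary sort
  sids <- names(featureValues(getFeature(co, "grade")))
  co2 <- addFeature(co, makeFeature("const", "continuous",
    stats::setNames(rep(1, 8), sids)))
  g2 <- deriveBlocks(co2, c("grade", "const"))
  expect_identical(
    blocks(sortBlockMulti(g2, 1, c("grade", "const")))[[1]]@order,
    blocks(sortBlock(g2, 1, "grade"))[[1]]@order)

  # randomized oracle comparison
  set.seed(77)
  for (i in 1:50) {
    nPat <- sample(3:30, 1)
    nKey <- sample(1:4, 1)
    ids <- paste0("f", seq_len(nKey))
    m <- matrix(sample(c(LETTERS[1:4], NA), nPat, TRUE), nrow = 1)
    co <- gridCohort(m, domain = LETTERS[1:4], id = "f1")
    sids <- sampleTable(co)$sample_id
    if (nKey > 1) for (k in 2:nKey) {
      if (k %% 2 == 0)
        co <- addFeature(co, makeFeature(ids[k], "continuous",
          stats::setNames(sample(c(1:5, NA), nPat, TRUE), sids)))
      else
        co <- addFeature(co, makeFeature(ids[k], "categorical",
          stats::setNames(sample(c(LETTERS[1:3], NA), nPat, TRUE), sids),
          domain = LETTERS[1:3]))
    }
    dirs <- sample(c("asc", "desc"), nKey, TRUE)
    g <- deriveBlocks(co, ids)
    got <- blocks(sortBlockMulti(g, 1, ids, dirs))[[1]]@order
    expect_identical(got, lexSortOracle(blocks(g)[[1]], ids, dirs))
  }
})

test_that("realignment propagates the reference order and is idempotent", {
  co <- tinyCohort()
  g <- deriveBlocks(co, c("grade", "mutation_count"))
  g <- sortBlock(g, 2, "mutation_count", "desc")
  ga <- realignAll(g, 2)
  refOrder <- blocks(ga)[[2]]@order
  for (b in blocks(ga)) expect_identical(b@order, refOrder)
  # lines between realigned neighbours connect monotone positions
  fs <- computeFlows(ga, 1, 2)
  src <- as.integer(fs@lines$source)
  tgt <- as.integer(fs@lines$target)
  expect_identical(order(src), order(tgt))  # zero crossings
  expect_equal(realignAll(ga, 2), ga)
  gg <- groupBlock(ga, 1, "grade")
  expect_error(realignAll(gg, 1), "ungrouped")
})

test_that("grouping partitions by domain order with nested summaries", {
  co <- tinyCohort()
  g <- deriveBlocks(co, c("MGMT", "grade", "mutation_count"))
  gg <- groupBlock(g, 1, "MGMT")
  gb <- groupedBlock(gg, 1)
  vals <- vapply(gb@groups, `[[`, character(1), "value")
  sizes <- vapply(gb@groups, function(x) length(x$patients), integer(1))
  expect_identical(vals, c("meth", "unmeth"))
  expect_identical(sizes, c(3L, 1L))       # meth: P1,P3,P4; unmeth: P2
  expect_identical(sort(gb@groups[[1]]$patients), c("P1", "P3", "P4"))
  # nested categorical counts sum to group size
  nc <- gb@nestedSummaries[["meth"]][["grade"]]
  expect_identical(sum(nc$counts) + nc$missing, 3L)
  # continuous nested summary is the exact five-number summary
  ns <- gb@nestedSummaries[["meth"]][["mutation_count"]]
  expect_equal(unname(ns$summary),
               unname(stats::quantile(c(20, 25, 45), c(0, .25, .5, .75, 1),
                                      type = 7)))
  expect_error(groupBlock(g, 1, "mutation_count"), "bin it first")

  # five-number summary of 1..5 in a single group
  co5 <- gridCohort(matrix("A", 1, 5), domain = "A", id = "g")
  sids <- sampleTable(co5)$sample_id
  co5 <- addFeature(co5, makeFeature("v", "continuous",
    stats::setNames(1:5, sids)))
  g5 <- groupBlock(deriveBlocks(co5, c("g", "v")), 1, "g")
  expect_equal(unname(groupedBlock(g5, 1)@nestedSummaries[["A"]][["v"]]$summary),
               c(1, 2, 3, 4, 5))
})

test_that("patients with a missing primary value form a trailing group", {
  m <- matrix(c("A", "B", NA, "A"), nrow = 1)
  co <- gridCohort(m, domain = c("A", "B"), id = "g")
  gg <- groupBlock(deriveBlocks(co, "g"), 1, "g")
  gb <- groupedBlock(gg, 1)
  vals <- vapply(gb@groups, `[[`, character(1), "value")
  expect_identical(vals, c("A", "B", "(missing)"))
  expect_identical(sum(vapply(gb@groups, function(x) length(x$patients),
                              integer(1))), 4L)
})

test_that("ungrouping restores the pre-grouping order exactly", {
  co <- sortFixture()
  g <- deriveBlocks(co, c("grade", "score"))
  g <- sortBlock(g, 1, "score", "desc")
  before <- blocks(g)[[1]]@order
  g <- groupBlock(g, 1, "grade")
  expect_false(identical(blocks(g)[[1]]@order, before))
  g <- ungroupBlock(g, 1)
  expect_identical(blocks(g)[[1]]@order, before)
  expect_false(blocks(g)[[1]]@grouped)
})

test_that("grouped-grouped flows enumerate patient transitions", {
  # 4 patients: MGMT meth,meth,meth,unmeth at t0; one meth->unmeth switch
  m <- rbind(c("meth", "meth", "meth", "unmeth"),
             c("meth", "meth", "unmeth", "unmeth"))
  co <- gridCohort(m, domain = c("meth", "unmeth"), id = "MGMT")
  g <- deriveBlocks(co, "MGMT")
  g <- groupBlock(groupBlock(g, 1, "MGMT"), 2, "MGMT")
  fs <- computeFlows(g, 1, 2)
  expect_identical(fs@mode, "flows")
  key <- vapply(fs@flows, function(f) paste(f$source, f$target), character(1))
  cnt <- vapply(fs@flows, function(f) length(f$patients), integer(1))
  expect_identical(stats::setNames(cnt, key),
                   c("meth meth" = 2L, "meth unmeth" = 1L,
                     "unmeth unmeth" = 1L))
})

test_that("ungrouped flows are per-patient lines excluding gap patients", {
  co <- tinyCohort()
  g <- deriveBlocks(co, "grade")
  fs <- computeFlows(g, 1, 2)
  expect_identical(fs@mode, "lines")
  expect_identical(nrow(fs@lines), 4L)
  expect_identical(fs@lines$source, fs@lines$target)  # parallel lines
  # block 2 -> 3: P1 and P4 have no third sample
  fs2 <- computeFlows(g, 2, 3)
  expect_identical(sort(fs2@exits), c("P1", "P4"))
  expect_identical(sort(fs2@lines$patient_id), c("P2", "P3"))
  expect_error(computeFlows(g, 1, 3), "adjacent")
})

test_that("flow counts conserve group sizes over random cohorts", {
  set.seed(99)
  for (i in 1:20) {
    res <- generateSyntheticCohort(syntheticCohortConfig(
      nPatients = sample(8:25, 1), seed = 1000 + i))
    co <- res$cohort
    g <- deriveBlocks(co, "grade")
    g <- groupBlock(groupBlock(g, 1, "grade"), 2, "grade")
    fs <- computeFlows(g, 1, 2)
    A <- blocks(g)[[1]]
    B <- blocks(g)[[2]]
    shared <- intersect(A@order[!A@gap[A@order]], B@order[!B@gap[B@order]])
    for (side in c("source", "target")) {
      blk <- if (side == "source") A else B
      for (grp in blk@grouping@groups) {
        fromFlows <- sum(vapply(fs@flows, function(f)
          if (f[[side]] == grp$value) length(f$patients) else 0L,
          integer(1)))
        expect_identical(fromFlows, length(intersect(grp$patients, shared)))
      }
    }
  }
})

test_that("mixed grouped/ungrouped pairs fan lines from group segments", {
  m <- rbind(c("A", "A", "B"), c("A", "B", "B"))
  co <- gridCohort(m, domain = c("A", "B"), id = "g")
  g <- groupBlock(deriveBlocks(co, "g"), 1, "g")
  fs <- computeFlows(g, 1, 2)
  expect_identical(fs@mode, "mixed")
  expect_identical(nrow(fs@lines), 3L)
  expect_identical(fs@lines$source[fs@lines$patient_id == "P003"], "B")
})

test_that("selections annotate lines, flows and groups", {
  co <- tinyCohort()
  g <- deriveBlocks(co, "grade")
  fsets <- flowSets(g)
  hl <- highlightSelection(g, fsets, "P2")
  for (fs in hl$flowsets)
    expect_identical(sum(fs@lines$selected),
                     as.integer("P2" %in% fs@lines$patient_id))
  # grouped case: 2 of 3 patients selected within one flow
  m <- rbind(c("meth", "meth", "meth", "unmeth"),
             c("meth", "meth", "meth", "unmeth"))
  co2 <- gridCohort(m, domain = c("meth", "unmeth"), id = "MGMT")
  g2 <- groupBlock(groupBlock(deriveBlocks(co2, "MGMT"), 1, "MGMT"),
                   2, "MGMT")
  hl2 <- highlightSelection(g2, flowSets(g2), c("P001", "P002"))
  fl <- hl2$flowsets[[1]]@flows
  mm <- fl[[which(vapply(fl, function(f)
    f$source == "meth" && f$target == "meth", logical(1)))]]
  expect_identical(length(mm$patients), 3L)
  expect_identical(mm$selectedCount, 2L)
  ann <- hl2$groupAnnotations
  expect_identical(ann$selected[ann$block_pos == 1 & ann$group == "meth"],
                   2L)
  # empty selection: all annotation counts zero
  hl0 <- highlightSelection(g2, flowSets(g2), character(0))
  expect_true(all(hl0$groupAnnotations$selected == 0))
  expect_error(highlightSelection(g, fsets, "P99"), "unknown patient")
})
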