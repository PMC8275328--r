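## Block-view arrangement: stable per-block sorting, multidimensional
## sorting, cohort-wide realignment, grouping into proportion blocks with
## nested summaries, patient lines / Sankey flows, selection highlighting.

blockAt <- function(grid, pos) {
  if (pos < 1L || pos > length(grid@blocks))
    stop("block position out of range: ", pos)
  grid@blocks[[pos]]
}

#' Stable sort of a block's patient columns by one feature
#'
#' The existing order is stably re-sorted by the feature's value
#' (ordinal/categorical: domain order; continuous/binary: numeric), so
#' tied patients keep their prior relative order. Missing values sort
#' after values, gaps last; the sorted feature becomes the block's
#' primary feature.
#'
#' @param grid a [BlockGrid-class].
#' @param pos block position in the grid (1-based).
#' @param featureId feature to sort by (must be a row of that block).
#' @param direction `"asc"` or `"desc"`.
#' @return The grid with the block re-ordered.
#' @export
sortBlock <- function(grid, pos, featureId, direction = c("asc", "desc")) {
  direction <- match.arg(direction)
  b <- blockAt(grid, pos)
  if (b@grouped) stop("cannot sort a grouped block; ungroup first")
  if (!featureId %in% b@rows)
    stop("feature '", featureId, "' is not displayed in this block")
  ord <- b@order
  v <- b@cells[[featureId]][ord]
  gap <- b@gap[ord]
  key <- cellSortKey(b@cells[[featureId]], v)
  cls <- ifelse(gap, 3L, ifelse(is.na(key), 2L, 1L))
  if (direction == "desc") key <- -key
  key[is.na(key)] <- 0
  b@order <- ord[order(cls, key, method = "radix")]
  b@primaryFeature <- featureId
  grid@blocks[[pos]] <- b
  grid
}

## grids carry no cohort reference; datatype/domain metadata travels on
## the cell vectors (attached when blocks are materialized)
cellSortKey <- function(cellVector, v) {
  dt <- attr(cellVector, "datatype")
  if (identical(dt, "categorical") || identical(dt, "ordinal"))
    as.numeric(match(v, attr(cellVector, "domain")))
  else as.numeric(v)
}

#' Multidimensional stable sort of a block
#'
#' Sorts by several features at once, most significant first: applying
#' [sortBlock()] per feature from least to most significant, so
#' stability yields the lexicographic order with the prior patient order
#' as final tiebreaker.
#'
#' @inheritParams sortBlock
#' @param featureIds features, most significant first.
#' @param directions `"asc"`/`"desc"` per feature (recycled if length 1).
#' @export
sortBlockMulti <- function(grid, pos, featureIds, directions = "asc") {
  if (length(directions) == 1L)
    directions <- rep(directions, length(featureIds))
  if (length(directions) != length(featureIds))
    stop("features and directions length mismatch")
  for (i in rev(seq_along(featureIds)))
    grid <- sortBlock(grid, pos, featureIds[i], directions[i])
  b <- grid@blocks[[pos]]
  b@primaryFeature <- featureIds[1L]
  grid@blocks[[pos]] <- b
  grid
}

#' Propagate one block's patient order to all ungrouped blocks
#'
#' Eliminates crossing lines among patients shared with the reference
#' block: every ungrouped block's order is set to the reference order,
#' with patients absent from the reference appended in their prior
#' relative order. Idempotent.
#'
#' @inheritParams sortBlock
#' @param refPos reference block position (must be ungrouped).
#' @export
realignAll <- function(grid, refPos) {
  ref <- blockAt(grid, refPos)
  if (ref@grouped) stop("reference block must be ungrouped")
  refOrder <- ref@order
  grid@blocks <- lapply(grid@blocks, function(b) {
    if (b@grouped) return(b)
    kept <- refOrder[refOrder %in% b@order]
    b@order <- c(kept, b@order[!b@order %in% kept])
    b
  })
  grid
}

fiveNumberSummary <- function(v) {
  v <- v[!is.na(v)]
  if (!length(v)) return(rep(NA_real_, 5))
  ## linear-interpolation quartiles (quantile type 7), bit-reproducible
  stats::setNames(stats::quantile(v, c(0, .25, .5, .75, 1), type = 7,
                                  names = FALSE),
                  c("min", "q1", "median", "q3", "max"))
}

#' Group a block by a primary feature into a proportion view
#'
#' Partitions the block's present patients by the value of a
#' categorical, ordinal or binary primary feature (continuous features
#' must be binned first); group order follows the feature's domain
#' order, and patients with a missing primary value form an explicit
#' `"(missing)"` group rendered last. Every other displayed feature gets
#' a nested per-group summary: a value-count map (categorical) or a
#' five-number summary plus the raw values (continuous).
#'
#' @inheritParams sortBlock
#' @param featureId primary (grouping) feature.
#' @return The grid with the block grouped.
#' @export
groupBlock <- function(grid, pos, featureId) {
  b <- blockAt(grid, pos)
  if (!featureId %in% b@rows)
    stop("feature '", featureId, "' is not displayed in this block")
  dt <- attr(b@cells[[featureId]], "datatype")
  if (identical(dt, "continuous"))
    stop("cannot group by continuous feature '", featureId,
         "': bin it first to make it categorical")
  dom <- attr(b@cells[[featureId]], "domain")
  present <- b@order[!b@gap[b@order]]
  v <- b@cells[[featureId]][present]
  groups <- list()
  for (g in dom) {
    members <- present[!is.na(v) & as.character(v) == as.character(g)]
    if (length(members))
      groups[[length(groups) + 1L]] <- list(value = as.character(g),
                                            patients = members)
  }
  missMembers <- present[is.na(v)]
  if (length(missMembers))
    groups[[length(groups) + 1L]] <- list(value = "(missing)",
                                          patients = missMembers)
  nested <- lapply(groups, function(grp) {
    out <- lapply(stats::setNames(setdiff(b@rows, featureId),
                                  setdiff(b@rows, featureId)),
                  function(fid) {
      gv <- b@cells[[fid]][grp$patients]
      if (identical(attr(b@cells[[fid]], "datatype"), "continuous")) {
        list(type = "continuous", summary = fiveNumberSummary(gv),
             values = unname(gv))
      } else {
        tab <- table(as.character(gv), useNA = "no")
        list(type = "categorical",
             counts = stats::setNames(as.integer(tab), names(tab)),
             missing = sum(is.na(gv)))
      }
    })
    out
  })
  names(nested) <- vapply(groups, `[[`, character(1), "value")
  b@grouping <- new("GroupedBlock", blockPos = as.integer(pos),
                    primaryFeature = featureId, groups = groups,
                    nestedSummaries = nested, preGroupOrder = b@order)
  b@grouped <- TRUE
  b@primaryFeature <- featureId
  b@order <- c(unlist(lapply(groups, `[[`, "patients")),
               b@order[b@gap[b@order]])
  grid@blocks[[pos]] <- b
  grid
}

#' Ungroup a block, restoring the pre-grouping patient order exactly
#' @inheritParams sortBlock
#' @export
ungroupBlock <- function(grid, pos) {
  b <- blockAt(grid, pos)
  if (!b@grouped) return(grid)
  b@order <- b@grouping@preGroupOrder
  b@grouped <- FALSE
  b@grouping <- NULL
  grid@blocks[[pos]] <- b
  grid
}

#' @describeIn groupBlock the [GroupedBlock-class] of a grouped block.
#' @export
groupedBlock <- function(grid, pos) {
  b <- blockAt(grid, pos)
  if (!b@grouped) stop("block at position ", pos, " is not grouped")
  b@grouping
}

## drawn column position of each present patient in a block
drawnPositions <- function(block) {
  drawn <- block@order[!block@gap[block@order]]
  stats::setNames(seq_along(drawn), drawn)
}

groupOf <- function(block, patients) {
  gs <- block@grouping@groups
  out <- stats::setNames(rep(NA_character_, length(patients)), patients)
  for (g in gs) out[g$patients[g$patients %in% patients]] <- g$value
  out
}

#' Connections between two adjacent blocks
#'
#' Both blocks ungrouped: one line per patient present in both, from its
#' drawn column position in the upper block to its position in the lower
#' one. Both grouped: counted group-to-group Sankey flows over the
#' shared patients. Mixed: per-patient lines fanning between a group
#' segment and a column position. Patients present on one side only are
#' reported as entries/exits.
#'
#' @param grid a [BlockGrid-class].
#' @param posA,posB adjacent block positions (`posB = posA + 1`).
#' @return A [FlowSet-class].
#' @export
computeFlows <- function(grid, posA, posB = posA + 1L) {
  if (posB != posA + 1L) stop("blocks must be adjacent")
  A <- blockAt(grid, posA)
  B <- blockAt(grid, posB)
  presA <- A@order[!A@gap[A@order]]
  presB <- B@order[!B@gap[B@order]]
  shared <- intersect(presA, presB)
  entries <- setdiff(presB, presA)
  exits <- setdiff(presA, presB)
  mode <- if (A@grouped && B@grouped) "flows"
          else if (!A@grouped && !B@grouped) "lines"
          else "mixed"
  lines <- data.frame(patient_id = character(0), source = character(0),
                      target = character(0), selected = logical(0),
                      stringsAsFactors = FALSE)
  flows <- list()
  if (mode == "flows") {
    gA <- groupOf(A, shared)
    gB <- groupOf(B, shared)
    ordA <- vapply(A@grouping@groups, `[[`, character(1), "value")
    ordB <- vapply(B@grouping@groups, `[[`, character(1), "value")
    for (ga in ordA) for (gb in ordB) {
      members <- shared[gA[shared] == ga & gB[shared] == gb]
      if (length(members))
        flows[[length(flows) + 1L]] <-
          list(source = ga, target = gb, patients = members)
    }
  } else {
    srcPos <- if (A@grouped) groupOf(A, shared)
              else as.character(drawnPositions(A)[shared])
    tgtPos <- if (B@grouped) groupOf(B, shared)
              else as.character(drawnPositions(B)[shared])
    if (length(shared))
      lines <- data.frame(patient_id = shared,
                          source = unname(srcPos[shared]),
                          target = unname(tgtPos[shared]),
                          selected = FALSE, stringsAsFactors = FALSE)
  }
  new("FlowSet", between = c(as.integer(posA), as.integer(posB)),
      mode = mode, lines = lines, flows = flows,
      entries = entries, exits = exits)
}

#' All flow sets of a grid
#'
#' Flow nodes are the timepoint blocks plus any grouped event blocks; an
#' ungrouped event block is skipped, so flows connect the flanking
#' timepoint blocks directly.
#'
#' @param grid a [BlockGrid-class].
#' @return List of [FlowSet-class], one per consecutive node pair.
#' @export
flowSets <- function(grid) {
  nodes <- which(vapply(grid@blocks, function(b)
    b@kind == "timepoint" || b@grouped, logical(1)))
  if (length(nodes) < 2L) return(list())
  out <- list()
  for (i in seq_len(length(nodes) - 1L))
    out[[i]] <- computeFlowsBetween(grid, nodes[i], nodes[i + 1L])
  out
}

## computeFlows for possibly non-consecutive grid positions (an ungrouped
## event block between two timepoint blocks is transparent to flows)
computeFlowsBetween <- function(grid, posA, posB) {
  fs <- computeFlows(
    local({
      g <- grid
      g@blocks <- g@blocks[c(posA, posB)]
      g
    }), 1L, 2L)
  fs@between <- c(as.integer(posA), as.integer(posB))
  fs
}

#' Flag a patient selection in flow sets and grouped blocks
#'
#' Lines are flagged selected/not; each flow and each group gets a
#' selected-patient count so bands can be partially highlighted; the
#' selection also applies to the timeline view via the returned id set.
#'
#' @param grid a [BlockGrid-class].
#' @param flowsets list of [FlowSet-class] (e.g. from [flowSets()]).
#' @param patients selected patient ids (must exist in the grid).
#' @return `list(flowsets=, groupAnnotations=, selection=)`:
#'   annotated flow sets (slot `highlight` set, `lines$selected`
#'   flagged, each flow gaining `selectedCount`), and a data.frame of
#'   per-group selected counts for every grouped block.
#' @export
highlightSelection <- function(grid, flowsets, patients) {
  unknown <- setdiff(patients, grid@patientIds)
  if (length(unknown))
    stop("unknown patient id(s): ", paste(unknown, collapse = ", "))
  flowsets <- lapply(flowsets, function(fs) {
    fs@highlight <- patients
    if (nrow(fs@lines))
      fs@lines$selected <- fs@lines$patient_id %in% patients
    fs@flows <- lapply(fs@flows, function(fl) {
      fl$selectedCount <- sum(fl$patients %in% patients)
      fl
    })
    fs
  })
  ann <- do.call(rbind, lapply(seq_along(grid@blocks), function(i) {
    b <- grid@blocks[[i]]
    if (!b@grouped) return(NULL)
    do.call(rbind, lapply(b@grouping@groups, function(g)
      data.frame(block_pos = i, group = g$value,
                 size = length(g$patients),
                 selected = sum(g$patients %in% patients),
                 stringsAsFactors = FALSE)))
  }))
  if (is.null(ann))
    ann <- data.frame(block_pos = integer(0), group = character(0),
                      size = integer(0), selected = integer(0))
  list(flowsets = flowsets, groupAnnotations = ann, selection = patients)
}
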