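## Block-grid construction and flexible timepoint alignment.
##
## A timepoint is the ordinal sample index per patient: by default patient
## samples are aligned so every patient's first available sample sits in
## timepoint block 0. shiftPatients()/alignToEvent() edit the per-patient
## assignment; the grid is then rebuilt from the assignment, so a shift and
## its reverse restore the original grid exactly.

#' Derive the alternating timepoint/event block grid
#'
#' Timepoint block `t` holds, for each patient, the value at that
#' patient's `t`-th assigned sample (a gap where the patient has no
#' sample there). With `includeEvents = TRUE`, event blocks are
#' interleaved between consecutive timepoint blocks; an event is assigned
#' to the interval whose flanking sample dates enclose its start date
#' (left-open, right-closed). Events dated before a patient's first or
#' after their last sample land in the event block immediately preceding
#' or following that patient's occupied range — a leading or trailing
#' block when that range touches the grid edge — so no event is dropped.
#'
#' @param cohort a [Cohort-class].
#' @param displayedFeatures feature ids to show as rows. Sample- and
#'   patient-level features become timepoint-block rows; event-level
#'   features become event-block rows.
#' @param includeEvents interleave event blocks.
#' @return A [BlockGrid-class].
#' @export
deriveBlocks <- function(cohort, displayedFeatures,
                         includeEvents = FALSE) {
  unknown <- setdiff(displayedFeatures, names(cohort@features))
  if (length(unknown))
    stop("displayed feature(s) not registered: ",
         paste(unknown, collapse = ", "))
  lv <- vapply(displayedFeatures,
               function(id) cohort@features[[id]]@level, character(1))
  if (!includeEvents && any(lv == "event"))
    stop("event-level feature(s) displayed but includeEvents is FALSE: ",
         paste(displayedFeatures[lv == "event"], collapse = ", "))
  s <- cohort@samples
  assignment <- data.frame(
    patient_id = s$patient_id, sample_id = s$sample_id,
    block = as.integer(stats::ave(rep(0L, nrow(s)), s$patient_id,
                                  FUN = function(z) seq_along(z) - 1L)),
    stringsAsFactors = FALSE)
  materializeGrid(cohort, displayedFeatures, includeEvents, assignment)
}

## Rebuild all Block objects from the sample-to-timepoint assignment.
materializeGrid <- function(cohort, displayedFeatures, includeEvents,
                            assignment) {
  pats <- cohort@patientIds
  nT <- max(assignment$block) + 1L
  tpRows <- displayedFeatures[vapply(displayedFeatures, function(id)
    cohort@features[[id]]@level, character(1)) != "event"]
  evRows <- setdiff(displayedFeatures, tpRows)

  ## per-patient occupied block range and dates
  occ <- lapply(stats::setNames(pats, pats), function(p) {
    a <- assignment[assignment$patient_id == p, , drop = FALSE]
    a <- a[order(a$block), , drop = FALSE]
    dates <- cohort@samples$date[match(a$sample_id, cohort@samples$sample_id)]
    list(blocks = a$block, samples = a$sample_id, dates = dates)
  })

  tpBlocks <- lapply(seq_len(nT) - 1L, function(t) {
    sid <- vapply(pats, function(p) {
      i <- match(t, occ[[p]]$blocks)
      if (is.na(i)) NA_character_ else occ[[p]]$samples[i]
    }, character(1))
    gap <- is.na(sid)
    cells <- lapply(stats::setNames(tpRows, tpRows), function(fid) {
      f <- cohort@features[[fid]]
      v <- if (f@level == "sample") f@values[sid] else f@values[pats]
      v[gap] <- NA
      v <- stats::setNames(v, pats)
      ## carry type metadata for sorting/grouping without a cohort ref
      attr(v, "datatype") <- f@datatype
      attr(v, "domain") <- f@domain
      v
    })
    new("Block", index = t, kind = "timepoint", rows = tpRows,
        columns = pats, sampleIds = stats::setNames(sid, pats),
        gap = stats::setNames(gap, pats), cells = cells,
        order = pats, grouped = FALSE)
  })

  if (!includeEvents)
    return(new("BlockGrid", blocks = tpBlocks, patientIds = pats,
               displayedFeatures = displayedFeatures,
               includeEvents = FALSE, assignment = assignment,
               nTimepoints = nT))

  ## event slot i = interval between timepoint blocks i and i+1;
  ## -1 = leading, nT-1 = trailing.
  slotEvents <- lapply(stats::setNames(pats, pats), function(p) {
    ev <- patientEvents(cohort, p)
    o <- occ[[p]]
    slot <- integer(nrow(ev))
    if (nrow(ev)) for (i in seq_len(nrow(ev))) {
      st <- ev$start_date[i]
      if (st <= o$dates[1]) slot[i] <- o$blocks[1] - 1L
      else if (st > o$dates[length(o$dates)])
        slot[i] <- o$blocks[length(o$blocks)]
      else {
        j <- findInterval(st, o$dates, left.open = TRUE,
                          rightmost.closed = FALSE) # st in (dates[j], dates[j+1]]
        slot[i] <- o$blocks[j]
      }
    }
    split(ev, factor(slot, levels = sort(unique(slot))))
  })

  anyAt <- function(i) any(vapply(pats, function(p)
    !is.null(slotEvents[[p]][[as.character(i)]]) &&
      nrow(slotEvents[[p]][[as.character(i)]]) > 0, logical(1)))
  slots <- seq_len(nT - 1L) - 1L                  # interior intervals
  if (anyAt(-1L)) slots <- c(-1L, slots)
  if (nT >= 1L && anyAt(nT - 1L)) slots <- c(slots, nT - 1L)

  evBlocks <- lapply(slots, function(i) {
    present <- vapply(pats, function(p) {
      b <- occ[[p]]$blocks
      i >= (b[1] - 1L) && i <= b[length(b)]
    }, logical(1))
    evs <- lapply(stats::setNames(pats, pats), function(p) {
      e <- slotEvents[[p]][[as.character(i)]]
      if (is.null(e)) cohort@events[0, , drop = FALSE] else e
    })
    cells <- lapply(stats::setNames(evRows, evRows), function(fid) {
      spec <- cohort@features[[fid]]@eventSpec
      v <- vapply(pats, function(p) {
        if (!present[[p]]) return(NA_integer_)
        m <- eventMatches(evs[[p]], spec$eventType, spec$attribute,
                          spec$value)
        as.integer(nrow(m) > 0)
      }, integer(1))
      v <- stats::setNames(v, pats)
      attr(v, "datatype") <- "binary"
      attr(v, "domain") <- c(0L, 1L)
      v
    })
    new("Block", index = i, kind = "event", rows = evRows,
        columns = pats,
        sampleIds = stats::setNames(rep(NA_character_, length(pats)), pats),
        gap = stats::setNames(!present, pats), cells = cells,
        events = evs, order = pats, grouped = FALSE)
  })
  names(evBlocks) <- as.character(slots)

  ordered <- list()
  if ("-1" %in% names(evBlocks)) ordered <- c(ordered, evBlocks["-1"])
  for (t in seq_len(nT) - 1L) {
    ordered <- c(ordered, list(tpBlocks[[t + 1L]]))
    if (as.character(t) %in% names(evBlocks))
      ordered <- c(ordered, evBlocks[as.character(t)])
  }
  new("BlockGrid", blocks = unname(ordered), patientIds = pats,
      displayedFeatures = displayedFeatures, includeEvents = TRUE,
      assignment = assignment, nTimepoints = nT)
}

#' @describeIn BlockGrid-class the ordered list of [Block-class] layers.
#' @param x a `BlockGrid`.
#' @export
setMethod("blocks", "BlockGrid", function(x) x@blocks)

## positions (1-based) of timepoint blocks within the grid list
timepointPositions <- function(grid) {
  which(vapply(grid@blocks, slot, character(1), "kind") == "timepoint")
}

stopIfGrouped <- function(grid, what) {
  if (any(vapply(grid@blocks, slot, logical(1), "grouped")))
    stop("ungroup all blocks before ", what)
}

#' Shift patients' sample sequences to later or earlier timepoints
#'
#' Moves the whole sample sequence of the selected patients by `offset`
#' timepoint positions, leaving gaps at vacated positions. The grid grows
#' when a shift extends past the last timepoint block. Sort/group state is
#' reset (alignment is applied before view styling).
#'
#' @param cohort the [Cohort-class] the grid was derived from.
#' @param grid a [BlockGrid-class] with no grouped blocks.
#' @param patients patient ids to shift.
#' @param offset signed integer number of timepoint positions.
#' @return A rebuilt [BlockGrid-class].
#' @export
shiftPatients <- function(cohort, grid, patients, offset) {
  stopIfGrouped(grid, "shifting patients")
  unknown <- setdiff(patients, grid@patientIds)
  if (length(unknown))
    stop("unknown patient id(s): ", paste(unknown, collapse = ", "))
  a <- grid@assignment
  sel <- a$patient_id %in% patients
  a$block[sel] <- a$block[sel] + as.integer(offset)
  if (any(a$block < 0))
    stop("shift would place sample(s) at a negative block index")
  materializeGrid(cohort, grid@displayedFeatures, grid@includeEvents, a)
}

#' Realign the cohort relative to an event
#'
#' For every patient with an event matching the filter, the first sample
#' dated on/after the event's start date is moved into a common reference
#' timepoint block (the maximum such index over matching patients, so all
#' shifts are forward). Patients without a matching event keep their
#' default alignment.
#'
#' @param cohort a [Cohort-class].
#' @param grid a [BlockGrid-class] with no grouped blocks.
#' @param eventType event type to match.
#' @param attribute,value optional attribute filter.
#' @return A rebuilt [BlockGrid-class]; attribute `"referenceBlock"`
#'   holds the common post-event timepoint index.
#' @export
alignToEvent <- function(cohort, grid, eventType, attribute = NULL,
                         value = NULL) {
  stopIfGrouped(grid, "realigning")
  a <- grid@assignment
  postIdx <- vapply(grid@patientIds, function(p) {
    ev <- eventMatches(patientEvents(cohort, p), eventType, attribute, value)
    if (!nrow(ev)) return(NA_integer_)
    st <- min(ev$start_date)
    ap <- a[a$patient_id == p, , drop = FALSE]
    ap <- ap[order(ap$block), , drop = FALSE]
    dates <- cohort@samples$date[match(ap$sample_id,
                                       cohort@samples$sample_id)]
    i <- which(dates >= st)
    if (!length(i)) NA_integer_ else ap$block[i[1]]
  }, integer(1))
  matched <- vapply(grid@patientIds, function(p) {
    nrow(eventMatches(patientEvents(cohort, p), eventType, attribute,
                      value)) > 0
  }, logical(1))
  if (!any(matched)) {
    filt <- paste0(eventType,
                   if (!is.null(attribute))
                     paste0(" [", attribute,
                            if (!is.null(value)) paste0("=", value), "]"))
    stop("no patient matches event filter: ", filt)
  }
  aligners <- grid@patientIds[!is.na(postIdx)]
  if (length(aligners)) {
    ref <- max(postIdx, na.rm = TRUE)
    for (off in setdiff(unique(ref - postIdx[aligners]), 0L))
      grid <- shiftPatients(cohort, grid,
                            aligners[(ref - postIdx[aligners]) == off], off)
    attr(grid, "referenceBlock") <- ref
  }
  grid
}

#' Per-patient dated series for the timeline view
#'
#' @param cohort a [Cohort-class].
#' @param featureId a sample-level feature coloring the sample markers.
#' @return Named list (per patient) of `list(samples=, events=)`:
#'   `samples` has `sample_id`, `date`, `value`; `events` has
#'   `event_type`, `start`, `stop`, `duration`, `point` (TRUE for
#'   zero-length/open-ended events drawn as point markers).
#' @export
timelineSeries <- function(cohort, featureId) {
  f <- getFeature(cohort, featureId)
  if (f@level != "sample")
    stop("timeline display feature must be sample-level")
  lapply(stats::setNames(cohort@patientIds, cohort@patientIds),
         function(p) {
    sid <- patientSamples(cohort, p)
    dates <- cohort@samples$date[match(sid, cohort@samples$sample_id)]
    ev <- patientEvents(cohort, p)
    stop <- if (nrow(ev)) ev$stop_date else integer(0)
    start <- if (nrow(ev)) ev$start_date else integer(0)
    stop[is.na(stop)] <- start[is.na(stop)]
    list(
      samples = data.frame(sample_id = sid, date = dates,
                           value = unname(f@values[sid]),
                           stringsAsFactors = FALSE),
      events = data.frame(
        event_type = if (nrow(ev)) ev$event_type else character(0),
        start = start, stop = stop, duration = stop - start,
        point = stop == start, stringsAsFactors = FALSE))
  })
}
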