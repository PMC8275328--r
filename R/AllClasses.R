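#' @import methods
NULL

.DATATYPES <- c("binary", "categorical", "ordinal", "continuous")
.SOURCES <- c("clinical_patient", "clinical_sample", "mutation", "cna",
              "expression", "derived")
.LEVELS <- c("sample", "patient", "event")

#' Feature: a typed cohort variable
#'
#' A `Feature` is one variable measured on samples, patients or events:
#' its datatype (binary, categorical, ordinal, continuous), provenance
#' (clinical file, mutation data, derived transform, ...), value domain and
#' color scale, plus the values themselves keyed by sample or patient id.
#' Event-level features carry an `eventSpec` (an event-type/attribute
#' predicate) instead of stored values; they are evaluated per patient and
#' per between-timepoint interval when blocks are derived.
#'
#' @slot featureId unique id string.
#' @slot displayName human-readable name.
#' @slot datatype one of `"binary"`, `"categorical"`, `"ordinal"`,
#'   `"continuous"`.
#' @slot source one of `"clinical_patient"`, `"clinical_sample"`,
#'   `"mutation"`, `"cna"`, `"expression"`, `"derived"`.
#' @slot level `"sample"`, `"patient"` or `"event"`.
#' @slot domain ordered category vector (categorical/ordinal/binary) or
#'   numeric length-2 range (continuous).
#' @slot colorScale named color vector (per category) or a single scheme
#'   name.
#' @slot values named vector keyed by sample id (level `"sample"`) or
#'   patient id (level `"patient"`); `NA` encodes missing.
#' @slot eventSpec for event-level features: `list(eventType=, attribute=,
#'   value=)`.
#' @exportClass Feature
setClass("Feature",
  representation(
    featureId = "character",
    displayName = "character",
    datatype = "character",
    source = "character",
    level = "character",
    domain = "ANY",
    colorScale = "ANY",
    values = "ANY",
    eventSpec = "list"
  ),
  prototype(domain = NULL, colorScale = character(0), values = NULL,
            eventSpec = list())
)

setValidity("Feature", function(object) {
  msg <- character(0)
  if (length(object@featureId) != 1L || !nzchar(object@featureId))
    msg <- c(msg, "featureId must be a single non-empty string")
  if (!object@datatype %in% .DATATYPES)
    msg <- c(msg, sprintf("datatype must be one of: %s",
                          paste(.DATATYPES, collapse = ", ")))
  if (!object@source %in% .SOURCES)
    msg <- c(msg, sprintf("source must be one of: %s",
                          paste(.SOURCES, collapse = ", ")))
  if (!object@level %in% .LEVELS)
    msg <- c(msg, "level must be sample, patient or event")
  v <- object@values
  if (object@level != "event" && length(v)) {
    if (is.null(names(v)) || any(!nzchar(names(v))))
      msg <- c(msg, "values must be named by sample/patient id")
    if (object@datatype %in% c("categorical", "ordinal")) {
      bad <- setdiff(unique(v[!is.na(v)]), object@domain)
      if (length(bad))
        msg <- c(msg, sprintf("values outside declared domain: %s",
                              paste(bad, collapse = ", ")))
      if (anyDuplicated(object@domain))
        msg <- c(msg, "domain categories must be unique")
    }
    if (object@datatype == "binary") {
      bad <- setdiff(unique(v[!is.na(v)]), c(0, 1))
      if (length(bad)) msg <- c(msg, "binary values must be 0/1 or NA")
    }
    if (object@datatype == "continuous" && !is.numeric(v))
      msg <- c(msg, "continuous values must be numeric")
  }
  if (length(msg)) msg else TRUE
})

#' Cohort: patients, timepoint samples, events and registered features
#'
#' The central container. Patients are kept in input order; each patient
#' has an ordered (by date) list of samples and a set of dated events.
#' Features live in a registry keyed by feature id, and every
#' feature-modifying operation appends a `TransformRecord` to the
#' operation log so any derived state can be replayed deterministically
#' (see [replayOpLog()]).
#'
#' @slot patientIds patient ids, input order.
#' @slot samples data.frame with columns `patient_id`, `sample_id`,
#'   `date` (integer days from the per-patient reference), ordered by
#'   patient then date.
#' @slot events data.frame with columns `patient_id`, `event_type`,
#'   `start_date`, `stop_date` (NA allowed) plus free attribute columns.
#' @slot features named list of [Feature-class] objects.
#' @slot opLog list of transform records `list(op=, params=, stamp=)`.
#' @exportClass Cohort
setClass("Cohort",
  representation(
    patientIds = "character",
    samples = "data.frame",
    events = "data.frame",
    features = "list",
    opLog = "list"
  )
)

setValidity("Cohort", function(object) {
  msg <- character(0)
  if (anyDuplicated(object@patientIds))
    msg <- c(msg, "duplicate patient ids")
  s <- object@samples
  if (!all(c("patient_id", "sample_id", "date") %in% names(s)))
    msg <- c(msg, "samples must have patient_id, sample_id, date")
  else {
    if (anyDuplicated(s$sample_id))
      msg <- c(msg, "duplicate sample ids across cohort")
    if (!all(s$patient_id %in% object@patientIds))
      msg <- c(msg, "sample referencing unknown patient")
    if (!all(object@patientIds %in% s$patient_id))
      msg <- c(msg, "every patient needs at least one sample")
    bad <- vapply(split(s$date, s$patient_id),
                  function(d) is.unsorted(d), logical(1))
    if (any(bad))
      msg <- c(msg, "sample dates must be non-decreasing per patient")
  }
  e <- object@events
  if (nrow(e)) {
    if (!all(c("patient_id", "event_type", "start_date") %in% names(e)))
      msg <- c(msg, "events must have patient_id, event_type, start_date")
    else {
      if (!all(e$patient_id %in% object@patientIds))
        msg <- c(msg, "event referencing unknown patient")
      if ("stop_date" %in% names(e)) {
        bad <- !is.na(e$stop_date) & e$stop_date < e$start_date
        if (any(bad)) msg <- c(msg, "stop_date before start_date")
      }
    }
  }
  for (f in object@features) {
    if (f@level == "sample") {
      unknown <- setdiff(names(f@values), s$sample_id)
      if (length(unknown))
        msg <- c(msg, sprintf("feature '%s' references unknown sample(s): %s",
                              f@featureId,
                              paste(utils::head(unknown, 3), collapse = ", ")))
    } else if (f@level == "patient") {
      unknown <- setdiff(names(f@values), object@patientIds)
      if (length(unknown))
        msg <- c(msg, sprintf("feature '%s' references unknown patient(s)",
                              f@featureId))
    }
  }
  if (length(object@features) &&
      !identical(names(object@features),
                 unname(vapply(object@features, slot, character(1),
                               "featureId"))))
    msg <- c(msg, "feature registry names must equal feature ids")
  if (length(msg)) msg else TRUE
})

#' Block: one timepoint or event layer of the block view
#'
#' A block holds, for every patient column, either a cell value per
#' displayed feature row or a gap (the patient has no sample/event at this
#' layer). Sorting and grouping state is per block: `order` is the drawn
#' permutation of patient columns, `grouped` flags a proportion view and
#' `grouping` then carries the [GroupedBlock-class] partition.
#'
#' @slot index timepoint index (0-based) for timepoint blocks; for event
#'   blocks, the index of the interval: `i` means between timepoints `i`
#'   and `i+1`, `-1` the leading block, `nTimepoints-1` the trailing one.
#' @slot kind `"timepoint"` or `"event"`.
#' @slot rows displayed feature ids (shared across blocks).
#' @slot columns all patient ids.
#' @slot sampleIds named by patient: the sample shown here (`NA` = gap;
#'   event blocks use `NA`).
#' @slot gap named logical: patient has no sample/interval at this block.
#' @slot cells list keyed by feature id of named (by patient) value
#'   vectors; `NA` = missing measurement, distinct from gap.
#' @slot events event blocks: list keyed by patient of event data.frames.
#' @slot order permutation of `columns` (current drawn order).
#' @slot grouped logical flag.
#' @slot primaryFeature feature id the block is sorted/grouped by (`NA`
#'   if none).
#' @slot grouping `GroupedBlock` when grouped, else `NULL`.
#' @exportClass Block
setClass("Block",
  representation(
    index = "integer",
    kind = "character",
    rows = "character",
    columns = "character",
    sampleIds = "character",
    gap = "logical",
    cells = "list",
    events = "list",
    order = "character",
    grouped = "logical",
    primaryFeature = "character",
    grouping = "ANY"
  ),
  prototype(events = list(), grouped = FALSE, primaryFeature = NA_character_,
            grouping = NULL)
)

setValidity("Block", function(object) {
  msg <- character(0)
  if (!object@kind %in% c("timepoint", "event"))
    msg <- c(msg, "kind must be timepoint or event")
  if (!setequal(object@order, object@columns) ||
      length(object@order) != length(object@columns))
    msg <- c(msg, "order must be a permutation of columns")
  if (!identical(sort(names(object@gap)), sort(object@columns)))
    msg <- c(msg, "gap must be named by all patient columns")
  if (length(msg)) msg else TRUE
})

#' GroupedBlock: proportion view of a block
#'
#' Partition of a block's present, non-missing-primary patients by the
#' primary feature's value, with per-group nested summaries of the other
#' displayed features (categorical: value counts; continuous: five-number
#' summary plus the raw values for gradient rendering). Patients whose
#' primary value is missing form an explicit `"(missing)"` group rendered
#' last.
#'
#' @slot blockPos position of the source block in its grid (1-based).
#' @slot primaryFeature grouping feature id.
#' @slot groups ordered list of `list(value=, patients=)`, order following
#'   the primary feature's domain order.
#' @slot nestedSummaries list keyed by group value, then by feature id.
#' @slot preGroupOrder patient order to restore on ungrouping.
#' @exportClass GroupedBlock
setClass("GroupedBlock",
  representation(
    blockPos = "integer",
    primaryFeature = "character",
    groups = "list",
    nestedSummaries = "list",
    preGroupOrder = "character"
  )
)

#' BlockGrid: the full alternating block-view layout state
#'
#' Ordered list of [Block-class] layers (timepoint blocks always present,
#' event blocks interleaved when requested) plus the per-patient
#' assignment of samples to timepoint indices, which flexible alignment
#' ([shiftPatients()], [alignToEvent()]) edits.
#'
#' @slot blocks list of `Block` in drawn (top-to-bottom) order.
#' @slot patientIds all patient ids, cohort order.
#' @slot displayedFeatures feature ids shown as rows.
#' @slot includeEvents whether event blocks are interleaved.
#' @slot assignment data.frame `patient_id`, `sample_id`, `block`
#'   (0-based timepoint index after any shifts).
#' @slot nTimepoints number of timepoint blocks.
#' @exportClass BlockGrid
setClass("BlockGrid",
  representation(
    blocks = "list",
    patientIds = "character",
    displayedFeatures = "character",
    includeEvents = "logical",
    assignment = "data.frame",
    nTimepoints = "integer"
  )
)

setValidity("BlockGrid", function(object) {
  msg <- character(0)
  kinds <- vapply(object@blocks, slot, character(1), "kind")
  if (sum(kinds == "timepoint") != object@nTimepoints)
    msg <- c(msg, "nTimepoints must equal the number of timepoint blocks")
  a <- object@assignment
  if (any(a$block < 0)) msg <- c(msg, "negative timepoint assignment")
  if (length(msg)) msg else TRUE
})

#' FlowSet: connections between two adjacent blocks
#'
#' Between two ungrouped blocks the connections are per-patient lines;
#' between two grouped blocks they are counted group-to-group Sankey
#' flows; mixed pairs fan lines from/to group segments. Patients present
#' on only one side are reported as entries/exits.
#'
#' @slot between grid positions (1-based) of the two connected blocks.
#' @slot mode `"lines"`, `"flows"` or `"mixed"`.
#' @slot lines data.frame `patient_id`, `source`, `target` (drawn column
#'   positions, or group labels on a grouped side), `selected`.
#' @slot flows list of `list(source=, target=, patients=)` for
#'   grouped-grouped pairs, ordered by source then target group order.
#' @slot entries patients present only in the lower block.
#' @slot exits patients present only in the upper block.
#' @slot highlight currently selected patient ids.
#' @slot proxyColors list(source=, target=) named color vectors repeating
#'   each side's primary-feature colors at the band ends.
#' @exportClass FlowSet
setClass("FlowSet",
  representation(
    between = "integer",
    mode = "character",
    lines = "data.frame",
    flows = "list",
    entries = "character",
    exits = "character",
    highlight = "character",
    proxyColors = "list"
  ),
  prototype(highlight = character(0), proxyColors = list())
)

#' SyntheticCohortConfig: parameters of the seeded cohort generator
#'
#' @slot nPatients number of patients.
#' @slot timepointWeights named weights over timepoint counts
#'   (names "2","3","4", summing to 1).
#' @slot categoricalFeatures list of specs: `list(id=, name=, categories=,
#'   initWeights=, switchProb=)` — per-patient first-order Markov chain
#'   with switch probability `p`.
#' @slot continuousFeatures list of specs: `list(id=, name=, baselineMean=,
#'   baselineSd=, drift=, noiseSd=)` — per-patient random walk.
#' @slot eventSpec `list(eventType=, attributes=, prob=)` — per-patient
#'   occurrence probability of one inter-timepoint event.
#' @slot effectSpec `list(feature=, prob=, threshold=)` — probability q
#'   that the timepoint following the event has the designated continuous
#'   feature raised above the threshold (emulating treatment-induced
#'   hypermutation).
#' @slot mafGenes gene symbols for generated binary mutation features.
#' @slot seed RNG seed; all generator randomness flows from it.
#' @exportClass SyntheticCohortConfig
setClass("SyntheticCohortConfig",
  representation(
    nPatients = "integer",
    timepointWeights = "numeric",
    categoricalFeatures = "list",
    continuousFeatures = "list",
    eventSpec = "list",
    effectSpec = "list",
    mafGenes = "character",
    seed = "integer"
  )
)

setValidity("SyntheticCohortConfig", function(object) {
  msg <- character(0)
  if (object@nPatients < 1L) msg <- c(msg, "nPatients must be >= 1")
  w <- object@timepointWeights
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
    msg <- c(msg, "timepointWeights must be non-negative and sum to 1")
  probs <- c(vapply(object@categoricalFeatures,
                    function(s) s$switchProb, numeric(1)),
             object@eventSpec$prob, object@effectSpec$prob)
  if (any(probs < 0 | probs > 1))
    msg <- c(msg, "all probabilities must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "Feature", function(object) {
  nv <- length(object@values)
  cat(sprintf("Feature '%s' (%s): %s %s-level, %d value(s)\n",
              object@featureId, object@displayName, object@datatype,
              object@level, nv))
  if (!is.null(object@domain))
    cat("  domain: ", paste(utils::head(object@domain, 8), collapse = " < "),
        "\n", sep = "")
})

setMethod("show", "Cohort", function(object) {
  cat(sprintf("Cohort: %d patient(s), %d sample(s), %d event(s), %d feature(s)\n",
              length(object@patientIds), nrow(object@samples),
              nrow(object@events), length(object@features)))
  cat(sprintf("  op log: %d record(s)\n", length(object@opLog)))
})

setMethod("show", "Block", function(object) {
  cat(sprintf("%s block [index %d]: %d feature row(s) x %d patient(s), %d gap(s)%s\n",
              object@kind, object@index, length(object@rows),
              length(object@columns), sum(object@gap),
              if (object@grouped)
                sprintf(", grouped by '%s'", object@primaryFeature) else ""))
})

setMethod("show", "BlockGrid", function(object) {
  kinds <- vapply(object@blocks, slot, character(1), "kind")
  cat(sprintf("BlockGrid: %d block(s) (%d timepoint, %d event), %d patient(s), %d feature row(s)\n",
              length(object@blocks), sum(kinds == "timepoint"),
              sum(kinds == "event"), length(object@patientIds),
              length(object@displayedFeatures)))
})

setMethod("show", "FlowSet", function(object) {
  cat(sprintf("FlowSet between blocks %d-%d, mode=%s: %d line(s), %d flow(s)\n",
              object@between[1], object@between[2], object@mode,
              nrow(object@lines), length(object@flows)))
})
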