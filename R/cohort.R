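#' Construct a Feature
#'
#' @param featureId unique id.
#' @param datatype `"binary"`, `"categorical"`, `"ordinal"` or
#'   `"continuous"`.
#' @param values named vector (names = sample or patient ids). Binary
#'   features use 0/1; missing is `NA`.
#' @param displayName human-readable name (defaults to `featureId`).
#' @param source data provenance; defaults to `"derived"`.
#' @param level `"sample"`, `"patient"` or `"event"`.
#' @param domain category order (categorical/ordinal). Defaults to sorted
#'   unique observed values; continuous features get the observed range.
#' @param colorScale named colors per category or a scheme name; defaults
#'   are assigned at render time.
#' @return A [Feature-class] object.
#' @export
makeFeature <- function(featureId, datatype, values,
                        displayName = featureId, source = "derived",
                        level = "sample", domain = NULL,
                        colorScale = character(0)) {
  if (datatype == "binary") {
    values <- stats::setNames(as.integer(values), names(values))
    if (is.null(domain)) domain <- c(0L, 1L)
  } else if (datatype == "continuous") {
    values <- stats::setNames(as.numeric(values), names(values))
    if (is.null(domain)) domain <- featureRange(values)
  } else {
    values <- stats::setNames(as.character(values), names(values))
    if (is.null(domain)) domain <- sortStrings(unique(values[!is.na(values)]))
  }
  new("Feature", featureId = featureId, displayName = displayName,
      datatype = datatype, source = source, level = level,
      domain = domain, colorScale = colorScale, values = values)
}

featureRange <- function(v) {
  v <- v[!is.na(v)]
  if (!length(v)) c(NA_real_, NA_real_) else range(v)
}

## locale-independent deterministic string ordering
sortStrings <- function(x) x[order(x, method = "radix")]

#' Define an event-level feature
#'
#' Event-level features are binary indicators evaluated per patient and
#' per event block: 1 if the patient has at least one event matching the
#' predicate in that block's interval, else 0. Displaying one requires
#' `includeEvents = TRUE` in [deriveBlocks()].
#'
#' @param featureId unique id.
#' @param eventType event type to match (e.g. `"TREATMENT"`).
#' @param attribute,value optional attribute filter (e.g.
#'   `attribute = "AGENT", value = "TMZ"`).
#' @param displayName human-readable name.
#' @return A [Feature-class] with `level = "event"`.
#' @export
makeEventFeature <- function(featureId, eventType, attribute = NULL,
                             value = NULL, displayName = featureId) {
  new("Feature", featureId = featureId, displayName = displayName,
      datatype = "binary", source = "derived", level = "event",
      domain = c(0L, 1L), colorScale = character(0),
      values = stats::setNames(integer(0), character(0)),
      eventSpec = list(eventType = eventType, attribute = attribute,
                       value = value))
}

#' Assemble a Cohort from tables
#'
#' @param samples data.frame with columns `patient_id`, `sample_id` and
#'   optionally `date` (integer days, per-patient reference). Without
#'   dates, samples get consecutive integer dates in input order.
#' @param features list of [Feature-class] objects (or named list).
#' @param events optional data.frame with `patient_id`, `event_type`,
#'   `start_date`, optional `stop_date` and free attribute columns.
#' @param patientOrder optional explicit patient order; defaults to order
#'   of first appearance in `samples`.
#' @return A validated [Cohort-class].
#' @examples
#' co <- buildCohort(
#'   samples = data.frame(patient_id = c("P1", "P1", "P2", "P2"),
#'                        sample_id = c("S1", "S2", "S3", "S4"),
#'                        date = c(0, 300, 0, 400)),
#'   features = list(makeFeature("grade", "categorical",
#'     c(S1 = "II", S2 = "III", S3 = "II", S4 = "II"),
#'     domain = c("II", "III", "IV"))))
#' @export
buildCohort <- function(samples, features = list(), events = NULL,
                        patientOrder = NULL) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!all(c("patient_id", "sample_id") %in% names(samples)))
    stop("samples must have patient_id and sample_id columns")
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample id(s): ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  if (is.null(samples$date)) {
    samples$date <- stats::ave(rep(0L, nrow(samples)), samples$patient_id,
                               FUN = function(z) seq_along(z) - 1L)
  }
  samples$date <- as.integer(samples$date)
  if (is.null(patientOrder)) patientOrder <- unique(samples$patient_id)
  ## order samples by (patient input order, date), stably
  pidx <- match(samples$patient_id, patientOrder)
  samples <- samples[order(pidx, samples$date, method = "radix"), , drop = FALSE]
  rownames(samples) <- NULL
  if (is.null(events))
    events <- data.frame(patient_id = character(0),
                         event_type = character(0),
                         start_date = integer(0), stop_date = integer(0),
                         stringsAsFactors = FALSE)
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  if (nrow(events)) {
    events$start_date <- as.integer(events$start_date)
    if (is.null(events$stop_date)) events$stop_date <- NA_integer_
    events$stop_date <- as.integer(events$stop_date)
  }
  feats <- as.list(features)
  if (length(feats))
    names(feats) <- vapply(feats, slot, character(1), "featureId")
  new("Cohort", patientIds = patientOrder, samples = samples,
      events = events, features = feats, opLog = list())
}

#' Register a feature in a cohort
#' @param cohort a [Cohort-class].
#' @param feature a [Feature-class].
#' @param overwrite replace an existing feature with the same id.
#' @export
addFeature <- function(cohort, feature, overwrite = FALSE) {
  id <- feature@featureId
  if (!overwrite && id %in% names(cohort@features))
    stop("feature '", id, "' already registered")
  cohort@features[[id]] <- feature
  validObject(cohort)
  cohort
}

#' @describeIn Cohort-class patient ids in cohort order.
#' @param x a `Cohort`.
#' @export
setMethod("patientIds", "Cohort", function(x) x@patientIds)

#' @describeIn Cohort-class registered feature ids.
#' @export
setMethod("featureIds", "Cohort", function(x) names(x@features))

#' @describeIn Cohort-class fetch one registered [Feature-class].
#' @param featureId feature id string.
#' @export
setMethod("getFeature", "Cohort", function(x, featureId) {
  f <- x@features[[featureId]]
  if (is.null(f)) stop("unknown feature: ", featureId)
  f
})

#' @describeIn Cohort-class the sample table (`patient_id`, `sample_id`,
#'   `date`).
#' @export
setMethod("sampleTable", "Cohort", function(x) x@samples)

#' @describeIn Cohort-class the event table.
#' @export
setMethod("eventTable", "Cohort", function(x) x@events)

#' @describeIn Cohort-class the transform operation log.
#' @export
setMethod("opLog", "Cohort", function(x) x@opLog)

#' @describeIn Feature-class the named value vector of a feature.
#' @param x a `Feature`.
#' @export
setMethod("featureValues", "Feature", function(x) x@values)

## per-patient ordered sample ids
patientSamples <- function(cohort, patientId) {
  s <- cohort@samples
  s$sample_id[s$patient_id == patientId]
}

## events of one patient as a data.frame (possibly 0 rows)
patientEvents <- function(cohort, patientId) {
  e <- cohort@events
  e[e$patient_id == patientId, , drop = FALSE]
}

eventMatches <- function(events, eventType, attribute = NULL, value = NULL) {
  if (!nrow(events)) return(events)
  keep <- events$event_type == eventType
  if (!is.null(attribute)) {
    if (!attribute %in% names(events)) keep[] <- FALSE
    else if (!is.null(value)) keep <- keep & !is.na(events[[attribute]]) &
        events[[attribute]] == value
    else keep <- keep & !is.na(events[[attribute]])
  }
  events[keep, , drop = FALSE]
}
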