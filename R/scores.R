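## Feature Explorer scoring framework: row (within-timepoint) and column
## (across-timepoint) variability scores, aggregation and ranking.
##
## Notation: n = non-missing observation count, f_m = modal frequency,
## K = number of categories observed in the scored multiset.

#' Mode-based variation (ModVR) of a categorical multiset
#'
#' Freeman's standardized variation ratio
#' `K * (n - f_m) / (n * (K - 1))`: 0 for a constant multiset, 1 exactly
#' when the observations are uniform over `K >= 2` observed categories.
#' `K` counts categories observed in the multiset, not the declared
#' domain.
#'
#' @param values character/factor vector; `NA` dropped. Fewer than 2
#'   non-missing values give `NA`.
#' @return Score in `[0, 1]`, or `NA`.
#' @examples
#' modvr(c("A", "A", "B", "C"))  # 0.75
#' @export
modvr <- function(values) {
  v <- as.character(values)
  v <- v[!is.na(v)]
  n <- length(v)
  if (n < 2L) return(NA_real_)
  tab <- table(v)
  K <- length(tab)
  if (K == 1L) return(0)
  fm <- max(tab)
  K * (n - fm) / (n * (K - 1))
}

#' Coefficient of unalikeability of a categorical multiset
#'
#' The proportion of ordered observation pairs (self-pairs included) that
#' differ: `1 - sum(p_k^2)` over observed category proportions. Bounded
#' by `1 - 1/K`.
#'
#' @inheritParams modvr
#' @return Score in `[0, 1)`, or `NA`.
#' @export
unalikeability <- function(values) {
  v <- as.character(values)
  v <- v[!is.na(v)]
  if (length(v) < 2L) return(NA_real_)
  p <- as.numeric(table(v)) / length(v)
  1 - sum(p^2)
}

#' Coefficient of variation of a numeric multiset
#'
#' Sample standard deviation (n-1 denominator) over the mean. A zero mean
#' gives `NA` with a warning; a negative mean returns the absolute ratio
#' (flagged via attribute `"negativeMean"`), keeping the CV<1 / CV>1
#' reading meaningful.
#'
#' @param values numeric vector; `NA` dropped.
#' @return Score `>= 0`, or `NA`.
#' @export
coefficientOfVariation <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2L) return(NA_real_)
  m <- mean(v)
  if (m == 0) {
    warning("coefficient of variation undefined for zero mean")
    return(NA_real_)
  }
  out <- abs(stats::sd(v) / m)
  if (m < 0) attr(out, "negativeMean") <- TRUE
  out
}

#' Sample variance (n-1 denominator) of a numeric multiset
#' @inheritParams coefficientOfVariation
#' @export
varianceScore <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2L) return(NA_real_)
  stats::var(v)
}

#' Rate of change of a per-patient categorical series
#'
#' Number of adjacent-timepoint transitions with a changed value over the
#' number of valid transitions. Pairs with a missing member (or spanning
#' a gap) are excluded from both counts.
#'
#' @param series values in timepoint order for one patient.
#' @return Score in `[0, 1]`; `NA` when no valid adjacent pair exists.
#' @export
rateOfChangeCategorical <- function(series) {
  v <- as.character(series)
  a <- v[-length(v)]
  b <- v[-1L]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NA_real_)
  sum(a[ok] != b[ok]) / sum(ok)
}

#' Rate of change of a per-patient continuous series
#'
#' Mean absolute step over valid adjacent pairs, divided by the
#' cohort-wide observed range of the feature. A zero range (constant
#' feature) scores 0 by convention.
#'
#' @param series values in timepoint order for one patient.
#' @param featureRange observed cohort-wide `max - min`.
#' @return Score in `[0, 1]`; `NA` when no valid adjacent pair exists.
#' @export
rateOfChangeContinuous <- function(series, featureRange) {
  v <- as.numeric(series)
  a <- v[-length(v)]
  b <- v[-1L]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NA_real_)
  if (featureRange <= 0) return(0)
  mean(abs(b[ok] - a[ok])) / featureRange
}

#' Score definitions available to [scoreFeature()] and [rankFeatures()]
#'
#' Row scores are computed once per timepoint block over the patients
#' present there; column scores once per patient over that patient's
#' timepoint series.
#'
#' @return data.frame with `score`, `orientation`, `datatypes`.
#' @export
scoreDefinitions <- function() {
  data.frame(
    score = c("modvr", "unalikeability", "cv", "variance", "roc"),
    orientation = c("row", "row", "row", "row", "column"),
    datatypes = c("binary,categorical,ordinal",
                  "binary,categorical,ordinal",
                  "continuous", "continuous",
                  "binary,categorical,ordinal,continuous"),
    stringsAsFactors = FALSE)
}

scoreApplicable <- function(score, datatype) {
  defs <- scoreDefinitions()
  dts <- strsplit(defs$datatypes[defs$score == score], ",")[[1]]
  datatype %in% dts
}

## per-block value multisets of a feature (timepoint blocks only)
rowMultisets <- function(grid, featureId) {
  lapply(Filter(function(b) b@kind == "timepoint", grid@blocks),
         function(b) {
    v <- b@cells[[featureId]]
    v[!b@gap[names(v)]]
  })
}

## per-patient series of a feature across timepoint blocks (NA at gaps,
## so pairs spanning a gap are excluded, not bridged)
columnSeries <- function(grid, featureId) {
  tps <- Filter(function(b) b@kind == "timepoint", grid@blocks)
  numericCells <- is.numeric(tps[[1]]@cells[[featureId]])
  lapply(stats::setNames(grid@patientIds, grid@patientIds), function(p) {
    if (numericCells)
      vapply(tps, function(b)
        if (b@gap[[p]]) NA_real_ else as.numeric(b@cells[[featureId]][[p]]),
        numeric(1))
    else
      vapply(tps, function(b)
        if (b@gap[[p]]) NA_character_ else b@cells[[featureId]][[p]],
        character(1))
  })
}

aggregateScores <- function(scores, aggregation) {
  s <- scores[!is.na(scores)]
  if (!length(s)) return(NA_real_)
  switch(aggregation, min = min(s), max = max(s), mean = mean(s),
         stop("aggregation must be min, max or mean"))
}

#' Aggregate variability score of one feature
#'
#' Row scores (`modvr`, `unalikeability`, `cv`, `variance`) are computed
#' per timepoint block across patients; the column score (`roc`, rate of
#' change, dispatching on datatype) is computed per patient across that
#' patient's timepoints. The per-block or per-patient scores are then
#' aggregated with the chosen statistic, ignoring missing entries.
#'
#' @param cohort a [Cohort-class].
#' @param grid a [BlockGrid-class].
#' @param featureId scored feature.
#' @param score one of [scoreDefinitions()]'s names.
#' @param aggregation `"min"`, `"max"` or `"mean"`.
#' @return A scalar score, or `NA`; attribute `"perUnit"` carries the
#'   pre-aggregation per-block or per-patient scores.
#' @export
scoreFeature <- function(cohort, grid, featureId, score,
                         aggregation = c("mean", "min", "max")) {
  aggregation <- match.arg(aggregation)
  f <- getFeature(cohort, featureId)
  if (!scoreApplicable(score, f@datatype))
    stop("score '", score, "' is not applicable to ", f@datatype,
         " feature '", featureId, "'")
  per <- if (score == "roc") {
    series <- columnSeries(grid, featureId)
    if (f@datatype == "continuous") {
      rng <- diff(featureRange(f@values))
      vapply(series, rateOfChangeContinuous, numeric(1),
             featureRange = rng)
    } else {
      vapply(series, rateOfChangeCategorical, numeric(1))
    }
  } else {
    fn <- switch(score, modvr = modvr, unalikeability = unalikeability,
                 cv = function(v) as.numeric(coefficientOfVariation(v)),
                 variance = varianceScore)
    vapply(rowMultisets(grid, featureId), fn, numeric(1))
  }
  out <- aggregateScores(per, aggregation)
  attr(out, "perUnit") <- per
  out
}

#' Rank features by variability scores
#'
#' One score column per request; descending rank per column (the most
#' variable feature is rank 1, ties share the minimum rank) with
#' missing scores placed after all scored features. Metadata columns
#' (display name, datatype, source, observed range or categories) are
#' always present.
#'
#' @param cohort a [Cohort-class].
#' @param grid a [BlockGrid-class].
#' @param scoreRequests list of `list(score=, aggregation=)`.
#' @param featureIds features to rank; defaults to the grid's displayed
#'   non-event features.
#' @return A `data.frame` score table.
#' @export
rankFeatures <- function(cohort, grid, scoreRequests,
                         featureIds = NULL) {
  if (!length(scoreRequests)) stop("at least one score request required")
  if (is.null(featureIds))
    featureIds <- Filter(function(id)
      cohort@features[[id]]@level != "event", grid@displayedFeatures)
  if (!length(featureIds)) stop("no features to rank")
  meta <- do.call(rbind, lapply(featureIds, function(id) {
    f <- cohort@features[[id]]
    rng <- if (f@datatype == "continuous")
      paste(signif(featureRange(f@values), 6), collapse = "..")
    else paste(f@domain, collapse = ",")
    data.frame(feature_id = id, name = f@displayName,
               datatype = f@datatype, source = f@source,
               range_or_categories = rng, stringsAsFactors = FALSE)
  }))
  for (req in scoreRequests) {
    col <- paste0(req$score, "_", req$aggregation)
    s <- vapply(featureIds, function(id) {
      f <- cohort@features[[id]]
      if (!scoreApplicable(req$score, f@datatype)) return(NA_real_)
      as.numeric(scoreFeature(cohort, grid, id, req$score,
                              req$aggregation))
    }, numeric(1))
    r <- rank(-s, ties.method = "min", na.last = "keep")
    r[is.na(s)] <- sum(!is.na(s)) + 1L
    meta[[col]] <- unname(s)
    meta[[paste0("rank_", col)]] <- as.integer(unname(r))
  }
  rownames(meta) <- NULL
  meta
}

#' Write a score table to TSV and JSON
#' @param scoreTable result of [rankFeatures()].
#' @param pathStem output path without extension; writes
#'   `<stem>.tsv` and `<stem>.json`.
#' @return The written paths, invisibly.
#' @export
writeScoreTable <- function(scoreTable, pathStem) {
  tsv <- paste0(pathStem, ".tsv")
  json <- paste0(pathStem, ".json")
  utils::write.table(scoreTable, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(scoreTable, json, dataframe = "rows", digits = NA,
                       auto_unbox = TRUE, na = "null")
  invisible(c(tsv, json))
}
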