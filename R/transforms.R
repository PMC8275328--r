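## Feature Manager: type conversions, binning, log transform, Boolean and
## gene-set combination, inversion, renaming, color scales, feature order.
##
## Every transform goes through applyOp(), which performs the operation
## and appends one TransformRecord, so replayOpLog() rebuilds the exact
## feature state from the raw cohort.

newRecord <- function(cohort, op, params) {
  c(cohort@opLog,
    list(list(op = op, params = params, stamp = length(cohort@opLog) + 1L)))
}

applyOp <- function(cohort, op, params) {
  fn <- .opTable[[op]]
  if (is.null(fn)) stop("unknown transform op: ", op)
  cohort <- fn(cohort, params)
  cohort@opLog <- newRecord(cohort, op, params)
  validObject(cohort)
  cohort
}

#' Replay an operation log on a freshly built cohort
#'
#' Deterministic transforms mean a raw cohort plus a log replays to the
#' identical feature state (and hence cell-identical blocks).
#'
#' @param cohort a raw [Cohort-class] (as returned by [buildCohort()]).
#' @param log an op log, e.g. `opLog(otherCohort)`.
#' @return The cohort with all logged transforms re-applied.
#' @export
replayOpLog <- function(cohort, log) {
  for (rec in log) cohort <- applyOp(cohort, rec$op, rec$params)
  cohort
}

derivedId <- function(cohort, base) {
  id <- base
  k <- 1L
  while (id %in% names(cohort@features)) {
    k <- k + 1L
    id <- paste0(base, k)
  }
  id
}

## ---- op implementations (params-only, deterministic) ----

.opBin <- function(cohort, p) {
  f <- getFeature(cohort, p$featureId)
  if (f@datatype != "continuous")
    stop("bin requires a continuous feature, got ", f@datatype)
  edges <- as.numeric(p$edges)
  labels <- as.character(p$labels)
  if (!length(edges)) stop("bin edges must be non-empty")
  if (is.unsorted(edges, strictly = TRUE))
    stop("bin edges must be strictly increasing")
  if (length(labels) != length(edges) + 1L || anyDuplicated(labels))
    stop("need length(edges)+1 unique bin labels")
  v <- f@values
  if (!is.numeric(v)) stop("non-numeric value encountered")
  ## v >= edge goes to the upper bin ('<150' vs '>=150')
  idx <- findInterval(v, edges, left.open = FALSE) + 1L
  out <- stats::setNames(labels[idx], names(v))
  out[is.na(v)] <- NA_character_
  g <- makeFeature(p$newId, "ordinal", out, displayName = p$newName,
                   source = "derived", level = f@level, domain = labels)
  addFeature(cohort, g)
}

.opLogT <- function(cohort, p) {
  f <- getFeature(cohort, p$featureId)
  if (f@datatype != "continuous")
    stop("log transform requires a continuous feature")
  v <- f@values + p$pseudocount
  bad <- !is.na(v) & v <= 0
  if (any(bad))
    stop("nonpositive value(s) after pseudocount for: ",
         paste(names(v)[bad], collapse = ", "))
  out <- log(v, base = p$base)
  g <- makeFeature(p$newId, "continuous", out, displayName = p$newName,
                   source = "derived", level = f@level)
  addFeature(cohort, g)
}

.opCombine <- function(cohort, p) {
  feats <- lapply(p$featureIds, getFeature, x = cohort)
  if (length(feats) < 2L) stop("combining requires at least 2 features")
  lvls <- unique(vapply(feats, slot, character(1), "level"))
  if (length(lvls) != 1L) stop("combined features must share a level")
  op <- p$operator
  dts <- vapply(feats, slot, character(1), "datatype")
  if (op %in% c("AND", "OR") && any(dts != "binary"))
    stop(op, " requires binary inputs")
  if (op == "MEAN" && any(dts != "continuous"))
    stop("MEAN requires continuous inputs")
  ids <- Reduce(union, lapply(feats, function(f) names(f@values)))
  ids <- sortStrings(ids)
  mat <- vapply(feats, function(f) as.numeric(f@values[ids]),
                numeric(length(ids)))
  if (length(ids) == 1L) mat <- matrix(mat, nrow = 1L)
  if (op %in% c("AND", "OR")) {
    ## fold over non-missing inputs; all-missing -> missing
    comb <- apply(mat, 1L, function(r) {
      r <- r[!is.na(r)]
      if (!length(r)) NA_integer_
      else if (op == "OR") as.integer(any(r == 1))
      else as.integer(all(r == 1))
    })
    ## short-circuit cases are already covered by the fold; an AND with a
    ## missing member but no observed 0 stays driven by observed values —
    ## except the undecidable (all-observed-1 + missing) case, which we
    ## resolve to missing since a hidden 0 could flip it
    if (op == "AND") {
      undec <- apply(mat, 1L, function(r)
        any(is.na(r)) && all(r[!is.na(r)] == 1) && any(!is.na(r)))
      comb[undec] <- NA_integer_
    }
    g <- makeFeature(p$newId, "binary", stats::setNames(comb, ids),
                     displayName = p$newName, source = "derived",
                     level = lvls)
  } else if (op == "MEAN") {
    comb <- apply(mat, 1L, function(r)
      if (all(is.na(r))) NA_real_ else mean(r, na.rm = TRUE))
    g <- makeFeature(p$newId, "continuous", stats::setNames(comb, ids),
                     displayName = p$newName, source = "derived",
                     level = lvls)
  } else stop("operator must be AND, OR or MEAN")
  addFeature(cohort, g)
}

.opInvert <- function(cohort, p) {
  f <- getFeature(cohort, p$featureId)
  if (f@datatype != "binary") stop("invert requires a binary feature")
  g <- makeFeature(p$newId, "binary", 1L - f@values,
                   displayName = p$newName, source = f@source,
                   level = f@level)
  addFeature(cohort, g)
}

.opToOrdinal <- function(cohort, p) {
  f <- getFeature(cohort, p$featureId)
  if (!f@datatype %in% c("categorical", "ordinal"))
    stop("ordinal conversion requires a categorical feature")
  ord <- as.character(p$order)
  if (!setequal(ord, f@domain) || length(ord) != length(f@domain))
    stop("category_order must be a permutation of the domain; missing: ",
         paste(setdiff(f@domain, ord), collapse = ", "))
  f@datatype <- "ordinal"
  f@domain <- ord
  cohort@features[[f@featureId]] <- f
  cohort
}

.opToCategorical <- function(cohort, p) {
  f <- getFeature(cohort, p$featureId)
  if (f@datatype != "ordinal")
    stop("categorical conversion requires an ordinal feature")
  f@datatype <- "categorical"
  cohort@features[[f@featureId]] <- f
  cohort
}

.opRename <- function(cohort, p) {
  f <- getFeature(cohort, p$featureId)
  f@displayName <- p$newName
  cohort@features[[f@featureId]] <- f
  cohort
}

.opColors <- function(cohort, p) {
  f <- getFeature(cohort, p$featureId)
  f@colorScale <- unlist(p$colorScale)
  cohort@features[[f@featureId]] <- f
  cohort
}

.opTable <- list(
  bin_continuous = .opBin,
  log_transform = .opLogT,
  combine = .opCombine,
  invert_binary = .opInvert,
  to_ordinal = .opToOrdinal,
  to_categorical = .opToCategorical,
  rename = .opRename,
  set_colors = .opColors
)

## ---- exported user surface ----

#' Bin a continuous feature into an ordinal one
#'
#' Value `v` falls in the upper bin of a threshold when `v >= edge`
#' (a 150 edge separates "<150" from ">=150").
#'
#' @param cohort a [Cohort-class].
#' @param featureId continuous feature to bin.
#' @param edges strictly increasing thresholds.
#' @param labels `length(edges) + 1` unique bin labels, low to high.
#' @param newId,newName id/name of the derived ordinal feature.
#' @return The cohort with the new feature registered and the op logged.
#' @export
binFeature <- function(cohort, featureId, edges, labels,
                       newId = derivedId(cohort, paste0(featureId, "_bin")),
                       newName = newId) {
  applyOp(cohort, "bin_continuous",
          list(featureId = featureId, edges = edges, labels = labels,
               newId = newId, newName = newName))
}

#' Log-transform a continuous feature
#' @inheritParams binFeature
#' @param base logarithm base (default 10).
#' @param pseudocount added before taking the log; any nonpositive
#'   shifted value is an error listing the offending ids.
#' @export
logFeature <- function(cohort, featureId, base = 10, pseudocount = 0,
                       newId = derivedId(cohort, paste0(featureId, "_log")),
                       newName = newId) {
  applyOp(cohort, "log_transform",
          list(featureId = featureId, base = base,
               pseudocount = pseudocount, newId = newId, newName = newName))
}

#' Combine features with a Boolean operator or a mean
#'
#' `AND`/`OR` fold binary features (e.g. per-gene mutation indicators
#' into a pathway status track) over non-missing inputs; a row with every
#' input missing stays missing, and an `AND` that cannot be decided from
#' the observed inputs (all observed 1, some missing) is missing. `MEAN`
#' averages continuous features (gene-set aggregation).
#'
#' @inheritParams binFeature
#' @param featureIds two or more input feature ids sharing a level.
#' @param operator `"AND"`, `"OR"` or `"MEAN"`.
#' @param newId,newName id/name of the combined feature.
#' @export
combineFeatures <- function(cohort, featureIds, operator, newId,
                            newName = newId) {
  applyOp(cohort, "combine",
          list(featureIds = featureIds, operator = operator,
               newId = newId, newName = newName))
}

#' Invert a binary feature (0 <-> 1, missing preserved)
#' @inheritParams binFeature
#' @export
invertFeature <- function(cohort, featureId,
                          newId = derivedId(cohort, paste0(featureId, "_inv")),
                          newName = newId) {
  applyOp(cohort, "invert_binary",
          list(featureId = featureId, newId = newId, newName = newName))
}

#' Convert a categorical feature to ordinal (or re-order an ordinal one)
#' @inheritParams binFeature
#' @param order permutation of the feature's domain, lowest first.
#' @export
toOrdinal <- function(cohort, featureId, order) {
  applyOp(cohort, "to_ordinal", list(featureId = featureId, order = order))
}

#' Drop an ordinal feature's order, making it categorical
#' @inheritParams binFeature
#' @export
toCategorical <- function(cohort, featureId) {
  applyOp(cohort, "to_categorical", list(featureId = featureId))
}

#' Rename a feature (display name)
#' @inheritParams binFeature
#' @param newName new display name.
#' @export
renameFeature <- function(cohort, featureId, newName) {
  applyOp(cohort, "rename", list(featureId = featureId, newName = newName))
}

#' Set a feature's color scale
#' @inheritParams binFeature
#' @param colors named category->color map, or a scheme name.
#' @export
setColorScale <- function(cohort, featureId, colors) {
  applyOp(cohort, "set_colors",
          list(featureId = featureId, colorScale = colors))
}

#' Reorder the displayed feature rows of a grid
#'
#' Either a stable sort by an attribute or an explicit permutation,
#' applied to all blocks uniformly.
#'
#' @param grid a [BlockGrid-class].
#' @param cohort the backing [Cohort-class] (for feature metadata).
#' @param sortKey `"datatype"`, `"source"` or `"name"`; ignored when
#'   `explicit` is given.
#' @param explicit explicit permutation of the current rows.
#' @return The grid with every block's rows reordered.
#' @export
reorderFeatures <- function(grid, cohort, sortKey = c("name", "datatype",
                                                      "source"),
                            explicit = NULL) {
  rows <- grid@displayedFeatures
  if (!is.null(explicit)) {
    if (!setequal(explicit, rows) || length(explicit) != length(rows))
      stop("explicit order must be a permutation of the displayed rows")
    newRows <- explicit
  } else {
    sortKey <- match.arg(sortKey)
    key <- switch(sortKey,
      name = vapply(rows, function(id)
        cohort@features[[id]]@displayName, character(1)),
      datatype = match(vapply(rows, function(id)
        cohort@features[[id]]@datatype, character(1)), .DATATYPES),
      source = match(vapply(rows, function(id)
        cohort@features[[id]]@source, character(1)), .SOURCES))
    newRows <- rows[order(key, method = "radix")]   # stable
  }
  grid@displayedFeatures <- newRows
  grid@blocks <- lapply(grid@blocks, function(b) {
    b@rows <- intersect(newRows, b@rows)
    b@cells <- b@cells[b@rows]
    b
  })
  grid
}
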