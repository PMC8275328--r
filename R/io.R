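## cBioPortal-format readers/writers, a cached REST client and the JSON
## view-metadata export.
##
## Clinical files use the cBioPortal dialect: four '#'-prefixed metadata
## header rows (display names, descriptions, datatypes, priorities), then
## a column-name row, then records. Datatypes NUMBER/STRING/BOOLEAN map
## to continuous/categorical/binary. Dates are integer days relative to a
## per-patient reference; no calendar parsing.

#' Read a cBioPortal clinical TSV
#'
#' Files without the `#` metadata headers are accepted with datatype
#' inference (all-numeric column -> continuous) and a warning, to
#' tolerate hand-made fixtures.
#'
#' @param path file path.
#' @param level `"sample"` or `"patient"`.
#' @return `list(features=, data=)`: one [Feature-class] per non-id
#'   column (source `clinical_<level>`) and the raw data.frame.
#' @export
readClinicalTsv <- function(path, level = c("sample", "patient")) {
  level <- match.arg(level)
  lines <- readLines(path)
  metaLines <- grep("^#", lines)
  hasMeta <- length(metaLines) >= 4 && identical(metaLines[1:4], 1:4)
  if (length(metaLines) && !hasMeta)
    stop("malformed metadata header: expected 4 leading '#' rows")
  body <- if (hasMeta) lines[-(1:4)] else lines
  dat <- utils::read.delim(text = paste(body, collapse = "\n"),
                           colClasses = "character",
                           na.strings = c("", "NA"), check.names = FALSE)
  idCol <- if (level == "sample") "SAMPLE_ID" else "PATIENT_ID"
  if (!idCol %in% names(dat)) stop("missing required column ", idCol)
  if (level == "sample" && !"PATIENT_ID" %in% names(dat))
    stop("missing required column PATIENT_ID")
  if (anyDuplicated(dat[[idCol]]))
    stop("duplicate ", idCol, " row(s): ",
         paste(unique(dat[[idCol]][duplicated(dat[[idCol]])]),
               collapse = ", "))
  valueCols <- setdiff(names(dat), c("PATIENT_ID", "SAMPLE_ID"))
  if (hasMeta) {
    displayNames <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
    datatypes <- strsplit(sub("^#", "", lines[3]), "\t", fixed = TRUE)[[1]]
    if (length(displayNames) != ncol(dat) || length(datatypes) != ncol(dat))
      stop("malformed metadata header: row width differs from table")
    names(displayNames) <- names(dat)
    names(datatypes) <- names(dat)
  } else {
    warning("no '#' metadata headers in ", basename(path),
            "; inferring datatypes")
    displayNames <- stats::setNames(names(dat), names(dat))
    datatypes <- vapply(dat[valueCols], function(col) {
      ok <- !is.na(col)
      if (any(ok) && !anyNA(suppressWarnings(as.numeric(col[ok]))))
        "NUMBER" else "STRING"
    }, character(1))
  }
  feats <- lapply(valueCols, function(col) {
    dtype <- switch(toupper(datatypes[[col]]),
                    NUMBER = "continuous", BOOLEAN = "binary",
                    "categorical")
    v <- stats::setNames(dat[[col]], dat[[idCol]])
    if (dtype == "continuous") v <- stats::setNames(as.numeric(v), names(v))
    if (dtype == "binary") v <- stats::setNames(as.integer(v), names(v))
    makeFeature(col, dtype, v, displayName = displayNames[[col]],
                source = paste0("clinical_", level), level = level)
  })
  names(feats) <- valueCols
  list(features = feats, data = dat)
}

#' Write features as a cBioPortal clinical TSV
#'
#' @param cohort a [Cohort-class].
#' @param path output path.
#' @param level `"sample"` or `"patient"`.
#' @param featureIds features to write; defaults to every feature of
#'   that level.
#' @export
writeClinicalTsv <- function(cohort, path, level = c("sample", "patient"),
                             featureIds = NULL) {
  level <- match.arg(level)
  if (is.null(featureIds))
    featureIds <- names(Filter(function(f) f@level == level,
                               cohort@features))
  feats <- lapply(featureIds, getFeature, x = cohort)
  if (level == "sample") {
    ids <- cohort@samples$sample_id
    dat <- data.frame(PATIENT_ID = cohort@samples$patient_id,
                      SAMPLE_ID = ids, stringsAsFactors = FALSE)
  } else {
    ids <- cohort@patientIds
    dat <- data.frame(PATIENT_ID = ids, stringsAsFactors = FALSE)
  }
  dtypeWord <- function(f) switch(f@datatype, continuous = "NUMBER",
                                  binary = "BOOLEAN", "STRING")
  for (f in feats) dat[[f@featureId]] <- unname(f@values[ids])
  header <- c(
    paste0("#", paste(c(if (level == "sample") c("Patient Identifier",
                                                 "Sample Identifier")
                        else "Patient Identifier",
                        vapply(feats, slot, character(1), "displayName")),
                      collapse = "\t")),
    paste0("#", paste(rep("-", ncol(dat)), collapse = "\t")),
    paste0("#", paste(c(rep("STRING", ncol(dat) - length(feats)),
                        vapply(feats, dtypeWord, character(1))),
                      collapse = "\t")),
    paste0("#", paste(rep("1", ncol(dat)), collapse = "\t")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(dat, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cBioPortal timeline TSV
#'
#' Required columns: `PATIENT_ID`, `START_DATE`, `EVENT_TYPE`;
#' `STOP_DATE` is optional (empty = open-ended, treated downstream as a
#' point event). Any other column is preserved as an event attribute.
#' Negative (pre-reference) dates are accepted.
#'
#' @param path file path.
#' @return data.frame with `patient_id`, `event_type`, `start_date`,
#'   `stop_date` and the attribute columns.
#' @export
readTimelineTsv <- function(path) {
  dat <- utils::read.delim(path, colClasses = "character",
                           na.strings = c("", "NA"), check.names = FALSE)
  req <- c("PATIENT_ID", "START_DATE", "EVENT_TYPE")
  miss <- setdiff(req, names(dat))
  if (length(miss))
    stop("timeline file missing column(s): ", paste(miss, collapse = ", "))
  start <- suppressWarnings(as.integer(dat$START_DATE))
  bad <- which(is.na(start) & !is.na(dat$START_DATE))
  if (length(bad))
    stop("non-integer START_DATE at data line ", bad[1], ": '",
         dat$START_DATE[bad[1]], "'")
  stopd <- if ("STOP_DATE" %in% names(dat))
    suppressWarnings(as.integer(dat$STOP_DATE)) else NA_integer_
  out <- data.frame(patient_id = dat$PATIENT_ID,
                    event_type = dat$EVENT_TYPE,
                    start_date = start, stop_date = stopd,
                    stringsAsFactors = FALSE)
  for (col in setdiff(names(dat), c(req, "STOP_DATE")))
    out[[col]] <- dat[[col]]
  out
}

#' Write an event table as a timeline TSV
#'
#' Sample dates are emitted as `SPECIMEN` rows (with a `SAMPLE_ID`
#' column) so that cohort sample timing round-trips through the
#' timeline format, cBioPortal-style.
#'
#' @param cohort a [Cohort-class].
#' @param path output path.
#' @param specimenRows also write per-sample SPECIMEN rows.
#' @export
writeTimelineTsv <- function(cohort, path, specimenRows = TRUE) {
  e <- cohort@events
  attrCols <- setdiff(names(e), c("patient_id", "event_type",
                                  "start_date", "stop_date"))
  rows <- data.frame(PATIENT_ID = e$patient_id,
                     START_DATE = e$start_date,
                     STOP_DATE = e$stop_date,
                     EVENT_TYPE = e$event_type,
                     stringsAsFactors = FALSE)
  for (col in attrCols) rows[[col]] <- e[[col]]
  if (!"SAMPLE_ID" %in% names(rows)) rows$SAMPLE_ID <- NA_character_
  if (specimenRows) {
    sp <- data.frame(PATIENT_ID = cohort@samples$patient_id,
                     START_DATE = cohort@samples$date,
                     STOP_DATE = NA_integer_,
                     EVENT_TYPE = "SPECIMEN",
                     stringsAsFactors = FALSE)
    for (col in setdiff(names(rows), names(sp))) sp[[col]] <- NA_character_
    sp$SAMPLE_ID <- cohort@samples$sample_id
    rows <- rbind(rows, sp[names(rows)])
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read per-gene binary mutation features from a MAF file
#'
#' MAF is a positive-report format: a requested gene with no record gets
#' an all-zero feature (observed, not mutated), never missing. Records
#' whose sample barcode is unknown to the cohort are ignored; their
#' count is returned as attribute `"ignoredSamples"`.
#'
#' @param path MAF path (tab-separated, `#` comment lines; needs at
#'   least `Hugo_Symbol` and `Tumor_Sample_Barcode`).
#' @param genes HUGO symbols to extract (must be non-empty).
#' @param sampleIds the cohort's sample ids.
#' @return Named list of binary sample-level [Feature-class] objects.
#' @export
readMaf <- function(path, genes, sampleIds) {
  if (!length(genes)) stop("empty gene list")
  dat <- utils::read.delim(path, comment.char = "#",
                           colClasses = "character", check.names = FALSE)
  req <- c("Hugo_Symbol", "Tumor_Sample_Barcode")
  miss <- setdiff(req, names(dat))
  if (length(miss))
    stop("MAF missing required column(s): ", paste(miss, collapse = ", "))
  known <- dat$Tumor_Sample_Barcode %in% sampleIds
  nIgnored <- length(unique(dat$Tumor_Sample_Barcode[!known]))
  dat <- dat[known, , drop = FALSE]
  feats <- lapply(genes, function(g) {
    hit <- unique(dat$Tumor_Sample_Barcode[dat$Hugo_Symbol == g])
    v <- stats::setNames(as.integer(sampleIds %in% hit), sampleIds)
    makeFeature(g, "binary", v, displayName = paste0(g, " mutated"),
                source = "mutation", level = "sample")
  })
  names(feats) <- genes
  attr(feats, "ignoredSamples") <- nIgnored
  feats
}

#' Write a minimal MAF file
#' @param mutations data.frame with `Hugo_Symbol`, `Tumor_Sample_Barcode`.
#' @param path output path.
#' @export
writeMaf <- function(mutations, path) {
  utils::write.table(mutations[, c("Hugo_Symbol", "Tumor_Sample_Barcode")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a cohort from local cBioPortal-style files
#'
#' Sample dates are taken from `SPECIMEN` timeline rows when present
#' (matching on a `SAMPLE_ID` column); otherwise samples get ordinal
#' dates in file order. Non-SPECIMEN timeline rows become events.
#'
#' @param clinicalSamplePath sample-level clinical TSV.
#' @param clinicalPatientPath optional patient-level clinical TSV.
#' @param timelinePath optional timeline TSV.
#' @param mafPath,mafGenes optional MAF file and gene symbols.
#' @return A [Cohort-class].
#' @export
loadCohort <- function(clinicalSamplePath, clinicalPatientPath = NULL,
                       timelinePath = NULL, mafPath = NULL,
                       mafGenes = NULL) {
  cs <- readClinicalTsv(clinicalSamplePath, "sample")
  samples <- data.frame(patient_id = cs$data$PATIENT_ID,
                        sample_id = cs$data$SAMPLE_ID,
                        stringsAsFactors = FALSE)
  events <- NULL
  if (!is.null(timelinePath)) {
    tl <- readTimelineTsv(timelinePath)
    isSpec <- tl$event_type == "SPECIMEN" & "SAMPLE_ID" %in% names(tl)
    if (any(isSpec)) {
      sp <- tl[isSpec, , drop = FALSE]
      samples$date <- sp$start_date[match(samples$sample_id, sp$SAMPLE_ID)]
      if (anyNA(samples$date))
        stop("SPECIMEN timeline rows missing for sample(s): ",
             paste(samples$sample_id[is.na(samples$date)], collapse = ", "))
    }
    events <- tl[!isSpec, , drop = FALSE]
    if (!nrow(events)) events <- NULL
  }
  feats <- cs$features
  if (!is.null(clinicalPatientPath)) {
    cp <- readClinicalTsv(clinicalPatientPath, "patient")
    feats <- c(feats, cp$features)
  }
  co <- buildCohort(samples, features = feats, events = events)
  if (!is.null(mafPath)) {
    mf <- readMaf(mafPath, mafGenes, co@samples$sample_id)
    for (f in mf) co <- addFeature(co, f)
  }
  co
}

## ---- cBioPortal REST client with an on-disk response cache ----

cacheKey <- function(url) {
  tf <- tempfile()
  writeLines(url, tf)
  k <- unname(tools::md5sum(tf))
  unlink(tf)
  k
}

cachedGET <- function(url, cacheDir) {
  if (!is.null(cacheDir)) {
    dir.create(cacheDir, showWarnings = FALSE, recursive = TRUE)
    f <- file.path(cacheDir, paste0(cacheKey(url), ".json"))
    if (file.exists(f)) return(paste(readLines(f, warn = FALSE),
                                     collapse = "\n"))
  }
  con <- url(url, headers = c(Accept = "application/json"))
  txt <- tryCatch(paste(readLines(con, warn = FALSE), collapse = "\n"),
                  error = function(e)
                    stop("HTTP request failed for ", url, ": ",
                         conditionMessage(e)),
                  finally = close(con))
  if (!is.null(cacheDir)) writeLines(txt, f)
  txt
}

#' Fetch a study from a cBioPortal instance
#'
#' Downloads patients, samples, sample/patient clinical data and timeline
#' events for a study and assembles a [Cohort-class]. Responses are
#' cached on disk (content-addressed by request URL), so a rerun with
#' the same cache directory works offline.
#'
#' @param studyId e.g. `"lgg_ucsf_2014"`.
#' @param baseUrl API root.
#' @param genes optional HUGO symbols for binary mutation features.
#' @param cacheDir response cache directory (`NULL` disables caching).
#' @return A [Cohort-class].
#' @export
fetchCbioportal <- function(studyId,
                            baseUrl = "https://www.cbioportal.org/api",
                            genes = character(0),
                            cacheDir = file.path(tempdir(), "cbp-cache")) {
  get <- function(path) jsonlite::fromJSON(
    cachedGET(paste0(baseUrl, path), cacheDir), simplifyVector = TRUE)
  samplesJs <- get(sprintf("/studies/%s/samples?pageSize=10000000", studyId))
  if (!length(samplesJs) || is.null(samplesJs$sampleId))
    stop("unknown study or empty sample list: ", studyId)
  clinS <- get(sprintf(
    "/studies/%s/clinical-data?clinicalDataType=SAMPLE&pageSize=10000000",
    studyId))
  clinP <- get(sprintf(
    "/studies/%s/clinical-data?clinicalDataType=PATIENT&pageSize=10000000",
    studyId))
  evJs <- tryCatch(get(sprintf(
    "/studies/%s/clinical-events?pageSize=10000000", studyId)),
    error = function(e) NULL)
  samples <- data.frame(patient_id = samplesJs$patientId,
                        sample_id = samplesJs$sampleId,
                        stringsAsFactors = FALSE)
  events <- NULL
  if (!is.null(evJs) && length(evJs) && !is.null(evJs$eventType)) {
    events <- data.frame(patient_id = evJs$patientId,
                         event_type = evJs$eventType,
                         start_date = evJs$startNumberOfDaysSinceDiagnosis,
                         stop_date =
                           if (!is.null(evJs$endNumberOfDaysSinceDiagnosis))
                             evJs$endNumberOfDaysSinceDiagnosis
                           else NA_integer_,
                         stringsAsFactors = FALSE)
    if (!is.null(evJs$attributes)) {
      for (i in seq_len(nrow(events))) {
        at <- evJs$attributes[[i]]
        if (length(at) && !is.null(at$key))
          for (j in seq_along(at$key)) events[i, at$key[j]] <- at$value[j]
      }
    }
    isSpec <- events$event_type %in% c("SPECIMEN", "Specimen")
    if (any(isSpec) && "SAMPLE_ID" %in% names(events)) {
      sp <- events[isSpec, , drop = FALSE]
      samples$date <- sp$start_date[match(samples$sample_id, sp$SAMPLE_ID)]
      events <- events[!isSpec, , drop = FALSE]
    }
  }
  pivot <- function(cd, idField, level) {
    if (!length(cd) || is.null(cd$clinicalAttributeId)) return(list())
    ids <- unique(cd[[idField]])
    lapply(stats::setNames(unique(cd$clinicalAttributeId),
                           unique(cd$clinicalAttributeId)), function(a) {
      sub <- cd[cd$clinicalAttributeId == a, , drop = FALSE]
      v <- stats::setNames(sub$value, sub[[idField]])[ids]
      names(v) <- ids
      num <- suppressWarnings(as.numeric(v))
      dtype <- if (all(is.na(num) == is.na(v))) "continuous" else "categorical"
      makeFeature(a, dtype, if (dtype == "continuous") num else v,
                  source = paste0("clinical_", level), level = level)
    })
  }
  feats <- c(pivot(clinS, "sampleId", "sample"),
             pivot(clinP, "patientId", "patient"))
  co <- buildCohort(samples, features = feats, events = events)
  for (g in genes) {
    mut <- tryCatch(get(sprintf(
      paste0("/molecular-profiles/%s_mutations/mutations?",
             "sampleListId=%s_all&projection=SUMMARY&pageSize=10000000"),
      studyId, studyId)), error = function(e) NULL)
    if (is.null(mut)) {
      warning("could not fetch mutations for gene ", g)
      next
    }
    ## mutation endpoint returns all genes; filter by symbol when present
    sym <- if (!is.null(mut$gene$hugoGeneSymbol)) mut$gene$hugoGeneSymbol
           else mut$hugoGeneSymbol
    hit <- unique(mut$sampleId[sym == g])
    v <- stats::setNames(as.integer(co@samples$sample_id %in% hit),
                         co@samples$sample_id)
    co <- addFeature(co, makeFeature(g, "binary", v,
                                     displayName = paste0(g, " mutated"),
                                     source = "mutation", level = "sample"))
  }
  co
}

## ---- view metadata export ----

featureMetadataList <- function(cohort, featureIds) {
  lapply(featureIds, function(id) {
    f <- cohort@features[[id]]
    hist <- Filter(function(rec) {
      p <- rec$params
      identical(p$newId, id) || identical(p$featureId, id) ||
        (is.character(p$featureIds) && id %in% p$featureIds)
    }, cohort@opLog)
    list(featureId = f@featureId, displayName = f@displayName,
         datatype = f@datatype, source = f@source, level = f@level,
         domain = f@domain, colorScale = as.list(f@colorScale),
         transformHistory = lapply(hist, function(rec)
           list(op = rec$op, params = rec$params, stamp = rec$stamp)))
  })
}

blockStateList <- function(grid) {
  lapply(grid@blocks, function(b) {
    st <- list(kind = b@kind, index = b@index, order = b@order,
               grouped = b@grouped,
               primaryFeature = b@primaryFeature)
    if (b@grouped)
      st$groups <- lapply(b@grouping@groups, function(g)
        list(value = g$value, patients = g$patients))
    st
  })
}

#' Export view metadata as JSON
#'
#' Captures what a figure shows: the displayed features with their
#' transform history (from the op log), every block's sort/group state,
#' and any score settings — the machine-readable sidecar of an exported
#' view.
#'
#' @param cohort a [Cohort-class].
#' @param grid a [BlockGrid-class].
#' @param path output JSON path.
#' @param scoreSettings optional list describing score/aggregation
#'   choices.
#' @return The metadata list, invisibly.
#' @export
exportViewMetadata <- function(cohort, grid, path, scoreSettings = NULL) {
  meta <- list(features = featureMetadataList(cohort,
                                              grid@displayedFeatures),
               opLog = lapply(cohort@opLog, function(rec)
                 list(op = rec$op, params = rec$params,
                      stamp = rec$stamp)),
               blocks = blockStateList(grid),
               scoreSettings = scoreSettings)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(meta)
}

#' Read back an exported view-metadata JSON
#' @param path JSON path.
#' @return The metadata list.
#' @export
readViewMetadata <- function(path) {
  jsonlite::read_json(path)
}
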