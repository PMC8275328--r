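## Seeded synthetic-cohort generator. Emulates the shape of a
## longitudinal glioma cohort: a few dozen patients sampled at 2-4
## timepoints, a categorical grade-like feature evolving as a per-patient
## Markov chain, a mutation-count-like random walk, inter-timepoint
## treatment events, and a planted treatment effect that pushes the
## designated continuous feature above a hypermutation threshold at the
## following timepoint. Ground truth is returned alongside the cohort.

## evaluate code under a temporary RNG state derived from `seed`
withSeed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else suppressWarnings(rm(".Random.seed", envir = genv))
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Configure the synthetic-cohort generator
#'
#' Defaults emulate a recurrence-sampled glioma cohort: 23 patients with
#' 2-4 timepoints, a three-level grade chain starting at grade II with
#' switch probability 0.3, a mutation-count walk held below the
#' 150-mutation hypermutation threshold unless the planted treatment
#' effect fires, and a TMZ treatment event in a random inter-timepoint
#' interval for half the patients.
#'
#' @param nPatients number of patients.
#' @param timepointWeights weights over 2/3/4 timepoints (sum to 1).
#' @param categoricalFeatures list of Markov-chain feature specs
#'   (`id`, `name`, `categories`, `initWeights`, `switchProb`).
#' @param continuousFeatures list of random-walk feature specs
#'   (`id`, `name`, `baselineMean`, `baselineSd`, `drift`, `noiseSd`).
#' @param eventSpec `list(eventType=, attributes=, prob=)`.
#' @param effectSpec `list(feature=, prob=, threshold=)`.
#' @param mafGenes genes for generated binary mutation features.
#' @param seed RNG seed.
#' @return A [SyntheticCohortConfig-class].
#' @export
syntheticCohortConfig <- function(
    nPatients = 23,
    timepointWeights = c(`2` = 0.5, `3` = 0.3, `4` = 0.2),
    categoricalFeatures = list(list(
      id = "grade", name = "Neoplasm Histologic Grade",
      categories = c("II", "III", "IV"),
      initWeights = c(1, 0, 0), switchProb = 0.3)),
    continuousFeatures = list(list(
      id = "mutation_count", name = "Mutation Count",
      baselineMean = 60, baselineSd = 20, drift = 5, noiseSd = 15)),
    eventSpec = list(eventType = "TREATMENT",
                     attributes = c(AGENT = "TMZ"), prob = 0.5),
    effectSpec = list(feature = "mutation_count", prob = 0.7,
                      threshold = 150),
    mafGenes = c("MLH1", "MSH6", "MSH3"),
    seed = 1L) {
  new("SyntheticCohortConfig",
      nPatients = as.integer(nPatients),
      timepointWeights = timepointWeights,
      categoricalFeatures = categoricalFeatures,
      continuousFeatures = continuousFeatures,
      eventSpec = eventSpec, effectSpec = effectSpec,
      mafGenes = mafGenes, seed = as.integer(seed))
}

#' Generate a synthetic cohort with ground truth
#'
#' Deterministic given the config seed; all randomness flows from it and
#' the global RNG state is restored afterwards. Categorical features
#' evolve per patient as first-order Markov chains that switch to a
#' different category with probability `switchProb` at each step (so the
#' expected categorical rate of change equals `switchProb`). Continuous
#' features are random walks; the effect feature's walk is capped below
#' the effect threshold so that a value in the high bin identifies a
#' planted post-event effect unambiguously. With probability
#' `effectSpec$prob`, the timepoint following a patient's event gets the
#' effect feature raised above the threshold. Generated binary
#' mutation-gene features are enriched in affected samples.
#'
#' @param config a [SyntheticCohortConfig-class].
#' @return `list(cohort=, truth=)` where `truth` records the planted
#'   parameters: `switchProb` per categorical feature, `effectProb`,
#'   `threshold`, `events` (patient/interval/date), `affectedSamples`
#'   and `eventFeatureId`.
#' @export
generateSyntheticCohort <- function(config) {
  validObject(config)
  withSeed(config@seed, {
    nP <- config@nPatients
    pats <- sprintf("P%03d", seq_len(nP))
    tpChoices <- as.integer(names(config@timepointWeights))
    nTp <- sample(tpChoices, nP, replace = TRUE,
                  prob = config@timepointWeights)
    sampleRows <- do.call(rbind, lapply(seq_len(nP), function(i) {
      k <- nTp[i]
      dates <- c(0L, cumsum(as.integer(round(stats::runif(k - 1, 180, 540)))))
      data.frame(patient_id = pats[i],
                 sample_id = sprintf("%s_S%d", pats[i], seq_len(k)),
                 date = dates, stringsAsFactors = FALSE)
    }))

    ## events: at most one per patient, placed strictly inside a random
    ## inter-timepoint interval
    ev <- config@eventSpec
    hasEvent <- stats::runif(nP) < ev$prob & nTp >= 2
    evRows <- NULL
    evTruth <- NULL
    for (i in which(hasEvent)) {
      iv <- if (nTp[i] == 2L) 1L else sample.int(nTp[i] - 1L, 1L)
      d <- sampleRows$date[sampleRows$patient_id == pats[i]]
      start <- as.integer(floor((d[iv] + d[iv + 1L]) / 2))
      stop <- start + as.integer(round(stats::runif(1, 30, 120)))
      stop <- min(stop, d[iv + 1L])      # treatment ends before next sample
      row <- data.frame(patient_id = pats[i], event_type = ev$eventType,
                        start_date = start, stop_date = stop,
                        stringsAsFactors = FALSE)
      for (a in names(ev$attributes)) row[[a]] <- unname(ev$attributes[[a]])
      evRows <- rbind(evRows, row)
      evTruth <- rbind(evTruth,
                       data.frame(patient_id = pats[i], interval = iv,
                                  start_date = start,
                                  stringsAsFactors = FALSE))
    }

    ## effect assignment: which post-event samples get the planted raise
    eff <- config@effectSpec
    affected <- character(0)
    if (!is.null(evTruth)) for (j in seq_len(nrow(evTruth))) {
      if (stats::runif(1) < eff$prob) {
        p <- evTruth$patient_id[j]
        affected <- c(affected,
                      sprintf("%s_S%d", p, evTruth$interval[j] + 1L))
      }
    }

    feats <- list()
    for (spec in config@categoricalFeatures) {
      vals <- character(0)
      for (i in seq_len(nP)) {
        k <- nTp[i]
        st <- sample(spec$categories, 1L, prob = spec$initWeights)
        series <- st
        for (t in seq_len(k - 1L)) {
          if (stats::runif(1) < spec$switchProb)
            st <- sample(setdiff(spec$categories, st), 1L)
          series <- c(series, st)
        }
        names(series) <- sprintf("%s_S%d", pats[i], seq_len(k))
        vals <- c(vals, series)
      }
      feats[[spec$id]] <- makeFeature(spec$id, "categorical", vals,
                                      displayName = spec$name,
                                      source = "clinical_sample",
                                      domain = spec$categories)
    }
    for (spec in config@continuousFeatures) {
      isEffect <- identical(spec$id, eff$feature)
      cap <- if (isEffect) eff$threshold - 10 else Inf
      vals <- numeric(0)
      for (i in seq_len(nP)) {
        k <- nTp[i]
        x <- numeric(k)
        x[1] <- stats::rnorm(1, spec$baselineMean, spec$baselineSd)
        for (t in seq_len(k - 1L))
          x[t + 1L] <- x[t] + spec$drift + stats::rnorm(1, 0, spec$noiseSd)
        x <- pmin(pmax(round(x), 0), cap)
        sids <- sprintf("%s_S%d", pats[i], seq_len(k))
        if (isEffect) {
          hit <- sids %in% affected
          if (any(hit))
            x[hit] <- round(stats::runif(sum(hit), eff$threshold * 1.3,
                                         eff$threshold * 4))
        }
        names(x) <- sids
        vals <- c(vals, x)
      }
      feats[[spec$id]] <- makeFeature(spec$id, "continuous", vals,
                                      displayName = spec$name,
                                      source = "clinical_sample")
    }
    for (g in config@mafGenes) {
      p <- ifelse(sampleRows$sample_id %in% affected, 0.9, 0.05)
      v <- stats::setNames(as.integer(stats::runif(nrow(sampleRows)) < p),
                           sampleRows$sample_id)
      feats[[g]] <- makeFeature(g, "binary", v,
                                displayName = paste0(g, " mutated"),
                                source = "mutation")
    }

    co <- buildCohort(sampleRows, features = feats, events = evRows)
    evFeatId <- NA_character_
    if (!is.null(ev$eventType)) {
      aName <- if (length(ev$attributes)) names(ev$attributes)[1] else NULL
      aVal <- if (length(ev$attributes)) unname(ev$attributes[[1]]) else NULL
      evFeatId <- paste0("evt_", if (!is.null(aVal)) aVal else ev$eventType)
      co <- addFeature(co, makeEventFeature(evFeatId, ev$eventType,
                                            attribute = aName,
                                            value = aVal,
                                            displayName = evFeatId))
    }
    list(cohort = co,
         truth = list(
           switchProb = as.list(stats::setNames(
             vapply(config@categoricalFeatures, `[[`, numeric(1),
                    "switchProb"),
             vapply(config@categoricalFeatures, `[[`, character(1), "id"))),
           effectProb = eff$prob, threshold = eff$threshold,
           effectFeature = eff$feature,
           events = if (is.null(evTruth))
             data.frame(patient_id = character(0), interval = integer(0),
                        start_date = integer(0)) else evTruth,
           affectedSamples = affected,
           eventFeatureId = evFeatId))
  })
}
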