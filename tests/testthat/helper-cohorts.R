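# Fixture cohorts built in code (deterministic, no files).

# 4 patients with 2/3/4/2 samples, grade + mutation count + MGMT status,
# TMZ treatment events for P1 (between samples 1-2) and P3 (between 2-3).
tinyCohort <- function() {
  samples <- data.frame(
    patient_id = c("P1", "P1", "P2", "P2", "P2", "P3", "P3", "P3", "P3",
                   "P4", "P4"),
    sample_id = c("S1", "S2", "S3", "S4", "S5", "S6", "S7", "S8", "S9",
                  "S10", "S11"),
    date = c(0, 300, 0, 250, 500, 0, 200, 400, 600, 0, 350),
    stringsAsFactors = FALSE)
  grade <- makeFeature("grade", "categorical",
    c(S1 = "II", S2 = "III", S3 = "II", S4 = "II", S5 = "IV", S6 = "II",
      S7 = "II", S8 = "III", S9 = "IV", S10 = "II", S11 = "II"),
    domain = c("II", "III", "IV"), source = "clinical_sample",
    displayName = "Neoplasm Histologic Grade")
  count <- makeFeature("mutation_count", "continuous",
    c(S1 = 20, S2 = 180, S3 = 30, S4 = 40, S5 = 35, S6 = 25, S7 = 60,
      S8 = 155, S9 = 200, S10 = 45, S11 = 50),
    source = "clinical_sample", displayName = "Mutation Count")
  mgmt <- makeFeature("MGMT", "categorical",
    c(S1 = "meth", S2 = "meth", S3 = "unmeth", S4 = "unmeth",
      S5 = "unmeth", S6 = "meth", S7 = "meth", S8 = "meth", S9 = "meth",
      S10 = "meth", S11 = "unmeth"),
    domain = c("meth", "unmeth"), source = "clinical_sample")
  events <- data.frame(
    patient_id = c("P1", "P3"), event_type = "TREATMENT",
    start_date = c(150L, 250L), stop_date = c(210L, NA),
    AGENT = "TMZ", stringsAsFactors = FALSE)
  buildCohort(samples, list(grade, count, mgmt), events)
}

# single-patient cohort holding one feature over n samples
flatCohort <- function(values, datatype = "continuous", domain = NULL,
                       id = "x") {
  n <- length(values)
  sids <- paste0("S", seq_len(n))
  samples <- data.frame(patient_id = "P1", sample_id = sids,
                        date = seq_len(n) - 1L, stringsAsFactors = FALSE)
  buildCohort(samples,
              list(makeFeature(id, datatype,
                               stats::setNames(values, sids),
                               domain = domain)))
}

# nPat patients x nTp timepoints; cellValues is a nTp x nPat matrix of a
# single feature's values (rows = timepoints)
gridCohort <- function(cellValues, datatype = "categorical",
                       domain = NULL, id = "x") {
  nTp <- nrow(cellValues)
  nPat <- ncol(cellValues)
  pats <- sprintf("P%03d", seq_len(nPat))
  samples <- do.call(rbind, lapply(seq_len(nPat), function(j)
    data.frame(patient_id = pats[j],
               sample_id = sprintf("%s_S%d", pats[j], seq_len(nTp)),
               date = (seq_len(nTp) - 1L) * 100L,
               stringsAsFactors = FALSE)))
  v <- stats::setNames(as.vector(cellValues),
                       as.vector(vapply(seq_len(nPat), function(j)
                         sprintf("%s_S%d", pats[j], seq_len(nTp)),
                         character(nTp))))
  buildCohort(samples, list(makeFeature(id, datatype, v, domain = domain)))
}

# brute-force lexicographic sort oracle: per key a (class, value) pair
# where class separates value < missing < gap; prior order breaks ties
lexSortOracle <- function(block, keys, directions) {
  ord <- block@order
  gap <- block@gap[ord]
  cols <- list()
  for (i in seq_along(keys)) {
    cv <- block@cells[[keys[i]]]
    v <- cv[ord]
    dt <- attr(cv, "datatype")
    k <- if (dt %in% c("categorical", "ordinal"))
      as.numeric(match(v, attr(cv, "domain"))) else as.numeric(v)
    cls <- ifelse(gap, 3L, ifelse(is.na(k), 2L, 1L))
    if (directions[i] == "desc") k <- -k
    k[is.na(k)] <- 0
    cols[[length(cols) + 1L]] <- cls
    cols[[length(cols) + 1L]] <- k
  }
  ord[do.call(order, c(cols, list(method = "radix")))]
}
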