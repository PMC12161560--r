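# Small dataset builders shared across tests.

tinySpec <- function(nPerGroup = 6L, Tn = 64L, seed = 7L, ...) {
  syntheticSpec(nSubjectsPerGroup = nPerGroup, nComponents = 6L,
                nTimesteps = Tn, contextDim = 2L, localDim = 3L,
                seed = seed, ...)
}

tinyCohort <- function(nPerGroup = 6L, Tn = 64L, seed = 7L, ...) {
  ds <- generateDataset(tinySpec(nPerGroup, Tn, seed, ...))
  split <- splitSubjects(ds$records, c(0.6, 0.2, 0.2), seed = 5L)
  windows <- makeWindows(ds$records, windowSpec(32L, 4L))
  diagnoses <- stats::setNames(
    vapply(ds$records@records, function(r) r@diagnosis, character(1)),
    subjectIds(ds$records))
  list(records = ds$records, truth = ds$truth, split = split,
       windows = windows, diagnoses = diagnoses)
}

randomWindowSet <- function(m = 5L, n = 5L, w = 20L, seed = 1L) {
  set.seed(seed)
  arr <- array(rnorm(n * w * m), c(n, w, m))
  new("WindowSet", data = arr, subjectId = rep("s1", m),
      start = as.integer(seq_len(m) - 1L), width = as.integer(w),
      stride = 1L, samplingInterval = 2)
}

# An embedding table with arbitrary embeddings over a synthetic cohort's
# windows, labelled by the cohort's split/diagnoses.
tableFor <- function(cohort, embedding) {
  embeddingTable(
    data.frame(subject_id = cohort$windows@subjectId,
               window_start = cohort$windows@start,
               split = splitOf(cohort$split, cohort$windows@subjectId),
               diagnosis = unname(cohort$diagnoses[cohort$windows@subjectId]),
               stringsAsFactors = FALSE),
    embedding, width = cohort$windows@width)
}
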