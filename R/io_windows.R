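#' @include AllGenerics.R
NULL

.fmtNum <- function(x) sprintf("%.17g", x)

#' Load subject timecourses and metadata from disk
#'
#' Reads a metadata CSV (columns \code{subject_id}, \code{diagnosis}, and
#' optionally \code{age}, \code{cognitive_score}, \code{sampling_interval})
#' and, for every row, a tab-separated matrix
#' \code{<dataPath>/<subject_id>.tsv} with components in rows and timesteps
#' in columns.  All subjects must share the component count; any non-finite
#' cell, any metadata row without a matrix file and any matrix file without
#' a metadata row is a hard error naming the subject.
#'
#' @param dataPath directory containing one TSV per subject
#' @param metadataPath path of the metadata CSV
#' @return a \linkS4class{TimecourseSet}
#' @export
loadTimecourses <- function(dataPath, metadataPath) {
  md <- utils::read.csv(metadataPath, stringsAsFactors = FALSE)
  need <- c("subject_id", "diagnosis")
  if (!all(need %in% names(md)))
    stop("metadata must have columns subject_id and diagnosis")
  onDisk <- sub("\\.tsv$", "", list.files(dataPath, pattern = "\\.tsv$"))
  extra <- setdiff(onDisk, as.character(md$subject_id))
  if (length(extra) > 0L)
    stop(sprintf("matrix file for subject '%s' has no metadata row", extra[1L]))
  if (nrow(md) == 0L) return(timecourseSet())

  recs <- vector("list", nrow(md))
  for (i in seq_len(nrow(md))) {
    sid <- as.character(md$subject_id[i])
    f <- file.path(dataPath, paste0(sid, ".tsv"))
    if (!file.exists(f))
      stop(sprintf("subject '%s' present in metadata but matrix file '%s' is missing",
                   sid, f))
    m <- as.matrix(utils::read.table(f, sep = "\t", header = FALSE))
    dimnames(m) <- NULL
    if (!all(is.finite(m))) {
      bad <- which(!is.finite(m), arr.ind = TRUE)[1L, ]
      stop(sprintf("subject '%s': non-finite value at component %d, timestep %d",
                   sid, bad[1L], bad[2L]))
    }
    recs[[i]] <- subjectRecord(
      subjectId = sid, diagnosis = as.character(md$diagnosis[i]), data = m,
      age = if ("age" %in% names(md)) as.numeric(md$age[i]) else NA_real_,
      cognitiveScore = if ("cognitive_score" %in% names(md))
        as.numeric(md$cognitive_score[i]) else NA_real_,
      samplingInterval = if ("sampling_interval" %in% names(md))
        as.numeric(md$sampling_interval[i]) else 2)
  }
  out <- timecourseSet(recs)
  validObject(out)
  out
}

#' Write a TimecourseSet to the on-disk layout read by loadTimecourses
#'
#' @param set a \linkS4class{TimecourseSet}
#' @param dataPath directory for the per-subject TSV matrices (created if
#'   needed)
#' @param metadataPath path of the metadata CSV to write
#' @return invisibly, the metadata data.frame
#' @export
writeTimecourses <- function(set, dataPath, metadataPath) {
  stopifnot(is(set, "TimecourseSet"))
  dir.create(dataPath, recursive = TRUE, showWarnings = FALSE)
  md <- data.frame(
    subject_id = subjectIds(set),
    diagnosis = vapply(set@records, function(r) r@diagnosis, character(1)),
    age = vapply(set@records, function(r) r@age, numeric(1)),
    cognitive_score = vapply(set@records, function(r) r@cognitiveScore,
                             numeric(1)),
    sampling_interval = vapply(set@records, function(r) r@samplingInterval,
                               numeric(1)),
    stringsAsFactors = FALSE)
  for (r in set@records) {
    out <- apply(r@data, 1L, function(row) paste(.fmtNum(row), collapse = "\t"))
    writeLines(out, file.path(dataPath, paste0(r@subjectId, ".tsv")))
  }
  utils::write.csv(md, metadataPath, row.names = FALSE)
  invisible(md)
}

setMethod("normalizeComponents", "SubjectRecord",
          function(x, method = c("zscore", "none")) {
  method <- match.arg(method)
  if (method == "none") return(x)
  d <- x@data
  mu <- rowMeans(d)
  sdv <- apply(d, 1L, stats::sd)   # sample sd, denominator T - 1
  if (any(!is.finite(sdv)) || any(sdv == 0)) {
    bad <- which(!is.finite(sdv) | sdv == 0)[1L]
    stop(sprintf("subject '%s': component %d has zero variance, cannot z-score",
                 x@subjectId, bad))
  }
  x@data <- (d - mu) / sdv
  x
})

setMethod("normalizeComponents", "TimecourseSet",
          function(x, method = c("zscore", "none")) {
  method <- match.arg(method)
  x@records <- lapply(x@records, normalizeComponents, method = method)
  x
})

setMethod("makeWindows", "SubjectRecord", function(x, spec = windowSpec()) {
  stopifnot(is(spec, "WindowSpec"))
  Tn <- ncol(x@data)
  W <- spec@width
  if (Tn < W)
    stop(sprintf("subject '%s' has %d timesteps, shorter than one window (%d)",
                 x@subjectId, Tn, W))
  starts <- seq.int(0L, Tn - W, by = spec@stride)
  arr <- array(0, c(nrow(x@data), W, length(starts)))
  for (i in seq_along(starts))
    arr[, , i] <- x@data[, (starts[i] + 1L):(starts[i] + W), drop = FALSE]
  new("WindowSet", data = arr, subjectId = rep(x@subjectId, length(starts)),
      start = as.integer(starts), width = W, stride = spec@stride,
      samplingInterval = x@samplingInterval)
})

setMethod("makeWindows", "TimecourseSet", function(x, spec = windowSpec()) {
  if (length(x@records) == 0L) stop("empty TimecourseSet")
  parts <- lapply(x@records, makeWindows, spec = spec)
  n <- nComponents(x)
  m <- sum(vapply(parts, nWindows, integer(1)))
  arr <- array(0, c(n, spec@width, m))
  sid <- character(m); st <- integer(m)
  at <- 0L
  for (p in parts) {
    k <- nWindows(p)
    arr[, , (at + 1L):(at + k)] <- p@data
    sid[(at + 1L):(at + k)] <- p@subjectId
    st[(at + 1L):(at + k)] <- p@start
    at <- at + k
  }
  new("WindowSet", data = arr, subjectId = sid, start = st,
      width = spec@width, stride = spec@stride,
      samplingInterval = x@records[[1L]]@samplingInterval)
})

#' Subset a WindowSet by subject ids
#' @param windows a \linkS4class{WindowSet}
#' @param ids subject ids to keep
#' @return a \linkS4class{WindowSet}
#' @export
subsetWindows <- function(windows, ids) {
  keep <- windows@subjectId %in% ids
  new("WindowSet", data = windows@data[, , keep, drop = FALSE],
      subjectId = windows@subjectId[keep], start = windows@start[keep],
      width = windows@width, stride = windows@stride,
      samplingInterval = windows@samplingInterval)
}

# Largest-remainder allocation of n items to fractions.
.largestRemainder <- function(n, fractions) {
  raw <- fractions * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE)  # ties -> earlier split
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Assign subjects to train/validation/test splits
#'
#' Deterministic given (subject ids, fractions, seed) and invariant to the
#' order of the input records (ids are sorted internally).  Stratified by
#' diagnosis with largest-remainder rounding, so each split's
#' patient/control ratio is within one subject of the global ratio.  Splits
#' are always by subject, never by window.
#'
#' @param records a \linkS4class{TimecourseSet}
#' @param fractions train/val/test fractions summing to 1
#' @param seed integer seed
#' @return a \linkS4class{DatasetSplit}
#' @export
splitSubjects <- function(records, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(is(records, "TimecourseSet"), length(fractions) == 3L)
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must sum to 1")
  if (any(fractions < 0)) stop("fractions must be non-negative")
  ids <- subjectIds(records)
  dg <- vapply(records@records, function(r) r@diagnosis, character(1))
  names(dg) <- ids
  ord <- order(ids)
  ids <- ids[ord]; dg <- dg[ord]

  assignment <- character(0)
  set.seed(as.integer(seed))
  for (g in unique(dg)) {
    gid <- ids[dg == g]
    gid <- gid[sample.int(length(gid))]
    counts <- .largestRemainder(length(gid), fractions)
    assignment <- c(assignment,
                    stats::setNames(rep(.SPLITS, counts), gid))
  }
  for (k in which(fractions > 0))
    if (sum(assignment == .SPLITS[k]) == 0L)
      stop(sprintf("requested nonempty split '%s' received no subjects",
                   .SPLITS[k]))
  new("DatasetSplit", assignment = assignment[order(names(assignment))])
}

#' Look up the split of given subjects
#' @param split a \linkS4class{DatasetSplit}
#' @param ids subject ids
#' @return character vector of split labels
#' @export
splitOf <- function(split, ids) {
  a <- split@assignment[as.character(ids)]
  if (anyNA(a)) stop(sprintf("subject '%s' is not in the split",
                             ids[which(is.na(a))[1L]]))
  unname(a)
}

#' Write / read an embedding table as TSV
#'
#' The dialect is UTF-8 TSV with "." decimal and a header of
#' \code{subject_id}, \code{window_start}, \code{split}, \code{diagnosis}
#' followed by one column (\code{z1}, \code{z2}, ...) per embedding
#' dimension.  Values are printed with 17 significant digits so the
#' write-read round trip is lossless.
#'
#' @param table an \linkS4class{EmbeddingTable}
#' @param path output file path
#' @return \code{writeEmbeddings} invisibly returns \code{path};
#'   \code{readEmbeddings} returns an \linkS4class{EmbeddingTable}
#' @export
writeEmbeddings <- function(table, path) {
  stopifnot(is(table, "EmbeddingTable"))
  k <- ncol(table@embedding)
  header <- c("subject_id", "window_start", "split", "diagnosis",
              if (k > 0) paste0("z", seq_len(k)))
  lines <- character(nrow(table@info))
  for (i in seq_len(nrow(table@info))) {
    lines[i] <- paste(c(table@info$subject_id[i],
                        table@info$window_start[i],
                        table@info$split[i],
                        table@info$diagnosis[i],
                        .fmtNum(table@embedding[i, ])), collapse = "\t")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(header, collapse = "\t"), lines), con, useBytes = TRUE)
  invisible(path)
}

#' @param path file to read
#' @rdname writeEmbeddings
#' @export
readEmbeddings <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty embeddings file")
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  need <- c("subject_id", "window_start", "split", "diagnosis")
  if (length(header) < 4L || !identical(header[1:4], need))
    stop("embeddings header must start with subject_id, window_start, split, diagnosis")
  k <- length(header) - 4L
  if (k > 0 && !identical(header[-(1:4)], paste0("z", seq_len(k))))
    stop("embedding value columns must be named z1, z2, ...")
  if (length(lines) == 1L) {
    return(embeddingTable(
      data.frame(subject_id = character(0), window_start = integer(0),
                 split = character(0), diagnosis = character(0),
                 stringsAsFactors = FALSE),
      matrix(0, 0, k)))
  }
  parts <- strsplit(lines[-1L], "\t", fixed = TRUE)
  if (any(lengths(parts) != length(header)))
    stop("embeddings row has wrong number of fields for the header")
  m <- do.call(rbind, parts)
  emb <- matrix(0, nrow(m), k)
  if (k > 0) emb <- matrix(as.numeric(m[, -(1:4), drop = FALSE]), nrow(m), k)
  embeddingTable(
    data.frame(subject_id = m[, 1L], window_start = as.integer(m[, 2L]),
               split = m[, 3L], diagnosis = m[, 4L], stringsAsFactors = FALSE),
    emb)
}
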