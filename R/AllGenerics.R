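#' @include AllClasses.R
NULL

#' Number of observed components
#' @param x a SubjectRecord, TimecourseSet or WindowSet
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' Number of timesteps of a subject's timecourse
#' @param x a SubjectRecord
#' @export
setGeneric("nTimesteps", function(x) standardGeneric("nTimesteps"))

#' Subject identifiers
#' @param x a TimecourseSet, DatasetSplit or EmbeddingTable
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' Number of windows
#' @param x a WindowSet or EmbeddingTable
#' @export
setGeneric("nWindows", function(x) standardGeneric("nWindows"))

#' Extract sliding windows
#' @param x a SubjectRecord or TimecourseSet
#' @param spec a WindowSpec
#' @export
setGeneric("makeWindows", function(x, spec = windowSpec())
  standardGeneric("makeWindows"))

#' Per-component normalization over the full timeseries
#' @param x a SubjectRecord or TimecourseSet
#' @param method "zscore" or "none"
#' @export
setGeneric("normalizeComponents", function(x, method = c("zscore", "none"))
  standardGeneric("normalizeComponents"))

#' Embedding matrix of a table
#' @param x an EmbeddingTable
#' @export
setGeneric("embeddingMatrix", function(x) standardGeneric("embeddingMatrix"))

#' Window provenance of a table
#' @param x an EmbeddingTable or ClusterReport
#' @export
setGeneric("windowInfo", function(x) standardGeneric("windowInfo"))

setMethod("nComponents", "SubjectRecord", function(x) nrow(x@data))
setMethod("nComponents", "TimecourseSet", function(x) {
  if (length(x@records) == 0L) return(NA_integer_)
  nrow(x@records[[1L]]@data)
})
setMethod("nComponents", "WindowSet", function(x) dim(x@data)[1L])
setMethod("nTimesteps", "SubjectRecord", function(x) ncol(x@data))
setMethod("subjectIds", "TimecourseSet", function(x)
  vapply(x@records, function(r) r@subjectId, character(1)))
setMethod("subjectIds", "DatasetSplit", function(x) names(x@assignment))
setMethod("subjectIds", "EmbeddingTable", function(x)
  unique(x@info$subject_id))
setMethod("nWindows", "WindowSet", function(x) dim(x@data)[3L])
setMethod("nWindows", "EmbeddingTable", function(x) nrow(x@info))
setMethod("embeddingMatrix", "EmbeddingTable", function(x) x@embedding)
setMethod("windowInfo", "EmbeddingTable", function(x) x@info)
setMethod("windowInfo", "ClusterReport", function(x) x@info)

setMethod("length", "TimecourseSet", function(x) length(x@records))

#' @param i index or logical vector
#' @rdname TimecourseSet-class
#' @export
setMethod("[[", "TimecourseSet", function(x, i) x@records[[i]])

#' @param x an EmbeddingTable
#' @param i row index (integer or logical) selecting windows
#' @rdname EmbeddingTable-class
#' @export
setMethod("[", "EmbeddingTable", function(x, i) {
  new("EmbeddingTable",
      info = x@info[i, , drop = FALSE],
      embedding = x@embedding[i, , drop = FALSE],
      width = x@width)
})

setMethod("show", "SubjectRecord", function(object) {
  cat(sprintf("SubjectRecord '%s' (%s): %d components x %d timesteps, TR %gs\n",
              object@subjectId, object@diagnosis, nrow(object@data),
              ncol(object@data), object@samplingInterval))
})

setMethod("show", "TimecourseSet", function(object) {
  n <- length(object@records)
  cat(sprintf("TimecourseSet with %d subject(s)", n))
  if (n > 0L) {
    dg <- vapply(object@records, function(r) r@diagnosis, character(1))
    cat(sprintf(", %d components (%d patient / %d control)",
                nComponents(object), sum(dg == "patient"),
                sum(dg == "control")))
  }
  cat("\n")
})

setMethod("show", "WindowSet", function(object) {
  cat(sprintf(
    "WindowSet: %d window(s) of %d components x %d timesteps (stride %d) from %d subject(s)\n",
    nWindows(object), nComponents(object), object@width, object@stride,
    length(unique(object@subjectId))))
})

setMethod("show", "EmbeddingTable", function(object) {
  cat(sprintf("EmbeddingTable: %d window(s), %d-dimensional embeddings\n",
              nrow(object@info), ncol(object@embedding)))
  spl <- table(object@info$split)
  cat("  split: ", paste(sprintf("%s=%d", names(spl), spl), collapse = ", "),
      "\n", sep = "")
})

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf(
    "ModelConfig: %s (LS=%d, CS=%d, beta=%g, gamma=%g, %s context encoder, hidden=%d, seed=%d)\n",
    object@variant, object@localSize, object@contextSize, object@beta,
    object@gamma, object@contextEncoderArch, object@hiddenSize, object@seed))
})

setMethod("show", "TrainedModel", function(object) {
  show(object@config)
  if (nrow(object@history) > 0L) {
    best <- min(object@history$val_total)
    cat(sprintf("  trained %d epoch(s); best validation total %.4f\n",
                nrow(object@history), best))
  } else {
    cat("  untrained (seeded initialization)\n")
  }
})

setMethod("show", "DiagonalGaussian", function(object) {
  cat(sprintf("DiagonalGaussian, dimension %d\n", length(object@mean)))
})

setMethod("show", "ReliabilityReport", function(object) {
  cat(sprintf("ReliabilityReport: %d ordered seed pair(s), mean R-squared %.4f\n",
              nrow(object@pairs), object@meanR2))
})

setMethod("show", "ClusterReport", function(object) {
  cat(sprintf("ClusterReport: k=%d over %d window(s) from %d subject(s)\n",
              object@k, length(object@assignment), nrow(object@counts)))
})
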