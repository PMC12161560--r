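#' @import methods
NULL

.DIAGNOSES <- c("patient", "control")
.SPLITS <- c("train", "val", "test")
.VARIANTS <- c("dsvae", "idsvae", "lvae", "cvae")

#' Sliding-window specification
#'
#' Width and stride of the overlapping windows cut from each subject's
#' timecourse matrix, in timesteps.  The defaults (width 32, stride 4)
#' correspond to 64-second windows spaced 8 seconds apart at a 2-second
#' sampling interval.
#'
#' @slot width window length in timesteps (>= 2)
#' @slot stride step between consecutive window starts (>= 1)
#' @export
setClass("WindowSpec",
  representation(width = "integer", stride = "integer"),
  prototype(width = 32L, stride = 4L))

setValidity("WindowSpec", function(object) {
  if (length(object@width) != 1L || is.na(object@width) || object@width < 2L)
    return("width must be a single integer >= 2")
  if (length(object@stride) != 1L || is.na(object@stride) || object@stride < 1L)
    return("stride must be a single integer >= 1")
  TRUE
})

#' @param width window length in timesteps
#' @param stride step between window starts in timesteps
#' @rdname WindowSpec-class
#' @export
windowSpec <- function(width = 32L, stride = 4L) {
  new("WindowSpec", width = as.integer(width), stride = as.integer(stride))
}

#' One subject's component timecourses plus phenotype
#'
#' Holds the N x T matrix of component timecourses (rows = components,
#' columns = timesteps) together with diagnosis and optional covariates.
#' Missing age or cognitive score is stored as \code{NA}, never imputed.
#'
#' @slot subjectId opaque subject identifier
#' @slot diagnosis \code{"patient"} or \code{"control"}
#' @slot age years, \code{NA} if unknown
#' @slot cognitiveScore composite cognitive score, \code{NA} if unknown
#' @slot samplingInterval seconds between timesteps (TR)
#' @slot data numeric matrix, components x timesteps
#' @export
setClass("SubjectRecord",
  representation(subjectId = "character", diagnosis = "character",
                 age = "numeric", cognitiveScore = "numeric",
                 samplingInterval = "numeric", data = "matrix"))

setValidity("SubjectRecord", function(object) {
  if (length(object@subjectId) != 1L || !nzchar(object@subjectId))
    return("subjectId must be a non-empty string")
  if (!object@diagnosis %in% .DIAGNOSES)
    return(sprintf("diagnosis must be one of %s",
                   paste(.DIAGNOSES, collapse = ", ")))
  d <- object@data
  if (nrow(d) < 2L) return("need at least 2 components")
  if (ncol(d) < 1L) return("need at least 1 timestep")
  if (!all(is.finite(d))) {
    bad <- which(!is.finite(d), arr.ind = TRUE)[1L, ]
    return(sprintf("subject '%s': non-finite value at component %d, timestep %d",
                   object@subjectId, bad[1L], bad[2L]))
  }
  if (length(object@samplingInterval) != 1L || object@samplingInterval <= 0)
    return("samplingInterval must be a positive scalar")
  TRUE
})

#' @param subjectId subject identifier
#' @param diagnosis "patient" or "control"
#' @param data components x timesteps matrix
#' @param age optional age in years
#' @param cognitiveScore optional cognitive composite score
#' @param samplingInterval seconds per timestep
#' @rdname SubjectRecord-class
#' @export
subjectRecord <- function(subjectId, diagnosis, data, age = NA_real_,
                          cognitiveScore = NA_real_, samplingInterval = 2) {
  new("SubjectRecord", subjectId = as.character(subjectId),
      diagnosis = as.character(diagnosis), age = as.numeric(age),
      cognitiveScore = as.numeric(cognitiveScore),
      samplingInterval = as.numeric(samplingInterval),
      data = as.matrix(data))
}

#' A collection of subjects sharing a component space
#'
#' All records must have the same number of components N; timecourse length
#' T may differ per subject.
#'
#' @slot records list of \linkS4class{SubjectRecord}
#' @export
setClass("TimecourseSet", representation(records = "list"))

setValidity("TimecourseSet", function(object) {
  recs <- object@records
  if (length(recs) == 0L) return(TRUE)
  if (!all(vapply(recs, is, logical(1), "SubjectRecord")))
    return("all records must be SubjectRecord objects")
  ns <- vapply(recs, function(r) nrow(r@data), integer(1))
  if (length(unique(ns)) > 1L)
    return(sprintf("all subjects must share the component count; saw %s",
                   paste(unique(ns), collapse = ", ")))
  ids <- vapply(recs, function(r) r@subjectId, character(1))
  if (anyDuplicated(ids))
    return(sprintf("duplicated subject id '%s'", ids[duplicated(ids)][1L]))
  TRUE
})

#' @param records list of SubjectRecord objects
#' @rdname TimecourseSet-class
#' @export
timecourseSet <- function(records = list()) {
  new("TimecourseSet", records = records)
}

#' A set of extracted windows
#'
#' Windows are stored as an N x width x M array; each window keeps its
#' provenance (subject id and 0-based start index).  Starts use half-open
#' [start, start + width) slicing of the source timecourse.
#'
#' @slot data array, components x width x windows
#' @slot subjectId character vector, one per window
#' @slot start integer vector of 0-based start indices
#' @slot width window width in timesteps
#' @slot stride stride used at extraction
#' @slot samplingInterval seconds per timestep
#' @export
setClass("WindowSet",
  representation(data = "array", subjectId = "character", start = "integer",
                 width = "integer", stride = "integer",
                 samplingInterval = "numeric"))

setValidity("WindowSet", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be a 3-d array")
  m <- d[3L]
  if (length(object@subjectId) != m || length(object@start) != m)
    return("provenance length must equal the number of windows")
  if (d[2L] != object@width) return("array width does not match width slot")
  if (any(object@start < 0L)) return("starts must be >= 0")
  TRUE
})

#' Train/validation/test assignment of subjects
#'
#' Each subject appears exactly once; all windows of a subject inherit its
#' split, so no window-level leakage between splits is possible.
#'
#' @slot assignment named character vector with values train/val/test
#' @export
setClass("DatasetSplit", representation(assignment = "character"))

setValidity("DatasetSplit", function(object) {
  a <- object@assignment
  if (is.null(names(a)) || any(!nzchar(names(a))))
    return("assignment must be named by subject id")
  if (anyDuplicated(names(a))) return("each subject must appear exactly once")
  if (!all(a %in% .SPLITS))
    return("split values must be train, val or test")
  TRUE
})

#' Per-window context embeddings with provenance
#'
#' One row per window: subject id, 0-based window start, split, diagnosis,
#' and the context embedding vector.
#'
#' @slot info data.frame with columns subject_id, window_start, split,
#'   diagnosis
#' @slot embedding numeric matrix, windows x embedding dimensions
#' @slot width window width the embeddings were computed from
#' @export
setClass("EmbeddingTable",
  representation(info = "data.frame", embedding = "matrix",
                 width = "integer"))

setValidity("EmbeddingTable", function(object) {
  need <- c("subject_id", "window_start", "split", "diagnosis")
  if (!all(need %in% names(object@info)))
    return(sprintf("info must have columns %s", paste(need, collapse = ", ")))
  if (nrow(object@info) != nrow(object@embedding))
    return("info and embedding must have the same number of rows")
  key <- paste(object@info$subject_id, object@info$window_start)
  if (anyDuplicated(key))
    return("(subject_id, window_start) must be unique")
  TRUE
})

#' @param info provenance data.frame
#' @param embedding numeric matrix of embeddings
#' @param width window width in timesteps
#' @rdname EmbeddingTable-class
#' @export
embeddingTable <- function(info, embedding, width = NA_integer_) {
  new("EmbeddingTable", info = as.data.frame(info),
      embedding = as.matrix(embedding), width = as.integer(width))
}

#' Model hyperparameter configuration
#'
#' @slot variant one of dsvae, idsvae, lvae, cvae
#' @slot localSize dimension of the per-timestep local embedding (LS)
#' @slot contextSize dimension of the per-window context embedding (CS)
#' @slot beta weight of the local KL term
#' @slot gamma weight of the context KL term
#' @slot contextEncoderArch "rnn" (bidirectional GRU) or "conv"
#' @slot hiddenSize hidden width of encoders/prior/decoder
#' @slot convKernel kernel length of the convolutional layers
#' @slot learningRate Adam learning rate
#' @slot maxEpochs training epoch budget
#' @slot inputNoiseStd std of Gaussian noise added to training inputs only
#' @slot seed seed for initialization, batching and sampling
#' @export
setClass("ModelConfig",
  representation(variant = "character", localSize = "integer",
                 contextSize = "integer", beta = "numeric", gamma = "numeric",
                 contextEncoderArch = "character", hiddenSize = "integer",
                 convKernel = "integer", learningRate = "numeric",
                 maxEpochs = "integer", inputNoiseStd = "numeric",
                 seed = "integer"))

setValidity("ModelConfig", function(object) {
  if (!object@variant %in% .VARIANTS)
    return(sprintf("variant must be one of %s", paste(.VARIANTS, collapse = ", ")))
  if (!object@contextEncoderArch %in% c("rnn", "conv"))
    return("contextEncoderArch must be 'rnn' or 'conv'")
  if (object@localSize < 1L || object@contextSize < 1L)
    return("localSize and contextSize must be positive")
  if (object@beta < 0 || object@gamma < 0)
    return("beta and gamma must be non-negative")
  if (object@inputNoiseStd < 0) return("inputNoiseStd must be >= 0")
  if (object@maxEpochs < 0L) return("maxEpochs must be >= 0")
  if (object@convKernel %% 2L != 1L) return("convKernel must be odd")
  TRUE
})

#' @param variant model variant
#' @param localSize local embedding dimension
#' @param contextSize context embedding dimension
#' @param beta local KL weight
#' @param gamma context KL weight
#' @param contextEncoderArch "rnn" or "conv"
#' @param hiddenSize hidden layer width
#' @param convKernel odd convolution kernel length
#' @param learningRate Adam step size
#' @param maxEpochs epoch budget
#' @param inputNoiseStd training-time input corruption std
#' @param seed integer seed
#' @rdname ModelConfig-class
#' @export
modelConfig <- function(variant = c("dsvae", "idsvae", "lvae", "cvae"),
                        localSize = 4L, contextSize = 2L, beta = 0.1,
                        gamma = 0.001, contextEncoderArch = c("rnn", "conv"),
                        hiddenSize = 32L, convKernel = 5L,
                        learningRate = 1e-3, maxEpochs = 20L,
                        inputNoiseStd = 0, seed = 42L) {
  new("ModelConfig", variant = match.arg(variant),
      localSize = as.integer(localSize), contextSize = as.integer(contextSize),
      beta = as.numeric(beta), gamma = as.numeric(gamma),
      contextEncoderArch = match.arg(contextEncoderArch),
      hiddenSize = as.integer(hiddenSize), convKernel = as.integer(convKernel),
      learningRate = as.numeric(learningRate),
      maxEpochs = as.integer(maxEpochs),
      inputNoiseStd = as.numeric(inputNoiseStd), seed = as.integer(seed))
}

#' A trained (or freshly initialized) model
#'
#' @slot config the \linkS4class{ModelConfig} used
#' @slot params named list of weight matrices/vectors
#' @slot history per-epoch loss breakdown on train and validation sets
#' @slot inputDim number of observed components N
#' @slot width window width the model was built for
#' @export
setClass("TrainedModel",
  representation(config = "ModelConfig", params = "list",
                 history = "data.frame", inputDim = "integer",
                 width = "integer"))

#' Diagonal-Gaussian distribution
#'
#' Variational posteriors and priors over embeddings are diagonal Gaussians
#' parameterized by a mean and a log-variance vector; log-variances are
#' clamped to [-10, 10].
#'
#' @slot mean numeric vector
#' @slot logVariance numeric vector, same length
#' @export
setClass("DiagonalGaussian",
  representation(mean = "numeric", logVariance = "numeric"))

setValidity("DiagonalGaussian", function(object) {
  if (length(object@mean) != length(object@logVariance))
    return("mean and logVariance must have equal length")
  if (!all(is.finite(object@logVariance)))
    return("logVariance must be finite")
  TRUE
})

#' @param mean mean vector
#' @param logVariance log-variance vector
#' @rdname DiagonalGaussian-class
#' @export
diagonalGaussian <- function(mean, logVariance) {
  new("DiagonalGaussian", mean = as.numeric(mean),
      logVariance = pmin(pmax(as.numeric(logVariance), -10), 10))
}

#' Synthetic dataset specification
#'
#' Describes a cohort of subjects whose windows carry a slowly drifting
#' context factor with a group-dependent mean, fast AR(1) local dynamics,
#' (non)linear mixing to the observed channels, and additive Gaussian noise.
#'
#' @slot nSubjectsPerGroup subjects per diagnosis group
#' @slot nComponents observed channels N
#' @slot nTimesteps scan length T
#' @slot contextDim dimension of the slow context factor
#' @slot localDim dimension of the fast local factor
#' @slot contextGroupOffset mean shift of the patient group's context factor
#' @slot contextDriftTimescale autocorrelation timescale of the context drift,
#'   in timesteps
#' @slot arCoefficient lag-1 coefficient of the local AR(1) process
#' @slot mixing "linear" or "tanh"
#' @slot noiseStd observation noise standard deviation
#' @slot seed master seed; every subject derives its own stream from it
#' @export
setClass("SyntheticSpec",
  representation(nSubjectsPerGroup = "integer", nComponents = "integer",
                 nTimesteps = "integer", contextDim = "integer",
                 localDim = "integer", contextGroupOffset = "numeric",
                 contextDriftTimescale = "numeric", arCoefficient = "numeric",
                 mixing = "character", noiseStd = "numeric", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  if (any(c(object@nSubjectsPerGroup, object@nComponents, object@nTimesteps,
            object@contextDim, object@localDim) < 1L))
    return("all dimensions must be positive")
  if (length(object@contextGroupOffset) != object@contextDim)
    return("contextGroupOffset must have length contextDim")
  if (abs(object@arCoefficient) >= 1)
    return("|arCoefficient| must be < 1 for stationarity")
  if (object@noiseStd < 0) return("noiseStd must be >= 0")
  if (object@contextDriftTimescale <= 0)
    return("contextDriftTimescale must be positive")
  if (!object@mixing %in% c("linear", "tanh"))
    return("mixing must be 'linear' or 'tanh'")
  TRUE
})

#' Ground-truth latent trajectories of a synthetic dataset
#'
#' Stored alongside, never inside, the subject records.
#'
#' @slot subjectId subject ids in generation order
#' @slot group group label per subject
#' @slot context list of contextDim x T matrices
#' @slot local list of localDim x T matrices
#' @slot spec the generating \linkS4class{SyntheticSpec}
#' @export
setClass("SyntheticTruth",
  representation(subjectId = "character", group = "character",
                 context = "list", local = "list", spec = "SyntheticSpec"))

#' Cross-seed reliability report
#'
#' @slot pairs data.frame with one row per ordered seed pair and its R-squared
#' @slot meanR2 mean R-squared across all ordered pairs
#' @export
setClass("ReliabilityReport",
  representation(pairs = "data.frame", meanR2 = "numeric"))

#' K-means cluster report over context embeddings
#'
#' @slot centroids k x d matrix of cluster centers
#' @slot info provenance of the clustered windows
#' @slot assignment integer cluster label in 1..k per window
#' @slot counts subjects x k matrix of window counts per cluster
#' @slot k number of clusters
#' @slot inertia total within-cluster sum of squares of the kept restart
#' @export
setClass("ClusterReport",
  representation(centroids = "matrix", info = "data.frame",
                 assignment = "integer", counts = "matrix", k = "integer",
                 inertia = "numeric"))

setValidity("ClusterReport", function(object) {
  if (any(object@assignment < 1L | object@assignment > object@k))
    return("assignments must lie in 1..k")
  if (sum(object@counts) != length(object@assignment))
    return("per-subject counts must sum to the window total")
  TRUE
})

#' Hyperparameter grid-search result
#'
#' @slot runs one row per (config, seed) with the final validation losses
#' @slot configMeans per-config mean validation total across seeds
#' @slot selected index of the selected config (lowest mean; ties broken by
#'   lowest config index)
#' @slot models list of lists of \linkS4class{TrainedModel}
#' @export
setClass("GridResult",
  representation(runs = "data.frame", configMeans = "data.frame",
                 selected = "integer", models = "list"))
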