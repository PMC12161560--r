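#' @include AllGenerics.R
NULL

#' Windowed functional network connectivity of one window
#'
#' Entry (i, j) is the Pearson correlation of components i and j across the
#' window's timesteps; symmetric with unit diagonal, entries in [-1, 1].
#' A component with zero variance inside the window is an error (silent
#' NaNs would corrupt downstream PCA and distances), naming the component
#' and, when available, the window's provenance.
#'
#' @param window numeric N x W matrix with at least 2 timesteps
#' @return N x N correlation matrix
#' @export
computeWfnc <- function(window) {
  w <- as.matrix(window)
  if (ncol(w) < 2L) stop("wFNC needs a window of at least 2 timesteps")
  sdv <- apply(w, 1L, stats::sd)
  if (any(sdv == 0) || any(!is.finite(sdv))) {
    bad <- which(sdv == 0 | !is.finite(sdv))[1L]
    prov <- attr(window, "provenance")
    stop(sprintf("component %d has zero variance within the window%s",
                 bad, if (is.null(prov)) "" else paste0(" (", prov, ")")))
  }
  m <- stats::cor(t(w))
  dimnames(m) <- NULL
  m
}

#' Vectorize the upper triangle of a wFNC matrix
#'
#' Row-major (i < j) ordering, diagonal excluded; length N(N-1)/2.  The
#' mapping is invertible up to the unit diagonal via
#' \code{unvectorizeUpper}.
#'
#' @param m symmetric N x N matrix
#' @return numeric vector of length N(N-1)/2
#' @export
vectorizeUpper <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8)
    stop("input must be a symmetric square matrix")
  t(m)[lower.tri(m)]   # row-major enumeration of the upper triangle
}

#' @param v vector produced by \code{vectorizeUpper}
#' @param n matrix dimension
#' @rdname vectorizeUpper
#' @export
unvectorizeUpper <- function(v, n) {
  if (length(v) != n * (n - 1) / 2)
    stop("vector length does not match n(n-1)/2")
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- v
  m <- t(m)
  m[lower.tri(m)] <- v
  diag(m) <- 1
  m
}

#' wFNC vectors for every window of a set
#'
#' @param windows a \linkS4class{WindowSet}
#' @return matrix, one row per window, N(N-1)/2 columns
#' @export
wfncVectors <- function(windows) {
  stopifnot(is(windows, "WindowSet"))
  n <- nComponents(windows)
  out <- matrix(0, nWindows(windows), n * (n - 1) / 2)
  for (i in seq_len(nWindows(windows))) {
    w <- windows@data[, , i]
    attr(w, "provenance") <- sprintf("subject %s, start %d",
                                     windows@subjectId[i], windows@start[i])
    out[i, ] <- vectorizeUpper(computeWfnc(w))
  }
  out
}

#' Elementwise average wFNC over a set of windows
#'
#' @param windows a \linkS4class{WindowSet} or list of N x W matrices
#' @return N x N matrix, symmetric with unit diagonal
#' @export
averageWfnc <- function(windows) {
  mats <- if (is(windows, "WindowSet")) {
    if (nWindows(windows) == 0L) stop("empty window set")
    lapply(seq_len(nWindows(windows)), function(i) windows@data[, , i])
  } else {
    if (length(windows) == 0L) stop("empty window list")
    windows
  }
  Reduce(`+`, lapply(mats, computeWfnc)) / length(mats)
}

#' PCA reduction fitted on train+validation, applied to test
#'
#' The rotation is estimated from the concatenated train and validation
#' vectors only (centering always, standardization optional) and the test
#' set is projected into the same space.  Component signs follow a fixed
#' convention: the loading with the largest magnitude is made positive.
#'
#' @param trainVectors,valVectors,testVectors row-per-window matrices
#' @param dim number of components to keep
#' @param standardize scale columns to unit variance before PCA
#' @return list with reduced \code{train}, \code{val}, \code{test} matrices
#'   and the fraction of variance explained by the kept components
#' @export
pcaReduce <- function(trainVectors, valVectors, testVectors, dim,
                      standardize = FALSE) {
  fit <- rbind(trainVectors, valVectors)
  if (dim > min(nrow(fit), ncol(fit)))
    stop("dim exceeds the rank bound min(samples, vector length)")
  pc <- stats::prcomp(fit, center = TRUE, scale. = standardize, rank. = dim)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  pc$rotation <- sweep(pc$rotation, 2L, flip, `*`)
  proj <- function(x) {
    if (nrow(x) == 0L) return(matrix(0, 0L, dim))
    stats::predict(pc, x)[, seq_len(dim), drop = FALSE]
  }
  totVar <- sum(pc$sdev^2)
  list(train = proj(trainVectors), val = proj(valVectors),
       test = proj(testVectors),
       explainedVariance = sum(pc$sdev[seq_len(dim)]^2) / totVar)
}

#' Context-sized wFNC baseline embeddings via PCA
#'
#' Computes per-window wFNC vectors, fits PCA on the train+validation
#' windows, projects every window, and returns the result in the same
#' \linkS4class{EmbeddingTable} form as the model embeddings so the same
#' classification protocol applies.
#'
#' @param windows a \linkS4class{WindowSet}
#' @param split a \linkS4class{DatasetSplit}
#' @param diagnoses named character vector subject -> diagnosis
#' @param dim embedding dimension to keep
#' @param standardize standardize wFNC vectors before PCA
#' @return an \linkS4class{EmbeddingTable}
#' @export
wfncPcaEmbeddings <- function(windows, split, diagnoses, dim = 2L,
                              standardize = FALSE) {
  vecs <- wfncVectors(windows)
  spl <- splitOf(split, windows@subjectId)
  red <- pcaReduce(vecs[spl == "train", , drop = FALSE],
                   vecs[spl == "val", , drop = FALSE],
                   vecs[spl == "test", , drop = FALSE], dim,
                   standardize = standardize)
  emb <- matrix(0, nrow(vecs), dim)
  emb[spl == "train", ] <- red$train
  emb[spl == "val", ] <- red$val
  emb[spl == "test", ] <- red$test
  embeddingTable(
    data.frame(subject_id = windows@subjectId, window_start = windows@start,
               split = spl, diagnosis = unname(diagnoses[windows@subjectId]),
               stringsAsFactors = FALSE),
    emb, width = windows@width)
}
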