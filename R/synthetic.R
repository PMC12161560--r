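#' @include AllGenerics.R
NULL

#' Construct a synthetic dataset specification
#'
#' Defaults describe the reference study conditions used throughout the
#' package's end-to-end evaluation: two groups of 50 subjects, 10 observed
#' channels over 160 timesteps, a 2-dimensional context factor drifting on a
#' 32-timestep (one-window) timescale whose group means differ by a vector
#' of norm 2, 4-dimensional AR(1) local dynamics, tanh mixing and mild
#' additive noise.
#'
#' @param nSubjectsPerGroup subjects per group
#' @param nComponents observed channels
#' @param nTimesteps timesteps per subject
#' @param contextDim context factor dimension
#' @param localDim local factor dimension
#' @param contextGroupOffset patient-group mean shift of the context factor;
#'   default is a vector of norm 2 spread evenly over the dimensions
#' @param contextDriftTimescale context autocorrelation timescale, timesteps
#' @param arCoefficient lag-1 coefficient of the local AR(1), in (-1, 1)
#' @param mixing "tanh" (default) or "linear"
#' @param noiseStd observation noise std
#' @param seed master seed
#' @return a \linkS4class{SyntheticSpec}
#' @export
syntheticSpec <- function(nSubjectsPerGroup = 50L, nComponents = 10L,
                          nTimesteps = 160L, contextDim = 2L, localDim = 4L,
                          contextGroupOffset = NULL,
                          contextDriftTimescale = 32, arCoefficient = 0.3,
                          mixing = c("tanh", "linear"), noiseStd = 0.1,
                          seed = 1L) {
  contextDim <- as.integer(contextDim)
  if (is.null(contextGroupOffset))
    contextGroupOffset <- rep(2 / sqrt(contextDim), contextDim)
  new("SyntheticSpec", nSubjectsPerGroup = as.integer(nSubjectsPerGroup),
      nComponents = as.integer(nComponents),
      nTimesteps = as.integer(nTimesteps), contextDim = contextDim,
      localDim = as.integer(localDim),
      contextGroupOffset = as.numeric(contextGroupOffset),
      contextDriftTimescale = as.numeric(contextDriftTimescale),
      arCoefficient = as.numeric(arCoefficient),
      mixing = match.arg(mixing), noiseStd = as.numeric(noiseStd),
      seed = as.integer(seed))
}

# Deterministic per-subject seed derived from the master seed and the
# subject index; keeps every subject's stream independent of generation
# order.  Lehmer-style mixing, exact in double arithmetic, result < 2^31.
.subjectSeed <- function(seed, index) {
  h <- (abs(as.numeric(seed)) %% 2147483647) + 1
  h <- (h * 48271) %% 2147483647
  h <- (h + index * 16807) %% 2147483647
  as.integer((h * 69621) %% 2147483647)
}

# Stationary AR(1) path: x_t = m + rho (x_{t-1} - m) + s e_t, unit
# stationary variance when s = sqrt(1 - rho^2).
.arPath <- function(d, Tn, rho, mean = rep(0, d), innovSd = sqrt(1 - rho^2),
                    statSd = 1) {
  x <- matrix(0, d, Tn)
  x[, 1L] <- mean + statSd * stats::rnorm(d)
  for (t in seq_len(Tn - 1L))
    x[, t + 1L] <- mean + rho * (x[, t] - mean) + innovSd * stats::rnorm(d)
  x
}

#' Generate a synthetic cohort with known slow/fast latent structure
#'
#' Per subject, a context factor follows a slow stationary
#' Ornstein-Uhlenbeck-style AR(1) drift (lag-1 correlation
#' \code{exp(-1/contextDriftTimescale)}, unit stationary variance) around a
#' group-dependent mean: zero for controls, \code{contextGroupOffset} for
#' patients.  A local factor follows an AR(1) with coefficient
#' \code{arCoefficient} and unit innovation variance.  The observed channels
#' are \code{mixing(A [context; local]) + noise}, with \code{A} a fixed
#' random matrix with unit-norm rows drawn once per dataset.  Subject-level
#' age and cognitive score covariates are drawn with a mild dependence on
#' the subject's mean context position along the group-offset direction, so
#' dwell-time analyses have recoverable structure.  Fully deterministic
#' given the spec's seed; each subject uses its own derived stream.
#'
#' @param spec a \linkS4class{SyntheticSpec}
#' @param mixingMatrix optional fixed mixing matrix overriding the random
#'   draw (must be nComponents x (contextDim + localDim))
#' @return list with elements \code{records} (a
#'   \linkS4class{TimecourseSet}) and \code{truth} (a
#'   \linkS4class{SyntheticTruth})
#' @export
generateDataset <- function(spec, mixingMatrix = NULL) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  d <- spec@contextDim + spec@localDim
  set.seed(spec@seed)
  A <- if (is.null(mixingMatrix)) {
    A0 <- matrix(stats::rnorm(spec@nComponents * d), spec@nComponents, d)
    A0 / sqrt(rowSums(A0^2))
  } else {
    stopifnot(nrow(mixingMatrix) == spec@nComponents,
              ncol(mixingMatrix) == d)
    mixingMatrix
  }
  rhoC <- exp(-1 / spec@contextDriftTimescale)
  phi <- spec@arCoefficient
  offDir <- if (sum(spec@contextGroupOffset^2) > 0)
    spec@contextGroupOffset / sqrt(sum(spec@contextGroupOffset^2))
  else c(1, rep(0, spec@contextDim - 1L))

  nTot <- 2L * spec@nSubjectsPerGroup
  groups <- rep(c("control", "patient"), each = spec@nSubjectsPerGroup)
  ids <- sprintf("subj%04d", seq_len(nTot))
  recs <- vector("list", nTot)
  ctxs <- vector("list", nTot)
  locs <- vector("list", nTot)
  for (i in seq_len(nTot)) {
    set.seed(.subjectSeed(spec@seed, i))
    m <- if (groups[i] == "patient") spec@contextGroupOffset
         else rep(0, spec@contextDim)
    C <- .arPath(spec@contextDim, spec@nTimesteps, rhoC, mean = m)
    L <- .arPath(spec@localDim, spec@nTimesteps, phi, innovSd = 1,
                 statSd = 1 / sqrt(1 - phi^2))
    Y <- A %*% rbind(C, L)
    if (spec@mixing == "tanh") Y <- tanh(Y)
    if (spec@noiseStd > 0)
      Y <- Y + spec@noiseStd * matrix(stats::rnorm(length(Y)), nrow(Y))
    proj <- mean(crossprod(offDir, C))
    age <- 39 + 6 * proj + 8 * stats::rnorm(1)
    score <- (if (groups[i] == "patient") -1.6 else 0) -
      0.4 * proj + 0.8 * stats::rnorm(1)
    recs[[i]] <- subjectRecord(ids[i], groups[i], Y, age = age,
                               cognitiveScore = score, samplingInterval = 2)
    ctxs[[i]] <- C
    locs[[i]] <- L
  }
  truth <- new("SyntheticTruth", subjectId = ids, group = groups,
               context = ctxs, local = locs, spec = spec)
  list(records = timecourseSet(recs), truth = truth)
}

#' Write / read synthetic ground truth as long-form TSV
#'
#' One row per (subject, timestep) with the context and local factor values.
#'
#' @param truth a \linkS4class{SyntheticTruth}
#' @param path file path
#' @return \code{writeGroundTruth} invisibly returns \code{path}
#' @export
writeGroundTruth <- function(truth, path) {
  cd <- truth@spec@contextDim; ld <- truth@spec@localDim
  header <- c("subject_id", "group", "t",
              paste0("c", seq_len(cd)), paste0("l", seq_len(ld)))
  out <- c(paste(header, collapse = "\t"))
  for (i in seq_along(truth@subjectId)) {
    C <- truth@context[[i]]; L <- truth@local[[i]]
    for (t in seq_len(ncol(C))) {
      out <- c(out, paste(c(truth@subjectId[i], truth@group[i], t - 1L,
                            .fmtNum(C[, t]), .fmtNum(L[, t])),
                          collapse = "\t"))
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, useBytes = TRUE)
  invisible(path)
}

#' Window-averaged ground-truth context targets
#'
#' For each row of an embedding table, the time-average of the true context
#' trajectory over that window.
#'
#' @param table an \linkS4class{EmbeddingTable}
#' @param truth a \linkS4class{SyntheticTruth}
#' @param width window width; defaults to the table's stored width
#' @return matrix, rows aligned with the table's windows
#' @export
windowContextTargets <- function(table, truth, width = NULL) {
  if (is.null(width)) width <- table@width
  if (is.na(width)) stop("window width unknown; pass width=")
  idx <- match(table@info$subject_id, truth@subjectId)
  if (anyNA(idx))
    stop(sprintf("subject '%s' missing from ground truth",
                 table@info$subject_id[which(is.na(idx))[1L]]))
  tg <- matrix(0, nrow(table@info), truth@spec@contextDim)
  for (r in seq_len(nrow(table@info))) {
    C <- truth@context[[idx[r]]]
    s <- table@info$window_start[r]
    tg[r, ] <- rowMeans(C[, (s + 1L):(s + width), drop = FALSE])
  }
  tg
}

#' Cross-validated recovery of the true context factor from embeddings
#'
#' Fits an affine map from context embeddings to the window-averaged true
#' context factor by subject-level cross-validation (subjects are split
#' into folds, so a subject's windows are never used to predict
#' themselves), and returns the uniformly averaged out-of-fold R-squared.
#' The score is invariant to any invertible affine transform of the
#' embeddings; a perfect linear recovery scores 1, independent noise scores
#' about 0 (can be negative).
#'
#' @param table an \linkS4class{EmbeddingTable} of context embeddings
#' @param truth the generating \linkS4class{SyntheticTruth}
#' @param nFolds number of subject-level folds
#' @param width window width; defaults to the table's stored width
#' @return a single R-squared value in (-Inf, 1]
#' @export
contextRecoveryScore <- function(table, truth, nFolds = 5L, width = NULL) {
  stopifnot(is(table, "EmbeddingTable"), is(truth, "SyntheticTruth"))
  targets <- windowContextTargets(table, truth, width)
  E <- table@embedding
  subj <- table@info$subject_id
  us <- sort(unique(subj))
  fold <- stats::setNames((seq_along(us) - 1L) %% nFolds + 1L, us)
  pred <- matrix(NA_real_, nrow(targets), ncol(targets))
  for (f in seq_len(nFolds)) {
    hold <- fold[subj] == f
    if (!any(hold) || all(hold)) next
    X <- cbind(1, E[!hold, , drop = FALSE])
    co <- stats::lm.fit(X, targets[!hold, , drop = FALSE])$coefficients
    co[is.na(co)] <- 0
    pred[hold, ] <- cbind(1, E[hold, , drop = FALSE]) %*% co
  }
  ok <- stats::complete.cases(pred)
  ssRes <- colSums((targets[ok, , drop = FALSE] - pred[ok, , drop = FALSE])^2)
  ssTot <- colSums(scale(targets[ok, , drop = FALSE], scale = FALSE)^2)
  r2 <- 1 - ssRes / pmax(ssTot, .Machine$double.eps)
  mean(r2)
}
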