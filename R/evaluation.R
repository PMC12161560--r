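#' @include AllGenerics.R
NULL

#' Linear-SVM window classification accuracy
#'
#' Fits a linear support-vector machine (fixed regularization constant,
#' not tuned) on the concatenated train and validation context embeddings,
#' labelled by each window's subject diagnosis, and returns the
#' window-level accuracy on the test-split windows.
#'
#' @param table an \linkS4class{EmbeddingTable} with split and diagnosis
#' @param cost SVM regularization constant C (fixed; logged via attribute)
#' @return accuracy in [0, 1], with attribute \code{cost}
#' @export
classifyContext <- function(table, cost = 1) {
  stopifnot(is(table, "EmbeddingTable"))
  fit <- table@info$split %in% c("train", "val")
  test <- table@info$split == "test"
  if (!any(test)) stop("test split is empty")
  yFit <- factor(table@info$diagnosis[fit], levels = .DIAGNOSES)
  if (length(unique(yFit)) < 2L)
    stop("training set contains a single class; cannot fit an SVM")
  sv <- e1071::svm(x = table@embedding[fit, , drop = FALSE], y = yFit,
                   kernel = "linear", cost = cost, scale = FALSE)
  pred <- stats::predict(sv, table@embedding[test, , drop = FALSE])
  acc <- mean(as.character(pred) == table@info$diagnosis[test])
  attr(acc, "cost") <- cost
  acc
}

.alignTables <- function(tables) {
  ref <- paste(tables[[1L]]@info$subject_id, tables[[1L]]@info$window_start)
  for (tb in tables[-1L]) {
    key <- paste(tb@info$subject_id, tb@info$window_start)
    if (!identical(ref, key))
      stop("embedding tables are not aligned on (subject_id, window_start)")
  }
  invisible(TRUE)
}

.multiR2 <- function(X, Y, Xeval, Yeval) {
  co <- stats::lm.fit(cbind(1, X), Y)$coefficients
  co[is.na(co)] <- 0
  pred <- cbind(1, Xeval) %*% co
  ssRes <- colSums((Yeval - pred)^2)
  ssTot <- colSums(scale(Yeval, scale = FALSE)^2)
  mean(1 - ssRes / pmax(ssTot, .Machine$double.eps))
}

#' Cross-seed reliability of context embedding spaces
#'
#' For each ordered pair of seeds (a, b), fits an ordinary-least-squares
#' affine map from seed-a embeddings to seed-b embeddings on the
#' concatenated train and validation windows and evaluates the uniformly
#' averaged multi-output R-squared on held-out (by default test) windows.
#' A model family that converges to the same space up to linear transforms
#' scores near 1 regardless of the initialization seed.
#'
#' @param tables list of \linkS4class{EmbeddingTable} objects, one per
#'   seed, aligned on (subject_id, window_start)
#' @param fitOn splits used for fitting the map
#' @param evalOn splits used for computing R-squared
#' @return a \linkS4class{ReliabilityReport}
#' @export
seedReliability <- function(tables, fitOn = c("train", "val"),
                            evalOn = "test") {
  if (length(tables) < 2L) stop("need at least 2 seeds")
  .alignTables(tables)
  spl <- tables[[1L]]@info$split
  fit <- spl %in% fitOn
  ev <- spl %in% evalOn
  if (!any(fit) || !any(ev)) stop("empty fit or evaluation subset")
  nm <- names(tables)
  if (is.null(nm)) nm <- as.character(seq_along(tables))
  rows <- list()
  for (a in seq_along(tables)) for (b in seq_along(tables)) {
    if (a == b) next
    r2 <- .multiR2(tables[[a]]@embedding[fit, , drop = FALSE],
                   tables[[b]]@embedding[fit, , drop = FALSE],
                   tables[[a]]@embedding[ev, , drop = FALSE],
                   tables[[b]]@embedding[ev, , drop = FALSE])
    rows[[length(rows) + 1L]] <- data.frame(
      seed_a = nm[a], seed_b = nm[b], r2 = r2, stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows)
  new("ReliabilityReport", pairs = pairs, meanR2 = mean(pairs$r2))
}

.pairIndices <- function(n, maxPairs, seed) {
  nPairs <- n * (n - 1) / 2
  take <- if (nPairs > maxPairs) {
    set.seed(as.integer(seed))
    sort(sample(nPairs, maxPairs))
  } else seq_len(nPairs)
  # map linear index (column-major over i < j) to (i, j)
  ends <- cumsum(seq_len(n - 1))            # pairs ending at column j+1
  j <- findInterval(take - 1L, ends) + 2L
  i <- take - c(0, ends)[j - 1L]
  cbind(i, j)
}

#' Similarity of two embedding manifolds via pairwise distances
#'
#' Euclidean distances between the same windows are computed in both
#' spaces, z-scored, and the squared Pearson correlation (the R-squared of
#' a simple linear regression of one normalized distance vector on the
#' other) is returned.  If the number of window pairs exceeds
#' \code{maxPairs}, a seeded uniform subsample of pairs is used.
#'
#' @param a,b row-per-window coordinate matrices or
#'   \linkS4class{EmbeddingTable} objects covering the same windows
#' @param maxPairs pair budget
#' @param seed seed for pair subsampling
#' @return R-squared in [0, 1]
#' @export
manifoldSimilarity <- function(a, b, maxPairs = 1e6, seed = 1L) {
  A <- if (is(a, "EmbeddingTable")) a@embedding else as.matrix(a)
  B <- if (is(b, "EmbeddingTable")) b@embedding else as.matrix(b)
  if (nrow(A) != nrow(B)) stop("both spaces must contain the same windows")
  if (nrow(A) < 2L) stop("need at least 2 windows")
  ij <- .pairIndices(nrow(A), maxPairs, seed)
  dA <- sqrt(rowSums((A[ij[, 1L], , drop = FALSE] -
                      A[ij[, 2L], , drop = FALSE])^2))
  dB <- sqrt(rowSums((B[ij[, 1L], , drop = FALSE] -
                      B[ij[, 2L], , drop = FALSE])^2))
  if (stats::sd(dA) == 0 || stats::sd(dB) == 0) {
    # degenerate geometry: identical point sets give identical distances
    return(if (isTRUE(all.equal(dA, dB))) 1 else 0)
  }
  unname(stats::cor(dA, dB)^2)
}

# k-means++ seeding: first center uniform, then D^2-weighted draws.
.kmeansppCenters <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- X[idx, ]
  d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
  for (c in seq_len(k - 1L)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx <- sample.int(n, 1L, prob = p)
    centers[c + 1L, ] <- X[idx, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[c + 1L, ])^2))
  }
  centers
}

#' K-means clustering of context embeddings
#'
#' k-means++ initialization from the given seed, ten restarts, Lloyd
#' iterations, keeping the restart with the lowest total within-cluster sum
#' of squares; assignment is by the nearest centroid in Euclidean distance.
#'
#' @param table an \linkS4class{EmbeddingTable} (typically the
#'   patient-window subset)
#' @param k number of clusters
#' @param seed integer seed
#' @param nstart number of seeded restarts
#' @return a \linkS4class{ClusterReport}
#' @export
kmeansFit <- function(table, k, seed = 1L, nstart = 10L) {
  stopifnot(is(table, "EmbeddingTable"))
  X <- table@embedding
  if (k > nrow(X)) stop("k exceeds the number of windows")
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(nstart)) {
    cen <- .kmeansppCenters(X, k)
    km <- suppressWarnings(
      stats::kmeans(X, centers = cen, iter.max = 100L, algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  subj <- sort(unique(table@info$subject_id))
  counts <- matrix(0L, length(subj), k,
                   dimnames = list(subj, paste0("cluster", seq_len(k))))
  tab <- table(factor(table@info$subject_id, levels = subj),
               factor(best$cluster, levels = seq_len(k)))
  counts[] <- as.integer(tab)
  new("ClusterReport", centroids = unname(best$centers), info = table@info,
      assignment = as.integer(best$cluster), counts = counts,
      k = as.integer(k), inertia = best$tot.withinss)
}

.safeT <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    return(c(t = NA_real_, p = NA_real_))
  tt <- tryCatch(stats::t.test(a, b, var.equal = FALSE),
                 error = function(e) NULL)
  if (is.null(tt)) return(c(t = 0, p = 1))   # essentially constant data
  c(t = unname(tt$statistic), p = tt$p.value)
}

.safeCor <- function(x, y) {
  if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(c(r = 0, p = 1))
  ct <- tryCatch(stats::cor.test(x, y), error = function(e) NULL)
  if (is.null(ct)) return(c(r = 0, p = 1))
  c(r = unname(ct$estimate), p = ct$p.value)
}

#' Dwell-time statistics of clusters against a covariate
#'
#' Per cluster: (i) a Welch two-sided t-test on the covariate between
#' patients with at least one window in the cluster and patients with none,
#' and (ii) the Pearson correlation (two-sided p) between each patient's
#' window count in the cluster -- the dwell time -- and the covariate.
#' Correlations are reported both for raw counts and for counts normalized
#' by each subject's window total.  Raw p-values are emitted together with
#' a Bonferroni-adjusted column (adjusted across clusters per statistic);
#' no correction is applied to the raw values.  Subjects lacking the
#' covariate are excluded and counted in the \code{excluded} attribute.
#'
#' @param report a \linkS4class{ClusterReport} over patient windows
#' @param subjects a \linkS4class{TimecourseSet} providing covariates
#' @param covariate \code{"age"} or \code{"cognitive_score"}
#' @return data.frame with one row per cluster
#' @export
dwellStatistics <- function(report, subjects,
                            covariate = c("age", "cognitive_score")) {
  covariate <- match.arg(covariate)
  stopifnot(is(report, "ClusterReport"), is(subjects, "TimecourseSet"))
  ids <- rownames(report@counts)
  recs <- stats::setNames(subjects@records, subjectIds(subjects))
  if (!all(ids %in% names(recs)))
    stop(sprintf("subject '%s' missing from the subject set",
                 setdiff(ids, names(recs))[1L]))
  cov <- vapply(recs[ids], function(r)
    if (covariate == "age") r@age else r@cognitiveScore, numeric(1))
  keep <- is.finite(cov)
  nExcluded <- sum(!keep)
  cov <- cov[keep]
  counts <- report@counts[keep, , drop = FALSE]
  totals <- rowSums(counts)

  rows <- lapply(seq_len(report@k), function(c) {
    inC <- counts[, c] > 0
    tt <- .safeT(cov[inC], cov[!inC])
    rc <- .safeCor(as.numeric(counts[, c]), cov)
    rn <- .safeCor(as.numeric(counts[, c]) / pmax(totals, 1L), cov)
    data.frame(cluster = c, covariate = covariate,
               n_in = sum(inC), n_out = sum(!inC),
               t = tt["t"], t_p = tt["p"],
               r = rc["r"], r_p = rc["p"],
               r_norm = rn["r"], r_norm_p = rn["p"], row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$t_p_bonferroni <- stats::p.adjust(out$t_p, method = "bonferroni")
  out$r_p_bonferroni <- stats::p.adjust(out$r_p, method = "bonferroni")
  attr(out, "excluded") <- nExcluded
  out
}

#' Cluster-average wFNC difference maps
#'
#' For each cluster, the elementwise mean wFNC over the cluster's windows
#' minus the mean wFNC over all clustered windows; symmetric with zero
#' diagonal.  Empty clusters yield a zero map flagged via the
#' \code{empty} attribute.
#'
#' @param report a \linkS4class{ClusterReport}
#' @param windows a \linkS4class{WindowSet} containing every clustered
#'   window (matched by subject id and window start)
#' @return list of k difference matrices; attribute \code{empty} marks
#'   clusters without windows
#' @export
clusterWfncMaps <- function(report, windows) {
  stopifnot(is(report, "ClusterReport"), is(windows, "WindowSet"))
  key <- paste(report@info$subject_id, report@info$window_start)
  wkey <- paste(windows@subjectId, windows@start)
  idx <- match(key, wkey)
  if (anyNA(idx))
    stop(sprintf("window (%s) not found in the window set",
                 key[which(is.na(idx))[1L]]))
  n <- nComponents(windows)
  wf <- vector("list", length(idx))
  for (r in seq_along(idx)) wf[[r]] <- computeWfnc(windows@data[, , idx[r]])
  grand <- Reduce(`+`, wf) / length(wf)
  empty <- logical(report@k)
  maps <- vector("list", report@k)
  for (c in seq_len(report@k)) {
    inC <- which(report@assignment == c)
    if (length(inC) == 0L) {
      empty[c] <- TRUE
      maps[[c]] <- matrix(0, n, n)
    } else {
      maps[[c]] <- Reduce(`+`, wf[inC]) / length(inC) - grand
    }
  }
  attr(maps, "empty") <- empty
  maps
}
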