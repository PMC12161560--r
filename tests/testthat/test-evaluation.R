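test_that("the SVM protocol classifies separable embeddings perfectly", {
  cohort <- tinyCohort(nPerGroup = 5L, Tn = 48L)
  lab <- cohort$diagnoses[cohort$windows@subjectId]
  emb <- cbind(ifelse(lab == "patient", 1, -1) + 0.01 * rnorm(length(lab)),
               rnorm(length(lab)))
  tb <- tableFor(cohort, emb)
  expect_equal(as.numeric(classifyContext(tb)), 1.0)

  # single-class training data is an error
  onlyPat <- tb[tb@info$diagnosis == "patient" | tb@info$split == "test"]
  expect_error(classifyContext(onlyPat), "single class")
})

test_that("seed reliability scores identities, affine maps and noise correctly", {
  cohort <- tinyCohort(nPerGroup = 8L, Tn = 96L)
  set.seed(31)
  n <- nWindows(cohort$windows)
  E <- matrix(rnorm(2 * n), n, 2)
  tbl <- function(e) tableFor(cohort, e)

  rep1 <- seedReliability(list(a = tbl(E), b = tbl(E), c = tbl(E)))
  expect_equal(rep1@meanR2, 1.0)
  expect_equal(nrow(rep1@pairs), 3 * 2)   # s(s-1) ordered pairs

  # an invertible affine transform of the space is perfectly predictable
  A <- matrix(c(1, 2, -1, 0.5), 2, 2)
  rep2 <- seedReliability(list(tbl(E), tbl(sweep(E %*% A, 2, c(3, -4), `+`))))
  expect_equal(rep2@meanR2, 1.0)

  # independent noise is not
  rep3 <- seedReliability(list(tbl(E), tbl(matrix(rnorm(2 * n), n, 2))))
  expect_lte(rep3@meanR2, 0.05)

  # misaligned tables are rejected
  shuf <- tbl(E)
  ord <- rev(seq_len(n))
  shuf <- shuf[ord]
  expect_error(seedReliability(list(tbl(E), shuf)), "aligned")
  expect_error(seedReliability(list(tbl(E))), "at least 2")
})

test_that("manifold similarity is exact on identities and small under the null", {
  set.seed(17)
  X <- matrix(rnorm(80 * 2), 80, 2)
  expect_equal(manifoldSimilarity(X, X), 1.0)
  # isotropic scaling and translation leave normalized distances unchanged
  expect_equal(manifoldSimilarity(X, sweep(3.7 * X, 2, c(1, 2), `+`)), 1.0)
  # independent point sets decorrelate
  Y <- matrix(rnorm(80 * 2), 80, 2)
  expect_lte(manifoldSimilarity(X, Y), 0.1)
  expect_error(manifoldSimilarity(X[1, , drop = FALSE], Y[1, , drop = FALSE]),
               "at least 2")
  # subsampling is seeded and deterministic
  s1 <- manifoldSimilarity(X, Y, maxPairs = 500, seed = 3L)
  s2 <- manifoldSimilarity(X, Y, maxPairs = 500, seed = 3L)
  expect_identical(s1, s2)
})

test_that("k-means recovers planted blobs and behaves canonically", {
  set.seed(23)
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10))
  truth <- rep(1:3, each = 60)
  X <- centers[truth, ] + matrix(rnorm(180 * 2, sd = 0.5), 180, 2)
  info <- data.frame(subject_id = sprintf("s%03d", seq_len(180)),
                     window_start = 0L, split = "train",
                     diagnosis = "patient")
  tb <- embeddingTable(info, X)
  rep <- kmeansFit(tb, k = 3L, seed = 1L)
  expect_gte(ari(rep@assignment, truth), 0.99)

  # duplicate run with the same seed is identical
  rep2 <- kmeansFit(tb, k = 3L, seed = 1L)
  expect_identical(rep@assignment, rep2@assignment)

  # k = 1 collapses to the grand mean
  rep1 <- kmeansFit(tb, k = 1L, seed = 1L)
  expect_equal(as.numeric(rep1@centroids), colMeans(X), tolerance = 1e-10)

  expect_error(kmeansFit(tb, k = 200L, seed = 1L), "exceeds")
})

test_that("dwell statistics handle degenerate and proportional covariates", {
  # a cohort of patients whose counts in cluster 1 are proportional to age
  n <- 12L
  recs <- lapply(seq_len(n), function(i)
    subjectRecord(sprintf("p%02d", i), "patient",
                  matrix(rnorm(2 * 8), 2, 8), age = 30 + 2 * i,
                  cognitiveScore = 0))
  subjects <- timecourseSet(recs)
  counts <- cbind(seq_len(n), rep(2L, n))   # cluster1 ~ age, cluster2 flat
  assignment <- rep(c(1L, 2L), times = c(sum(counts[, 1]), sum(counts[, 2])))
  info <- data.frame(subject_id = rep(sprintf("p%02d", seq_len(n)),
                                      times = rowSums(counts)),
                     window_start = seq_len(sum(counts)) - 1L,
                     split = "train", diagnosis = "patient")
  repc <- new("ClusterReport", centroids = matrix(0, 2, 2), info = info,
              assignment = assignment,
              counts = matrix(as.integer(counts), n, 2,
                              dimnames = list(sprintf("p%02d", seq_len(n)),
                                              c("cluster1", "cluster2"))),
              k = 2L, inertia = 0)

  res <- dwellStatistics(repc, subjects, "age")
  expect_equal(res$r[1], 1.0, tolerance = 1e-12)   # counts proportional to age
  # every patient has windows in both clusters: the in/out t-test side is
  # empty, so the statistic is undefined, not an exception
  expect_true(is.na(res$t[1]))

  # constant covariate: t degenerates to 0 with p = 1, r to 0
  res2 <- dwellStatistics(repc, subjects, "cognitive_score")
  expect_equal(res2$r, c(0, 0))
  expect_equal(res2$r_p, c(1, 1))

  # missing covariates exclude the subject and are counted
  recs[[1]] <- subjectRecord("p01", "patient", matrix(rnorm(16), 2, 8),
                             age = NA)
  res3 <- dwellStatistics(repc, timecourseSet(recs), "age")
  expect_equal(attr(res3, "excluded"), 1L)
})

test_that("dwell statistics detect a constructed membership effect", {
  set.seed(41)
  n <- 40L
  age <- rnorm(n, 40, 10)
  member <- age > stats::median(age)   # cluster-2 membership by covariate
  recs <- lapply(seq_len(n), function(i)
    subjectRecord(sprintf("p%02d", i), "patient", matrix(rnorm(16), 2, 8),
                  age = age[i]))
  counts <- cbind(rep(3L, n), ifelse(member, 3L, 0L))
  total <- sum(counts)
  info <- data.frame(
    subject_id = rep(sprintf("p%02d", seq_len(n)), times = rowSums(counts)),
    window_start = seq_len(total) - 1L, split = "train",
    diagnosis = "patient")
  assignment <- unlist(lapply(seq_len(n), function(i)
    rep(c(1L, 2L), times = counts[i, ])))
  repc <- new("ClusterReport", centroids = matrix(0, 2, 2), info = info,
              assignment = assignment,
              counts = matrix(as.integer(counts), n, 2,
                              dimnames = list(sprintf("p%02d", seq_len(n)),
                                              c("c1", "c2"))),
              k = 2L, inertia = 0)
  res <- dwellStatistics(repc, timecourseSet(recs), "age")
  expect_lt(res$t_p[2], 0.001)
  expect_gt(res$t[2], 0)
})

test_that("cluster wFNC maps are grand-mean deviations", {
  ws <- randomWindowSet(m = 12L, n = 4L, w = 20L, seed = 3L)
  info <- data.frame(subject_id = ws@subjectId, window_start = ws@start,
                     split = "train", diagnosis = "patient")

  mkReport <- function(assign, k) {
    counts <- as.matrix(table(info$subject_id, factor(assign, levels = 1:k)))
    new("ClusterReport", centroids = matrix(0, k, 2), info = info,
        assignment = as.integer(assign),
        counts = matrix(as.integer(counts), nrow(counts), k,
                        dimnames = dimnames(counts)),
        k = as.integer(k), inertia = 0)
  }

  # k = 1: the difference map is exactly zero
  maps1 <- clusterWfncMaps(mkReport(rep(1L, 12), 1L), ws)
  expect_identical(maps1[[1]], matrix(0, 4, 4))

  # two equal-size clusters: deviations are mirror images
  maps2 <- clusterWfncMaps(mkReport(rep(c(1L, 2L), each = 6), 2L), ws)
  expect_equal(maps2[[1]], -maps2[[2]], tolerance = 1e-12)
  expect_equal(diag(maps2[[1]]), rep(0, 4))

  # brute-force per-cell recomputation
  assign <- rep(c(1L, 2L, 3L), times = c(3, 4, 5))
  maps3 <- clusterWfncMaps(mkReport(assign, 3L), ws)
  wf <- lapply(1:12, function(i) computeWfnc(ws@data[, , i]))
  grand <- Reduce(`+`, wf) / 12
  for (c in 1:3) {
    brute <- Reduce(`+`, wf[assign == c]) / sum(assign == c) - grand
    expect_equal(maps3[[c]], brute, tolerance = 1e-12)
  }

  # weighted by cluster size, the deviations cancel exactly
  sizes <- table(assign)
  wsum <- Reduce(`+`, lapply(1:3, function(c) sizes[c] * maps3[[c]]))
  expect_equal(max(abs(wsum)), 0, tolerance = 1e-12)

  # an empty cluster yields a flagged zero map
  maps4 <- clusterWfncMaps(mkReport(rep(c(1L, 3L), 6), 3L), ws)
  expect_true(attr(maps4, "empty")[2])
  expect_identical(maps4[[2]], matrix(0, 4, 4))
})
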