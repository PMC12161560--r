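test_that("generation is deterministic and order-reproducible per subject", {
  ds1 <- generateDataset(tinySpec())
  ds2 <- generateDataset(tinySpec())
  expect_identical(lapply(ds1$records@records, slot, "data"),
                   lapply(ds2$records@records, slot, "data"))
  expect_identical(ds1$truth@context, ds2$truth@context)
  expect_identical(ds1$truth@local, ds2$truth@local)
})

test_that("identity mixing with zero noise exposes the stacked latents", {
  spec <- syntheticSpec(nSubjectsPerGroup = 2L, nComponents = 5L,
                        nTimesteps = 30L, contextDim = 2L, localDim = 3L,
                        mixing = "linear", noiseStd = 0, seed = 4L)
  ds <- generateDataset(spec, mixingMatrix = diag(5))
  for (i in seq_len(4L)) {
    expect_identical(ds$records[[i]]@data,
                     rbind(ds$truth@context[[i]], ds$truth@local[[i]]))
  }
})

test_that("latent processes have the designed second-order structure", {
  spec <- syntheticSpec(nSubjectsPerGroup = 1L, nComponents = 4L,
                        nTimesteps = 6000L, contextDim = 1L, localDim = 1L,
                        contextGroupOffset = 0, arCoefficient = 0.5,
                        contextDriftTimescale = 32, seed = 12L)
  ds <- generateDataset(spec)
  loc <- ds$truth@local[[1]][1, ]
  # stationary variance of the unit-innovation AR(1) is 1/(1 - phi^2)
  expect_lt(abs(var(loc) / (1 / (1 - 0.5^2)) - 1), 0.1)
  # slow/fast separation: the context factor is more autocorrelated than
  # the local factor whenever timescale > 1/(1 - phi)
  ctx <- ds$truth@context[[1]][1, ]
  acf1 <- function(x) cor(x[-1], x[-length(x)])
  expect_gt(acf1(ctx), acf1(loc))
  expect_gt(32, 1 / (1 - 0.5))
})

test_that("group separability of true window-averaged context grows with the offset", {
  accAt <- function(offset, seed) {
    spec <- syntheticSpec(nSubjectsPerGroup = 10L, nComponents = 4L,
                          nTimesteps = 64L, contextDim = 2L, localDim = 2L,
                          contextGroupOffset = rep(offset / sqrt(2), 2),
                          seed = seed)
    ds <- generateDataset(spec)
    windows <- makeWindows(ds$records, windowSpec(32L, 8L))
    split <- splitSubjects(ds$records, c(0.5, 0, 0.5), seed = seed)
    diagnoses <- stats::setNames(
      vapply(ds$records@records, function(r) r@diagnosis, character(1)),
      subjectIds(ds$records))
    tb <- embeddingTable(
      data.frame(subject_id = windows@subjectId,
                 window_start = windows@start,
                 split = splitOf(split, windows@subjectId),
                 diagnosis = unname(diagnoses[windows@subjectId]),
                 stringsAsFactors = FALSE),
      windowContextTargets(
        embeddingTable(data.frame(subject_id = windows@subjectId,
                                  window_start = windows@start,
                                  split = "train", diagnosis = "control"),
                       matrix(0, nWindows(windows), 1),
                       width = windows@width), ds$truth))
    as.numeric(classifyContext(tb))
  }
  seeds <- 1:20
  means <- vapply(c(0, 1, 2), function(off)
    mean(vapply(seeds, function(s) accAt(off, s), numeric(1))), numeric(1))
  expect_lte(means[1], means[2])
  expect_lte(means[2], means[3])
  expect_gt(means[3], 0.8)
})

test_that("a zero offset leaves the two groups statistically indistinguishable", {
  pvals <- vapply(1:20, function(s) {
    spec <- syntheticSpec(nSubjectsPerGroup = 8L, nComponents = 4L,
                          nTimesteps = 48L, contextDim = 2L, localDim = 2L,
                          contextGroupOffset = c(0, 0), seed = 100L + s)
    ds <- generateDataset(spec)
    feat <- vapply(ds$records@records, function(r) mean(r@data), numeric(1))
    grp <- ds$truth@group
    stats::t.test(feat[grp == "patient"], feat[grp == "control"])$p.value
  }, numeric(1))
  # expected false-positive rate at alpha = 0.01 over 20 replicates
  expect_lte(sum(pvals < 0.01), 2)
})

test_that("context recovery scores its identities and nulls correctly", {
  cohort <- tinyCohort(nPerGroup = 8L, Tn = 160L)
  targets <- windowContextTargets(
    tableFor(cohort, matrix(0, nWindows(cohort$windows), 1)), cohort$truth)
  expect_gte(nrow(targets), 500)

  # the true factors themselves score 1
  tb <- tableFor(cohort, targets)
  expect_equal(contextRecoveryScore(tb, cohort$truth), 1.0)

  # any invertible affine transform of them also scores 1
  A <- matrix(c(2, -1, 0.5, 3), 2, 2)
  tbA <- tableFor(cohort, sweep(targets %*% A, 2, c(5, -7), `+`))
  expect_equal(contextRecoveryScore(tbA, cohort$truth), 1.0)

  # independent Gaussian noise scores near zero
  set.seed(9)
  tbN <- tableFor(cohort, matrix(rnorm(2 * nrow(targets)), ncol = 2))
  expect_lte(contextRecoveryScore(tbN, cohort$truth), 0.05)
})

test_that("spec validation rejects non-stationary and inconsistent settings", {
  expect_error(syntheticSpec(arCoefficient = 1), "stationarity")
  expect_error(syntheticSpec(contextGroupOffset = c(1, 2, 3)), "length")
  expect_error(syntheticSpec(noiseStd = -1), ">= 0")
})
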