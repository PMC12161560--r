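test_that("diagonal-Gaussian KL matches its closed form and Monte-Carlo", {
  q <- diagonalGaussian(c(0, 0), c(0, 0))
  expect_identical(klDiagGaussian(q, q), 0)

  # 1-d N(1,1) vs N(0,1): KL = mu^2 / 2 = 0.5
  expect_equal(klDiagGaussian(diagonalGaussian(1, 0), diagonalGaussian(0, 0)),
               0.5)

  # shrinking q's variance against a unit prior diverges monotonically
  sigmas <- c(0.5, 0.2, 0.1, 0.05)
  kls <- vapply(sigmas, function(s)
    klDiagGaussian(diagonalGaussian(0, log(s^2)), diagonalGaussian(0, 0)),
    numeric(1))
  expect_true(all(diff(kls) > 0))
  expect_equal(kls, -log(sigmas) + (sigmas^2 - 1) / 2)

  expect_error(klDiagGaussian(diagonalGaussian(0, 0),
                              diagonalGaussian(c(0, 0), c(0, 0))),
               "dimension")

  # Monte-Carlo cross-check on a few random pairs
  set.seed(21)
  for (i in 1:5) {
    muq <- rnorm(1, sd = 0.7); lvq <- rnorm(1, sd = 0.4)
    mup <- rnorm(1, sd = 0.7); lvp <- rnorm(1, sd = 0.4)
    x <- rnorm(1e6, muq, exp(0.5 * lvq))
    mc <- mean(dnorm(x, muq, exp(0.5 * lvq), log = TRUE) -
               dnorm(x, mup, exp(0.5 * lvp), log = TRUE))
    expect_lt(abs(mc - klDiagGaussian(diagonalGaussian(muq, lvq),
                                      diagonalGaussian(mup, lvp))), 0.01)
  }
})

test_that("context encoding is deterministic, clamped, and arch-agnostic in shape", {
  set.seed(3)
  w <- matrix(rnorm(6 * 16), 6, 16)
  for (arch in c("rnn", "conv")) {
    m <- initializeModel(modelConfig("idsvae", contextSize = 3L,
                                     contextEncoderArch = arch,
                                     hiddenSize = 8L, seed = 5L), 6L, 16L)
    g1 <- encodeContext(w, m)
    g2 <- encodeContext(w, m)
    expect_identical(g1@mean, g2@mean)
    expect_equal(length(g1@mean), 3L)
    # all-zero window through an untrained network: finite clamped logvars
    g0 <- encodeContext(matrix(0, 6, 16), m)
    expect_true(all(is.finite(g0@logVariance)))
    expect_true(all(abs(g0@logVariance) <= 10))
  }
  m <- initializeModel(modelConfig("idsvae", hiddenSize = 8L, seed = 5L),
                       6L, 16L)
  expect_error(encodeContext(matrix(0, 6, 20), m), "width")
  ml <- initializeModel(modelConfig("lvae", hiddenSize = 8L, seed = 5L),
                        6L, 16L)
  expect_error(encodeContext(w, ml), "lvaeContext")
})

test_that("the local encoder honors the dependent/independent factorization", {
  set.seed(4)
  w <- matrix(rnorm(6 * 12), 6, 12)
  md <- initializeModel(modelConfig("dsvae", localSize = 3L, contextSize = 2L,
                                    hiddenSize = 8L, seed = 1L), 6L, 12L)
  mi <- initializeModel(modelConfig("idsvae", localSize = 3L, contextSize = 2L,
                                    hiddenSize = 8L, seed = 1L), 6L, 12L)

  expect_error(encodeLocal(w, md), "requires a context sample")
  p1 <- encodeLocal(w, md, contextSample = c(1, -1))
  p2 <- encodeLocal(w, md, contextSample = c(-2, 3))
  expect_equal(length(p1), 12L)
  # context-dependence is live for the dsvae
  expect_false(isTRUE(all.equal(p1[[1]]@mean, p2[[1]]@mean)))

  # the independent variant rejects a context sample outright
  expect_error(encodeLocal(w, mi, contextSample = c(1, -1)),
               "independent of the context")
  q <- encodeLocal(w, mi)
  expect_equal(length(q), 12L)
  expect_equal(length(q[[1]]@mean), 3L)

  # default-width check: a 32-step window yields 32 local posteriors
  m32 <- initializeModel(modelConfig("idsvae", hiddenSize = 8L, seed = 1L),
                         6L, 32L)
  expect_equal(length(encodeLocal(matrix(0, 6, 32), m32)), 32L)
})

test_that("the autoregressive prior is driven by conditioning and sampled path", {
  md <- initializeModel(modelConfig("dsvae", localSize = 2L, contextSize = 2L,
                                    hiddenSize = 6L, seed = 2L), 4L, 8L)
  mi <- initializeModel(modelConfig("idsvae", localSize = 2L, contextSize = 2L,
                                    hiddenSize = 6L, seed = 2L), 4L, 8L)
  zl <- matrix(rnorm(2 * 8), 2, 8)

  # degenerate weights: all prior parameters zeroed -> one shared prior
  mz <- md
  for (nm in grep("^pr_", names(mz@params), value = TRUE))
    mz@params[[nm]] <- mz@params[[nm]] * 0
  pr <- localPrior(mz, zl, contextSample = c(1, 2))
  for (t in 2:8) {
    expect_equal(pr[[t]]@mean, pr[[1]]@mean)
    expect_equal(pr[[t]]@logVariance, pr[[1]]@logVariance)
  }

  # dsvae: the context sample moves the step-1 prior
  a <- localPrior(md, zl, contextSample = c(1, 0))
  b <- localPrior(md, zl, contextSample = c(0, 1))
  expect_false(isTRUE(all.equal(a[[1]]@mean, b[[1]]@mean)))

  # idsvae: step-1 prior is shared across all windows (pure conditioning)
  c1 <- localPrior(mi, zl)
  c2 <- localPrior(mi, matrix(rnorm(2 * 8), 2, 8))
  expect_equal(c1[[1]]@mean, c2[[1]]@mean)
  # but later steps depend on the sampled path
  expect_false(isTRUE(all.equal(c1[[3]]@mean, c2[[3]]@mean)))

  expect_error(localPrior(mi, zl, contextSample = c(1, 2)), "learnable vector")
  expect_error(localPrior(md, matrix(0, 3, 8), c(1, 2)), "localSize")
})

test_that("decoding is deterministic with the expected output dimensions", {
  m <- initializeModel(modelConfig("dsvae", localSize = 3L, contextSize = 2L,
                                   hiddenSize = 8L, seed = 3L), 53L, 8L)
  x1 <- decodeLatent(m, c(0.3, -1), c(1, 2, 3))
  x2 <- decodeLatent(m, c(0.3, -1), c(1, 2, 3))
  expect_identical(x1, x2)
  expect_equal(length(x1), 53L)

  mc <- initializeModel(modelConfig("cvae", contextSize = 2L, hiddenSize = 8L,
                                    seed = 3L), 5L, 12L)
  xw <- decodeLatent(mc, c(1, -1))
  expect_equal(dim(xw), c(5L, 12L))
})

test_that("the LVAE context surrogate is the arithmetic mean of local means", {
  g <- function(v) diagonalGaussian(v, rep(0, length(v)))
  expect_equal(lvaeContext(list(g(c(1, 2)), g(c(1, 2)))), c(1, 2))
  expect_equal(lvaeContext(list(g(c(3, -4)), g(c(-3, 4)))), c(0, 0))
  set.seed(8)
  means <- matrix(rnorm(2 * 32), 2, 32)
  posts <- lapply(seq_len(32), function(t) g(means[, t]))
  brute <- c(sum(means[1, ]) / 32, sum(means[2, ]) / 32)
  expect_equal(lvaeContext(posts), brute)
  expect_error(lvaeContext(list()), "empty")
})

test_that("the loss decomposes as reconstruction + beta*localKL + gamma*contextKL", {
  set.seed(11)
  w <- matrix(rnorm(5 * 10), 5, 10)
  base <- modelConfig("dsvae", localSize = 2L, contextSize = 2L,
                      hiddenSize = 6L, seed = 9L)
  m <- initializeModel(base, 5L, 10L)
  eps <- list(context = matrix(rnorm(2), 2, 1),
              local = array(rnorm(2 * 10), c(2, 1, 10)))

  # weights-off identity
  m0 <- m; m0@config@beta <- 0; m0@config@gamma <- 0
  l0 <- elboLoss(w, m0, eps = eps)
  expect_equal(l0$total, l0$reconstruction)

  # linear response to gamma at frozen samples
  m2 <- m; m2@config@beta <- 0; m2@config@gamma <- 2
  l2 <- elboLoss(w, m2, eps = eps)
  expect_equal(l2$total - l0$total, 2 * l2$context_kl)
  expect_equal(l2$context_kl, l0$context_kl)

  # a context posterior forced to N(0, 1) has zero context KL
  mN <- m
  mN@params$ce_mu_W <- mN@params$ce_mu_W * 0
  mN@params$ce_mu_b <- mN@params$ce_mu_b * 0
  mN@params$ce_lv_W <- mN@params$ce_lv_W * 0
  mN@params$ce_lv_b <- mN@params$ce_lv_b * 0
  expect_equal(elboLoss(w, mN, eps = eps)$context_kl, 0)

  # KL terms are non-negative for random models
  expect_gte(l0$local_kl, 0)
  expect_gte(l0$context_kl, 0)
})

test_that("the compiled loss equals an independent R composition for all variants", {
  set.seed(13)
  B <- 3L
  x <- array(rnorm(5 * 8 * B), c(5, 8, B))
  for (variant in c("dsvae", "idsvae", "lvae")) {
    for (arch in if (variant == "dsvae") c("rnn", "conv") else "rnn") {
      cfg <- modelConfig(variant, localSize = 2L, contextSize = 2L,
                         beta = 0.7, gamma = 1.3, contextEncoderArch = arch,
                         hiddenSize = 6L, convKernel = 3L, seed = 17L)
      m <- initializeModel(cfg, 5L, 8L)
      eps <- list(context = matrix(rnorm(2 * B), 2, B),
                  local = array(rnorm(2 * B * 8), c(2, B, 8)))
      got <- elboLoss(x, m, eps = eps)
      ref <- refSeqLossBatch(m, x, eps)
      for (k in c("reconstruction", "local_kl", "context_kl", "total"))
        expect_equal(got[[k]], ref[[k]], tolerance = 1e-10)
    }
  }
  # context-only convolutional model
  cfg <- modelConfig("cvae", contextSize = 2L, gamma = 1.3, hiddenSize = 6L,
                     convKernel = 3L, seed = 17L)
  m <- initializeModel(cfg, 5L, 8L)
  eps <- list(context = matrix(rnorm(2 * B), 2, B))
  got <- elboLoss(x, m, eps = eps)
  refs <- lapply(seq_len(B), function(b)
    refCvaeLoss1(m@params, x[, , b], eps$context[, b], 1.3, 3L, 6L))
  expect_equal(got$reconstruction,
               mean(vapply(refs, `[[`, numeric(1), "reconstruction")),
               tolerance = 1e-10)
  expect_equal(got$total, mean(vapply(refs, `[[`, numeric(1), "total")),
               tolerance = 1e-10)
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(19)
  B <- 2L
  x <- array(rnorm(4 * 6 * B), c(4, 6, B))
  epsC <- matrix(rnorm(2 * B), 2, B)
  epsL <- array(rnorm(2 * B * 6), c(2, B, 6))
  for (variant in c("dsvae", "idsvae", "lvae", "cvae")) {
    cfg <- modelConfig(variant, localSize = 2L, contextSize = 2L, beta = 0.6,
                       gamma = 1.1, hiddenSize = 4L, convKernel = 3L,
                       seed = 23L)
    m <- initializeModel(cfg, 4L, 6L)
    f <- function(p) {
      mm <- m; mm@params <- p
      elboLoss(x, mm, eps = list(context = epsC, local = epsL))$total
    }
    res <- if (variant == "cvae")
      dsvae:::cpp_cvae_step(m@params, x, epsC, cfg@gamma, cfg@convKernel, TRUE)
    else
      dsvae:::cpp_seq_step(m@params, x, epsC, epsL, variant,
                           cfg@contextEncoderArch, cfg@beta, cfg@gamma,
                           cfg@convKernel, TRUE)
    for (nm in names(m@params)) {
      idx <- seq_along(m@params[[nm]])
      if (length(idx) > 4) idx <- sample(idx, 4)
      for (i in idx) {
        h <- 1e-5
        pp <- m@params; pp[[nm]][i] <- pp[[nm]][i] + h; fp <- f(pp)
        pp[[nm]][i] <- pp[[nm]][i] - 2 * h; fm <- f(pp)
        num <- (fp - fm) / (2 * h)
        ana <- as.numeric(res$grads[[nm]])[i]
        expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-4)
      }
    }
  }
})

test_that("DSVAE and IDSVAE differ only in local-encoder input and prior conditioning", {
  cd <- modelConfig("dsvae", localSize = 3L, contextSize = 2L,
                    hiddenSize = 8L, seed = 31L)
  ci <- modelConfig("idsvae", localSize = 3L, contextSize = 2L,
                    hiddenSize = 8L, seed = 31L)
  md <- initializeModel(cd, 6L, 12L)
  mi <- initializeModel(ci, 6L, 12L)

  # identical context encoders under identical seeds (drawn first)
  for (nm in grep("^ce_", names(md@params), value = TRUE))
    expect_identical(md@params[[nm]], mi@params[[nm]])

  # decoder and readout shapes coincide; only the local-encoder input width
  # (broadcast-concatenated context) and the prior conditioning differ
  expect_equal(ncol(md@params$le_f_Wx) - ncol(mi@params$le_f_Wx), 2L)
  expect_identical(dim(md@params$de_W1), dim(mi@params$de_W1))
  expect_true(all(c("pr_h0_W", "pr_h0_b") %in% names(md@params)))
  expect_true("pr_h0_v" %in% names(mi@params))
  expect_false("pr_h0_v" %in% names(md@params))

  count <- function(p) sum(vapply(p, length, integer(1)))
  H <- 8L
  # extra parameters: 2 columns in each local-encoder direction's input map
  # (2 * 3H*CS) plus the conditioning map (H*CS + H) replacing the vector (H)
  expect_equal(count(md@params) - count(mi@params),
               2L * 3L * H * 2L + (H * 2L + H) - H)
})

test_that("a checkpoint reloads to bit-identical embeddings", {
  cohort <- tinyCohort(nPerGroup = 5L, Tn = 44L)
  cfg <- modelConfig("dsvae", hiddenSize = 8L, maxEpochs = 2L, seed = 7L)
  fit <- trainModel(subsetWindows(cohort$windows,
                                  subjectIds(cohort$records)[1:4]),
                    subsetWindows(cohort$windows,
                                  subjectIds(cohort$records)[5:6]),
                    cfg, batchSize = 16L)
  tb1 <- embedDataset(fit, cohort$windows, cohort$split, cohort$diagnoses)
  f <- withr::local_tempfile(fileext = ".json")
  saveModel(fit, f)
  fit2 <- loadModel(f)
  expect_identical(fit@params, fit2@params)
  tb2 <- embedDataset(fit2, cohort$windows, cohort$split, cohort$diagnoses)
  expect_identical(tb1@embedding, tb2@embedding)
})
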