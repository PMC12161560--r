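#' @include AllGenerics.R
#' @useDynLib dsvae, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

.clampLv <- function(x) pmin(pmax(x, -10), 10)

.unif <- function(nr, nc, a) matrix(stats::runif(nr * nc, -a, a), nr, nc)

# Seeded parameter initialization.  Uniform(-1/sqrt(fan), 1/sqrt(fan)) per
# tensor; the draw order is fixed so a config seed fully determines the
# initialization.
.initParams <- function(config, N, W) {
  v <- config@variant
  H <- config@hiddenSize; CS <- config@contextSize; LS <- config@localSize
  K <- config@convKernel
  set.seed(config@seed)
  p <- list()
  a <- 1 / sqrt(H)

  convEnc <- function(p) {
    ac <- 1 / sqrt(N * K)
    p$ce_c1_W <- .unif(H, N * K, ac); p$ce_c1_b <- stats::runif(H, -ac, ac)
    ac2 <- 1 / sqrt(H * K)
    p$ce_c2_W <- .unif(H, H * K, ac2); p$ce_c2_b <- stats::runif(H, -ac2, ac2)
    aH <- 1 / sqrt(H)
    p$ce_mu_W <- .unif(CS, H, aH); p$ce_mu_b <- stats::runif(CS, -aH, aH)
    p$ce_lv_W <- .unif(CS, H, aH); p$ce_lv_b <- stats::runif(CS, -aH, aH)
    p
  }

  if (v == "cvae") {
    p <- convEnc(p)
    aC <- 1 / sqrt(CS)
    p$de_W0 <- .unif(H * W, CS, aC); p$de_b0 <- stats::runif(H * W, -aC, aC)
    acd <- 1 / sqrt(H * K)
    p$de_cv_W <- .unif(N, H * K, acd); p$de_cv_b <- stats::runif(N, -acd, acd)
    return(p)
  }

  if (v != "lvae") {
    if (config@contextEncoderArch == "rnn") {
      for (pre in c("ce_f", "ce_b")) {
        p[[paste0(pre, "_Wx")]] <- .unif(3 * H, N, a)
        p[[paste0(pre, "_Wh")]] <- .unif(3 * H, H, a)
        p[[paste0(pre, "_bx")]] <- stats::runif(3 * H, -a, a)
        p[[paste0(pre, "_bh")]] <- stats::runif(3 * H, -a, a)
      }
      fin <- 2 * H
      af <- 1 / sqrt(fin)
      p$ce_mu_W <- .unif(CS, fin, af); p$ce_mu_b <- stats::runif(CS, -af, af)
      p$ce_lv_W <- .unif(CS, fin, af); p$ce_lv_b <- stats::runif(CS, -af, af)
    } else {
      p <- convEnc(p)
    }
  }
  D <- N + if (v == "dsvae") CS else 0L
  for (pre in c("le_f", "le_b")) {
    p[[paste0(pre, "_Wx")]] <- .unif(3 * H, D, a)
    p[[paste0(pre, "_Wh")]] <- .unif(3 * H, H, a)
    p[[paste0(pre, "_bx")]] <- stats::runif(3 * H, -a, a)
    p[[paste0(pre, "_bh")]] <- stats::runif(3 * H, -a, a)
  }
  a2 <- 1 / sqrt(2 * H)
  p$le_mu_W <- .unif(LS, 2 * H, a2); p$le_mu_b <- stats::runif(LS, -a2, a2)
  p$le_lv_W <- .unif(LS, 2 * H, a2); p$le_lv_b <- stats::runif(LS, -a2, a2)
  p$pr_Wx <- .unif(3 * H, LS, a); p$pr_Wh <- .unif(3 * H, H, a)
  p$pr_bx <- stats::runif(3 * H, -a, a); p$pr_bh <- stats::runif(3 * H, -a, a)
  aH <- 1 / sqrt(H)
  p$pr_mu_W <- .unif(LS, H, aH); p$pr_mu_b <- stats::runif(LS, -aH, aH)
  p$pr_lv_W <- .unif(LS, H, aH); p$pr_lv_b <- stats::runif(LS, -aH, aH)
  if (v == "dsvae") {
    aC <- 1 / sqrt(CS)
    p$pr_h0_W <- .unif(H, CS, aC); p$pr_h0_b <- stats::runif(H, -aC, aC)
  } else {
    p$pr_h0_v <- stats::runif(H, -a, a)
  }
  din <- LS + if (v != "lvae") CS else 0L
  ad <- 1 / sqrt(din)
  p$de_W1 <- .unif(H, din, ad); p$de_b1 <- stats::runif(H, -ad, ad)
  p$de_W2 <- .unif(N, H, aH); p$de_b2 <- stats::runif(N, -aH, aH)
  p
}

#' Initialize a model with seeded random weights
#'
#' @param config a \linkS4class{ModelConfig}
#' @param nComponents number of observed components N
#' @param width window width W in timesteps
#' @return an untrained \linkS4class{TrainedModel}
#' @export
initializeModel <- function(config, nComponents, width = 32L) {
  stopifnot(is(config, "ModelConfig"))
  validObject(config)
  new("TrainedModel", config = config,
      params = .initParams(config, as.integer(nComponents),
                           as.integer(width)),
      history = data.frame(), inputDim = as.integer(nComponents),
      width = as.integer(width))
}

.asCube <- function(window, model) {
  if (is(window, "WindowSet")) {
    if (window@width != model@width)
      stop(sprintf("window width %d does not match model width %d",
                   window@width, model@width))
    return(window@data)
  }
  if (is.array(window) && length(dim(window)) == 3L) {
    if (dim(window)[1L] != model@inputDim)
      stop(sprintf("windows have %d components, model expects %d",
                   dim(window)[1L], model@inputDim))
    if (dim(window)[2L] != model@width)
      stop(sprintf("window width %d does not match model width %d",
                   dim(window)[2L], model@width))
    return(window)
  }
  w <- as.matrix(window)
  if (nrow(w) != model@inputDim)
    stop(sprintf("window has %d components, model expects %d",
                 nrow(w), model@inputDim))
  if (ncol(w) != model@width)
    stop(sprintf("window width %d does not match model width %d",
                 ncol(w), model@width))
  array(w, c(nrow(w), ncol(w), 1L))
}

#' Context posterior of a window
#'
#' Runs the (deterministic) context encoder of a trained model on one
#' window and returns the diagonal-Gaussian posterior over the context
#' embedding z_c.  The LVAE has no context encoder; use
#' \code{\link{lvaeContext}} on its local posteriors instead.
#'
#' @param window numeric N x W matrix (or a single-window
#'   \linkS4class{WindowSet})
#' @param model a \linkS4class{TrainedModel}
#' @return a \linkS4class{DiagonalGaussian} of dimension contextSize
#' @export
encodeContext <- function(window, model) {
  cfg <- model@config
  if (cfg@variant == "lvae")
    stop("the LVAE has no context encoder; average its local embeddings with lvaeContext()")
  x <- .asCube(window, model)
  enc <- if (cfg@variant == "cvae")
    cpp_cvae_encode(model@params, x, cfg@convKernel)
  else
    cpp_seq_encode(model@params, x, cfg@variant, cfg@contextEncoderArch,
                   cfg@convKernel, FALSE)
  diagonalGaussian(enc$ctx_mu[, 1L], enc$ctx_lv[, 1L])
}

# Single-step GRU cell on vectors, shared by the R-level sequence ops.
.gruCellR <- function(params, pre, x, h) {
  H <- length(h)
  ax <- as.numeric(params[[paste0(pre, "_Wx")]] %*% x) +
    params[[paste0(pre, "_bx")]]
  ah <- as.numeric(params[[paste0(pre, "_Wh")]] %*% h) +
    params[[paste0(pre, "_bh")]]
  r <- stats::plogis(ax[1:H] + ah[1:H])
  z <- stats::plogis(ax[(H + 1):(2 * H)] + ah[(H + 1):(2 * H)])
  n <- tanh(ax[(2 * H + 1):(3 * H)] + r * ah[(2 * H + 1):(3 * H)])
  (1 - z) * n + z * h
}

#' Per-timestep local posteriors of a window
#'
#' Runs the bidirectional local encoder.  For the DSVAE the context sample
#' is broadcast-concatenated to every timestep's input and is required; the
#' IDSVAE and LVAE local encoders see only the window and supplying a
#' context sample is an error (the factorization distinction between the
#' two model families).
#'
#' @param window numeric N x W matrix
#' @param model a \linkS4class{TrainedModel}
#' @param contextSample numeric vector of length contextSize (DSVAE only)
#' @return list of W \linkS4class{DiagonalGaussian} objects
#' @export
encodeLocal <- function(window, model, contextSample = NULL) {
  cfg <- model@config
  if (cfg@variant == "cvae") stop("the CVAE has no local encoder")
  if (cfg@variant == "dsvae") {
    if (is.null(contextSample))
      stop("the DSVAE local encoder requires a context sample")
    if (length(contextSample) != cfg@contextSize)
      stop("context sample must have length contextSize")
  } else if (!is.null(contextSample)) {
    stop(sprintf("the %s local encoder is independent of the context; do not supply a context sample",
                 cfg@variant))
  }
  x <- .asCube(window, model)[, , 1L]
  W <- ncol(x); H <- cfg@hiddenSize
  ins <- lapply(seq_len(W), function(t)
    if (cfg@variant == "dsvae") c(x[, t], contextSample) else x[, t])
  hf <- vector("list", W); hb <- vector("list", W)
  h <- numeric(H)
  for (t in seq_len(W)) h <- hf[[t]] <- .gruCellR(model@params, "le_f", ins[[t]], h)
  h <- numeric(H)
  for (t in rev(seq_len(W))) h <- hb[[t]] <- .gruCellR(model@params, "le_b", ins[[t]], h)
  lapply(seq_len(W), function(t) {
    u <- c(hf[[t]], hb[[t]])
    diagonalGaussian(
      as.numeric(model@params$le_mu_W %*% u) + model@params$le_mu_b,
      as.numeric(model@params$le_lv_W %*% u) + model@params$le_lv_b)
  })
}

#' Autoregressive local prior along a sampled latent path
#'
#' The local prior is a learnable GRU: at step t it emits a diagonal
#' Gaussian as a function of a recurrent state driven by the sampled
#' z_(<t).  The initial state is conditioned on the context sample for the
#' DSVAE and on a learnable vector for the IDSVAE/LVAE, so the step-1 prior
#' depends only on the conditioning.
#'
#' @param model a \linkS4class{TrainedModel}
#' @param sampledLocals localSize x W matrix of sampled local latents
#' @param contextSample context sample (required iff the variant is dsvae)
#' @return list of W \linkS4class{DiagonalGaussian} objects
#' @export
localPrior <- function(model, sampledLocals, contextSample = NULL) {
  cfg <- model@config
  if (cfg@variant == "cvae") stop("the CVAE has no local prior")
  sampledLocals <- as.matrix(sampledLocals)
  if (nrow(sampledLocals) != cfg@localSize)
    stop("sampledLocals must be localSize x W")
  W <- ncol(sampledLocals)
  p <- model@params
  if (cfg@variant == "dsvae") {
    if (is.null(contextSample))
      stop("the DSVAE local prior requires a context sample")
    h <- tanh(as.numeric(p$pr_h0_W %*% contextSample) + p$pr_h0_b)
  } else {
    if (!is.null(contextSample))
      stop(sprintf("the %s local prior is conditioned on a learnable vector, not a context sample",
                   cfg@variant))
    h <- tanh(p$pr_h0_v)
  }
  out <- vector("list", W)
  for (t in seq_len(W)) {
    xin <- if (t == 1L) numeric(cfg@localSize) else sampledLocals[, t - 1L]
    h <- .gruCellR(p, "pr", xin, h)
    out[[t]] <- diagonalGaussian(
      as.numeric(p$pr_mu_W %*% h) + p$pr_mu_b,
      as.numeric(p$pr_lv_W %*% h) + p$pr_lv_b)
  }
  out
}

#' Decode latents to the observation space
#'
#' For the sequential variants, maps one (context, local) pair through the
#' MLP decoder to the reconstruction mean of a single timestep; the same
#' context sample is reused for every timestep of a window.  For the CVAE
#' the decoder consumes the context sample alone and emits the full
#' N x W window.
#'
#' @param model a \linkS4class{TrainedModel}
#' @param contextSample context sample (NULL for the LVAE)
#' @param localSample local sample of length localSize (ignored by the CVAE)
#' @return numeric vector of length N, or an N x W matrix for the CVAE
#' @export
decodeLatent <- function(model, contextSample = NULL, localSample = NULL) {
  cfg <- model@config
  p <- model@params
  if (cfg@variant == "cvae") {
    if (length(contextSample) != cfg@contextSize)
      stop("context sample must have length contextSize")
    H <- cfg@hiddenSize; W <- model@width
    f <- as.numeric(p$de_W0 %*% contextSample) + p$de_b0
    Mp <- matrix(pmax(f, 0), H, W)
    Xp <- matrix(0, H, W + cfg@convKernel - 1L)
    pad <- (cfg@convKernel - 1L) / 2L
    Xp[, (pad + 1L):(pad + W)] <- Mp
    out <- matrix(0, model@inputDim, W)
    for (k in seq_len(cfg@convKernel)) {
      Wk <- p$de_cv_W[, ((k - 1L) * H + 1L):(k * H), drop = FALSE]
      out <- out + Wk %*% Xp[, k:(k + W - 1L), drop = FALSE]
    }
    return(out + p$de_cv_b)
  }
  if (cfg@variant == "lvae") {
    if (!is.null(contextSample))
      stop("the LVAE decoder consumes local samples only")
    zin <- localSample
  } else {
    if (length(contextSample) != cfg@contextSize)
      stop("context sample must have length contextSize")
    zin <- c(contextSample, localSample)
  }
  if (length(localSample) != cfg@localSize && cfg@variant != "cvae")
    stop("local sample must have length localSize")
  h <- pmax(as.numeric(p$de_W1 %*% zin) + p$de_b1, 0)
  as.numeric(p$de_W2 %*% h) + p$de_b2
}

#' KL divergence between diagonal Gaussians
#'
#' Closed form, summed over dimensions:
#' \deqn{KL(q\|p) = \frac12 \sum_d \left( \ell_p - \ell_q +
#'   \frac{e^{\ell_q} + (\mu_q-\mu_p)^2}{e^{\ell_p}} - 1 \right)}
#' with \eqn{\ell} the log-variances.  Always non-negative; zero iff q = p.
#'
#' @param q,p \linkS4class{DiagonalGaussian} objects of equal dimension
#' @return a single non-negative number
#' @export
klDiagGaussian <- function(q, p) {
  stopifnot(is(q, "DiagonalGaussian"), is(p, "DiagonalGaussian"))
  if (length(q@mean) != length(p@mean))
    stop("q and p must have the same dimension")
  lq <- q@logVariance; lp <- p@logVariance
  sum(0.5 * (lp - lq + (exp(lq) + (q@mean - p@mean)^2) / exp(lp) - 1))
}

#' Time-averaged local embedding (the LVAE's context surrogate)
#'
#' The LVAE carries no context channel; its window-level embedding is the
#' arithmetic mean of the per-timestep local posterior means.
#'
#' @param localPosteriors list of \linkS4class{DiagonalGaussian} objects
#' @return numeric vector of length localSize
#' @export
lvaeContext <- function(localPosteriors) {
  if (length(localPosteriors) == 0L) stop("empty local posterior sequence")
  means <- vapply(localPosteriors, function(g) g@mean,
                  numeric(length(localPosteriors[[1L]]@mean)))
  if (is.null(dim(means))) means <- matrix(means, 1L)
  rowMeans(means)
}

#' Negative-ELBO loss breakdown of one window (or a batch)
#'
#' Computes the minimized objective: per-timestep Gaussian reconstruction
#' negative log-likelihood with unit variance (averaged over the W
#' timesteps), plus \code{beta} times the per-timestep KL between the local
#' posterior and the autoregressive GRU prior evaluated along one sampled
#' latent path (averaged over W), plus \code{gamma} times the KL between
#' the context posterior and the standard-normal context prior (not
#' averaged over W).  One reparameterized sample per window per evaluation.
#'
#' @param window N x W matrix or a \linkS4class{WindowSet}
#' @param model a \linkS4class{TrainedModel}
#' @param eps optional list with elements \code{context} (CS x B) and
#'   \code{local} (LS x B x W array) of standard-normal draws; if NULL they
#'   are drawn using \code{seed}
#' @param seed seed for the reparameterization noise when \code{eps} is NULL
#' @return list with reconstruction, local_kl, context_kl, total,
#'   window_count
#' @export
elboLoss <- function(window, model, eps = NULL, seed = 1L) {
  cfg <- model@config
  x <- .asCube(window, model)
  B <- dim(x)[3L]; W <- dim(x)[2L]
  CS <- cfg@contextSize; LS <- cfg@localSize
  if (is.null(eps)) {
    set.seed(as.integer(seed))
    eps <- list(context = matrix(stats::rnorm(CS * B), CS, B),
                local = array(stats::rnorm(LS * B * W), c(LS, B, W)))
  }
  res <- if (cfg@variant == "cvae")
    cpp_cvae_step(model@params, x, eps$context, cfg@gamma, cfg@convKernel,
                  FALSE)
  else
    cpp_seq_step(model@params, x, eps$context, eps$local, cfg@variant,
                 cfg@contextEncoderArch, cfg@beta, cfg@gamma, cfg@convKernel,
                 FALSE)
  res[c("reconstruction", "local_kl", "context_kl", "total", "window_count")]
}

#' Save / load a model as a JSON checkpoint
#'
#' The checkpoint stores the full configuration, the input dimension and
#' window width, and every weight tensor at full precision (17 significant
#' digits), so embeddings recomputed after a load are bit-for-bit identical
#' to the pre-save embeddings.
#'
#' @param model a \linkS4class{TrainedModel}
#' @param path file path (.json)
#' @return \code{saveModel} invisibly returns \code{path}
#' @export
saveModel <- function(model, path) {
  cfg <- model@config
  obj <- list(
    config = list(variant = cfg@variant, localSize = cfg@localSize,
                  contextSize = cfg@contextSize, beta = cfg@beta,
                  gamma = cfg@gamma,
                  contextEncoderArch = cfg@contextEncoderArch,
                  hiddenSize = cfg@hiddenSize, convKernel = cfg@convKernel,
                  learningRate = cfg@learningRate, maxEpochs = cfg@maxEpochs,
                  inputNoiseStd = cfg@inputNoiseStd, seed = cfg@seed),
    inputDim = model@inputDim, width = model@width,
    history = as.list(model@history),
    params = lapply(model@params, function(w)
      list(dim = if (is.matrix(w)) dim(w) else length(w),
           # 17 significant digits round-trip doubles exactly; stored as
           # strings because JSON writers truncate numeric precision
           values = sprintf("%.17g", as.numeric(w)))))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @param path checkpoint to read
#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(modelConfig, obj$config)
  params <- lapply(obj$params, function(w) {
    v <- as.numeric(w$values)
    if (length(w$dim) == 2L) matrix(v, w$dim[1L], w$dim[2L]) else v
  })
  hist <- if (length(obj$history) > 0)
    as.data.frame(obj$history, stringsAsFactors = FALSE) else data.frame()
  new("TrainedModel", config = cfg, params = params, history = hist,
      inputDim = as.integer(obj$inputDim), width = as.integer(obj$width))
}
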