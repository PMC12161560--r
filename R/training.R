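#' @include models.R
NULL

# Adam optimizer state over a named parameter list.
.adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

.drawEps <- function(cfg, B, W) {
  list(context = matrix(stats::rnorm(cfg@contextSize * B), cfg@contextSize, B),
       local = array(stats::rnorm(cfg@localSize * B * W),
                     c(cfg@localSize, B, W)))
}

.stepLoss <- function(params, cfg, x, eps, wantGrads) {
  if (cfg@variant == "cvae")
    cpp_cvae_step(params, x, eps$context, cfg@gamma, cfg@convKernel,
                  wantGrads)
  else
    cpp_seq_step(params, x, eps$context, eps$local, cfg@variant,
                 cfg@contextEncoderArch, cfg@beta, cfg@gamma, cfg@convKernel,
                 wantGrads)
}

.checkFinite <- function(loss, epoch) {
  for (term in c("reconstruction", "local_kl", "context_kl", "total"))
    if (!is.finite(loss[[term]]))
      stop(sprintf("non-finite loss term '%s' at epoch %d; aborting training",
                   term, epoch))
}

# Average loss over a window set without updating weights.
.evalLoss <- function(params, cfg, windows, chunk = 256L) {
  M <- nWindows(windows)
  acc <- c(reconstruction = 0, local_kl = 0, context_kl = 0, total = 0)
  at <- 1L
  while (at <= M) {
    idx <- at:min(at + chunk - 1L, M)
    x <- windows@data[, , idx, drop = FALSE]
    eps <- .drawEps(cfg, length(idx), windows@width)
    l <- .stepLoss(params, cfg, x, eps, FALSE)
    for (term in names(acc)) acc[term] <- acc[term] + l[[term]] * length(idx)
    at <- at + chunk
  }
  acc / M
}

#' Train a model with seeded Adam and early stopping
#'
#' All randomness (initialization, batch order, reparameterization noise,
#' optional input corruption) flows from the config seed, so two runs with
#' identical inputs and config produce identical weights and history.
#' Training stops after \code{patience} epochs without improvement of the
#' validation total, and the returned model carries the weights of the best
#' validation epoch seen.  With \code{maxEpochs = 0} the seeded
#' initialization is returned unchanged.
#'
#' @param trainWindows training \linkS4class{WindowSet}
#' @param valWindows validation \linkS4class{WindowSet}
#' @param config a \linkS4class{ModelConfig}
#' @param batchSize windows per optimizer step
#' @param patience epochs without validation improvement before stopping
#' @param verbose print per-epoch losses
#' @return a \linkS4class{TrainedModel}
#' @export
trainModel <- function(trainWindows, valWindows, config, batchSize = 64L,
                       patience = 10L, verbose = FALSE) {
  stopifnot(is(trainWindows, "WindowSet"), is(valWindows, "WindowSet"),
            is(config, "ModelConfig"))
  if (nWindows(trainWindows) == 0L) stop("empty training set")
  if (trainWindows@width != valWindows@width)
    stop("train and validation windows must share the width")
  N <- nComponents(trainWindows)
  W <- trainWindows@width
  M <- nWindows(trainWindows)

  model <- initializeModel(config, N, W)  # seeds the RNG stream
  params <- model@params
  state <- .adamInit(params)
  hist <- vector("list", config@maxEpochs)
  bestVal <- Inf; bestParams <- params; sinceBest <- 0L; nEpochs <- 0L

  for (epoch in seq_len(config@maxEpochs)) {
    ord <- sample.int(M)
    trAcc <- c(reconstruction = 0, local_kl = 0, context_kl = 0, total = 0)
    at <- 1L
    while (at <= M) {
      idx <- ord[at:min(at + batchSize - 1L, M)]
      x <- trainWindows@data[, , idx, drop = FALSE]
      if (config@inputNoiseStd > 0)
        x <- x + config@inputNoiseStd * array(stats::rnorm(length(x)), dim(x))
      eps <- .drawEps(config, length(idx), W)
      res <- .stepLoss(params, config, x, eps, TRUE)
      .checkFinite(res, epoch)
      for (term in names(trAcc))
        trAcc[term] <- trAcc[term] + res[[term]] * length(idx)
      upd <- .adamStep(params, res$grads, state, config@learningRate)
      params <- upd$params; state <- upd$state
      at <- at + batchSize
    }
    trAcc <- trAcc / M
    valAcc <- .evalLoss(params, config, valWindows)
    nEpochs <- epoch
    hist[[epoch]] <- data.frame(
      epoch = epoch,
      train_recon = trAcc["reconstruction"], train_local_kl = trAcc["local_kl"],
      train_context_kl = trAcc["context_kl"], train_total = trAcc["total"],
      val_recon = valAcc["reconstruction"], val_local_kl = valAcc["local_kl"],
      val_context_kl = valAcc["context_kl"], val_total = valAcc["total"],
      row.names = NULL)
    if (verbose)
      message(sprintf("epoch %d: train %.4f, val %.4f", epoch,
                      trAcc["total"], valAcc["total"]))
    if (valAcc["total"] < bestVal) {
      bestVal <- valAcc["total"]; bestParams <- params; sinceBest <- 0L
    } else {
      sinceBest <- sinceBest + 1L
      if (sinceBest >= patience) break
    }
  }
  model@params <- if (config@maxEpochs > 0L) bestParams else params
  model@history <- if (nEpochs > 0L)
    do.call(rbind, hist[seq_len(nEpochs)]) else data.frame()
  model
}

#' Multi-config, multi-seed grid search with validation-based selection
#'
#' Trains every (config, seed) pair; the config whose validation total,
#' averaged across seeds, is lowest is selected (ties broken by the lowest
#' config index).  A config is excluded from selection if any of its runs
#' aborts (logged as a warning).  The default seed list is
#' 42, 1337, 1212, 9999.
#'
#' @param trainWindows,valWindows \linkS4class{WindowSet} objects
#' @param configs list of \linkS4class{ModelConfig} objects
#' @param seeds integer seeds applied to each config
#' @param ... passed to \code{\link{trainModel}}
#' @return a \linkS4class{GridResult}
#' @export
gridSearch <- function(trainWindows, valWindows, configs,
                       seeds = c(42L, 1337L, 1212L, 9999L), ...) {
  stopifnot(length(configs) > 0L, length(seeds) > 0L)
  runs <- list(); models <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    models[[i]] <- vector("list", length(seeds))
    for (j in seq_along(seeds)) {
      cfg <- configs[[i]]
      cfg@seed <- as.integer(seeds[j])
      fit <- tryCatch(trainModel(trainWindows, valWindows, cfg, ...),
                      error = function(e) e)
      if (inherits(fit, "error")) {
        warning(sprintf("config %d seed %d aborted: %s", i, seeds[j],
                        conditionMessage(fit)))
        runs[[length(runs) + 1L]] <- data.frame(
          config = i, seed = seeds[j], val_total = NA_real_, ok = FALSE)
      } else {
        models[[i]][[j]] <- fit
        vt <- if (nrow(fit@history) > 0L) min(fit@history$val_total)
              else .evalLoss(fit@params, cfg, valWindows)["total"]
        runs[[length(runs) + 1L]] <- data.frame(
          config = i, seed = seeds[j], val_total = unname(vt), ok = TRUE)
      }
    }
  }
  runs <- do.call(rbind, runs)
  means <- vapply(seq_along(configs), function(i) {
    ri <- runs[runs$config == i, ]
    if (any(!ri$ok)) NA_real_ else mean(ri$val_total)
  }, numeric(1))
  cm <- data.frame(config = seq_along(configs), mean_val_total = means,
                   valid = !is.na(means))
  if (all(is.na(means))) stop("every grid configuration aborted")
  selected <- which.min(means)  # NA excluded; ties -> lowest index
  new("GridResult", runs = runs, configMeans = cm,
      selected = as.integer(selected), models = models)
}

#' Embed a window set with a trained model
#'
#' Context embeddings are posterior means (no sampling), so the result is
#' deterministic.  The LVAE substitutes the time-average of the local
#' posterior means.  Each row carries subject id, window start, split and
#' diagnosis.
#'
#' @param model a \linkS4class{TrainedModel}
#' @param windows a \linkS4class{WindowSet}
#' @param split a \linkS4class{DatasetSplit} covering all window subjects
#' @param diagnoses named character vector subject -> diagnosis
#' @param chunk windows per forward batch
#' @return an \linkS4class{EmbeddingTable}
#' @export
embedDataset <- function(model, windows, split, diagnoses, chunk = 512L) {
  stopifnot(is(model, "TrainedModel"), is(windows, "WindowSet"))
  if (windows@width != model@width)
    stop(sprintf("window width %d does not match model width %d",
                 windows@width, model@width))
  cfg <- model@config
  M <- nWindows(windows)
  spl <- splitOf(split, windows@subjectId)
  dg <- diagnoses[windows@subjectId]
  if (anyNA(dg))
    stop(sprintf("no diagnosis for subject '%s'",
                 windows@subjectId[which(is.na(dg))[1L]]))
  dim <- if (cfg@variant == "lvae") cfg@localSize else cfg@contextSize
  emb <- matrix(0, M, dim)
  at <- 1L
  while (at <= M) {
    idx <- at:min(at + chunk - 1L, M)
    x <- windows@data[, , idx, drop = FALSE]
    if (cfg@variant == "cvae") {
      enc <- cpp_cvae_encode(model@params, x, cfg@convKernel)
      emb[idx, ] <- t(enc$ctx_mu)
    } else if (cfg@variant == "lvae") {
      enc <- cpp_seq_encode(model@params, x, cfg@variant,
                            cfg@contextEncoderArch, cfg@convKernel, TRUE)
      emb[idx, ] <- t(apply(enc$loc_mu, c(1L, 2L), mean))
    } else {
      enc <- cpp_seq_encode(model@params, x, cfg@variant,
                            cfg@contextEncoderArch, cfg@convKernel, FALSE)
      emb[idx, ] <- t(enc$ctx_mu)
    }
    at <- at + chunk
  }
  embeddingTable(
    data.frame(subject_id = windows@subjectId,
               window_start = windows@start, split = spl,
               diagnosis = unname(dg), stringsAsFactors = FALSE),
    emb, width = windows@width)
}
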