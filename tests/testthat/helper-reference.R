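# Independent reference implementations used as oracles.  Everything here is
# written directly from the model description (plain R, loops, no reuse of
# the package's compiled path) so tests compare two routes to the same
# quantity.

refClamp <- function(x) pmin(pmax(x, -10), 10)

refGruStep <- function(p, pre, x, h) {
  H <- length(h)
  ax <- as.numeric(p[[paste0(pre, "_Wx")]] %*% x) + p[[paste0(pre, "_bx")]]
  ah <- as.numeric(p[[paste0(pre, "_Wh")]] %*% h) + p[[paste0(pre, "_bh")]]
  r <- 1 / (1 + exp(-(ax[1:H] + ah[1:H])))
  z <- 1 / (1 + exp(-(ax[(H + 1):(2 * H)] + ah[(H + 1):(2 * H)])))
  n <- tanh(ax[(2 * H + 1):(3 * H)] + r * ah[(2 * H + 1):(3 * H)])
  (1 - z) * n + z * h
}

refBiGru <- function(p, preF, preB, ins, H) {
  W <- length(ins)
  hf <- vector("list", W); hb <- vector("list", W)
  h <- numeric(H)
  for (t in 1:W) h <- hf[[t]] <- refGruStep(p, preF, ins[[t]], h)
  h <- numeric(H)
  for (t in W:1) h <- hb[[t]] <- refGruStep(p, preB, ins[[t]], h)
  list(f = hf, b = hb)
}

refConv <- function(Wk, b, X, K) {
  Cin <- nrow(X); W <- ncol(X); Cout <- nrow(Wk)
  pad <- (K - 1) / 2
  Xp <- matrix(0, Cin, W + K - 1)
  Xp[, (pad + 1):(pad + W)] <- X
  out <- matrix(0, Cout, W)
  for (k in 1:K)
    out <- out + Wk[, ((k - 1) * Cin + 1):(k * Cin), drop = FALSE] %*%
      Xp[, k:(k + W - 1), drop = FALSE]
  out + b
}

refConvEncoder <- function(p, X, K) {
  h1 <- pmax(refConv(p$ce_c1_W, p$ce_c1_b, X, K), 0)
  h2 <- pmax(refConv(p$ce_c2_W, p$ce_c2_b, h1, K), 0)
  rowMeans(h2)
}

refKl <- function(muq, lvq, mup, lvp) {
  sum(0.5 * (lvp - lvq + (exp(lvq) + (muq - mup)^2) / exp(lvp) - 1))
}

# Negative ELBO of a single window under the sequential variants.
refSeqLoss1 <- function(p, x, epsC, epsL, variant, arch, beta, gamma, K, H) {
  N <- nrow(x); W <- ncol(x)
  hasCtx <- variant != "lvae"
  zc <- NULL; ctxKl <- 0
  if (hasCtx) {
    feat <- if (arch == "rnn") {
      g <- refBiGru(p, "ce_f", "ce_b", lapply(1:W, function(t) x[, t]), H)
      c(g$f[[W]], g$b[[1]])
    } else refConvEncoder(p, x, K)
    muC <- as.numeric(p$ce_mu_W %*% feat) + p$ce_mu_b
    lvC <- refClamp(as.numeric(p$ce_lv_W %*% feat) + p$ce_lv_b)
    zc <- muC + exp(0.5 * lvC) * epsC
    ctxKl <- sum(0.5 * (exp(lvC) + muC^2 - 1 - lvC))
  }
  ins <- lapply(1:W, function(t) if (variant == "dsvae") c(x[, t], zc)
                else x[, t])
  g <- refBiGru(p, "le_f", "le_b", ins, H)
  LS <- nrow(p$le_mu_W)
  muL <- matrix(0, LS, W); lvL <- matrix(0, LS, W); zl <- matrix(0, LS, W)
  for (t in 1:W) {
    u <- c(g$f[[t]], g$b[[t]])
    muL[, t] <- as.numeric(p$le_mu_W %*% u) + p$le_mu_b
    lvL[, t] <- refClamp(as.numeric(p$le_lv_W %*% u) + p$le_lv_b)
    zl[, t] <- muL[, t] + exp(0.5 * lvL[, t]) * epsL[, t]
  }
  h <- if (variant == "dsvae") tanh(as.numeric(p$pr_h0_W %*% zc) + p$pr_h0_b)
       else tanh(p$pr_h0_v)
  locKl <- 0
  for (t in 1:W) {
    xin <- if (t == 1) numeric(LS) else zl[, t - 1]
    h <- refGruStep(p, "pr", xin, h)
    muP <- as.numeric(p$pr_mu_W %*% h) + p$pr_mu_b
    lvP <- refClamp(as.numeric(p$pr_lv_W %*% h) + p$pr_lv_b)
    locKl <- locKl + refKl(muL[, t], lvL[, t], muP, lvP)
  }
  locKl <- locKl / W
  recon <- 0
  for (t in 1:W) {
    zin <- if (hasCtx) c(zc, zl[, t]) else zl[, t]
    hid <- pmax(as.numeric(p$de_W1 %*% zin) + p$de_b1, 0)
    xhat <- as.numeric(p$de_W2 %*% hid) + p$de_b2
    recon <- recon + 0.5 * sum((x[, t] - xhat)^2)
  }
  recon <- recon / W + 0.5 * N * log(2 * pi)
  list(reconstruction = recon, local_kl = locKl, context_kl = ctxKl,
       total = recon + beta * locKl + gamma * ctxKl)
}

refCvaeLoss1 <- function(p, x, epsC, gamma, K, H) {
  N <- nrow(x); W <- ncol(x)
  feat <- refConvEncoder(p, x, K)
  muC <- as.numeric(p$ce_mu_W %*% feat) + p$ce_mu_b
  lvC <- refClamp(as.numeric(p$ce_lv_W %*% feat) + p$ce_lv_b)
  zc <- muC + exp(0.5 * lvC) * epsC
  ctxKl <- sum(0.5 * (exp(lvC) + muC^2 - 1 - lvC))
  f <- as.numeric(p$de_W0 %*% zc) + p$de_b0
  A <- pmax(matrix(f, H, W), 0)
  xhat <- refConv(p$de_cv_W, p$de_cv_b, A, K)
  recon <- 0.5 * sum((x - xhat)^2) / W + 0.5 * N * log(2 * pi)
  list(reconstruction = recon, context_kl = ctxKl,
       total = recon + gamma * ctxKl)
}

# Batch average of the reference loss, matching the compiled step contract.
refSeqLossBatch <- function(model, x, eps) {
  cfg <- model@config
  B <- dim(x)[3]
  terms <- lapply(seq_len(B), function(b)
    refSeqLoss1(model@params, x[, , b], eps$context[, b], eps$local[, b, ],
                cfg@variant, cfg@contextEncoderArch, cfg@beta, cfg@gamma,
                cfg@convKernel, cfg@hiddenSize))
  out <- lapply(c("reconstruction", "local_kl", "context_kl", "total"),
                function(k) mean(vapply(terms, `[[`, numeric(1), k)))
  names(out) <- c("reconstruction", "local_kl", "context_kl", "total")
  out
}

# Adjusted Rand index between two labelings (closed form from the
# contingency table).
ari <- function(a, b) {
  tab <- table(a, b)
  sc <- function(x) sum(choose(x, 2))
  n <- length(a)
  sij <- sc(as.numeric(tab))
  si <- sc(rowSums(tab)); sj <- sc(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Two-loop Pearson-correlation oracle with explicit covariance convention
# (sample covariance, denominator W - 1; the convention cancels in the
# correlation ratio but is pinned here for the record).
bruteWfnc <- function(w) {
  n <- nrow(w); W <- ncol(w)
  out <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    xi <- w[i, ]; xj <- w[j, ]
    cov <- sum((xi - mean(xi)) * (xj - mean(xj))) / (W - 1)
    out[i, j] <- cov / (sd(xi) * sd(xj))
  }
  out
}
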