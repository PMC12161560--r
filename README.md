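# dsvae

Disentangled sequential variational autoencoders for windowed multivariate
timecourses — for example, NeuroMark ICA component timecourses from
resting-state fMRI.

## The problem

Time-resolved functional connectivity analyses usually represent a sliding
window of brain activity by its windowed functional network connectivity
(wFNC): the Pearson correlation matrix of the component timecourses inside
the window.  Correlations are linear and blind to temporal order, so they
compress away much of the within-window dynamics.  This package implements
a generative, non-linear alternative for researchers studying fMRI
dynamics in clinical populations: each window
`x_w ∈ R^(N×W)` is factorized into a **context embedding** `z_c` (one per
window, slowly varying information) and **local embeddings** `z_t` (one
per timestep, fast dynamics), trained as a sequential VAE with the
negative evidence lower bound

    (1/W) Σ_t −log ψ(x_t | z_c, z_t)
      + β (1/W) Σ_t KL( q(z_t | ·) ‖ p(z_t | z_<t) )
      + γ       KL( q(z_c | x_w) ‖ N(0, I) )

where the context prior is standard normal and the local prior is a
learnable GRU conditioned on `z_c` (dependent variant, **DSVAE**) or on a
learnable vector (independent variant, **IDSVAE**).  Local-only (**LVAE**)
and context-only convolutional (**CVAE**) baselines, a wFNC + PCA
baseline, and the full evaluation suite — linear-SVM window
classification, cross-seed reliability, context-space versus wFNC-space
manifold comparison, and patient clustering with dwell-time statistics —
are included, along with a synthetic cohort generator with known
slow/fast latent structure so every stage is testable without
access-restricted clinical data.

The recurrent encoders, autoregressive GRU prior and decoders, with
hand-derived analytic gradients, are implemented in compiled code
(RcppArmadillo) and validated against finite differences and an
independent R composition in the test suite.

## Worked example

```r
library(dsvae)

spec <- syntheticSpec(nSubjectsPerGroup = 20, seed = 7)
ds <- generateDataset(spec)
ds$records
#> TimecourseSet with 40 subject(s), 10 components (20 patient / 20 control)

split <- splitSubjects(ds$records, c(0.6, 0.2, 0.2), seed = 1)
windows <- makeWindows(ds$records, windowSpec(32, 4))
windows
#> WindowSet: 1320 window(s) of 10 components x 32 timesteps (stride 4) from 40 subject(s)

diagnoses <- setNames(vapply(ds$records@records, function(r) r@diagnosis,
                             character(1)), subjectIds(ds$records))
ids <- names(split@assignment)
fit <- trainModel(subsetWindows(windows, ids[split@assignment == "train"]),
                  subsetWindows(windows, ids[split@assignment == "val"]),
                  modelConfig("dsvae", localSize = 4, contextSize = 2,
                              maxEpochs = 10, seed = 42))
fit
#> ModelConfig: dsvae (LS=4, CS=2, beta=0.1, gamma=0.001, rnn context encoder, hidden=32, seed=42)
#>   trained 10 epoch(s); best validation total 9.9874

emb <- embedDataset(fit, windows, split, diagnoses)
classifyContext(emb)                      # SVM fit on train+val, accuracy on test windows
#> 0.951
contextRecoveryScore(emb, ds$truth)       # cross-validated R2 vs the planted slow factor
#> 0.919
manifoldSimilarity(embeddingMatrix(emb), wfncVectors(windows), seed = 1)
#> 0.020
```

A test accuracy of 0.95 means the 2-dimensional context embeddings
linearly separate patient from control windows; the recovery score of
0.92 confirms they are an affine image of the planted slow factor rather
than an arbitrary discriminative feature; and the manifold R² of 0.02
shows the context space organizes windows very differently from wFNC —
the embeddings are complementary to, not a proxy for, connectivity.

The whole study (simulate → train → embed → evaluate, all four variants,
several seeds) can be driven from a single config:

```r
cfg <- defaultExperimentConfig("runs/demo", seeds = c(42L, 1337L), maxEpochs = 10L)
report <- runExperiment(cfg, stage = "all")
```

or from a shell via `inst/scripts/dsvae-run all --config cfg.yaml`.
Completed stages are skipped on re-run unless `--force` is given; every
run directory receives a frozen resolved config and an artifact manifest.

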