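# scpilot

Synthetic single-cell RNA-seq data from small pilot studies, for
experimental design.

## The problem

Planning a scRNA-seq experiment means deciding how many cells to
sequence before knowing what the data look like. A small pilot — one or
a few 384-well plates — can be turned into an arbitrary amount of
synthetic data by a deep generative model trained on it; running the
planned downstream analysis (clustering, cell-type discovery) on
synthetic datasets of different sizes then indicates how many cells a
full-scale study needs. The open question is whether synthetic cells
generated from so few real ones still carry the structure that matters:
cluster separation, cluster proportions, and per-gene count
distributions. `scpilot` implements both the generative models and the
evaluation framework to answer that question.

## What is in the package

**Single-cell deep Boltzmann machine (scDBM).** A three-layer Boltzmann
machine whose visible units are negative-binomial (an exponential-family
harmonium): for UMI counts `x` over `M` genes and binary hidden layers
`h1` (size `K`), `h2` (size `L`), the energy is

```
E(x, h1, h2) = -a'x - Σ_m log[(x_m + θ_m - 1)! / ((θ_m - 1)! x_m!)]
               - b1'h1 - b2'h2 - x'W1 h1 - h1'W2 h2
```

with per-gene inverse dispersion `θ_m` (NB variance `μ + μ²/θ`). The
conditionals are NB for the visible layer — gene `m` has natural
parameter `â_m = a_m + Σ_k W1_mk h1_k` and mean
`μ̂_m = θ_m e^â / (1 - e^â)` — and Bernoulli-sigmoid for both hidden
layers. Validity requires `a ≤ -ε` and `W1 ≤ 0`, enforced after every
training step. Because the recommended latent spaces are small
(`K, L` in 2–4), the package computes both training phases *exactly* by
enumerating the `2^(K+L)` hidden configurations after integrating the
visible layer out analytically; synthetic cells are generated by Gibbs
sampling through the three conditionals.

**Regularized Fisher scoring for θ.** Per-gene inverse dispersion is
estimated by the damped Newton iteration

```
θ_{k+1} = θ_k + (V(θ_k) + 2λ/θ_k³) / (I(θ_k) + 6λ/θ_k⁴)
```

where `V` is the score and `I` the observed information of the NB
log-likelihood. The penalty pushes small `θ` (large apparent
heterogeneity) upward, protecting the estimate from cluster structure
and excess zeros. During scDBM training, `θ` is held fixed and refreshed
every few epochs.

**Minimal NB-VAE.** A one-hidden-layer variational autoencoder with a
Gaussian latent `z` (default 10-d), a one-dimensional Gaussian log
library size `l`, softmax decoder proportions scaled by `exp(l)` as the
NB mean, and learned per-gene `θ` — no batch covariate, no
zero-inflation. Two generation modes: posterior sampling
(replicate-and-stack the pilot cells through `q(z|x)`) and prior
sampling (`z ~ N(0,1)`, `l ~ N(l_μ, 1)`), which needs no original cells
at all.

**Evaluation.** A frozen reference clustering of the original data
(log1p median-library normalization → PCA → 2-d embedding → Louvain on a
kNN graph; or user-supplied coordinates/labels) defines ground truth.
Each synthetic cell takes the label of its nearest reference cell by
Euclidean distance in embedding space. Reports contain the
Davies–Bouldin index (classical `(S_i+S_j)/M_ij` and a difference
variant behind a flag), the adjusted Rand index between transferred
labels and a de-novo clustering of the synthetic data,
cluster-proportion deviations, per-gene mean-absolute deviations of
median/IQR/CV/zero-fraction, and a zero-preservation check against
imputation.

**Pilot workflow.** `run_pilot_experiment()` sweeps plate sizes ×
repetitions × generators (scDBM, VAE-prior, VAE-posterior, and a
training-free gamma-Poisson noise baseline that bounds pure sampling
bias), returning a tidy tibble with full provenance; `autoplot()` turns
it into the usual boxplot panels. `simulate_nb_mixture()` generates
ground-truth NB mixtures with cluster structure for validation.

## Worked example

```r
library(scpilot)

# ground truth: 2000 cells, 50 genes, two equal populations with
# 10 marker genes at 8-fold change
fx <- two_population_fixture(seed = 1)

# one 384-well plate as the pilot
pilot <- subsample_plates(fx$counts, n_plates = 1, seed = 52)

fit <- train_scdbm(pilot, scdbm_config(seed = 53))
#> <scdbm> negative-binomial deep Boltzmann machine
#>   genes: 50  hidden: K = 3 , L = 3
#>   trained on 384 cells for 60 epochs

synthetic <- scdbm_generate(fit, n_cells = 2000, seed = 54)

ref <- reference_clustering(fx$counts, seed = 1)
#> <ref_clustering> 2000 cells, 2 clusters (provider: pca)

evaluate_synthetic(ref, fx$counts, synthetic)
#>     dbi   ari cluster_count_mad mad_median mad_iqr mad_cv mad_zero_fraction
#> 1 0.527 0.904                91        0.2   0.465  0.055             0.018
davies_bouldin(ref$coords, ref$labels$label)
#> [1] 0.41
```

Reading: from a single plate, the scDBM regenerates the full-size
dataset with a Davies–Bouldin index of 0.53 against 0.41 for the real
data's own clustering (lower = tighter, better-separated clusters), an
adjusted Rand index of 0.90 between transferred and de-novo labels
(1 = identical partitions), and cluster sizes off by 91 cells out of
~1000 per cluster. Per-gene medians deviate by 0.2 counts and zero
fractions by under 2 percentage points on average.

A command-line wrapper for the same steps is installed at
`system.file("cli/scpilot", package = "scpilot")` with `simulate`,
`train`, `generate` and `evaluate` subcommands.

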