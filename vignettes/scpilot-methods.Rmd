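---
title: "Models and design choices in scpilot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in scpilot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scpilot)
```

# Purpose

`scpilot` asks a practical experimental-design question: if only a small
pilot of single cells is available (one to a few 384-well plates), can a
generative model trained on it produce synthetic data whose *downstream
analysis* — clustering, cell-type proportions, per-gene count
distributions — behaves like the full-scale data would? The package
provides two generative models (a negative-binomial deep Boltzmann
machine and a minimal NB variational autoencoder), a training-free noise
baseline, and an evaluation pipeline tying them together. This vignette
explains the models, the estimation choices, and the points where the
design was genuinely open.

# The NB deep Boltzmann machine

## Model

UMI counts are modelled per cell as the visible layer `x` (one unit per
gene) of a three-layer Boltzmann machine with binary hidden layers `h1`
(`K` units) and `h2` (`L` units). The visible units are negative
binomial in the mean/inverse-dispersion parametrization

$$p_{NB}(v;\mu,\theta) = \frac{\Gamma(v+\theta)}{\Gamma(v+1)\Gamma(\theta)}
\left(\frac{\theta}{\theta+\mu}\right)^{\theta}
\left(\frac{\mu}{\theta+\mu}\right)^{v},$$

mean $\mu$, variance $\mu + \mu^2/\theta$; smaller $\theta_m$ means more
between-cell heterogeneity for gene $m$. The joint energy is

$$E(x,h^{(1)},h^{(2)}) = -a^\top x
- \sum_m \log\frac{(x_m+\theta_m-1)!}{(\theta_m-1)!\,x_m!}
- b^{(1)\top}h^{(1)} - b^{(2)\top}h^{(2)}
- x^\top W^{(1)} h^{(1)} - h^{(1)\top} W^{(2)} h^{(2)},$$

the factorial term computed through log-gamma so non-integer $\theta$ is
exact. The three conditionals used everywhere (training, generation, and
the exactness diagnostic) are: NB for each gene with natural parameter
$\hat a_m = a_m + \sum_k W^{(1)}_{mk} h^{(1)}_k$ and mean
$\hat\mu_m = \theta_m e^{\hat a_m}/(1-e^{\hat a_m})$; and
Bernoulli-sigmoid units for both hidden layers.

Because $a$ is the *natural parameter* (log scale) of the NB visible
units, the model is only normalizable when every $\hat a_m < 0$. The
constraints $a_m \le -\varepsilon$ (with $\varepsilon = 10^{-10}$) and
$W^{(1)} \le 0$ guarantee this for every hidden configuration; they are
re-applied after every gradient step (`apply_constraints()`, idempotent).
Whether $W^{(2)}$ should also be sign-constrained is not forced by
normalizability; it is unconstrained by default with a `constrain_w2`
switch.

## Exact enumeration instead of chain-based approximations

The standard recipe for DBMs is a mean-field variational positive phase
plus persistent contrastive divergence (PCD) for the negative phase. Both
are implemented (`negative_phase = "pcd"` or `"cd"`), but the package's
default exploits a structural fact: for an exponential-family harmonium
the visible layer integrates out in closed form,

$$\sum_{x_m \ge 0} \exp(\hat a_m x_m + \log\binom{x_m+\theta_m-1}{x_m})
= (1-e^{\hat a_m})^{-\theta_m},$$

so for the small latent spaces this model is meant to use (`K`, `L` of
2–4, i.e. at most a few thousand hidden configurations) the *entire*
model distribution over $(h^{(1)}, h^{(2)})$ — and hence every moment the
gradient needs — can be enumerated exactly. The same trick gives the
exact per-cell posterior over hidden configurations for the positive
phase. Training is then true (minibatch) likelihood ascent with no
chain-mixing error. This matters in practice: NB Gibbs chains mix very
slowly between well-separated count modes, and the relative mass of two
modes is exponential in small energy differences, so chain-based
estimates of mode proportions are fragile exactly where this application
needs them most. Chain-based modes remain available and are used
automatically when `K + L > 12`.

## Initialization

Parameters are initialized from the data ("some reasonable values"):
k-means with `K` centers on log1p median-library-normalized counts gives
crude cluster profiles; the visible bias is set to the natural parameter
of the per-gene *envelope* (the maximum profile across clusters), and
column `k` of $W^{(1)}$ to the non-positive offset taking the envelope
down to cluster `k`'s profile, so each one-hot hidden configuration
reproduces one crude cluster. Hidden biases are set from the analytic
visible normalizer so those configurations start with mass roughly
proportional to cluster sizes, and $W^{(2)}$ is initialized as a soft
winner-take-all pattern ($6(2I-J)$): each `h2` unit excites one `h1`
unit and inhibits the rest, which penalizes the all-off and multi-on
"chimera" configurations — a correlation structure that single-layer
biases cannot express (softplus contributions are convex along any
direction in `h1`). Greedy layer-wise CD pretraining is retained
(`pretrain_epochs`) but defaults to 0 since the informed initialization
supersedes it.

## Training schedule and numerical guards

Gradients of $a$ and $W^{(1)}$ live on the raw count scale while the
parameters live on the log scale, so they are preconditioned by
$1/(\bar x_m + 1)$ (turning them into relative errors) and clipped to
$\pm 1$; model-side means entering the gradients are capped at twice the
maximum observed count. Near $\hat a \to 0^-$ the conditional mean
diverges, and without these guards training oscillates between mean
explosion and collapse of whole genes. The step size decays linearly to
20% of its initial value. The inverse dispersion is *fixed* during
gradient steps and refreshed every `theta_refresh_every` epochs (default
5) by regularized Fisher scoring, with the per-cell posterior-predictive
reconstruction mean as the NB mean (`theta_mu = "reconstruction"`; the
per-gene empirical mean is the alternative).

After the gradient epochs, a final deterministic calibration refits the
hidden prior $(b^{(1)}, b^{(2)}, W^{(2)})$ so that the enumerated model
marginal over hidden configurations matches the aggregated data
posterior occupancy. The motivation is the exponential sensitivity noted
above: stochastic training leaves cluster proportions orbiting the
target without ever settling; the calibration pins them. It is a small
convex-like fit over at most a few thousand configurations and costs
milliseconds (`calibrate_prior = TRUE` by default, available whenever
the hidden space is enumerable).

## Generation

`scdbm_generate()` runs one independent Gibbs chain per synthetic cell,
alternating the three conditionals, and returns the final visible state.
When the hidden space is enumerable, chains are initialized at exact
draws from the enumerated hidden joint — i.e. at stationarity — so the
burn-in (default 100 sweeps) is a safety margin rather than a necessity;
otherwise chains start from bias-only NB draws. Everything is
reproducible from a single integer seed.

## Validating the sampler

`scdbm_gibbs_tv()` checks energy and conditionals against each other on
a toy model (2 genes truncated to counts 0–10, `K = L = 2`): the full
joint over 1936 states is enumerated, the Boltzmann distribution
$e^{-E}/Z$ computed exactly, and a long vectorized Gibbs run (with the
visible conditional renormalized over the truncated support) is compared
by total-variation distance. Observed values are ~0.005 on three million
samples, against a 0.02 acceptance bound.

# Dispersion estimation

The score of the NB log-likelihood in $\theta$ for counts $x_i$ with
means $\mu_i$ is

$$V(\theta) = \sum_i \psi(x_i+\theta) - \psi(\theta)
+ \log\frac{\theta}{\theta+\mu_i} + 1 - \frac{x_i+\theta}{\theta+\mu_i},$$

and the package uses the *observed* information
$I(\theta) = -\partial V/\partial\theta$ (trigamma-based) rather than
the expected information: it is simpler and directly verifiable against
finite differences, which the tests do at 1e-6/1e-5 relative tolerance.
The regularized update is

$$\theta_{k+1} = \theta_k + \frac{V(\theta_k) + 2\lambda/\theta_k^3}
{I(\theta_k) + 6\lambda/\theta_k^4},$$

iterated from a method-of-moments start until the relative change drops
below `tol`, clipped into `theta_bounds` (default `[0.01, 1000]`).
All-zero genes return the upper bound with a warning. The update
corresponds to *subtracting* $\lambda/\theta^2$ from the log-likelihood;
this is the form whose fixed point moves upward with $\lambda$
(verified as a monotone $\hat\theta(\lambda)$ path in the tests), i.e.
small $\theta$ estimates — inflated heterogeneity from cluster structure
or excess zeros — are shrunk toward larger values. A caveat worth
recording: the *single-step* comparison is not monotone in $\lambda$
everywhere (as $\theta_k \to 0$ the unpenalized step approaches
$\sim\theta_k$ while the penalty-dominated step approaches $\theta_k/3$),
so the tests assert the fixed-point property, plus strict upward movement
of the penalized update at the unpenalized optimum. The default
$\lambda = 5$ is deliberately mild at the few-hundred-cell scale; it is
exposed in both `fisher_scoring_config()` and `scdbm_config()`.

# The minimal NB-VAE

The VAE is the reduced form appropriate for this comparison: no batch
covariate and no zero-inflation. The variational posterior factorizes as
$q(z, l \mid x) = q(z \mid x)\, q(l \mid x)$ with a `latent_dim`-Gaussian
$z$ (default 10) and a one-dimensional Gaussian log library size $l$;
the objective is the evidence lower bound

$$\log p(x) \ge E_q \log p(x \mid z, l) - D_{KL}(q(z \mid x)\,\|\,p(z))
- D_{KL}(q(l \mid x)\,\|\,p(l)).$$

Encoder and decoder each have one ReLU hidden layer (default width 128);
the decoder ends in a softmax over genes — the proportion of transcripts
per gene — scaled by $e^l$ to give the NB mean; $\theta_m$ is a free
log-parameterized vector learned by gradient. The library-size prior
takes its mean and variance from the log total counts of the training
cells. Optimization is Adam with the reparameterization trick; the
backpropagation is hand-derived (the network is three matrix products
deep) and verified against finite differences of the ELBO in the test
suite, which is the reason it can be trusted without an autodiff
framework.

Generation has two modes. *Posterior* sampling replicates the pilot
cells $\lceil n_{target}/n \rceil$ times, draws $z, l$ from the
variational posterior of each copy, and decodes — so a 384-cell pilot
taken to 2688 cells stacks seven passes, and sampling artifacts of
individual pilot cells are amplified accordingly. *Prior* sampling draws
$z \sim N(0, I)$ and $l \sim N(l_\mu, 1)$ with no access to any original
cell; its variance-1 library prior is intentionally broader than the
fitted one.

# Evaluation

The reference workflow is a pluggable provider, not a re-implementation
of any specific toolchain: log1p median-library normalization, PCA
(default 10 components), a 2-d embedding, and Louvain community
detection on a kNN graph (`k = 15`, resolution 0.25 — calibrated for
coarse cell-type structure; higher resolutions split the planted
populations). The default embedding is the first two principal
components because it is deterministic and admits an exact out-of-sample
projection; a UMAP option exists, and user-supplied coordinates plus
labels are accepted verbatim so external clustering results can be
dropped in. Labels are transferred to synthetic cells by 1-nearest
neighbour in embedding space (ties to the lowest reference index; an
O(n²) oracle cross-checks this in tests).

Indices: the Davies–Bouldin index is computed with $p = q = 2$ in
embedding space, with per-cluster dispersion
$S_k = (\frac{1}{n_k}\sum \|x_i-\bar x_k\|^q)^{1/q}$ and both the
classical similarity $R_{ij} = (S_i+S_j)/M_{ij}$ (default) and a
difference variant $(S_i-S_j)/M_{ij}$ behind `variant = "as_printed"`;
both are covered by hand-computed fixtures. The adjusted Rand index uses
exact binomial-coefficient arithmetic and is compared between the
transferred labels of the synthetic cells and a de-novo clustering of
the synthetic data by the same provider — this makes "does the synthetic
data cluster the way its inherited labels say it should" a well-defined
question. Cluster-proportion deviation is the mean absolute difference
in per-cluster cell counts over the union of cluster ids (absent
clusters count zero). Per-gene deviations are mean absolute differences
of median, IQR, CV (genes with zero mean excluded and counted), and zero
fraction on raw counts. `zero_preservation_check()` compares per-gene
zero fractions of generated data against the corrupted training data and
flags genes whose zeros were refilled beyond a margin — the signature of
imputation, which a generator for design purposes must not do.

# The synthetic ground-truth generator

`simulate_nb_mixture()` emulates what these models assume: cells drawn
from a cluster mixture, NB counts with per-cluster mean vectors and
per-gene inverse dispersion, log-normal library-size factors, optional
uniform excess zeros. The canonical study conditions used throughout the
tests and the acceptance script are `two_population_fixture()`: 2000
cells, 50 genes, two equal populations, 10 marker genes at 8-fold
change (half up in each population), $\theta = 2$ per gene — a typical
post-filtering UMI regime — and library factors with sdlog 0.2. What it
deliberately does not emulate: batch effects, gene–gene correlation
beyond cluster structure, bimodal within-cluster genes, and the extreme
sparsity of shallow 10x runs. Passing tests on this fixture therefore
demonstrate correct mechanics and faithful recovery of coarse cluster
structure, not performance on any particular real dataset.

# Pilot workflow

`run_pilot_experiment()` executes the full design: for each plate size
(default 384–2304 in plate steps), repetition (default 30), and
generator (scDBM, VAE-prior, VAE-posterior, baseline), it subsamples a
pilot (repetition `r` uses seed `base_seed + r`), trains, generates to
the original size, and evaluates against a reference clustering computed
*once* on the original data. Per-run seeds derive from a deterministic
counter (`base_seed + 1000 * plate_index + repetition`), all below
2^31. Failures are recorded per row; an optional on-disk cache keyed by
(generator, size, repetition) makes sweeps resumable. The noise baseline
needs no training: per replicate and cell a gamma variate (scale ~
U(0,5), shape ~ U(0,10)) is used as a Poisson rate added to the pilot
counts — one rate per cell reused across genes by default (the literal
reading), `per_gene = TRUE` for the alternative — and noisy replicates
are stacked to the target size.

# Problem sizes and runtimes

All defaults are sized for a single CPU core. The canonical conditions —
384-cell pilots from a 2000 x 50 fixture, 60 training epochs, 2000
generated cells — train an scDBM in a few seconds and run the complete
acceptance script in under a minute; the full test suite runs in about
two minutes. The VAE at fixture scale uses 200 epochs and hidden width
64 (its full-data defaults are 400 and 128). The Gibbs exactness
diagnostic uses 2000 chains x 1500 post-burn-in sweeps (3 million
samples over 1936 states).

# Known limitations

- The scDBM's exact-enumeration training is only available for small
  hidden layers; beyond `K + L = 12` it falls back to mean-field + CD/PCD,
  which inherit the usual mode-proportion fragility.
- With `W1 ≤ 0`, every hidden configuration's mean profile lies below
  the visible-bias envelope; expression patterns that are not
  "suppressions of a common envelope" must be absorbed by the envelope
  itself, which can waste capacity when clusters are many and disjoint.
- An NB visible unit cannot represent strong zero-inflation at high
  mean; after 20% artificial zeros the fitted model under-produces zeros
  slightly on high-mean marker genes (gaps of 0.05–0.07 in zero
  fraction at the pilot scale) without crossing the imputation margin.
- The reference provider is intentionally simple; for real analyses,
  supply your own embedding and labels.
- Posterior-sampling VAE results amplify pilot sampling artifacts by
  construction; that is the phenomenon under study, not a bug.
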