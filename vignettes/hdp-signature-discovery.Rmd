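---
title: "Discovering mutational signatures with HDP mixture models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering mutational signatures with HDP mixture models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A mutational signature is a multinomial probability vector over a fixed set
of mutation classes — 96 single-base-substitution classes in trinucleotide
context (SBS-96) or 83 small insertion/deletion classes (ID-83). Each
mutational process active in a tumor generates mutations by sampling classes
from its signature, and the observed mutational spectrum of a tumor is the
class-wise sum over processes. Signature discovery inverts this: given a
catalog (classes x samples count matrix), infer how many signatures are
present, their profiles, and how many mutations each contributed to each
sample (the exposures).

Most discovery tools factorize the catalog with non-negative matrix
factorization and need the number of signatures chosen by some outer
criterion. `hdpsig` instead models individual mutations with a hierarchical
Dirichlet process (HDP) mixture: mutations are assigned to clusters, each
cluster is generated by one signature, and the Dirichlet-process prior makes
the number of clusters part of the posterior rather than a tuning constant.

## The model

Each sample owns a Dirichlet process over signatures whose base distribution
is a parent process shared by all samples (two-layer model), optionally with
an intermediate per-group (e.g. per cancer type) process between samples and
root (three-layer; used automatically when the catalog carries sample
groups). The root's base distribution $H$ is uniform on the simplex of
signatures — a symmetric Dirichlet with all concentration parameters 1 over
the $C$ mutation classes. A mutation in sample $j$ picks a signature from
$j$'s process; with probability controlled by the concentration parameters
the pick recurses to the parent and, ultimately, to $H$, which is how new
signatures enter the model.

Inference uses the Chinese-restaurant-franchise (CRF) representation:
mutations are customers, each restaurant (node) seats customers at tables,
every table serves a dish (a global mutation cluster = signature
realization), and each table is itself a customer of its parent restaurant.
Because $H$ is Dirichlet(1), a dish with class counts $n_{k\cdot}$ predicts
class $c$ with the Dirichlet-multinomial posterior predictive
$(n_{kc}+1)/(n_{k\cdot}+C)$, and all continuous signature values integrate
out exactly; the sampler state is purely discrete.

A Gibbs sweep removes and reseats every mutation: an existing table $t$ is
chosen with probability proportional to $n_t \cdot f_k(c)$ and a new table
proportional to $\alpha \cdot p_{\text{parent}}(c)$, where
$p_{\text{parent}}$ recurses up the hierarchy and equals $1/C$ at $H$.
Opening a table seats a virtual customer at the parent by the same rule;
emptying one retracts it. A new table at the root opens a new dish — a new
candidate signature. Reseating order is reshuffled every sweep from the
chain's own RNG stream. This item-level scan leaves the correct CRF joint
distribution invariant and is ergodic; the test suite verifies it against
exhaustive enumeration of all seating arrangements for small catalogs
(partition frequencies match exact probabilities within 0.01 over $2\times
10^5$ sweeps).

## Priors on concentration parameters

Each hierarchy level shares one concentration parameter (configurable to
per-node), resampled once per sweep by the standard auxiliary-variable
update for gamma-prior DP concentrations: with $n_j$ customers and $t_j$
tables in restaurant $j$, draw $w_j \sim \mathrm{Beta}(\alpha+1, n_j)$,
$s_j \sim \mathrm{Bernoulli}(n_j/(n_j+\alpha))$, then $\alpha' \sim
\Gamma(\mathrm{shape} + \sum t_j - \sum s_j,\; \mathrm{rate} = \beta - \sum
\log w_j)$. All processes share a single $\Gamma(\mathrm{shape}, \beta)$
prior. The prior rate $\beta$ is the main lever on the number of discovered
signatures: $\Gamma(1, 1)$ has mean $\approx 1$ while $\Gamma(1, 20)$ has
mean $0.05$, and smaller concentrations make brand-new signatures rarer,
reducing false positives. Defaults are shape 1 with $\beta = 20$ for SBS-96
and $\beta = 50$ for ID-83, the values found best in benchmarking;
both are exposed in `hdp_config()`.

## From posterior samples to signatures

After burn-in, the sampler snapshots a Gibbs sample every `spacing` sweeps:
the per-dish class counts and per-sample counts ("clusters of category
counts"). Across samples and chains the same underlying signature appears
as many slightly different mutation clusters, and a single Gibbs sample may
contain several clusters from one process, so clusters must be grouped
before point estimates are formed — this grouping, not the sampler, is what
mainly determines the false-discovery behaviour.

`hdpsig` pools all non-empty clusters from all Gibbs samples and groups them
by divisive (DIANA-style) hierarchical clustering on cosine distance
($1-$cosine similarity of profiles): a branch is split by seeding a splinter
with the member of maximal average dissimilarity (ties broken by lowest
column index) and moving members whose average dissimilarity to the splinter
is smaller than to the remainder. Recursion stops on a branch when the mean
cosine similarity of its members to the branch's summed-count profile
reaches the cohesion threshold (default 0.90); the stopped branches are the
groups. The divisive literature offers no canonical tree cut; this cohesion
rule directly encodes "members resemble their common profile" and is
exposed as `cohesion_threshold`. A test cross-checks the splinter step
against `cluster::diana`.

Each group's support is the fraction of distinct Gibbs samples contributing
at least one member (several members from one sample count once). Groups
with support at or above `support_cutoff` (default 0.9) become signatures:
profile = class-wise summed counts divided by the group total. Raising the
cutoff can only reduce the number of signatures (tested property).
Exposures are posterior means over *all* Gibbs samples — a sample without a
member contributes zero — with the spread reported as a standard deviation
across samples; averaging over contributing samples only would bias
low-support signatures upward. Groups whose profile puts more than 0.95 of
its mass on one class are flagged `single_class` — a known false-positive
mode of HDP discovery on SBS data — but are not removed.

## Downsampling

Sampler cost is proportional to the number of mutations, and hypermutated
samples also inflate false discoveries on SBS data. `downsample_spectra()`
rescales any sample whose total exceeds the threshold, mapping each class
count $c$ to $\lfloor c\,T/\mathrm{tot} + 0.5\rfloor$. Half-up rounding is
deterministic (reproducibility; stochastic rounding would add a second
noise source), keeps resulting totals within $C/2$ of the threshold and
per-class proportions within $1/T$. The SBS-96 default in `hdp_fit()` is
the benchmarked threshold 3000; for ID-83 downsampling degrades accuracy
and is off by default.

## The synthetic-data generator

The generator emulates signature activity in a cohort, per tumor type and
signature $s$: presence is Bernoulli($p_s$); if present the burden is
$m_s \sim \mathrm{NB}(\mu_s, \mathrm{size}_s)$ (mean/size parameterization,
variance $\mu + \mu^2/\mathrm{size}$); expected class counts are $m_s$
times the profile; and realistic resampling noise redraws each class count
from $\mathrm{NB}(m_{s,t}, d)$ independently ($d = 30$ for SBS, 10 for
indels, the values matching real-data reconstruction accuracy; $d=\infty$
disables noise, and $\mathrm{NB}(0, d)$ is a deterministic 0). The spectrum
is the rounded class-wise sum. `fit_prevalence_model()` estimates
$(p_s, \mu_s, \mathrm{size}_s)$ from a real exposure matrix: $p_s$ as the
proportion of exposed tumors, $(\mu_s, \mathrm{size}_s)$ by maximum
likelihood (`fitdistrplus`) on positive exposures; with fewer than three
exposed tumors no dispersion is identifiable, so `size` is fixed at $10^6$
(effectively Poisson) and $\mu$ at the sample mean.

What the generator does *not* emulate: correlation between signature
presences within a tumor, cross-class covariance of the noise, sequencing
artifacts, or inter-sample contamination. Tests passing on these catalogs
therefore show correct recovery under the stated generative model, not
robustness to everything real cohorts contain.

A consequence of the noise model worth knowing: as the burden grows the
per-class relative noise tends to $1/\sqrt{d}$, not to 0, so a single noisy
spectrum's cosine to its generating profile plateaus near $1 - 1/(2d)$
($\approx 0.983$ at $d = 30$ — comparable to reconstruction accuracies in
real tumors). Extracted signatures do better than single spectra because
grouping averages over many clusters; the end-to-end tests require
per-match cosine $\ge 0.95$ and typically observe $0.96$–$0.99$.

## Assessing discovered signatures

`match_signatures()` matches discovered to ground-truth signatures:
cosine distances above 0.1 are replaced by a large constant $L$, a
minimum-total-distance assignment is found with the Hungarian algorithm
(rectangular matrices padded with $L$-cost dummies), and pairs at cost $L$
are discarded. Matched pairs are true positives; leftovers are false
positives/negatives. $L = 1000$ — any value far above
$n \times 0.1$ gives the identical assignment; it is fixed for
determinism. Metrics are PPV, TPR, the mean cosine over true-positive
pairs (defined as 0 when there are none, keeping the composite measure
well-defined), and the composite = PPV + TPR + mean cosine. The assignment
is verified against exhaustive permutation minima up to $5\times 5$.
`reconstruct_signature()` solves the non-negative least-squares problem of
expressing a profile as a mixture of reference signatures
(`pracma::lsqnonneg`), the standard check for merged-signature false
positives; no penalty on the number of references used is applied.

## Numerical and design choices

* **Initialization**: mutations are spread round-robin over `init_dishes`
  (default 8–10) dishes, one table per (node, dish) pair along each
  leaf-to-root path, concentrations at their prior mean. A dispersed start
  mixes faster than a single-cluster start and is fully reproducible.
* **RNG**: each chain owns a self-contained xoshiro256++ stream seeded with
  `seed + chain_id`; R's global RNG is untouched by the sampler, chains are
  independent, and serial vs parallel execution gives identical archives.
  The generator and metric code use R's RNG under explicit seeds.
* **Checkpointing**: the full serialized CRF state (including the RNG
  state) is written periodically; resuming reproduces the uninterrupted
  run bit-for-bit, which also makes extending burn-in cheap.
* **Degenerate inputs**: empty catalogs, zero-count clusters, zero-mutation
  samples, and empty discovered sets are all defined (dropped, proportion
  0, all-false-negative) rather than errors; a catalog with no mutations at
  all is rejected.
* **Ties**: splinter seeding and assignment are deterministic (lowest
  index), so grouping is invariant to column permutations of the pool.
* **Problem sizes**: the default `hdp_config()` is a desk-scale profile — 4
  chains x 20 Gibbs samples, spacing 10, burn-in 500, which recovers 3–5
  well-separated signatures from 30–100 tumors in well under a minute of
  sampling. Cohort-scale analyses use the same code with the larger profile
  (20 chains x 200 samples, spacing 100, longer burn-in) via
  `hdp_config()`; accuracy results in the benchmarking literature refer to
  that scale.

## Known limitations

* The sweep reseats individual mutations only; split–merge or table-level
  dish reassignment moves, which can speed mixing on large catalogs, are
  not implemented.
* Posterior samples are used only through the grouping stage; no
  convergence diagnostics beyond support fractions are computed —
  inspecting per-chain cluster counts over checkpoints is the practical
  substitute.
* The two- and three-layer hierarchies are supported; deeper or
  non-tree structures are not.
* Matching COSMIC signature names to discovered profiles is out of scope;
  `reconstruct_signature()` is provided for manual follow-up.
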