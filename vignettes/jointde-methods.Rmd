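---
title: "Methods: joint Bayesian inference of transcript expression and differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint Bayesian inference of transcript expression and differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jointde)
```

## The inference problem

RNA-seq reads aligned to an annotated transcriptome rarely identify their
transcript of origin uniquely: isoforms of a gene share exons, so a read is
compatible with several transcripts. Quantification therefore works with a
mixture model — each transcript is a mixture component with weight equal to
its relative abundance, and the component density $f_k(x_i)$ is the
probability of read $i$ arising from a position on transcript $k$. Given two
samples, the scientific question is which transcripts changed abundance.
`jointde` treats quantification and differential expression (DE) as one
inference: the two abundance vectors $\theta$ (sample x, $r$ reads) and $w$
(sample y, $s$ reads) are coupled through a binary state vector $c$ with
$c_k = 0 \iff \theta_k = w_k$.

Because $\theta$ and $w$ are points of the $(K-1)$-simplex, no single
coordinate can change alone; the state space excludes $\sum_k c_k = 1$. The
"dead" (equal) coordinates are listed before the "alive" (changed) ones by a
canonical permutation $\tau$, and the free parameters are

* $u$: a $K$-simplex that permutes into $\theta$,
* $v$: a $c_+$-simplex ($c_+ = \sum_k c_k$) giving the alive coordinates of
  $w$ after scaling by the total alive mass of $\theta$ (alive mass is
  conserved between samples),
* $\pi$: the prior DE probability, with indicators $c_k \sim$
  Bernoulli($\pi$) truncated to the valid set, and
  $\pi \sim \mathrm{Beta}(1/2,\,1/2)$ (Jeffreys) or fixed.

Priors $u \sim \mathrm{Dir}(\alpha_1,\dots,\alpha_K)$ and
$v \sim \mathrm{Dir}(\gamma_1,\dots,\gamma_{c_+})$ default to all-ones
(uniform on both simplexes). With exchangeable $\alpha = \gamma$ the implied
marginals of $\theta$ and $w$ are each $\mathrm{Dir}(\alpha,\dots,\alpha)$ —
the coupling adds an atom at $\theta_k = w_k$ without distorting the
marginal abundance law. The test suite verifies this by KS tests of every
coordinate against its Beta marginal.

## Conjugacy and the two samplers

Given the latent per-read allocations $\xi$ (sample x) and $z$ (sample y)
with count tallies $s_k(\xi)$, $s_k(z)$, the model is conjugate at fixed
dimension: $v$ has a Dirichlet full conditional and $u$ a generalized
Dirichlet (Connor–Mosimann) full conditional, sampled exactly by its
stick-breaking representation (`rgdirichlet()`, $O(K)$). The corresponding
parameters are exposed as `posterior_free_params()`, and their two limiting
cases are verified in tests: with $c_+ = 0$ the generalized Dirichlet
collapses to the pooled-sample Dirichlet, with $c_+ = K$ it factorises into
two independent Dirichlets. The mixed case is checked against brute-force
quadrature of prior × likelihood on the 2-simplex.

Integrating $u$ and $v$ out analytically gives a collapsed marginal over
$(\xi, z, c)$ built from Gamma functions of the count tallies
(`collapsed_log_mass()`). One derivation subtlety is worth recording: when
this mass is compared *across* states (block updates of $c$, exact
enumeration), the normaliser of the $v$ prior
$\Gamma(\sum_{l \le c_+}\gamma_l)/\prod_{l\le c_+}\Gamma(\gamma_l)$ must be
kept, because the dimension of $v$ changes with $c_+$; it cancels only at
fixed $c$. The implementation keeps it, and the exact enumeration built on
it is validated independently by the reversible-jump sampler, which never
touches the collapsed mass.

Two samplers target the same posterior:

* **Collapsed Gibbs** (default): systematic single-site resampling of every
  $\xi_i$ and $z_j$ from two-branch categorical conditionals (dead branch:
  pooled predictive; alive branch: sample-specific predictive with a ratio
  prefactor), followed by $K$ pairwise block updates of $c$ — two
  transcripts drawn at random, the at-most-four valid configurations
  resampled exactly from their joint conditional — and a Beta update of
  $\pi$. Expression draws (step "e") are optional and only needed for
  abundance reporting. Under exchangeable hyperparameters all block-update
  terms are maintained incrementally in $O(1)$; otherwise an $O(K)$
  recomputation path is used.
* **RJMCMC**: allocations given $(\theta, w)$, conjugate redraw of
  $(u, v) \to (\theta, w)$, then $K$ birth/death proposals. A birth moves a
  uniformly chosen dead index alive, inserting a new $v$ coordinate by a
  $\mathrm{Beta}(1,1)$ stick split ($e$) of the alive mass with
  Metropolis–Hastings–Green Jacobian $(1-e)^{c_+-1}$; death is the exact
  reverse. Pair moves bridge $c_+ = 0 \leftrightarrow 2$ since single moves
  through $c_+ = 1$ are forbidden. The proposal mechanics were designed
  here; their correctness is established empirically by total-variation
  agreement with exact enumeration (below), not by construction.

Both samplers initialise at the all-null state with allocations drawn
proportionally to alignment densities, run in compiled code, and draw all
randomness from the R RNG so a seed fixes the chain exactly.

### Exact enumeration oracle

For instances with $K \le 4$ and $r + s \le 8$ reads,
`exact_state_posterior()` sums the collapsed mass over every allocation of
every read and every valid state, aggregating allocations into unique count
vectors first. The acceptance tests require both samplers to match these
exact posteriors within total-variation distance 0.02–0.03 at
$2\times10^5$ sweeps on five random instances, and to match each other on
$q_k$. This is the package's primary correctness argument, and it covers
the allocation conditionals, the block update, the birth/death acceptance
ratios, and the cross-state mass normalisation simultaneously — an error in
any one of them shows up as a TV gap.

## Clusters

Reads only ever align to small transcript subsets, so the bipartite
read–transcript graph (both samples pooled) splits into connected
components. `fit_de()` runs one chain per component with a cluster-local
state vector (the $c_+ \ne 1$ constraint applied within the cluster) and a
cluster-local $\pi$, dispatching the largest clusters first and deriving
per-cluster seeds from the master seed, so results are identical for any
worker count. Global abundances are reassembled as within-cluster posterior
means times posterior-mean cluster masses (Dirichlet-multinomial over
per-cluster read totals, prior mass $\sum_{k \in \text{cluster}} \alpha_k$);
the merged vectors sum to one by construction.

Two caveats are deliberate design choices. First, a transcript in a
singleton cluster has a one-point within-cluster simplex, so it can never be
flagged DE by the cluster-local model ($q = 0$, flagged in the output);
changes in its read totals still appear in the abundance estimates. Second,
the cluster-local constraint differs from the global one on boundary states
(one alive transcript in each of two clusters is globally valid but
cluster-locally invalid), so raw and clusterwise posteriors agree exactly
only where such boundary states carry negligible mass — in practice, when
the data are informative. The acceptance test compares per-transcript
marginals on a two-cluster instance with clear signal and requires agreement
within 0.02; on deliberately weak data the two models genuinely differ, and
the raw (`cluster = FALSE`, or `run_chain()`) model is the exact one.
Relatedly, the cluster-local model detects changes of *within-cluster*
shares; simulation truths whose DE pattern changes a cluster's total mass
(compensated in other clusters) match the raw model, while isoform-switch
patterns (mass conserved within the gene) match both. Calibration
simulations in this package therefore use the raw sampler.

## Decision rules

With $q_k = \hat P(c_k = 1 \mid \text{data})$, any decision vector $d$ has
posterior expected FDR $\sum_k (1-q_k) d_k / \sum_k d_k$. Three rules are
provided: the conservative threshold $q_k > 1-\alpha$; the optimal-loss
threshold $q_k > c/(c+1)$ under loss $c\,\mathrm{FD} + \mathrm{FN}$; and the
step-up rule that sorts $q$ descending and rejects the largest prefix whose
running mean of $(1-q)$ stays at or below $\alpha$ — this controls the
expected FDR at exactly $\alpha$ by direct substitution, which the suite
checks on $10^4$ random probability vectors. Ties break by input order so
decisions are reproducible.

## Synthetic data and study conditions

`simulate_dataset()` runs the generative model forward and is the basis of
all simulation tests. Multi-mapping is emulated structurally rather than at
the sequence level: transcripts are grouped into gene-like ambiguity groups
(`group_size` isoforms), and a read reports each other group member with
probability `multimap_prob`, by default at full density (`dampening = 1`,
the worst case in which true and spurious alignments are
indistinguishable). Alignment densities follow the uniform-position model
$1/\max(\ell_k - L + 1, 1)$; positional or sequence bias is out of scope, so
the generator does not emulate it and passing tests say nothing about bias
robustness. Replicates are not modelled — the two samples are single pools —
so inter-replicate dispersion is likewise outside what the tests
demonstrate.

Two generator options define the benchmark scenarios:

* `effect_size` (log2 units): DE coordinates of $w$ are set to
  $\theta_k 2^{\pm\text{effect\_size}}$. Because alive mass is conserved,
  signs cannot all be free; the up-regulated group is chosen as the
  lowest-abundance alive transcripts holding an alive-mass fraction of about
  $1/(2^{\text{effect\_size}}+1)$, making the conserving rescale close to 1
  so realised folds sit near the target.
* `de_expressed`: places DE flags on transcripts at or above the median
  abundance. A "strong signal" benchmark with DE on a transcript whose
  abundance rounds to zero reads would be unrecoverable by any method, and
  DE benchmarks conventionally define DE on expressed transcripts.

Study conditions used by the acceptance suite, chosen once: oracle checks at
$K=3$, $r=s=2$, fixed $\pi=0.5$, $2\times10^5$ sweeps; prior-law check with
$10^5$ draws at $K=3$; FDR calibration with truth drawn from the model's own
prior ($\pi = 0.2$, $K = 200$, $r=s=2000$, 20 seeds — calibration is only
guaranteed when the data come from the model itself); recovery at $K=50$,
$r=s=5000$, $c_+=10$, unique mapping, `effect_size = 3` (8-fold, a large
change), `de_expressed = TRUE`; depth comparison at $r \in
\{10^3, 10^4\}$ averaged over five seeds. Default chain lengths are
10,000 sweeps with 2,000 burn-in; the calibration and depth studies use
4,000–6,000 sweeps, which the oracle comparisons show is ample at these
sizes.

## Numerical choices and edge cases

* All mass computations are in log space with `lgamma`; block-update
  configuration weights are normalised by their maximum before
  exponentiation.
* Duplicate (read, transcript) alignment records collapse to the maximum
  density; reads with no surviving alignment are dropped with a count.
* The SAM density denominator is floored at 1 so reads as long as the
  transcript keep a proper density.
* `q` ties in the calling rules break by original order (stable sort).
* Degenerate truths (no DE, or all DE) make AUROC undefined; reporting
  flags this instead of guessing.
* Beta draws for $\pi$ and the stick-breaking components use R's RNG inside
  the compiled samplers, so `set.seed()` reproduces chains bit for bit, and
  per-cluster seeds derive deterministically from the master seed.

## Known limitations

* The uniform-position alignment density is a simplification; supplying
  externally computed densities via the `.prob` format is the intended route
  for bias-aware analyses.
* Only two conditions are supported; the parameterisation extends to more
  conditions in principle but is not implemented.
* Clusterwise inference is exact only up to the boundary-state caveat above;
  for small problems `cluster = FALSE` gives the exact global model.
* The FDR guarantee is Bayesian (conditional on the model); under model
  misspecification the realised FDR can exceed the nominal level, as the
  difference between the calibrated and strong-signal simulations
  illustrates.
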