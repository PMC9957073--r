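---
title: "Modeling the tempo and mode of chromosome-number evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the tempo and mode of chromosome-number evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyorate)
```

## The model

karyorate treats the haploid chromosome number of the homogametic sex as
the state of a continuous-time Markov chain evolving along a
time-calibrated phylogeny.  Three events change the state:

* **fusion** (rate $\delta$): two chromosomes join, $n \to n - 1$;
* **fission** (rate $\gamma$): one chromosome splits, $n \to n + 1$;
* **whole-genome duplication** (rate $\rho$): $n \to 2n$.

All three rates are per lineage per million years and constant across
lineages and states.  The *simple* model pins $\rho = 0$ (fusions and
fissions only); the *complex* model frees all three.  Because insect
counts span roughly 1 to a few hundred, the chain lives on a bounded
contiguous range of counts; `rate_matrix()` builds the generator $Q$ with
$q_{n,n-1} = \delta$ (absent at the smallest state), $q_{n,n+1} = \gamma$
(absent at the largest), $q_{n,2n} = \rho$, and diagonal entries making
every row sum to zero.

Given tip counts, `log_likelihood()` computes the probability of the data
by the standard post-order pruning recursion: tip partials are indicator
vectors, each branch of length $t$ propagates partials through
$e^{Qt}$, and the root partials are combined with a root-state
distribution.  Estimation is Bayesian: `run_mcmc()` samples the posterior
of the free rates under independent exponential priors by per-parameter
slice sampling, and `summarize_posterior()` reduces pooled draws to
means, 95% highest-posterior-density (HPD) intervals, and the
**normalized rates ratio** $\delta / (\delta + \gamma)$.  The ratio is the
headline "mode" statistic: 0.5 means fusions and fissions balance, and
because stretching every branch by a constant rescales both rates by the
inverse constant, the ratio is unaffected by systematic errors in tree
depth — rates from differently calibrated trees are not comparable, but
their ratios are.

## Parameters that matter, and their defaults

* **State-space bounds** (`build_state_space()`): observed count range
  padded by 50% on each side, floored at 1.  The padding keeps boundary
  effects away from the data while keeping the generator small enough for
  dense matrix exponentials (a few hundred states at most in practice).
  Both the padding and the polyploidy boundary policy (`truncate_to_max`,
  i.e. doublings that would overshoot land on the largest state, versus
  `forbid`) are configurable because neither is dictated by the model
  itself; results with wildly different paddings should agree, and a
  sensitivity run with `forbid` is cheap.
* **Prior** (`mcmc_settings(prior_rate = 2)`): each free rate has an
  Exp(rate = 2) prior, mean 0.5 events/lineage/My.  An exponential prior
  with "shape 2" admits a second reading (mean 2); we adopt the
  small-mean reading because the prior's purpose is to discourage
  unrealistically high rates, and `prior_rate` is an explicit argument so
  the other convention is one keystroke away.
* **Run protocol**: 1000 generations, the first 700 discarded, starting
  values uniform on [0, 1].  For a posterior sample of trees the fit runs
  on 100 randomly drawn trees and keeps 3 evenly spaced post-burn-in
  draws per tree (generations 800/900/1000 under defaults), pooling 300
  draws; a single tree keeps all 300 post-burn-in draws.  Which 3 draws
  to keep is not pinned down by convention; evenly spaced draws are used
  for determinism, with per-tree seeds derived as master seed + tree
  index so pooled runs reproduce regardless of execution order.  These
  chains are short; `run_mcmc()` computes a two-half split-chain
  diagnostic on the retained draws and warns when it exceeds 1.1 rather
  than failing silently.
* **Root treatment** (`likelihood_settings()`): `weighted_by_partials`
  (FitzJohn-style, the default of the comparative-methods frameworks this
  package follows), `flat`, or `fixed` at a known count.  The choice is
  reported in output metadata because no convention is canonical.

## The synthetic-data generator

`simulate_tree()` grows a constant-rate birth-death tree conditioned on
its number of extant tips (simple rejection of extinct histories), and
`simulate_counts()` runs an exact Gillespie simulation of the
fusion/fission/polyploidy process down the tree.  The generative process
uses the same state space and boundary policy as the inference, so
parameter-recovery experiments compare like with like.  Two deliberate
simplifications:

* The simulator stops just before the first event after the $n$-th tip
  appears, so every pendant edge has positive length and, for pure-birth
  trees, the root depth is a sum of exponential waits with mean
  $(1/\lambda)\sum_{k=2}^{n} 1/k$ — a closed form the test suite checks
  the generator against.  With extinction the stopping rule is one of
  several defensible conventions; rate estimation never depends on it.
* One seeded random stream is consumed in fixed (cladewise) edge order.
  Identical configuration and seed give byte-identical output; adding
  tips re-randomizes earlier branches, which nothing downstream relies
  on.

What the generator does **not** emulate: real karyotype databases carry
taxonomic misidentifications, conflicting counts per species (the package
resolves these by median, rounded half up — a choice, since no published
convention exists), phylogenetic uncertainty beyond a fixed tree set, and
lineage-specific rate variation.  Passing recovery tests on synthetic
data therefore demonstrates the estimator is consistent under its own
assumptions, not that those assumptions hold for any particular insect
order.

## Recovery experiments and the root

A parameter-recovery experiment is only well posed when the inferential
model matches the generative one exactly — same state space, same root
information.  With the default FitzJohn root the root state is
re-estimated from the same tips whose drift away from the root carries
the $\delta$ versus $\gamma$ signal; on a single tree the shared ancestry
then leaves effectively one observation of net drift, and the posterior
mean of the ratio scatters widely (standard deviation about 0.14 across
200-tip replicates in our experiments) even though HPD intervals remain
honest.  Conditioning the root on the generating count
(`likelihood_settings("fixed", root_state = ...)`) restores the drift
signal: across 20 replicates of 200 tips simulated at
$\delta = \gamma = 0.2$, posterior-mean ratios concentrate at
$0.51 \pm 0.04$.  The acceptance suite runs exactly this matched design.
On real data the root count is unknown and the FitzJohn default applies
— with the corollary, worth remembering when reading any single-clade
ratio estimate, that the ratio's information content on one tree is
limited.

## Numerical choices

* $e^{Qt}$ acts on partial-likelihood vectors through one
  eigendecomposition of $Q$ per likelihood call ($O(K^2)$ per branch
  instead of $O(K^3)$).  For $\rho = 0$ the generator satisfies detailed
  balance, so $D^{1/2} Q D^{-1/2}$ is symmetric for
  $D = \mathrm{diag}((\gamma/\delta)^i)$ and a symmetric
  eigendecomposition is used — stable for any positive rates, where a
  general eigenbasis degenerates like $(\gamma/\delta)^{K/2}$.  Two
  safeguards police the similarity scaling: entries of a propagated
  partial below the transform's own round-off noise floor are zeroed,
  and since a stochastic propagation of partials scaled to maximum 1 can
  never exceed 1, any violation reroutes that branch through a Padé
  matrix exponential (also the fallback whenever no reliable
  eigendecomposition exists, e.g. the defective $\delta = 0$ or
  $\rho > 0$ corners).
* Partials are rescaled to a maximum of 1 at every edge with accumulated
  log scalers (no underflow on large trees).  A per-edge conditional
  factor at or below $10^{-12}$ — the noise floor of the propagation —
  is treated as an impossible dataset and the log-likelihood returns
  $-\infty$; genuinely impossible data (for example, zero rates with
  unequal tip counts) are reported the same way.  The practical effect
  is that parameter corners whose posterior mass is astronomically small
  (hundreds of log units below the mode) may be truncated to $-\infty$
  rather than evaluated to low precision; no reported posterior can be
  affected by mass that small.
* Tiny negative matrix-exponential entries from round-off are clamped to
  zero; `transition_matrix()` then renormalizes rows (relative effect
  below $10^{-12}$).
* HPD intervals are the shortest contiguous window over the sorted draws
  containing `ceiling(mass * n)` of them; ties break toward the lowest
  start for determinism.
* The ratio is summarized as the mean of per-draw ratios, not the ratio
  of mean rates: the two differ whenever draws of the rates and of their
  sum are correlated, and only the per-draw summary is invariant to
  joint rescaling of the rates (the tree-depth argument above).
* The slice sampler uses a unit initial bracket with stepping-out and
  shrinkage; random-walk Metropolis on log rates is available as a
  cross-check (`sampler = "metropolis"`).

## Analysis procedures

**Clade-removal sensitivity** (`sensitivity_removal()`): comparative rate
estimates can be driven by a single extreme clade.  The procedure refits
the simple model with all tips of a chosen genus pruned (the genus can be
picked automatically as the highest-variance genus with at least 10
records, `pick_high_variance_genus()`) and reports the percent change of
each posterior-mean parameter.  Both fits share one seed so the
difference is not MCMC noise.  The scale of the percent changes on real
data depends on the clade's weight; the package's own checks verify the
direction on synthetic data with a planted fast-evolving subclade.

**Sex-chromosome fusion signal** (`fusion_signal()`): transitions from XO
to XY, and from XY to neo-XY, are typically created by an autosome fusing
with a sex chromosome, which removes one autosome pair.  Within every
genus containing species of both systems the procedure compares mean
autosome counts and reports the fraction of genera where the derived
system's mean is strictly lower (ties do not count).  When only haploid
counts are available, autosomes are derived as haploid count minus one
per-system sex-chromosome (the homogametic haploid set carries one); the
offset convention is configurable but cancels out of the within-genus
comparison.  The statistic is a tabulation, not a model fit — it makes no
correction for phylogeny within genera.

## Problem sizes used in the test suite

The packaged checks run at desk scale, chosen to keep the full suite in
the tens of minutes on one core while leaving Monte-Carlo error well
inside each assertion's tolerance: exhaustive pruning-versus-enumeration
checks on all tree shapes up to 4 tips with up to 6 states; 10,000
Gillespie replicates against a matrix-exponential row (total variation
tolerance 0.02); 20 recovery replicates of 200 tips at reduced chain
length (400 generations / 200 burn-in); a 20,000-generation chain against
a dense-grid posterior on a 2-state toy problem (total variation
tolerance 0.05); and 5 seeded replicates of the planted-subclade
sensitivity check.

## Known limitations

* Rates are state-independent; no per-chromosome scaling, no
  demi-polyploidy, no chromosome-arm (fundamental number) modeling.
* Chromosome change is anagenetic only — no cladogenetic change, no
  character-dependent diversification.
* No co-evolving binary character channel; no ancestral-state
  reconstruction; no marginal-likelihood model comparison (the two
  models are reported side by side instead).
* Name matching is exact after case/underscore normalization — no fuzzy
  taxonomy reconciliation, by design, so every match is auditable.
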