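---
title: "Comparative MRF analysis of differential gene regulation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative MRF analysis of differential gene regulation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmrf)
```

## The problem

A perturbation experiment measures gene expression before (*control*) and
after (*non-control*) an external stimulus — a drug, radiation, a disease
state. When the samples fall into two groups (two populations, two
phenotypes, two treatment histories), a gene can respond to the perturbation
in one group and not in the other. Such a gene is *differentially regulated*
(DR), as opposed to *equally regulated* (ER) genes whose response status
agrees across groups. A DR gene may be *primarily* differentially regulated
(PDR) — changed by the perturbation itself — or *secondarily* (SDR) —
dragged along through its interactions with other responding genes. `cmrf`
identifies and ranks candidate PDR genes from four expression matrices
(control and non-control for each group) and a directed gene interaction
network.

## The hidden-variable hierarchy

Three layers of discrete hidden variables sit above the data:

* **States** `S_A[i], S_B[i] ∈ {0, 1}`: whether gene *i* is differentially
  expressed (DE, 1) or equally expressed (EE, 0) within each group.
* **Regulation** `Z[i] ∈ {1..4}` encodes the pair `(S_A, S_B)`:
  1 = DE/DE, 2 = DE/EE, 3 = EE/DE, 4 = EE/EE. Values 2 and 3 are the DR
  cases; `encode_regulation()` and `decode_interaction()` expose the maps.
* **Interactions** `X[ij] = 4 (Z_i − 1) + Z_j ∈ {1..16}`, one per directed
  edge of the *extended network*: the input network plus a *metagene* that
  represents the perturbation and points at every gene. The metagene is DE
  in both groups by convention, so its regulation value is pinned at 1 and
  its edges can only take values 1–4; values 2 and 3 on a metagene edge mean
  the target gene is DR because of the perturbation itself — the PDR signal.

## Prior: a Markov random field over interaction variables

The prior lives on an MRF whose nodes are the `X[ij]` variables. Two nodes
are neighbors when they share a source or a target and the genes in the
remaining position interact; neighbor slots whose interaction does not exist
as a network edge are kept *virtually*, their values derived from the
current regulation vector. Seven feature functions weight the cliques:

* `F1 = [X = 2]`, `F2 = [X = 3]`, `F3 = [X ∉ {2,3}]` — how common the two
  DR-because-of-the-source patterns are, versus everything else;
* `F4` — the number of the source's incoming regulators whose regulation
  value matches the source's (agreement flowing into the edge);
* `F5` — the number of the target's outgoing regulatees whose regulation
  value matches the target's (agreement flowing out of it);
* `F6 = [Z_i ∈ {1,4}]`, `F7 = [Z_j ∈ {1,4}]` — a preference for either
  endpoint being equally regulated, encoding the belief that most genes
  respond similarly in comparable groups.

Each coefficient `gamma_1..gamma_7` scales its feature inside an
exponential-family potential. The global normalizing constant is never
computed: all inference goes through the node-wise *conditional* prior
(`conditional_prior()`), a softmax over the 16 candidate values of one node
with every neighbor held fixed — the standard pseudo-likelihood route. The
conditionals are evaluated in log space with max subtraction.

## Likelihood: hierarchical Gaussian marginals

Measurements of one gene in one sample set are modeled as
`z_k ~ N(mu, sigma²)` with a latent set mean `mu ~ N(mu0, tau²)` shared
genome-wide; integrating `mu` out gives a multivariate normal with
covariance `sigma² I + tau² J`, evaluated in closed form from the sufficient
statistics `(n, Σz, Σz²)` (`marginal_loglik()`). A DE gene uses independent
latent means for its control and non-control sets; an EE gene pools the two
sets under a single mean. The DR-versus-ER contrast therefore rests on an
Occam factor: pooling 2n null samples beats splitting them by roughly
`log(n)/2` log-units — about 1.4 at n = 33 and 2.5 at n = 155. This number
matters below. The metagene's likelihood is fixed at one for DE and zero for
EE; the resulting `-Inf` log-likelihoods are propagated as absorbing
sentinels, which is also how metagene edges end up restricted to values 1–4
in every posterior.

`theta_Y = (mu0, sigma, tau)` is a single global triple; there are no
per-gene variances. Translation invariance (shifting all data and `mu0`
together) holds exactly and is tested.

## Fitting

`cmrf_fit()` alternates three steps after a per-gene, per-group two-sample
pooled t-test initialization of the states (level `ttest_alpha`, default
0.05; constant-data degeneracies fall back to p = 1 on equal means):

1. **`theta_Y`** maximizes the summed edge likelihood of the current
   assignment by differential evolution (DE, rand/1/bin; population 40, 100
   generations, crossover 0.9, weight 0.8 — the optimizer is deterministic
   given a seed, and every seed is derived from the single config seed).
   Bounds: `mu0` spans the data range; `sigma`, `tau` span `[1e-3, 10] ×
   sd(data)`.
2. **`gamma`** maximizes the summed log conditional prior, also by DE,
   within `gamma_bounds` (default `[-10, 10]` per coefficient; `gamma_fixed`
   pins chosen coefficients). This objective is concave, so DE's answer can
   be (and in development was) cross-checked against quasi-Newton ascent.
3. **ICM** sweeps the genes in network order; each gene evaluates its four
   state pairs and keeps the best, with ties kept at the current state.
   A candidate is scored over every interaction node whose posterior factor
   depends on that gene's regulation value — the node set with the gene (or
   one of its regulators/regulatees) in the matching position. Scoring the
   full dependency set makes each update exact coordinate ascent, so the
   pseudo-log-likelihood never decreases within a sweep; re-scoring only the
   gene's own edges, a tempting shortcut, cannot guarantee that.

The loop stops when a sweep flips no state — the discrete fixed point — or
after `max_cycles` (default 20). Parameter movement between cycles is
recorded in the trace for diagnostics but is not part of the stopping rule:
the DE runs are re-seeded each cycle, so their stochastic jitter never falls
below a meaningful tolerance, while the state fixed point is well defined.

### Prior strength, and when to restrain it

The DR-versus-ER decision for a gene with no real signal in the second group
is a contest between the Occam factor above (≈ 1.4–2.5 log-units per
incident edge) and the fitted equal-regulation preference (`gamma_6`,
`gamma_7`, plus the `gamma_1..gamma_3` contrast). When almost every observed
interaction node is ER, the prior fit faces quasi-complete separation:
nothing in the data prevents `gamma_6`/`gamma_7` from climbing to their
bound, after which each ICM sweep erases a few more marginal DR calls and
the next prior fit grows harsher — a ratchet that ends with every gene
equally regulated. On genuinely weak, small-sample data this is the model
saying "no evidence of differential regulation", and the permutation null
(`permutation_test()`) behaves accordingly. On well-powered data it is a
failure mode, and the remedy is to restrain those two coefficients:
`restricted_gamma_bounds()` caps `gamma_6, gamma_7` in `[0, 2]` — just
under the n = 155 Occam factor, so data of that size can overrule the prior
while the preference still regularizes — and `gamma_fixed = c(gamma6 = 0,
gamma7 = 0)` removes the preference entirely (used by
`significance_experiment()`, whose n = 33 could never overcome a free
prior). The default `cmrf_fit()` bounds stay free, which is the right
behavior for null screening; the benchmark defaults document the restrained
choice.

## Ranking

DR genes (fitted `Z ∈ {2, 3}`) are ranked by `rank_pdr()`:

* **`reverse_ll`** (default): the log-likelihood of the *opposite*
  assignment (`loglik_Z` at 3 for a gene fitted at 2 and vice versa),
  ascending — the worse the reverse hypothesis fits, the stronger the DR
  call. This is the score whose distribution `significance_experiment()`
  tracks across planted shift sizes.
* **`metagene_lik`**: the likelihood of the gene's metagene edge at its
  fitted value, descending.

`posterior_interaction()` exposes the full 16-value posterior of any edge.
Baselines for comparison: `ttest_rank()` per group and `unified_rank()`,
which scans two group rankings and drops genes that appear in both top-k
prefixes (the equally regulated intersection). The prefix intersection is
inclusive of position k itself, per its defining formula; a gene ranked
identically in both groups is therefore never emitted — two identical
rankings produce an empty unified list. When both group candidates qualify
at the same position, the group-A gene is appended first. `sensitivity_at_k()`
scores any ranking against a truth set.

## Synthetic benchmarks

The generators produce the package's test beds; none of them reuse real
microarray data, so their defaults state what they emulate.

* `generate_control()` draws per-gene `mu_i ~ U(6, 9)` and
  `sigma_i ~ U(0.8, 1.2)` and Gaussian samples — normalized log-scale
  intensities of expressed genes with replicate noise of order one, 155
  samples by default (the scale of a large population study). Passing `mu`/
  `sigma` reuses a gene population, which is how the two groups of a
  benchmark share biology while keeping independent measurement noise.
* `select_affected_sets()` / `build_two_group_truth()` implement the
  breadth-first construction: random primaries, secondaries labelled with
  probability `1 − (1 − q)^eta` (`q = 0.4`; `eta` counts currently-DE
  regulators at visit time), three disjoint sets of which one is applied to
  both groups and the other two to one group each; the group-specific
  primaries are the planted PDR genes.
* `generate_two_group()` shifts affected genes' non-control means by
  `± d_p` (primary) or `± d_s` (secondary) *per-gene standard deviations*
  with unchanged variance; the sign is drawn once per gene and group.
  `dp_grid()` returns the 30-step shift schedule with its secondary-shift
  rule (`d_s = 1` once `d_p > 1.1`, else `d_s = d_p / 2`).
* `sigmoid_propagate()` models network transmission: primary genes get a
  relative change `deviation ∈ (0, 1]`; each other gene receives the signed,
  weighted sum of its regulators' changes, normalized by its regulator count
  plus one basal slot, thresholded at `h = 0.1`, and squashed through a
  steep logistic (`beta = 0.01`, gain `alpha = 1`, weights `k_ac = k_in =
  1`). The normalization makes each hop a strict contraction, so cascades
  attenuate with distance and terminate instead of saturating the network —
  without it, a dozen primaries on a scale-free graph perturb most of the
  genome in both groups and the notion of a group-specific planted truth
  collapses. Unreachable genes are untouched; every sample of an affected
  gene is scaled by `1 + delta`.
* `random_scalefree_network()` grows a preferential-attachment graph and
  orients each edge at random, so hubs both regulate and are regulated and
  every gene tends to have in- and out-edges — without that, half the genes
  have out-degree zero and the `F6` feature faces exactly the separation
  pathology described above.
* `sigmoid_benchmark()` wires these into the full comparison: 300 genes,
  155 samples per matrix, 12 shared primaries (most of a perturbation
  response is common to comparable populations) plus 6 + 6 group-specific
  ones, deviation 0.8, fit, PDR ranking, and sensitivity at rank 15 for both
  the model and the t-test unified-rank baseline. Draws whose cascades reach
  a group-specific primary in the *other* group are rejected and redrawn, so
  the planted PDR labels are true by construction.

What these simulations do not contain: probe-level noise, missing values,
batch effects, heavy-tailed expression, per-gene variance structure beyond
the drawn `sigma_i`, or feedback dynamics richer than the contraction
transfer. Passing benchmarks therefore demonstrates correctness of the
machinery and the qualitative method ordering under the stated model, not
performance on any particular real dataset.

## Problem sizes and runtime choices

The shipped tests run the structural and oracle checks at full precision and
the simulation reproductions at deliberately small scale: the benchmark at
300 genes × 5 seeds (about a minute of fitting), the shift-grid experiment
at 100 genes × 9 grid points, and the null screens at 60 genes × 33 samples.
The shift-grid experiment shares its network, truth, controls and non-control
noise (common random numbers) across grid points, so its trend reflects the
planted effect rather than regeneration noise. Unit-test fits shrink the DE
generation count; all defaults remain those documented above.

## Known limitations

* The DR evidence per group is an Occam factor of order `log(n)/2`, so the
  method is inherently small-sample-shy; with tens of samples it will
  declare nothing DR unless the equal-regulation prior is restrained.
* A single global `(mu0, sigma, tau)` misfits data whose per-gene variances
  span orders of magnitude; log-transform (or otherwise variance-stabilize)
  expression first.
* Activation/inhibition signs are ignored by the prior (the feature
  functions are sign-blind by design); only the propagation simulator uses
  them.
* The pseudo-likelihood surface is multimodal in the discrete states; ICM
  finds a coordinatewise optimum dependent on the t-test initialization.
* Edges of the input network are trusted as-is: no weighting, no confidence
  filtering, no undirected support.
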