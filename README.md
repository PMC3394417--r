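# cmrf

Comparative Markov random field analysis of differential gene regulation in
two-group perturbation experiments.

## The problem

Perturbation experiments measure gene expression before (*control*) and
after (*non-control*) an external stimulus — a drug, radiation, a disease.
When the samples split into two groups (two populations, two phenotypes),
some genes respond to the perturbation in one group but not the other:
they are *differentially regulated* (DR). A DR gene may be **primarily**
differentially regulated (PDR) — changed by the perturbation itself — or
**secondarily** (SDR) — changed through its interactions with other
responding genes. `cmrf` identifies and ranks candidate PDR genes from four
expression matrices and a directed gene interaction network, for analysts
who have two-group perturbation expression data and a pathway-derived edge
list.

## The model

Per gene and group a binary state `S` marks differential expression; the
pair `(S_A, S_B)` encodes a regulation value `Z ∈ {1..4}` (2 and 3 are the
DR cases); each directed edge `g_i → g_j` of the network — extended by a
*metagene* `g0` that represents the perturbation and points at every gene —
carries an interaction variable `X_ij = 4(Z_i − 1) + Z_j ∈ {1..16}`.
A Markov random field over the `X_ij` with seven feature functions
(DR frequency, neighbor agreement along edges, and a preference for equal
regulation) forms the prior `p(X | θ_X) ∝ exp(Σ γ_k F_k)`; a hierarchical
Gaussian marginal likelihood `∫ Π N(z | μ, σ²) N(μ | μ0, τ²) dμ` scores DE
(split latent means) against EE (pooled) per gene and group. Inference
maximizes the pseudo-likelihood `Π_ij p(X_ij | X_-ij, Y)` by alternating
differential evolution over `θ_Y = (μ0, σ, τ)` and `γ_1..γ_7` with iterated
conditional modes over the gene states. DR genes are then ranked by the
log-likelihood of the *reverse* hypothesis (DE and EE groups swapped):
the lower, the stronger the PDR candidate. See the methods vignette
(`vignettes/cmrf-methods.Rmd`) for the full account.

## Worked example

Simulate a small benchmark with known ground truth, fit, and rank:

```r
library(cmrf)

b <- sigmoid_benchmark(M = 300, N = 155, deviation = 0.8, seed = 1)
b$fit
#> cmrf_fit: 300 genes; DR: 21 (A-only 15, B-only 6); cycles: 2; converged: TRUE
#> theta_y: mu0 = 7.774, sigma = 1.056, tau = 1.619
#> gamma: 2.06 1.38 1.33 0.529 1.11 2 1.85

head(as.data.frame(b$ranking), 3)
#>   rank gene     score
#> 1    1 g209 -2847.963
#> 2    2 g281 -2736.424
#> 3    3 g235 -2647.063

b$sensitivity_cmrf   # fraction of the 12 planted PDR genes in the top 15
#> [1] 1
b$sensitivity_ttest  # t-test + unified-rank baseline on the same data
#> [1] 0.75
```

The fit found 21 DR genes; the ranking's `score` is the reverse-hypothesis
log-likelihood (ascending, so the top gene's reverse hypothesis fits worst),
and all 12 planted PDR genes land in the top 15 here, against 9 of 12 for
the t-test baseline.

On your own data:

```r
net <- read_edge_list("network.tsv")            # source  target  [sign]
dat <- read_expression("A_ctrl.tsv", "A_non.tsv",
                       "B_ctrl.tsv", "B_non.tsv") # genes x samples, TSV
fit <- cmrf_fit(restrict_to_network(dat, net), net,
                fit_config(seed = 1))
rank_pdr(fit)
```

A thin command-line shell (`inst/scripts/cmrf`) drives the same pipeline
from a YAML config with subcommands `fit`, `rank`, `simulate`,
`significance`, and `permute`.

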