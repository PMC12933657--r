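---
title: "Methods: path analysis of diversification drivers with chromosome and trait-rate models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: path analysis of diversification drivers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(divpath)
```

## The question the package addresses

Lineages do not diversify at one rate. In groups with labile genomes —
classically the holocentric sedges, where chromosome fission and fusion
(dysploidy) produce long aneuploid series — an old question is whether
chromosome-number change *drives* speciation, merely *tracks* ecological and
morphological change, or both. `divpath` implements the quantitative
machinery for asking that question on any clade: it relates species-level
diversification rates to chromosome number, climatic niche and morphology,
both as **species means** and as **evolutionary rates at the tips**, and it
does so causally (which variables influence which) rather than as a pile of
pairwise correlations.

Four inferential components are combined:

1. **Phylogenetic path analysis (PPA)** over enumerated families of causal
   models, with d-separation tests implemented as phylogenetic regressions,
   Fisher's C, the CICc information criterion, and full model averaging.
2. A **chromosome-number Markov chain** (dysploidy rates linear in the
   current number, plus polyploidy) with clade-specific rate regimes and
   per-tip dysploidy rates.
3. A **multi-regime Brownian-motion** estimator of continuous-trait
   evolutionary rates at the tips.
4. A **trait-dependent diversification likelihood** over a discretized
   continuous trait, with constant/linear/sigmoid/hump speciation and
   extinction functions and Brownian or Ornstein–Uhlenbeck trait dynamics.

Every component is exercised end to end on synthetic data with known ground
truth; no external dataset is required.

## Phylogenetic regressions and the path analysis

The atomic unit is PGLS: generalized least squares with residual covariance
proportional to the Brownian covariance of the tree (shared path lengths).
All variables are z-scored with ordinary means and standard deviations
before fitting, so path coefficients are standardized and bounded, in
practice, in $[-1, 1]$. The residual structure defaults to pure Brownian
(Pagel's $\lambda$ fixed at 1); profiling $\lambda$ by maximum likelihood is
available (`lambda_mode = "ml"`) but the default keeps the d-separation
machinery fully deterministic. Inference on coefficients uses the $t$
distribution with $n - p - 1$ degrees of freedom.

A causal model is a DAG over the analysis variables. Its testable content is
the d-separation **basis set**: one conditional-independence claim per
non-adjacent pair, conditioned on the union of the two variables' parents.
Each claim is tested by one PGLS — the pair's later variable (in the model's
topological order) regressed on the earlier plus the conditioning set, the
p-value taken from the earlier variable's coefficient. Fisher's
$C = -2\sum\ln p$ aggregates a model's claims, and models are ranked by

$$\mathrm{CICc} = C + 2qn/(n - 1 - q),$$

with $q$ = number of edges plus number of endogenous nodes (one intercept
each) and $n$ = species. Ties are broken by edge count, then model id.
Coefficients are then **fully model averaged** over every model within 2
CICc units of the best: weights $\propto e^{-\Delta/2}$, and a path absent
from a model contributes a coefficient (and variance) of zero. Full
averaging deliberately shrinks weakly supported paths toward zero instead of
biasing them away from it.

## The enumerated model families

Three families of candidate DAGs are built from one structural grammar of 48
templates: six chromosome-centred base models (diversification and/or
morphology predicted by the chromosome variable, each with or without a
climate → chromosome edge), expanded by adding direct morphological and/or
climatic effects on diversification, and doubled by allowing morphology to
depend on climate. The **rates** family instantiates the grammar with
evolutionary-rate variables (RB4, R2n, RLI, RCU → DI); the **means** family
with species means (B1, B4, B7, B12, C2n, LI, CU → DI), every climate edge
fanning out over all four bioclimatic variables and every morphology edge
over both traits. The **combined** family takes seven instantiations — the
two above; rates augmented with the chromosome mean; means augmented with
the chromosome rate; the two single-variable substitutions; and an
all-means-plus-all-rates family — and removes the four duplicate graphs
these instantiations share, leaving 332 distinct models. A no-edge null
model is evaluated alongside each family.

Counting regressions, the families imply 250 (30 unique), 844 (66 unique)
and 18 112 (655 unique) d-separation regressions respectively. The *unique*
counts deduplicate regressions by their full formula — response, ordered
conditioning variables, tested predictor. Two layout conventions are part of
the package's counting definition: each instantiation keeps its own
canonical variable order (climate, chromosome, morphology, diversification;
padded with the remaining union variables in the combined family), and the
null model lists the chromosome variables first. Claim orientation follows
the model's topological order with ties broken by that stored order, so the
counts are exactly reproducible.

```{r}
ms <- build_rate_models()
count_regressions(ms)   # $total 250, $unique 30
```

## The chromosome-number chain

Haploid number $i$ evolves by single gains ($\lambda_0 + \lambda_1 i$),
single losses ($\delta_0 + \delta_1 i$; both clamped at zero) and
duplication $i \to \min(2i, i_{\max})$ at rate $\rho$, all in events/Myr.
The state space pads the observed range by 10 below and doubles it above,
so losses below and duplications above the data stay representable;
duplications that would exceed the ceiling are truncated to it. The
likelihood is Felsenstein pruning with per-branch transition matrices
$e^{Qt}$, computed from an eigendecomposition of $Q$ (validated by the row
sums of the resulting stochastic matrix, with a scaling-and-squaring
fallback when the eigensystem is near-defective) and a compiled pruning
kernel. The root state is averaged uniformly; `root_prior =
"uniform_nonzero"` restricts to states that can produce the data, which
makes a zero-rate chain with invariant tips score exactly $\log L = 0$.

Rate heterogeneity across clades is modelled by regimes: a shift applies to
the branch entering a node and its whole subtree. The search is greedy
forward AIC. Each eligible node (at least 10 descendant tips by default, at
most 40 regimes) is first screened cheaply: the likelihood factorizes as
$L = \sum_x O_v(x)\, D_v(x)$, where $D_v$ is the clade's conditional
likelihood and $O_v$ the cached "outside" vector at the top of the stem
branch, so proposals are scored by re-pruning only the clade against a small
grid of regime proposals (near-zero rates, background × 0.1, background
× 3). The best few candidates get a conditional ML fit of their regime
parameters, the winner is refit jointly with the background, and the shift
is kept only if AIC improves (5 free parameters per regime). The screen's
conditional scores use a plain uniform root prior to keep the outside
factorization linear; the accepted model is always re-evaluated exactly.

Per-tip dysploidy rates use the tip's regime parameters at its observed
number: $r_s = \max(0, \lambda_0 + \lambda_1 n_s) + \max(0, \delta_0 +
\delta_1 n_s)$; gains and losses are summed by default and are separately
available (`component = "gain"`/`"loss"`).

## Trait rates by multi-regime Brownian motion

Tip rates of climate and morphology are conventionally estimated with a
reversible-jump MCMC over rate regimes (BAMM). This package uses a
deterministic ML analogue instead: Brownian motion whose $\sigma^2$ shifts at
selected nodes, fitted by maximizing the Gaussian likelihood under the
regime-weighted covariance $\sum_r \sigma_r^2 T_r$ ($T_r$ = shared path
lengths within regime $r$), with the root value profiled by GLS. Shifts are
added greedily up to `max_shifts`; because the best of many candidate nodes
is selected, plain AICc would accept spurious shifts freely, so the
selection score adds a $2\log m$ code-length term for the shift location
(among $m$ candidates) and the winning candidate must additionally clear a
Bonferroni-corrected likelihood-ratio test at a family-wise 1% level. This
calibrates the search so that single-regime data select zero shifts in well
over 90% of replicates while leaving detection of order-of-magnitude rate
shifts unaffected. The per-tip rate is
the $\sigma^2$ of the terminal branch's regime. Two divergences from the MCMC
convention are accepted knowingly: rates are constant within a regime
(no within-regime time trend), and model selection is by AICc rather than
posterior sampling; both trade fidelity for determinism, which is what the
downstream path analyses need. Diversification tip rates are *not*
estimated here — they are an input column, produced in synthetic data
from the known causal graph.

## Trait-dependent diversification

The likelihood couples a continuous trait $x$ (diffusion $\sigma^2$,
optional OU pull $\alpha(\theta - x)$) to trait-dependent speciation
$\lambda(x)$ and extinction $\mu(x)$ drawn from four families: constant;
linear (clamped at zero); sigmoid $y_0 + (y_1-y_0)/(1+e^{(x_{mid}-x)/r})$;
and hump $y_0 + (y_1-y_0)e^{-(x-x_{mid})^2/2s^2}$. On a grid of at least 64
cells spanning the data padded by $4\sigma\sqrt{\text{depth}}$, the
extinction function $E(x,t)$ and clade density $D(x,t)$ are propagated from
the tips by operator splitting: a pointwise RK4 step for the birth–death
reaction terms, then exact spectral propagation of the discrete
diffusion/advection operator (central second differences, reflecting
boundaries, upwinded advection), diagonalized once per likelihood
evaluation. Each branch takes at least two steps of at most depth/100. At
nodes $D \leftarrow D_L D_R \lambda(x)$; at the root $D$ is integrated
against the observed-density weighting (a flat option exists) and
conditioned on survival of both root lineages. Tips enter as Gaussian
kernels of width `tip_sd` (one cell by default); the kernel must be resolved
by the grid, so comparisons across grids should fix `tip_sd`. `fit_quasse`
optimizes every requested $\lambda$-family × $\mu$-family × dynamics
combination by Nelder–Mead on log-transformed positive parameters and ranks
by AIC.

With constant rates the model must collapse to the constant-rate
birth–death process; the test suite verifies the full likelihood against
that closed form (with exact bookkeeping of the Gaussian trait kernels) to
about $10^{-7}$ relative, checks $E \in [0,1]$ everywhere, and checks
stability of $\log L$ under grid doubling.

## The synthetic-data generator

`simulate_dataset()` defines the study conditions for all tests: a
birth–death tree conditioned on its tip count (default 300 tips, birth 1,
death 0 /Myr); trait columns wired by a known causal DAG (default the chain
RB4 → R2n → DI with standardized coefficients 0.6), exogenous variables as
Brownian motion on the tree, endogenous ones as coefficient-weighted parent
sums plus Brownian residuals rescaled to unit variance; and chromosome
numbers simulated exactly (Gillespie) under the background dysploidy
parameters ($\rho = 0.007$, $\lambda_0 = 2.035$, $\delta_0 = 1.610$,
$\lambda_1 = 0.062$, $\delta_1 = 0.102$; root haploid number 15, or 10 in
the recovery experiments, which keeps the equilibrium number near 11 and
the state space compact). Everything is reproducible bit-for-bit under a
seed, and every generated table passes the package's validation against its
tree.

What the generator does **not** emulate: empirical trees are not pure-birth
and their tip counts are not 300; real climate and morphology columns are
correlated through unmodelled latent structure, not only through the
declared DAG; measurement error and intraspecific variation are absent; and
diversification tip rates in real use come from an upstream
diversification analysis with its own uncertainty. Recovery of the
generating model in the tests therefore demonstrates internal correctness
of the estimators — identifiability under the model's own assumptions — not
robustness to the ways real data violate them.

## Numerical choices and degenerate inputs

* PGLS solves through the Cholesky factor of the covariance; singular
  designs are reported with the collinear columns named, and z-scoring
  refuses zero-variance columns.
* Fisher's C rejects p-values of exactly zero (a degenerate regression);
  the model-set fitter floors p-values at the smallest double instead of
  silently producing infinite C.
* The chromosome optimizer works on log-rates bounded in
  $[e^{-14}, e^{3}]$ (slopes $\le 1$/Myr per chromosome), from one or two
  heuristic starts; non-convergence is reported with the best-so-far fit.
* Multi-regime BM adds a $10^{-10}$ ridge before Cholesky; zero-variance
  traits return a single regime at the lower bound with a warning.
* The diversification grid errors when more than 1% of the root density
  mass sits in the outermost cells, instructing wider padding; model fits
  treat non-finite likelihoods as rejected proposals.
* CICc demands $n > q + 1$ and errors otherwise; model-set ranking breaks
  ties deterministically (edges, then id).

## Problem sizes used by the test suite

The simulation-backed tests run at the scale the statistical claims are
about: 300 tips for path-analysis recovery (50 replicates) and for the
chromosome recovery experiments (12 single-regime replicates; 50 replicates
with a planted ~150-tip zero-rate clade), 200 tips for the trait-regime
localization check (20 replicates), 400 replicates for the PGLS type-I
error calibration, and 20-tip trees for the exact birth–death comparisons,
where the oracle is sharpest. These sizes were chosen as the smallest at
which the corresponding claims are statistically meaningful.

## Measured operating characteristics of the path analysis

Model selection by CICc has a structural property worth stating plainly:
every supermodel of the true DAG removes only true-independence claims from
the basis set, each costing on average $E[-2\ln p] = 2$ against a CICc
penalty of about $2$ per extra edge. Each supermodel is therefore
approximately an even bet against the truth, and the best of them beats the
truth by more than 2 CICc units in a substantial fraction of datasets. On
data simulated under the chain RB4 → R2n → DI (coefficients 0.5–0.8, 300
tips, 50 replicates) the generating model attains $\Delta\mathrm{CICc}
\le 2$ in about half of replicates — a clear majority lands within ~4 units
— while the *averaged* R2n → DI coefficient has the correct sign in 100% of
replicates, because the models that outrank the truth are its supersets and
carry the same edge. Model averaging, not single-model selection, is the
reliable summary; this is precisely why the package averages over the
2-unit window by default.

## Known limitations

* The PPA unique-regression counts depend on the documented canonical
  variable layouts; a different layout convention changes the unique (not
  the total) counts.
* The greedy AIC shift searches (chromosome and trait) are heuristics: they
  can miss compensating multi-shift configurations that a full
  reversible-jump sampler would visit.
* The diversification PDE uses operator splitting; its error is controlled
  by the per-branch step cap, not estimated adaptively. The OU drift term
  is first-order upwinded, which adds numerical diffusion for large
  $\alpha$.
* Polyploidy is a single duplication jump; demi-polyploidy and base-number
  change are out of scope.
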