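---
title: "Mobile resistance genes and microbiome stability: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mobile resistance genes and microbiome stability: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgtstab)
```

## The question

A stressor pulse — an antibiotic dose, a pollutant spike — perturbs a
microbial community. If one taxon carries a resistance gene, and that gene
can move into other taxa by conjugation, the consequences for the community
are not obvious: the carrier is protected, recipients become protected, but
taxa that never receive the gene may face *stronger* competition from the
protected ones. `hgtstab` quantifies these effects with ensemble
simulations of a mechanistic model.

## The model

Each taxon is split into a gene-free and a gene-bearing population. Per
taxon $i$:

$$
\frac{dX^s_i}{dt} = X^s_i\Big(r_i - s_i(X^s_i + X^r_i)
  + \sum_{j \ne i} a_{ij}(X^s_j + X^r_j)\Big)
  - \sum_j \gamma_{ij} X^s_i X^r_j - \beta_s D\, X^s_i
$$
$$
\frac{dX^r_i}{dt} = X^r_i\Big((r_i - c) - s_i(X^s_i + X^r_i)
  + \sum_{j \ne i} a_{ij}(X^s_j + X^r_j)\Big)
  + \sum_j \gamma_{ij} X^s_i X^r_j - \beta_r D\, X^r_i
$$

Assumptions worth making explicit:

* **Interactions act on totals.** A partner taxon affects taxon $i$ through
  its total abundance $X^s_j + X^r_j$; carrying the gene does not change how
  a taxon interacts ecologically.
* **Transfer is mass action.** The conjugative flux into taxon $i$ is
  $\sum_j \gamma_{ij} X^s_i X^r_j$, summing over all donors including the
  recipient taxon's own gene-bearing cells ($j = i$), so within-taxon and
  between-taxa transfer are both present.
* **Resistance is costly but not absolute.** Gene-bearing cells grow at
  $r_i - c$ and are still killed at the reduced rate $\beta_r D$
  ($\beta_r < \beta_s$).
* **Dynamics are deterministic.** No demographic noise; all stochasticity
  is in community construction.
* **Segregation loss** (gene-bearing cells reverting at rate $\delta$) is
  available but off by default; the default variant returns revertants to
  the gene-free compartment (cells are conserved), with a pure-loss switch
  (`segregation_pure_loss`) since the removal convention is a genuine
  modelling choice.

## Parameters

`hgt_params()` bundles the standard set used in all analyses:

| parameter | default | meaning |
|---|---|---|
| `N` | 10 | taxa per community |
| `C` | 0.7 | probability an off-diagonal interaction term is present |
| `sigma` | 0.015 | half-normal scale of interaction magnitudes (growth-rate per unit abundance) |
| `s` | 0.1 | self-inhibition (sets the dynamical timescale; carrying capacity $r/s$) |
| `positivity` | 0.5 | fraction of present interaction terms that are positive |
| `c_cost` | 0.005 | growth cost of the gene (5% of the baseline growth rate) |
| `gamma_bar` | 5e-4 | mean per-cell conjugation rate; swept over $[10^{-6}, 10^{-2}]$ |
| `gamma_noise_rel` | 0.1 | relative sd of per-pair transfer noise, $\gamma_{ij} = \bar\gamma(1 + 0.1 Z_{ij})$, truncated at 0 |
| `beta_s`, `beta_r` | 1, 0.1 | kill susceptibility of gene-free / gene-bearing cells |
| `D_perturb`, `D_prior` | 0.1, 0.01 | stressor dose during the pulse / during exposed adjustment |
| `t_adjust`, `t_perturb` | 500, 25 | phase durations (time units of the gLV rates) |

With these values the perturbation is severe for susceptible cells
($\beta_s D = r$: growth fully offset) but mild for resistant ones
($\beta_r D + c \ll r$), which is what makes the gene's presence and spread
consequential.

## Community generation

`sample_interactions()` draws presence per **ordered** off-diagonal element
($a_{ij}$ independent of $a_{ji}$), so `positivity` is an element-level
proportion; pairwise interaction types (competition $-/-$, exploitation
$+/-$, cooperation $+/+$, and the one-sided forms) then arise implicitly.
A `pairwise_presence` switch draws presence per unordered pair instead, for
users who prefer jointly-present links. `sigma` is read as the scale of the
half-normal's parent normal, so present magnitudes have mean
$\sigma\sqrt{2/\pi} \approx 0.012$.

Growth rates are not free parameters: `calibrate_growth_rates()` sets
$r_i = s_i - \sum_{j\ne i} a_{ij}$ so that the gene-free, stressor-free
system has a fixed point with every abundance at 1. This builds in a
trade-off — taxa receiving much cooperation get low intrinsic growth — that
tames explosive dynamics in highly cooperative communities.
`generate_ensemble()` keeps only draws whose Jacobian at the all-ones state,
$A - \mathrm{diag}(s)$, has all eigenvalue real parts negative, redrawing
whole communities (never repairing them, which would distort the interaction
statistics) up to `max_attempts = 1000` per member before declaring the
regime infeasible. Each member gets a deterministic sub-seed hop from the
top-level seed, so ensembles are bitwise reproducible, order-independent,
and individual members can be regenerated in isolation.

## The perturbation protocol

Every scenario starts all taxa at total abundance `x0 = 0.1` — well below
the equilibrium at 1, so the adjustment phase performs genuine assembly
rather than starting at the answer. In gene-carrying scenarios the focal
taxon starts fully gene-bearing (`init_res_frac = 1`, adjustable), mirroring
a clonal introduction. The four scenarios cross gene presence with prior
exposure (adjustment dose 0 or `D_prior`); all four run on the *same*
community object so ΔR and ΔE are within-community paired differences,
invariant to scenario order.

Abundances are read exactly at the phase boundaries: $A^b$ at
$t =$ `t_adjust` (the instant before the pulse) and $A^a$ at
$t =$ `t_adjust + t_perturb` (the end of the pulse window, with no
relaxation). Resistance frequencies are recorded at the same instants;
community-level frequency is abundance-weighted,
$\sum X^r / \sum (X^s + X^r)$ over the taxon set.

## Stability metrics

Per-taxon stability is $\min(0, \log_{10}(A^a_i / A^b_i))$; the cap at zero
means "grew during the pulse" counts as unharmed, not as extra-stable.
Robustness is the plain mean over a taxon set, so whole-community robustness
decomposes exactly as $((N-1)\,\mathrm{background} + \mathrm{focal})/N$ — a
useful internal consistency check.

Degenerate cases are handled explicitly rather than silently: a taxon below
the extinction floor *before* the pulse is recorded missing and excluded
from means (with the exclusion count reported); a taxon driven extinct *by*
the pulse gets the finite value $\log_{10}(\mathrm{floor}/A^b_i)$ instead of
$-\infty$, keeping robustness finite and monotone in severity.

ΔR is `R-naive − S-naive`. ΔE is defined on the gene-carrying pair,
`R-exposed − R-naive`: an exposure effect mediated by gene spread is only
meaningful with a gene present. The susceptible-pair contrast
(`S-exposed − S-naive`) is computed and reported alongside for completeness.

Two complementary metrics guard against the robustness summary hiding
compositional change: Bray–Curtis dissimilarity between $A^b$ and $A^a$
(computed on absolute abundances, since the model tracks absolute density;
a `relative` switch exists), and the return time — the first time in a
stressor-free recovery phase at which every surviving taxon is back within
5% of its pre-pulse abundance and stays there for the rest of the horizon
(500 time units by default; missing if never achieved).

## Numerical choices

* **Integrator**: `deSolve::ode` with lsoda (stiff-capable, adaptive),
  `rtol = 1e-8`, `atol = 1e-10`. Halving both tolerances moves reported
  abundances by far less than 0.1% (tested); a fixed-step RK4 reference
  agrees to $10^{-6}$ relative error on small systems.
* **Extinction floor** $10^{-9}$, applied at phase boundaries: seven orders
  of magnitude below the equilibria at $\approx 1$, so it only prevents
  revival from numerically meaningless densities.
* **Common random numbers in sweeps**: mobility sweeps reuse one ensemble
  across all $\bar\gamma$ cells, rescaling each community's stored noise
  matrix ($\gamma_{ij} = \bar\gamma(1 + 0.1 Z_{ij})$, re-truncated at zero).
  The gene-free scenarios do not depend on $\gamma$ at all and are computed
  once per community. This is a variance-reduction choice that sharpens the
  mobility curves; `paired = FALSE` restores independent ensembles per cell.
* **Ties and caps**: the stability cap at 0 and the floor-based extinction
  value are the only non-smooth steps in the metric chain; both are applied
  after integration, never inside the ODE.

## What the generator emulates — and what it does not

The ensemble generator reproduces the statistical structure of the study
system: sparse random interaction networks with controllable sign
composition, equilibrium-calibrated growth, and conjugation rates with
mild pairwise heterogeneity. It does **not** emulate features of real
microbiomes such as phylogenetically structured transfer (beyond a
user-supplied binary mask), de novo resistance mutation, demographic noise,
spatial structure, or fluctuating/repeated perturbations. Passing tests on
these ensembles therefore validates the mechanism — competitive release,
exposure-assisted gene spread, mobility thresholds — not quantitative
predictions for any particular real community.

## Problem sizes

The bundled analyses and checks run at desk scale, chosen so the full suite
completes in well under a minute of simulation per analysis: 30 communities
per grid point on an 11-point mobility grid (the headline sweeps), 50
communities for the competitive-release scan, and 5×5 grids for the
heatmaps. These are deliberate package defaults; the full-scale analyses
(100 communities, 101-point grids) use the same code paths via the `config`
interface and differ only in Monte-Carlo error.

## Known limitations

* In strongly cooperative regimes (`positivity` near 1 with large `sigma`)
  the rejection sampler can approach its attempt cap; the error message
  names the regime rather than looping forever.
* Return time is reported relative to a finite recovery horizon; slowly
  recovering communities yield missing values rather than extrapolation.
* The model is deterministic; ensemble standard deviations quantify
  between-community variation, not within-community stochasticity.
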