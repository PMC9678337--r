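# hgtstab

Microbial communities are full of genes that protect their hosts against
stressors — antibiotics, toxins, pollutants — and many of these genes sit on
conjugative plasmids that move between taxa. `hgtstab` simulates what such
mobile resistance genes do to the *stability* of a community: when a stressor
pulse hits, who crashes, who persists, and how does the answer change with
the gene's mobility, with prior low-level stressor exposure, and with the way
taxa interact?

The package is aimed at theoretical ecologists and microbiome researchers who
want a fast, reproducible pipeline for ensemble simulations of
eco-evolutionary community dynamics.

## Model

Each community has N taxa, and each taxon i is split into a gene-free
(susceptible) population X<sup>s</sup><sub>i</sub> and a gene-bearing
(resistant) population X<sup>r</sup><sub>i</sub>:

```
dXs_i/dt = Xs_i ( r_i − s_i (Xs_i + Xr_i) + Σ_j a_ij (Xs_j + Xr_j) )
           − Σ_j γ_ij Xs_i Xr_j − β_s D Xs_i
dXr_i/dt = Xr_i ( (r_i − c) − s_i (Xs_i + Xr_i) + Σ_j a_ij (Xs_j + Xr_j) )
           + Σ_j γ_ij Xs_i Xr_j − β_r D Xr_i
```

a generalized Lotka–Volterra system (interaction matrix `a_ij`,
self-inhibition `s_i`, growth rate `r_i`) extended with mass-action
conjugation at per-cell rates `γ_ij`, a growth cost `c` of carrying the gene,
and stressor killing at dose `D` with susceptibilities `β_s > β_r`.
Communities are drawn at random (connectance `C`, half-normal interaction
magnitudes with scale `σ`, a tunable fraction of positive interactions) and
calibrated so the gene-free, stressor-free system has a linearly stable
equilibrium with every abundance at 1.

Stability is measured with a perturbation experiment: adjust for t = 500 time
units (optionally at a low prior dose D = 0.01), pulse at D = 0.1 for t = 25,
and score each taxon as `Stability_i = min(0, log10(A_after / A_before))`.
Robustness is the mean stability over a taxon set (whole community,
background = all but the focal gene carrier, or the focal taxon alone). Two
paired contrasts summarise each community:

* **ΔR** — robustness with the resistance gene minus without it;
* **ΔE** — robustness with prior low-level exposure minus without it
  (gene present).

## Worked example

```r
library(hgtstab)
params <- hgt_params()                       # standard parameter set
ens    <- generate_ensemble(params, 1, seed = 20260922)
quartet <- run_quartet(ens[[1]], params)
delta_metrics(quartet, ens[[1]], params)
```

For the community above (focal taxon 7, 60 nonzero interactions) the four
scenarios give:

```
   scenario   whole background   focal bray_curtis
1   S-naive -0.5698    -0.5700 -0.5684      0.5630
2 S-exposed -0.5378    -0.5381 -0.5359      0.5347
3   R-naive -0.2624    -0.2853 -0.0563      0.2813
4 R-exposed -0.0646    -0.0671 -0.0424      0.0732

dR (whole / background / focal): +0.3074 / +0.2846 / +0.5121
dE (whole / background / focal): +0.1978 / +0.2183 / +0.0139
```

Reading this: in the fully susceptible community the pulse knocks every
taxon down by ~0.57 log10 units. Introducing the resistance gene into one
taxon raises whole-community robustness by 0.31 (ΔR), and prior low-level
exposure — which lets the gene spread into the background before the pulse —
adds another 0.20 (ΔE). The Bray–Curtis column shows the matching drop in
compositional displacement.

The numbered scripts under `analysis/` run the full pipeline:

* `01_single_quartet.R` — the example above;
* `02_mobility_sweep.R` — ΔR/ΔE and background resistance frequency across
  gene mobilities 10⁻⁶–10⁻² in noninteracting communities (curves + CSV);
* `03_positivity_grid.R` — heatmaps of ΔR/ΔE over interaction positivity ×
  mobility, showing the sign flip of the background effect between
  competitive and cooperative communities.

Each writes tables (and figures) under `results/`.

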