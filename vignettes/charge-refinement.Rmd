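---
title: "Refining neutral-lipid partial charges by thermodynamic reweighting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refining neutral-lipid partial charges by thermodynamic reweighting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recharge)
```

## The problem

Neutral lipids such as triacylglycerols (TG) and diacylglycerols (DG) carry
no charged groups, yet the partial charges assigned to their glycerol-ester
region control how hydrophilic that region is. Charges inherited from
phospholipid force fields make simulated TG/DG oils far too water-loving:
the oil-water interfacial tension (IT) comes out ~40% low and an order of
magnitude too much water dissolves into the oil phase. `recharge`
implements the refinement loop that fixes this: adjust only the
glycerol-ester charges, keep everything else frozen, and fit the simulated
IT / surface tension (ST) / density of a small training set to experiment —
together with the trajectory observables used to diagnose and validate the
resulting models.

## The refinement model

Let $q$ be the vector of free partial charges (atoms outside the
glycerol-ester region are frozen; chemically equivalent atoms share one
parameter; the molecular net charge is fixed at zero). Each training target
$t$ has an experimental mean $E_t$, a 95% confidence half-width $c_t$, and a
dimensionless scale factor $s_t$. The per-cycle objective is weighted least
squares with a quadratic charge restraint:

$$
F(q) \;=\; \sum_t \left[ s_t \,\frac{m_t(q) - E_t}{c_t} \right]^2
\;+\; \lambda \sum_k \left( q_k - q_k^{\mathrm{ref}} \right)^2 ,
$$

where $m_t(q)$ is the simulated mean of the observable realizing target
$t$. Target weights are inversely proportional to the experimental
uncertainties; the scale factors bring heterogeneous properties (tensions
in mN/m, densities in g/cm^3) to a similar order of magnitude. The source
protocol describes both ingredients but never writes the composed formula;
multiplying the scaled residual by $1/c_t$ is our reading, recorded here as
a design choice.

Within one cycle the sampled ensemble is fixed and $m_t(q)$ is estimated by
**thermodynamic reweighting**: frames sampled at $q_0$ are reweighted to a
trial $q$ with
$w_i \propto \exp[-\beta\,(U(x_i;q) - U(x_i;q_0))]$
(computed in log space), and

$$
\frac{\partial \langle O \rangle}{\partial q_k}
= -\beta \left( \langle O\, \partial_k U \rangle_w
  - \langle O \rangle_w \langle \partial_k U \rangle_w \right),
$$

the exact derivative of the importance-weighted mean. The Kish effective
sample size $\mathrm{ESS} = 1/\sum_i w_i^2$ guards validity: when ESS drops
below a floor (default 20% of the frames), the cycle stops trusting
extrapolation and fresh sampling is required — matching the published
protocol, which re-simulated every cycle.

After every inner gradient step the charges are projected onto (i)
equivalence groups, (ii) net-charge conservation (the uniform shift over
free atoms is removed), and (iii) a hard per-cycle box cap
$|q_k - q_k^{\text{cycle start}}| \le \Delta$. The published protocols
bound the per-cycle change at $\Delta = 0.005\,e$ (cutoff-consistent
parameter set) and $\Delta = 0.02\,e$ (LJ-PME-consistent set); these are the
`"C36-c"` and `"C36-p"` presets. The source achieved the caps indirectly
through regularization weights; a hard box projection is reproducible and
independent of $\lambda$, which remains available separately — a deliberate
deviation, documented here.

The outer loop alternates sampling and refinement until, for every target,
the closed interval $m_t \pm c^{sim}_t$ intersects $E_t \pm c_t$
(CI-overlap stopping, touching endpoints count), or `max_cycles` is
reached.

## Uncertainties

Simulated means carry 95% confidence intervals from a moving-block
bootstrap over frames (default 20 contiguous blocks, 1000 resamples,
seeded), which respects autocorrelation; the source states only that CIs
come from the sampled distributions. Time-series utilities provide the
complementary running averages and fixed-duration blocking averages
(default 100 ns) with Student-t CIs over block means. Blocking CIs are only
honest when blocks exceed the correlation time — the toy defaults below
were sized accordingly, and the coverage is itself property-tested against
AR(1) series with known mean.

Experimental uncertainties for targets lacking replicated measurements use
the 8% relative-95%-CI rule (`relative_ci95()`), which reproduces the CI
column of the published training table.

## Trajectory observables

* **Tension** (`kirkwood_irving_tension`): for a z-normal slab with two
  interfaces, $\gamma_i = (L_{z,i}/2)\,[P_{zz,i} - (P_{xx,i}+P_{yy,i})/2]$
  in bar nm, converted with the exact factor 0.1 to mN/m. We take $L_z$
  per-frame inside the average; the printed formula has $L$ outside, but
  with a z-fluctuating barostat the per-frame reading is the defensible
  one and the difference is second order.
* **Oil-core hydration** (`water_in_oil_content`): oil mass-density
  profile along z (0.07 nm bins), core defined as the contiguous region at
  ≥ 50% of the plateau density (a Gibbs-dividing-surface convention — the
  source never defines "inside the core"), water oxygens counted inside,
  reported as g water / kg oil. Equilibration is detected from this series
  (`detect_equilibration`, window 100 ns, relative slope tolerance 0.05 by
  default): the post-convergence window is the one that should feed mean-IT
  estimation.
* **Profiles and PMFs** (`lateral_density_profile`, `boltzmann_invert`,
  `flip_flop_barrier`, `replica_aggregate`): density profiles along the
  bilayer normal at 0.07 nm bins (optionally recentered so the midpoint
  between the two phosphate peaks sits at z = 0), Boltzmann inversion
  $\mathrm{PMF}(z) = -k_BT \ln[\rho(z)/\rho_{max}]$ anchored at zero
  minimum, flip-flop barrier as PMF(midplane) − PMF(minimum) (the
  max-minus-min convention is exposed as an option; the two coincide for
  well-formed profiles), and replica aggregation as bin-wise mean ± SD after
  per-replica anchoring, with barrier statistics propagated from
  per-replica barriers. Empty bins are masked (`NA`), never zero. The
  anchoring convention is ours: the source anchors "using the C2 atom as
  reference", which names a species, not a zero; barriers are offset
  invariant either way.
* **Fragment dipoles** (`fragment_dipole`, `delta_dipole_distribution`):
  glycerol-ester dipole moments $\mu = \sum_i q_i (r_i - r_{\mathrm{cog}})$
  (1 e nm = 48.03205 D), with the origin at the fragment's center of
  geometry — fragments carved from a molecule can carry net charge, making
  the dipole origin-dependent, and the source is silent on its convention
  (center of mass is available as an option). Dipole-modulus changes
  between charge sets are histogrammed at 0.01 D and Gaussian-fitted by
  least squares, with moment-matched estimates reported alongside.

## The toy sampler: what it emulates, and what a green test proves

No MD engine ships with this package. `metropolis_sample` runs
single-particle-displacement Metropolis Monte Carlo on small charged
Lennard-Jones fluids (minimum-image, truncated interactions, optional
harmonic tether) and emits exactly what the refinement machinery consumes:
per-frame energies, exact energy derivatives with respect to the free
charge parameters (charges enter the Coulomb sum bilinearly, so
$U(\theta) = c_0 + b\cdot\theta + \theta^{\top} M \theta$ per frame with
coefficients accumulated during sampling), diagonal virial pressures, and
configuration-only observables.

The built-in recovery harness (`toy_recovery_harness`) stands in for the
published sample-and-refine workflow: 24 particles, two equivalence groups
of six particles with opposite charge (±0.2 e truth) plus twelve frozen
neutral particles, in a 2.8 nm box at 298.15 K. With equal multiplicities,
neutrality ties the two free parameters together — the smallest structure
exercising every constraint. Design notes, fixed before the acceptance
checks were run:

* ±0.2 e keeps contact pairs a few kT deep so the Markov chain mixes;
  at ±0.3 e the fluid ion-pairs into long-lived clusters and single-particle
  moves decorrelate too slowly for honest error bars.
* Run lengths (800k moves for the target-defining truth run, 400k per
  cycle) were sized so the 0.05 e starting offset displaces the training
  observables by clearly more than the combined CIs, and so bootstrap
  blocks exceed the observable correlation time. With calibrated CIs the
  0.02 e cap needs about three cycles to traverse the offset.

A green toy test establishes that the estimators and the optimizer are
correct on a system obeying their assumptions. It does **not** establish
anything about real lipid force fields: no Ewald electrostatics, no water,
no interfaces, 10^4 times fewer atoms, and Boltzmann sampling by
construction. The cluster-scale numbers of the source study (TOG IT
31 mN/m, water content ~1 g/kg, flip-flop barriers of 1 and 3.5 kcal/mol)
are reproducible only with external microsecond MD and are deliberately not
acceptance-gated here.

## Numerical choices and degenerate inputs

* Log-sum-exp guard on all weight normalizations; non-finite trial
  energies abort with the frame index.
* Net-charge tolerance 1e-9 e on load; optional `repair_net_charge`
  spreads printed-topology rounding residuals uniformly over free atoms
  (off by default).
* Equivalence groups come from a sidecar config (TOML subset or JSON), not
  from atom-type inference: the chain-equivalence of a TG is
  molecule-specific knowledge the topology format does not carry.
* The inner optimizer is backtracking line-search gradient descent; the
  step parameter is the largest per-charge move in e, making the search
  scale-free in the gradient magnitude. A cap of zero is the documented
  no-op. Cyclic projection (equivalence → neutrality → cap) runs to joint
  fixed point; infeasible combinations error rather than silently violate
  a constraint.
* Profile bins are half-open `[lo, hi)`; the midplane sits at z = 0; an
  all-zero profile, a masked midplane bin, and fewer than two complete
  blocks are all explicit errors or signalled `NA`s, never silent zeros.
* All stochastic components (sampler, bootstrap, generators) draw from
  seeds derived from one master seed via a splittable mix, so every run is
  replayable from its provenance block.

## Worked example

```{r example, eval = FALSE}
## tension from a synthetic pressure-tensor series
s <- synth_tension_series(mean_anisotropy = 100, lz = 12,
                          ar1_phi = 0.6, noise_sd = 25,
                          n = 8000, seed = 1, dt = 0.25)
ki <- kirkwood_irving_tension(s)
running_and_block_stats(ki$gamma, s$time, block_duration = 100)

## charge refinement on the toy recovery harness
h <- toy_recovery_harness(seed = 1)
cfg <- optimizer_config(preset = "C36-p", max_cycles = 10, seed = 1)
res <- run_optimization(h$sampler, h$targets, h$q_start, cfg)
res$converged
free_parameters(res$charges)   # compare h$theta_truth
```

## Known limitations

* The toy Coulomb interaction is truncated at the cutoff (no Ewald); the
  sampler validates estimators, not electrostatics.
* `water_in_oil_content` assigns one water molar mass per detected oxygen;
  exotic water models with several oxygens per molecule would be
  miscounted.
* The Gaussian histogram fit can fail on degenerate (zero-variance)
  samples; it reports `NA` and the moment-matched values remain available.
* Reweighting is exact only for observables that do not themselves depend
  on the charges; pressure-derived series are reweighted as fixed per-frame
  records, which is the standard first-order treatment.
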