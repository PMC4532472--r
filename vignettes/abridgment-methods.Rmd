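---
title: "Abridging stochastic chain reaction systems: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Abridging stochastic chain reaction systems: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abridger)
```

## The problem

Multisite phosphorylation chains are a recurring motif in stochastic models
of cellular regulation: a protein hops between adjacent phosphoforms
`S1 <-> S2 <-> ... <-> Sn` much faster than anything else in the system,
while a slow reaction (degradation of a partner, an irreversible conversion)
fires from one of the chain states. Simulating such systems with Gillespie's
direct method spends nearly all its effort on chain hops that cancel each
other out. *Abridgment* replaces the chain plus its slow exit with a single
effective reaction `S1 -> S(n+1)`; this package computes when that
replacement is accurate and what the effective rate is, and verifies both by
exact stochastic simulation.

## The spectral analysis

For one particle on the chain, the state probabilities obey the chemical
master equation `dP/dt = A P`, with `A` the tridiagonal generator carrying
the forward rates on its subdiagonal, the backward rates on its
superdiagonal, and the exit rate `f_n` subtracted from the diagonal entry of
the exit state (`build_generator_A()`). Removing the exit gives the
conservative fast-subsystem generator `B` (`build_generator_B()`); the two
differ by a rank-one matrix whose single entry is `-f_n`.

Three quantities organise everything:

* **Relaxation time** `T_relax = 1/|lambda_hat_(n-1)|`, the reciprocal
  spectral gap of `B` (`relaxation_time()`): the time the fast chain needs
  to forget a perturbation.
* **Reduced rate**. The exit time of a particle started in `S1` has survival
  `1' exp(At) e_1`; when the dominant eigenvalue `lambda_n` of `A` is well
  separated from the rest, this is exponential with rate `|lambda_n|`.
  Because solving an eigenproblem per slow step is wasteful, the rate is
  also computed as the equilibrium exit flux `gamma = -f_n pi_u`, with `pi`
  the stationary distribution of `B` obtained from the reduced linear system
  in `equilibrium_distribution()` (and, for birth-death chains, equal to the
  detailed-balance closed form). A rank-one perturbation argument gives
  `|lambda_n - gamma|/|lambda_n| = O(f_n T_relax)`, so the cheap flux formula
  is accurate exactly when the reduction itself is. With `m` independent
  particles the first exit is the minimum of `m` i.i.d. times and the
  reduced rate is `m |lambda_n|` (`reduced_rate()`, `m_particle_survival()`).
* **Validity ratio** `rho = f_n * T_relax` (`validity_check()`): the
  reduction is sound when the chain relaxes much faster than the slow
  reaction fires, `rho << 1`. The interlacing inequality
  `0 <= lambda_hat_i - lambda_i <= f_n`, asserted on every
  `spectral_report()`, is what ties the spectra of `A` and `B` together and
  implies `|lambda_n| <= f_n`.

The package keeps *both* rate estimates and reports their relative gap
rather than silently choosing one; `glance()` on a spectral report exposes
`lambda_n`, `gamma`, the gap and `rho` in one row.

### Numerical choices

Eigenvalues come from a dense nonsymmetric solver; the chains of interest
have at most a few hundred states, so no structure-exploiting factorization
is needed. Birth-death generators are similar to symmetric tridiagonal
matrices, so their spectra are real: imaginary parts below `1e-9` of the
spectral radius are truncated, anything larger is a hard error. A chain with
a zero internal rate is reducible; `equilibrium_distribution()` and
`relaxation_time()` refuse (multiple near-zero eigenvalues) rather than
regularize. The degenerate single-state chain is handled exactly:
`A = [-f_1]`, `T_relax = 0`, `gamma = -f_1`. The default validity threshold
is `rho < 0.1`: the reduced-rate error is of order `rho`, so 0.1 keeps it
near 10%; it is an argument everywhere.

`survival_function()` uses the eigen-expansion when the eigenvector matrix
has condition number below `1e8` and falls back to a scaling-and-squaring
matrix exponential otherwise — the expansion assumes diagonalizability, and
near-degenerate spectra need the robust path. The two paths agree to solver
precision on diagonalizable problems, and the tests pin the curve against an
independent stiff ODE integration.

## Exact simulation

`simulate_ssa()` implements the direct method: waiting time
`tau = log(1/r1)/a0`, then the firing channel as the smallest `j` with
`sum(a[1:j]) > r2 a0`, the two uniforms drawn in that fixed order so a seed
pins the trajectory bit-for-bit. A tie between `r2 a0` and a partial sum (a
measure-zero event) selects the next channel, which is what the strict
inequality dictates. The event loop is compiled; propensities are
re-evaluated from the current state at every step, with no caching across
states, so state-dependent rate laws are always current. Structured
propensity kinds (mass action; mass action times a linear state weight; a
chain-equilibrium weight described below) are evaluated in compiled code;
arbitrary R-function propensities are supported but call back into R per
step. The tests verify the structured kinds against an R-closure
re-implementation trajectory-for-trajectory.

Time-fraction distributions (the fraction of simulated time a species spends
at each copy number, after a burn-in) are accumulated online in the
simulation loop, so long runs can drop or thin their trajectory record
without biasing the estimate; for fully recorded paths the piecewise-constant
integration from the jump record gives the same numbers to machine
precision.

## The bistable switch testbed

The concrete system exercising all of this is a two-protein switch: Cdh1
with 10 phosphoforms `Cdh1P0..Cdh1P9`, phosphorylated at rate `k * Clb2` per
particle and step (Clb2 is the kinase), dephosphorylated at rate `k * kp`;
Clb2 synthesised at constant rate `ks` and degraded with propensity
`ka * (sum_i (10 - i) X_i) * Clb2` — unphosphorylated Cdh1 is the most
effective degrader, so Clb2 and Cdh1 inhibit each other and the stationary
distribution of Clb2 is bimodal. Published parameter values are the
defaults: `kp = 8`, `ka = 5.5e-4`, `ks = 350 ka`, 10 Cdh1 particles,
initial Clb2 = 10. The scale `k` multiplies only the chain rates, making the
timescale separation a single experimental knob.

The abridged form (`build_reduced_switch()`) keeps only Clb2 and replaces
the degradation weight by its frozen-chain equilibrium expectation
`m * W(Clb2)`, where `W` is computed from the truncated-geometric
equilibrium with ratio `Clb2/kp` in closed form (cross-checked against the
linear solve in the tests). The weight is re-evaluated at the current Clb2
before every firing. At `Clb2 = kp` the occupancy is uniform and `W = 5.5`;
`W -> 10` as `Clb2 -> 0` and `W -> 1` as `Clb2 -> Inf`.

Choices that were genuinely open:

* **Level count.** The model is built with 10 phosphoforms (weights
  `10 - i`, `i = 0..9`), the variant whose published density errors we
  compare against; `levels` is a parameter.
* **Initial phospho-configuration.** Only total Cdh1 is published; runs
  start with all particles unphosphorylated. Experiments with all particles
  fully phosphorylated and with a uniform spread changed the measured
  density errors by a few percentage points at most, so the choice is not
  load-bearing.
* **Burn-in.** No burn-in is published; the default discards the first 1%
  of the horizon, which removes the initial transient at every chain scale
  tried while costing a negligible share of the sample.
* **The degradation propensity** multiplies the weighted Cdh1 count by the
  Clb2 copy number (a unimolecular decay whose rate constant depends on the
  antagonist's state). This is the only reading under which the reduced
  model's propensity `m * lambda(Clb2) * X_Clb2` is the quasi-steady-state
  expectation of the original one.

### The slow-interval curve

The validity condition compares `T_relax` of the frozen chain against the
mean time between slow (Clb2-changing) events.
`relaxation_vs_firing_curve()` reports, per Clb2 copy number, the interval
`1/(ks + a_deg)`. For `a_deg` the default uses the degradation propensity at
its maximum over Cdh1 configurations, `ka * m * levels * Clb2` (every
particle unphosphorylated): a conservative shortest-interval bound, so a
relaxation curve below it certifies validity against *any* Cdh1
configuration the run may pass through, not just the equilibrium one. With
this bound the `k = 0.5` curves cross near Clb2 = 5 and 15, the `k = 5`
relaxation curve stays below the interval everywhere in 1–35 and the
`k = 0.05` and `k = 0.01` curves stay above it. The frozen-chain
quasi-steady-state expectation `ka * m * W(Clb2) * Clb2` is available via
`interval = "qss"`; it is less conservative and moves the crossings inward.
At `Clb2 = 0` the frozen chain has no forward rates; its relaxation time is
still defined (the generator is triangular with a single zero eigenvalue)
and the row is flagged `chain_reducible`.

## What the validation shows — and what it does not

`compare_switch_models()` runs full and reduced switch for `1e6` time units
and reports `100 * sum_x |p(x) - q(x)|` between the two time-fraction
distributions of Clb2 (the percent L1 distance, range 0–200; implemented
over raw copy numbers, no binning). Across `k = 5, 0.5, 0.05, 0.01` the
error rises monotonically (roughly 4%, 5%, 46%, 110% in this
implementation, averaged over seeds), and the regime change is qualitative:
at `k = 5` both models are bimodal with matching modes, while at `k = 0.01`
the full model is effectively unimodal (brief high-state excursions only)
although the reduced model still shows two modes — the reduction invents
bistability that the slow-chain dynamics do not sustain.

These experiments emulate a well-stirred, single-compartment system with
time-homogeneous rate laws; they say nothing about spatial effects,
extrinsic noise, or rate laws outside the mass-action/weighted families
implemented here. The property suite runs on randomly generated chains with
log-uniform rates over one to two decades; the structural spectrum
properties (signs, interlacing, `|lambda_n| <= f_n`) are asserted with
solver tolerances, and the `O(rho)` error bound on the reduced rate is
checked on chains whose dominant eigenvalue is large enough for a dense
eigensolver to resolve — chains with equilibrium occupancies below roughly
`1e-12` at the exit state defeat any floating-point check of that bound,
though the closed-form flux `gamma` remains accurate there.

Problem sizes in the tests were chosen to keep the whole suite comfortable
on one CPU: the slower chain scales run the full published horizon (`1e6`
time units, seconds per run in compiled code), the `k = 5` comparison runs
`5e5` time units (its error has settled well below the asserted 10% bound
by then), and Monte-Carlo checks use 1–2 thousand replicates with
3-standard-error bands or 1% Kolmogorov–Smirnov critical values.
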