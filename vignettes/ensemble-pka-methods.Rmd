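---
title: "Methods: ensemble pKa by the linear response approximation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble pKa by the linear response approximation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protolra)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter, what the
synthetic generator does and does not emulate, and the numerical choices
made where the method descriptions in the literature are silent.

## 1. The model

### Microstate titration of one conformation

A conformation's electrostatics are reduced to `n` titratable sites with
intrinsic pKa values `pkint_i` and a symmetric matrix `w` of pairwise
charge–charge couplings, all in pK units (energy divided by kT·ln 10).
A protonation microstate `s ∈ {0,1}^n` has free energy

    G(s; pH) = Σ_i s_i (pH − pkint_i) + Σ_{i<j} w_ij q_i q_j

with site charges `q_i = s_i − 1` for anionic and `q_i = s_i` for
cationic sites, and Boltzmann weight `10^(−G)`. This is the standard
reduced-site formalism of continuum-electrostatics pKa programs; the
package deliberately does *not* compute `pkint`/`w` from structures (a
Poisson–Boltzmann solver's job) — they are the input contract. The
protonation variable means "proton bound" for acids and bases alike; all
site-specific chemistry is absorbed into `pkint`, so exact enumeration
(`exact_titration()`, up to 20 sites with log-sum-exp accumulation) and
Metropolis sampling (`mc_titration()`) share one energy function.

The Monte Carlo sampler runs an independent chain at every pH point (no
replica exchange). One *step* is a random-scan sweep of `n` proposals —
the step convention under which the stated 10⁵-step accuracy targets are
statistically attainable; with 10⁵ *single* proposals shared among 8
sites the per-site sampling error alone would exceed them. With
probability `pair_move_fraction` (default 0.1) a proposal flips the
chosen site together with its most strongly coupled partner, which
rescues mixing for strongly anti-correlated pairs. Errors are batch
means over 20 post-burn-in blocks; burn-in defaults to 10% of steps.
Chains start all-deprotonated. At `pH = pkint` of an uncoupled site every
flip has ΔG = 0 and the chain alternates deterministically — the mean is
then exactly ½ with zero batch error, which tests must treat as the
correct degenerate outcome, not a failure.

### pKhalf versus pKa

`pkhalf()` reports the pH at which one site's per-conformation average
protonation crosses ½, linearly interpolated between grid points. On the
default grid (pH −10…+20, step 0.25, mirroring the wide scans used for
buried sites) the interpolation of a sigmoid carries an O(step²) error of
up to ~7×10⁻⁴ pK for off-grid pKints; on-grid values are exact. Coupled
sites can titrate non-monotonically, so several crossings are possible:
the median crossing is returned with a multiplicity flag (deterministic
and symmetric); no crossing yields `NA` with a boundary flag. pKhalf is a
*microscopic* quantity — one conformation's energetics — and is used for
population diagnostics, never as the macroscopic estimate.

### The LRA estimate

The macroscopic pKa is estimated from two fixed-protonation ensembles:

1. `pool_protonation()` — grand mean over all frames (equal weights) of
   the target's average protonation at each pH. For equal-length
   replicates this equals the mean of replicate means; the grand mean is
   the default because it remains well-defined after population
   filtering leaves unequal replicate counts.
2. `hh_transform()` — `pKa(pH) = pH + log10(p/(1−p))`. Points with
   `p < ε` or `p > 1−ε` (default ε = 10⁻⁶) are left *undefined rather
   than clamped*: the log diverges there, and clamping would leak
   arbitrary values into the endpoint average.
3. `lra_average()` — pointwise mean of the P and D curves, undefined
   wherever either endpoint is.
4. `macroscopic_pka()` — root of `f(pH) = pKa(pH) − pH` between
   consecutive defined grid points, linearly interpolated. No sign
   change: nearest point with a boundary flag. Several sign changes
   (possible for near-flat curves): the root whose bracket has the
   smallest |f|, flagged. For a single uncoupled site the HH transform
   inverts the exact sigmoid identically, so the whole chain returns
   `pkint` to numerical precision — the key closed-form regression
   anchor.

The jackknife error is the delete-one formula
`SE = sqrt((n−1)/n · Σ(θ_i − θ̄)²)` over the replicates (default) or, after
population filtering, over three contiguous time-ordered thirds of the
retained frames — contiguity respects the strong autocorrelation of the
substate process, which random thirds would hide. The literature wording
for this error oscillates between "jackknife" and "standard error of the
mean"; the two differ by a constant factor at n = 3, and the explicit
jackknife formula is implemented because it is the named procedure.

### Population splitting

`split_pkhalf_populations()` partitions defined pKhalf values by an exact
1-D two-cluster split (sorted prefix-sum scan minimizing within-cluster
sum of squares; clusters of an optimal 1-D 2-means are contiguous in
sorted order) with the threshold at the midpoint of the cluster means, or
by a fixed threshold (`high = pkhalf ≥ threshold`). `stats::kmeans` with
random restarts was rejected: the determinism contracts require identical
output on identical input. A separation below 1 pK unit triggers a
likely-unimodal warning rather than an error — the caller decides.

## 2. The synthetic world and its oracle

`simulate_ensemble()` emulates the statistical structure of
fixed-protonation MD + per-frame electrostatics: per replicate, a Markov
chain over conformational substates with persistence `ρ` (transition
matrix `ρ·I + (1−ρ)·1πᵀ`, so the stationary law is the stated occupancy);
per frame, a target pKint drawn from the substate's Normal law, plus
fixed neighbor sites and couplings. Defaults mirror the emulated
protocol: 3 replicates × 1001 frames (100 ns at 100 ps including t = 0 —
`frame_count(100000, 100, 3)` = 3003), persistence 0.99, within-substate
spread σ = 0.3 pK (a realistic per-frame electrostatic fluctuation for a
buried site).

**Occupancy convention.** Thermodynamic consistency of a joint model in
which a frame in substate `k` titrates with pKint `pk_k` forces a single
conformational surface: the protonated-ensemble occupancy is then
*determined* by reweighting, `π_P(k) ∝ π_D(k)·10^{pk_k}`. The generator
derives `occupancy_P` this way by default. An explicit `occupancy_P` is
accepted — it emulates kinetically trapped sampling, e.g. a substate flip
occurring in only some replicates — but such a world is deliberately
inconsistent with the equilibrium oracle, and tests against the oracle
then only assert direction, not agreement. Neighbor sites are shared
across substates; this is what makes the conditional-ensemble identities
exact.

`oracle_macroscopic_pka()` is the ground truth: the joint partition
function over (substate, microstate) with weight
`10^{−(E_k(s_target) + G_k(s; pH))}`, exact target protonation, ½
crossing. Two readings of a two-substate sanity case make the convention
concrete: with equal conformational energies on both surfaces and pKints
6 and 8, the *fast-exchange* ensemble value is
`log10(½(10⁶+10⁸)) ≈ 7.703` (binding constants average), whereas a
*frozen* 50:50 mixture of titration curves crosses ½ at exactly 7.0 (by
sigmoid symmetry). The oracle computes the former — the equilibrium
quantity the LRA is meant to approximate; the pooled per-ensemble curves
of the pipeline are of the frozen kind, and it is precisely the P/D
endpoint averaging that recovers the equilibrium value (numerically: the
intrinsic LRA bias against the oracle is < 0.002 pK for substate shifts
up to 2 pK — far below the 0.3 pK recovery tolerance, which is therefore
dominated by sampling noise).

What a green recovery test establishes: the pipeline correctly averages
conformational substates with Markov persistence, Gaussian microscopic
spread and site–site couplings. What it does not establish: correctness
of upstream PB electrostatics, force-field adequacy, membrane effects, or
convergence of real MD sampling — none of which the generator emulates.

## 3. Geometry metrics

All metrics are driven by a Ballesteros–Weinstein map (YAML) so the same
code serves any class A receptor. Choices where conventions vary:

* Backbone = N, CA, C, O. Side chain = heavy atoms strictly beyond the
  backbone (CB included, OXT and hydrogens excluded) — analysis
  structures frequently lack hydrogens, and including them would make
  COMs protonation-state dependent.
* `npxxy_rmsd()` superposes on *all mapped* backbone atoms by default
  before measuring the 7.49–7.53 motif RMSD: a motif-only fit would
  subtract the very displacement that is the signal. The constructed
  1 Å-shift fixture is validated with an anchors-only fit, where the
  expected value is exactly 1.
* Dihedrals follow the IUPAC sign convention, `(−180°, 180°]`,
  cross-checked against an independent implementation (and, during
  development, against MDAnalysis — an initial sign error in the package
  formula was caught exactly this way).
* Heron's formula clamps a negative radicand within 10⁻⁹ (collinear
  COMs) to zero; beyond that tolerance a triangle-inequality violation
  is an input error, not a silent zero.
* The A100 index: the 0/55 thresholds are hard-coded published cut
  points (boundary values are *intermediate*); the five distance pairs
  and coefficients are configuration, because they belong to the index's
  defining publication, which is not redistributable here — the shipped
  example coefficients are marked synthetic/illustrative.
* Structures are consumed as PDB (single- or multi-MODEL). Binary
  trajectory formats are out of scope in this environment; a 100-ps
  stride multi-model PDB is the supported exchange format.

## 4. Numerical and degenerate-input policy

* All titration arithmetic in log-space where overflow is possible (the
  −10…+20 grid makes naive `10^{−G}` overflow around 30+ sites·pH
  units).
* Empty frame files warn and return empty; malformed JSON-lines report
  the line number; coupling triplets contradicting symmetry are parse
  errors, not averaged away.
* Glycine has no heavy side-chain atoms: side-chain COM requests on it
  are structure errors by design.
* Every stochastic entry point takes an explicit seed and is
  reproducible bit-for-bit; pipeline outputs regenerate identically for
  identical config + seed.

## 5. Known limitations

* The LRA is itself an approximation; its bias grows with the
  protonation-coupled reorganization energy. The oracle quantifies this
  on synthetic models only.
* `occupancy_P` override breaks equilibrium consistency by construction
  (intended for trapped-sampling studies).
* The per-frame titration models are trusted inputs; no attempt is made
  to validate them against structures.
* kmeans2 splitting assumes at most two populations; more substates
  need a fixed threshold or upstream clustering.
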