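---
title: "Fluctuation-matched elastic networks for filament lattices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fluctuation-matched elastic networks for filament lattices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmnet)
library(dplyr)
```

## The problem

Coarse-grained force fields for proteins trade chemical detail for reach:
with a few interaction sites per residue one can simulate assemblies —
microtubules, virus capsids, filament bundles — far beyond atomistic
scales. The price is that the coarse Hamiltonian alone rarely holds a large
lattice together with the right stiffness: protein–protein interfaces that
are stabilized by ligands or nucleotides in reality (and therefore by
interactions the coarse model does not carry) fall apart or over-twist. The
standard remedy is an *elastic network*: harmonic springs between nearby
sites that pin the assembly near its reference structure.

A uniform network (one spring constant everywhere) over-constrains mobile
regions and under-constrains stiff ones. `fmnet` implements the
heterogeneous alternative: spring constants are *fluctuation-matched*, pair
by pair, so that the coarse model reproduces the per-pair distance
fluctuations of a trusted reference — typically an all-atom simulation of a
small patch of the same lattice. The package also builds the helical
lattices such networks are deployed on, measures mechanical observables
(Young's modulus, flexural rigidity) and structural observables (contacts,
angles, correlations, ion densities), and ships a small Brownian-dynamics
simulator so the whole optimize–simulate–analyze loop can run and be tested
without any external MD engine.

## The model

### Contact selection

Given backbone-site coordinates of the reference structure, candidate
springs connect pairs whose distance $d_{ij}$ lies in a window
$[L_\mathrm{low}, L_\mathrm{high}]$ (defaults 0.5–0.9 nm, the conventional
elastic-network window for coarse protein models) and whose sequence
separation exceeds two residues on the same chain; inter-chain pairs are
always eligible. Disordered segments (e.g. the charged C-terminal tails of
tubulin, ~18–19 residues) are excluded by residue range, since pinning them
with springs would misrepresent their dynamics.

When reference fluctuation statistics are available, a second filter drops
pairs whose *structural* distance is an outlier of the *dynamical*
distribution: $|d_{ij} - \mu_{ij}| / \sigma_{ij} \ge 3$, assuming a local
normal distribution. This removes springs from highly dynamic regions
where a crystallographic distance is not representative.

### Initialization

Spring constants start inversely proportional to the reference distance
variance,

$$k_{ij} = k_0 \, \frac{\min_{ij}(\sigma^2_{ij})}{\sigma^2_{ij}},$$

with base constant $k_0 = 500$ kJ mol$^{-1}$ nm$^{-2}$. The least-mobile
pair carries exactly $k_0$; everything else is softer in proportion to how
much it fluctuates. The assignment is invariant to rescaling all variances
by a common factor — only the *heterogeneity* of the fluctuations enters.

### Iterative matching

The coarse model with the current network is then simulated, per-pair
variances $\sigma^2_{ij,\mathrm{model}}$ measured, and every constant
updated by

$$k_{ij} \leftarrow k_{ij} - \frac{\alpha\, k_B T}{L_\mathrm{cutoff}^4}
  \left(\sigma^2_{ij,\mathrm{ref}} - \sigma^2_{ij,\mathrm{model}}\right),$$

with gain $\alpha = 1050$ (dimensionless), $k_BT = 2.494$ kJ/mol (300 K)
and $L_\mathrm{cutoff} = 0.9$ nm, the upper window bound. A model that
fluctuates too little softens; one that fluctuates too much stiffens.
Updated constants are floored at zero and the bond *retained*, so the
network topology is fixed across iterations — the update rule implicitly
assumes a stable contact set. Convergence is tracked by
$D = \langle \sigma^2_\mathrm{ref} - \sigma^2_\mathrm{model} \rangle$, the
signed mean mismatch in nm².

The local convergence behaviour is easy to read off for an isolated pair,
where $\sigma^2 = k_BT/k$: the iteration contracts when
$\alpha k_BT^2 / (L_\mathrm{cutoff}^4 k^2) < 2$, i.e. for
$k \gtrsim 70$ kJ mol$^{-1}$ nm$^{-2}$ at the defaults. Very soft springs
therefore converge slowly or not at all under the raw update — one reason
the variance-inverse initialization (which starts everything at or below
$k_0$ but well above this bound for real contact networks) matters.

### Stopping rule

The reference criterion for "converged" is not fully specified in the
sources this design follows, so the package declares its own and exposes
it: stop when $|D_n| \le$ `convergence_tol` (default $10^{-4}$ nm²), or
when $D$ changes by at most a tenth of the tolerance on two consecutive
iterations (a flat-lined trail), or at `max_iterations`. The full trail is
always returned so a user can apply a stricter criterion after the fact.

```{r iterate}
k_true <- c(450, 300, 220, 160, 500)
target <- tibble::tibble(i = 1:5, j = 6:10, var = 2.494 / k_true)
springs0 <- tibble::tibble(i = 1:5, j = 6:10, d0 = 0.7, k = 500)
fit <- iterate_to_convergence(springs0, target, evaluator_analytic(),
                              enm_config())
glance(fit)
round(fit$springs$k, 1)  # compare k_true
```

### The fluctuation evaluator is pluggable

`iterate_to_convergence()` takes any `function(springs) -> stats`. In
production that wraps an external MD engine; in this package two evaluators
are provided: `evaluator_analytic()` (the stationary variance $k_BT/k$ of
an isolated harmonic pair — exact for independent-pair networks, instant)
and `evaluator_brownian()` (runs the internal Brownian simulator and
measures variances from the trajectory, discarding a 20% burn-in). The
tests close the loop both ways.

## The lattice builder

A helical filament lattice is generated from an asymmetric unit (a dimer)
by the rule: protofilament $p$ is the unit rotated by $p \cdot$ twist about
the axis and raised by $p \cdot$ rise along it; layers are axial copies at
the layer period. Defaults are the 14-protofilament microtubule geometry:
twist 25.77° and rise 0.874 nm per protofilament. Two conventions are
worth stating explicitly:

* **The lattice skew is preserved.** $14 \times 25.77° = 360.78°$, not
  360°. The builder never renormalizes the twist to close the turn; the
  0.78° excess is a real geometric feature (it is what produces a seam),
  and `measure_helical_params()` round-trips it to $10^{-6}$.
* **Axis and ends.** The axis is $+z$; the minus end is at low $z$ and cap
  layers (built from a separate, e.g. GTP-analog-stabilized, cap unit) are
  appended at the high-$z$ plus end.

Tip lengths can be randomized — each protofilament independently loses a
uniform number of layers in $[0, \texttt{tip\_max\_removed}]$ at each end,
from one seeded RNG stream — which mimics the ragged tips of real
filaments and removes artificial symmetry at the ends. The distribution is
uniform because the emulated protocol states only that lengths were
randomized; the seed makes any choice reproducible.

## Mechanics

Two independent routes to flexural rigidity are implemented, mirroring how
filament mechanics is measured in periodic-compression and tip-bending
simulations:

1. **Axial stress–strain.** Per pressure condition,
   $\sigma_{zz} = (P_{zz} - P_n)\,\langle L_x L_y\rangle / A_z$ and
   $\epsilon_{zz} = (\langle L_z\rangle - L_{z,\mathrm{eq}}) /
   L_{z,\mathrm{eq}}$; the Young's modulus $E_a$ is the least-squares
   slope. The cross-section $A_z = \pi(r_o^2 - r_i^2)$ and second moment
   $I = \frac{\pi}{4}(r_o^4 - r_i^4)$ come from wall radii inferred as the
   inflection points of the radial site-density histogram (Gaussian
   smoothing with bandwidth two bins, then the extrema of the
   finite-difference slope; the estimator is declared because "inflection
   point" alone does not pick one). Rigidity is $\gamma = E_a I$.
2. **Tip-load bending.** Inverting the clamped-beam relation
   $w = FL^3/(3EI)$ per measurement. The independent check here is a
   *discrete elastica*: an $n$-segment chain with curvature penalized at
   the joints, relaxed by BFGS energy minimization. Its linearized tip
   deflection is $\frac{FL^3}{3EI}\cdot\frac{(n+1)(2n+1)}{2n^2}$, i.e.
   $+1.5\%$ at $n = 100$, converging as $3/(2n)$ — so oracle and closed
   form agree within 2% at the resolutions the tests use.

Units are bridged once, centrally: pressures in bar with box lengths in nm
give stress in bar, reported in GPa ($10^{-4}$ GPa/bar); modulus times
second moment in GPa nm⁴ is reported in pN μm² ($10^{-3}$ pN μm² per
GPa nm⁴, since 1 GPa nm⁴ = $10^{-27}$ N m² and 1 pN μm² = $10^{-24}$ N m²).

## Structural observables

* **Residue contacts**: two residues are in contact when *any* pair of
  their sites is closer than 0.7 nm (minimum inter-site distance — the
  criterion is stated at residue level, so the most permissive site-level
  reading is used) and, on the same chain, more than two residues apart.
  Contacts are classified by labels into mutually exclusive classes
  (tail–self, tail–body intra/inter-dimer, intradimer, interdimer,
  inter-protofilament, seam), tail classes taking precedence.
* **Contact survival**: maximal presence runs, with interruptions up to
  `gap_tolerance` frames bridged; bridged gaps count toward the duration.
* **Angles**: total-least-squares line fits (first principal direction)
  per point set; the acute angle between directions serves both
  helix-orientation and protofilament-vs-axis measurements.
* **Separation correlation**: Pearson on raw series plus normalized mutual
  information from a 20-bin 2D histogram, normalized by the arithmetic
  mean of the marginal entropies. NMI estimates depend strongly on the
  binning and estimator, so printed literature scores are not comparable
  across implementations; the package documents its estimator and tests
  the degenerate points (identical series → 1, independent series → ~0)
  instead.
* **Radial ion density**: cylindrical-shell histogram normalized to 1 over
  a user-declared bulk window, with an optional exponential fit of the
  excess beyond the filament surface returning a screening length. The fit
  window ends where the excess decays below 2% of its starting value,
  which keeps far-field counting noise out of the fit.

## The toy simulator and what passing tests mean

`simulate_brownian()` integrates overdamped Langevin dynamics
(first-order Euler–Maruyama): displacement $(dt/\gamma) F$ plus Gaussian
noise of standard deviation $\sqrt{2 k_BT\, dt/\gamma}$ per coordinate,
with an explicit stability refusal when $dt\,k_\mathrm{max}/\gamma \ge
0.1$. Restrained sites are frozen by default (exactly reproducible), with
an optional finite harmonic restraint. Units are nm, ps, kJ/mol —
GROMACS-style — with $k_BT = 2.494$ kJ/mol at 300 K.

The simulator gives the package closed-loop oracles: equipartition
($\sigma^2 = k_BT/k$ for stiff isolated pairs, verified within 5% on
$\sim 10^5$ pooled samples), zero-temperature descent, and
fluctuation-matching recovery of known spring constants. What it does
*not* emulate: excluded volume, solvent structure, electrostatics,
realistic kinetics, or anharmonicity. Passing tests therefore demonstrate
that the estimators and the matching algebra are correct, not that any
particular force field is accurate — on real data the fluctuation targets
carry all of that physics.

Problem sizes in the tests are deliberately modest (hundreds of beads,
$10^4$–$10^5$ samples, 20-seed repetitions); each scales linearly if a
user wants tighter statistics.

## Numerical choices and degenerate inputs

* Population variance (denominator $n$) everywhere: the matching equations
  treat $\sigma^2$ as a distribution property, and mixing conventions
  would bias the update by $n/(n-1)$.
* Analysis windows default to the last 50% of frames (burn-in discard
  20% in the Brownian evaluator); both configurable.
* Zero reference variance is a hard error naming the pair (a rigid pair
  cannot be fluctuation-matched); missing stats coverage is an error
  listing pairs, while candidate pairs merely absent from an *optional*
  outlier screen are kept and logged.
* Negative updated spring constants are floored (default at 0), never
  deleted.
* Degenerate geometry — collinear centroids for helical measurement,
  zero-variance point sets for line fits, non-annular radial
  distributions — raise typed errors rather than returning numbers.
* All writers emit stable orderings and fixed float formats, so repeated
  writes are byte-identical; all generators take explicit seeds.
* Site indices are 1-based throughout (R convention), including in
  written topology files.

## Known limitations

* The matching update is a fixed-gain relaxation; very soft targets
  (below the contraction bound above) can oscillate. The trail makes this
  visible, but the package does not adapt the gain.
* The inflection-point radius estimator assumes a genuinely annular,
  reasonably sharp-walled distribution; heavily smeared walls push the
  inferred radii inward/outward by up to the smoothing bandwidth.
* The stress–strain route assumes a uniform isotropic thin cylinder; the
  bending route assumes small deflections ($w/L \le 0.1$). Both are flagged
  at run time when violated, not silently accepted.
* GRO files carry no chain identifiers, so lattice labels written to GRO
  round-trip through the residue-number convention only; PDB preserves
  chain and segment labels fully.
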