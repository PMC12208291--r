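# fmnet

Fluctuation-matched heterogeneous elastic networks for coarse-grained
filament lattices — with a helical lattice builder, trajectory statistics,
mechanical inference, and structural analysis.

## Who this is for

Coarse-grained simulations of large protein lattices (microtubules are the
motivating case) usually need an elastic network — harmonic springs between
nearby sites — to stay assembled, because the coarse Hamiltonian alone does
not carry the ligand- and nucleotide-mediated interactions that stabilize
the real lattice. A *uniform* network makes the assembly artificially stiff
and can induce systematic twisting. `fmnet` builds *heterogeneous*
networks whose per-pair spring constants are tuned so the coarse model
reproduces the per-pair distance fluctuations of a trusted reference
(typically an all-atom simulation of a small patch), and provides the
surrounding toolchain: lattice construction, per-pair statistics, mechanics,
structural observables, and standard-format IO. A built-in
Brownian-dynamics bead-spring simulator closes the
optimize–simulate–analyze loop so everything is testable without an MD
engine.

## The method in brief

Contacts are backbone-site pairs of the reference structure with
d<sub>ij</sub> ∈ [0.5, 0.9] nm, sequence separation |i−j| > 2 within a
chain, disordered segments excluded, and (optionally) pairs whose
structural distance is a ≥3σ outlier of the reference fluctuation
distribution dropped. Spring constants are initialized inversely
proportional to the reference distance variances,

&nbsp;&nbsp;&nbsp;&nbsp;k<sub>ij</sub> = k₀ · min(σ²) / σ²<sub>ij</sub>,&nbsp;&nbsp;&nbsp;k₀ = 500 kJ mol⁻¹ nm⁻²,

then refined by fluctuation matching,

&nbsp;&nbsp;&nbsp;&nbsp;k<sub>ij</sub> ← k<sub>ij</sub> − (α·k<sub>B</sub>T / L<sub>cutoff</sub>⁴) · (σ²<sub>ref</sub> − σ²<sub>model</sub>),

with α = 1050, k<sub>B</sub>T = 2.494 kJ/mol, L<sub>cutoff</sub> = 0.9 nm,
tracking the mean mismatch D = ⟨σ²<sub>ref</sub> − σ²<sub>model</sub>⟩
until convergence. The fluctuation evaluator is pluggable: an external MD
engine in production, the internal Brownian simulator or a closed-form
k<sub>B</sub>T/k oracle in tests.

Around the core: `build_lattice()` assembles N-protofilament helical
lattices (default: 14 protofilaments, 25.77° twist, 0.874 nm rise per
protofilament, optional stabilized cap layers and randomized tip lengths);
`stress_strain_curve()` and `rigidity_from_bend()` infer the axial Young's
modulus (σ<sub>zz</sub> = (P<sub>zz</sub> − P<sub>n</sub>)·L<sub>x</sub>L<sub>y</sub>/A<sub>z</sub>, ε<sub>zz</sub> = ΔL<sub>z</sub>/L<sub>z,eq</sub>) and
flexural rigidity (w = FL³/3EI); `residue_contacts()`,
`contact_survival()`, `axis_angle()`, `dimer_separation_correlation()` and
`radial_density()` cover the structural observables.

## Worked example

```r
library(fmnet)
library(tibble)

# --- fluctuation-match springs against a known reference -------------
k_true <- c(450, 300, 220, 160, 500)                 # ground truth
target <- tibble(i = 1:5, j = 6:10, var = 2.494 / k_true)
springs0 <- tibble(i = 1:5, j = 6:10, d0 = 0.7, k = 500)

fit <- iterate_to_convergence(springs0, target, evaluator_analytic(),
                              enm_config())
glance(fit)
#> # A tibble: 1 × 4
#>   iterations   D_final k_mean_final converged
#>        <int>     <dbl>        <dbl> <lgl>
#> 1         32 0.0000950         331. TRUE
round(fit$springs$k, 1)
#> [1] 461.5 310.6 221.0 160.0 500.0
```

After 32 iterations the mean variance mismatch D has fallen to
9.5×10⁻⁵ nm² and the recovered constants sit within a few percent of the
ground truth (the stiffest springs converge slowest — the update gradient
scales as 1/k²). `autoplot(fit)` shows the |D| trail.

```r
# --- mechanics: Young's modulus from synthetic compression runs ------
g <- cylinder_geometry(8.4, 12.5)     # r_i, r_o in nm
g
#> # A tibble: 1 × 4
#>     r_i   r_o   A_z      I
#>   <dbl> <dbl> <dbl>  <dbl>
#> 1   8.4  12.5  269. 15264.
runs <- make_box_runs(E_a = 0.64, geometry = g,
                      pressures = c(-0.25, 0.5, 1.25, 2),
                      noise = 0.02, n_frames_per_run = 40, seed = 1)
res <- stress_strain_curve(runs, g, reference = "ref")
res
#> <stress_strain_result> E_a = 0.634 +/- 0.016 GPa over 5 conditions
gpa_nm4_to_pn_um2(res$E_a * g$I)      # flexural rigidity, pN um^2
#> [1] 9.68
```

The fitted slope recovers the seeded 0.64 GPa within its standard error;
multiplying by the second moment of the cross-section gives the flexural
rigidity in pN μm².

```r
# --- build a capped 14-protofilament lattice and measure it back -----
dimer <- tibble(x = c(0.3, 0.1), y = c(11, 11.2), z = c(0, 4),
                chain_id = "A", residue_index = 1:2,
                monomer_id = c("alpha", "beta"))
mt <- build_lattice(dimer,
                    helical_params(n_layers = 19, cap_layers = 6,
                                   layer_period = 8),
                    cap_unit = dimer)
mt
#> <lattice_assembly> 700 sites, 14 protofilaments, 25 layers
measure_helical_params(mt)
#> # A tibble: 1 × 3
#>   twist_per_pf rise_per_pf n_protofilaments
#>          <dbl>       <dbl>            <int>
#> 1         25.8       0.874               14
```

`write_structure(mt, "mt.pdb")` writes the assembly with one chain per
protofilament and the layer encoded in the residue numbering; a thin
command-line wrapper over these functions is installed at
`system.file("cli", "fmnet.R", package = "fmnet")`.

See `vignette("fluctuation-matched-networks")` for the model, the
parameter meanings and defaults, and the design decisions.

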