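# prefint

Quantifies how cosolvents (osmolytes such as glycerol) shift
protein-protein association equilibria, for structural-bioinformatics and
protein-formulation work. The same cosolvent can strengthen one complex
and weaken another; `prefint` resolves this through preferential
interaction theory and the quantitative characterization of local protein
solvation from solvent configurations around rigid structures.

The central quantity is the preferential interaction coefficient of a
protein state, computed per trajectory frame by two-domain counting at
the protein van der Waals surface (local = any solvent heavy atom within
5 Å of the surface):

    Gamma(t) = n_x(t) - n_w(t) * (N_x - n_x(t)) / (N_w - n_w(t))

with `n` the local and `N` the total molecule counts of cosolvent (`x`)
and water (`w`). Wyman linkage connects the association-induced change
`DeltaGamma = Gamma(AB) - Gamma(A) - Gamma(B)` to the association
constant: `d ln K_A / d ln a_x = DeltaGamma`, i.e.
`ln(K_A/K_A0) = DeltaGamma(m)` when `Gamma` is linear in cosolvent
molality. The package computes `Gamma` at global, interface-region and
single-residue resolution (with block-averaged standard errors),
determines the interface distance `D*` at which solvation changes vanish,
accumulates volumetric solvent density maps with hydration-site
detection, estimates `K_A` from steady-state binding responses by
Scatchard analysis, and generates synthetic solvent configurations with
known ground truth so every estimator is testable offline.

## Worked example

A two-blob "complex" with a dewetted contact (cosolvent totally excluded
from the contact cylinder, water reduced), its two free blobs, and the
full analysis chain:

```r
library(prefint)

spec <- dewetted_contact_scenario(seed = 816)
free <- split_free_states(spec)
cpx <- generate_system(spec)
fa  <- generate_system(free$A)
fb  <- generate_system(free$B)

g_cpx <- gamma_per_residue(cpx$sol, cpx$traj)   # cutoff 5 A
g_fa  <- gamma_per_residue(fa$sol, fa$traj)
g_fb  <- gamma_per_residue(fb$sol, fb$traj)

g_cpx$global
#> Gamma (global, cutoff 5.0 A): 22.488 +/- 0.231  [400 frames]

delta_gamma(g_cpx$global, g_fa$global, g_fb$global)
#> Delta-Gamma (global): -5.54 +/- 0.45

dst <- determine_interface_distance(cpx$sol, "A", g_cpx, g_fa, g_fb,
                                    D_grid = 3:12, k = 1)
dst$D_star
#> [1] 8
```

Reading: each free blob carries a positive `Gamma` (two-fold cosolvent
shell enrichment), but association expels the enriched cosolvent from the
contact, so the complex's coefficient falls short of the sum of the free
ones -- `DeltaGamma < 0`, meaning this cosolvent weakens the association
(`ln K_A` drops by ~5.5 at the reference molality). The interface scan
finds `D* = 8` Å: residues farther than 8 Å from the partner protein
solvate identically in the free and associated states, so the whole
solvation change is carried by the interface region. `residue_delta_map()`
then localizes it residue by residue, and `write_residue_coloring()`
exports the map for molecular viewers.

On the experimental side:

```r
C <- c(0.1, 0.2, 0.5, 1, 2, 5) * 1e-6            # molar
R <- 150 * 2e6 * C / (1 + 2e6 * C)               # steady-state responses
scatchard_ka(binding_isotherm(C, R))$K_A
#> [1] 2e+06

fit <- linkage_fit(c(0, 3, 6), 2e6 * exp(c(0, -0.6, -1.2)))
dgamma_exp(fit, 6)$value                         # implied solvation change
#> [1] -1.2
```

A thin command-line pipeline over the same functions lives in
`inst/cli/prefint.R` (subcommands `gamma`, `interface`, `delta`, `maps`,
`linkage`, `synth`).

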