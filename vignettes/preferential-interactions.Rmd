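---
title: "Quantifying cosolvent effects on protein-protein association from local solvation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cosolvent effects on protein-protein association from local solvation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prefint)
```

## The problem

Osmolytes and other cosolvents (glycerol, TMAO, urea, ...) shift
protein-protein association constants, and they do so in a
protein-specific way: the same cosolvent can strengthen one complex and
weaken another. Preferential-interaction (Wyman linkage) theory explains
this through the preferential interaction coefficient $\Gamma$ of each
protein state -- the excess number of cosolvent molecules in the protein's
local solvation domain relative to the bulk solvent composition. Adding
cosolvent pushes the association equilibrium towards the state with the
larger $\Gamma$:

$$\left(\frac{\partial \ln K_A}{\partial \ln a_x}\right) = \Delta\Gamma
  = \Gamma_{AB} - \Gamma_A - \Gamma_B,$$

with $a_x$ the cosolvent activity and $\Gamma_{AB}$, $\Gamma_A$,
$\Gamma_B$ the coefficients of the complex and the two free proteins.
When $\Gamma$ is linear in cosolvent molality $m$ -- the regime in which
equilibrium constants respond exponentially to cosolvent concentration --
and activity is treated as proportional to molality, this integrates to
the simple working form $\ln\!\big(K_A(m)/K_{A,0}\big) = \Delta\Gamma(m)$.
`prefint` implements both directions of this linkage: from solvent
configurations around rigid structures to $\Delta\Gamma$, and from
measured $K_A(m)$ responses to an experimental $\Delta\Gamma_{\exp}$.

## The two-domain counting model

A solvent molecule belongs to the *local* domain of a protein when its
surface distance -- the minimum over its heavy atoms and all protein atoms
of the atom--atom distance minus the protein atom's van der Waals radius
-- is at most a cutoff, 5 Å by default. Per frame $t$, with $n^{II}$ the
local counts and $N$ the totals per species ($w$ water, $x$ cosolvent),

$$\Gamma(t) = n_x^{II}(t)
 - n_w^{II}(t)\,\frac{N_x - n_x^{II}(t)}{N_w - n_w^{II}(t)},$$

and the reported coefficient is the mean of this series (the
*instantaneous* estimator). A ratio-of-means variant (trajectory-mean
counts inserted into the same formula) is available through
`gamma_global(..., estimator = "ratio_of_means")`; on every test fixture
the two agree within one standard error, and the instantaneous form is
the default because it makes the residue decomposition exact (below).

Each local molecule is assigned to the single residue whose surface it is
nearest to; exact distance ties go to the lowest (chain, residue number).
Because this is a partition, the residue coefficients
$\Gamma_{\mathrm{res}}$ sum to the global $\Gamma$ *frame by frame*, and
any regional sum (for example over interface residues) inherits the same
exact additivity:
$\Gamma = \Gamma^{\mathrm{inte}(D)} + \Gamma^{\mathrm{non\text{-}inte}(D)}$.
The suite asserts these identities to machine precision on 50 seeded
fixtures, and checks the optimized neighbor search against an all-pairs
brute-force recount (`brute_force_gamma`), which must agree exactly.

Conventions applied throughout: coordinates in Å; solvent hydrogens are
ignored (heavy atoms only), which makes occupancy statistics robust to
trajectories stripped of hydrogens; with orthorhombic box lengths present,
distances use the minimum-image convention, otherwise boundaries are open;
the bundled Bondi-type radii table (`vdw_radii()`) defines the protein
surface and can be overridden entry-wise. The radii source of the original
force-field-based analyses is not part of this package's scope; at a fixed
5 Å cutoff $\Gamma$ is only weakly sensitive to the table, but the table
is pinned for reproducibility.

## Errors for correlated series

Simulation frames are autocorrelated, so naive standard errors understate
the uncertainty. `block_error()` divides a series into $2^k$ blocks
($k \ge 2$), computes $\mathrm{SE}(k) =
\mathrm{sd}(\text{block means})/\sqrt{\#\text{blocks}}$, and returns the
plateau value, taken as the maximum over the two largest block lengths
with at least four blocks, floored at half the naive i.i.d. SE. The rule
is deliberately pinned and testable: on i.i.d. data it reproduces
$\mathrm{sd}/\sqrt{n}$ within sampling error, and on an AR(1) series with
$\rho = 0.9$ it recovers the
$\sqrt{(1+\rho)/(1-\rho)} \approx 4.4$-fold inflation to well over twice
the naive value. Series shorter than 8 frames fall back to the naive SE
(and `block_error` itself refuses them).

## The interface region and D*

The interface region $\mathrm{inte}(D)$ of a complex contains every
residue with at least one atom within an atom-center distance $D$ of the
partner protein, pooled over both sides; the rest is
$\mathrm{non\text{-}inte}(D)$. Atom-center distances (not vdW-surface
distances) define membership -- interface proximity is a
protein-protein statement, distinct from the solvation-shell definition.

The working distance $D^*$ is the smallest grid value at which the
non-interface solvation change
$\Delta\Gamma^{\mathrm{non\text{-}inte}}(D)$ does not significantly
differ from zero, $|\Delta| \le k\,\mathrm{SE}$ with $k = 1$ by default
and SEs combined in quadrature across the three independent trajectories.
The default grid is 3--12 Å in 1 Å steps, which brackets the published
working distances (7 and 9 Å) for the two antibody--lysozyme systems this
methodology was developed on. Two choices here were genuinely open and are
therefore configurable: the significance rule behind "not significantly
different" (the $k=1$ quadrature rule is consistent with the published
non-interface differences of $-1.2\pm1.5$ and $-0.5\pm2.4$), and whether
$D^*$ must hold for all larger $D$ (we adopt the minimal-$D$ rule and
expose the full scan so the plateau behaviour is visible). Residue-level
maps use $k = 2$ and can be written onto the structure's B-factor column
with `write_residue_coloring()` for the usual red/blue rendering.

$D^*$ is a stochastic estimator: each grid point is an accept/reject test
at $\approx 1\sigma$, so repeated realizations of the same system scatter
$D^*$ by about a grid step around its noise-free value. This is why
`determine_interface_distance()` always returns the full scan, not just
the selected distance.

## Volumetric maps and hydration sites

`accumulate_grid()` deposits solvent heavy atoms on a 3D grid (default
0.5 Å spacing, 10 Å padding, half-open voxels) per species. The bulk
reference composition is measured from voxels farther than 8 Å from the
solute surface -- outside the 5 Å local domain with margin -- rather than
from whole-box averages, so the perturbed shell does not contaminate the
reference. A voxel is classified cosolvent-preferred when its occupancy
ratio exceeds the bulk ratio by more than a fold factor $f$ (default 2)
with both species above a minimum occupancy (default 20 counts); the
water-preferred condition is symmetric with $1/f$; low-occupancy voxels
are reported as undersampled rather than forced into a class. The numeric
threshold behind published "high local concentration" wireframes is not
printed anywhere authoritative, so $f = 2$ is a pinned package default,
not a literature value.

Hydration sites -- localized positions occupied by a water molecule in a
large fraction of frames, the simulation analogue of crystallographic
waters -- are detected as greedy non-overlapping local maxima of the
water grid, scored by the fraction of frames with at least one water
heavy atom within the site radius of the center, and ranked by that
occupancy with lexicographic tie-breaks. Grids and classifications export
to OpenDX text (`write_volumetric()`, z index fastest, the layout
molecular viewers expect) for visual inspection.

## The synthetic-configuration generator

Every estimator is testable without any download because the `scenario()`
/ `generate_system()` pair produces solvent configurations with known
ground truth. Solvent molecules are placed by rejection sampling: uniform
proposals in the box, rejection inside the solute's hard core, and
acceptance proportional to the enrichment factor of the region the
proposal falls in (contact cylinder > binding patch > solvation shell >
bulk), normalized so the largest factor maps to probability 1. Counts per
species are exact every frame, and a fixed seed regenerates trajectories
bit for bit. Frames are i.i.d. by default -- separating estimator
correctness from time-correlation handling -- and an AR(1) mode (each
molecule retained with probability $\rho$, resampled otherwise) exists to
validate the block-error machinery.

What the generator emulates: shell enrichment/exclusion (preferential
binding or hydration), a dewetted protein-protein contact (per-species
exclusion from a cylinder around the contact axis), peripheral binding
patches, and frame autocorrelation. What it does not emulate: real
solvent structure (radial distribution shells, hydrogen-bond networks,
orientational order) and force-field-level solvation numbers. Passing
tests therefore demonstrate that the estimators recover known composition
biases of the sampling density, not that any particular force field is
reproduced.

Two independent oracles close the loop. `brute_force_gamma()` recounts
everything all-pairs with no indexing and must agree exactly.
`expected_gamma()` integrates the acceptance density on a fine
deterministic grid to give analytic expectations of local counts, global
and per-residue $\Gamma$ -- it never sees sampled frames, so agreement of
measured values within a few SE is a genuine recovery test.

## Reference study conditions

The dewetted-contact demonstration (`dewetted_contact_scenario()`) uses a
26-residue two-blob complex (blob radius 4 Å, centers 12 Å apart) in a
$56 \times 44 \times 44$ Å box with 3400 waters and 370 cosolvent
molecules -- approximately liquid-water number density (0.031 Å$^{-3}$)
and a 6 molal-like mole ratio -- two-fold cosolvent shell enrichment, and
a contact cylinder (radius 5 Å, half-length 3 Å) with total cosolvent
exclusion and water reduced to 30%. The reservoir size matters: with few
hundred molecules, the net cosolvent excluded at the contact measurably
shifts the bulk composition ratio and thereby couples a small bias into
*every* residue's coefficient -- a finite-size effect that vanishes at
realistic reservoir sizes and would otherwise smear the perturbation over
the whole surface. Free-state references are generated by splitting the
complex and re-solvating each blob alone with the same shell factors and
no contact region. The generator-truth perturbation extent is defined
from the quadrature oracle as the largest partner-distance among residues
with analytic $|\Delta\Gamma_{\mathrm{res}}| > 0.15$.

The test suite and the acceptance script run this scenario at 400 frames
per system, the null calibration at 2000 frames, and the identity suite on
50 four-frame fixtures; these sizes were chosen to keep every stochastic
check several standard errors away from its threshold while remaining
desk-scale.

## Experimental side: Scatchard and the linkage fit

`scatchard_ka()` estimates $K_A$ from steady-state binding responses at a
series of analyte concentrations by the classical linearization $R/C =
K_A R_{\max} - K_A R$; it refuses non-negative (or exactly flat) slopes
and flags curvature, which indicates non-1:1 binding. A direct nonlinear
isotherm fit (`isotherm_ka_nls()`) is provided purely as a cross-check
and agrees within 10% on clean data. `linkage_fit()` then regresses
$\ln(K_A/K_{A,0})$ on molality through the origin by weighted least
squares -- $K_{A,0}$ is the measured reference, not a free parameter --
and `dgamma_exp()` converts the slope into the experimentally implied
$\Delta\Gamma_{\exp}(m)$. The proportionality of activity to molality is
an assumption (recorded in the fit object's `assumptions` field), adopted
because it is what makes the exponential $K_A$ response equivalent to a
molality-linear $\Gamma$.

## Statistical calibration and known limitations

Residue-level significance calls use $|\Delta\Gamma_{\mathrm{res}}| >
k\,\mathrm{SE}$ with $k = 2$. Under a null generator the per-residue
false-positive rate sits at its nominal $\approx 5\%$ level (asserted in
the suite). Note what this implies: with $R$ residues the probability of
at least one spurious flag is $1 - 0.95^R$, so a whole-structure map of a
null system will typically show a few flagged residues; interpret maps
residue-wise, or raise $k$ for family-wise control.

Other limitations worth knowing: frames are assumed pre-aligned to the
rigid solute (no superposition is performed, matching the
constrained-backbone setting this methodology requires); the finite
solvent reservoir couples strong local perturbations weakly into all
residues through the bulk ratio (see above); $D^*$ inherits grid-step
sampling noise; and reproducing published force-field solvation numbers
requires the original >100 ns simulations of the real systems, which is
outside what this package (or any desk-scale test) does.
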