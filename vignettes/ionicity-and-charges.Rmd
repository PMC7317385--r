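---
title: "Atomic partial charges and principal components of ionicity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atomic partial charges and principal components of ionicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chargekit)
```

## The problem

Atomic partial charges are not observables: they are definitions, and dozens
of competing definitions are in routine use. chargekit implements a
representative member of every major family — orbital-partition charges
(Mulliken, Loewdin, Bickelhaupt, and their minimal-basis-projected variants),
stockholder density partitioning (Hirshfeld, iterative Hirshfeld, ISA, MBIS),
discrete density partitioning (grid Bader/QTAIM, Voronoi deformation
density), electrostatic-potential fitting (CHELPG-style point selection),
and the empirical CM5 and EEQ models — together with a statistical engine
that treats the per-atom outputs of many schemes as one multivariate sample
and asks how much independent information they actually carry. The working
hypothesis, supported by large published surveys, is that a latent
"ionicity" scale dominates: all schemes move together along one leading
principal component, a second component separates QTAIM-type charges from
the rest, and a weak third separates electrostatic from orbital-based
schemes.

## Orbital-partition charges

Given a closed-shell one-particle density matrix $P$ and overlap matrix $S$
in the atomic-orbital basis, the gross overlap populations are
$q_{ij} = P_{ij} S_{ij}$, which sum to the electron count. Mulliken
condensation splits every off-diagonal pair evenly,

$$Q'_{ii} = q_{ii} + \tfrac12\sum_{j \ne i} (q_{ij} + q_{ji}),$$

while the Bickelhaupt variant weights the split by the diagonal populations,

$$Q'_{ii} = q_{ii} + \sum_{j \ne i} \frac{q_{ii}}{q_{ii} + q_{jj}}
           \,(q_{ij} + q_{ji}),$$

so the function with the larger diagonal population claims the larger share.
Both conserve the total population exactly; when all diagonal populations
are equal the two coincide. Pairs with $|q_{ii} + q_{jj}| < 10^{-10}$ have
no defined weight; they fall back to an even split and the event is counted
in the diagnostics (this preserves conservation, which we consider
non-negotiable).

Full-basis Mulliken-type analyses are pathologically basis-set dependent.
The minimal-basis-projected variants (MBS-Mulliken, MBS-Bickelhaupt) fix
this by projecting the occupied orbitals onto one minimal function set:
$C_m = S_{mm}^{-1} S_{mf} C_{occ}$, followed by Loewdin symmetric
orthonormalization of the projected orbitals within the minimal basis.
We chose occupied-orbital projection plus re-orthonormalization — rather
than projecting the density matrix directly — because it restores
idempotency and the exact electron count without any ad hoc rescaling.
Whether published implementations renormalize per orbital or globally is
not documented; our contract is simply an orthonormal occupied space, and
the package documents this choice. The projection is exactly the identity
when the minimal basis equals the working basis, and is invariant to adding
working-basis functions that the occupied space does not touch; both
properties are tested.

chargekit deliberately contains no integral engine: overlap matrices
(including the cross overlap $S_{mf}$) are part of the wavefunction
container, which keeps the package honest about what it computes and makes
fixtures exact.

## Real-space charges and quadrature

All real-space schemes reduce to integrals of weighted densities. Two
substrates are provided: cube lattices (every voxel a quadrature point with
the voxel volume as weight) and Becke-style molecular grids. The Becke grid
uses Gauss-Chebyshev (second kind) radial nodes under the map
$r = R_m (1+x)/(1-x)$ with $R_m$ from Bragg-Slater radii, and a spherical
product rule — Gauss-Legendre in $\cos\theta$ times a uniform azimuthal
grid — for the angular part, with the standard Becke fuzzy-cell weights
($k = 3$ smoothing iterations) combining atomic grids. We use the product
rule rather than Lebedev nodes because no table-free construction of Lebedev
weights exists and the product rule integrates spherical harmonics exactly
to the corresponding degree; at the defaults (75 radial nodes, 24 theta
nodes, hence 1152 angular points) fixture densities integrate to the
electron count to better than $10^{-4}$ relative, the contract the grid has
to meet, and the radial-refinement error decreases monotonically.

Proatom reference densities come from a database keyed by (element, integer
charge). The bundled database is an analytic single-exponential Slater
model, $\rho(r) = N\zeta^3/(8\pi)\, e^{-\zeta r}$ with $N = Z - q$, one
documented $\zeta_0$ per element (H-Ar) and
$\zeta(q) = \zeta_0 (1 + 0.15\,q)$ so cations are more compact than anions.
This keeps the package self-contained and — because the synthetic scenes are
drawn from the same family — makes parameter-recovery tests sharp rather
than approximate. Users with ab initio atomic densities can supply tabulated
profiles; tabulated entries are interpolated linearly in log-density,
extrapolated exponentially beyond the last radius (fit over the outermost
decade) and held constant below the first, so stockholder weights always
see strictly positive promolecule values.

### Stockholder family

Hirshfeld charges share each point among atoms in proportion to neutral
proatom densities. Hirshfeld-I iterates the proatom populations to
self-consistency, linearly interpolating proatom profiles between the
bracketing integer charge states; iteration 0 is plain Hirshfeld, the
default convergence is $\max_A |\Delta N_A| < 10^{-6}$ (500 iterations cap),
and a population that leaves the available charge-state bracket (-1..+2
bundled) is an error rather than an extrapolation, because extrapolated
proatoms are unphysical. ISA removes proatoms entirely: each atom's radial
profile is the spherical average of its own share of the density, computed
on 64 log-spaced shells between 0.02 and 20 Bohr with triangular binning in
log-radius. MBIS represents each proatom as one Slater shell per period row
(H, He: 1; Li-Ne: 2; Na-Ar: 3) and updates shell populations and widths
with the standard moment formulas; shells whose population or width
collapses are pruned with a recorded warning. For a single atom whose
density is itself one Slater shell the MBIS fixed point is exact, which the
tests exploit ($N$ and $\sigma$ recovered to $10^{-4}$). When a
multi-shell element is asked to fit a single-exponential density the
decomposition is nearly degenerate and convergence is slow — a property of
the model, not the implementation; the relevant tests use a looser
tolerance there and we document that charge sums are conserved at any
stopping point.

Grid points where the promolecule density falls below
$10^{-12}\,e/\mathrm{Bohr}^3$ get zero weight for every atom and are
excluded from integrals: this avoids 0/0 in essentially empty space and
affects charges far below grid accuracy. Every scheme records its grid
normalization defect and enforces charge-vector sum consistency within 1.5
times that defect.

### Discrete domains

VDD assigns each voxel to the nearest atom (ties to the lower atom index —
determinism over elegance; the effect vanishes under refinement) and
integrates the deformation density $\rho - \rho_\text{promolecule}$ over the
cells. The grid Bader implementation does near-grid steepest ascent: each
voxel points to the 26-neighbour with the largest density gain per unit
distance (exact ties to the lowest voxel index), pointer-jumping resolves
every path to a local maximum, maxima within 0.4 Bohr of a nucleus become
that nucleus's attractor, and non-nuclear maxima are merged into the
nearest nucleus with a recorded warning. Voxels below
$10^{-8}\,e/\mathrm{Bohr}^3$ are vacuum and stay unassigned. This is a
deterministic on-grid approximation to the true zero-flux partition; basin
populations sum exactly to the assigned voxel sum by construction, and the
error against analytic oracles shrinks monotonically under refinement on
the tested scenes.

## ESP fitting and empirical models

The ESP fitter minimizes the squared deviation from the potential at a
CHELPG-style point set — a rectangular lattice (default 0.3 Angstrom
spacing) clipped to the shell between the scaled Bondi van der Waals
surface and a 2.8 Angstrom outer envelope — under the total-charge
constraint, solved exactly as one augmented linear system; the relative RMS
residual is reported in the diagnostics. The named ESP schemes in the
literature (Merz-Kollman, RESP, HLY, CHELPG) share this physical basis and
differ only in point selection, so the package implements one generic
constrained fitter and names the output `esp-chelpg` to avoid overclaiming.
A field generated by nuclear-centred point charges is recovered to machine
precision for any geometry and any valid point set — that is the defining
property of the estimator and is tested as such.

CM5 adds an antisymmetric pairwise correction to Hirshfeld charges with the
published global exponent and atomwise/pairwise parameters (bundled for
H-Ar; missing elements are an error, never a silent zero). Antisymmetry
makes charge conservation exact. EEQ minimizes the classical
electronegativity-equalization energy with Gaussian-smeared Coulomb
interactions, one $(n+1) \times (n+1)$ solve; the bundled
electronegativity/hardness/width table is a self-contained model
parameterization documented in the source (the coordination-number-dependent
flavour of some published EEQ fits is out of scope), and a user table can
replace it wholesale.

## The meta-analysis engine

One atom is one observation; atoms are pooled across molecules, unweighted.
Published surveys do not state any weighting, and pooling is the only
choice that treats every charge the same — but it does mean abundant
elements (hydrogens above all) dominate the sample, which users should keep
in mind. Holes (missing method/atom combinations) are first-class and
resolved by complete-case filtering with a reported drop count, never by
imputation. Molecules whose atoms are all symmetry-equivalent (atoms,
homonuclear diatomics, P4-like clusters) carry no information and are
filtered by a sorted-distance fingerprint; duplicate species are detected
by stoichiometry plus principal moments of inertia within a relative
tolerance of $10^{-4}$ (enantiomers collapse — a documented limitation of
the rotational-constant criterion).

PCA is an eigendecomposition of the correlation or covariance matrix with
loadings signed so each vector's largest-magnitude entry is negative — the
convention of published loading tables where the leading ionicity component
has every method pulling with the same (negative) sign; the convention is
cosmetic and recorded on the result. Backward elimination repeatedly drops
the variable with the largest coefficient in the smallest-eigenvalue
eigenvector. The GCD (generalized coefficient of determination) of a
variable subset of size $k$ is the overlap
$\mathrm{tr}(P_S P_K)/k$ between the projector onto the subset's centered
data columns and the projector onto the first $k$ principal-component score
vectors; the package evaluates it directly from the covariance matrix via
$\sum_{i \le k} v_i^\top \Sigma_{\cdot S}\,\Sigma_{SS}^{-1}\,
\Sigma_{S\cdot} v_i / \lambda_i$, which agrees with the brute-force
projector computation (tested) and works when only a covariance matrix is
available. Subset search is exhaustive up to 20 variables and simulated
annealing (single swaps, geometric cooling, fixed seed) beyond; on every
fixture up to 12 variables the annealer matches the exhaustive optimum
across seeds.

The noise-robustness check appends a fraction (default 10%) of synthetic
observations drawn independently from each method's empirical marginal —
preserving scales, destroying cross-correlation — and reports eigenvalue
shifts and principal angles between original and perturbed loading
subspaces over replicates. This marginal-resampling reading of "adding
random numbers from the dataset" is one of two defensible interpretations;
we chose it because it is scale-free, and the qualitative result it is used
for (leading two components stable, third fragile) does not depend on the
choice. All randomized routines take explicit seeds, restore the caller's
RNG state, and are bitwise reproducible.

`reconstruct_covariance()` completes a published leading-PC summary
(eigenvalues plus rounded loading vectors) into a full-rank covariance by
adding an isotropic remainder on the orthogonal complement, sized to a
known total variance. That is the maximum-entropy completion given the
printed information. Quantities dominated by leading structure —
regressions among strongly loading variables, GCD selection, PC fits —
are insensitive to the completion; quantities that probe the trailing
space (e.g. the leading *correlation* eigenvalue, which divides by
variances the truncation underestimates) inherit a visible bias, and the
acceptance script reports them as computed rather than adjusting them.

## What the synthetic generators emulate — and what they do not

The polar-diatomic generator produces exact two-orbital closed-shell states
with closed-form Mulliken charges; the Slater-scene generator plants
per-atom populations whose continuum charges are known exactly; the ESP
generator plants point charges that the fitter must reproduce to machine
precision; the factor-table generator plants a low-rank covariance
(dominant shared factor, one opposed method, homoscedastic or per-method
noise) mirroring the structure real surveys find. Passing these tests shows
the estimators are correct on their own model families and that the
statistical machinery recovers planted structure at realistic sample sizes.
It does not show that any scheme is chemically right, that real molecular
densities (with shell structure, lone pairs and covalent bridges) are
partitioned with the same accuracy, or that the generators' chemical
composition resembles any benchmark set — no attempt is made to mimic one.

## Problem sizes and numerical defaults

The test suite and the acceptance script run stockholder schemes on Becke
grids of 60 radial x 14 theta nodes (about 24k points per atom), cube
scenes at 0.15-0.25 Bohr spacing with 6 Bohr margins, factor tables of
600-3000 observations, and a synthetic survey sample of 2125 pooled
observations whose sample covariance is constrained exactly to the
reconstructed published covariance. These sizes were chosen so every
tolerance in the contracts is met with an order of magnitude to spare while
a full run stays comfortably interactive. Key defaults: stockholder
convergence $10^{-6}$ e (populations) with 500-iteration caps, ISA profile
tolerance $10^{-5}$, promolecule underflow $10^{-12}$, Bader vacuum
threshold $10^{-8}$, ESP lattice 0.3 Angstrom / envelope 2.8 Angstrom,
annealing schedule $T_0 = 0.1$, cooling 0.97, 3000 steps.

## Known limitations

Closed-shell densities only (open shells enter as summed alpha+beta
densities); elements beyond Ar have no bundled parameters; grid Bader is an
approximation to analytic zero-flux partitioning and should not be expected
to match analytic-basin codes beyond grid accuracy; the bundled EEQ table
is a model parameterization, not a published fit, so EEQ magnitudes are
indicative; the workbook reader requires an explicit column-to-method map
because no standard layout exists for distributed charge spreadsheets.
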