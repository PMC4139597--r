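---
title: "Mean-field coarse-grained modelling of proteins, nucleic acids and polysaccharides"
author: "mfcg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mean-field coarse-grained modelling of proteins, nucleic acids and polysaccharides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfcg)
```

## The model

`mfcg` implements a unified coarse-grained representation of the three major
biopolymer classes, built on two observations: (i) the repeating unit of each
polymer carries one strongly polar group (the peptide bond, the nucleic-acid
base, the sugar ring) whose charge distribution is crudely a point dipole, and
(ii) the mean-field interaction between these dipoles, averaged over the
internal rotations that the coarse description discards, is what selects the
regular architectures - alpha-helices and beta-sheets, double helices,
helicoidally packed polysaccharide fibres.

All three chain classes share one geometric design:

* **protein** - a C-alpha anchor trace with 3.8 A virtual bonds (2.8 A for
  bonds flagged *cis*), united peptide groups (`p`) at the bond midpoints and
  one united side chain (`SC`) per residue attached to its anchor (glycine is
  a zero-offset site that rides its anchor);
* **nucleic acid** - a sugar-center (`S`) anchor trace, phosphate sites (`P`)
  midway between consecutive anchors, and one base site (`B`) per nucleotide;
* **polysaccharide** - a glycosidic-oxygen (`O`) anchor trace for 1,4-linked
  glucose chains, with one sugar-ring site per unit lying midway between
  consecutive anchors (a chain of *n* units has *n*+1 anchors).

Chain geometry is carried by virtual-bond lengths *d*, virtual-bond angles
*theta*, virtual-bond dihedrals *gamma* (IUPAC right-handed sign convention,
*cis* = 0, *trans* = pi - the zero points of these conventions are ours, they
are not dictated by the physics) and branch polar angles (*alpha*, *beta*)
measured in the local triad of the two flanking virtual bonds (outward
bisector, chain tangent, their cross product). Terminal residues borrow the
triad of the nearest interior anchor; two-anchor chains use a deterministic
perpendicular completion of the single bond direction. `internal_to_cartesian()`
/ `cartesian_to_internal()` are exact inverses, and the stored per-chain seed
frames make the round trip exact for multi-chain systems too.

## The energy functions

Every model's energy is a weighted sum of term classes; the per-term weights
and parameter tables live in YAML files under `inst/extdata/ff/`, never in
code. The shared ingredients:

* **Mean-field dipole-dipole interactions.** Each polar site carries a dipole
  with a component `mu_par` fixed along its rotation axis (the virtual bond
  for peptide and ring sites, the anchor-to-base vector for bases) and a
  component `mu_perp` that rotates freely about it. The reference evaluator
  `mean_field_dipole_energy()` computes the Boltzmann log-average of the
  point dipole-dipole energy over the two independent rotation angles by an
  equal-weight quadrature on a periodic grid (spectrally accurate; K = 36 is
  converged to well below 1e-6 kcal/mol). Inside the chain energy the
  second-order cumulant closed form
  `U = <E> - Var(E)/(2 R T0)` is used instead - the lambda-averages are
  analytic - which agrees with the quadrature to better than 5% beyond 6 A at
  the force fields' own dipole strengths and is orders of magnitude faster.
  Because purine bases carry a dominant `mu_par` and pyrimidines a dominant
  `mu_perp`, the averaged base-base energy is minimised when the two base
  axes are perpendicular - the geometry of Watson-Crick pairing emerges from
  the averaging, not from any pairing-specific term.
* **Gay-Berne anisotropic contacts** between side chains, bases, and sugar
  rings (orientation-dependent contact distance and well depth, 12-6 radial
  shape, spherical limit = plain Lennard-Jones).
* **Debye-Hueckel screened electrostatics** between phosphate sites, with
  the screening constant computed from a configurable ionic strength
  (default 0.1 mol/L) at the reference temperature.
* **Local terms**: harmonic virtual-bond stretching and angle bending,
  sixth-order Fourier torsional potentials (residue-type-pair lookup with a
  default table), a product-Fourier double-torsional surface, and a
  harmonic-plus-Fourier rotamer surface in (*alpha*, *beta*).
* **Correlation terms** (protein and sugar only; the nucleic-acid model has
  no correlation terms beyond its torsional potential): a simplified product
  form - the mean-field dipole kernel of a site pair multiplied by cosines of
  the flanking dihedrals - for the third-order terms, plus turn terms over
  consecutive segments (the adjacent-pair dipole interactions excluded from
  the long-range electrostatic sum by its `i < j - 1` index range live here).

Terms that originate from an order-*n* factor of the cluster-cumulant
expansion are multiplied by the temperature factor
`f_n(T) = ln(e + 1/e) / ln(exp((T/T0)^(n-1)) + exp(-(T/T0)^(n-1)))`,
which is exactly 1 at the reference temperature `T0` (300 K) and decays as
`1/T^(n-1)`: order 2 on the plain dipole electrostatics and torsions, order 3
on double-torsional, third-order correlation and three-segment turn terms,
order 4 on the four-segment turn term. The dipole kernels themselves are
evaluated at `T0`; all explicit temperature dependence of those terms is
carried by the multipliers, so the dependence is not double counted.

### Index ranges and exclusions

Peptide-peptide (and sugar ring-ring) electrostatic pairs skip nearest
neighbours (`i < j - 1`; adjacent pairs share an anchor and appear in the
turn terms instead). Phosphate-base excluded volume skips the two
nucleotides flanking the phosphate's own bond. All cross-chain pairs
interact; no bonded terms cross a chain break.

### Numerical safeguards

Two regularizations keep the force field integrable and are deliberate parts
of this implementation:

* every pair term is capped at +-1e4 kcal/mol (configurable `cap`);
* polar sites entering the plain dipole classes carry a repulsive
  excluded-volume core (peptide groups: `ev_sigma` 3.8 A), and the
  point-dipole kernel saturates below a core radius `r_core`
  (`r_eff^2 = r^2 + r_core^2`). Without these, the `1/r^6` second-order
  cumulant attraction is unbounded below and becomes a collapse attractor in
  dynamics; physically, the point-dipole approximation is invalid at contact
  anyway. Above ~1.5 contact diameters the softening changes the kernel by a
  few percent at most.

### Parameter provenance

The published, fully calibrated parameter tables of this model family are
not printed in the open literature, so the shipped tables are this package's
own documented defaults: side-chain Gay-Berne well depths follow a
hydrophobicity ordering; base dipole magnitudes are the physical gas-phase
base dipoles (purines parallel-dominant, pyrimidines perpendicular-dominant);
nucleic-acid weights use the printed 0.5 (base-base Gay-Berne) / 2.0 (all
other terms); protein weights default to 1. The nucleic-acid bonded
equilibria (d = 5.5 A, theta = 151.9 deg, gamma = -22.7 deg) are the internal
coordinates of an ideal right-handed duplex trace (radius 7 A, twist 36 deg,
rise 3.4 A), and base-base contact diameters (~3.4 A) put stacked neighbours
at the Gay-Berne minimum - knowledge-based calibration against the duplex
geometry, in the same spirit as deriving local terms from structural
databases. They should be read as calibration-pending defaults, not as the
published force field.

## Forces

Forces are the exact negative gradient of the total energy. The stiff local
terms (bond, angle, torsion) have analytic gradients; every other term class
uses central differences on the *defining points* of each pair term
(h = 1e-6 A, the last point by translation invariance), evaluated in
compiled code. This is a documented design choice, not an approximation of
consequence: the suite verifies agreement with central differences of the
total energy to 1e-4 kcal/(mol A) on all three chain classes, and the R and
compiled implementations of every kernel against each other to 1e-12.

## Dynamics

The integrator works in Cartesian site coordinates with lumped site masses
(anchors carry the backbone share, branches the residue remainder;
zero-offset glycine side chains ride their anchor). This differs from the
generalized virtual-bond-vector Lagrangian of the original protein model;
the contract preserved here is correct canonical sampling of the
coarse-grained coordinates, which the suite checks against closed-form
stationary statistics. One BAOAB Langevin step is
half-kick / half-drift / Ornstein-Uhlenbeck / half-drift / half-kick; with
zero friction it reduces exactly to velocity-Verlet (energy drift < 1e-5
relative over 10^4 steps on a soft harmonic dimer).

`amts_run()` adds the multiple-time-step structure: slow forces (all
nonbonded, mean-field, correlation, rotamer, double-torsion terms) enter as
impulses at the outer step; the stiff local forces advance on the inner step
(`dt/ratio`). At each outer step the inner step is halved, and the inner
count doubled, until the largest fast-force component falls below the
threshold `fmax` (default 100 kcal/(mol A)) times the accumulated halving
factor; more than `max_halvings` (8) aborts the run with a diagnostic. On
the 20-residue helix fixture the scheme completes 10^4 outer steps at outer
steps of 20 fs (and 25 fs) with bounded energies; friction default 0.1/fs.
Same seed and configuration give bit-identical trajectories (single RNG
stream, reseeded per run).

## Replica exchange

`mremd_run()` runs `length(temperatures) x mux` replicas, attempting
Metropolis temperature swaps every `exchange_interval` outer steps with
`min(1, exp[(1/RT_i - 1/RT_j)(U_i - U_j)])`, alternating even/odd neighbour
pairs across cycles; multiplexed layers swap within a temperature
(unconditionally, Delta = 0). Exchanges swap slot temperatures, velocities
are rescaled by `sqrt(T_new/T_old)`, and the full attempt log reconstructs
every replica's walk. With the temperature-dependent multipliers the
standard criterion is an approximation (exact whenever no multiplied term
contributes, as in the harmonic test systems); this is deliberate and
matches common practice. Per-segment MD seeds are derived deterministically
from the ladder seed, so a single-temperature, single-layer run is
bit-identical to the corresponding chain of plain MD segments.

## WHAM and melting analysis

`wham_solve()` iterates the *binless* (sample-based) WHAM equations - no
histogram bin widths to choose - to a 1e-8 tolerance on the dimensionless
free energies, reported relative to the first temperature, with a warning
when neighbouring temperatures' energy ranges barely overlap.
`thermo_curves()` reweights to arbitrary temperatures: mean energy, heat
capacity from energy fluctuations (`Cv >= 0` by construction), melting
temperature from the Cv peak by quadratic interpolation through the three
highest grid points, and - given a folded/duplex indicator - a two-state
van't Hoff analysis of the melting equilibrium constant (`dH` from the
`ln K` vs `1/T` slope over the 5-95% transition window, `Tm` from the
midpoint, `dS = dH/Tm`). The duplex indicator is the fraction of native
inter-strand base-base contacts within 1.5x their minimum-energy contact
distance (`native_base_contacts()` / `contact_fraction()`); the cutoff
factor is a configurable declaration, not a reconstruction of any published
criterion.

`kabsch_rmsd()` minimises RMSD over proper rotations (reflections excluded);
`cluster_conformations()` performs single-linkage clustering on pairwise
trace RMSD and reports the coordinate average of the most populated cluster
after superposing its members - the ensemble-averaged representative used in
ensemble-based structure prediction protocols.

## The restricted-free-energy machinery

The force-field terms are, conceptually, factors of a cluster-cumulant
expansion of the chain's potential of mean force. The `pmf` module makes
that derivation executable on toy systems: `restricted_free_energy()`
integrates component energies over uniform periodic grids of secondary
variables (trapezoid = equal weights, spectrally accurate; 72 points per
angle by default), `subset_rfe()` restricts to component subsets, and
`cluster_cumulant()` forms the signed inclusion-exclusion factor. Factors
vanish identically when components share no secondary variables; the sum of
all factors telescopes back to the full RFE; a factor whose lowest nonzero
cumulant has order *m* decays as `1/T^(m-1)` - all three properties are
verified in the suite. `derive_dipole_table()` reproduces the
derive-then-fit workflow for the dipole potentials: tabulate the averaged
energy over separations (3-15 A) times a deterministic quasi-uniform
(Fibonacci-sphere) orientation sample - the orientation design is ours, the
original sampling is not published - and fit a documented analytic basis
(fixed-dipole kernel, isotropic `1/r^6`, axial-projection corrections) by
linear least squares.

## What the synthetic fixtures emulate

* `helix20` - a 20-residue poly-alanine chain in a compact helical start
  (theta 90 deg, gamma 48 deg): the stability workhorse for the integrator.
* `duplex12` - two complementary 12-nucleotide strands (the size of the
  smallest duplex the model family was demonstrated on) as an ideal
  right-handed double helix plus separated extended chains. It is an
  idealized cylinder trace, labelled synthetic: real duplexes have sequence-
  dependent twist, grooves, and end fraying that the fixture does not.
* `sugar12` - a 12-unit alpha-D-glucose chain (one strand of the amylose
  test dimer), extended.
* `two_state_toy` - exact Boltzmann draws from a two-state melt
  (dH = 50 kcal/mol, Tm = 350 K, 2 kcal/mol Gaussian width): the ground
  truth for WHAM/van't Hoff recovery.

Passing tests on these fixtures demonstrate correctness of the machinery -
geometric identities, canonical statistics, estimator consistency, and the
mechanistic role of the base-base electrostatics (removing that term
measurably destabilises the pre-built duplex: the full model retains ~95% of
native contacts over 30 ps at 310 K where the electrostatics-free model
keeps ~45%; global RMSD is deliberately not the indicator, since the
electrostatic term also relaxes the idealized start). They do *not*
demonstrate folding of real sequences to experimental structures, which
requires calibrated parameter tables and cluster-scale replica-exchange
sampling far beyond these problem sizes.

## Problem sizes and numerical choices used by the checks

Chosen as the package's own verification scale: stationary-statistics runs
use the harmonic dimer for 1.2x10^5 steps of 1 fs at friction 0.05/fs (the
variance oracle is the exact radial Boltzmann integral, the comparison is
within three standard errors from long-block estimates); the integrator
stability runs use 2x10^3 (tests) / 10^4 (acceptance script) outer steps on
`helix20`; replica-exchange acceptance uses two replicas at 300/400 K with
200-step segments against a dense numerical double integral over the exact
energy densities; WHAM recovery uses 4-7 temperatures with 800-3000 exact
two-state samples each. Seeds are fixed throughout; every stochastic
tolerance is stated in standard errors or as the 5%/2 K recovery bands.

## Known limitations

* Parameters are documented defaults, calibration-pending; no claim is made
  to reproduce published melting thermodynamics or structure-prediction
  benchmarks.
* Disulfide terms, the trans-cis double-well stretching extension,
  fourth-order correlation terms (present only as an off-by-default stub for
  sugars), off-1,4 glycosidic linkages, branching, and protein-nucleic-acid
  cross potentials are out of scope.
* The rotamer surface uses a single generic parameter set for all residue
  types; torsional tables fall back to a single default entry.
* The exchange criterion ignores the temperature dependence of the
  multipliers (exact for the harmonic validation systems).
* Cartesian-site dynamics with lumped masses, not the generalized
  virtual-bond Lagrangian; kinetics are therefore not comparable to the
  original implementation, equilibrium sampling is.
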