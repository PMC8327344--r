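---
title: "Methods: quantifying lipid-binding sites on pentameric channels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying lipid-binding sites on pentameric channels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidsite)
```

`lipidsite` quantifies how lipid headgroups of different charge classes
engage a C5-symmetric membrane protein: which residues they contact, where
they accumulate, how stably they sit in a binding site, and how closely a
cationic headgroup approaches an aromatic ring. A companion set of
dose–response tools covers the electrophysiological side of the same
question. This vignette describes the models, the conventions that were
fixed where more than one choice was defensible, and what the built-in
synthetic membrane does and does not establish.

## Contact profiles

A residue is *in contact* with a lipid class in a frame when any of its
particles (any bead in coarse-grained mode; any non-hydrogen atom in
atomistic mode) lies within a threshold distance — 5.5 Å (CG) or 3.2 Å
(atomistic) by default — of any headgroup particle of any lipid of that
class, under the minimum-image convention for orthorhombic boxes. The
profile value is the **frame-occupancy frequency**: the fraction of
analyzed frames with at least one contact. A per-frame count of distinct
contacting lipids is reported as a secondary column (`mean_contacts`), but
the frequency is the primary statistic: it is the only reading of a
"normalized contact number" that is consistent with flagging residues
above a 33% cutoff. Two further conventions are fixed for exact
reproducibility:

* the threshold comparison is **inclusive** (`<=`), so oracle tests can
  assert exact equality at the boundary;
* hot-residue classification is **strictly** above the cutoff (a residue
  at exactly 0.33 is not hot).

Subunit averaging is the plain arithmetic mean of the five per-chain
frequencies at each residue number; the symmetry map is the ordered list
of the five protein chains with residue correspondence by identical
author numbering (numbering is never re-indexed). Default analysis
windows discard the first 25% of frames in CG mode and 50% in atomistic
mode — the equilibration conventions appropriate to long CG versus
shorter atomistic runs — and are freely overridable, including as
explicit time intervals. Replicates are windowed first, then pooled with
equal frame weight; per-replicate profiles remain available for
dispersion estimates.

The distance search is a dense vectorized all-pairs computation. At the
system sizes this package targets (hundreds of protein particles against
hundreds of headgroups) this is faster in R than maintaining cell lists,
and it *is* the all-pairs contract; the test suite still verifies it
against an independent scalar-loop implementation on randomized systems.

## Occupancy densities

The density grid covers the full periodic box at 2 Å spacing by default.
Per frame, each selected particle is wrapped into the primary cell and
increments the voxel `floor((x - origin)/spacing)`; particles landing
exactly on the upper box face wrap to voxel 0. This half-open convention
makes mass conservation exact: `sum(values) * voxel_volume` equals the
mean number of selected particles per frame to rounding error, which the
tests assert at 1e-9. Values are reported in molecules/nm³ (1 nm³ =
1000 Å³). No smoothing is applied; a five-fold symmetrized variant
(`symmetrize_c5()`) is available as a variance-reduction device, with the
raw grid always primary. Isosurface masking (`threshold_mask()`) uses
`>= level` and reports 6-connected components with value-weighted
centroids; grids round-trip through OpenDX text files at full double
precision.

## Site geometry

Site stability is measured the way a structural analysis would do it by
hand: for each frame, the reference Cα set (by default the pore-lining M2
helix Cαs of all five chains) is superposed onto its pose in a reference
frame by Kabsch least squares (proper rotation, det = +1; degenerate
collinear sets are rejected), the resulting transform is applied to the
site lipid's non-hydrogen headgroup atoms, and their RMSD against the
reference pose is recorded — with *no* re-fitting on the lipid itself, so
genuine lipid motion is not absorbed into the alignment. The default
reference is the first analyzed frame's pose; any frame (e.g. a minimized
starting structure) can be passed instead. Site lipids are assigned once
at the reference frame and never re-assigned — mirroring simulations
started with a lipid placed at each site — with an optional nearest-lipid
mode (ties broken by lowest lipid id) for unbiased runs.

Cation–π geometry is the minimum-image distance from the headgroup cation
particle (choline nitrogen for PC/TAP; phosphorus for PG, which has no
choline) to the centroid of the aromatic ring heavy atoms. The ring atom
set is configurable; all nine indole heavy atoms for a tryptophan, or a
6-membered subset, are both supported (the synthetic placeholder uses a
6-particle ring). The series reports the fractions of frames within
4.5 Å — the ideal cation–π contact distance — and within 6 Å.

Distributions pool the per-frame samples of all five sites and all
replicates with equal weight (pooling, not averaging of per-site scalars,
is what reproduces a distribution); per-site medians are also returned.
Quartiles use the median-unbiased convention (R `type = 8`), whiskers the
1.5 × IQR rule. For an even pooled sample split between two values the
median is their midpoint.

## The synthetic membrane generator

The generator emulates exactly the statistical structure the analyses
assume, and nothing more. Defaults describe a laterally square
300 × 300 Å membrane with an 80/20 PC/PG mix (the reference composition
for charge-discrimination runs), 200 lipids per leaflet, headgroup planes
at ±17 Å. The protein placeholder is built from one chain rotated by
exactly 72° four times: Cα traces for the M1–M4 helices, a 6-particle
planar aromatic ring on M1 (residue 206) facing the outer leaflet, a
polar side-chain bead on M3 (residue 264) at the site mouth, and an
inner-leaflet basic cluster (residues 286/299/301). Five Gaussian wells
(width 3 Å) sit over the aromatic sites in the outer leaflet and five
over the basic clusters in the inner leaflet; their depths (in kT) are
per lipid class, defaulting to PC 6 / TAP 8 / PG 0 outside and PG 6
inside — cation-selective outer binding of order a few kT, the magnitude
expected for a cation–π contact, and anionic binding only at the basic
patch.

Lipids are ideal (non-interacting) single-bead headgroups, optionally
with two rigid ghost tail particles, performing 2D overdamped Langevin
dynamics at fixed leaflet height:

    dx = -(D/kT) ∇U dt + sqrt(2 D dt) ξ

with periodic wrapping, a soft harmonic wall at the protein footprint,
and the protein static. 2D dynamics suffice because every analysis
interrogates lateral organization; distances to the ring centroid remain
fully 3D. Two integrator guards are enforced: the well-force drift per
step must stay below half the well width (otherwise the run aborts
instructing a smaller `dt`), and the wall spring must satisfy the
overdamped stability condition `(D/kT)·k·dt < 1`.

Ground truth comes from `ground_truth_occupancy()`: direct 2D quadrature
of the Boltzmann weight `exp(-U/kT)` on a 1 Å grid, with the *same*
contact criterion as the profile code (3D distance from the headgroup
plane to the site residue particles). For `n` independent lipids of a
class the any-contact occupancy is `1 - (1 - p_single)^n`.

Three numerical points matter when comparing sampled runs against the
quadrature:

* **Initialization.** Uniform (jittered-lattice) starts need of order
  `L²/4D` to equilibrate across a 300 Å box — far longer than a
  desk-scale run. For oracle comparisons the generator therefore supports
  `init = "equilibrium"`, drawing initial positions from the single-lipid
  Boltzmann density so the chain starts stationary.
* **Discretization bias.** Euler–Maruyama sampling concentrates slightly
  too much weight in deep wells as `dt·depth/width²` grows; at 4–5 kT
  wells with `dt = 0.125` the bias is well inside sampling error.
* **Correlation.** Site occupancy decorrelates on well-escape timescales
  (hundreds of time units at 4–5 kT), so a single run's time average is
  an unreliable estimator. Statistical checks build several independent
  replicates (separately built and simulated from derived seeds) and use
  the standard error across replicate means — with five sites pooled per
  replicate — rather than naive per-frame binomial errors.

The validation suite runs planted-site recovery at 200 lipids/leaflet
with a 60/20/20 PC/PG/TAP mix, 4 kT (PC) and 5 kT (TAP) outer wells, five
replicates of 100 frames at a 5-time-unit stride; free-diffusion MSD
checks use 300 lipids over 20 saved frames; problem sizes chosen so the
whole suite completes in about a minute while leaving every statistical
band dominated by sampling error, not by bias.

What passing these tests shows: the contact, density and geometry
operators are exact (oracle-identical) on arbitrary inputs, and they
recover planted, charge-dependent binding sites with the correct
equilibrium statistics from trajectories with realistic lateral
diffusion, crowding levels and five-fold symmetry. What it does not show:
anything about force-field realism — the generator has no electrostatics,
no lipid–lipid correlations, no leaflet coupling, no protein motion, and
its "membrane" is two flat planes. Conclusions about a real channel
require real trajectories, which the same operators accept through the
PDB/DCD readers.

## Dose–response analysis

The model is the four-parameter logistic in its standard (GraphPad-style)
parameterization,

    F([A]) = Fmin + (Fmax − Fmin) / (1 + 10^((−pEC50 − log10[A])·nH)),

with `[A]` molar. `fit_hill()` fits all four parameters by
Levenberg–Marquardt in pEC50 space (far better conditioned than fitting
EC50 directly), with multi-start initialization over Hill slopes
{0.5, 1, 2, 4} and five pEC50 starts spanning the sampled concentration
range; the best converged start by residual sum of squares wins, and
universal non-convergence or flat data raise explicit errors rather than
returning NaNs. No box constraints are imposed on Fmin/Fmax; fits that
converge "upside down" (Fmax < Fmin with negative slope) are re-expressed
in the canonical orientation, so `Fmax > Fmin` always holds and
`EC50 = 10^-pEC50` exactly. Zero-concentration (buffer) rows cannot enter
the log-domain fit; they seed the Fmin start. The returned object is a
standard S3 fitted model with `print`, `summary`, `coef`, `predict`,
`fitted`, `residuals`, `plot` and `simulate` methods.

Derived statistics follow the field's conventions: EC50 fold shift as
mutant/wild-type; the fluorination plot as ordinary least squares of
log10(EC50 ratio) against the cation-π binding energy of each
progressively fluorinated aromatic substitution (the binding energies are
user-supplied quantum-chemistry literature values, not computed here);
and Welch's unpaired two-tailed t-test from group means, SDs and sizes,
with Welch–Satterthwaite degrees of freedom — numerically identical to
`stats::t.test` on raw data when the summaries come from that data, which
the tests verify.

## Design choices that were genuinely open

* **Coarse-grained "headgroup bead".** Taken as the single terminal
  charged bead per lipid (choline-like NC3 for PC/TAP, phosphate PO4 for
  PG); headgroup membership is configuration (a `selection_spec`), not
  code, so atomistic atom sets can be audited and overridden.
* **Contact counting.** Any residue bead counts in CG mode (a side-chain
  restriction flag would be a selection away); frame occupancy rather
  than raw contact counts is the primary normalization, as above.
* **Density symmetrization.** Maps are *not* symmetrized by default;
  `symmetrize_c5()` is explicit and clearly secondary.
* **RMSD reference.** The first analyzed frame's pose, configurable;
  an energy-minimized pose is equally valid and changes only the offset.
* **Per-construct fits.** Dose–response constructs are fitted
  independently (no shared Fmin/Fmax across curves).
* **Trajectory formats.** DCD is read natively (via bio3d) and written by
  the package for round-trip testing; XTC is not parsed in R — convert to
  DCD or the documented plain-text format.
* **Indexing.** Particle indices are 1-based R row indices; residue
  numbers are author numbering and never re-indexed.

## Known limitations

Orthorhombic boxes only (triclinic input errors out explicitly). The
text trajectory reader keeps the raw file text in memory (analyses still
consume one parsed frame at a time); at the intended desk scale this is
irrelevant, but multi-gigabyte trajectories should use DCD. The Hill fit
reports asymptotic standard errors from the least-squares Jacobian, which
understate uncertainty for near-perfect (noiseless) fits — the printed
`r^2` and residuals are the honest diagnostics there.
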