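---
title: "Methods: chirality-dependent peptide-membrane adsorption analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chirality-dependent peptide-membrane adsorption analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chiradsorb)
```

## The scientific problem

Mirror-image peptides built entirely of L- or D-amino acids are chemically
identical except for their handedness, yet on a chiral interface — a
phospholipid bilayer whose lipids carry a stereocenter at the glycerol C2
carbon — their adsorption kinetics can differ. For an 18-residue amphipathic
helix of arginines, leucines and a single tryptophan
(`Ac-RLLRLLLRLWRRLLRLLR-NH2`, called C6 here), the L form adsorbs with a
single-exponential first-passage-time (FPT) distribution, while the D form
shows a two-exponential mixture with a slow minority mode, a marginal
free-energy barrier along the adsorption pathway, and distinctive tryptophan
behavior. This package implements the full analysis chain needed to
quantify that asymmetry — FPT survival analysis, umbrella-sampling
reweighting into a two-dimensional potential of mean force (PMF), and
rotation-resolved lipid contact statistics — together with a synthetic-data
module that generates every input with known ground truth, so each estimator
can be validated by parameter recovery.

Throughout, coordinates are in nm, times in ns, angles in degrees and
energies in kBT at 303.15 K. The two collective variables are

* `dz`, the z-component of the distance between the peptide and bilayer
  centers of mass (the membrane normal is z; adsorption decreases `dz`), and
* `theta`, the helix rotation angle: the dihedral about the oriented helix
  axis (residue 1 toward residue 18) between the half-plane containing +z
  and the half-plane containing the Trp CG atom, measured by the right-hand
  rule and wrapped to [0, 360).

## Synthetic systems

`build_peptide()` constructs an ideal helix (rise 0.15 nm, twist 100 degrees
per residue) with a CB pseudo-atom per residue and a rigid three-atom indole
proxy (CG, CD1, CH2) on the tryptophan, the CD1-to-CH2 long axis fixed at
0.55 nm. Only that long-axis vector enters any statistic, so the proxy loses
nothing relative to a full side chain. The D enantiomer is the mirror image
through the plane containing the helix axis and the membrane normal, which
keeps every intramolecular distance identical while mapping
`theta` to `360 - theta`.

Nonpolar residues (Leu, Trp) are grouped into stacked surface fragments from
their helical-wheel angles: links are allowed between nonpolar residues
separated by one to four positions whose circular wheel-angle distance is at
most the band width (default 100 degrees), accepted greedily by increasing
angular distance with one predecessor and successor per residue; the
resulting chains are the fragments. For C6 this produces four stacked
fragments, with the tryptophan on a longest (four-member) one. The band
width is exposed because other sequences may need a different granularity.

`build_bilayer()` places pseudo-lipids on a jittered lattice, 64 per leaflet
by default at 0.68 nm^2 per lipid. Each lipid has two head atoms (phosphate
and choline proxies), one chiral-carbon atom C2 between head and tail along
z, and three tail atoms — the minimum structure on which head/tail contact
typing and C2-based side classification are well defined. No attempt is
made to emulate lipid conformational flexibility; the bilayer is a geometric
stage, not a thermodynamic model.

`ref_surface()` defines the analytic free-energy surfaces used as ground
truth. The `barrier` preset has a pre-adsorption basin near dz = 2.2 nm, a
post-adsorption basin near dz = 1.2 nm, and a valley `theta*(dz)` passing
through a requested saddle location (default dz = 1.8 nm, theta = 150 in the
D convention). A Gaussian ridge along dz is calibrated by root finding so
that the minimum-over-paths maximum between the basins equals the requested
height (default 4.3 kBT) exactly; `surface_ref_barrier()` verifies this by
dense grid search. The angular restraint is `B (1 - cos(theta -
theta*(dz)))` with B = 3 kBT, giving a valley wide enough (about 33 degrees
standard deviation) that umbrella sampling in dz alone still explores theta,
as in the real system. The `downhill` preset is the single-funnel analogue
in the L sense; `flat` and `harmonic` exist for closed-form checks.

`simulate_traces()` integrates overdamped Langevin dynamics
(Euler--Maruyama) on a surface, by default dt = 0.01 ns over 200 ns, the
typical trajectory span of the study conditions. Diffusion coefficients
(0.01 nm^2/ns in dz, 300 deg^2/ns in theta) were chosen once so that the
downhill funnel produces mean FPTs of order 15-20 ns at the 1.5 nm
threshold, the same scale as the fast adsorption mode, and are config
exposed. The integrator aborts a trajectory on a non-finite force rather
than truncating silently.

`sample_umbrella()` draws from the biased densities with a Metropolis
random-walk chain per window (25 independent chains by default, burn-in 10%
of each chain with a 200-step floor). Any correctly weighted sampler
suffices for reweighting, and a Metropolis chain is the simplest one whose
equilibrium distribution is exact. The default 16 windows span dz in
[1.0, 2.5] nm; the harmonic force constant, 1000 kJ/mol/nm^2, is a
configuration choice (it gives a window width of about 0.05 nm against a
0.1 nm spacing, i.e. generous overlap), not a literature value.
Adjacent-window histogram overlap is computed and warned on when below 1%.

`place_contact_fixture()` generates frames whose Trp--head-group contact
count is Poisson with a requested mean. Placement is verified geometrically
frame by frame — the drawn count must equal the distance-based count after
placement — so the fixture tests the counting rule itself, not merely the
intent.

## First-passage kinetics

`extract_fpt()` defines the FPT as the first time `dz` reaches 1.5 nm, with
linear interpolation between bracketing samples to remove frame-stride bias;
traces that never cross are censored at their end time. `empirical_ccd()`
is the Kaplan--Meier product-limit estimator (via the survival package),
which reduces to one minus the ECDF without censoring.

`fit_ccd()` fits the complementary cumulative distribution by maximum
likelihood with censoring: uncensored times contribute density terms,
censored times survival terms. This matters because finite trajectories
censor exactly the slow tail that distinguishes the two enantiomers. Models:

* `exp1` — closed form: the MLE is total observed time over event count,
  with standard error tau over the square root of the event count.
* `exp2` — normalized two-exponential mixture (weight_fast, tau_fast,
  tau_slow with weight_slow = 1 - weight_fast), optimized on transformed
  parameters from eight deterministic quantile-based starting points
  (tau_fast from the lower-half mean, tau_slow from the upper-decile mean),
  with best-likelihood selection. If the two time constants collapse
  (log-ratio below 0.1) the fit is flagged degenerate. Standard errors come
  from the observed information (numerical Hessian at the MLE);
  `boot_se()` provides a seeded bootstrap alternative since asymptotic
  errors can be optimistic near the weight boundary.
* `gamma` — shape/scale by the same censored-MLE machinery.

AIC (via `logLik`) compares models; on funnel-like synthetic data the gamma
model beats the single exponential, reproducing the qualitative
model-selection result expected for downhill kinetics. A secondary
least-squares-on-log-CCD criterion (`method = "lsq"`) is included for
sensitivity analysis because the fitting objective is a genuine analysis
choice.

## PMF estimation and the barrier

`estimate_pmf()` solves the umbrella-window free energies two independent
ways, both implemented in the package so they can cross-check each other:
WHAM (self-consistent iteration on a fine dz histogram) and MBAR (the
unbinned estimating equations, solved by BFGS on the convex multistate
objective and polished by self-consistent iteration until the maximum
free-energy change is below 1e-7 kBT). Samples are first decorrelated by
subsampling at the statistical inefficiency of dz, capped so that at least
4000 samples per window remain. With the solved free energies every sample
receives an unbiased weight, and the 2D PMF over (dz, theta) is the negative
log of the binned weights, normalized to zero at its sampled minimum;
unsampled bins carry an explicit mask and are never interpolated. The
default grid is 30 dz bins by 36 theta bins. Bin-averaging flattens sharp
features slightly: on the calibrated 4.3 kBT reference saddle the
discretization alone reduces the measured barrier to about 4.22 kBT at the
default grid, well inside the 0.5 kBT acceptance band but worth remembering
when reading absolute numbers off a binned PMF.

`reweighted_expectation()` gives conditional means and standard deviations
of any per-sample observable per dz bin under the unbiased weights, as used
for the descending/ascending lipid census profile.

`find_barrier()` locates the adsorption barrier as a minimax path: the
path between the two basin bins (8-connected, theta-periodic, sampled bins
only) whose maximum free energy is smallest, found by bisection over the
free-energy threshold with flood-fill connectivity. The saddle is the
highest bin on that path; the barrier is measured from the pre-adsorption
basin, the approach side of the adsorption process. Basin seeds are snapped
to the nearest sampled bin and relaxed to their local minimum first.
Minimax height is direction invariant, which the tests assert.

## Contacts, sides, and the rotation score

Ambient lipids are those whose nearest heavy atom lies within 0.3 nm of any
peptide heavy atom. The vertical plane containing the helix axis and z
splits space in two; under the chirality's rotation sense (L: theta
decreasing; D: theta increasing) one side of the helix cylinder moves
downward, and that side is the descending side. Each ambient lipid is
labeled by the side of its C2 atom (or optionally its center of mass). The
sense-based definition is used rather than instantaneous angular velocity
because per-frame velocities are noisy while the adsorption pathway's
rotation direction is a property of the chirality. A C2 exactly in the
dividing plane (a measure-zero event) is deterministically assigned
ascending and flagged.

A residue--lipid pair is in contact when any heavy-atom pair is within
0.5 nm. Contacts are classified into {descending, ascending} x
{hydrophobic, polar}: the side from the lipid's label, the type from the
nearest contacting lipid atom (tail = hydrophobic, head = polar; the C2
atom counts as head by default, sitting in the glycerol region). A strict
mode counts only matched pairs — nonpolar residue with tail atoms, charged
residue with head atoms — for sensitivity analysis. The rotation score is

    S_rot = w_dp N_dp + w_dh N_dh + w_ah N_ah + w_ap N_ap.

The weight values are not fixed by theory here; the shipped default
(+1, +1, -1, -1) encodes that descending-side contacts drive the rotation
while ascending-side contacts impede it, and every output records the
weights used so alternative weightings are reproducible.

Trp--head contacts count distinct lipids with at least one head atom within
0.5 nm of any Trp heavy atom — at most one contact per lipid, so the count
is the number of interacting lipids. The Trp orientation statistic is
`t . l`, where `t` is the tangent at Trp of its surface fragment (quadratic
arc fit through the member CB positions; the chord for a two-member
fragment) and `l` is the CD1-to-CH2 unit vector: near 1 is cis
("well-orientated"), near 0 perpendicular, near -1 trans
("bad-orientated").

Side-switch events per lipid are label changes persisting at least a
debounce window (default 5 frames, configurable, since no persistence rule
is canonical); a lipid "experiences switching" with at least one event, and
systems are compared by the count of such lipids.

## States and reporting

Pre- and post-adsorption states are theta intervals, chirality symmetric
under parity: pre is theta > 225 for L (theta < 135 for D), post is
theta < 180 for L (theta > 180 for D). The inequalities are strict as
stated, so boundary angles are "neither" and excluded from state averages.
Per-window state summaries report the mean, SEM = s/sqrt(n) and n, with
Welch unequal-variance tests between requested window pairs at level 0.1
and no multiplicity correction — flagged in the output metadata so users
can correct downstream. `assemble_report()` writes the JSON + CSV bundle,
stamped with the configuration hash and all seeds; it is a pure function of
its inputs and reruns byte-identically.

## Numerical choices and degenerate inputs

* Theta is wrapped to [0, 360); state thresholds need an absolute
  convention. The parity identity `label(theta, L) =
  label(360 - theta, D)` holds everywhere except the single wrap point
  theta = 0, where 360 - 0 re-wraps to 0.
* The helix axis is the first principal direction of the CA cloud, signed
  from residue 1 to the last residue. A finite discrete helix tilts the
  principal direction a couple of degrees off the construction axis (the
  turns do not close); all downstream statistics use the PCA axis
  consistently, and near-equal top singular values raise an ambiguity flag.
* `rotation_angle()` errors when CG projects onto the axis (undefined
  half-plane) and `classify_sides()` when the axis is within 1 degree of
  vertical (undefined dividing plane).
* Distances use the minimum-image convention when a periodic box is
  present.
* All generators accept integer seeds and are bit-reproducible; generator
  code saves and restores the caller's RNG state.

## Problem sizes and what the tests show

The validation suite runs at desk scale by design: 5000 FPT draws for the
kinetic parameter recoveries, 16 windows at 20000 retained samples for the
barrier recovery, 5000 frames for the contact-mean recovery, and brute-force
oracle comparisons on systems of up to 5 lipids over hundreds of random
placements. Passing these shows that the estimators recover known ground
truth under the stated noise models — it does not show that the simplified
generators capture real lipid flexibility, water, or peptide internal
degrees of freedom. On real trajectories the same estimators apply
unchanged through the structure/trace readers, but their inputs then carry
whatever systematic error the simulation or experiment carries.

## Known limitations

* The pseudo-bilayer is static and lipids are rigid; lipid-side entropy and
  packing effects are outside the generators' scope.
* The two-exponential fit's asymptotic standard errors degrade near the
  weight boundary; use `boot_se()` there.
* The binned 2D PMF slightly flattens sharp saddles (see above); refine the
  grid when barriers are small relative to the bin-scale curvature.
* The rotation-score weights are a modeling choice, not fitted quantities;
  conclusions that depend on their magnitudes should be checked across
  weightings.
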