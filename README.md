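# chiradsorb

Analysis of chirality-dependent adsorption kinetics of amphipathic helical
peptides on lipid bilayers.

## The problem

Mirror-image peptides (all-L vs all-D amino acids) are identical except for
handedness, yet on a bilayer of chiral lipids their adsorption kinetics can
differ: for the 18-residue amphipathic helix C6
(`Ac-RLLRLLLRLWRRLLRLLR-NH2`), the L enantiomer adsorbs with a
single-exponential first-passage-time (FPT) distribution while the D
enantiomer shows a two-exponential mixture with a slow minority mode, a
small free-energy barrier along its adsorption pathway, and anomalous
tryptophan–lipid interactions. `chiradsorb` provides the complete analysis
chain for dissecting this asymmetry, for computational biophysicists
working with peptide–membrane trajectories:

- **FPT survival analysis** — Kaplan–Meier CCD curves and censored
  maximum-likelihood fits of single-exponential, normalized two-exponential
  mixture, and gamma models (`fit_ccd()`, a classed fit with
  `coef`/`summary`/`predict`/`simulate`/`plot` methods);
- **umbrella-sampling reweighting** — in-package WHAM and MBAR solvers
  turning biased windows into a 2D potential of mean force over the
  insertion depth `dz` and the helix rotation angle `theta`, with a
  minimax-path barrier finder (`estimate_pmf()`, `find_barrier()`);
- **rotation-resolved contact statistics** — ambient-lipid filtering, the
  weighted rotation score
  `S_rot = w_dp N_dp + w_dh N_dh + w_ah N_ah + w_ap N_ap` over
  {descending, ascending} × {hydrophobic, polar} contact classes, the side
  census `delta_n = n_des − n_asc`, side-switch counting, Trp–head-group
  contacts and the Trp indole orientation statistic `t · l`;
- **synthetic systems with known ground truth** — ideal helix enantiomers,
  pseudo-POPC bilayers, overdamped Langevin traces on calibrated analytic
  free-energy surfaces, Metropolis umbrella samples, and Poisson contact
  fixtures, so every estimator is validated by parameter recovery.

Real trajectories enter through `read_structure()` (PDB/GRO) and
`read_traces()` (columnar CSV of `time_ns, dz_nm, theta_deg`).

## Worked example

```r
library(chiradsorb)

peptide <- build_peptide(C6_SEQUENCE, chirality = "D")
peptide
#> peptide_model: 18 residues (RLLRLLLRLWRRLLRLLR), chirality D
#>   Trp index: 10 | nonpolar surface fragments: 4 | atoms: 39

# kinetics: 25 downhill trajectories -> FPTs at dz = 1.5 nm -> CCD fit
traces <- simulate_traces(ref_surface("downhill"),
                          langevin_config(seed = 1), n_traj = 25)
fpt <- fpt_samples(traces, threshold = 1.5)
fit_ccd(fpt, model = "exp1")
#> ccd_fit: model exp1 (mle), 25 samples (25 events)
#>   tau             20.2449  (se 4.0490)
#>   logLik -100.20 | AIC 202.40

# free energy: 16 umbrella windows -> MBAR -> 2D PMF -> barrier
surf <- ref_surface("barrier")            # saddle calibrated at 4.3 kBT
uws <- sample_umbrella(surf, n_samples = 20000, seed = 1)
pmf <- estimate_pmf(uws, estimator = "mbar")
find_barrier(pmf, basin_a = c(2.2, 90), basin_b = c(1.2, 230))
#> barrier_report: 4.20 kBT from pre basin (dz 2.18, theta 85)
#>   saddle at dz = 1.77 nm, theta = 155 deg (F = 8.37 kBT)

# Trp-head contacts on a Poisson placement fixture
frames <- place_contact_fixture(peptide, mean_heads_near_trp = 1.54,
                                n_frames = 2000, seed = 1)
counts <- vapply(frames, function(f) trp_head_contacts(peptide, f),
                 integer(1))
mean(counts)
#> [1] 1.52
```

The fitted `tau` is the mean adsorption time of the funnel-like (fast)
pathway; the barrier report recovers the 4.3 kBT saddle planted at
dz = 1.8 nm on the reference surface to within the bin resolution; the
contact mean recovers the generating Poisson rate of the slow-mode
Trp–head interaction.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/chiradsorb` (subcommands `simulate`, `fpt`, `fit-ccd`,
`pmf`, `states`, `report`).

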