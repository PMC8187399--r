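---
title: "Methods: ensemble landscapes, NMR observables and trial power in foldscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble landscapes, NMR observables and trial power in foldscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldscape)
```

foldscape analyses conformational ensembles of short peptides — optionally in
complex with fatty-acid ligands — and the solution observables that
characterise such systems: translational diffusion, transverse relaxation,
binding stoichiometry, hydrodynamic radii and circular dichroism. A companion
module computes the exact power of a paired t-test design. This vignette
documents the models, the tunable parameters and the numerical choices, and
states what the synthetic-data generator does and does not emulate.

## Dihedral PCA and the free-energy surface

Backbone torsions are periodic, so ordinary PCA on raw angles is distorted by
the branch cut at ±180°. `fit_dpca()` therefore embeds every angle as the
pair (cos θ, sin θ) — the standard dihedral-PCA transform — and
eigendecomposes the covariance of the embedded matrix. Because dihedrals are
internal coordinates, the result is exactly invariant under rigid rotation
and translation of the structures; the test suite asserts this, together with
the PCA identities (orthonormal eigenvectors, projection variance equal to
the eigenvalue, eigenvalue sum equal to the covariance trace). Constant
angle columns contribute zero eigenvalues and are not an error. Whether to
mass-weight the dihedral covariance is a genuinely open choice; foldscape
uses the plain (unweighted) covariance, which is the common choice for
backbone torsion analysis.

`build_fes()` histograms the first two projections on a regular grid and
Boltzmann-inverts the populations,

$$F_i = -RT \ln(P_i / P_o),$$

with R = 0.0083145 kJ/(mol K), T = 300 K by default, and P_o the population
of the most populated bin. Consequences that the suite checks: F = 0 exactly
at the modal bin, F ≥ 0 everywhere, and F is invariant to rescaling all
counts. Empty bins are left masked (`NA`) rather than capped at a large
value — assigning them any number would silently break the F ≥ 0 contract
and invent free energies for unsampled states. Ties for the modal bin are
broken by the lowest flat (column-major) index, documented so that results
are reproducible bit for bit.

The default grid is 64 × 64, appropriate for trajectories of 10^4–10^5
frames. For desk-scale ensembles of a few hundred frames a coarser grid
(roughly √n bins per axis) should be used, otherwise sampling noise
fragments each occupied region into disconnected islands; the basin tests
use 8–16 bins for 300–8000 frames.

`locate_basins()` finds local minima (occupied bins not exceeded by any
occupied 4-connected neighbour) and grows each by flood fill up to
`min F + depth_cutoff`, claiming bins deepest-first so the basins partition
the claimed region. The default depth cutoff of 2 kJ/mol is roughly the
thermal energy at 300 K: features shallower than kT are sampling texture,
not metastable states. With `depth_cutoff = 0` a basin is exactly its
minimum bin. The representative structure of a basin is the medoid of its
frames — the frame minimising the summed superposed RMSD to the others —
computed when a trajectory is supplied; basins larger than 200 frames are
subsampled evenly before the medoid search to keep the quadratic RMSD cost
bounded (the medoid of 200 well-spread frames is statistically
indistinguishable from the full medoid at these ensemble sizes).

## GROMOS clustering and RMSD

`gromos_cluster()` implements the Daura neighbour-counting scheme: the frame
with the most neighbours within the RMSD cutoff becomes a cluster centre,
the cluster is removed, and the procedure repeats. Ties are broken by the
lowest frame index, and final labels are ordered by decreasing size (then by
earlier centre), so the partition is fully deterministic. The suite proves
the implementation equivalent to an exhaustive neighbour-count oracle on all
small instances across 50 seeds. The RMSD cutoff is a tunable with no
universal value; the default 0.2 nm is a common choice for peptide backbone
clustering and should be examined per system.

Pairwise RMSD superposes every frame pair by the optimal least-squares
rotation and translation (Kabsch fit via `bio3d::fit.xyz()`) on the backbone
selection by default; the RMSD arithmetic itself is done in-package at full
precision because downstream tests compare at 10^-8 nm. An independent
quaternion (Horn) superposition oracle in the test suite guards the
geometry.

## Secondary structure and contacts

The conventional grouping — 3_10, α and π helices count as helix, β-sheet and
isolated β-bridge as sheet, everything else as other — is implemented in
`group_ss_labels()` and accepts externally computed DSSP letter streams, so
real hydrogen-bond-based assignments can be aggregated identically.
`ss_propensity()` itself classifies by dihedral region (helix:
φ ∈ [-100°, -30°], ψ ∈ [-80°, -5°]; extended: φ ∈ [-180°, -90°],
ψ ∈ [90°, 180°] ∪ [-180°, -170°]): the synthetic ensembles control their
labels through backbone dihedral modes, and a hydrogen-bond assignment on a
reduced four-atom-per-residue geometry would be meaningless. This is the one
deliberate substitution in the package: propensity *aggregation* is
identical to the DSSP-based workflow, the per-frame *assignment* is
dihedral-based.

`contact_probability()` scores a residue in contact when the minimum
distance between its side-chain protons and any ligand atom is strictly
below 0.55 nm (strict, matching the convention "less than 0.55 nm"); the
per-residue probability is the fraction of contact frames, and `overall`
uses all selected atoms at once. Probability is monotone in the cutoff, 0 at
cutoff 0 and 1 at unbounded cutoff — all asserted in the suite.

## The synthetic generator

`gen_conformer_ensemble()` draws per-residue backbone (φ, ψ) from a helical
von Mises mode centred at (-60°, -45°) with probability `helix_fraction`,
otherwise from a coil mode, and builds Cartesian frames by standard peptide
geometry (fixed bond lengths/angles, trans ω, one side-chain pseudo-proton
per residue). Two sampling modes cover the two uses:

* `"independent"` (default): each residue flips independently each frame,
  and the coil mode is a broad mixture (70% extended region, 30%
  left-handed-helical region, uniform within each). This is the right model
  for propensity-recovery statistics: the mean helical propensity is an
  unbiased binomial estimate of `helix_fraction`.
* `"collective"`: one state per frame applied to all residues, with a
  concentrated extended coil mode at (-135°, 135°). This produces a genuine
  two-state ensemble with per-frame ground-truth labels, used for
  separability (silhouette along PC1) and two-basin tests.

The coil regions are chosen disjoint from the helix classification box so
that state labels and dihedral classification agree by construction; the
default κ = 50 (≈8° circular spread) keeps >99.9% of helical draws inside
the box, and the default coordinate noise of 0.002 nm perturbs extracted
torsions by well under a degree.

The ligand cluster (default 4 pseudo-atoms, emulating a 1:4 peptide:lipid
ratio) is placed 0.20–0.45 nm from a randomly chosen side-chain proton in a
`contact_fraction` share of frames and at least 1.2 nm from every peptide
atom otherwise, so the measured overall contact probability at 0.55 nm is an
exact binomial realisation of `contact_fraction`.

What the generator does **not** emulate: force-field energetics, solvent,
realistic side chains, kinetic correlation between frames, or NMR
lineshapes. Passing tests therefore demonstrate the correctness of the
estimators and their statistical calibration — not that any particular real
peptide behaves this way. Decay generators likewise use ideal mono/
bi-exponential forms with multiplicative Gaussian noise (the realistic model
for spectrometer intensity error); deviations such as convection artefacts
or non-uniform gradients are out of scope.

All randomness flows through an explicit integer seed
(`withr::with_seed()`), so every generated object is bit-reproducible and no
function touches the caller's RNG state.

## Replica ladders

`geometric_ladder()` spaces replica temperatures geometrically,
T_i = T_min (T_max/T_min)^{(i-1)/(n-1)}, the spacing that keeps
neighbour-overlap roughly uniform along the ladder. Temperatures are kept at
full precision internally and conventionally reported to 3 decimals. The
Hamiltonian scaling factors follow the solute-tempering convention
λ_i = T_ref/T_i (λ = 1 at the reference rung, λT constant). This convention
choice is flagged prominently because scaling schemes differ in how λ is
split between charge and Lennard-Jones terms; only the temperature list
itself is convention-free. Exchange acceptance statistics are properties of
an actual simulation and are deliberately not predicted.

## NMR observables

**Diffusion.** `fit_stejskal_tanner()` fits
I(g) = I0 Σ f_j exp(-D_j σ γ² g² δ² (Δ - δ/3)). The gradient shape factor σ
defaults to (2/π)², the value for half-sine-shaped pulses; it multiplies D
wherever it appears, so it cancels exactly in any radius derived by internal
referencing, and it is configurable for other pulse shapes. The
one-component fit is seeded by log-linear regression and refined by
Levenberg–Marquardt; the two-component fit starts from the one-component D
split by three log-spaced ratios (3, 10, 30) and keeps the best residual —
a cheap multi-start that avoids the local minimum where both components
collapse prematurely. Components are reported in decreasing D. With equal
true components the two-component model is degenerate in the fraction; the
mixture-weighted D remains identifiable and is what the suite asserts.

**Hydrodynamic radius.** With an internal reference of known radius measured
in the same run, the Stokes–Einstein relation reduces to the ratio
R_H = R_ref · D_ref/D_solute: temperature, viscosity and the gradient
calibration (including σ and the instrument's absolute gradient scale)
cancel. The conventional internal reference is 1,4-dioxane at
R_H = 2.12 Å. Printed diffusion values on a fixed instrument scale
(e.g. 10⁻¹⁰ m²/s) can be used directly since only the ratio enters.
Reported radii conventionally carry 2 decimals up to 20 Å and 1 above
(`round_rh()`); full precision is kept internally.

**Relaxation.** `fit_t2()` fits a monoexponential by least squares and
reports T2 and R_2 = 1/T2. A decay with no measurable attenuation across the
sampled delays has unidentifiable (effectively infinite) T2 and raises an
error rather than returning a number. The fit is flagged well-conditioned
when the delay schedule extends to at least the fitted T2 — the reason
CPMG schedules are chosen per sample (`cpmg_delays()` defaults to 15
log-spaced delays up to 1.2 s).

**Stoichiometry.** Peak areas are normalised by the proton count behind each
region; the ligand:peptide ratio is averaged over all region pairs. The
round trip at a ratio of 3.7 — the regime of a multi-lipid peptide
complex — is part of the acceptance checks.

**SE-HPLC.** `calibrate_sehplc()` fits log10(R_H) against elution volume on
≥3 standards. The linearity of such calibrations is known to fail beyond
about 3.8 mL of elution volume, so standards beyond that bound are rejected
and predictions outside the calibrated range are flagged as extrapolations
(with a warning) rather than silently returned.

**CD.** `mean_residue_ellipticity()` uses the mg/mL convention,
[θ] = θ(mdeg) · MRW / (10 · l(cm) · c(mg/mL)), with MRW the mean residue
weight. Molar-concentration conventions can be mapped onto this one by
rescaling, which is why the convention is documented rather than guessed at
run time.

## Trial power

The paired design with null "mean within-subject change = 0" is a one-sample
t-test on the changes. `power_paired_t()` evaluates the exact noncentral-t
power, P(T' > t_{1-α, n-1}) with noncentrality (mean/SD)√n, and
`minimal_n()` scans n upward from 2. The exactness matters: for an effect of
0.684 SD at α = 0.05 one-tailed and 90% power, the normal approximation
gives n ≈ 18.3 while the t-based scan gives 20 — the t-correction is
precisely what separates the two, and the suite asserts the
normal-approximation lower bound as an invariant.

```{r}
minimal_n(trial_design(41.3, 60.4, alpha = 0.05, power = 0.90, tails = 1))
```

## Problem sizes and degenerate inputs

The test suite runs entirely on synthetic data generated at call time:
ensembles of 5–10 residues and up to 5000 frames, 50-seed small-instance
clustering sweeps, and 200-seed decay-recovery panels at 1% noise — sizes at
which every statistical tolerance in the suite (3 binomial SE bands, 2%
median relative error) has comfortable margin, chosen once from the
binomial/fit error budget rather than tuned. Degenerate inputs are defined
behaviour throughout: a zero-variance ensemble has all-zero eigenvalues, a
flat ladder (t_min = t_max) is allowed, a flat decay and an empty atom
selection are errors, and an all-masked free-energy grid yields no basins.

## Known limitations

* The dihedral-region secondary-structure classifier is not DSSP; real
  trajectories should be assigned by DSSP and aggregated via
  `group_ss_labels()`.
* Continuous diffusion distributions (CONTIN-style) and non-uniform-gradient
  DOSY processing are not implemented; only discrete 1–2 component fits.
* Free-energy surfaces are built from a single unweighted ensemble; no
  multi-replica reweighting.
* The ligand in the generator is a point cluster, adequate for contact
  statistics but not for shape- or orientation-dependent observables.
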