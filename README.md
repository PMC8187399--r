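# foldscape

Free-energy landscapes and solution observables for peptide and
peptide–lipid conformational ensembles.

Short membrane-active peptides — such as fatty-acid-complexed
alpha-helical fragments studied as tumoricidal agents — interconvert
between helical and disordered states, and their characterisation combines
enhanced-sampling simulation analysis with solution measurements. foldscape
implements the analysis layer of that workflow as a tested R package:

* **Ensemble analysis** — dihedral principal component analysis (PCA on the
  sin/cos embedding of backbone φ/ψ torsions), Boltzmann free-energy
  surfaces `F_i = −RT ln(P_i/P_o)` over the two leading components with
  flood-fill basin detection and medoid representatives, GROMOS (Daura)
  geometric clustering on optimally superposed RMSD, dihedral-region
  secondary-structure propensities with the 3₁₀/α/π → helix grouping, and
  per-residue peptide–ligand contact probabilities at a 0.55 nm cutoff.
* **Replica-exchange setup** — geometric-progression temperature ladders
  `T_i = T_min (T_max/T_min)^{(i−1)/(n−1)}` and solute-tempering scaling
  factors `λ_i = T_ref/T_i`.
* **NMR and biophysical observables** — Stejskal–Tanner fits of
  pulsed-field-gradient decays
  `I(g) = I0 Σ f_j exp(−D_j σγ²g²δ²(Δ−δ/3))` (1 or 2 components), CPMG
  T₂ relaxation fits, hydrodynamic radii by internal dioxane referencing
  (`R_H = 2.12 Å · D_dioxane/D_solute`), SE-HPLC calibration
  (`log₁₀ R_H` vs elution volume, 3.8 mL linearity bound), peak-area
  binding stoichiometry, and mean residue ellipticity.
* **Trial design** — exact noncentral-t power and minimal sample size for
  paired t-test designs.
* **Synthetic data** — seeded generators for two-state helix/coil
  ensembles with a ligand cluster at controlled contact fraction,
  mono/bi-exponential decays and peak tables, all carrying their ground
  truth, so every estimator is validated end to end.

See the methods vignette (`vignettes/foldscape-methods.Rmd`) for the
models, parameter conventions and numerical choices.

## Worked example

```r
library(foldscape)

## replica ladder, 20 rungs over 300-800 K
lad <- geometric_ladder(300, 800, 20)
round(lad$temperatures[1:5], 3)
#> [1] 300.000 315.893 332.629 350.251 368.807

## a two-state synthetic ensemble with known ground truth
spec <- ensemble_spec(n_residues = 8, n_frames = 600, helix_fraction = 0.5,
                      kappa = 100, noise_sd = 0, seed = 23,
                      mode = "collective")
traj <- gen_conformer_ensemble(spec)
traj
#> <trajectory> 600 frames, 36 atoms (8 peptide residues, 4 ligand atoms)

## dihedral PCA and the free-energy surface
pc <- fit_dpca(dihedral_timeseries(traj))
pc
#> <pc_model> 24-dim embedding, 600 frames projected
#>   leading eigenvalues: 8.127, 0.01232, 0.01108, 0.01095  (98.7% of trace in PC1-2)
fes <- build_fes(pc$projections, bins = 16, temperature = 300)
fes
#> <fes_grid> 16x16 bins, 600 frames, T = 300 K, max F = 10.13 kJ/mol
basins <- locate_basins(fes, depth_cutoff = 8, traj = traj)
length(basins)
#> [1] 2
sapply(basins, `[[`, "representative_frame")
#> [1] 318 308

## GROMOS clustering recovers the two states
gromos_cluster(traj, cutoff = 0.15)
#> <cluster_result> 2 clusters over 600 frames (cutoff 0.15 nm)
#>   sizes: 304, 296

## ligand contacts (generated at contact_fraction = 0.5)
contact_probability(traj, cutoff = 0.55)
#> <contact_profile> sidechain-protons vs ligand, cutoff 0.55 nm, overall P(contact) = 0.468

## diffusion, radii, stoichiometry
fit_stejskal_tanner(gen_pfg_decay(D = 2.162e-10, noise_sd = 0.01, seed = 7))
#> <diffusion_fit> 1 component(s)
#>   D1 = 2.172e-10 (fraction 1.000)
#>   I0 = 1.003, RSS = 0.00422
round_rh(hydrodynamic_radius(2.162, 14.10))   # peptide vs dioxane
#> [1] 13.83
round_rh(hydrodynamic_radius(0.986, 13.61))   # peptide-lipid complex
#> [1] 29.3
stoichiometry_from_peaks(gen_peak_table(3.7))
#> [1] 3.7

## paired-t sample size (mean change 41.3, SD 60.4, alpha 0.05 one-tailed)
des <- trial_design(41.3, 60.4, alpha = 0.05, power = 0.90, tails = 1)
minimal_n(des)
#> [1] 20
round(power_paired_t(des, 19), 3)   # one fewer subject misses the target
#> [1] 0.889
```

The eigenvalue spectrum shows a single dominant collective coordinate (the
helix/coil transition) carrying ~99% of the embedded variance; the surface
over it has two basins whose representative frames belong to opposite
states; clustering, contacts and the decay fits recover the generator's
ground truth (2.172e-10 vs a true D of 2.162e-10 at 1% noise); and the
hydrodynamic radii reproduce the internal-referencing arithmetic for the
printed diffusion pairs. The sample-size computation shows why the exact
noncentral-t iteration matters: 20 subjects clear 90% power, 19 do not.

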