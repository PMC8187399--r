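test_that("generator is bit-identical under a fixed seed", {
  sp <- ensemble_spec(n_residues = 6, n_frames = 25, seed = 42)
  t1 <- gen_conformer_ensemble(sp)
  t2 <- gen_conformer_ensemble(sp)
  expect_identical(t1$coords, t2$coords)
  expect_identical(attr(t1, "ground_truth")$contact,
                   attr(t2, "ground_truth")$contact)
  t3 <- gen_conformer_ensemble(ensemble_spec(n_residues = 6, n_frames = 25,
                                             seed = 43))
  expect_false(identical(t1$coords, t3$coords))
})

test_that("generated trajectories satisfy the container invariants", {
  tr <- gen_conformer_ensemble(ensemble_spec(n_residues = 5, n_frames = 10))
  expect_s3_class(tr, "trajectory")
  expect_false(is.unsorted(tr$topology$resid))
  expect_true(all(is.finite(tr$coords)))
  expect_equal(dim(tr$coords)[2], nrow(tr$topology))
  expect_setequal(unique(tr$topology$group), c("peptide", "ligand"))
})

test_that("trajectory constructor rejects malformed input", {
  tr <- gen_conformer_ensemble(ensemble_spec(n_residues = 4, n_frames = 2))
  expect_error(trajectory(tr$coords, tr$topology[-1, ]), "rows")
  bad <- tr$topology; bad$group[1] <- "solvent"
  expect_error(trajectory(tr$coords, bad), "group")
  bad <- tr$topology; bad$resid <- rev(bad$resid)
  expect_error(trajectory(tr$coords, bad), "non-decreasing")
  cc <- tr$coords; cc[1] <- NA
  expect_error(trajectory(cc, tr$topology), "finite")
  expect_error(ensemble_spec(helix_fraction = 1.4), "probability")
  expect_error(ensemble_spec(contact_fraction = -0.1), "probability")
})

test_that("pure-helix ensembles classify fully helical", {
  tr <- gen_conformer_ensemble(ensemble_spec(
    n_residues = 8, n_frames = 60, helix_fraction = 1, noise_sd = 0,
    kappa = 200, seed = 5))
  ss <- ss_propensity(dihedral_timeseries(tr))
  expect_equal(unname(ss$propensity), rep(1, 6))
})

test_that("contact fraction is recovered within binomial error", {
  frac <- 0.5; nf <- 2000
  tr <- gen_conformer_ensemble(ensemble_spec(
    n_residues = 8, n_frames = nf, contact_fraction = frac, seed = 11))
  cp <- contact_probability(tr)
  se <- sqrt(frac * (1 - frac) / nf)
  expect_lt(abs(cp$overall - frac), 3 * se)
  # the generator's own contact labels agree exactly with the measurement
  gt <- attr(tr, "ground_truth")$contact
  expect_equal(cp$overall, mean(gt))
})

test_that("PFG generator obeys the attenuation law", {
  g <- c(0, 0.05, 0.1, 0.2, 0.3, 0.4)
  d1 <- gen_pfg_decay(2e-10, gradients = g, noise_sd = 0, I0 = 7)
  expect_equal(d1$intensity[1], 7)  # zero gradient, zero attenuation
  # doubling D doubles the log-attenuation slope
  d2 <- gen_pfg_decay(4e-10, gradients = g, noise_sd = 0, I0 = 7)
  ratio <- log(d2$intensity / 7) / log(d1$intensity / 7)
  expect_equal(ratio[-1], rep(2, 5), tolerance = 1e-10)
  expect_error(gen_pfg_decay(-1e-10), "D")
})

test_that("noiseless PFG decay round-trips through the fitter", {
  d <- gen_pfg_decay(2.162e-10, noise_sd = 0)
  fit <- fit_stejskal_tanner(d)
  expect_lt(abs(fit$D - 2.162e-10) / 2.162e-10, 1e-6)
  expect_equal(fit$I0, 1, tolerance = 1e-6)
})

test_that("CPMG generator hits the T2 definition and round-trips", {
  T2 <- 0.8
  d <- gen_cpmg_decay(T2, delays = c(0.1, 0.4, T2, 1.6, 2.4), noise_sd = 0,
                      I0 = 3)
  expect_equal(d$intensity[3], 3 / exp(1))  # t = T2
  fit <- fit_t2(d)
  expect_equal(fit$T2, T2, tolerance = 1e-8)
  # delays extending to 1.2 s comfortably bracket a fast-relaxing component
  fit2 <- fit_t2(gen_cpmg_decay(0.6, delays = cpmg_delays(t_max = 1.2),
                                noise_sd = 0))
  expect_true(fit2$well_conditioned)
  expect_error(gen_cpmg_decay(-2), "T2")
})

test_that("peak tables encode the requested stoichiometry", {
  expect_equal(stoichiometry_from_peaks(gen_peak_table(3.7)), 3.7)
  # equal proton counts and stoichiometry 1 give equal areas
  tab <- gen_peak_table(1, protons_peptide = 3, protons_ligand = 3)
  expect_equal(tab$area[tab$species == "ligand"],
               tab$area[tab$species == "peptide"])
  # stoichiometry 2 with 2 ligand vs 1 peptide proton gives area ratio 4
  tab <- gen_peak_table(2, protons_peptide = 1, protons_ligand = 2,
                        n_regions = 1)
  expect_equal(tab$area[tab$species == "ligand"] /
                 tab$area[tab$species == "peptide"], 4)
  expect_error(gen_peak_table(0), "stoich")
})

test_that("decay-curve validation enforces its invariants", {
  expect_error(decay_curve(c(1, 2, 3), c(1, 1, 1), "cpmg"), "4 points")
  expect_error(decay_curve(c(1, 2, 2, 3), rep(1, 4), "cpmg"), "increasing")
  expect_error(decay_curve(1:4, c(1, NA, 1, 1), "cpmg"), "finite")
  expect_error(decay_curve(1:4, rep(1, 4), "pfg"), "delta")
})
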