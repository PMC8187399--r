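test_that("two-component Stejskal-Tanner fit resolves a 90/10 mixture", {
  g <- dosy_gradients(g_max = 1.2)
  k <- st_kernel(g, 0.005, 0.1)
  D <- c(2e-10, 2e-11)
  I <- 0.9 * exp(-D[1] * k) + 0.1 * exp(-D[2] * k)
  set.seed(123)
  I <- I * (1 + rnorm(length(I), sd = 0.01))
  d <- decay_curve(g, I, "pfg", delta = 0.005, big_delta = 0.1)
  fit <- fit_stejskal_tanner(d, n_components = 2)
  expect_equal(fit$n_components, 2L)
  expect_true(all(diff(fit$D) < 0))  # ordered by decreasing D
  expect_lt(abs(fit$D[1] - D[1]) / D[1], 0.05)
  expect_lt(abs(fit$D[2] - D[2]) / D[2], 0.05)
  expect_equal(sum(fit$fractions), 1)
  expect_lt(abs(fit$fractions[1] - 0.9), 0.05)
})

test_that("two equal components collapse to the one-component solution", {
  d <- gen_pfg_decay(1.5e-10, noise_sd = 0)
  one <- fit_stejskal_tanner(d, 1)
  two <- fit_stejskal_tanner(d, 2)
  expect_equal(one$D, 1.5e-10, tolerance = 1e-6)
  # mixture-weighted D of the two-component fit equals the true D
  expect_equal(sum(two$fractions * two$D), 1.5e-10, tolerance = 1e-3)
  expect_error(fit_stejskal_tanner(d, 3), "1 or 2")
  expect_error(fit_stejskal_tanner(gen_cpmg_decay(1)), "pfg")
})

test_that("T2 estimation is scale-equivariant and reports R2 = 1/T2", {
  d1 <- gen_cpmg_decay(0.9, noise_sd = 0, I0 = 1)
  d5 <- gen_cpmg_decay(0.9, noise_sd = 0, I0 = 5)
  f1 <- fit_t2(d1); f5 <- fit_t2(d5)
  expect_equal(f1$T2, f5$T2, tolerance = 1e-10)
  expect_identical(f1$R2, 1 / f1$T2)
  # flat 'decay': T2 unidentifiable
  flat <- decay_curve(c(0.1, 0.2, 0.4, 0.8), rep(2, 4), "cpmg")
  expect_error(fit_t2(flat), "no attenuation")
})

test_that("internal referencing reproduces the printed radii", {
  # peptide: D = 2.162 vs dioxane 14.10 (instrument scale cancels)
  rh_pep <- hydrodynamic_radius(2.162, 14.10)
  expect_equal(round_rh(rh_pep), 13.83)
  expect_lt(abs(rh_pep - 13.82), 0.02)
  # peptide-oleate complex: D = 0.986 vs dioxane 13.61
  rh_cpx <- hydrodynamic_radius(0.986, 13.61)
  expect_equal(round_rh(rh_cpx), 29.3)
  expect_lt(abs(rh_cpx - 29.3), 0.05)
  # identity ratio returns the reference radius itself
  expect_equal(hydrodynamic_radius(3.3, 3.3), 2.12)
  # scale invariance: units cancel
  expect_equal(hydrodynamic_radius(2.162e-10, 14.10e-10), rh_pep)
  expect_error(hydrodynamic_radius(0, 14.1), "d_solute")
})

test_that("stoichiometry follows the proton-normalised area ratio", {
  peaks <- data.frame(species = c("peptide", "ligand"), area = c(1, 8),
                      protons_per_molecule = c(1, 2))
  expect_equal(stoichiometry_from_peaks(peaks), 4)
  equal <- data.frame(species = c("peptide", "ligand"), area = c(6, 6),
                      protons_per_molecule = c(3, 3))
  expect_equal(stoichiometry_from_peaks(equal), 1)
  zero <- data.frame(species = c("peptide", "ligand"), area = c(0, 5),
                     protons_per_molecule = c(1, 1))
  expect_error(stoichiometry_from_peaks(zero), "zero peptide")
  expect_error(stoichiometry_from_peaks(
    data.frame(species = "peptide", area = 1, protons_per_molecule = 1)),
    "ligand")
})

test_that("SE-HPLC calibration round-trips and flags extrapolation", {
  # standards on a known line log10(rh) = 3.1 - 0.55 * volume
  vols <- c(1.5, 2.0, 2.6, 3.2, 3.7)
  standards <- data.frame(rh = 10^(3.1 - 0.55 * vols), volume = vols)
  model <- calibrate_sehplc(standards)
  expect_equal(model$slope, -0.55, tolerance = 1e-10)
  expect_equal(model$intercept, 3.1, tolerance = 1e-10)
  # query at a knot returns that standard's radius
  expect_equal(as.numeric(sehplc_rh(model, 2.6)), standards$rh[3],
               tolerance = 1e-10)
  # beyond the 3.8 mL linearity bound: flagged extrapolation
  expect_warning(out <- sehplc_rh(model, 4.0), "extrapolated")
  expect_true(attr(out, "extrapolated"))
  expect_error(calibrate_sehplc(standards[1:2, ]), "3 calibration")
  expect_error(calibrate_sehplc(data.frame(rh = c(10, 20, 30),
                                           volume = c(1, 2, 3.9))),
               "linearity")
})

test_that("mean residue ellipticity applies the standard convention", {
  # theta 100 mdeg, MRW 110, 0.2 mg/mL, 0.1 cm path -> 55000 deg cm^2/dmol
  expect_equal(mean_residue_ellipticity(100, conc = 0.2, path = 0.1,
                                        mrw = 110), 55000)
  expect_equal(mean_residue_ellipticity(0, 0.2, 0.1, 110), 0)
  expect_equal(mean_residue_ellipticity(100, 0.2, 0.2, 110),
               mean_residue_ellipticity(100, 0.2, 0.1, 110) / 2)
  spec <- data.frame(wavelength = c(200, 210, 222), theta = c(-5, -8, -12))
  out <- mean_residue_ellipticity(spec, 0.2, 0.1, 110)
  expect_s3_class(out, "ellipticity_spectrum")
  expect_equal(out$mre, spec$theta * 110 / (10 * 0.1 * 0.2))
  expect_error(mean_residue_ellipticity(100, 0, 0.1, 110), "conc")
})

test_that("radius referencing is invariant to the diffusion unit scale", {
  for (s in c(1, 1e-10, 42)) {
    expect_equal(hydrodynamic_radius(2.162 * s, 14.10 * s),
                 hydrodynamic_radius(2.162, 14.10))
  }
})
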