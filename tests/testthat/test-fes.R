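test_that("uniform occupancy gives a flat zero surface", {
  centers <- seq(0.5, 3.5, by = 1) / 4  # one point per bin on a 4x4 grid
  p <- as.matrix(expand.grid(x = centers, y = centers))
  fes <- build_fes(p, bins = 4)
  expect_true(all(fes$counts == 1))
  expect_equal(unname(fes$free_energy), matrix(0, 4, 4), tolerance = 1e-12)
})

test_that("a half-populated bin sits RT ln 2 above the modal bin", {
  # two occupied bins: modal with 2 frames, the other with 1
  p <- rbind(c(0.1, 0.1), c(0.1, 0.1), c(0.9, 0.9))
  fes <- build_fes(p, bins = 2, temperature = 300)
  f <- fes$free_energy
  expect_equal(f[fes$ref_bin], 0)
  expect_equal(max(f, na.rm = TRUE), 0.0083145 * 300 * log(2),
               tolerance = 1e-10)
  expect_equal(round(max(f, na.rm = TRUE), 3), 1.729)
})

test_that("free energy is invariant to rescaling the counts", {
  set.seed(4)
  p <- matrix(rnorm(400), ncol = 2)
  f1 <- build_fes(p, bins = 8)
  f2 <- build_fes(rbind(p, p), bins = 8)  # every count doubled
  expect_equal(f1$free_energy, f2$free_energy, tolerance = 1e-12)
  expect_equal(sum(f2$counts), 2 * sum(f1$counts))
})

test_that("surface normalization invariants hold on random clouds", {
  for (seed in 1:5) {
    set.seed(seed)
    p <- matrix(rnorm(600), ncol = 2)
    fes <- build_fes(p, bins = 10)
    f <- fes$free_energy
    expect_true(all(f[!is.na(f)] >= 0))
    expect_equal(min(f, na.rm = TRUE), 0)
    expect_equal(f[fes$ref_bin], 0)
    expect_true(all(is.na(f[fes$counts == 0])))  # masked, never zero
  }
})

test_that("a unimodal cloud yields a single basin", {
  set.seed(7)
  p <- matrix(rnorm(8000, sd = 1), ncol = 2)
  fes <- build_fes(p, bins = 8)
  basins <- locate_basins(fes, depth_cutoff = 50)
  expect_length(basins, 1)
})

test_that("two separated states yield two basins matching the labels", {
  tr <- gen_conformer_ensemble(ensemble_spec(
    n_residues = 8, n_frames = 600, helix_fraction = 0.5, kappa = 100,
    noise_sd = 0, seed = 23, mode = "collective"))
  labels <- attr(tr, "ground_truth")$frame_state
  pc <- fit_dpca(dihedral_timeseries(tr))
  # ~sqrt(n_frames) bins per axis keeps occupied bins contiguous at this n
  fes <- build_fes(pc$projections, bins = 16)
  basins <- locate_basins(fes, depth_cutoff = 50, traj = tr)
  expect_length(basins, 2)
  # frames in each basin carry a single ground-truth state >= 95% purely
  for (b in basins) {
    frames <- which(fes$frame_bins %in% b$bins)
    purity <- max(table(labels[frames])) / length(frames)
    expect_gte(purity, 0.95)
    expect_true(b$representative_frame %in% frames)
  }
  # the two basins pick up opposite states
  state_of <- vapply(basins, function(b) {
    frames <- which(fes$frame_bins %in% b$bins)
    names(which.max(table(labels[frames])))
  }, character(1))
  expect_setequal(state_of, c("H", "C"))
})

test_that("zero depth cutoff reduces basins to their minima bins", {
  set.seed(12)
  p <- matrix(rnorm(300), ncol = 2)
  fes <- build_fes(p, bins = 6)
  basins <- locate_basins(fes, depth_cutoff = 0)
  expect_true(all(vapply(basins, function(b) length(b$bins), integer(1)) >= 1))
  # every basin's bins all sit at its minimum free energy
  for (b in basins)
    expect_true(all(fes$free_energy[b$bins] == b$min_free_energy))
})

test_that("basin count is monotone non-increasing in depth cutoff", {
  set.seed(31)
  p <- rbind(matrix(rnorm(300, -2, 0.7), ncol = 2),
             matrix(rnorm(300, 2, 0.7), ncol = 2))
  fes <- build_fes(p, bins = 12)
  counts <- vapply(c(0, 0.5, 1, 2, 4, 8, 50),
                   function(d) length(locate_basins(fes, d)), integer(1))
  expect_true(all(diff(counts) <= 0))
})
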