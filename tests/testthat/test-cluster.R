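test_that("superposed RMSD is zero on self and on rigid copies", {
  tr <- gen_conformer_ensemble(ensemble_spec(n_residues = 6, n_frames = 4,
                                             seed = 6))
  rm <- pairwise_rmsd(tr)
  expect_equal(diag(rm), rep(0, 4), ignore_attr = TRUE)
  expect_equal(rm, t(rm))
  # a rigidly rotated + translated copy of a frame is at RMSD 0
  set.seed(55)
  two <- tr
  two$coords <- tr$coords[c(1, 1), , , drop = FALSE]
  two <- rigid_transform_frame2(two)
  rm2 <- pairwise_rmsd(two)
  expect_lt(rm2[1, 2], 1e-8)
})

test_that("pairwise RMSD matches the quaternion (Horn) oracle", {
  set.seed(17)
  # 4-atom toy pair
  A <- matrix(rnorm(12), 4, 3)
  B <- A %*% t(random_rotation()) + matrix(rnorm(12, sd = 0.1), 4, 3)
  coords <- array(NA_real_, dim = c(2, 4, 3))
  coords[1, , ] <- A; coords[2, , ] <- B
  top <- data.frame(name = c("N", "CA", "C", "O"), element = "C",
                    resid = c(1, 1, 1, 1), resname = "ALA",
                    group = "peptide", is_proton = FALSE)
  tr <- trajectory(coords, top)
  rm <- pairwise_rmsd(tr, selection = 1:4)
  expect_equal(rm[1, 2], quaternion_rmsd(A, B), tolerance = 1e-8)
  # and on generated ensembles, every pair
  tr <- gen_conformer_ensemble(ensemble_spec(n_residues = 5, n_frames = 5,
                                             seed = 77))
  sel <- select_atoms(tr, "backbone")
  rm <- pairwise_rmsd(tr)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(rm[i, j],
                 quaternion_rmsd(tr$coords[i, sel, ], tr$coords[j, sel, ]),
                 tolerance = 1e-8)
  }
})

test_that("pairwise RMSD agrees with the bio3d fitted-RMSD reference", {
  tr <- gen_conformer_ensemble(ensemble_spec(n_residues = 6, n_frames = 6,
                                             seed = 88))
  sel <- select_atoms(tr, "backbone")
  rm <- pairwise_rmsd(tr)
  inds <- seq_len(3L * length(sel))
  for (i in 1:5) for (j in (i + 1):6) {
    # bio3d reports to 3 decimals; compare in Angstrom at that precision
    ref <- bio3d::rmsd(as.vector(t(tr$coords[i, sel, ])) * 10,
                       as.vector(t(tr$coords[j, sel, ])) * 10,
                       a.inds = inds, b.inds = inds, fit = TRUE)
    expect_equal(rm[i, j] * 10, ref, tolerance = 2e-3, ignore_attr = TRUE)
  }
})

test_that("trivial cutoffs give one cluster or all singletons", {
  tr <- gen_conformer_ensemble(ensemble_spec(n_residues = 5, n_frames = 6,
                                             seed = 19))
  rm <- pairwise_rmsd(tr)
  all_in <- gromos_cluster(tr, cutoff = max(rm) + 1, rmsd_matrix = rm)
  expect_equal(length(all_in$sizes), 1)
  expect_equal(all_in$sizes, 6)
  nonzero <- rm[rm > 0]
  singles <- gromos_cluster(tr, cutoff = min(nonzero) * 0.99, rmsd_matrix = rm)
  expect_equal(length(singles$sizes), 6)
  expect_true(all(singles$sizes == 1))
})

test_that("a constructed 7-frame set matches the exhaustive oracle", {
  tr <- gen_conformer_ensemble(ensemble_spec(
    n_residues = 6, n_frames = 7, helix_fraction = 0.5, seed = 101,
    mode = "collective"))
  rm <- pairwise_rmsd(tr)
  cutoff <- stats::median(rm[rm > 0])
  got <- gromos_cluster(tr, cutoff = cutoff, rmsd_matrix = rm)
  ora <- gromos_oracle(rm, cutoff)
  expect_equal(got$ids, ora$ids)
  expect_equal(got$centers, ora$centers)
  expect_equal(got$sizes, ora$sizes)
})

test_that("GROMOS partition equals the oracle on all small instances", {
  for (seed in 1:50) {
    tr <- gen_conformer_ensemble(ensemble_spec(
      n_residues = 4, n_frames = 3 + (seed %% 6), helix_fraction = 0.5,
      seed = seed))
    rm <- pairwise_rmsd(tr)
    cutoff <- stats::quantile(rm[rm > 0], 0.4)
    got <- gromos_cluster(tr, cutoff = cutoff, rmsd_matrix = rm)
    ora <- gromos_oracle(rm, cutoff)
    expect_equal(got$ids, ora$ids)
    # conservation: cluster sizes sum to the frame count
    expect_equal(sum(got$sizes), nrow(rm))
    # ordering: cluster 1 is (one of) the largest
    expect_true(all(got$sizes[1] >= got$sizes))
  }
})

test_that("clustering input validation works", {
  tr <- gen_conformer_ensemble(ensemble_spec(n_residues = 5, n_frames = 3))
  expect_error(pairwise_rmsd(tr, selection = c(1, 2)), "3 selected atoms")
})
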