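# Backbone phi/psi extraction, vectorized over frames.

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# torsion a-b-c-d for all frames at once; atoms are frames x 3 matrices;
# returns radians in (-pi, pi] (IUPAC sign convention)
torsion_frames <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  x <- rowSums(n1 * n2)
  y <- rowSums(b1 * n2) * sqrt(rowSums(b2 * b2))
  wrap_angle(atan2(y, x))
}

#' Backbone phi/psi time series of a trajectory
#'
#' Computes the standard four-atom backbone torsions for every internal
#' peptide residue: `phi_i = C_(i-1)-N_i-CA_i-C_i` and
#' `psi_i = N_i-CA_i-C_i-N_(i+1)`. Terminal residues, which lack one of the
#' flanking atoms, are excluded.
#'
#' @param traj a [trajectory()] whose peptide residues carry backbone atoms
#'   named `N`, `CA`, `C`.
#' @return a `dihedral_series`: numeric matrix `frames x (2 * n_internal)`
#'   of angles in radians, in `(-pi, pi]`, columns ordered
#'   `phi_2, psi_2, phi_3, psi_3, ...` by residue, with attribute
#'   `residues` giving the residue index of each phi/psi pair.
#' @examples
#' traj <- gen_conformer_ensemble(
#'   ensemble_spec(n_residues = 5, n_frames = 10, helix_fraction = 1,
#'                 noise_sd = 0))
#' dh <- dihedral_timeseries(traj)
#' range(dh[, 1]) * 180 / pi   # phi of residue 2, ~ -60 degrees
#' @export
dihedral_timeseries <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  top <- traj$topology
  pep <- which(top$group == "peptide")
  resids <- sort(unique(top$resid[pep]))
  if (length(resids) < 3L)
    stop_param("dihedral analysis needs at least 3 peptide residues")
  atom_of <- function(res, nm) {
    i <- which(top$group == "peptide" & top$resid == res & top$name == nm)
    if (length(i) != 1L)
      stop_param("residue %d is missing backbone atom '%s'", res, nm)
    i
  }
  internal <- resids[-c(1L, length(resids))]
  nf <- dim(traj$coords)[1]
  out <- matrix(NA_real_, nrow = nf, ncol = 2L * length(internal))
  cn <- character(2L * length(internal))
  at <- function(i) traj$coords[, i, , drop = FALSE][, 1, ]
  for (j in seq_along(internal)) {
    r <- internal[j]
    rprev <- resids[match(r, resids) - 1L]
    rnext <- resids[match(r, resids) + 1L]
    Cm <- at(atom_of(rprev, "C")); Ni <- at(atom_of(r, "N"))
    CAi <- at(atom_of(r, "CA")); Ci <- at(atom_of(r, "C"))
    Nn <- at(atom_of(rnext, "N"))
    if (nf == 1L) {  # drop=FALSE path yields vectors for single frames
      Cm <- rbind(Cm); Ni <- rbind(Ni); CAi <- rbind(CAi)
      Ci <- rbind(Ci); Nn <- rbind(Nn)
    }
    out[, 2L * j - 1L] <- torsion_frames(Cm, Ni, CAi, Ci)
    out[, 2L * j] <- torsion_frames(Ni, CAi, Ci, Nn)
    cn[2L * j - 1L] <- paste0("phi_", r)
    cn[2L * j] <- paste0("psi_", r)
  }
  colnames(out) <- cn
  structure(out, residues = internal, class = c("dihedral_series", "matrix"))
}
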