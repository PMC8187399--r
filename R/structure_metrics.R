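# Secondary-structure propensities and peptide-ligand contact statistics.

# default phi/psi boxes, degrees
.HELIX_BOX <- list(phi = c(-100, -30), psi = c(-80, -5))
.SHEET_PHI <- c(-180, -90)
.SHEET_PSI_A <- c(90, 180)
.SHEET_PSI_B <- c(-180, -170)

#' Secondary-structure propensity from backbone dihedrals
#'
#' Classifies each internal residue in each frame by its (phi, psi) pair:
#' `H` (helical) inside the helix region, `E` (extended/sheet) inside the
#' extended region, `O` otherwise; the per-residue helical propensity is the
#' mean over frames of the `H` indicator.
#'
#' This is a dihedral-region classifier, not a hydrogen-bond (DSSP-style)
#' assignment: it is designed for ensembles whose labels are controlled
#' through the backbone dihedral modes. Externally computed DSSP label
#' streams can be aggregated with the same grouping via [group_ss_labels()].
#'
#' @param dihedrals a `dihedral_series` from [dihedral_timeseries()]
#'   (radians).
#' @param helix_phi,helix_psi helical region bounds, degrees.
#' @param sheet_phi extended-region phi bounds, degrees.
#' @return object of class `ss_matrix`: `labels` (frames x residues character
#'   matrix of `"H"`, `"E"`, `"O"`), `propensity` (per-residue helical
#'   propensity in [0, 1]), `residues`.
#' @export
ss_propensity <- function(dihedrals,
                          helix_phi = .HELIX_BOX$phi,
                          helix_psi = .HELIX_BOX$psi,
                          sheet_phi = .SHEET_PHI) {
  x <- unclass(dihedrals)
  if (!is.matrix(x) || ncol(x) %% 2L != 0L)
    stop_param("'dihedrals' must be a frames x (2 * residues) matrix")
  residues <- attr(dihedrals, "residues") %||% seq_len(ncol(x) / 2L)
  nr <- ncol(x) / 2L
  phi <- rad2deg(x[, 2L * seq_len(nr) - 1L, drop = FALSE])
  psi <- rad2deg(x[, 2L * seq_len(nr), drop = FALSE])
  h <- phi >= helix_phi[1] & phi <= helix_phi[2] &
       psi >= helix_psi[1] & psi <= helix_psi[2]
  e <- phi >= sheet_phi[1] & phi <= sheet_phi[2] &
       ((psi >= .SHEET_PSI_A[1] & psi <= .SHEET_PSI_A[2]) |
        (psi >= .SHEET_PSI_B[1] & psi <= .SHEET_PSI_B[2]))
  labels <- matrix("O", nrow = nrow(x), ncol = nr)
  labels[e] <- "E"
  labels[h] <- "H"   # helix wins if regions are configured to overlap
  colnames(labels) <- paste0("res_", residues)
  structure(list(labels = labels, propensity = colMeans(labels == "H"),
                 residues = residues),
            class = "ss_matrix")
}

#' Group detailed secondary-structure labels into H/E/O
#'
#' Maps a stream of per-residue DSSP-style letters onto the three-state
#' grouping used throughout the package: 3_10 (`G`), alpha (`H`) and pi
#' (`I`) helices count as helix `H`; beta sheet (`E`) and isolated beta
#' bridge (`B`, DSSP also prints `b`) count as sheet `E`; everything else is
#' `O`. A matrix input (frames x residues) is aggregated into an `ss_matrix`
#' with per-residue helical propensities.
#'
#' @param labels character vector or frames x residues matrix of one-letter
#'   codes.
#' @return same shape as the input with values in `{"H","E","O"}`, or an
#'   `ss_matrix` when the input is a matrix.
#' @export
group_ss_labels <- function(labels) {
  map <- function(l) {
    out <- rep("O", length(l))
    out[l %in% c("G", "H", "I")] <- "H"
    out[l %in% c("E", "B", "b")] <- "E"
    out
  }
  if (is.matrix(labels)) {
    grouped <- matrix(map(labels), nrow = nrow(labels),
                      dimnames = dimnames(labels))
    return(structure(list(labels = grouped,
                          propensity = colMeans(grouped == "H"),
                          residues = seq_len(ncol(grouped))),
                     class = "ss_matrix"))
  }
  map(labels)
}

#' Peptide-ligand contact probability per residue
#'
#' For every residue, the minimum distance between its `group_a` atoms and
#' any `group_b` atom is computed frame by frame; a contact is scored when
#' that minimum is strictly below `cutoff`. The per-residue probability is
#' the fraction of contact frames; `overall` uses the minimum over all
#' `group_a` atoms at once.
#'
#' @param traj a [trajectory()].
#' @param group_a,group_b atom selections (see [select_atoms()]); defaults:
#'   side-chain protons vs ligand atoms.
#' @param cutoff contact cutoff in nm; default 0.55, scored strictly
#'   (`distance < cutoff`).
#' @return object of class `contact_profile`: data frame `profile`
#'   (`resid`, `probability`), scalar `overall`, `cutoff`, group labels.
#' @export
contact_probability <- function(traj, group_a = "sidechain-protons",
                                group_b = "ligand", cutoff = 0.55) {
  stopifnot(inherits(traj, "trajectory"))
  check_pos(cutoff, "cutoff", strict = FALSE)
  a <- select_atoms(traj, group_a)
  b <- select_atoms(traj, group_b)
  if (length(a) == 0L) stop_param("'group_a' selects no atoms")
  if (length(b) == 0L) stop_param("'group_b' selects no atoms")
  nf <- n_frames(traj)
  resid_a <- traj$topology$resid[a]
  res_list <- sort(unique(resid_a))
  hits <- matrix(FALSE, nrow = nf, ncol = length(res_list))
  overall_hits <- logical(nf)
  for (f in seq_len(nf)) {
    pa <- traj$coords[f, a, , drop = FALSE][1, , , drop = TRUE]
    pb <- traj$coords[f, b, , drop = FALSE][1, , , drop = TRUE]
    if (length(a) == 1L) pa <- matrix(pa, nrow = 1L)
    if (length(b) == 1L) pb <- matrix(pb, nrow = 1L)
    # squared distance matrix |a|^2 + |b|^2 - 2 a.b
    d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
    dmin_a <- sqrt(pmax(apply(d2, 1, min), 0))
    for (j in seq_along(res_list))
      hits[f, j] <- min(dmin_a[resid_a == res_list[j]]) < cutoff
    overall_hits[f] <- min(dmin_a) < cutoff
  }
  structure(list(
    profile = data.frame(resid = res_list, probability = colMeans(hits)),
    overall = mean(overall_hits), cutoff = cutoff,
    group_a = if (is.character(group_a)) group_a else "custom",
    group_b = if (is.character(group_b)) group_b else "custom"),
    class = "contact_profile")
}

#' @export
print.contact_profile <- function(x, ...) {
  cat(sprintf(
    "<contact_profile> %s vs %s, cutoff %g nm, overall P(contact) = %.3f\n",
    x$group_a, x$group_b, x$cutoff, x$overall))
  invisible(x)
}
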