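#' Multi-frame trajectory container
#'
#' A `trajectory` bundles Cartesian coordinates for a stack of conformers with
#' a per-atom topology table. It is the object every structural analysis in
#' the package consumes: dihedral extraction ([dihedral_timeseries()]),
#' RMSD-based clustering ([gromos_cluster()]), and peptide-ligand contact
#' statistics ([contact_probability()]).
#'
#' @param coords numeric array `frames x atoms x 3`, in nanometres. A single
#'   frame may be given as an `atoms x 3` matrix.
#' @param topology data frame with one row per atom and columns `name` (atom
#'   name, e.g. `"CA"`), `element`, `resid` (1-based residue index,
#'   non-decreasing), `resname`, `group` (one of `"peptide"`, `"ligand"`,
#'   `"other"`), and `is_proton` (logical).
#' @param frame_times optional numeric vector of frame times in picoseconds.
#'
#' @return An object of class `trajectory`: a list with elements `coords`,
#'   `topology` and `frame_times`.
#'
#' @details Validation enforces the container invariants: every frame has the
#'   same atom count (guaranteed by the array shape), residue indices are
#'   non-decreasing, group labels are from the allowed set, and all
#'   coordinates are finite.
#'
#' @seealso [gen_conformer_ensemble()] for the synthetic generator,
#'   [write_traj_pdb()] / [write_traj_xyz()] for serialization.
#' @export
trajectory <- function(coords, topology, frame_times = NULL) {
  if (is.matrix(coords)) {
    coords <- array(coords, dim = c(1L, nrow(coords), ncol(coords)))
  }
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop_param("'coords' must be a frames x atoms x 3 array")
  if (!all(is.finite(coords)))
    stop_param("'coords' contains non-finite values")
  need <- c("name", "element", "resid", "resname", "group", "is_proton")
  if (!is.data.frame(topology) || !all(need %in% names(topology)))
    stop_param("'topology' must be a data frame with columns %s",
               paste(need, collapse = ", "))
  if (nrow(topology) != dim(coords)[2])
    stop_param("topology has %d rows but coords has %d atoms",
               nrow(topology), dim(coords)[2])
  if (is.unsorted(topology$resid))
    stop_param("residue indices in topology must be non-decreasing")
  if (!all(topology$group %in% c("peptide", "ligand", "other")))
    stop_param("topology 'group' must be 'peptide', 'ligand' or 'other'")
  if (!is.null(frame_times) && length(frame_times) != dim(coords)[1])
    stop_param("'frame_times' length must equal the number of frames")
  structure(
    list(coords = coords, topology = topology, frame_times = frame_times),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$coords)
  np <- length(unique(x$topology$resid[x$topology$group == "peptide"]))
  nl <- sum(x$topology$group == "ligand")
  cat(sprintf(
    "<trajectory> %d frames, %d atoms (%d peptide residues, %d ligand atoms)\n",
    d[1], d[2], np, nl))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [trajectory()].
#' @return integer frame count.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  dim(traj$coords)[1]
}

#' Select atom indices from a trajectory topology
#'
#' Convenience selector used by the RMSD, clustering and contact routines.
#'
#' @param traj a [trajectory()].
#' @param selection either an integer vector of atom indices (returned
#'   unchanged after bounds checking), or one of the named selections
#'   `"backbone"` (peptide N, CA, C), `"peptide"`, `"ligand"`,
#'   `"sidechain-protons"` (peptide protons outside the backbone),
#'   `"all"`.
#' @return integer vector of atom indices.
#' @export
select_atoms <- function(traj, selection = "all") {
  stopifnot(inherits(traj, "trajectory"))
  top <- traj$topology
  if (is.numeric(selection)) {
    idx <- as.integer(selection)
    if (any(idx < 1L | idx > nrow(top)))
      stop_param("atom indices out of range 1..%d", nrow(top))
    return(idx)
  }
  selection <- match.arg(selection,
    c("all", "backbone", "peptide", "ligand", "sidechain-protons"))
  switch(selection,
    all = seq_len(nrow(top)),
    backbone = which(top$group == "peptide" & top$name %in% c("N", "CA", "C")),
    peptide = which(top$group == "peptide"),
    ligand = which(top$group == "ligand"),
    `sidechain-protons` = which(top$group == "peptide" & top$is_proton &
                                  !top$name %in% c("N", "CA", "C", "H", "HN"))
  )
}
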