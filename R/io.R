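# Plain-text serialization: multi-model PDB and XYZ trajectories with a
# topology CSV, decay-curve and peak-table CSV. Coordinates are stored in
# the PDB's native Angstrom and converted back to nm on read.

#' Write a trajectory as a multi-model PDB file
#'
#' One `MODEL`/`ENDMDL` block per frame, coordinates converted from nm to
#' Angstrom. Readable with any multi-model-aware PDB reader (e.g.
#' `bio3d::read.pdb(..., multi = TRUE)`).
#'
#' @param traj a [trajectory()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_traj_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  top <- traj$topology
  con <- file(path, "w")
  on.exit(close(con))
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- traj$coords[f, , , drop = FALSE][1, , ] * 10  # nm -> Angstrom
    if (nrow(top) == 1L) xyz <- matrix(xyz, nrow = 1L)
    lines <- sprintf(
      "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(top)), substr(top$name, 1, 4),
      substr(top$resname, 1, 3), top$resid,
      xyz[, 1], xyz[, 2], xyz[, 3], substr(top$element, 1, 2))
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB file into a trajectory
#'
#' Thin wrapper over [bio3d::read.pdb()] (`multi = TRUE`). Atoms whose
#' residue name is `OLE` are tagged `ligand`, others `peptide`; protons are
#' recognised by an element/name starting with `H`.
#'
#' @param path PDB file path.
#' @return a [trajectory()] with coordinates in nm.
#' @export
read_traj_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  at <- pdb$atom
  n_atoms <- nrow(at)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  nf <- nrow(xyz)
  coords <- array(NA_real_, dim = c(nf, n_atoms, 3L))
  for (f in seq_len(nf))
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE) / 10
  elem <- ifelse(is.na(at$elesy) | at$elesy == "",
                 substr(trimws(at$elety), 1, 1), trimws(at$elesy))
  top <- data.frame(
    name = trimws(at$elety), element = elem, resid = at$resno,
    resname = trimws(at$resid),
    group = ifelse(trimws(at$resid) == "OLE", "ligand", "peptide"),
    is_proton = toupper(substr(elem, 1, 1)) == "H",
    stringsAsFactors = FALSE)
  trajectory(coords, top)
}

#' Write a trajectory in multi-frame XYZ format
#'
#' Standard XYZ blocks (atom count, comment, `element x y z` rows) per
#' frame, coordinates in Angstrom.
#'
#' @param traj a [trajectory()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_traj_xyz <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  n_atoms <- nrow(traj$topology)
  for (f in seq_len(n_frames(traj))) {
    writeLines(c(as.character(n_atoms), sprintf("frame %d", f)), con)
    xyz <- traj$coords[f, , , drop = FALSE][1, , ] * 10
    if (n_atoms == 1L) xyz <- matrix(xyz, nrow = 1L)
    writeLines(sprintf("%-2s %12.6f %12.6f %12.6f", traj$topology$element,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ file
#'
#' @param path XYZ file path.
#' @param topology optional topology data frame (see [trajectory()]); when
#'   omitted a minimal one is built from the element column.
#' @return a [trajectory()] with coordinates in nm.
#' @export
read_traj_xyz <- function(path, topology = NULL) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- as.integer(trimws(lines[i]))
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- do.call(rbind, strsplit(trimws(block), "\\s+"))
    frames[[length(frames) + 1L]] <-
      matrix(as.numeric(parts[, 2:4]), ncol = 3L) / 10
    if (is.null(topology)) {
      el <- parts[, 1]
      topology <- data.frame(
        name = el, element = el, resid = seq_len(n),
        resname = "UNK", group = "other",
        is_proton = toupper(substr(el, 1, 1)) == "H",
        stringsAsFactors = FALSE)
    }
    i <- i + 2L + n
  }
  coords <- array(NA_real_, dim = c(length(frames), nrow(frames[[1]]), 3L))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  trajectory(coords, topology)
}

#' Write / read a topology table as CSV
#'
#' @param topology topology data frame (see [trajectory()]).
#' @param path CSV path.
#' @return `path` invisibly (write) or the topology data frame (read).
#' @export
write_topology_csv <- function(topology, path) {
  utils::write.csv(topology, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_topology_csv
#' @export
read_topology_csv <- function(path) {
  top <- utils::read.csv(path, stringsAsFactors = FALSE)
  top$is_proton <- as.logical(top$is_proton)
  top
}

#' Write / read a decay curve as CSV
#'
#' Two columns, `abscissa` and `intensity`; the acquisition constants are
#' carried as comment-free extra columns (`kind`, `delta`, `big_delta`) on
#' the first row.
#'
#' @param decay a `decay_curve`.
#' @param path CSV path.
#' @return `path` invisibly (write) or a `decay_curve` (read).
#' @export
write_decay_csv <- function(decay, path) {
  stopifnot(inherits(decay, "decay_curve"))
  df <- data.frame(abscissa = decay$abscissa, intensity = decay$intensity,
                   kind = decay$kind,
                   delta = decay$delta %||% NA_real_,
                   big_delta = decay$big_delta %||% NA_real_)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_decay_csv
#' @export
read_decay_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  kind <- df$kind[1]
  decay_curve(df$abscissa, df$intensity, kind = kind,
              delta = if (kind == "pfg") df$delta[1] else NULL,
              big_delta = if (kind == "pfg") df$big_delta[1] else NULL)
}

#' Write / read a peak table as CSV
#'
#' @param peaks a `peak_table` data frame.
#' @param path CSV path.
#' @return `path` invisibly (write) or a `peak_table` (read).
#' @export
write_peaks_csv <- function(peaks, path) {
  utils::write.csv(as.data.frame(peaks), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peaks_csv
#' @export
read_peaks_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(tab) <- c("peak_table", "data.frame")
  tab
}
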