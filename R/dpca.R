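# Dihedral principal component analysis and free-energy surfaces.
#
# Backbone torsions are periodic, so PCA is performed on the sin/cos
# embedding of each angle (the standard dPCA transform): theta -> (cos theta,
# sin theta). The resulting collective coordinates are invariant to overall
# rotation and translation of the structures. A Boltzmann inversion of the
# 2-D histogram over the first two components gives the free-energy surface
# F_i = -RT ln(P_i / P_o), referenced to the most populated bin.

#' Fit a dihedral principal component model
#'
#' Embeds every angle as `(cos theta, sin theta)`, eigendecomposes the
#' covariance matrix of the embedded data, and projects the mean-centred
#' embeddings onto the leading eigenvectors.
#'
#' @param dihedrals a `dihedral_series` from [dihedral_timeseries()], or any
#'   frames x angles matrix of radians.
#' @param k number of components to keep projections for (default 2).
#' @return object of class `pc_model`: list with `mean` (embedding mean),
#'   `vectors` (orthonormal eigenvector columns), `values` (eigenvalues,
#'   non-increasing), and `projections` (frames x k scores).
#' @details Constant angle columns simply contribute zero-variance embedding
#'   coordinates and zero eigenvalues; they are not an error. The eigenvalue
#'   sum equals the trace of the embedded covariance.
#' @export
fit_dpca <- function(dihedrals, k = 2) {
  x <- unclass(dihedrals)
  if (!is.matrix(x)) stop_param("'dihedrals' must be a matrix")
  if (nrow(x) < 2L) stop_param("dPCA needs at least 2 frames")
  k <- check_count(k, "k")
  emb <- embed_angles(x)
  mu <- colMeans(emb)
  cc <- stats::cov(emb)
  eig <- eigen(cc, symmetric = TRUE)
  vals <- pmax(eig$values, 0)  # clip eigenvalue noise at -1e-10 scale
  k <- min(k, ncol(emb))
  centred <- sweep(emb, 2, mu)
  proj <- centred %*% eig$vectors[, seq_len(k), drop = FALSE]
  colnames(proj) <- paste0("PC", seq_len(k))
  structure(list(mean = mu, vectors = eig$vectors, values = vals,
                 projections = proj),
            class = "pc_model")
}

# (cos, sin) interleaved per angle column
embed_angles <- function(x) {
  d <- ncol(x)
  emb <- matrix(NA_real_, nrow = nrow(x), ncol = 2L * d)
  emb[, 2L * seq_len(d) - 1L] <- cos(x)
  emb[, 2L * seq_len(d)] <- sin(x)
  cn <- colnames(x) %||% paste0("a", seq_len(d))
  colnames(emb) <- as.vector(rbind(paste0("cos_", cn), paste0("sin_", cn)))
  emb
}

#' @export
print.pc_model <- function(x, ...) {
  tot <- sum(x$values)
  v <- x$values[1:min(4, length(x$values))]
  cat(sprintf("<pc_model> %d-dim embedding, %d frames projected\n",
              length(x$mean), nrow(x$projections)))
  cat("  leading eigenvalues:", paste(signif(v, 4), collapse = ", "),
      sprintf(" (%.1f%% of trace in PC1-2)\n",
              100 * sum(x$values[1:2]) / max(tot, .Machine$double.eps)))
  invisible(x)
}

#' Free-energy surface over two collective coordinates
#'
#' Bins the projections on a regular 2-D grid and Boltzmann-inverts the
#' populations: `F_i = -RT ln(P_i / P_o)` with `R = 0.0083145` kJ/(mol K)
#' and `P_o` the population of the most populated bin, so `F = 0` exactly at
#' the modal bin and `F >= 0` everywhere. Empty bins are left `NA` (masked),
#' never 0.
#'
#' @param projections frames x 2 matrix of scores (e.g.
#'   `fit_dpca(...)$projections`).
#' @param bins number of bins per axis (default 64).
#' @param temperature temperature in K entering `RT` (default 300).
#' @return object of class `fes_grid`: list with `x_edges`, `y_edges`,
#'   `counts` (bins x bins matrix), `free_energy` (same shape, kJ/mol, `NA`
#'   where empty), `temperature`, `gas_constant`, `ref_bin` (flat
#'   column-major index of the modal bin; ties resolved to the lowest flat
#'   index), and `frame_bins` (flat bin index of every frame).
#' @export
build_fes <- function(projections, bins = 64, temperature = 300) {
  p <- as.matrix(projections)
  if (ncol(p) < 2L) stop_param("'projections' must have at least 2 columns")
  p <- p[, 1:2, drop = FALSE]
  if (nrow(p) < 1L) stop_param("at least one frame is required")
  bins <- check_count(bins, "bins", min = 2L)
  check_pos(temperature, "temperature")
  xe <- bin_edges(p[, 1], bins)
  ye <- bin_edges(p[, 2], bins)
  ix <- bin_index(p[, 1], xe)
  iy <- bin_index(p[, 2], ye)
  counts <- matrix(0L, nrow = bins, ncol = bins)
  flat <- ix + (iy - 1L) * bins
  tab <- tabulate(flat, nbins = bins * bins)
  counts[] <- tab
  ref <- which.max(counts)  # lowest flat (column-major) index on ties
  fe <- matrix(NA_real_, nrow = bins, ncol = bins)
  nz <- counts > 0
  fe[nz] <- -GAS_CONSTANT_KJ * temperature * log(counts[nz] / counts[ref])
  structure(list(x_edges = xe, y_edges = ye, counts = counts,
                 free_energy = fe, temperature = temperature,
                 gas_constant = GAS_CONSTANT_KJ, ref_bin = ref,
                 frame_bins = flat),
            class = "fes_grid")
}

bin_edges <- function(v, bins) {
  r <- range(v)
  if (r[1] == r[2]) r <- r + c(-0.5, 0.5)  # degenerate axis: unit-wide box
  seq(r[1], r[2], length.out = bins + 1L)
}

bin_index <- function(v, edges) {
  i <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  pmin(pmax(i, 1L), length(edges) - 1L)
}

#' @export
print.fes_grid <- function(x, ...) {
  cat(sprintf(
    "<fes_grid> %dx%d bins, %d frames, T = %g K, max F = %.2f kJ/mol\n",
    nrow(x$counts), ncol(x$counts), sum(x$counts), x$temperature,
    max(x$free_energy, na.rm = TRUE)))
  invisible(x)
}

#' Locate free-energy basins on a surface
#'
#' Local minima are occupied bins whose free energy does not exceed that of
#' any occupied 4-connected neighbour. Each basin is grown from its minimum
#' by flood fill over 4-connected occupied bins with
#' `F <= F_min + depth_cutoff`; bins already claimed by a deeper basin are
#' not revisited, so basins partition the claimed bins. With
#' `depth_cutoff = 0` each basin is the single bin at its minimum.
#'
#' @param fes a [build_fes()] grid.
#' @param depth_cutoff basin depth in kJ/mol (default 2, roughly kT at 300 K).
#' @param traj optional [trajectory()] aligned with the frames that built the
#'   surface; when supplied, each basin's representative frame is the medoid
#'   (minimum summed superposed RMSD) of the frames in its bins.
#' @param selection atom selection for the medoid RMSD (default
#'   `"backbone"`).
#' @return list of `basin` objects: `bins` (flat indices), `min_free_energy`,
#'   `n_frames`, `representative_frame` (`NA` without `traj`), ordered by
#'   increasing minimum free energy.
#' @export
locate_basins <- function(fes, depth_cutoff = 2, traj = NULL,
                          selection = "backbone") {
  stopifnot(inherits(fes, "fes_grid"))
  check_pos(depth_cutoff, "depth_cutoff", strict = FALSE)
  fe <- fes$free_energy
  nb <- nrow(fe)
  occ <- which(!is.na(fe))
  if (length(occ) == 0L) return(list())
  neighbours <- function(i) {
    r <- (i - 1L) %% nb + 1L; c <- (i - 1L) %/% nb + 1L
    out <- integer(0)
    if (r > 1L) out <- c(out, i - 1L)
    if (r < nb) out <- c(out, i + 1L)
    if (c > 1L) out <- c(out, i - nb)
    if (c < ncol(fe)) out <- c(out, i + nb)
    out
  }
  is_min <- vapply(occ, function(i) {
    nb_occ <- setdiff(neighbours(i), which(is.na(fe)))
    all(fe[i] <= fe[nb_occ])
  }, logical(1))
  minima <- occ[is_min]
  minima <- minima[order(fe[minima], minima)]
  claimed <- rep(FALSE, length(fe))
  basins <- list()
  for (m in minima) {
    if (claimed[m]) next  # plateau already swallowed by a deeper basin
    lim <- fe[m] + depth_cutoff
    members <- integer(0)
    queue <- m
    claimed[m] <- TRUE
    while (length(queue)) {
      i <- queue[[1]]; queue <- queue[-1]
      members <- c(members, i)
      for (j in neighbours(i)) {
        if (!claimed[j] && !is.na(fe[j]) && fe[j] <= lim) {
          claimed[j] <- TRUE
          queue <- c(queue, j)
        }
      }
    }
    frames <- which(fes$frame_bins %in% members)
    rep_frame <- NA_integer_
    if (!is.null(traj) && length(frames) > 0) {
      rep_frame <- medoid_frame(traj, frames, selection)
    }
    basins[[length(basins) + 1L]] <- structure(
      list(bins = sort(members), min_free_energy = fe[m],
           n_frames = length(frames), representative_frame = rep_frame),
      class = "basin")
  }
  basins
}

# medoid by summed pairwise superposed RMSD; subsample deterministically if
# the basin is very large (evenly spaced frames)
medoid_frame <- function(traj, frames, selection, max_frames = 200L) {
  if (length(frames) == 1L) return(frames)
  use <- frames
  if (length(use) > max_frames)
    use <- use[round(seq(1, length(use), length.out = max_frames))]
  rm <- pairwise_rmsd(traj, selection = selection, frames = use)
  use[which.min(rowSums(rm))]
}
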