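# Pairwise superposed RMSD and GROMOS (Daura) geometric clustering.

# minimal RMSD between two centred coordinate sets by the Kabsch/SVD trace
# identity: msd = (|A|^2 + |B|^2 - 2 tr(Sigma)) / n with Sigma the singular
# values of t(A) B, the smallest negated for improper alignments
kabsch_rmsd <- function(A, B) {
  S <- svd(crossprod(A, B))
  tr <- sum(S$d[1:2]) + sign(det(S$u %*% t(S$v))) * S$d[3]
  sqrt(max(sum(A^2) + sum(B^2) - 2 * tr, 0) / nrow(A))
}

#' Pairwise optimally-superposed RMSD matrix
#'
#' Every pair of frames is superposed by the optimal least-squares rotation
#' and translation (Kabsch algorithm; the RMSD is evaluated directly from
#' the singular values of the 3x3 cross-covariance, with the proper-rotation
#' determinant correction) before the RMSD is taken, so the matrix reflects
#' internal conformational differences only.
#'
#' @param traj a [trajectory()].
#' @param selection atom selection (see [select_atoms()]); default
#'   `"backbone"`.
#' @param frames optional integer vector of frame indices (default: all).
#' @return symmetric `length(frames)` square matrix of RMSD values in the
#'   coordinate units (nm), zero diagonal.
#' @export
pairwise_rmsd <- function(traj, selection = "backbone", frames = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  sel <- select_atoms(traj, selection)
  if (length(sel) < 3L)
    stop_param("superposition needs at least 3 selected atoms, got %d",
               length(sel))
  frames <- frames %||% seq_len(n_frames(traj))
  nf <- length(frames)
  if (nf < 2L) stop_param("at least 2 frames are required")
  centred <- lapply(frames, function(f) {
    m <- traj$coords[f, sel, , drop = FALSE][1, , ]
    if (length(sel) == 1L) m <- matrix(m, nrow = 1L)
    sweep(m, 2, colMeans(m))
  })
  out <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1L)) {
    for (j in (i + 1L):nf) {
      r <- kabsch_rmsd(centred[[i]], centred[[j]])
      out[i, j] <- r
      out[j, i] <- r
    }
  }
  dimnames(out) <- list(frames, frames)
  out
}

#' GROMOS (Daura) geometric clustering
#'
#' Iterative neighbour counting on the pairwise superposed RMSD matrix: the
#' frame with the most neighbours within `cutoff` becomes a cluster centre
#' (ties broken by the lowest frame index); it and its neighbours are removed
#' as one cluster, and the procedure repeats on the remaining frames.
#' Clusters are then renumbered by decreasing size, ties by the earlier
#' central frame.
#'
#' @param traj a [trajectory()].
#' @param cutoff RMSD neighbour cutoff in nm (default 0.2; the choice is a
#'   tunable of the method, not a universal constant).
#' @param selection atom selection used for the RMSD (default `"backbone"`).
#' @param rmsd_matrix optional precomputed matrix from [pairwise_rmsd()]
#'   (useful to reuse across cutoffs).
#' @return object of class `cluster_result`: `ids` (per-frame cluster id,
#'   1-based, cluster 1 largest), `centers` (central frame per cluster),
#'   `sizes`, `cutoff`, `selection`.
#' @export
gromos_cluster <- function(traj, cutoff = 0.2, selection = "backbone",
                           rmsd_matrix = NULL) {
  check_pos(cutoff, "cutoff", strict = FALSE)
  rm <- rmsd_matrix %||% pairwise_rmsd(traj, selection = selection)
  nf <- nrow(rm)
  adj <- rm <= cutoff  # a frame is always its own neighbour (diagonal 0)
  remaining <- rep(TRUE, nf)
  ids <- integer(nf)
  centers <- integer(0)
  k <- 0L
  while (any(remaining)) {
    counts <- rowSums(adj[, remaining, drop = FALSE])
    counts[!remaining] <- -1L
    center <- which.max(counts)  # lowest index on ties
    members <- which(remaining & adj[center, ])
    k <- k + 1L
    ids[members] <- k
    centers[k] <- center
    remaining[members] <- FALSE
  }
  sizes <- tabulate(ids, nbins = k)
  ord <- order(-sizes, centers)
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  structure(list(ids = relabel[ids], centers = centers[ord],
                 sizes = sizes[ord], cutoff = cutoff,
                 selection = if (is.character(selection)) selection
                             else "custom"),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d clusters over %d frames (cutoff %g nm)\n",
              length(x$sizes), length(x$ids), x$cutoff))
  n <- min(5L, length(x$sizes))
  cat("  sizes:", paste(x$sizes[1:n], collapse = ", "),
      if (length(x$sizes) > n) "..." else "", "\n")
  invisible(x)
}
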