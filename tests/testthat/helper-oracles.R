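# Independent oracles and small fixture builders used across the suite.

# scalar torsion a-b-c-d via explicit cross/dot products and atan2 (radians)
torsion_oracle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                         u[3] * v[1] - u[1] * v[3],
                         u[1] * v[2] - u[2] * v[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  atan2(sum(b1 * n2) * sqrt(sum(b2^2)), sum(n1 * n2))
}

# optimal superposed RMSD by Horn's quaternion method (no SVD): the largest
# eigenvalue of the 4x4 quaternion matrix gives the maximal correlation.
quaternion_rmsd <- function(A, B) {
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  S <- t(A) %*% B
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(A^2) + sum(B^2) - 2 * lambda) / nrow(A)
  sqrt(max(msd, 0))
}

# exhaustive Daura neighbour-count partition from an RMSD matrix
gromos_oracle <- function(rm, cutoff) {
  nf <- nrow(rm)
  remaining <- seq_len(nf)
  ids <- integer(nf)
  centers <- integer(0)
  k <- 0L
  while (length(remaining) > 0) {
    counts <- vapply(remaining, function(i)
      sum(rm[i, remaining] <= cutoff), integer(1))
    center <- remaining[which.max(counts)]
    members <- remaining[rm[center, remaining] <= cutoff]
    k <- k + 1L
    ids[members] <- k
    centers[k] <- center
    remaining <- setdiff(remaining, members)
  }
  sizes <- tabulate(ids, nbins = k)
  ord <- order(-sizes, centers)
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  list(ids = relabel[ids], centers = centers[ord], sizes = sizes[ord])
}

# mean silhouette of a 1-D embedding given two-group labels
silhouette_1d <- function(x, labels) {
  labs <- unique(labels)
  stopifnot(length(labs) == 2)
  s <- vapply(seq_along(x), function(i) {
    own <- labels == labels[i]
    a <- mean(abs(x[i] - x[own & seq_along(x) != i]))
    b <- mean(abs(x[i] - x[!own]))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# minimal single-residue-contact fixture: one peptide residue (N, CA, C, HB)
# plus one ligand atom placed at the given distance from HB in each frame
make_contact_traj <- function(distances) {
  base <- rbind(N = c(0, 0, 0), CA = c(0.146, 0, 0),
                C = c(0.2, 0.14, 0), HB = c(0.1, -0.2, 0))
  nf <- length(distances)
  coords <- array(NA_real_, dim = c(nf, 5L, 3L))
  for (f in seq_len(nf)) {
    coords[f, 1:4, ] <- base
    coords[f, 5, ] <- base["HB", ] + c(distances[f], 0, 0)
  }
  top <- data.frame(
    name = c("N", "CA", "C", "HB", "HO"),
    element = c("N", "C", "C", "H", "H"),
    resid = c(1L, 1L, 1L, 1L, 2L), resname = c(rep("ALA", 4), "OLE"),
    group = c(rep("peptide", 4), "ligand"),
    is_proton = c(FALSE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  trajectory(coords, top)
}

# standard single-chain topology for hand-built backbone frames
backbone_topology <- function(n_res) {
  data.frame(
    name = rep(c("N", "CA", "C", "HB"), n_res),
    element = rep(c("N", "C", "C", "H"), n_res),
    resid = rep(seq_len(n_res), each = 4L),
    resname = "ALA",
    group = "peptide",
    is_proton = rep(c(FALSE, FALSE, FALSE, TRUE), n_res),
    stringsAsFactors = FALSE)
}

# random proper rotation matrix (det +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# apply a random rigid rotation + translation to frame 2 only
rigid_transform_frame2 <- function(traj) {
  R <- random_rotation(); shift <- stats::rnorm(3)
  m <- traj$coords[2, , , drop = FALSE][1, , ]
  traj$coords[2, , ] <- sweep(m %*% t(R), 2, -shift)
  traj
}

# apply a rigid rotation + translation to every frame of a trajectory
rigid_transform <- function(traj, R = random_rotation(),
                            shift = stats::rnorm(3)) {
  out <- traj
  for (f in seq_len(dim(traj$coords)[1])) {
    m <- traj$coords[f, , , drop = FALSE][1, , ]
    if (dim(traj$coords)[2] == 1L) m <- matrix(m, nrow = 1L)
    out$coords[f, , ] <- sweep(m %*% t(R), 2, -shift)
  }
  out
}
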