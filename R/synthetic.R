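# Synthetic conformer ensembles with known ground truth.
#
# The generator emulates the statistical structure the downstream analyses
# assume: a two-state helix/coil peptide backbone (dihedral modes) plus a
# small cluster of ligand pseudo-atoms that is in contact with a side-chain
# proton in a controlled fraction of frames. Coordinates are built from
# dihedrals by standard peptide geometry with fixed bond lengths and angles;
# each residue carries one side-chain pseudo-proton.

# canonical backbone geometry (nm / degrees)
.BOND_N_CA <- 0.1458
.BOND_CA_C <- 0.1525
.BOND_C_N  <- 0.1329
.ANG_C_N_CA <- 121.7
.ANG_N_CA_C <- 111.2
.ANG_CA_C_N <- 116.6

# von Mises sampler, Best & Fisher (1979) rejection scheme; mu in radians
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    if (any(ok)) {
      th <- sign(u3[ok] - 0.5) * acos(pmax(-1, pmin(1, f[ok])))
      take <- min(sum(ok), n - got)
      out[(got + 1L):(got + take)] <- th[seq_len(take)]
      got <- got + take
    }
  }
  wrap_angle(mu + out)
}

# Place atom d bonded to c, given the three preceding atoms a-b-c, the bond
# length |cd|, bond angle b-c-d and torsion a-b-c-d (NeRF construction).
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  ang <- deg2rad(angle_deg); tor <- deg2rad(torsion_deg)
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * cos(tor) * sin(ang), bond * sin(tor) * sin(ang))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Build one backbone frame (N, CA, C per residue + side-chain pseudo-proton)
# from per-residue phi/psi (degrees). Returns an (4*n_res) x 3 matrix in the
# atom order N, CA, C, HB per residue.
build_peptide_frame <- function(phi, psi) {
  n_res <- length(phi)
  stopifnot(length(psi) == n_res, n_res >= 2)
  xyz <- matrix(NA_real_, nrow = 4L * n_res, ncol = 3L)
  idx <- function(i, k) 4L * (i - 1L) + k  # k: 1=N 2=CA 3=C 4=HB
  xyz[idx(1, 1), ] <- c(0, 0, 0)
  xyz[idx(1, 2), ] <- c(.BOND_N_CA, 0, 0)
  ang <- deg2rad(.ANG_N_CA_C)
  xyz[idx(1, 3), ] <- xyz[idx(1, 2), ] +
    .BOND_CA_C * c(-cos(ang), sin(ang), 0)
  for (i in 2:n_res) {
    Np <- xyz[idx(i - 1, 1), ]; CAp <- xyz[idx(i - 1, 2), ]; Cp <- xyz[idx(i - 1, 3), ]
    Ni <- place_atom(Np, CAp, Cp, .BOND_C_N, .ANG_CA_C_N, psi[i - 1])
    CAi <- place_atom(CAp, Cp, Ni, .BOND_N_CA, .ANG_C_N_CA, 180)  # trans omega
    Ci <- place_atom(Cp, Ni, CAi, .BOND_CA_C, .ANG_N_CA_C, phi[i])
    xyz[idx(i, 1), ] <- Ni; xyz[idx(i, 2), ] <- CAi; xyz[idx(i, 3), ] <- Ci
  }
  for (i in 1:n_res) {
    # side-chain pseudo-proton off CA, roughly where a CB proton sits
    xyz[idx(i, 4), ] <- place_atom(xyz[idx(i, 3), ], xyz[idx(i, 1), ],
                                   xyz[idx(i, 2), ], 0.215, 110, 122)
  }
  xyz
}

#' Specification for a synthetic conformer ensemble
#'
#' Collects the knobs of the two-state helix/coil generator. Defaults are the
#' package's reference desk-scale conditions.
#'
#' @param n_residues number of peptide residues (>= 3 for dihedral analysis).
#' @param n_frames number of frames.
#' @param helix_fraction probability that a residue (or, in collective mode, a
#'   whole frame) is drawn from the helical dihedral mode.
#' @param n_ligand number of ligand pseudo-atoms (olefinic-proton stand-ins);
#'   default 4, one per fatty-acid molecule at a 1:4 peptide:lipid ratio.
#' @param contact_fraction share of frames in which the ligand cluster is
#'   placed within 0.55 nm of a randomly chosen side-chain proton; in the
#'   remaining frames it sits more than 1.0 nm from every peptide atom.
#' @param noise_sd additive Gaussian coordinate noise, nm.
#' @param seed integer seed; all randomness in the generator flows through it.
#' @param kappa von Mises concentration of the dihedral modes (~50 gives an
#'   8 degree circular spread).
#' @param mode `"independent"` draws a helix/coil state per residue per frame
#'   (broad coil mixture over the extended and left-handed regions);
#'   `"collective"` draws one state per frame applied to all residues, with a
#'   concentrated extended coil mode, yielding a genuinely two-state ensemble
#'   for separability tests.
#' @return object of class `ensemble_spec`.
#' @seealso [gen_conformer_ensemble()]
#' @export
ensemble_spec <- function(n_residues = 10, n_frames = 500,
                          helix_fraction = 0.5, n_ligand = 4,
                          contact_fraction = 0.5, noise_sd = 0.002,
                          seed = 1, kappa = 50,
                          mode = c("independent", "collective")) {
  check_count(n_residues, "n_residues", min = 2L)
  check_count(n_frames, "n_frames", min = 1L)
  check_prob(helix_fraction, "helix_fraction")
  check_count(n_ligand, "n_ligand", min = 0L)
  check_prob(contact_fraction, "contact_fraction")
  check_pos(noise_sd, "noise_sd", strict = FALSE)
  check_pos(kappa, "kappa")
  structure(
    list(n_residues = as.integer(n_residues), n_frames = as.integer(n_frames),
         helix_fraction = helix_fraction, n_ligand = as.integer(n_ligand),
         contact_fraction = contact_fraction, noise_sd = noise_sd,
         seed = as.integer(seed), kappa = kappa, mode = match.arg(mode)),
    class = "ensemble_spec")
}

# draw (phi, psi) in degrees for one residue-state
.draw_dihedrals <- function(n, state, kappa, collective) {
  phi <- numeric(n); psi <- numeric(n)
  h <- state == "H"
  if (any(h)) {
    phi[h] <- rad2deg(rvonmises(sum(h), deg2rad(-60), kappa))
    psi[h] <- rad2deg(rvonmises(sum(h), deg2rad(-45), kappa))
  }
  if (any(!h)) {
    m <- sum(!h)
    if (collective) {
      phi[!h] <- rad2deg(rvonmises(m, deg2rad(-135), kappa))
      psi[!h] <- rad2deg(rvonmises(m, deg2rad(135), kappa))
    } else {
      beta <- stats::runif(m) < 0.7
      phi[!h] <- ifelse(beta, stats::runif(m, -170, -95), stats::runif(m, 40, 90))
      psi[!h] <- ifelse(beta, stats::runif(m, 95, 175), stats::runif(m, 10, 70))
    }
  }
  cbind(phi = phi, psi = psi)
}

#' Generate a synthetic helix/coil conformer ensemble
#'
#' Builds a [trajectory()] whose backbone dihedrals are drawn from a helical
#' mode (phi ~ -60, psi ~ -45 degrees) with probability `helix_fraction` and
#' from a coil mode otherwise, and whose ligand pseudo-atoms are in contact
#' (< 0.55 nm from a randomly chosen side-chain proton) in a
#' `contact_fraction` share of frames and > 1.0 nm from every peptide atom in
#' the rest. The generator is deterministic under a fixed seed.
#'
#' Ground truth is attached as `attr(x, "ground_truth")`: the per-frame,
#' per-residue state matrix (`"H"`/`"C"`), the per-frame state label in
#' collective mode, the logical contact indicator per frame, and the contacted
#' residue index.
#'
#' @param spec an [ensemble_spec()].
#' @return a [trajectory()] with a `ground_truth` attribute.
#' @examples
#' traj <- gen_conformer_ensemble(ensemble_spec(n_residues = 6, n_frames = 50))
#' traj
#' @export
gen_conformer_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  nr <- spec$n_residues; nf <- spec$n_frames; nl <- spec$n_ligand
  n_pep_atoms <- 4L * nr
  n_atoms <- n_pep_atoms + nl
  with_seed(spec$seed, {
    if (spec$mode == "collective") {
      frame_state <- ifelse(stats::runif(nf) < spec$helix_fraction, "H", "C")
      state <- matrix(frame_state, nrow = nf, ncol = nr)
    } else {
      frame_state <- rep(NA_character_, nf)
      state <- matrix(ifelse(stats::runif(nf * nr) < spec$helix_fraction,
                             "H", "C"), nrow = nf, ncol = nr)
    }
    contact <- if (nl > 0) stats::runif(nf) < spec$contact_fraction
               else rep(FALSE, nf)
    contact_res <- ifelse(contact, sample.int(nr, nf, replace = TRUE),
                          NA_integer_)
    coords <- array(NA_real_, dim = c(nf, n_atoms, 3L))
    hb_rows <- 4L * seq_len(nr)  # side-chain proton row per residue
    for (f in seq_len(nf)) {
      dh <- .draw_dihedrals(nr, state[f, ], spec$kappa,
                            collective = spec$mode == "collective")
      frame <- build_peptide_frame(dh[, "phi"], dh[, "psi"])
      if (nl > 0) {
        if (contact[f]) {
          anchor <- frame[hb_rows[contact_res[f]], ]
          u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
          lig1 <- anchor + u * stats::runif(1, 0.20, 0.45)
          lig <- matrix(rep(lig1, each = nl), nrow = nl)
          if (nl > 1) {
            jit <- matrix(stats::rnorm(3 * (nl - 1), sd = 0.03), ncol = 3)
            jit <- jit * pmin(1, 0.08 / sqrt(rowSums(jit^2)))  # cap at 0.08 nm
            lig[-1, ] <- lig[-1, , drop = FALSE] + jit
          }
        } else {
          cen <- colMeans(frame)
          rad <- max(sqrt(rowSums(sweep(frame, 2, cen)^2)))
          u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
          far <- cen + u * (rad + 1.2 + stats::runif(1, 0, 0.8))
          lig <- matrix(rep(far, each = nl), nrow = nl)
          if (nl > 1) {
            jit <- matrix(stats::rnorm(3 * (nl - 1), sd = 0.02), ncol = 3)
            jit <- jit * pmin(1, 0.05 / sqrt(rowSums(jit^2)))
            lig[-1, ] <- lig[-1, , drop = FALSE] + jit
          }
        }
        frame <- rbind(frame, lig)
      }
      if (spec$noise_sd > 0)
        frame <- frame + stats::rnorm(length(frame), sd = spec$noise_sd)
      coords[f, , ] <- frame
    }
    top <- data.frame(
      name = c(rep(c("N", "CA", "C", "HB"), nr), rep("HO", nl)),
      element = c(rep(c("N", "C", "C", "H"), nr), rep("H", nl)),
      resid = c(rep(seq_len(nr), each = 4L), rep(nr + seq_len(max(nl, 0)),
                                                 length.out = nl)),
      resname = c(rep("ALA", 4L * nr), rep("OLE", nl)),
      group = c(rep("peptide", 4L * nr), rep("ligand", nl)),
      is_proton = c(rep(c(FALSE, FALSE, FALSE, TRUE), nr), rep(TRUE, nl)),
      stringsAsFactors = FALSE)
    traj <- trajectory(coords, top)
    attr(traj, "ground_truth") <- list(
      spec = spec, state = state, frame_state = frame_state,
      contact = contact, contact_residue = contact_res)
    traj
  })
}
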