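#' Generate a toy helical Calpha filament
#'
#' Places one residue per helical step at radius `radius`, axial rise `rise`
#' and twist `twist` degrees per residue about the z axis; the sign of the
#' twist sets the handedness (positive = right-handed). With
#' `with_backbone = TRUE`, ideal N and C' positions are attached to each
#' Calpha in the local helix frame (canonical bond lengths N-CA 1.46 A,
#' CA-C' 1.52 A) so that backbone phi/psi dihedrals are defined. The
#' attachment uses only the local tangent and inward normal, so a mirrored
#' spec (twist negated) yields an exact mirror-image structure.
#'
#' @param n_residues number of residues (>= 4).
#' @param rise axial rise per residue, Angstrom (> 0).
#' @param twist twist per residue, degrees in (-180, 180], sign = handedness.
#' @param radius helix radius, Angstrom (>= 0; 0 gives a straight line).
#' @param with_backbone also emit N and C' atoms per residue.
#' @param residue_name residue names recycled along the chain.
#' @return a `cg_structure`.
#' @export
make_filament <- function(n_residues, rise = 1.5, twist = 100,
                          radius = 2.3, with_backbone = FALSE,
                          residue_name = "ALA") {
  if (n_residues < 4L) stop("n_residues must be >= 4")
  if (rise <= 0) stop("rise must be > 0")
  if (radius < 0) stop("radius must be >= 0")
  if (twist <= -180 || twist > 180) stop("twist must be in (-180, 180]")
  i <- seq_len(n_residues) - 1L
  th <- i * twist * pi / 180
  ca <- cbind(radius * cos(th), radius * sin(th), i * rise)
  rname <- rep_len(residue_name, n_residues)
  if (!with_backbone) {
    return(cg_structure(ca, residue_id = seq_len(n_residues),
                        residue_name = rname))
  }
  # local frame per residue: chain tangent and inward normal (towards axis)
  tangent <- ca[pmin(i + 2L, n_residues), ] - ca[pmax(i, 1L), ]
  tangent <- tangent / sqrt(rowSums(tangent^2))
  normal <- cbind(-cos(th), -sin(th), 0)
  dN <- -0.80 * tangent + 0.60 * normal
  dC <-  0.80 * tangent + 0.60 * normal
  dN <- dN / sqrt(rowSums(dN^2)); dC <- dC / sqrt(rowSums(dC^2))
  coords <- matrix(NA_real_, 3L * n_residues, 3L)
  for (k in seq_len(n_residues)) {
    coords[3L * k - 2L, ] <- ca[k, ] + 1.46 * dN[k, ]
    coords[3L * k - 1L, ] <- ca[k, ]
    coords[3L * k, ]      <- ca[k, ] + 1.52 * dC[k, ]
  }
  cg_structure(coords,
               residue_id = rep(seq_len(n_residues), each = 3L),
               residue_name = rep(rname, each = 3L),
               atom_role = rep(c("N", "CA", "C"), n_residues))
}

#' Build a peptide backbone from internal coordinates
#'
#' Natural-extension-reference-frame (z-matrix style) chain growth with
#' canonical peptide geometry: bond lengths N-CA 1.46, CA-C' 1.52,
#' C'-N 1.33 Angstrom; bond angles N-CA-C' 111, CA-C'-N 117.2,
#' C'-N-CA 121.7 degrees; omega fixed at 180 (trans). Dihedrals are set
#' exactly, so programmed phi/psi values are recovered by
#' [phi_psi_series()] to machine precision.
#'
#' @param phi,psi per-residue dihedrals, degrees; `phi[1]` and `psi[n]` are
#'   ignored (undefined at chain termini). Scalars are recycled.
#' @param n_residues chain length; defaults to `max(length(phi), length(psi))`.
#' @param residue_name residue names recycled along the chain.
#' @return a `cg_structure` with N, CA, C atoms per residue.
#' @export
build_backbone <- function(phi, psi, n_residues = NULL,
                           residue_name = "ALA") {
  if (is.null(n_residues)) n_residues <- max(length(phi), length(psi))
  if (n_residues < 2L) stop("need at least 2 residues")
  phi <- rep_len(phi, n_residues); psi <- rep_len(psi, n_residues)
  bl <- c(N_CA = 1.46, CA_C = 1.52, C_N = 1.33)
  ba <- c(N_CA_C = 111, CA_C_N = 117.2, C_N_CA = 121.7)
  coords <- matrix(NA_real_, 3L * n_residues, 3L)
  # seed triad: N1, CA1, C1 in the xy-plane
  coords[1L, ] <- c(0, 0, 0)
  coords[2L, ] <- c(bl["N_CA"], 0, 0)
  th <- (180 - ba["N_CA_C"]) * pi / 180
  coords[3L, ] <- coords[2L, ] + bl["CA_C"] * c(cos(th), sin(th), 0)
  for (r in 2L:n_residues) {
    iN <- 3L * r - 2L; iCA <- 3L * r - 1L; iC <- 3L * r
    coords[iN, ] <- nerf_place(coords[iC - 5L, ], coords[iC - 4L, ],
                               coords[iC - 3L, ], bl["C_N"], ba["CA_C_N"],
                               psi[r - 1L])
    coords[iCA, ] <- nerf_place(coords[iC - 4L, ], coords[iC - 3L, ],
                                coords[iN, ], bl["N_CA"], ba["C_N_CA"], 180)
    coords[iC, ] <- nerf_place(coords[iC - 3L, ], coords[iN, ],
                               coords[iCA, ], bl["CA_C"], ba["N_CA_C"],
                               phi[r])
  }
  cg_structure(coords,
               residue_id = rep(seq_len(n_residues), each = 3L),
               residue_name = rep(rep_len(residue_name, n_residues),
                                  each = 3L),
               atom_role = rep(c("N", "CA", "C"), n_residues))
}

# place atom D given A-B-C, bond |CD|, angle B-C-D (deg), torsion A-B-C-D (deg)
nerf_place <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

#' Four toy filament conformations standing in for the RadA rotary cycle
#'
#' Generates four congruent-topology backbone structures emulating the
#' four-state cycle of RecA-family filaments: a left-handed helix, a
#' high-curvature ring-like conformation, an intermediate-twist state and a
#' right-handed helix. All four share atom count and residue ids; pairwise
#' fitted Calpha RMSDs exceed 1 Angstrom (checked at generation).
#'
#' @param n_residues residues per filament.
#' @param rise,twist,radius base helical parameters (see [make_filament()]);
#'   `twist` sets the magnitude used for the two handed states.
#' @param with_backbone emit N, CA, C per residue (default `TRUE`, required
#'   for dihedral analysis of simulated trajectories).
#' @return a named list of four `cg_structure`s: `left`, `ring`,
#'   `intermediate`, `right`.
#' @export
make_state_quartet <- function(n_residues = 20, rise = 1.5, twist = 100,
                               radius = 2.3, with_backbone = TRUE) {
  states <- list(
    left = make_filament(n_residues, rise, -abs(twist), radius,
                         with_backbone),
    ring = make_filament(n_residues, rise * 0.4, -abs(twist) * 0.25,
                         radius * 2.6, with_backbone),
    intermediate = make_filament(n_residues, rise * 1.2, abs(twist) * 0.5,
                                 radius * 1.5, with_backbone),
    right = make_filament(n_residues, rise, abs(twist), radius,
                          with_backbone)
  )
  for (i in 1:3) for (j in (i + 1):4) {
    d <- rmsd(states[[i]]$coords, states[[j]]$coords, fit = TRUE)
    if (d <= 1)
      stop("quartet states ", names(states)[i], "/", names(states)[j],
           " are not distinct (fitted RMSD ", round(d, 3), " A <= 1 A)")
  }
  states
}

#' Trajectory with programmed per-residue dihedral rotations
#'
#' Builds frames by internal-coordinate perturbation of a backbone: every
#' programmed (residue, phi/psi) dihedral advances linearly from its base
#' value to `base + winding * 360` degrees across the frames, all dihedrals
#' receive independent Gaussian jitter (`noise_sd` degrees, seeded), and
#' each frame is rebuilt with [build_backbone()]'s canonical geometry.
#' Because noise is applied in dihedral space, the ground-truth winding of
#' every series is exact: [ccda_table()] on the output recovers
#' `360 * |winding|` for each programmed entry and 0 elsewhere (for
#' `noise_sd` up to ~20 degrees).
#'
#' @param topology a backbone `cg_structure` (N, CA, C roles); its own
#'   phi/psi values are the base angles.
#' @param program data.frame with columns `residue_id`, `angle` ("phi" or
#'   "psi"), `winding` (integer, may be negative); may be empty.
#' @param n_frames number of frames (>= 2).
#' @param noise_sd angular jitter standard deviation, degrees.
#' @param seed RNG seed for the jitter.
#' @param dt_ns inter-frame time, ns.
#' @return a `cg_trajectory`.
#' @export
make_rotation_trajectory <- function(topology, program = NULL,
                                     n_frames = 144, noise_sd = 0,
                                     seed = 1, dt_ns = 0.01) {
  if (n_frames < 2L) stop("need at least 2 frames")
  if (is.null(program))
    program <- data.frame(residue_id = integer(0), angle = character(0),
                          winding = integer(0))
  rids <- unique(topology$residue_id)
  nres <- length(rids)
  if (nrow(program)) {
    if (!all(program$residue_id %in% rids))
      stop("program names residues absent from the topology")
    if (!all(program$angle %in% c("phi", "psi")))
      stop("program angle must be phi or psi")
    step <- max(abs(program$winding)) * 360 / (n_frames - 1L)
    if (step >= 150)
      stop("infeasible program: per-frame step ", round(step, 1),
           " deg leaves no unwinding headroom (need < 150 deg)")
    chain_pos <- match(program$residue_id, rids)
    if (any(chain_pos == 1L & program$angle == "phi") ||
        any(chain_pos == nres & program$angle == "psi"))
      stop("cannot program an undefined terminal dihedral")
  }
  base <- base_phi_psi(topology)
  noise_sd <- max(0, noise_sd)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  frac <- (seq_len(n_frames) - 1L) / (n_frames - 1L)
  frames <- array(NA_real_, dim = c(3L * nres, 3L, n_frames))
  for (f in seq_len(n_frames)) {
    phi <- base$phi; psi <- base$psi
    if (noise_sd > 0) {
      phi <- phi + stats::rnorm(nres, 0, noise_sd)
      psi <- psi + stats::rnorm(nres, 0, noise_sd)
    }
    if (nrow(program)) for (p in seq_len(nrow(program))) {
      k <- match(program$residue_id[p], rids)
      adv <- program$winding[p] * 360 * frac[f]
      if (program$angle[p] == "phi") phi[k] <- phi[k] + adv
      else psi[k] <- psi[k] + adv
    }
    frames[, , f] <- build_backbone(phi, psi, nres)$coords
  }
  cg_trajectory(topology, frames, times = (seq_len(n_frames) - 1L) * dt_ns)
}

# base phi/psi of a single backbone structure (undefined termini -> -57/-47)
base_phi_psi <- function(topology) {
  traj1 <- cg_trajectory(topology,
                         array(topology$coords,
                               dim = c(nrow(topology$coords), 3L, 2L)),
                         times = c(0, 1))
  ser <- phi_psi_series(traj1)
  rids <- unique(topology$residue_id)
  phi <- rep(-57, length(rids)); psi <- rep(-47, length(rids))
  for (s in ser) {
    if (!s$defined) next
    k <- match(s$residue_id, rids)
    if (s$angle == "phi") phi[k] <- s$raw[1L] else psi[k] <- s$raw[1L]
  }
  list(phi = phi, psi = psi)
}
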