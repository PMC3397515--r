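#' Build an elastic-network model from a reference structure
#'
#' Harmonic springs between every atom pair within `cutoff` in the reference
#' conformation, with rest lengths equal to the reference distances. This is
#' the coarse-grained stand-in force field the targeted-MD engine runs on.
#'
#' @param ref reference `cg_structure` (all its atoms become beads).
#' @param cutoff pair cutoff, Angstrom.
#' @param k_spring spring constant, kcal/mol/A^2.
#' @return list of class `elastic_network` with `pairs` (m x 2, i < j),
#'   `rest_lengths` (Angstrom), `k_spring`, `cutoff`, `n_atoms`.
#' @export
build_elastic_network <- function(ref, cutoff = 10, k_spring = 1) {
  x <- ref$coords
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  if (cutoff <= min(d[upper.tri(d)]))
    stop("cutoff must exceed the smallest inter-bead distance")
  sel <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  pairs <- sel[order(sel[, 1L], sel[, 2L]), , drop = FALSE]
  colnames(pairs) <- c("i", "j")
  lonely <- setdiff(seq_len(n), unique(as.vector(pairs)))
  if (length(lonely))
    warning("elastic network disconnected: atoms with no springs: ",
            paste(lonely, collapse = ", "))
  out <- list(pairs = pairs, rest_lengths = d[pairs],
              k_spring = k_spring, cutoff = cutoff, n_atoms = n)
  class(out) <- "elastic_network"
  out
}

#' Elastic-network energy and forces
#'
#' @param coords `n x 3` coordinate matrix.
#' @param network an `elastic_network`.
#' @param rest_lengths optional override of the network rest lengths (used
#'   by the blended-basin cycle driver).
#' @return list with `energy` (kcal/mol) and `forces` (`n x 3`,
#'   kcal/mol/Angstrom).
#' @export
enm_energy_forces <- function(coords, network, rest_lengths = NULL) {
  i <- network$pairs[, 1L]; j <- network$pairs[, 2L]
  r0 <- if (is.null(rest_lengths)) network$rest_lengths else rest_lengths
  dx <- coords[i, , drop = FALSE] - coords[j, , drop = FALSE]
  d <- sqrt(rowSums(dx^2))
  dev <- d - r0
  energy <- 0.5 * network$k_spring * sum(dev^2)
  fmag <- -network$k_spring * dev / d          # along dx, on atom i
  fij <- dx * fmag
  forces <- matrix(0, nrow(coords), 3L)
  for (c in 1:3) {
    forces[, c] <- tapply_add(fij[, c], i, nrow(coords)) -
      tapply_add(fij[, c], j, nrow(coords))
  }
  list(energy = energy, forces = forces)
}

tapply_add <- function(v, idx, n) {
  out <- numeric(n)
  s <- rowsum(v, idx)
  out[as.integer(rownames(s))] <- s
  out
}

#' Harmonic targeted-MD restraint
#'
#' Encodes the biasing potential
#' `U = K / (2 N) * (RMSD(t) - RMSD0(t))^2`, where `RMSD(t)` is the best-fit
#' RMSD of the current coordinates to the target over the selection, `N` the
#' number of selected target atoms, and `RMSD0(t)` the prescribed target
#' RMSD at time `t`. This is the per-atom-normalized (NAMD-style) convention:
#' with K = 200 kcal/mol/A^2, N = 100 and a 1 Angstrom offset the restraint
#' energy is 1.0 kcal/mol.
#'
#' @param target target `cg_structure`.
#' @param K force constant, kcal/mol/A^2 (default 200).
#' @param selection backbone roles restrained (default `"CA"`).
#' @param schedule function of time (ns) returning RMSD0 in Angstrom; must
#'   be defined over the leg duration.
#' @param duration schedule domain length, ns.
#' @return a list of class `tmd_restraint`.
#' @export
tmd_restraint <- function(target, K = 200, selection = "CA",
                          schedule = NULL, duration = Inf) {
  stopifnot(inherits(target, "cg_structure"))
  if (K <= 0) stop("K must be positive")
  n_sel <- length(role_selection(target, selection))
  if (n_sel < 3L) stop("restraint needs at least 3 selected atoms")
  if (is.null(schedule)) schedule <- function(t) 0
  out <- list(target = target, K = K, selection = selection, N = n_sel,
              schedule = schedule, duration = duration)
  class(out) <- "tmd_restraint"
  out
}

#' Linearly decreasing target-RMSD schedule
#'
#' `RMSD0(t) = initial_rmsd * (1 - t / duration)`, clamped at zero — the
#' standard continuously-decreasing prescription that drags the system onto
#' the target over the course of a leg.
#'
#' @param initial_rmsd starting RMSD0, Angstrom (>= 0).
#' @param duration leg duration, ns (> 0).
#' @return function of time (ns).
#' @export
rmsd0_linear_schedule <- function(initial_rmsd, duration) {
  if (initial_rmsd < 0) stop("initial_rmsd must be >= 0")
  if (duration <= 0) stop("duration must be > 0")
  function(t) pmax(0, initial_rmsd * (1 - t / duration))
}

#' Targeted-MD restraint energy and forces
#'
#' @param coords `n x 3` coordinates of the full system.
#' @param restraint a `tmd_restraint`.
#' @param t time within the leg, ns.
#' @param sel_idx indices of `coords` rows entering the RMSD (defaults to
#'   the restraint selection applied to the target topology, which must be
#'   congruent with the system).
#' @return list with `energy` (kcal/mol), `forces` (`n x 3`), `rmsd`,
#'   `rmsd0` (Angstrom).
#' @export
tmd_energy_forces <- function(coords, restraint, t = 0, sel_idx = NULL) {
  if (!is.finite(t) || t < 0 || t > restraint$duration)
    stop("time ", t, " outside the restraint schedule domain [0, ",
         restraint$duration, "]")
  if (is.null(sel_idx))
    sel_idx <- role_selection(restraint$target, restraint$selection)
  g <- rmsd_gradient(coords, restraint$target, sel_idx,
                     target_sel = restraint$selection)
  rmsd0 <- restraint$schedule(t)
  dev <- g$rmsd - rmsd0
  energy <- restraint$K / (2 * restraint$N) * dev^2
  forces <- -(restraint$K / restraint$N) * dev * g$gradient
  list(energy = energy, forces = forces, rmsd = g$rmsd, rmsd0 = rmsd0)
}

# kcal/mol -> amu A^2 / ps^2
.KCAL <- 418.4
.KB <- 0.0019872041  # kcal/mol/K

#' Run one targeted-MD leg
#'
#' Langevin dynamics (velocity Verlet with the BAOAB splitting) on the
#' elastic-network potential plus the TMD restraint, at Calpha/backbone-bead
#' resolution with uniform 110 Da beads. Deterministic for a fixed seed.
#'
#' @param start starting `cg_structure` (topology of the whole run).
#' @param network an `elastic_network` over the same atoms.
#' @param restraint a `tmd_restraint` with a schedule covering the leg.
#' @param steps number of integration steps.
#' @param dt_fs time step, femtoseconds (default 10).
#' @param friction Langevin friction, 1/ps (default 1).
#' @param temperature thermostat temperature, K (default 310).
#' @param mass bead mass, Da.
#' @param output_stride record every this many steps (frame 0 always
#'   recorded).
#' @param seed RNG seed.
#' @param rest_lengths_end optional rest-length vector toward which the
#'   network rest lengths are linearly blended over the leg (dual-basin
#'   morphing network); `NULL` keeps the network static.
#' @param blend_frac fraction of the leg over which the rest-length blend
#'   completes (the remainder runs on the final network).
#' @param t_offset time origin of this leg in the parent run, ns (only
#'   shifts the reported times).
#' @return list with `trajectory` (a `cg_trajectory`), `energy` (data.frame
#'   `time_ns`, `potential`, `restraint`, `rmsd_to_target`, `rmsd0`), and
#'   `final` (final coordinates).
#' @export
run_tmd_leg <- function(start, network, restraint, steps, dt_fs = 10,
                        friction = 1, temperature = 310, mass = 110,
                        output_stride = 10, seed = 1,
                        rest_lengths_end = NULL, blend_frac = 1,
                        t_offset = 0) {
  x <- start$coords
  n <- nrow(x)
  stopifnot(network$n_atoms == n)
  sel_idx <- role_selection(start, restraint$selection)
  if (length(sel_idx) != restraint$N)
    stop("system selection does not match restraint target selection")
  dt <- dt_fs * 1e-3                      # ps
  if (dt * network$k_spring * .KCAL / mass > 2)
    stop("dt too large for this spring stiffness")
  kT <- .KB * max(temperature, 0) * .KCAL # amu A^2/ps^2
  c1 <- exp(-friction * dt)
  c2 <- sqrt(kT / mass * (1 - c1^2))
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))

  leg_ns <- steps * dt_fs * 1e-6
  blend <- !is.null(rest_lengths_end)
  morph <- blend && is.matrix(rest_lengths_end)   # n x 3 end coordinates:
  # rest lengths follow the pair distances of the Cartesian interpolation
  # between the start structure and the superposed end structure, a path of
  # realizable shapes along which the handedness changes near the achiral
  # midpoint instead of jumping between strained chiral geometries.
  ip <- network$pairs[, 1L]; jp <- network$pairs[, 2L]
  rl <- function(frac) {
    if (!blend) return(NULL)
    frac <- min(frac / blend_frac, 1)
    if (!morph)
      return((1 - frac) * network$rest_lengths + frac * rest_lengths_end)
    xt <- (1 - frac) * start$coords + frac * rest_lengths_end
    sqrt(rowSums((xt[ip, , drop = FALSE] - xt[jp, , drop = FALSE])^2))
  }
  v <- matrix(0, n, 3L)
  force_at <- function(x, t_ns, frac) {
    e <- enm_energy_forces(x, network, rest_lengths = rl(frac))
    u <- tmd_energy_forces(x, restraint, t_ns, sel_idx)
    list(f = e$forces + u$forces, pot = e$energy, res = u$energy,
         rmsd = u$rmsd, rmsd0 = u$rmsd0)
  }
  fr <- force_at(x, 0, 0)
  rec_idx <- unique(c(0L, seq_len(steps)[seq_len(steps) %% output_stride == 0]))
  nrec <- length(rec_idx)
  frames <- array(NA_real_, dim = c(n, 3L, nrec))
  en <- data.frame(time_ns = numeric(nrec), potential = numeric(nrec),
                   restraint = numeric(nrec), rmsd_to_target = numeric(nrec),
                   rmsd0 = numeric(nrec))
  rec <- function(slot, step, fr, x) {
    frames[, , slot] <<- x
    en[slot, ] <<- c(t_offset + step * dt_fs * 1e-6, fr$pot, fr$res,
                     fr$rmsd, fr$rmsd0)
  }
  rec(1L, 0L, fr, x)
  slot <- 1L
  acc_scale <- .KCAL / mass               # kcal/mol/A -> A/ps^2 per amu
  for (s in seq_len(steps)) {
    v <- v + 0.5 * dt * fr$f * acc_scale
    x <- x + 0.5 * dt * v
    v <- c1 * v + c2 * matrix(stats::rnorm(3L * n), n, 3L)
    x <- x + 0.5 * dt * v
    t_ns <- min(s * dt_fs * 1e-6, leg_ns)
    fr <- force_at(x, t_ns, s / steps)
    if (!all(is.finite(x)) || !is.finite(fr$pot) || max(abs(x)) > 1e6)
      stop("numerical blow-up at step ", s, " (frame ", slot, ")")
    v <- v + 0.5 * dt * fr$f * acc_scale
    if (s %% output_stride == 0) {
      slot <- slot + 1L
      rec(slot, s, fr, x)
    }
  }
  traj <- cg_trajectory(start, frames,
                        times = t_offset + rec_idx * dt_fs * 1e-6)
  final <- cg_structure(x, start$residue_id, start$residue_name,
                        start$atom_role)
  list(trajectory = traj, energy = en, final = final)
}

#' Drive a four-state conformational cycle by targeted MD
#'
#' Runs four consecutive TMD legs state1 -> state2 -> state3 -> state4 ->
#' state1 (the rotary cycle: left-handed, ring-like, intermediate,
#' right-handed, back to left-handed). Each leg's target-RMSD schedule
#' restarts linearly from the current fitted RMSD to the leg target and
#' decreases to zero over the leg. The elastic network is built on the
#' initial state; with `network_mode = "blend"` (default) its rest lengths
#' are morphed linearly toward each leg target's distances, a dual-basin
#' choice that lets the toy filament actually reach each state.
#'
#' The potential-energy profile is zero-referenced to the initial state's
#' network energy, so its first value is exactly 0.
#'
#' @param states list of four congruent-topology `cg_structure`s.
#' @param K restraint force constant, kcal/mol/A^2.
#' @param selection restrained backbone roles.
#' @param cutoff,k_spring elastic-network parameters.
#' @param steps_per_leg integration steps per leg.
#' @param dt_fs,friction,temperature,mass,output_stride integrator
#'   parameters, see [run_tmd_leg()].
#' @param seed RNG seed; each leg uses a sub-seed derived from it.
#' @param network_mode `"blend"` (rest lengths morph toward the leg target)
#'   or `"static"` (initial-state network throughout).
#' @param settle_frac fraction of each leg over which RMSD0 decreases to
#'   zero (and the network blend completes); the remainder of the leg
#'   anneals the structure in the target basin with RMSD0 = 0.
#' @return list with `trajectory` (concatenated `cg_trajectory`), `energy`
#'   (zero-referenced data.frame with a `leg` column), `legs` (per-leg
#'   summary data.frame: start/end/max potential, barrier height, final
#'   fitted RMSD to the leg target), and `final` (`cg_structure`).
#' @export
run_cycle <- function(states, K = 200, selection = "CA", cutoff = 10,
                      k_spring = 3, steps_per_leg = 6000, dt_fs = 10,
                      friction = 1, temperature = 310, mass = 110,
                      output_stride = 20, seed = 1,
                      network_mode = c("blend", "static"),
                      settle_frac = 0.7) {
  network_mode <- match.arg(network_mode)
  if (settle_frac <= 0 || settle_frac > 1)
    stop("settle_frac must be in (0, 1]")
  if (length(states) != 4L) stop("need exactly four states")
  n <- nrow(states[[1L]]$coords)
  for (s in states) {
    if (nrow(s$coords) != n ||
        !identical(s$residue_id, states[[1L]]$residue_id) ||
        !identical(s$atom_role, states[[1L]]$atom_role))
      stop("states must share one topology")
  }
  state_names <- names(states)
  if (is.null(state_names)) state_names <- paste0("state", 1:4)
  network <- build_elastic_network(states[[1L]], cutoff, k_spring)
  e0 <- enm_energy_forces(states[[1L]]$coords, network)$energy
  current <- states[[1L]]
  targets <- c(states[-1L], states[1L])
  leg_ns <- steps_per_leg * dt_fs * 1e-6
  all_frames <- list(); all_times <- list(); all_energy <- list()
  leg_sum <- data.frame()
  t_offset <- 0
  for (leg in 1:4) {
    target <- targets[[leg]]
    r_init <- rmsd(current, target, fit = TRUE, selection = selection)
    restr <- tmd_restraint(target, K, selection,
                           rmsd0_linear_schedule(r_init,
                                                 leg_ns * settle_frac),
                           duration = leg_ns)
    rl_end <- if (network_mode == "blend") {
      # superpose the target onto the current structure, then morph the
      # rest lengths along the Cartesian interpolation between the two
      apply_superposition(superpose(target, current, selection),
                          target$coords)
    } else NULL
    res <- run_tmd_leg(current, network, restr, steps_per_leg, dt_fs,
                       friction, temperature, mass, output_stride,
                       seed = seed * 10L + leg,
                       rest_lengths_end = rl_end, blend_frac = settle_frac,
                       t_offset = t_offset)
    if (network_mode == "blend")
      network$rest_lengths <-
        sqrt(rowSums((rl_end[network$pairs[, 1L], , drop = FALSE] -
                      rl_end[network$pairs[, 2L], , drop = FALSE])^2))
    en <- res$energy
    en$leg <- leg
    keep <- if (leg == 1L) seq_len(nrow(en)) else -1L  # drop duplicate joins
    all_energy[[leg]] <- en[keep, , drop = FALSE]
    nf <- n_frames(res$trajectory)
    fkeep <- if (leg == 1L) seq_len(nf) else 2:nf
    all_frames[[leg]] <- res$trajectory$frames[, , fkeep, drop = FALSE]
    all_times[[leg]] <- res$trajectory$times[fkeep]
    pot <- en$potential - e0
    leg_sum <- rbind(leg_sum, data.frame(
      leg = leg, target = state_names[c(2:4, 1L)][leg],
      start_potential = pot[1L], end_potential = pot[length(pot)],
      max_potential = max(pot), barrier_height = max(pot) - pot[1L],
      initial_rmsd = r_init,
      final_rmsd_to_target = en$rmsd_to_target[nrow(en)]))
    current <- res$final
    t_offset <- t_offset + leg_ns
  }
  energy <- do.call(rbind, all_energy)
  energy$potential <- energy$potential - e0
  energy$potential[1L] <- 0   # exact zero reference at t = 0
  frames <- array(unlist(all_frames),
                  dim = c(n, 3L, length(unlist(all_times))))
  traj <- cg_trajectory(states[[1L]], frames, unlist(all_times))
  list(trajectory = traj, energy = energy, legs = leg_sum, final = current,
       network = network, closure_rmsd = rmsd(current, states[[1L]],
                                              fit = TRUE,
                                              selection = selection))
}
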