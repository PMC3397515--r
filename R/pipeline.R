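#' Fitted RMSD profiles of a trajectory against reference conformations
#'
#' Best-fit RMSD of every frame to each reference, the standard way of
#' tracing which state of the cycle a TMD trajectory is visiting.
#'
#' @param traj a `cg_trajectory`.
#' @param references named list of congruent `cg_structure`s.
#' @param selection backbone roles used for the fit.
#' @return data.frame with `time_ns` and one RMSD column (Angstrom) per
#'   reference.
#' @export
rmsd_profiles <- function(traj, references, selection = "CA") {
  sel <- role_selection(traj$topology, selection)
  out <- data.frame(time_ns = traj$times)
  for (nm in names(references)) {
    ref <- references[[nm]]
    refc <- ref$coords[role_selection(ref, selection), , drop = FALSE]
    if (nrow(refc) != length(sel))
      stop("reference ", nm, " selection is not congruent with trajectory")
    out[[nm]] <- vapply(seq_len(n_frames(traj)), function(f) {
      superpose(traj$frames[sel, , f], refc)$rmsd
    }, numeric(1))
  }
  out
}

#' Per-leg energy-barrier summary
#'
#' For each leg of the cycle, reports the potential at the leg start and
#' end, the maximum along the leg, and the barrier height (maximum minus
#' start); the leg holding the global maximum is flagged.
#'
#' @param energy data.frame with `time_ns`, `potential` and a `leg` column
#'   (as produced by [run_cycle()]), or no `leg` column if `boundaries` is
#'   given.
#' @param boundaries optional numeric times (ns) splitting the profile into
#'   legs, used when `energy` has no `leg` column.
#' @return data.frame with one row per leg: `leg`, `start`, `end`, `max`,
#'   `barrier_height`, `global_max` (logical).
#' @export
barrier_summary <- function(energy, boundaries = NULL) {
  if (is.null(energy$leg)) {
    if (is.null(boundaries)) stop("need a leg column or boundaries")
    energy$leg <- findInterval(energy$time_ns, boundaries,
                               rightmost.closed = FALSE) + 1L
  }
  legs <- sort(unique(energy$leg))
  out <- do.call(rbind, lapply(legs, function(l) {
    p <- energy$potential[energy$leg == l]
    if (!length(p)) stop("empty leg segment ", l)
    data.frame(leg = l, start = p[1L], end = p[length(p)], max = max(p),
               barrier_height = max(p) - p[1L])
  }))
  out$global_max <- out$max == max(out$max)
  if (sum(out$global_max) > 1L) {       # flag the first in case of ties
    first <- which(out$global_max)[1L]
    out$global_max <- seq_len(nrow(out)) == first
  }
  out
}

#' Pairwise percent identity by global alignment
#'
#' Needleman-Wunsch global alignment with match +1, mismatch 0 and linear
#' gap penalty -1 (via Biostrings), reporting
#' `matches / alignment length * 100`. Identical sequences give exactly
#' 100; this is the degenerate case relating the right- and left-handed
#' RadA crystal forms, which share one protein sequence.
#'
#' @param seq_a,seq_b amino-acid strings (20-letter alphabet, X tolerated).
#' @param match,mismatch,gap scoring parameters.
#' @return percent identity in `[0, 100]`.
#' @export
percent_identity <- function(seq_a, seq_b, match = 1, mismatch = 0,
                             gap = -1) {
  seq_a <- toupper(gsub("\\s", "", as.character(seq_a)))
  seq_b <- toupper(gsub("\\s", "", as.character(seq_b)))
  if (nchar(seq_a) == 0L || nchar(seq_b) == 0L)
    stop("sequences must be non-empty")
  ab <- unique(strsplit(paste0(seq_a, seq_b, "X"), "")[[1L]])
  if (!all(ab %in% strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1L]]))
    stop("sequences must use the amino-acid alphabet (X tolerated)")
  m <- matrix(mismatch, length(ab), length(ab), dimnames = list(ab, ab))
  diag(m) <- match
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = m, gapOpening = 0, gapExtension = -gap,
    type = "global")
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  100 * sum(pa == sa & pa != "-") / length(pa)
}

#' Read amino-acid sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Run the full filament-cycle analysis
#'
#' End-to-end driver: generate the four-state toy filament quartet, run the
#' four-leg TMD cycle, and write every analysis product under `out_dir`:
#' the state structures and trajectory (PDB), the zero-referenced energy
#' profile and barrier summary, fitted RMSD profiles against all four
#' references, the per-residue CCDA table over the linker region, the
#' rotary/zero-rotary classification, and a MANIFEST recording parameters,
#' seed and completed stages. Identical config and seed give byte-identical
#' tables.
#'
#' @param config list of parameters; see `default_config()` for the
#'   complete set and defaults. Any subset may be overridden.
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with the in-memory results (`states`, `cycle`,
#'   `rmsd_profiles`, `barriers`, `ccda`, `classification`).
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("radmotor_")) {
  cfg <- utils::modifyList(default_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- c(sprintf("radmotor %s",
                        as.character(utils::packageVersion("radmotor"))),
                sprintf("seed\t%d", cfg$seed),
                sprintf("%s\t%s", names(cfg),
                        vapply(cfg, function(v)
                          paste(format(v), collapse = ","), "")))
  done <- character(0)
  finish <- function() {
    writeLines(c(manifest, "completed_stages",
                 paste0("  ", done)), file.path(out_dir, "MANIFEST"))
  }
  on.exit(finish())

  states <- make_state_quartet(cfg$n_residues, cfg$rise, cfg$twist,
                               cfg$radius, with_backbone = TRUE)
  for (nm in names(states))
    write_pdb(states[[nm]], file.path(out_dir, paste0("state_", nm, ".pdb")))
  done <- c(done, "states")

  if (cfg$steps_per_leg > 0) {
    cyc <- run_cycle(states, K = cfg$K, cutoff = cfg$cutoff,
                     k_spring = cfg$k_spring,
                     steps_per_leg = cfg$steps_per_leg, dt_fs = cfg$dt_fs,
                     friction = cfg$friction, temperature = cfg$temperature,
                     output_stride = cfg$output_stride, seed = cfg$seed,
                     network_mode = cfg$network_mode,
                     settle_frac = cfg$settle_frac)
    traj <- cyc$trajectory
    energy <- cyc$energy
  } else {                 # rigid replay: no dynamics, frozen start state
    frames <- array(states[[1L]]$coords,
                    dim = c(nrow(states[[1L]]$coords), 3L, 2L))
    traj <- cg_trajectory(states[[1L]], frames, times = c(0, cfg$dt_fs * 1e-6))
    energy <- data.frame(time_ns = traj$times, potential = c(0, 0),
                         restraint = c(0, 0), rmsd_to_target = c(0, 0),
                         rmsd0 = c(0, 0), leg = c(1L, 1L))
    cyc <- list(trajectory = traj, energy = energy,
                legs = data.frame(), closure_rmsd = 0)
  }
  write_pdb(traj, file.path(out_dir, "trajectory.pdb"))
  write_tsv(energy, file.path(out_dir, "energy_profile.tsv"))
  done <- c(done, "tmd_cycle")

  barriers <- barrier_summary(energy)
  write_tsv(barriers, file.path(out_dir, "barrier_summary.tsv"))
  profs <- rmsd_profiles(traj, states)
  write_tsv(profs, file.path(out_dir, "rmsd_profiles.tsv"))
  done <- c(done, "profiles")

  region <- cfg$linker_region
  if (is.null(region))
    region <- unique(traj$topology$residue_id)
  tab <- ccda_table(traj, region = region)
  write_tsv(tab, file.path(out_dir, "ccda_table.tsv"))
  cls <- classify_rotary(tab, skip_undefined = TRUE)
  jsonlite::write_json(cls, file.path(out_dir, "classification.json"),
                       auto_unbox = FALSE, pretty = TRUE)
  done <- c(done, "ccda")

  invisible(list(states = states, cycle = cyc, rmsd_profiles = profs,
                 barriers = barriers, ccda = tab, classification = cls,
                 out_dir = out_dir))
}

#' @rdname run_pipeline
#' @export
default_config <- function() {
  list(n_residues = 20, rise = 1.5, twist = 100, radius = 2.3,
       K = 200, cutoff = 10, k_spring = 3,
       steps_per_leg = 6000, dt_fs = 10, friction = 1, temperature = 310,
       output_stride = 20, seed = 1, network_mode = "blend",
       settle_frac = 0.7, linker_region = NULL)
}

write_tsv <- function(df, path) {
  df <- as.data.frame(lapply(df, function(c)
    if (is.numeric(c)) signif(c, 10) else c))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
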