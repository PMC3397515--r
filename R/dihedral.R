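#' Signed dihedral (torsion) angle of four points
#'
#' IUPAC sign convention: looking down the p2-p3 bond, a clockwise rotation
#' of the far bond relative to the near bond is positive. Result in degrees
#' in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric 3-vectors, Angstrom.
#' @return angle in degrees in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  if (sqrt(sum(n1^2)) < 1e-9 || sqrt(sum(n2^2)) < 1e-9 || nb2 < 1e-12)
    stop("undefined dihedral: three consecutive points are collinear")
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2) / nb2
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

wrap180 <- function(x) {
  # map into (-180, 180]
  y <- x - 360 * floor(x / 360)   # [0, 360)
  ifelse(y > 180, y - 360, y)
}

#' Backbone phi/psi time series of a trajectory
#'
#' For each residue, phi is the torsion C'(i-1)-N(i)-CA(i)-C'(i) and psi the
#' torsion N(i)-CA(i)-C'(i)-N(i+1); phi of the first and psi of the last
#' residue of a chain are undefined and reported as `NA` series, never
#' zero-filled. Raw angles are in degrees in (-180, 180].
#'
#' @param traj a `cg_trajectory` whose topology has N, CA and C roles.
#' @param topology optional `cg_structure` overriding `traj$topology`.
#' @return a list of dihedral series; each element is a list with
#'   `residue_id`, `residue_name`, `angle` (`"phi"` or `"psi"`), `raw`
#'   (per-frame degrees) and `defined` (logical).
#' @export
phi_psi_series <- function(traj, topology = NULL) {
  topo <- if (is.null(topology)) traj$topology else topology
  rids <- unique(topo$residue_id)
  idx_of <- function(rid, role) {
    i <- which(topo$residue_id == rid & topo$atom_role == role)
    if (length(i) == 1L) i else NA_integer_
  }
  nf <- n_frames(traj)
  series <- list()
  for (k in seq_along(rids)) {
    rid <- rids[k]
    rname <- topo$residue_name[which(topo$residue_id == rid)[1L]]
    iN <- idx_of(rid, "N"); iCA <- idx_of(rid, "CA"); iC <- idx_of(rid, "C")
    iCprev <- if (k > 1L) idx_of(rids[k - 1L], "C") else NA_integer_
    iNnext <- if (k < length(rids)) idx_of(rids[k + 1L], "N") else NA_integer_
    for (angle in c("phi", "psi")) {
      quad <- if (angle == "phi") c(iCprev, iN, iCA, iC)
              else c(iN, iCA, iC, iNnext)
      s <- list(residue_id = rid, residue_name = rname, angle = angle,
                raw = rep(NA_real_, nf), defined = FALSE)
      if (!anyNA(quad)) {
        s$raw <- vapply(seq_len(nf), function(f) {
          fc <- traj$frames[, , f]
          dihedral_angle(fc[quad[1L], ], fc[quad[2L], ],
                         fc[quad[3L], ], fc[quad[4L], ])
        }, numeric(1))
        s$defined <- TRUE
      }
      series[[length(series) + 1L]] <- s
    }
  }
  series
}

#' Unwind a wrapped angular series into a continuous one
#'
#' Each per-frame difference is mapped into (-180, 180] and cumulatively
#' summed from the first raw value, removing the 360-degree wraps. Valid as
#' long as true per-frame angular steps stay below 180 degrees.
#'
#' @param raw numeric vector of wrapped angles, degrees, or a series list
#'   from [phi_psi_series()].
#' @return the unwound series (numeric vector), or the input series list
#'   with `unwound` and `winding` filled in.
#' @export
unwind <- function(raw) {
  if (is.list(raw)) {
    s <- raw
    if (!isTRUE(s$defined)) { s$unwound <- s$raw; s$winding <- NA_real_;
                              return(s) }
    s$unwound <- unwind(s$raw)
    s$winding <- (s$unwound[length(s$unwound)] - s$unwound[1L]) / 360
    return(s)
  }
  if (length(raw) < 2L) stop("unwinding needs at least 2 frames")
  steps <- wrap180(diff(raw))
  cumsum(c(raw[1L], steps))
}

#' Cumulative changed dihedral angle (CCDA) of one series
#'
#' The net number of full 360-degree rotations completed by the unwound
#' angle over the trajectory, reported in degrees:
#' `360 * |round((unwound_last - unwound_first) / 360)|`. Every value is a
#' non-negative multiple of 360; excursions that never complete a full turn
#' report 0.
#'
#' @param series a series list (from [phi_psi_series()], unwound or not) or
#'   a raw numeric angle vector.
#' @return CCDA in degrees, or `NA` for an undefined dihedral.
#' @export
ccda <- function(series) {
  if (is.numeric(series)) series <- list(raw = series, defined = TRUE)
  if (!isTRUE(series$defined)) return(NA_real_)
  if (is.null(series$unwound)) series <- unwind(series)
  u <- series$unwound
  360 * abs(round((u[length(u)] - u[1L]) / 360))
}

#' Per-residue CCDA table over a residue region
#'
#' @param traj a `cg_trajectory` with backbone topology.
#' @param region integer vector (range) of residue ids to analyse; defaults
#'   to all residues.
#' @param topology optional override of `traj$topology`.
#' @return a data.frame with columns `residue_id`, `residue_name`,
#'   `ccda_phi`, `ccda_psi` (degrees; `NA` marks an undefined dihedral at a
#'   chain terminus or missing backbone atom).
#' @export
ccda_table <- function(traj, region = NULL, topology = NULL) {
  topo <- if (is.null(topology)) traj$topology else topology
  rids <- unique(topo$residue_id)
  if (is.null(region)) region <- rids
  region <- intersect(rids, region)
  if (length(region) == 0L) stop("empty residue region")
  series <- phi_psi_series(traj, topo)
  tab <- data.frame(residue_id = region,
                    residue_name = NA_character_,
                    ccda_phi = NA_real_, ccda_psi = NA_real_)
  for (s in series) {
    i <- match(s$residue_id, region)
    if (is.na(i)) next
    tab$residue_name[i] <- s$residue_name
    v <- ccda(s)
    if (s$angle == "phi") tab$ccda_phi[i] <- v else tab$ccda_psi[i] <- v
  }
  tab
}

#' Classify residues as rotary or zero-rotary from a CCDA table
#'
#' A residue is zero-rotary when both its phi and psi CCDA are exactly zero
#' (winding numbers are integers by construction, so the threshold is exact
#' zero, not a degree tolerance); every other residue in the region is
#' rotary. Undefined entries are an error unless `skip_undefined = TRUE`, in
#' which case those residues are reported separately.
#'
#' @param table a data.frame with `residue_id`, `ccda_phi`, `ccda_psi` (and
#'   optionally `residue_name`), as from [ccda_table()].
#' @param skip_undefined skip residues with undefined (NA) entries instead
#'   of failing.
#' @return list with `rotary`, `zero_rotary`, `undefined` (residue-id
#'   vectors) and `region`.
#' @export
classify_rotary <- function(table, skip_undefined = FALSE) {
  undef <- table$residue_id[is.na(table$ccda_phi) | is.na(table$ccda_psi)]
  if (length(undef) && !skip_undefined)
    stop("undefined CCDA entries for residues: ",
         paste(undef, collapse = ", "),
         " (use skip_undefined = TRUE to drop them)")
  ok <- !(table$residue_id %in% undef)
  zero <- table$residue_id[ok & table$ccda_phi == 0 & table$ccda_psi == 0]
  rot <- setdiff(table$residue_id[ok], zero)
  list(rotary = rot, zero_rotary = zero, undefined = undef,
       region = table$residue_id)
}

#' Published reference CCDA values for the RadA linker region
#'
#' Per-residue phi/psi CCDA values (degrees) for the linker region I71-K88
#' of the Sulfolobus solfataricus RadA filament, as reported from 40 ns
#' targeted-MD simulations of the four-state rotary cycle. Used as a
#' reference pattern for validating the CCDA recovery machinery.
#'
#' @return data.frame with `residue_id`, `residue_name`, `ccda_phi`,
#'   `ccda_psi`.
#' @export
rada_linker_ccda <- function() {
  path <- system.file("extdata", "rada_linker_ccda.tsv",
                      package = "radmotor", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
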