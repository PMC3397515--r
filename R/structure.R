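#' Coarse-grained structures and trajectories
#'
#' A `cg_structure` holds named backbone coordinates for one filament
#' conformation: per-atom residue ids (1-based, PDB convention), 3-letter
#' residue names, backbone atom roles (`"N"`, `"CA"`, `"C"`), and an
#' `n_atoms x 3` coordinate matrix in Angstrom. A `cg_trajectory` holds an
#' ordered stack of frames sharing one `cg_structure` topology, with frame
#' times in nanoseconds.
#'
#' @param coords numeric matrix, `n_atoms x 3`, Angstrom.
#' @param residue_id integer vector, one entry per atom; non-decreasing, with
#'   residue blocks strictly increasing.
#' @param residue_name character vector of residue names, one per atom.
#' @param atom_role character vector, one of `"N"`, `"CA"`, `"C"` per atom.
#' @return An object of class `cg_structure`.
#' @export
cg_structure <- function(coords, residue_id, residue_name = NULL,
                         atom_role = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L)
    stop("coords must be an n x 3 matrix")
  n <- nrow(coords)
  if (!all(is.finite(coords)))
    stop("coords must be finite; non-finite value at atom ",
         which(!apply(is.finite(coords), 1L, all))[1L])
  residue_id <- as.integer(residue_id)
  if (length(residue_id) != n)
    stop("residue_id length must match atom count")
  if (is.null(atom_role)) atom_role <- rep("CA", n)
  if (is.null(residue_name)) residue_name <- rep("ALA", n)
  if (length(atom_role) != n || length(residue_name) != n)
    stop("atom_role and residue_name must have one entry per atom")
  if (!all(atom_role %in% c("N", "CA", "C")))
    stop("atom_role entries must be one of N, CA, C")
  # residue blocks must appear in strictly increasing id order
  rid_rle <- rle(residue_id)$values
  if (any(diff(rid_rle) <= 0))
    stop("residue ids must be strictly increasing along the chain")
  # within a residue carrying backbone roles, atoms come in N, CA, C order
  for (r in rid_rle) {
    roles <- atom_role[residue_id == r]
    if (length(roles) > 1L) {
      want <- c("N", "CA", "C")[c("N", "CA", "C") %in% roles]
      if (!identical(roles, want))
        stop("atoms of residue ", r, " must be ordered N, CA, C")
    }
  }
  out <- list(coords = coords, residue_id = residue_id,
              residue_name = as.character(residue_name),
              atom_role = as.character(atom_role))
  class(out) <- "cg_structure"
  out
}

#' @export
print.cg_structure <- function(x, ...) {
  cat("<cg_structure> ", nrow(x$coords), " atoms, ",
      length(unique(x$residue_id)), " residues (roles: ",
      paste(sort(unique(x$atom_role)), collapse = ","), ")\n", sep = "")
  invisible(x)
}

n_atoms <- function(structure) nrow(structure$coords)

#' @rdname cg_structure
#' @param topology a `cg_structure` giving the shared atom naming.
#' @param frames `n_atoms x 3 x n_frames` numeric array of coordinates.
#' @param times numeric vector of frame times, ns, strictly increasing.
#' @export
cg_trajectory <- function(topology, frames, times) {
  stopifnot(inherits(topology, "cg_structure"))
  if (is.list(frames))
    frames <- array(unlist(frames), dim = c(nrow(frames[[1L]]), 3L,
                                            length(frames)))
  if (length(dim(frames)) != 3L || dim(frames)[2L] != 3L)
    stop("frames must be an n_atoms x 3 x n_frames array")
  if (dim(frames)[1L] != n_atoms(topology))
    stop("frame atom count does not match topology")
  if (!all(is.finite(frames))) stop("frames must be finite")
  times <- as.numeric(times)
  if (length(times) != dim(frames)[3L])
    stop("times length must equal frame count")
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing")
  out <- list(topology = topology, frames = frames, times = times)
  class(out) <- "cg_trajectory"
  out
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("<cg_trajectory> ", dim(x$frames)[3L], " frames x ",
      dim(x$frames)[1L], " atoms, t = ", min(x$times), "..",
      max(x$times), " ns\n", sep = "")
  invisible(x)
}

n_frames <- function(traj) dim(traj$frames)[3L]

frame_coords <- function(traj, i) traj$frames[, , i, drop = TRUE]

#' Select atoms of a structure by backbone role
#'
#' @param structure a `cg_structure`.
#' @param selection character vector of roles to keep (default `"CA"`).
#' @return integer indices of the selected atoms, in structure order.
#' @export
role_selection <- function(structure, selection = "CA") {
  if (!all(selection %in% c("N", "CA", "C")))
    stop("selection must be a subset of N, CA, C")
  which(structure$atom_role %in% selection)
}

#' Read a PDB file into a structure or trajectory
#'
#' Parses fixed-column `ATOM` records, keeping backbone atoms whose names
#' match `roles` (default N, CA, C). Files with multiple `MODEL` blocks yield
#' a `cg_trajectory` with one frame per model; frame times default to the
#' model index in nanoseconds starting at 0.
#'
#' @param path PDB file path.
#' @param roles atom names to retain.
#' @return a `cg_structure`, or a `cg_trajectory` for multi-model files.
#' @export
read_pdb <- function(path, roles = c("N", "CA", "C")) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  model_breaks <- which(trimws(rec) == "MODEL")
  atom_idx <- which(rec == "ATOM  ")
  if (length(atom_idx) == 0L)
    stop("no ATOM records in ", path)

  parse_block <- function(idx) {
    nm <- trimws(substr(lines[idx], 13L, 16L))
    keep <- nm %in% roles
    idx <- idx[keep]; nm <- nm[keep]
    if (length(idx) == 0L)
      stop("no usable backbone atoms (", paste(roles, collapse = "/"),
           ") in ", path)
    num <- function(a, b, what) {
      v <- suppressWarnings(as.numeric(substr(lines[idx], a, b)))
      bad <- which(!is.finite(v))
      if (length(bad))
        stop("malformed ", what, " field at line ", idx[bad[1L]],
             " of ", path)
      v
    }
    x <- num(31L, 38L, "x"); y <- num(39L, 46L, "y"); z <- num(47L, 54L, "z")
    rid <- suppressWarnings(as.integer(substr(lines[idx], 23L, 26L)))
    bad <- which(is.na(rid))
    if (length(bad))
      stop("malformed residue number at line ", idx[bad[1L]], " of ", path)
    list(coords = cbind(x, y, z), residue_id = rid,
         residue_name = trimws(substr(lines[idx], 18L, 20L)),
         atom_role = nm)
  }

  if (length(model_breaks) <= 1L) {
    b <- parse_block(atom_idx)
    return(cg_structure(b$coords, b$residue_id, b$residue_name, b$atom_role))
  }
  ends <- c(model_breaks[-1L] - 1L, length(lines))
  blocks <- lapply(seq_along(model_breaks), function(i) {
    parse_block(atom_idx[atom_idx > model_breaks[i] & atom_idx <= ends[i]])
  })
  b1 <- blocks[[1L]]
  topo <- cg_structure(b1$coords, b1$residue_id, b1$residue_name,
                       b1$atom_role)
  frames <- array(NA_real_, dim = c(nrow(b1$coords), 3L, length(blocks)))
  for (i in seq_along(blocks)) {
    if (nrow(blocks[[i]]$coords) != nrow(b1$coords))
      stop("MODEL ", i, " has a different atom count")
    frames[, , i] <- blocks[[i]]$coords
  }
  cg_trajectory(topo, frames, times = seq_along(blocks) - 1)
}

#' Write a structure or trajectory as PDB
#'
#' Structures become a single block of fixed-column `ATOM` records;
#' trajectories one `MODEL`/`ENDMDL` block per frame. Coordinates are written
#' to 3 decimals, so a read/write round trip preserves them to 1e-3 Angstrom.
#'
#' @param x a `cg_structure` or `cg_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  fmt_block <- function(coords, topo) {
    if (!all(is.finite(coords)))
      stop("non-finite coordinate at atom ",
           which(!apply(is.finite(coords), 1L, all))[1L])
    nm <- topo$atom_role
    nm_fmt <- ifelse(nchar(nm) < 4L, sprintf(" %-3s", nm), nm)
    sprintf("ATOM  %5d %4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            seq_len(nrow(coords)), nm_fmt,
            substr(topo$residue_name, 1L, 3L), topo$residue_id,
            coords[, 1L], coords[, 2L], coords[, 3L])
  }
  if (inherits(x, "cg_structure")) {
    writeLines(c(fmt_block(x$coords, x), "END"), path)
  } else if (inherits(x, "cg_trajectory")) {
    out <- character(0)
    for (i in seq_len(n_frames(x))) {
      out <- c(out, sprintf("MODEL     %4d", i),
               fmt_block(frame_coords(x, i), x$topology), "ENDMDL")
    }
    writeLines(c(out, "END"), path)
  } else stop("x must be a cg_structure or cg_trajectory")
  invisible(path)
}
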