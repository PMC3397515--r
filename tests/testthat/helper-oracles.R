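# Independent oracles used across the suite. Each re-derives a quantity by
# brute force or an unrelated construction, never through the package's own
# computational path.

# Best-fit RMSD by exhaustive Euler-angle grid search + local refinement.
grid_search_rmsd <- function(a, b, coarse_deg = 15) {
  a <- sweep(a, 2, colMeans(a)); b <- sweep(b, 2, colMeans(b))
  rot <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1)) %*%
      rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy)) %*%
      rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  }
  obj <- function(ang) sqrt(mean(rowSums((a %*% t(rot(ang)) - b)^2)))
  step <- coarse_deg * pi / 180
  grid <- as.matrix(expand.grid(seq(0, 2 * pi - step, step),
                                seq(0, pi, step),
                                seq(0, 2 * pi - step, step)))
  vals <- apply(grid, 1, obj)
  best <- grid[which.min(vals), ]
  opt <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

# Net winding number by counting directed wrap crossings of the raw series.
crossing_count_winding <- function(raw) {
  d <- diff(raw)
  wraps <- sum(d < -180) - sum(d > 180)
  round((raw[length(raw)] - raw[1] + 360 * wraps) / 360)
}

# Needleman-Wunsch percent identity by explicit dynamic programming with
# traceback (match +1, mismatch 0, linear gap -1).
nw_identity <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  sc <- matrix(0, n + 1, m + 1)
  sc[, 1] <- gap * (0:n); sc[1, ] <- gap * (0:m)
  for (i in 1:n) for (j in 1:m) {
    sc[i + 1, j + 1] <- max(
      sc[i, j] + if (a[i] == b[j]) match else mismatch,
      sc[i, j + 1] + gap, sc[i + 1, j] + gap)
  }
  i <- n; j <- m; matches <- 0; len <- 0
  while (i > 0 || j > 0) {
    len <- len + 1
    if (i > 0 && j > 0 &&
        sc[i + 1, j + 1] ==
          sc[i, j] + (if (a[i] == b[j]) match else mismatch)) {
      if (a[i] == b[j]) matches <- matches + 1
      i <- i - 1; j <- j - 1
    } else if (i > 0 && sc[i + 1, j + 1] == sc[i, j + 1] + gap) {
      i <- i - 1
    } else j <- j - 1
  }
  100 * matches / len
}

# Four points with a prescribed torsion, built directly from the geometric
# definition: p4 is placed by rotating an off-axis direction about the
# p2-p3 bond by the requested angle.
points_with_torsion <- function(torsion_deg, bond = 1.5, angle_deg = 111) {
  th <- torsion_deg * pi / 180
  an <- angle_deg * pi / 180
  p1 <- c(1, 0, -1); p2 <- c(0, 0, 0); p3 <- c(0, 0, 1.4)
  # in-plane (torsion 0) direction for p4 is +x rotated by the bond angle
  d0 <- c(sin(an), 0, cos(an) * -1)
  rotz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  p4 <- p3 + bond * as.vector(rotz %*% d0)
  list(p1 = p1, p2 = p2, p3 = p3, p4 = p4)
}

# Small random coordinate cloud.
random_cloud <- function(n, seed, sd = 2) {
  set.seed(seed)
  matrix(rnorm(3 * n, sd = sd), n, 3)
}

# Reference CCDA pattern of the RadA linker as a winding program on a
# synthetic chain: region residues get phi/psi windings = value / 360.
linker_program <- function(region_ids) {
  ref <- rada_linker_ccda()
  stopifnot(length(region_ids) == nrow(ref))
  prog <- data.frame(residue_id = integer(0), angle = character(0),
                     winding = integer(0))
  for (k in seq_len(nrow(ref))) {
    if (ref$ccda_phi[k] > 0)
      prog <- rbind(prog, data.frame(residue_id = region_ids[k],
                                     angle = "phi",
                                     winding = ref$ccda_phi[k] / 360))
    if (ref$ccda_psi[k] > 0)
      prog <- rbind(prog, data.frame(residue_id = region_ids[k],
                                     angle = "psi",
                                     winding = ref$ccda_psi[k] / 360))
  }
  prog
}
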