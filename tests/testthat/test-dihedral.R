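test_that("dihedral angle honours the sign convention and planar cases", {
  p <- points_with_torsion(0)
  expect_equal(dihedral_angle(p$p1, p$p2, p$p3, p$p4), 0, tolerance = 1e-9)
  p <- points_with_torsion(180)
  expect_equal(dihedral_angle(p$p1, p$p2, p$p3, p$p4), 180,
               tolerance = 1e-9)
  p <- points_with_torsion(-57)
  expect_equal(dihedral_angle(p$p1, p$p2, p$p3, p$p4), -57,
               tolerance = 1e-6)
  for (tor in c(-170, -91, 13.5, 88, 179)) {
    p <- points_with_torsion(tor)
    expect_equal(dihedral_angle(p$p1, p$p2, p$p3, p$p4), tor,
                 tolerance = 1e-6)
  }
})

test_that("dihedral angle agrees with bio3d on random quadruples", {
  skip_if_not_installed("bio3d")
  for (seed in 1:10) {
    q <- random_cloud(4, seed = seed)
    ours <- dihedral_angle(q[1, ], q[2, ], q[3, ], q[4, ])
    ref <- bio3d::torsion.xyz(as.vector(t(q)))
    expect_equal(ours, as.numeric(ref), tolerance = 1e-6)
  }
})

test_that("collinear points raise an undefined-dihedral error", {
  expect_error(dihedral_angle(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2),
                              c(1, 0, 3)), "collinear")
})

test_that("phi/psi series: rigid trajectories are constant, termini NA", {
  topo <- build_backbone(-57, -47, n_residues = 6)
  frames <- array(topo$coords, c(nrow(topo$coords), 3, 4))
  traj <- cg_trajectory(topo, frames, times = 0:3)
  ser <- phi_psi_series(traj)
  for (s in ser) {
    first <- s$residue_id == 1 && s$angle == "phi"
    last <- s$residue_id == 6 && s$angle == "psi"
    if (first || last) {
      expect_false(s$defined)
      expect_true(all(is.na(s$raw)))
    } else {
      expect_true(s$defined)
      expect_equal(diff(range(s$raw)), 0, tolerance = 1e-9)
    }
  }
})

test_that("phi/psi series recover the generator's canonical helix angles", {
  topo <- build_backbone(-57, -47, n_residues = 8)
  traj <- make_rotation_trajectory(topo, n_frames = 3, noise_sd = 0)
  ser <- phi_psi_series(traj)
  for (s in ser) {
    if (!s$defined) next
    want <- if (s$angle == "phi") -57 else -47
    expect_equal(s$raw, rep(want, 3), tolerance = 2)
  }
})

test_that("a programmed single-residue sweep wraps exactly once", {
  topo <- build_backbone(-57, -47, n_residues = 8)
  prog <- data.frame(residue_id = 5, angle = "psi", winding = 1)
  traj <- make_rotation_trajectory(topo, prog, n_frames = 36, noise_sd = 0)
  ser <- phi_psi_series(traj)
  for (s in ser) {
    if (!s$defined) next
    u <- unwind(s)
    if (s$residue_id == 5 && s$angle == "psi") {
      expect_equal(u$winding, 1)
      expect_gt(sum(abs(diff(s$raw)) > 180), 0)   # raw series wrapped
    } else {
      expect_equal(u$winding, 0)
    }
  }
})

test_that("unwinding reconstructs continuous series from wrapped ones", {
  expect_equal(unwind(rep(42, 5)), rep(42, 5))
  ramp <- wrap180(10 * (0:72))                    # +10 deg/frame, 2 turns
  u <- unwind(ramp)
  expect_equal(u[1], ramp[1])
  expect_true(all(diff(u) > -180 & diff(u) <= 180))
  expect_equal((u[73] - u[1]) / 360, 2)
  expect_error(unwind(5), "2 frames")
})

test_that("noisy programmed sweeps match the crossing-count oracle", {
  set.seed(99)
  for (rep in 1:10) {
    w <- sample(c(-2, -1, 1, 2), 1)
    n <- 100
    true_ang <- w * 360 * (0:(n - 1)) / (n - 1) +
      rnorm(n, 0, 20)
    raw <- wrap180(true_ang)
    u <- unwind(raw)
    winding <- round((u[n] - u[1]) / 360)
    expect_equal(winding, crossing_count_winding(raw))
    expect_equal(winding, w)
  }
})

test_that("ccda quantizes net rotation to multiples of 360", {
  expect_equal(ccda(rep(10, 4)), 0)
  two_turns <- wrap180(10 * (0:72))
  expect_equal(ccda(two_turns), 720)
  half_turn <- wrap180(seq(0, 180, length.out = 40))
  expect_equal(ccda(half_turn), 0)
  neg <- wrap180(seq(0, -360, length.out = 80))
  expect_equal(ccda(neg), 360)          # magnitude, sign dropped
})

test_that("ccda table localizes programmed rotations", {
  topo <- build_backbone(-57, -47, n_residues = 8)
  frames <- array(topo$coords, c(nrow(topo$coords), 3, 3))
  rigid <- cg_trajectory(topo, frames, times = 0:2)
  tab <- ccda_table(rigid)
  expect_true(all(tab$ccda_phi[-1] == 0))
  expect_true(all(tab$ccda_psi[-8] == 0))
  expect_true(is.na(tab$ccda_phi[1]) && is.na(tab$ccda_psi[8]))

  prog <- data.frame(residue_id = c(2, 5), angle = c("phi", "phi"),
                     winding = c(1, 1))
  traj <- make_rotation_trajectory(topo, prog, n_frames = 72,
                                   noise_sd = 0)
  tab <- ccda_table(traj)
  expect_equal(tab$ccda_phi[tab$residue_id %in% c(2, 5)], c(360, 360))
  expect_true(all(tab$ccda_phi[!tab$residue_id %in% c(1, 2, 5)] == 0))
  expect_true(all(tab$ccda_psi[-8] == 0))
  expect_error(ccda_table(traj, region = 100:120), "empty")
})

test_that("ccda is invariant under per-frame rigid motions", {
  topo <- build_backbone(-57, -47, n_residues = 8)
  prog <- data.frame(residue_id = c(3, 6), angle = c("psi", "phi"),
                     winding = c(2, -1))
  traj <- make_rotation_trajectory(topo, prog, n_frames = 80,
                                   noise_sd = 5, seed = 17)
  tab <- ccda_table(traj)
  set.seed(41)
  moved <- traj
  for (f in seq_len(dim(traj$frames)[3])) {
    ang <- runif(3, -pi, pi)
    rz <- rbind(c(cos(ang[1]), -sin(ang[1]), 0),
                c(sin(ang[1]), cos(ang[1]), 0), c(0, 0, 1))
    ry <- rbind(c(cos(ang[2]), 0, sin(ang[2])), c(0, 1, 0),
                c(-sin(ang[2]), 0, cos(ang[2])))
    shift <- matrix(runif(3, -20, 20), nrow(topo$coords), 3, byrow = TRUE)
    moved$frames[, , f] <- traj$frames[, , f] %*% t(rz %*% ry) + shift
  }
  expect_identical(ccda_table(moved), tab)
})

test_that("winding is additive under trajectory concatenation", {
  topo <- build_backbone(-57, -47, n_residues = 6)
  progA <- data.frame(residue_id = 3, angle = "psi", winding = 1)
  a <- make_rotation_trajectory(topo, progA, n_frames = 60, noise_sd = 0)
  # continue from the final frame: second segment adds one more turn
  lastA <- cg_structure(a$frames[, , 60], topo$residue_id,
                        topo$residue_name, topo$atom_role)
  b <- make_rotation_trajectory(lastA, progA, n_frames = 60, noise_sd = 0)
  both <- cg_trajectory(topo,
                        array(c(a$frames, b$frames[, , -1]),
                              c(nrow(topo$coords), 3, 119)),
                        times = seq(0, by = 0.01, length.out = 119))
  tab <- ccda_table(both)
  expect_equal(tab$ccda_psi[tab$residue_id == 3], 720)
})

test_that("rotary classification partitions the analysed region", {
  ref <- rada_linker_ccda()
  cls <- classify_rotary(ref)
  expect_setequal(cls$zero_rotary, c(71, 74, 82, 83, 88))
  expect_length(cls$zero_rotary, 5)
  expect_length(cls$rotary, 13)
  expect_length(intersect(cls$rotary, cls$zero_rotary), 0)
  expect_setequal(c(cls$rotary, cls$zero_rotary), 71:88)
  # F73 and N85 carry a single 360 entry and are rotary under the rule
  expect_true(all(c(73, 85) %in% cls$rotary))

  allzero <- data.frame(residue_id = 1:4, ccda_phi = 0, ccda_psi = 0)
  expect_length(classify_rotary(allzero)$rotary, 0)

  withna <- data.frame(residue_id = 1:3, ccda_phi = c(NA, 0, 360),
                       ccda_psi = 0)
  expect_error(classify_rotary(withna), "residues: 1")
  cls2 <- classify_rotary(withna, skip_undefined = TRUE)
  expect_equal(cls2$undefined, 1)
  expect_equal(length(cls2$rotary) + length(cls2$zero_rotary) +
                 length(cls2$undefined), 3)
})

test_that("generator round trip recovers random winding programs exactly", {
  topo <- build_backbone(-57, -47, n_residues = 10)
  for (seed in 1:10) {
    set.seed(seed + 500)
    picks <- sample(2:9, 3)
    prog <- data.frame(residue_id = picks,
                       angle = sample(c("phi", "psi"), 3, replace = TRUE),
                       winding = sample(-3:3, 3, replace = TRUE))
    traj <- make_rotation_trajectory(topo, prog, n_frames = 150,
                                     noise_sd = 15, seed = seed)
    tab <- ccda_table(traj)
    for (p in seq_len(nrow(prog))) {
      col <- if (prog$angle[p] == "phi") "ccda_phi" else "ccda_psi"
      expect_equal(tab[[col]][tab$residue_id == prog$residue_id[p]],
                   360 * abs(prog$winding[p]))
    }
    expected_zero <- sum(!is.na(tab$ccda_phi)) + sum(!is.na(tab$ccda_psi)) -
      sum(360 * abs(prog$winding) > 0)
    expect_equal(sum(c(tab$ccda_phi, tab$ccda_psi) == 0, na.rm = TRUE),
                 expected_zero)
  }
})

test_that("the reference linker pattern survives a generator round trip", {
  topo <- build_backbone(-57, -47, n_residues = 20)
  region <- 2:19
  prog <- linker_program(region)
  traj <- make_rotation_trajectory(topo, prog, n_frames = 160,
                                   noise_sd = 10, seed = 42)
  tab <- ccda_table(traj, region = region)
  ref <- rada_linker_ccda()
  expect_equal(tab$ccda_phi, ref$ccda_phi)
  expect_equal(tab$ccda_psi, ref$ccda_psi)
  cls <- classify_rotary(tab)
  expect_equal(region[match(c(71, 74, 82, 83, 88), ref$residue_id)],
               cls$zero_rotary)
})
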