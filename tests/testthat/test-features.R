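# Featurization: torsions, distances, superposition RMSD, panel, smoothing.

test_that("torsions reproduce textbook cases and the normal-vector oracle", {
  # anti-periplanar (trans) arrangement -> pi
  traj <- coord_traj(rbind(c(-1, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, -1, 0)),
                     topology(c("A1", "A2", "A3", "A4"), 1:4))
  ft <- compute_dihedrals(traj, which = list(tr = 1:4))
  expect_equal(unname(ft$values[1, ]), c(sin(pi), cos(pi)), tolerance = 1e-12)
  # planar cis arrangement -> 0
  traj <- coord_traj(rbind(c(-1, -1, 0), c(0, 0, 0), c(1, 0, 0), c(2, -1, 0)),
                     topology(c("A1", "A2", "A3", "A4"), 1:4))
  ft <- compute_dihedrals(traj, which = list(cz = 1:4))
  expect_equal(unname(ft$values[1, ]), c(0, 1), tolerance = 1e-12)

  # random 4-point sets match the independent geometric oracle
  set.seed(31)
  for (rep in 1:20) {
    P <- matrix(rnorm(12), 4, 3)
    traj <- coord_traj(P, topology(paste0("A", 1:4), 1:4))
    ft <- compute_dihedrals(traj, which = list(x = 1:4))
    ang <- unname(atan2(ft$values[1, 1], ft$values[1, 2]))
    expect_equal(ang, oracle_dihedral(P[1, ], P[2, ], P[3, ], P[4, ]),
                 tolerance = 1e-10)
    expect_equal(unname(sum(ft$values[1, ]^2)), 1, tolerance = 1e-12)
  }
})

test_that("backbone phi/psi extraction resolves atoms and flags missing ones", {
  fx <- make_toy_structure_pair(5, seed = 1)
  ft <- compute_dihedrals(fx$reference, which = "backbone")
  # 4 phi + 4 psi angles for 5 residues, each as a (sin, cos) pair
  expect_equal(ncol(ft$values), 16)
  expect_true(all(abs(rowSums(matrix(ft$values[1, ]^2, ncol = 2,
                                     byrow = TRUE)) - 1) < 1e-12))
  top_bad <- fx$topology[fx$topology$atom != "N" | fx$topology$resno != 3, ]
  traj_bad <- coord_traj(fx$reference$coords[, fx$topology$atom != "N" |
                                               fx$topology$resno != 3, ,
                                             drop = FALSE], top_bad)
  expect_error(compute_dihedrals(traj_bad), "residue 3")
})

test_that("minimum heavy-atom distances match brute force and exclude hydrogens", {
  top <- topology(c("CA", "HA", "CA"), c(1, 1, 2),
                  element = c("C", "H", "C"))
  # 3-4-5 triangle between the two heavy atoms; hydrogen nearer but ignored
  P <- rbind(c(0, 0, 0), c(1, 0, 0), c(3, 4, 0))
  ft <- compute_min_heavy_distances(coord_traj(P, top), list(c(1, 2)))
  expect_equal(unname(ft$values[1, 1]), 5)
  # symmetry of the pair order
  ft2 <- compute_min_heavy_distances(coord_traj(P, top), list(c(2, 1)))
  expect_equal(unname(ft$values[1, 1]), unname(ft2$values[1, 1]))

  set.seed(8)
  fx <- make_toy_structure_pair(6, seed = 8)
  ft <- compute_min_heavy_distances(fx$reference, list(c(1, 4), c(2, 6)))
  P <- matrix(fx$reference$coords[1, , ], ncol = 3)
  top <- fx$topology
  for (k in 1:2) {
    pr <- list(c(1, 4), c(2, 6))[[k]]
    expect_equal(unname(ft$values[1, k]),
                 oracle_min_dist(P[top$resno == pr[1] & top$heavy, , drop = FALSE],
                                 P[top$resno == pr[2] & top$heavy, , drop = FALSE]),
                 tolerance = 1e-12)
  }
})

test_that("superposition RMSD is rigid-invariant and matches the quaternion oracle", {
  fx <- make_toy_structure_pair(8, seed = 3)
  all_idx <- seq_len(nrow(fx$topology))
  expect_equal(superpose_rmsd(fx$reference, fx$reference, all_idx)[1], 0,
               tolerance = 1e-12)
  expect_lt(superpose_rmsd(fx$transformed, fx$reference, all_idx)[1], 1e-8)

  # random rigid transforms leave fitted RMSD unchanged (property loop)
  set.seed(17)
  ref <- matrix(fx$reference$coords[1, , ], ncol = 3)
  pert <- ref + matrix(rnorm(length(ref), sd = 0.3), nrow(ref))
  base <- superpose_rmsd(coord_traj(pert, fx$topology), ref, all_idx)[1]
  for (rep in 1:5) {
    qr_ <- qr(matrix(rnorm(9), 3)); Q <- qr.Q(qr_)
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    moved <- pert %*% t(Q) + matrix(rnorm(3, sd = 5), nrow(pert), 3,
                                    byrow = TRUE)
    expect_equal(superpose_rmsd(coord_traj(moved, fx$topology), ref,
                                all_idx)[1], base, tolerance = 1e-8)
  }
  # independent quaternion-based superposition oracle
  expect_equal(base, oracle_superpose_rmsd(pert, ref), tolerance = 1e-8)
  expect_error(superpose_rmsd(coord_traj(pert, fx$topology), ref,
                              integer(0)), "empty")
})

test_that("atom pair distances are exact", {
  top <- topology(c("CD", "CZ"), c(439, 468))
  P <- rbind(c(0, 0, 0), c(0, 0, 0))
  d <- atom_pair_distance(coord_traj(P, top),
                          list(c(439, "CD"), c(468, "CZ")))
  expect_equal(d, 0)
  P2 <- rbind(c(0, 0, 0), c(0, 1, 0))
  expect_equal(atom_pair_distance(coord_traj(P2, top),
                                  list(c(439, "CD"), c(468, "CZ"))), 1)
  set.seed(2)
  frames <- array(rnorm(5 * 2 * 3), c(5, 2, 3))
  d <- atom_pair_distance(coord_traj(frames, top, dt = 1),
                          list(c(439, "CD"), c(468, "CZ")))
  expect_equal(d, sqrt(rowSums((frames[, 1, ] - frames[, 2, ])^2)),
               tolerance = 1e-12)
  expect_error(atom_pair_distance(coord_traj(P, top),
                                  list(c(439, "CD"), c(468, "NZ"))),
               "NZ")
})

test_that("order-parameter panel has stable columns and analytic values", {
  fx <- make_toy_structure_pair(12, displacement = 3, seed = 6)
  spec <- order_parameter_spec(fx$topology, fx$reference,
                               aloop = 4:9, dfg = 4:6, ploop = 1:3,
                               rspine = c(2, 5, 8, 11),
                               sb1 = list(c(4, "CD"), c(6, "CZ")),
                               sb2 = list(c(10, "CD"), c(9, "NZ")))
  # reference against itself: every RMSD column exactly 0
  pan <- order_parameter_panel(fx$reference, spec)
  expect_identical(colnames(pan$values),
                   c("aloop_rmsd", "r468_e439_dist", "k430_e445_dist",
                     "ploop_rmsd", "rspine_rmsd", "dfg_rmsd"))
  expect_lt(max(pan$values[1, c(1, 4, 5, 6)]), 1e-10)

  # displaced middle residue (resno 6), no fit: RMSD = d sqrt(k/N)
  spec_nofit <- order_parameter_spec(fx$topology, fx$reference,
                                     aloop = 4:9, dfg = 4:6, ploop = 1:3,
                                     rspine = c(2, 5, 8, 11),
                                     sb1 = list(c(4, "CD"), c(6, "CZ")),
                                     sb2 = list(c(10, "CD"), c(9, "NZ")))
  top <- fx$topology
  sel <- which(top$resno %in% 4:9 & top$heavy)
  k <- sum(top$resno[sel] == fx$displaced_resno)
  r <- superpose_rmsd(fx$displaced, fx$reference, sel, fit = FALSE)
  expect_equal(r[1], 3 * sqrt(k / length(sel)), tolerance = 1e-10)

  # panel is reproducible bit-for-bit
  pan2 <- order_parameter_panel(fx$reference, spec)
  expect_identical(pan$values, pan2$values)
})

test_that("moving average is a trailing mean with prefix handling", {
  expect_equal(moving_average(c(4, 2, 9), 1), c(4, 2, 9))
  expect_equal(moving_average(rep(3, 10), 4), rep(3, 10))
  ma <- moving_average(1:10, 10)
  expect_equal(ma[10], 5.5)
  expect_equal(ma[1:3], c(1, 1.5, 2))  # prefix averages
  expect_equal(moving_average(1:6, 3)[4:6], c(3, 4, 5))
  expect_error(moving_average(1:3, 5), "exceeds")
})

test_that("pooled normalization z-scores and flags constant columns", {
  set.seed(9)
  xs <- list(feature_traj(matrix(rnorm(300, 5, 2), 100), dt = 1),
             feature_traj(matrix(rnorm(150, 5, 2), 50), dt = 1))
  nm <- normalize_features(xs)
  pooled <- do.call(rbind, lapply(nm$trajs, function(t) t$values))
  expect_lt(max(abs(colMeans(pooled))), 1e-12)
  expect_equal(apply(pooled, 2, sd), rep(1, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  # already standardized input is unchanged
  again <- normalize_features(nm$trajs)
  expect_equal(again$trajs[[1]]$values, nm$trajs[[1]]$values,
               tolerance = 1e-12)
  # constant column flagged, not divided by zero
  xs2 <- list(feature_traj(cbind(rnorm(50), 7), dt = 1))
  nm2 <- normalize_features(xs2)
  expect_true(nm2$constant[2])
  expect_equal(nm2$scale[2], 1, ignore_attr = TRUE)
  expect_true(all(is.finite(nm2$trajs[[1]]$values)))
  expect_error(normalize_features(list()), "empty")
})
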