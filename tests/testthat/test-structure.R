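test_that("superposition of identical and rigidly moved conformers", {
  set.seed(1)
  A <- toy_conformer(matrix(rnorm(15, sd = 3), ncol = 3))
  expect_equal(kabsch_superpose(A, A)$rmsd, 0, tolerance = 1e-12)
  B <- rigid_move(A, angle = pi / 2)
  sup <- kabsch_superpose(A, B)
  expect_lt(sup$rmsd, 1e-10)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-12)
  # applying the transform reproduces the target
  Afit <- apply_superposition(A, sup)
  expect_equal(as.matrix(Afit[, c("x", "y", "z")]),
               as.matrix(B[, c("x", "y", "z")]), tolerance = 1e-9)
})

test_that("Kabsch rmsd matches the rotation-grid brute force on toys", {
  set.seed(7)
  for (rep in 1:3) {
    n <- sample(4:6, 1)
    P <- matrix(rnorm(3 * n, sd = 2), ncol = 3)
    Q <- matrix(rnorm(3 * n, sd = 2), ncol = 3)
    r_kabsch <- kabsch_superpose(toy_conformer(P), toy_conformer(Q))$rmsd
    r_grid <- grid_rmsd_min(P, Q)
    expect_equal(r_kabsch, r_grid, tolerance = 1e-3 / max(r_kabsch, 1e-3))
    expect_lte(r_kabsch, r_grid + 1e-9)   # grid can never beat the optimum
  }
})

test_that("degenerate selections raise typed errors", {
  A <- toy_conformer(matrix(rnorm(6), ncol = 3))
  expect_error(kabsch_superpose(A, toy_conformer(matrix(rnorm(6), ncol = 3))),
               class = "fracnmr_bad_selection")
  line <- cbind(1:5, 1:5, 1:5)
  expect_error(kabsch_superpose(toy_conformer(line), toy_conformer(line)),
               class = "fracnmr_bad_selection")
})

test_that("ensemble mean: identity, rigid-motion pairs, noise averaging", {
  set.seed(11)
  base <- helix_backbone(10)
  # identical conformers -> the conformer itself
  m <- ensemble_mean(list(base, base, base))
  expect_equal(as.matrix(m[, c("x", "y", "z")]),
               as.matrix(base[, c("x", "y", "z")]), tolerance = 1e-6)
  # two conformers differing by rigid motion only: mean matches both
  moved <- rigid_move(base)
  m2 <- ensemble_mean(list(base, moved))
  expect_lt(rmsd_between(m2, base), 1e-6)
  expect_lt(rmsd_between(m2, moved), 1e-6)
  # Gaussian noise averages out ~ sigma/sqrt(n_models)
  g <- gen_ensemble(n_models = 20, n_residues = 10, sigma = 0.5, seed = 2)
  mg <- ensemble_mean(g$ensemble)
  sup <- kabsch_superpose(mg, g$base)
  expect_lt(sup$rmsd, 3 * 0.5 / sqrt(20) * 2)  # loose 2x guard on rms bound
})

test_that("rmsd_matrix follows the mean-vs-bundle convention", {
  # identical members: all-zero within-bundle entry
  base <- helix_backbone(8)
  same <- structure(list(base, base, base), class = "ensemble")
  rm0 <- rmsd_matrix(list(a = same), atoms = "backbone")
  expect_equal(unname(rm0$mean["a", "a"]), 0, tolerance = 1e-9)
  expect_equal(unname(rm0$sd["a", "a"]), 0, tolerance = 1e-9)

  set.seed(3)
  gA <- gen_ensemble(n_models = 10, n_residues = 12, sigma = 0.3, seed = 21)
  gB <- gen_ensemble(n_models = 10, n_residues = 12, sigma = 0.3, seed = 22)
  rmab <- rmsd_matrix(list(A = gA$ensemble, B = gB$ensemble))
  # both bundles scatter around the same base.  Pairwise member-member
  # distances carry the noise of two models (rmsd ~ sigma*sqrt(6)); the
  # mean structure carries only sigma/sqrt(n) of it, so mean-vs-bundle
  # entries sit at sqrt((1 + 1/n)/2) of the within-bundle value.
  diag_mean <- mean(c(rmab$mean["A", "A"], rmab$mean["B", "B"]))
  off_mean <- mean(c(rmab$mean["A", "B"], rmab$mean["B", "A"]))
  expect_equal(off_mean / diag_mean, sqrt((1 + 1 / 10) / 2),
               tolerance = 0.10)

  # translating a whole bundle changes nothing
  shifted <- lapply(gB$ensemble, function(cf) { cf$x <- cf$x + 5; cf })
  rm2 <- rmsd_matrix(list(A = gA$ensemble, B = shifted))
  expect_equal(rm2$mean, rmab$mean, tolerance = 1e-9)
})

test_that("within-bundle rmsd scales like sqrt(2) x the model displacement", {
  g <- gen_ensemble(n_models = 20, n_residues = 15, sigma = 0.5, seed = 13)
  rmm <- rmsd_matrix(list(x = g$ensemble))
  # each model is displaced by sigma per coordinate, i.e. sigma*sqrt(3) in
  # 3D; two independent models differ by sqrt(2) times that, so pairwise
  # rmsd ~ sigma*sqrt(6) (superposition removes a few dof; 15% band)
  expect_equal(unname(rmm$mean["x", "x"]), 0.5 * sqrt(6), tolerance = 0.15)
})

test_that("displacement profile localizes a constructed displacement", {
  base <- helix_backbone(12)
  expect_equal(displacement_profile(base, base)$d_backbone, rep(0, 12),
               tolerance = 1e-12)
  # displace one residue rigidly by 1 A, fit on the others
  B <- base
  idx <- B$resno == 6
  B$x[idx] <- B$x[idx] + 1.0
  prof <- displacement_profile(base, B)
  expect_equal(prof$d_backbone[prof$resno == 6], 1.0, tolerance = 0.15)
  expect_true(all(prof$d_backbone[prof$resno != 6] < 0.2))
  expect_true(all(prof$d_backbone >= 0 & prof$d_heavy >= 0, na.rm = TRUE))
  # a residue missing in one structure yields a gap, not zero
  Bgap <- B[B$resno != 3, ]
  prof2 <- displacement_profile(base, conformer(Bgap), residues = 1:12)
  expect_true(is.na(prof2$d_backbone[prof2$resno == 3]))
})

test_that("all RMSD quantities are rigid-motion invariant", {
  g <- gen_ensemble(n_models = 5, n_residues = 10, sigma = 0.4, seed = 31)
  ens <- g$ensemble
  moved <- structure(lapply(ens, rigid_move, angle = 1.1,
                            axis = c(1, 2, -1), shift = c(-4, 7, 3)),
                     class = "ensemble")
  r1 <- rmsd_matrix(list(a = ens))$mean["a", "a"]
  r2 <- rmsd_matrix(list(a = moved))$mean["a", "a"]
  expect_equal(r1, r2, tolerance = 1e-9)
  m1 <- ensemble_mean(ens); m2 <- ensemble_mean(moved)
  p1 <- displacement_profile(m1, ens[[1]])
  p2 <- displacement_profile(rigid_move(m1), ens[[1]])
  expect_equal(p1$d_backbone, p2$d_backbone, tolerance = 1e-9)
  # symmetry for single conformers
  expect_equal(rmsd_between(ens[[1]], ens[[2]]),
               rmsd_between(ens[[2]], ens[[1]]), tolerance = 1e-9)
})
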