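test_that("built alpha-helix reproduces canonical helix geometry", {
  ch <- ideal_helix(24, start_id = 210L)
  validate_chain(ch)
  ax <- fit_helix_axis(ch, 210:233)
  ca <- atom_xyz(ch, "CA")
  rises <- diff(as.numeric(sweep(ca, 2, ax$origin) %*% ax$direction))
  expect_true(all(abs(rises - 1.5) < 0.05))
  expect_equal(ax$radius, 2.3, tolerance = 0.3 / 2.3)
  len <- helix_axial_length(210:233, ch)
  expect_identical(len$nominal, 36)
  expect_equal(len$projected, 34.5, tolerance = 0.5 / 34.5)
})

test_that("two-residue chain keeps the CA-CA virtual bond", {
  ch <- build_backbone(c("ALA", "GLY"), dihedral_set(c(NA, -70), c(120, NA)))
  ca <- atom_xyz(ch, "CA")
  expect_equal(sqrt(sum((ca[2, ] - ca[1, ])^2)), 3.80, tolerance = 0.15 / 3.8)
})

test_that("fully extended chain is near-linear", {
  ch <- build_backbone(rep("ALA", 10), dihedral_set(rep(180, 10), rep(180, 10)))
  expect_lt(fit_helix_axis(ch, 1:10)$radius, 1.2)
})

test_that("backbone bond invariants hold for arbitrary legal dihedrals", {
  set.seed(42)
  for (rep in 1:15) {
    n <- sample(5:30, 1)
    ch <- build_backbone(sample(c("ALA", "GLY", "SER", "PRO"), n, TRUE),
                         dihedral_set(stats::runif(n, -179, 180),
                                      stats::runif(n, -179, 180),
                                      stats::runif(n, 170, 180)))
    expect_silent(validate_chain(ch))
  }
  expect_error(build_backbone(character(0), dihedral_set(numeric(0),
                                                         numeric(0))),
               "empty")
})

test_that("helix axis is equivariant under rigid motion and needs >= 7 residues", {
  ch <- ideal_helix(24, start_id = 210L)
  ax <- fit_helix_axis(ch, 210:233)
  R <- random_rotation(5)
  ch2 <- transform_chain(ch, R, c(3, -8, 12))
  ax2 <- fit_helix_axis(ch2, 210:233)
  rotated <- as.numeric(ax$direction %*% t(R))
  ang <- acos(min(1, abs(sum(ax2$direction * rotated)))) * 180 / pi
  expect_lt(ang, 0.5)
  expect_error(fit_helix_axis(ch, 210:215), ">= 7")
})

test_that("an ideal helix shows no bend between its halves", {
  ch <- ideal_helix(24, start_id = 210L)
  expect_lt(bend_angle(ch, 210:220, 222:233), 2)
  expect_lt(abs(bend_angle(ch, 210:221, 222:233)), 2)
})

test_that("a psi perturbation at the pivot produces a measurable kink", {
  n <- 24
  psi <- rep(-47, n); psi[12] <- -37  # +10 deg at the residue between ranges
  ch <- build_backbone(rep("ALA", n),
                       dihedral_set(rep(-57, n), psi), start_id = 210L)
  expect_gt(bend_angle(ch, 210:220, 222:233), 3)
})

test_that("bend angle rejects overlapping ranges and is rotation invariant", {
  ch <- gen_tmd_ensemble(seed = 8)$clean
  expect_error(bend_angle(ch, 210:222, 222:233), "overlap")
  b1 <- bend_angle(ch, 210:220, 222:233)
  b2 <- bend_angle(rigid_copy(ch, 9), 210:220, 222:233)
  expect_equal(b1, b2, tolerance = 1e-6)
})

test_that("axial length handles the degenerate single-residue range", {
  expect_identical(helix_axial_length(210L)$nominal, 1.5)
  expect_error(helix_axial_length(integer(0)), "empty")
})

test_that("superposition recovers rigid transforms exactly", {
  ch <- ideal_helix(20)
  expect_lt(superpose(ch, ch, 1:20)$rmsd, 1e-6)
  moved <- rigid_copy(ch, 11)
  sp <- superpose(moved, ch, 1:20)
  expect_lt(sp$rmsd, 1e-6)
  expect_true(coords_equal(sp$mobile, ch, tol = 1e-6))
  expect_error(superpose(ch, ch, 1:20, atoms = character(0)), ">= 3")
})

test_that("superposition RMSD tracks the injected noise magnitude", {
  ch <- ideal_helix(30)
  set.seed(21)
  devs <- replicate(40, {
    noisy <- ch
    noisy$x <- noisy$x + stats::rnorm(nrow(ch), sd = 0.5 / sqrt(3))
    noisy$y <- noisy$y + stats::rnorm(nrow(ch), sd = 0.5 / sqrt(3))
    noisy$z <- noisy$z + stats::rnorm(nrow(ch), sd = 0.5 / sqrt(3))
    superpose(noisy, ch, 1:30)$rmsd
  })
  # per-atom displacement magnitude is 0.5 A; allow 20%
  expect_equal(mean(devs), 0.5, tolerance = 0.2)
})

test_that("Kabsch minimum matches an independent quaternion search and bio3d", {
  skip_if_not_installed("bio3d")
  set.seed(33)
  P <- matrix(stats::rnorm(15, sd = 4), ncol = 3)
  Q <- matrix(stats::rnorm(15, sd = 4), ncol = 3)
  chP <- bead_chain(P); chQ <- bead_chain(Q)
  r_kabsch <- superpose(chP, chQ, 1:5, atoms = "CA")$rmsd
  # quaternion sampling: no sampled rotation may beat the closed form
  qc <- colMeans(Q); pc <- colMeans(P)
  Pc <- sweep(P, 2, pc); Qc <- sweep(Q, 2, qc)
  best <- Inf
  for (k in 1:4000) {
    R <- random_rotation()
    r <- sqrt(mean(rowSums((Pc %*% R - Qc)^2)))
    best <- min(best, r)
  }
  expect_gte(best, r_kabsch - 1e-9)
  expect_lt(best - r_kabsch, 0.05 * max(r_kabsch, 1))
  # bio3d cross-check
  ft <- bio3d::fit.xyz(as.numeric(t(Q)), as.numeric(t(P)),
                       fixed.inds = 1:15, mobile.inds = 1:15)
  expect_equal(bio3d::rmsd(as.numeric(t(Q)), ft), r_kabsch,
               tolerance = 1e-4)
})

test_that("ensemble pairwise RMSD behaves on degenerate and synthetic ensembles", {
  ch <- ideal_helix(20, start_id = 206L)
  id5 <- rep(list(ch), 5)
  r <- ensemble_pairwise_rmsd(id5, 206:225)
  expect_equal(r$mean, 0, tolerance = 1e-9)
  expect_equal(r$sd, 0, tolerance = 1e-9)
  two <- ensemble_pairwise_rmsd(list(ch, rigid_copy(ch, 2)), 206:225)
  expect_identical(two$sd, 0)
  ens <- gen_tmd_ensemble(n = 6, seed = 13)
  r2 <- ensemble_pairwise_rmsd(ens$models, 209:235)
  expect_gt(r2$mean, 0)
  expect_length(r2$rmsd, choose(6, 2))
  manual <- superpose(ens$models[[1]], ens$models[[2]], 209:235)$rmsd
  expect_equal(r2$rmsd[1], manual, tolerance = 1e-12)
  expect_error(ensemble_pairwise_rmsd(list(ch), 206:225), ">= 2")
})
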