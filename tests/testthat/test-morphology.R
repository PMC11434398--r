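# Gyration-tensor shape descriptors, inertia axes, minimal projection area,
# Kabsch superposition, per-frame trajectory morphology.

test_that("cube and rod hit the exact symmetry limits", {
  cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  g <- gyration_descriptors(cube, mass_weighted = FALSE)
  expect_equal(g$eigenvalues, c(1, 1, 1), tolerance = 1e-12)
  expect_equal(g$asphericity, 0, tolerance = 1e-12)
  expect_equal(g$acylindricity, 0, tolerance = 1e-12)
  expect_equal(g$kappa2, 0, tolerance = 1e-12)
  expect_equal(g$rg, sqrt(3), tolerance = 1e-12)

  rod <- rbind(c(-1, 0, 0), c(1, 0, 0))
  gr <- gyration_descriptors(rod, mass_weighted = FALSE)
  expect_equal(gr$eigenvalues, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(gr$asphericity, 1, tolerance = 1e-12)
  expect_equal(gr$acylindricity, 0, tolerance = 1e-12)
  expect_equal(gr$kappa2, 1, tolerance = 1e-12)
})

test_that("random clouds match the double-sum tensor oracle to 1e-10", {
  set.seed(5)
  for (rep in 1:25) {
    n <- sample(5:50, 1)
    coords <- matrix(rnorm(3 * n, 0, 2), ncol = 3)
    w <- runif(n, 1, 200)
    g <- gyration_descriptors(coords, masses = w)
    ev <- oracle_gyration_eigenvalues(coords, w)
    expect_equal(g$eigenvalues, ev, tolerance = 1e-10)
    expect_equal(g$rg, sqrt(sum(ev)), tolerance = 1e-10)
    expect_equal(g$asphericity, ev[3] - (ev[1] + ev[2]) / 2, tolerance = 1e-10)
    expect_equal(g$acylindricity, ev[2] - ev[1], tolerance = 1e-10)
    expect_true(g$kappa2 >= 0 && g$kappa2 <= 1)
  }
})

test_that("coincident atoms flag kappa2 as undefined", {
  expect_warning(g <- gyration_descriptors(matrix(1, 4, 3),
                                           mass_weighted = FALSE),
                 "coincident")
  expect_equal(g$rg, 0)
  expect_true(is.na(g$kappa2))
})

test_that("inertia axes align with molecular symmetry and reconstruct I", {
  line <- cbind(0, 0, seq(-3, 3))
  m <- rep(12, nrow(line))
  pa <- principal_inertia_axes(line, m)
  expect_equal(abs(pa$axes[, 1]), c(0, 0, 1), tolerance = 1e-9)
  expect_equal(pa$moments[1], 0, tolerance = 1e-9)

  square <- rbind(c(1, 1, 0), c(-1, 1, 0), c(-1, -1, 0), c(1, -1, 0))
  pa2 <- principal_inertia_axes(square, rep(1, 4))
  expect_equal(abs(pa2$axes[, 3]), c(0, 0, 1), tolerance = 1e-9)

  set.seed(9)
  coords <- matrix(rnorm(36), ncol = 3)
  masses <- runif(12, 1, 16)
  pa3 <- principal_inertia_axes(coords, masses)
  centre <- colSums(coords * masses) / sum(masses)
  d <- sweep(coords, 2, centre)
  I <- diag(sum(masses * rowSums(d^2)), 3) - t(d * masses) %*% d
  expect_equal(pa3$axes %*% diag(pa3$moments) %*% t(pa3$axes), I,
               tolerance = 1e-9)
  expect_equal(t(pa3$axes) %*% pa3$axes, diag(3), tolerance = 1e-9)
})

test_that("MPA reproduces the single-disk area within 0.5%", {
  s <- mol_structure("C", matrix(0, 1, 3))   # r = 1.70
  pr <- minimal_projection_area(s, 0.05)
  expect_equal(pr$mpa, min(pr$areas))
  for (a in pr$areas)
    expect_lt(abs(a - pi * 1.7^2) / (pi * 1.7^2), 0.005)
})

test_that("MPA of a far-separated pair collapses to one disk along the bond", {
  # two P atoms (r = 1.80... use radius 1.5 via custom list) 10 A apart on x
  st <- list(xyz = rbind(c(0, 0, 0), c(10, 0, 0)), vdw = c(1.5, 1.5),
             mass = c(1, 1))
  pr <- minimal_projection_area(st, 0.05)
  expect_equal(pr$mpa, pi * 1.5^2, tolerance = 0.005 * pi * 1.5^2)
  expect_equal(sort(pr$areas)[2], 2 * pi * 1.5^2,
               tolerance = 0.005 * 2 * pi * 1.5^2)
})

test_that("MPA matches the closed-form two-circle union within 0.5%", {
  st <- list(xyz = rbind(c(0, 0, 0), c(2, 0, 0)), vdw = c(1.7, 1.7),
             mass = c(1, 1))
  pr <- minimal_projection_area(st, 0.05)
  truth <- oracle_two_circle_union(1.7, 1.7, 2.0)
  # perpendicular-to-bond projections show the lens-corrected union
  expect_equal(max(pr$areas), truth, tolerance = 0.005 * truth)
  expect_equal(pr$mpa, pi * 1.7^2, tolerance = 0.005 * pi * 1.7^2)
})

test_that("MPA converges under grid halving and respects union bounds", {
  s <- make_structure("ring", 8, size = 2.2, element = "N", metal = "Cu")
  a1 <- minimal_projection_area(s, 0.05)
  a2 <- minimal_projection_area(s, 0.025)
  expect_lt(abs(a1$mpa - a2$mpa) / a2$mpa, 0.002)
  biggest_disk <- pi * max(s$vdw)^2
  expect_gte(a1$mpa, biggest_disk * (1 - 0.005))
  expect_lte(a1$mpa, sum(pi * s$vdw^2))
  expect_error(minimal_projection_area(s, -0.1), "positive")
})

test_that("Kabsch RMSD is zero on rigid copies and symmetric", {
  set.seed(31)
  A <- matrix(rnorm(30), 10, 3)
  B <- A %*% random_rotation_matrix() +
    matrix(rep(runif(3, -5, 5), each = 10), 10, 3)
  expect_equal(kabsch_rmsd(A, B), 0, tolerance = 1e-9)
  C <- A + matrix(rnorm(30, 0, 0.3), 10, 3)
  expect_equal(kabsch_rmsd(A, C), kabsch_rmsd(C, A), tolerance = 1e-9)
  expect_warning(kabsch_rmsd(A[1:2, ], C[1:2, ]), "translation-only")
})

test_that("Kabsch RMSD agrees with a multi-start SO(3) search oracle", {
  set.seed(13)
  A <- matrix(rnorm(30), 10, 3)
  B <- A %*% random_rotation_matrix() + matrix(rnorm(30, 0, 0.4), 10, 3)
  expect_equal(kabsch_rmsd(A, B), oracle_min_rmsd(A, B), tolerance = 1e-3)
})

test_that("trajectory morphology summarises static and permuted frames", {
  s <- make_structure("ring", 8, size = 2.2, element = "N", metal = "Cu")
  tr <- make_trajectory(s$xyz, s, n_frames = 10, jitter_sigma = 0)
  m <- trajectory_morphology(tr, grid_resolution = 0.1)
  expect_equal(nrow(m$per_frame), 10L)
  expect_true(all(m$summary$sd == 0))

  tr2 <- make_trajectory(s$xyz, s, n_frames = 12, jitter_sigma = 0.1, seed = 3)
  perm <- trajectory(tr2$topology, rev(tr2$frames))
  m1 <- trajectory_morphology(tr2, mpa = FALSE)
  m2 <- trajectory_morphology(perm, mpa = FALSE)
  expect_equal(m1$summary$mean, m2$summary$mean, tolerance = 1e-12)
})

test_that("morphology descriptors are invariant under rigid motions", {
  set.seed(77)
  s <- make_structure("random_cloud", 20, size = 3, seed = 8)
  tr <- make_trajectory(s$xyz, s, n_frames = 5, jitter_sigma = 0.1, seed = 2)
  rotated <- trajectory(tr$topology, lapply(tr$frames, function(f)
    sweep(f %*% random_rotation_matrix(), 2, runif(3, -10, 10), `+`)))
  m1 <- trajectory_morphology(tr, grid_resolution = 0.05)
  m2 <- trajectory_morphology(rotated, grid_resolution = 0.05)
  for (col in c("rg", "asphericity", "acylindricity", "kappa2"))
    expect_equal(m2$per_frame[[col]], m1$per_frame[[col]], tolerance = 1e-6)
  # the rasterised MPA is grid-aligned, so allow the grid tolerance
  expect_equal(m2$per_frame$mpa, m1$per_frame$mpa, tolerance = 0.005)
})

test_that("kappa2 spans [0,1] with exact collinear and cubic limits", {
  set.seed(19)
  for (rep in 1:200) {
    coords <- matrix(rnorm(3 * sample(4:30, 1)), ncol = 3)
    k <- gyration_descriptors(coords, mass_weighted = FALSE)$kappa2
    expect_true(k >= 0 && k <= 1)
  }
  coll <- cbind(seq(0, 5, length.out = 7), 2 * seq(0, 5, length.out = 7),
                -seq(0, 5, length.out = 7))
  expect_equal(gyration_descriptors(coll, mass_weighted = FALSE)$kappa2, 1,
               tolerance = 1e-12)
  tetra <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  expect_equal(gyration_descriptors(tetra, mass_weighted = FALSE)$kappa2, 0,
               tolerance = 1e-12)
})
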