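# Seminario force-constant extraction against analytic harmonic Hessians.

test_that("a diatomic spring constant is recovered to 1e-6 relative", {
  geom <- rbind(c(0, 0, 0), c(1.5, 0, 0))
  h <- make_harmonic_hessian(geom, bonds = data.frame(i = 1, j = 2, k = 500))
  bc <- bond_constant(h, 1, 2)
  expect_equal(bc$k_bond, 500, tolerance = 1e-6)
  expect_equal(bc$r_eq, 1.5, tolerance = 1e-12)
  expect_error(bond_constant(h, 1, 1), "differ")
})

test_that("bond recovery is invariant under rigid rotation of the system", {
  set.seed(3)
  geom <- rbind(c(0, 0, 0), c(1.5, 0, 0))
  h <- make_harmonic_hessian(geom, bonds = data.frame(i = 1, j = 2, k = 500))
  for (rep in 1:5) {
    R <- random_rotation_matrix()
    # rotate geometry and Hessian blocks consistently: H' = (I x R) H (I x R)^T
    big <- matrix(0, 6, 6)
    big[1:3, 1:3] <- R; big[4:6, 4:6] <- R
    h2 <- cartesian_hessian(big %*% h$matrix %*% t(big), geom %*% t(R))
    expect_equal(bond_constant(h2, 1, 2)$k_bond, 500, tolerance = 1e-6)
  }
})

test_that("spring-network bond constants match their generators within 1%", {
  # bent triatomic with unequal springs, plus an angle term as interference
  geom <- rbind(c(2, 0, 0), c(0, 0, 0), c(-0.6, 1.9, 0))
  h <- make_harmonic_hessian(
    geom,
    bonds = data.frame(i = c(2, 2), j = c(1, 3), k = c(400, 650)),
    angles = data.frame(i = 1, j = 2, k = 3, k_theta = 120))
  expect_equal(bond_constant(h, 2, 1)$k_bond, 400, tolerance = 0.01)
  expect_equal(bond_constant(h, 2, 3)$k_bond, 650, tolerance = 0.01)
})

test_that("ij and ji block estimates coincide when the block is symmetric", {
  # a pure bond term gives a symmetric (normal) interatomic block, so the
  # right eigenvectors of the ij and ji blocks agree; with bending terms the
  # block is non-normal and only the averaged estimate is meaningful
  geom <- rbind(c(0.3, -0.2, 0.5), c(1.7, 0.9, -0.4))
  h <- make_harmonic_hessian(geom, bonds = data.frame(i = 1, j = 2, k = 777))
  u <- geom[2, ] - geom[1, ]
  u <- u / sqrt(sum(u^2))
  k_ij <- radchel:::.eigen_projection(-radchel:::.block(h$matrix, 1, 2), u)
  k_ji <- radchel:::.eigen_projection(-radchel:::.block(h$matrix, 2, 1), u)
  expect_equal(k_ij, k_ji, tolerance = 1e-9)
  expect_equal(k_ij, 777, tolerance = 1e-9)
})

test_that("an isolated right-angle bend needs the coupling correction", {
  geom <- rbind(c(2, 0, 0), c(0, 0, 0), c(0, 2, 0))
  h <- make_harmonic_hessian(geom,
                             angles = data.frame(i = 1, j = 2, k = 3,
                                                 k_theta = 100))
  # plain compliance series halves an isolated angle spring at 90 degrees
  plain <- angle_constant(h, 1, 2, 3)
  expect_equal(plain$k_angle, 50, tolerance = 1e-9)
  expect_equal(plain$theta_eq, 90, tolerance = 1e-9)
  corrected <- angle_constant(h, 1, 2, 3, coupling_correction = TRUE)
  expect_equal(corrected$k_angle, 100, tolerance = 0.02)
})

test_that("the isolated-bend recovery factor is (1 - cos(theta))/2", {
  for (theta in c(75, 104.5, 120, 160)) {
    t <- theta * pi / 180
    geom <- rbind(c(1.8, 0, 0), c(0, 0, 0), 1.8 * c(cos(t), sin(t), 0))
    h <- make_harmonic_hessian(geom,
                               angles = data.frame(i = 1, j = 2, k = 3,
                                                   k_theta = 80))
    expect_equal(angle_constant(h, 1, 2, 3)$k_angle,
                 80 * (1 - cos(t)) / 2, tolerance = 1e-8)
  }
})

test_that("on a full bonded Hessian the plain series lands near k_theta", {
  geom <- rbind(c(2, 0, 0), c(0, 0, 0), c(0, 2, 0))
  h <- make_harmonic_hessian(
    geom,
    bonds = data.frame(i = c(2, 2), j = c(1, 3), k = c(400, 400)),
    angles = data.frame(i = 1, j = 2, k = 3, k_theta = 100))
  expect_equal(angle_constant(h, 1, 2, 3)$k_angle, 100, tolerance = 0.05)
})

test_that("angle recovery is rotation invariant and arm-symmetric", {
  set.seed(7)
  geom <- rbind(c(2, 0, 0), c(0, 0, 0), c(0, 2, 0))
  h <- make_harmonic_hessian(geom,
                             angles = data.frame(i = 1, j = 2, k = 3,
                                                 k_theta = 100))
  k0 <- angle_constant(h, 1, 2, 3, coupling_correction = TRUE)$k_angle
  for (rep in 1:5) {
    R <- random_rotation_matrix()
    big <- matrix(0, 9, 9)
    for (a in 0:2) big[3 * a + 1:3, 3 * a + 1:3] <- R
    h2 <- cartesian_hessian(big %*% h$matrix %*% t(big), geom %*% t(R))
    expect_equal(angle_constant(h2, 1, 2, 3, coupling_correction = TRUE)$k_angle,
                 k0, tolerance = 1e-6)
  }
  swapped <- angle_constant(h, 3, 2, 1, coupling_correction = TRUE)
  expect_equal(swapped$k_angle, k0, tolerance = 1e-9)
  expect_error(angle_constant(h, 1, 2, 2), "distinct")
  lin <- make_harmonic_hessian(rbind(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0)),
                               bonds = data.frame(i = c(1, 2), j = c(2, 3),
                                                  k = c(100, 100)))
  expect_error(angle_constant(lin, 1, 2, 3), "collinear")
})

test_that("frcmod fragments are fixed-decimal and round-trip", {
  bonds <- data.frame(type_i = "M", type_j = "O", k_bond = 512.3456,
                      r_eq = 2.12345)
  angles <- data.frame(type_i = "O", type_j = "M", type_k = "O",
                       k_angle = 97.531, theta_eq = 91.2345)
  txt <- write_frcmod_fragment(bonds, angles)
  expect_true(any(grepl("^BOND$", txt)) && any(grepl("^ANGLE$", txt)))
  expect_false(any(grepl("[eE]\\+", txt)))   # no scientific notation
  p <- withr::local_tempfile(fileext = ".frcmod")
  write_frcmod_fragment(bonds, angles, path = p)
  back <- read_frcmod_fragment(p)
  expect_equal(back$bonds$k_bond, 512.35)      # 2-decimal force constants
  expect_equal(back$bonds$r_eq, 2.123)         # 3-decimal equilibria
  expect_equal(back$angles$k_angle, 97.53)
  expect_error(write_frcmod_fragment(NULL, NULL), "no force constants")
  expect_error(write_frcmod_fragment(
    data.frame(type_i = NA, type_j = "O", k_bond = 1, r_eq = 1)), "labels")
})
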