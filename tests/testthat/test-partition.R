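test_that("Hessian spectra classify rigid, single-body and floppy clusters", {
  sys <- toy_chiral_system(E_b = 2)
  sp <- hessian_spectrum(sys$dimer, sys$interactions, sys$repulsion)
  expect_equal(sp$zero_mode_count, 6L)
  expect_equal(sp$ndof, 12L)
  expect_true(all(sp$eigenvalues[7:12] > 0))

  # eigenvalues match a finite-difference Hessian oracle. At the exact
  # minimum the attraction has an |u|^3 term (Richardson-extrapolated away)
  # and the contact repulsion a (d-r)^2.5 kink that contributes nothing to
  # the true Hessian, so the oracle differences the attraction only.
  ev_h <- function(h) {
    sort(eigen(fd_hessian(sys$dimer, sys$interactions, NULL, h = h),
               symmetric = TRUE, only.values = TRUE)$values)
  }
  ev_fd <- 2 * ev_h(1e-4) - ev_h(2e-4)
  expect_equal(sp$eigenvalues[7:12], ev_fd[7:12], tolerance = 1e-5)

  # a single monomer is all zero modes
  spm <- hessian_spectrum(sys$monomer_L_structure, sys$interactions,
                          sys$repulsion)
  expect_equal(spm$zero_mode_count, 6L)

  # one patch pair leaves a rotation about the patch axis: floppy
  sys1 <- toy_chiral_system(E_b = 2, n_patches = 1)
  expect_error(hessian_spectrum(sys1$dimer, sys1$interactions, sys1$repulsion),
               class = "assemblyyield_floppy_cluster")

  # gradient precondition is enforced
  off <- displace_structure(sys$dimer, rep(0.05, 12))
  expect_error(hessian_spectrum(off, sys$interactions, sys$repulsion),
               class = "assemblyyield_not_at_minimum")
})

test_that("the overlapping spherical dimer has eigenvalues 2 E0 alpha^2 in the relative chart", {
  sd <- spherical_dimer_system(E_b = 3, alpha = 5)
  sp <- hessian_spectrum(sd$dimer, sd$interactions, chart = "relative")
  expect_equal(sp$eigenvalues, rep(2 * 3 * 25, 3), tolerance = 1e-10)
  expect_equal(sp$zero_mode_count, 0L)

  # block chart: 3 translational zeros and 3 modes at 4 E0 alpha^2, with a
  # compensating 2^{3/2} center-of-mass Jacobian (same Z either way)
  spb <- hessian_spectrum(sd$dimer, sd$interactions)
  expect_equal(spb$zero_mode_count, 3L)
  expect_equal(spb$eigenvalues[4:6], rep(4 * 3 * 25, 3), tolerance = 1e-10)
})

test_that("vibrational factors follow prod sqrt(2 pi / beta w^2)", {
  sys <- toy_chiral_system(E_b = 2)
  spm <- hessian_spectrum(sys$monomer_L_structure, sys$interactions,
                          sys$repulsion)
  expect_equal(vibrational_Z(spm, beta = 1), 0)   # empty product

  # one mode with w^2 = 2 pi / beta contributes a unit factor
  fake <- structure(list(eigenvalues = c(0, 2 * pi / 1.3),
                         zero_mode_count = 1L), class = "hessian_spectrum")
  expect_equal(vibrational_Z(fake, beta = 1.3), 0)

  # spherical dimer (relative chart): (pi / (beta E0))^{3/2} alpha^{-3}
  sd <- spherical_dimer_system(E_b = 3, alpha = 5)
  sp <- hessian_spectrum(sd$dimer, sd$interactions, chart = "relative")
  beta <- 1.7
  expect_equal(vibrational_Z(sp, beta),
               1.5 * log(pi / (beta * 3)) - 3 * log(5), tolerance = 1e-12)
})

test_that("the center-of-mass map acts by translation, rotation and vibration", {
  sys <- toy_chiral_system(E_b = 2)
  sp <- hessian_spectrum(sys$dimer, sys$interactions, sys$repulsion)
  map <- build_com_map(sys$dimer, sp)

  t0 <- c(0.3, -1, 2)
  moved <- com_map_apply(map, q_c = t0)
  for (k in 1:2) {
    expect_equal(moved$blocks[[k]]$pose$position,
                 sys$dimer$blocks[[k]]$pose$position + t0)
    expect_equal(moved$blocks[[k]]$pose$orientation,
                 sys$dimer$blocks[[k]]$pose$orientation)
  }

  q <- axis_angle_quat(c(1, 1, 0), 0.8)
  rot <- com_map_apply(map, q_quat = q)
  R <- quat_to_rotmat(q); com <- center_of_mass(sys$dimer)
  for (k in 1:2) {
    expect_equal(rot$blocks[[k]]$pose$position,
                 as.numeric(com + R %*% (sys$dimer$blocks[[k]]$pose$position - com)),
                 tolerance = 1e-12)
  }
  expect_equal(cluster_energy(rot, sys$interactions, sys$repulsion),
               cluster_energy(sys$dimer, sys$interactions, sys$repulsion),
               tolerance = 1e-10)

  # a small displacement along one eigenmode raises the energy by w^2 xi^2 / 2
  xi <- rep(0, 6); xi[3] <- 1e-4
  w2 <- sp$eigenvalues[6 + 3]
  e <- cluster_energy(com_map_apply(map, xi = xi), sys$interactions,
                      sys$repulsion) -
    cluster_energy(sys$dimer, sys$interactions, sys$repulsion)
  expect_equal(e, 0.5 * w2 * 1e-8, tolerance = 1e-3)
})

test_that("planar dimer Jacobians match the closed forms", {
  for (phi in c(pi / 7, pi / 5, 0.9)) {
    expect_equal(planar_dimer_jacobian(a = 1, phi = phi, oriented = TRUE),
                 2 * sqrt(2) * sqrt(cos(phi)^2 + 1), tolerance = 1e-8)
    # without rotational degrees of freedom: J = 2 sqrt(2) a cos(phi),
    # equal to N * sqrt(I) with I the unit-mass moment of inertia
    a <- 1.4
    J <- planar_dimer_jacobian(a = a, phi = phi, oriented = FALSE)
    expect_equal(J, 2 * sqrt(2) * a * cos(phi), tolerance = 1e-8)
    I <- 2 * (a * cos(phi))^2
    expect_equal(J, 2 * sqrt(I), tolerance = 1e-8)
  }
  # independence of the spring constant
  expect_equal(planar_dimer_jacobian(1, 0.5, k = 1),
               planar_dimer_jacobian(1, 0.5, k = 17), tolerance = 1e-9)
})

test_that("3D Jacobian of isotropic clusters equals sqrt(N^3 det I), any orientation", {
  for (pos in list(tri_positions(), tet_positions())) {
    sys <- make_iso_cluster(pos)
    sp <- hessian_spectrum(sys$structure, sys$interactions)
    map <- build_com_map(sys$structure, sp)
    N <- nrow(pos)
    closed <- sqrt(N^3 * det(inertia_tensor(sys$structure)))
    expect_equal(jacobian_det(map), closed, tolerance = 1e-10)
    qs <- sample_uniform_orientations(5, 3)
    for (i in 1:5) {
      expect_equal(jacobian_det(map, qs[i, ]), closed, tolerance = 1e-9)
    }
  }
})

test_that("Monte Carlo rotational integrals are normalized, scaled and seeded correctly", {
  sys <- make_iso_cluster(tri_positions())
  sp <- hessian_spectrum(sys$structure, sys$interactions)
  map <- build_com_map(sys$structure, sp)
  # constant J integrates to exactly 8 pi^2 * J with vanishing error
  mc <- rotational_Z_mc(map, mc_config(500, 4))
  expect_equal(mc$Jtilde, 8 * pi^2 * jacobian_det(map), tolerance = 1e-10)
  expect_lt(mc$stderr, 1e-8 * mc$Jtilde)

  # oriented system: stderr ~ 1/sqrt(n), seeds agree within 3 sigma
  toy <- toy_chiral_system(E_b = 2)
  spd <- hessian_spectrum(toy$dimer, toy$interactions, toy$repulsion)
  mapd <- build_com_map(toy$dimer, spd)
  m1 <- rotational_Z_mc(mapd, mc_config(1000, 10))
  m4 <- rotational_Z_mc(mapd, mc_config(4000, 10))
  expect_equal(m1$stderr / m4$stderr, 2, tolerance = 0.5)
  mA <- rotational_Z_mc(mapd, mc_config(4000, 21))
  mB <- rotational_Z_mc(mapd, mc_config(4000, 22))
  expect_lt(abs(mA$Jtilde - mB$Jtilde),
            3 * sqrt(mA$stderr^2 + mB$stderr^2))
  expect_equal(rotational_Z_mc(mapd, mc_config(1000, 10))$Jtilde, m1$Jtilde)
})

test_that("inertia-route rotational factors cover nonlinear, linear and point clusters", {
  tri <- make_iso_cluster(tri_positions())
  I <- inertia_tensor(tri$structure)
  expect_equal(rotational_Z_inertia(tri$structure),
               log(8 * pi^2 * sqrt(det(I))) + 1.5 * log(3), tolerance = 1e-12)

  # linear dimer at separation r0: 4 pi I_perp (I_perp = r0^2/2) times the
  # center-of-mass factor; validated against the exact radial Laplace form
  r0 <- 1.2; Eb <- 4; al <- 5; V <- 9000; beta <- 1
  blk <- function(nm, ty) building_block(nm, c(0, 0, 0), 1,
                                         patches = c(0, 0, 0),
                                         patch_types = ty, isotropic = TRUE)
  tbl <- interaction_table(data.frame(type_a = "sa", type_b = "sb",
                                      p_contact = 1),
                           epsilon = Eb, alpha = al, r0 = r0)
  dimer <- cluster_structure(list(
    list(block = blk("A", "sa"), pose = pose(c(0, 0, 0))),
    list(block = blk("B", "sb"), pose = pose(c(0, 0, r0)))), label = "AB")
  expect_equal(rotational_Z_inertia(dimer),
               log(4 * pi * r0^2 / 2) + 1.5 * log(2), tolerance = 1e-12)
  zd <- compute_partition_function(dimer, tbl, beta = beta, V = V)
  zA <- compute_partition_function(cluster_structure(
    list(list(block = blk("A", "sa"), pose = pose())), label = "A"), V = V)
  Upp <- morse_smoothed(r0, morse_params(Eb, al, r0 = r0), deriv = 2)
  radial_laplace <- 4 * pi * r0^2 * exp(beta * Eb) *
    sqrt(2 * pi / (beta * Upp)) / V
  expect_equal(exp(zd$ln_Z - 2 * zA$ln_Z), radial_laplace, tolerance = 1e-10)

  # point-like cluster: no rotational volume beyond the COM factor
  sd <- spherical_dimer_system()
  expect_equal(rotational_Z_inertia(sd$dimer), 1.5 * log(2))

  # mixed oriented/isotropic is rejected
  toy <- toy_chiral_system()
  mixed <- cluster_structure(list(
    toy$dimer$blocks[[1]],
    list(block = blk("A", "sa"), pose = pose(c(3, 0, 0)))))
  expect_error(rotational_Z_inertia(mixed), "Monte Carlo")
})

test_that("symmetry numbers are counted by brute force over proper rotations", {
  sd <- spherical_dimer_system()
  expect_equal(symmetry_number(sd$dimer), 1)   # distinct species

  blk <- building_block("S", c(0, 0, 0), 1, isotropic = TRUE)
  homo <- cluster_structure(list(
    list(block = blk, pose = pose(c(0, 0, 0))),
    list(block = blk, pose = pose(c(1, 0, 0)))))
  expect_equal(symmetry_number(homo), 2)

  tri <- make_iso_cluster(tri_positions())
  expect_equal(symmetry_number(tri$structure), 6)
  tet <- make_iso_cluster(tet_positions())
  expect_equal(symmetry_number(tet$structure), 12)

  # a scalene triangle has no nontrivial symmetry
  sc <- make_iso_cluster(rbind(c(0, 0, 0), c(1, 0, 0), c(0.3, 0.9, 0)))
  expect_equal(symmetry_number(sc$structure), 1)

  # oriented clusters fall back to the stored value, with a warning
  toy <- toy_chiral_system()
  expect_warning(s <- symmetry_number(toy$dimer), "user-supplied")
  expect_equal(s, 1)
})

test_that("assemble_Z composes the factorization and is linear in V", {
  z1 <- assemble_Z(E0 = -2, ln_Zvib = 0.5, Jtilde = 10, sigma = 2, V = 100,
                   beta = 1.5)
  expect_equal(z1$ln_Z, 3 + log(100) + log(10) - log(2) + 0.5)
  z2 <- assemble_Z(E0 = -2, ln_Zvib = 0.5, Jtilde = 10, sigma = 2, V = 200,
                   beta = 1.5)
  expect_equal(z2$ln_Z - z1$ln_Z, log(2))

  # monomer: Z = V * orientation volume
  sys <- toy_chiral_system()
  zm <- compute_partition_function(sys$monomer_L_structure, V = 50)
  expect_equal(zm$ln_Z, log(50) + log(8 * pi^2))

  # spherical overlap dimer assembled from parts reproduces the closed-form
  # Laplace ratio exactly
  sd <- spherical_dimer_system(E_b = 3, alpha = 5)
  V <- 18000
  zd <- compute_partition_function(sd$dimer, sd$interactions, V = V)
  zb <- compute_partition_function(sd$monomer_b, V = V)
  expect_equal(exp(zd$ln_Z - 2 * zb$ln_Z),
               spherical_dimer_laplace_ratio(morse_params(3, 5), 1, V),
               tolerance = 1e-12)
})

test_that("partition functions are invariant under rigid motion of the input", {
  toy <- toy_chiral_system(E_b = 2)
  mc <- mc_config(3000, 17)
  z0 <- compute_partition_function(toy$dimer, toy$interactions, toy$repulsion,
                                   mc = mc, sigma = 1)
  q <- axis_angle_quat(c(2, -1, 1), 1.1)
  moved <- transform_structure(toy$dimer, q, c(4, 5, -6))
  z1 <- compute_partition_function(moved, toy$interactions, toy$repulsion,
                                   mc = mc, sigma = 1)
  bound <- 3 * sqrt((z0$mc_stderr / z0$Jtilde)^2 +
                      (z1$mc_stderr / z1$Jtilde)^2)
  expect_lt(abs(z1$ln_Z - z0$ln_Z), bound + 1e-6)

  # isotropic route is exactly invariant
  tri <- make_iso_cluster(tri_positions())
  zi0 <- compute_partition_function(tri$structure, tri$interactions)
  moved_tri <- transform_structure(tri$structure, q, c(1, 2, 3))
  zi1 <- compute_partition_function(moved_tri, tri$interactions)
  expect_equal(zi1$ln_Z, zi0$ln_Z, tolerance = 1e-9)
})

test_that("the radial quartic correction sits between Laplace and exact", {
  p <- morse_params(30, 5)
  ex <- spherical_dimer_exact_ratio(p, 1, 1)
  la <- spherical_dimer_laplace_ratio(p, 1, 1)
  q4 <- laplace4_radial_Z(p, 1, 1)
  expect_gt(q4, min(ex, la)); expect_lt(q4, max(ex, la))

  # quadrature convergence
  expect_equal(laplace4_radial_Z(p, 1, 1, rel_tol = 1e-8),
               laplace4_radial_Z(p, 1, 1, rel_tol = 1e-12),
               tolerance = 1e-8)

  # Laplace asymptotics: the ratio to the second-order value approaches 1
  # from above (the residual decays like (beta E0)^{-1/2})
  resid <- vapply(c(100, 1000, 10000), function(bE) {
    pp <- morse_params(bE, 5)
    exp(laplace4_radial_Z(pp, 1, 1, log = TRUE) -
          spherical_dimer_laplace_ratio(pp, 1, 1, log = TRUE)) - 1
  }, numeric(1))
  expect_true(all(diff(resid) < 0))
  expect_lt(resid[3], 0.03)
})

test_that("soft modes integrate over the bond-topology window", {
  # square of sticky spheres: 4 bonds, flexes; the short range (8/alpha =
  # 1/3) keeps the diagonals outside the cutoff r0 + 8/alpha
  a <- 1
  sq <- make_iso_cluster(rbind(c(0, 0, 0), c(a, 0, 0), c(a, a, 0), c(0, a, 0)),
                         E_b = 2, alpha = 24, r0 = a)
  expect_error(hessian_spectrum(sq$structure, sq$interactions),
               class = "assemblyyield_floppy_cluster")
  sp <- hessian_spectrum(sq$structure, sq$interactions,
                         soft_modes = "integrate")
  expect_gte(sp$soft_mode_count, 1L)
  vols <- soft_mode_volumes(sq$structure, sq$interactions, sp, beta = 1)
  expect_length(vols, sp$soft_mode_count)
  expect_true(all(is.finite(vols)))
  # windows are bounded: the diagonals enter the cutoff under shear
  expect_true(all(vols < log(4)))
})
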