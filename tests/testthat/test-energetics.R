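test_that("Coulomb pair energy: closed form, symmetry, contract", {
  expect_equal(coulomb_pair(0, 0.7, 3), 0)
  expect_equal(coulomb_pair(1, 1, 1), 332.0636)
  expect_equal(coulomb_pair(0.3, -0.2, 2.5), -coulomb_pair(0.3, 0.2, 2.5))
  expect_equal(coulomb_pair(0.3, 0.2, 2.5), coulomb_pair(0.2, 0.3, 2.5))
  expect_equal(coulomb_pair(1, 1, 2, eps_in = 2), 332.0636 / 4)
  expect_error(coulomb_pair(1, 1, 0), "rij must be > 0")
})

test_that("LJ pair energy: minimum, zero crossing, contract", {
  # minimum exactly -eps_ij at r = Rmin_ij
  expect_equal(lj_pair(1.9, 0.12, 1.7, 0.08, 1.9 + 1.7),
               -sqrt(0.12 * 0.08))
  expect_equal(lj_pair(1.9, 0, 1.7, 0.3, 2.2), 0)
  # zero at r = Rmin * 2^(-1/6)
  expect_equal(lj_pair(1.9, 0.12, 1.7, 0.08, 3.6 * 2^(-1 / 6)), 0,
               tolerance = 1e-12)
  expect_error(lj_pair(1.9, 0.1, 1.7, 0.1, 0), "rij must be > 0")
})

test_that("effective Born radii: limits and independent HCT oracle", {
  expect_equal(effective_born_radii(matrix(0, 1, 3), 1.5, 0.8), 1.5)
  # two far-apart atoms: descreening vanishes
  xyz2 <- rbind(c(0, 0, 0), c(100, 0, 0))
  r2 <- effective_born_radii(xyz2, c(1.5, 1.7), c(0.8, 0.85))
  expect_equal(r2, c(1.5, 1.7), tolerance = 1e-6)

  # 5-atom cluster, incl. one pair with overlapping descreening spheres
  xyz <- rbind(c(0, 0, 0), c(1.6, 0, 0), c(0, 2.1, 0),
               c(-1.2, -0.8, 1.0), c(0.5, 0.4, -2.4))
  rho <- c(1.5, 1.2, 1.7, 1.3, 1.6)
  scr <- c(0.8, 0.85, 0.72, 0.9, 0.78)
  expect_equal(effective_born_radii(xyz, rho, scr),
               oracle_hct_radii(xyz, rho, scr), tolerance = 1e-10)

  # larger random cluster against the oracle
  set.seed(3)
  n <- 20
  xyzr <- matrix(rnorm(3 * n, sd = 3), n, 3)
  rhor <- runif(n, 1.1, 2.0)
  scrr <- runif(n, 0.7, 0.9)
  expect_equal(effective_born_radii(xyzr, rhor, scrr),
               oracle_hct_radii(xyzr, rhor, scrr), tolerance = 1e-10)
})

test_that("GB polar energy: Born ion, null cases, oracle equality", {
  s <- gb_settings()
  born <- gb_polar_energy(matrix(0, 1, 3), charge = 1, gb_radius = 2.0,
                          gb_screen = 0.8, settings = s)
  expect_equal(born$total, -166.0318 * (1 - 1 / 78.5) / 2.0,
               tolerance = 1e-6)
  expect_equal(born$radii, 2.0)

  xyz <- rbind(c(0, 0, 0), c(2.5, 0, 0), c(0, 3, 1))
  zero <- gb_polar_energy(xyz, charge = c(0, 0, 0),
                          gb_radius = c(1.5, 1.4, 1.6),
                          gb_screen = c(0.8, 0.8, 0.8), settings = s)
  expect_equal(zero$total, 0)

  # no dielectric contrast -> energy tends to 0
  s_eq <- gb_settings(eps_in = 1, eps_out = 1 + 1e-9)
  near0 <- gb_polar_energy(xyz, charge = c(0.5, -0.3, 0.4),
                           gb_radius = c(1.5, 1.4, 1.6),
                           gb_screen = c(0.8, 0.8, 0.8), settings = s_eq)
  expect_lt(abs(near0$total), 1e-6)

  g <- gb_polar_energy(xyz, charge = c(0.5, -0.3, 0.4),
                       gb_radius = c(1.5, 1.4, 1.6),
                       gb_screen = c(0.8, 0.8, 0.8), settings = s)
  expect_equal(g$total, oracle_gb_total(xyz, c(0.5, -0.3, 0.4), g$radii),
               tolerance = 1e-10)
  expect_equal(sum(g$pair), g$total, tolerance = 1e-12)
  expect_equal(g$pair, t(g$pair), tolerance = 1e-12)
})

test_that("SASA: sphere closed form, no occlusion, buried atom", {
  a1 <- sasa(matrix(0, 1, 3), 1.5)
  expect_equal(a1, 4 * pi * 2.9^2, tolerance = 0.01)
  # lattice refinement converges toward the closed form
  err <- function(np) abs(sasa(matrix(0, 1, 3), 1.5, sasa_points = np) -
                            4 * pi * 2.9^2)
  expect_lte(err(3840), err(240))

  # two spheres farther apart than the sum of expanded radii: no occlusion
  xyz <- rbind(c(0, 0, 0), c(10, 0, 0))
  a2 <- sasa(xyz, c(1.5, 1.2))
  expect_equal(a2[1], 4 * pi * 2.9^2, tolerance = 0.01)
  expect_equal(a2[2], 4 * pi * 2.6^2, tolerance = 0.01)

  # atom caged by neighbours covering its whole expanded sphere
  shell <- fibonacci_sphere_pts(26) * 2.0
  cage <- rbind(c(0, 0, 0), shell)
  radii <- c(1.2, rep(2.0, 26))
  a3 <- sasa(cage, radii)
  expect_equal(a3[1], 0)
  # dense-lattice oracle confirms full burial
  expect_equal(sasa(cage, radii, sasa_points = 5000L)[1], 0)

  # determinism for a fixed lattice
  expect_identical(sasa(cage, radii), a3)
})

test_that("ligand-residue decomposition conserves intermolecular totals", {
  ens <- get_toy(n_snapshots = 3L)
  rows <- decompose_ligand_residue(ens)
  p <- ens$params
  lig <- which(ens$atoms$segment == "ligand")
  rec <- which(ens$atoms$segment == "receptor")
  for (m in 1:3) {
    xyz <- ens$coords[[m]]
    mm <- oracle_intermolecular_mm(xyz, p$charge, p$lj_rmin_half,
                                   p$lj_epsilon, lig, rec)
    born <- oracle_hct_radii(xyz, p$gb_radius, p$gb_screen)
    gbx <- oracle_gb_cross(xyz, p$charge, born, lig, rec)
    sub <- rows[rows$snapshot == m, ]
    expect_equal(sum(sub$ele), mm$ele, tolerance = 1e-6)
    expect_equal(sum(sub$vdw), mm$vdw, tolerance = 1e-6)
    expect_equal(sum(sub$gb_polar), gbx, tolerance = 1e-6)
    expect_equal(sub$total, sub$ele + sub$vdw + sub$gb_polar,
                 tolerance = 1e-9)
  }
})

test_that("two-body decomposition equals hand-summed pair terms", {
  # one ligand atom + one single-atom residue
  atoms <- data.frame(atom_id = 1:2, name = c("CA", "L1"),
                      chain = c("A", "L"), resid = c(1L, 2L),
                      resname = c("GLY", "LIG"),
                      stringsAsFactors = FALSE)
  params <- data.frame(atom_id = 1:2, charge = c(0.4, -0.3),
                       lj_rmin_half = c(1.9, 1.7),
                       lj_epsilon = c(0.12, 0.08),
                       gb_radius = c(1.5, 1.6), gb_screen = c(0.8, 0.85),
                       atom_type = c("C", "C"), stringsAsFactors = FALSE)
  labels <- data.frame(chain = c("A", "L"), resid = c(1L, 2L),
                       resname = c("GLY", "LIG"), label = c("G1", "LIG"),
                       segment = c("receptor", "ligand"),
                       stringsAsFactors = FALSE)
  xyz <- rbind(c(0, 0, 0), c(3.2, 0, 0))
  ens <- lripscreen:::build_ensemble(atoms, list(xyz), params, labels)
  row <- decompose_ligand_residue(ens)
  expect_equal(row$ele, coulomb_pair(0.4, -0.3, 3.2))
  expect_equal(row$vdw, lj_pair(1.9, 0.12, 1.7, 0.08, 3.2))
  born <- oracle_hct_radii(xyz, params$gb_radius, params$gb_screen)
  expect_equal(row$gb_polar,
               oracle_gb_cross(xyz, params$charge, born, 2L, 1L),
               tolerance = 1e-10)
})

test_that("decomposition is zero for a chargeless, epsilon-free system", {
  ens <- get_toy(n_snapshots = 2L)
  ens$params$charge[] <- 0
  ens$params$lj_epsilon[] <- 0
  rows <- decompose_ligand_residue(ens)
  expect_true(all(rows$ele == 0))
  expect_true(all(rows$vdw == 0))
  expect_true(all(rows$gb_polar == 0))
  expect_true(all(rows$total == 0))
})

test_that("energies are invariant under rigid rotation + translation", {
  ens <- get_toy(n_snapshots = 2L)
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
  ens2 <- ens
  ens2$coords <- lapply(ens$coords,
                        function(x) x %*% t(rot) +
                          matrix(c(5, -3, 11), nrow(x), 3, byrow = TRUE))
  r1 <- decompose_ligand_residue(ens)
  r2 <- decompose_ligand_residue(ens2)
  expect_equal(r2$total, r1$total, tolerance = 1e-6)
  expect_equal(r2$ele, r1$ele, tolerance = 1e-6)
})

test_that("empty ligand segment is rejected", {
  ens <- get_toy(n_snapshots = 2L)
  ens$atoms$segment[] <- "receptor"
  expect_error(decompose_ligand_residue(ens), "empty ligand")
})
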