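test_that("restraint energy has its minimum -K at the center and decays to zero", {
  for (kind in c("bend", "dihedral")) {
    ctr <- if (kind == "bend") 96 else 60
    spec <- restraint_spec(kind, ctr, depth_k = 50)
    expect_equal(restraint_energy(ctr, spec), -50)
    xs <- if (kind == "bend") seq(1, 179, by = 1) else seq(-179, 180, by = 1)
    vals <- restraint_energy(xs, spec)
    expect_true(all(vals >= -50))
    expect_true(all(vals[abs(xs - ctr) > 0.5] > -50))
  }
  # far-from-center evaluation: the opposite mode center is effectively free
  spec <- restraint_spec("bend", 96, width_sigma = 14, depth_k = 50)
  expect_equal(restraint_energy(124, spec), -50 * exp(-784 / 14), tolerance = 1e-12)
  expect_lt(abs(restraint_energy(124, spec)), 1e-20)
})

test_that("dihedral periodic images make the well periodic across the boundary", {
  spec <- restraint_spec("dihedral", 60)
  expect_equal(spec$images, c(-300, 420))
  # wrapped coordinates give identical energies through the images
  expect_equal(restraint_energy(-179, spec), restraint_energy(181 - 360, spec))
  # continuity across +/-180
  jump <- abs(restraint_energy(179.9995, spec) - restraint_energy(-179.9995, spec))
  expect_lt(jump, 1e-8)
})

test_that("internal gradient is analytic: zero and odd at the center, matches finite differences", {
  spec <- restraint_spec("bend", 96, depth_k = 50)
  expect_equal(restraint_internal_gradient(96, spec), 0)
  expect_equal(restraint_internal_gradient(101, spec),
               -restraint_internal_gradient(91, spec))
  set.seed(2)
  h <- 1e-4
  for (x in runif(50, 80, 112)) {
    fd <- (restraint_energy(x + h, spec) - restraint_energy(x - h, spec)) / (2 * h)
    expect_equal(restraint_internal_gradient(x, spec), fd,
                 tolerance = 1e-6)
  }
})

test_that("cartesian forces vanish at the restrained pose and obey Newton's third law", {
  chain <- build_ideal_chain(5, 96, 60)
  set <- build_conformation_restraints(5, "helical")
  for (spec in restraint_specs(set)) {
    ef <- cartesian_forces(chain, spec)
    expect_lt(max(abs(ef$forces)), 1e-10)
    expect_equal(ef$energy, -spec$depth, tolerance = 1e-10)
  }
  set.seed(3)
  for (rep in 1:25) {
    P <- random_pose(4)
    for (spec in list(restraint_spec("bend", 96, beads = 1:3),
                      restraint_spec("dihedral", 60, beads = 1:4))) {
      ef <- cartesian_forces(P, spec)
      expect_lt(max(abs(colSums(ef$forces))), 1e-10)
      expect_lt(max(abs(net_torque(P, ef$forces))), 1e-10)
    }
  }
})

test_that("cartesian forces match the finite-difference oracle on random poses", {
  set.seed(4)
  for (rep in 1:50) {
    P <- random_pose(4)
    for (spec in list(restraint_spec("bend", 96, beads = 1:3, depth_k = 30),
                      restraint_spec("dihedral", 100, beads = 1:4, depth_k = 80))) {
      ef <- cartesian_forces(P, spec)
      fd <- fd_forces(P, spec)
      scale <- max(abs(fd), 1e-8)
      expect_lt(max(abs(ef$forces - fd)) / scale, 1e-5)
    }
  }
})

test_that("conformation restraint sets have the right counts, centers and modes", {
  hel <- build_conformation_restraints(30, "helical")
  expect_equal(sum(hel$kind == "bend"), 28)
  expect_equal(sum(hel$kind == "dihedral"), 27)
  expect_true(all(hel$center[hel$kind == "bend"] == 96))
  expect_true(all(hel$center[hel$kind == "dihedral"] == 60))

  ext <- build_conformation_restraints(30, "extended")
  expect_true(all(ext$center[ext$kind == "bend"] == 124))
  expect_true(all(ext$center[ext$kind == "dihedral"] == 100))
  # modes differ only in centers
  expect_equal(as.data.frame(dplyr::select(hel, -center)),
               as.data.frame(dplyr::select(ext, -center)),
               ignore_attr = TRUE)

  minimal <- build_conformation_restraints(3, "extended")
  expect_equal(nrow(minimal), 1)
  expect_equal(minimal$center, 124)
  expect_error(build_conformation_restraints(2, "helical"))
})

test_that("invalid restraint specs are rejected", {
  expect_error(restraint_spec("bend", 96, width_sigma = 0))
  expect_error(restraint_spec("bend", 96, depth_k = -1))
  expect_error(restraint_spec("bend", 190))
  expect_error(restraint_spec("dihedral", 200))
  expect_error(restraint_spec("bend", 96, beads = c(1, 1, 2)))
})

test_that("tabulated export is periodic, centered and numerically consistent", {
  bend <- restraint_spec("bend", 96)
  tb <- export_tabulated_potential(bend, 1)
  expect_equal(nrow(tb), 181)
  expect_equal(tb$x[which.min(tb$V)], 96)

  dih <- restraint_spec("dihedral", 60)
  td <- export_tabulated_potential(dih, 1)
  expect_equal(nrow(td), 361)
  expect_lt(abs(td$V[1] - td$V[361]), 1e-10)

  # column 3 equals the negative central difference of column 2 at 0.1 deg.
  # The truncation error of the central difference is proportional to K, so
  # the absolute 1e-3 consistency bound is checked at K = 5 kJ/mol.
  tf <- export_tabulated_potential(restraint_spec("dihedral", 60, depth_k = 5), 0.1)
  n <- nrow(tf)
  num <- -(tf$V[3:n] - tf$V[1:(n - 2)]) / 0.2
  expect_lt(max(abs(num - tf$minus_dV[2:(n - 1)])), 1e-3)

  expect_error(export_tabulated_potential(bend, 0.7))
})

test_that("written tables round-trip and interpolate the analytic energy", {
  # linear-interpolation error is also proportional to K; checked at K = 5
  spec <- restraint_spec("dihedral", 100, depth_k = 5)
  path <- withr::local_tempfile(fileext = ".xvg")
  export_tabulated_potential(spec, 0.1, path = path)
  tab <- read_tabulated_potential(path)
  xq <- seq(-179.95, 179.95, by = 0.5)  # mid-grid points
  vi <- approx(tab$x, tab$V, xout = xq)$y
  expect_lt(max(abs(vi - restraint_energy(xq, spec))), 1e-3)
})

test_that("restraint config serialization records mode and parameters", {
  set <- build_conformation_restraints(10, "extended", sigma = 14, depth_k = 50)
  path <- withr::local_tempfile(fileext = ".cfg")
  write_restraint_config(set, path)
  lines <- readLines(path)
  expect_true(any(grepl("mode: extended", lines)))
  expect_true(any(grepl("bend_center_deg: 124", lines)))
  expect_true(any(grepl("dihedral_center_deg: 100", lines)))
  expect_true(any(grepl("sigma: 14", lines)))
})
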