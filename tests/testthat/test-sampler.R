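test_that("boltzmann density is normalized, peaked at the center, uniform as K -> 0", {
  spec <- restraint_spec("dihedral", 60, depth_k = 50)
  dens <- boltzmann_density(spec, 310)
  dx <- diff(dens$x)
  integral <- sum(dx * (head(dens$density, -1) + tail(dens$density, -1)) / 2)
  expect_equal(integral, 1, tolerance = 1e-6)
  expect_equal(dens$x[which.max(dens$density)], 60, tolerance = 0.06)

  flat <- boltzmann_density(restraint_spec("bend", 96, depth_k = 1e-9), 310)
  expect_lt(diff(range(flat$density)) / mean(flat$density), 1e-6)
})

test_that("metropolis sampling is deterministic given the seed", {
  spec <- restraint_spec("bend", 124)
  cfg <- sampler_config(310, 5000, 3, seed = 99, burn_in = 100, thinning = 2)
  s1 <- metropolis_sample(spec, cfg)
  s2 <- metropolis_sample(spec, cfg)
  expect_identical(s1$values, s2$values)
  expect_identical(s1$acceptance_rate, s2$acceptance_rate)
})

test_that("a deep well localizes the sampler at the quadrature mean", {
  spec <- restraint_spec("bend", 96, depth_k = 100)
  cfg <- sampler_config(310, 1e5, 2, seed = 17, burn_in = 1000, thinning = 1)
  s <- metropolis_sample(spec, cfg)
  expect_lt(abs(mean(s$values) - quadrature_mean(spec, 310)), 0.5)
  expect_lt(abs(mean(s$values) - 96), 0.5)
})

test_that("metropolis samples match the Boltzmann distribution (KS)", {
  # moderate-n version of the fidelity check, both kinds and modes
  for (case in list(list("bend", 96), list("dihedral", 100))) {
    spec <- restraint_spec(case[[1]], case[[2]], depth_k = 50)
    s <- metropolis_sample(spec, sampler_config(310, 2e5, 3, seed = 21,
                                                burn_in = 2000, thinning = 2))
    expect_lt(ks_against_boltzmann(s, spec, 310), 0.02)
  }
})

test_that("sampled dihedral spread broadens with temperature across the ladder", {
  spec <- restraint_spec("dihedral", 60, depth_k = 50)
  temps <- seq(310, 450, by = 10)
  # common random numbers: same seed at every temperature pairs the estimates
  circ_sd <- vapply(temps, function(T) {
    s <- metropolis_sample(spec, sampler_config(T, 5e4, 3, seed = 31,
                                                burn_in = 2000, thinning = 1))
    th <- s$values * pi / 180
    R <- sqrt(mean(sin(th))^2 + mean(cos(th))^2)
    sqrt(-2 * log(R)) * 180 / pi
  }, 0)
  expect_true(all(diff(circ_sd) > 0))
})

test_that("helical and extended bend samples are separable with non-overlapping intervals", {
  cfg <- sampler_config(310, 2e4, 2, seed = 41, burn_in = 2000, thinning = 1)
  hel <- metropolis_sample(restraint_spec("bend", 96, depth_k = 50), cfg)
  ext <- metropolis_sample(restraint_spec("bend", 124, depth_k = 50), cfg)
  q_hel <- quantile(hel$values, c(0.025, 0.975))
  q_ext <- quantile(ext$values, c(0.025, 0.975))
  expect_lt(q_hel[2], q_ext[1])
})

test_that("brownian dynamics is stationary at zero temperature from the restrained pose", {
  chain <- build_ideal_chain(5, 96, 60)
  set <- build_conformation_restraints(5, "helical")
  traj <- brownian_dynamics(chain, set,
                            config = sampler_config(0, 1000, 1e-4, seed = 1,
                                                    thinning = 100))
  drift <- max(abs(traj$frames[[length(traj$frames)]] - chain_coords(chain)))
  expect_lt(drift, 1e-8)
})

test_that("brownian dynamics is reproducible and samples the restrained bend angle", {
  chain <- build_ideal_chain(4, 96, 60)
  set <- build_conformation_restraints(4, "helical")
  cfg <- sampler_config(310, 1.5e4, 1e-4, seed = 8, burn_in = 5000, thinning = 10)
  t1 <- brownian_dynamics(chain, set, config = cfg)
  t2 <- brownian_dynamics(chain, set, config = cfg)
  expect_identical(t1$frames, t2$frames)

  ic <- trajectory_internal_coords(t1)
  mean_bend <- mean(ic$angle_deg[ic$kind == "bend"])
  target <- quadrature_mean(restraint_spec("bend", 96), 310, sin_jacobian = TRUE)
  expect_lt(abs(mean_bend - target), 1)
  expect_lt(abs(mean_bend - 96), 1)
})

test_that("force blow-up raises an integration error naming the step", {
  chain <- build_ideal_chain(4, 96, 60)
  set <- build_conformation_restraints(4, "helical")
  # absurd time step destabilizes the bond terms
  expect_error(
    brownian_dynamics(chain, set,
                      config = sampler_config(310, 500, 10, seed = 2),
                      force_cap = 1e4),
    class = "cgmelt_integration_error")
})

test_that("sampler config validates its invariants", {
  expect_error(sampler_config(n_steps = 10, burn_in = 10))
  expect_error(sampler_config(step_size = 0))
  expect_error(sampler_config(thinning = 0))
})
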