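test_that("analytic providers pass finite-difference gradient checks", {
  set.seed(67)
  g <- grid_spec(c(4, 3, 2), c(2, 1.5, 1))
  specs <- list(
    analytic_functional(g, "quadratic", a = 2, m_star = 1, kappa_grad = 0.8),
    analytic_functional(g, "double_well", a = 1.3, m1 = 0.5, m2 = 2.5,
                        kappa_grad = 1.1,
                        tilt = array(stats::runif(prod(g$n), -0.1, 0.1), g$n)))
  for (spec in specs) {
    prov <- make_analytic_provider(spec)
    m <- as.vector(rand_field(g, 0, 3)$values)
    mu <- provider_grad(prov, g, m)  # dV * mu
    h <- 1e-6
    for (j in sample(prod(g$n), 6)) {
      mp <- m; mp[j] <- mp[j] + h
      mm <- m; mm[j] <- mm[j] - h
      fd <- (provider_F(prov, g, mp) - provider_F(prov, g, mm)) / (2 * h)
      expect_equal(mu[j], fd, tolerance = 1e-6)
    }
  }
})

test_that("both wells of the double-well functional are stationary", {
  g <- grid_spec(c(5, 1, 1), c(2.5, 1, 1))
  prov <- make_analytic_provider(
    analytic_functional(g, "double_well", a = 2, m1 = 0.5, m2 = 2.5,
                        kappa_grad = 3))
  for (w in c(0.5, 2.5)) {
    mu <- chemical_potential(prov, density_field(g, w))
    expect_equal(max(abs(mu$values)), 0, tolerance = 1e-14)
  }
  q <- make_analytic_provider(analytic_functional(g, "quadratic", a = 1,
                                                  m_star = 1.7))
  expect_equal(max(abs(chemical_potential(q, density_field(g, 1.7))$values)), 0)
})

test_that("the mock sampler inverts the estimator and scales with kappa", {
  g <- grid_spec(c(3, 3, 1), 1)
  prov <- make_analytic_provider(
    analytic_functional(g, "double_well", a = 1, m1 = 0.5, m2 = 2.5))
  # at a stationary field the restrained average equals the target
  p <- umbrella_params()
  samp <- make_mock_sampler(prov, p)
  well <- density_field(g, 2.5)
  expect_equal(restrained_average(samp, well, 5, seed = 1)$values,
               well$values)
  set.seed(71)
  tgt <- rand_field(g, 0.5, 2.5)
  dev1 <- tgt$values -
    restrained_average(make_mock_sampler(prov, umbrella_params(kappa = 50)),
                       tgt, 5, seed = 1)$values
  dev2 <- tgt$values -
    restrained_average(make_mock_sampler(prov, umbrella_params(kappa = 100)),
                       tgt, 5, seed = 1)$values
  expect_equal(dev2, dev1 / 2, tolerance = 1e-12)
})

test_that("bilayer fixtures store exact interface metadata", {
  g <- grid_spec(c(8, 8, 120), c(4, 4, 12))
  f <- make_bilayer_field(g, gap = 1.2, thickness = 3, interface_width = 0.15)
  md <- f$metadata
  expect_equal(md$gap_at_threshold, 1.2, tolerance = 1e-9)
  # plateau density reaches bulk at slab centers (narrow interfaces)
  kc <- which.min(abs(cell_centers(g, 3) - md$z_centers[1]))
  expect_equal(f$values[1, 1, kc], 5, tolerance = 1e-6)
  # step-profile limit puts the crossings exactly at the slab edges
  fs <- make_bilayer_field(g, z_centers = c(3.5, 8.5), thickness = 3,
                           interface_width = 0)
  above <- which(fs$values[1, 1, ] >= 2.2)
  zc <- cell_centers(g, 3)
  expect_true(all(abs(zc[above] - 3.5) <= 1.5 + 1e-9 |
                    abs(zc[above] - 8.5) <= 1.5 + 1e-9))
  expect_error(make_bilayer_field(g, z_centers = c(5, 6), thickness = 3),
               "overlap")
  expect_error(make_bilayer_field(g, gap = 11, thickness = 3), "fit")
})

test_that("vesicle fixtures respect the box-gap-radius constraint", {
  g <- grid_spec(c(45, 45, 45), c(26.31, 26.83, 20.74))
  f <- make_vesicle_pair_field(g, R_v = 9.2, thickness = 3.5, gap = 2.3)
  expect_equal(f$metadata$R_outer_threshold, (20.74 - 2.3) / 2)
  expect_error(make_vesicle_pair_field(g, R_v = 12, thickness = 3.5,
                                       gap = 2.3), "impossible")
  # zero neck radius leaves the base field untouched
  b <- make_stalk_field(f, neck_radius = 0)
  expect_identical(b$values, f$values)
})

test_that("the toy Langevin integrator equilibrates, quenches and replays", {
  k <- 25; dt <- 0.002; gamma <- 1
  spec <- toy_langevin_spec(1, box = 4,
                            potential = harmonic_potential(k, c(2, 2, 2)),
                            friction = gamma, dt = dt,
                            init_positions = matrix(c(2, 2, 2), 1))
  traj <- run_toy_langevin(spec, n_steps = 6e4, seed = 7, stride = 10)
  pos <- t(vapply(traj$configurations, function(c) c$positions[1, ],
                  numeric(3)))
  v <- apply(pos[501:6000, ], 2, stats::var)
  kBT <- KB_KJMOL * 300
  # Euler-Maruyama stationary variance of the discretized trap
  mob <- dt / gamma
  v_exact <- 2 * kBT * mob / (1 - (1 - k * mob)^2)
  expect_equal(v_exact, kBT / k, tolerance = 0.05)  # small discretization bias
  expect_equal(unname(v), rep(v_exact, 3), tolerance = 0.12)
  # identical seeds give identical trajectories
  t1 <- run_toy_langevin(spec, n_steps = 500, seed = 3)
  t2 <- run_toy_langevin(spec, n_steps = 500, seed = 3)
  expect_identical(t1$configurations, t2$configurations)
  # zero temperature descends deterministically to the minimum
  spec0 <- toy_langevin_spec(1, box = 4,
                             potential = harmonic_potential(k, c(2, 2, 2)),
                             temperature = 0, dt = dt,
                             init_positions = matrix(c(0.5, 1, 3.2), 1))
  tq <- run_toy_langevin(spec0, n_steps = 4000, seed = 1, stride = 400)
  expect_equal(tq$configurations[[10]]$positions, matrix(c(2, 2, 2), 1),
               tolerance = 1e-6)
})

test_that("a restrained free particle reproduces a deep target density", {
  # an umbrella restraint alone (no external potential) holds the sampled
  # density near the target: the averaged field approaches the kernel density
  # of the trap center within a few standard errors
  g <- grid_spec(c(4, 4, 4), c(4, 4, 4))
  p <- umbrella_params(kappa = 400)
  tgt <- map_density(particle_configuration(matrix(c(2, 2, 2), 1), 4), g)
  spec <- toy_langevin_spec(1, box = 4, dt = 0.001,
                            init_positions = matrix(c(2, 2, 2), 1))
  ls <- langevin_sampler(spec, p, stride = 5)
  avg <- restrained_average(ls, tgt, n_samples = 600, n_discard = 100,
                            seed = 11)
  expect_equal(sum(avg$values) * g$dV, 1, tolerance = 1e-9)
  # mass stays concentrated on the 8 cells around the trap center
  near <- order(tgt$values, decreasing = TRUE)[1:8]
  expect_gt(sum(avg$values[near]) * g$dV, 0.85)
})

test_that("the string pipeline runs end to end through the sampling plumbing", {
  # mock-sampler-backed provider: the full restrained-sampling loop recovers
  # the analytic MFEP barrier
  lnd <- two_cell_landscape()
  p <- umbrella_params()
  prov_sampled <- sampling_provider(make_mock_sampler(lnd$provider, p), p,
                                    n_samples = 3, seed = 5)
  path0 <- initialize_path(density_field(lnd$grid, lnd$m_a),
                           density_field(lnd$grid, lnd$m_b), 25)
  cfg <- string_config(epsilon = 0.03, max_iterations = 4000,
                       tol_disp = 1e-8, tol_F = 1e-8, clip_negative = FALSE)
  res <- run_string(path0, prov_sampled, cfg)
  expect_true(res$converged)
  mu <- lapply(res$path$replicas, function(r)
    chemical_potential(lnd$provider, r))
  prof <- integrate_profile(res$path, mu, n_dense = 401)
  oracle <- provider_F(lnd$provider, lnd$grid, lnd$saddle) -
    provider_F(lnd$provider, lnd$grid, lnd$m_a)
  expect_equal(prof$dF_b, oracle, tolerance = 1e-3)
})
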