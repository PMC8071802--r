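test_that("path initialization is the pointwise convex combination", {
  set.seed(31)
  g <- grid_spec(c(3, 3, 3), 2)
  a <- rand_field(g); b <- rand_field(g)
  p <- initialize_path(a, b, 3)
  expect_identical(p$replicas[[1]]$values, a$values)
  expect_identical(p$replicas[[3]]$values, b$values)
  expect_equal(p$replicas[[2]]$values, (a$values + b$values) / 2)
  p24 <- initialize_path(a, b, 24)
  for (i in c(2, 9, 17)) {
    t <- (i - 1) / 23
    expect_equal(p24$replicas[[i]]$values, (1 - t) * a$values + t * b$values,
                 tolerance = 1e-14)
  }
  same <- initialize_path(a, a, 5)
  for (i in 1:5) expect_equal(same$replicas[[i]]$values, a$values)
  expect_error(initialize_path(a, rand_field(grid_spec(4, 2)), 5),
               "different grids")
})

test_that("Allen-Cahn updates follow m - epsilon * mu with clipping accounted", {
  set.seed(37)
  g <- grid_spec(c(2, 2, 2), 1)
  a <- rand_field(g); b <- rand_field(g)
  path <- initialize_path(a, b, 5)
  zero_mu <- lapply(1:5, function(i) density_field(g, 0))
  expect_equal(path_interpolate(allen_cahn_step(path, zero_mu), path$s),
               path_interpolate(path, path$s))
  # brute-force loop comparison
  mu <- lapply(1:5, function(i) rand_field(g, -2, 2))
  cfg <- string_config(epsilon = 0.1, clip_negative = FALSE)
  stepped <- allen_cahn_step(path, mu, cfg)
  for (i in 1:5)
    expect_equal(stepped$replicas[[i]]$values,
                 path$replicas[[i]]$values - 0.1 * mu[[i]]$values)
  # clipping reports the number of clipped cells
  cfg_clip <- string_config(epsilon = 10, clip_negative = TRUE)
  clipped <- allen_cahn_step(path, mu, cfg_clip)
  expect_gt(attr(clipped, "n_clipped"), 0)
  expect_true(all(vapply(clipped$replicas, function(r) min(r$values), 0) >= 0))
  # pinned endpoints stay put
  cfg_pin <- string_config(epsilon = 0.1, endpoint_mode = "pinned",
                           clip_negative = FALSE)
  pinned <- allen_cahn_step(path, mu, cfg_pin)
  expect_identical(pinned$replicas[[1]]$values, a$values)
  expect_identical(pinned$replicas[[5]]$values, b$values)
})

test_that("scalar Allen-Cahn recursion converges geometrically", {
  # single cell, quadratic functional: m_{k+1} - m* = (1 - eps a)(m_k - m*)
  g <- grid_spec(1, 1)
  a <- 2; mstar <- 1.5; eps <- 0.1
  prov <- make_analytic_provider(analytic_functional(g, "quadratic", a = a,
                                                     m_star = mstar))
  cfg <- string_config(epsilon = eps, clip_negative = FALSE)
  m <- 3
  for (k in 1:25) {
    pth <- string_path(list(density_field(g, m), density_field(g, m)))
    mu <- lapply(pth$replicas, function(r) chemical_potential(prov, r))
    m_new <- allen_cahn_step(pth, mu, cfg)$replicas[[1]]$values[1]
    expect_equal((m_new - mstar) / (m - mstar), 1 - eps * a,
                 tolerance = 1e-12)
    m <- m_new
  }
  expect_equal(m, mstar, tolerance = (1 - eps * a)^25 * 1.5 * 1.01)
})

test_that("replica distances are normalized Euclidean segment lengths", {
  set.seed(41)
  g <- grid_spec(c(2, 2, 1), 1)
  a <- rand_field(g); b <- rand_field(g)
  p <- initialize_path(a, b, 7)
  expect_equal(replica_distances(p), rep(1 / 6, 6), tolerance = 1e-12)
  p2 <- string_path(list(a, b))
  expect_equal(replica_distances(p2), 1)
  reps <- lapply(1:5, function(i) rand_field(g))
  p5 <- string_path(reps)
  raw <- vapply(1:4, function(i)
    sqrt(sum((reps[[i + 1]]$values - reps[[i]]$values)^2)), 0)
  expect_equal(replica_distances(p5), raw / sum(raw), tolerance = 1e-12)
  expect_equal(sum(replica_distances(p5)), 1, tolerance = 1e-12)
  expect_error(replica_distances(string_path(list(a, a))), "degenerate")
})

test_that("reparameterization uniformizes clustered paths and fixes endpoints", {
  g <- grid_spec(c(2, 1, 1), c(2, 1, 1))
  # strongly end-clustered parameterization of a smooth curve
  ts <- c(0, 0.01, 0.02, 0.05, 0.12, 0.3, 0.6, 1)
  reps <- lapply(ts, function(t) density_field(g, c(t, t^2)))
  p <- string_path(reps)
  rp <- reparameterize(p)
  d <- replica_distances(rp)
  expect_lt(max(abs(d - mean(d))) / mean(d), 1e-3)
  expect_equal(sum(d), 1, tolerance = 1e-12)
  expect_identical(rp$replicas[[1]]$values, reps[[1]]$values)
  expect_identical(rp$replicas[[8]]$values, reps[[8]]$values)
  # an already-uniform straight path is a fixed point
  a <- density_field(g, c(0, 0)); b <- density_field(g, c(1, 2))
  lin <- initialize_path(a, b, 9)
  rl <- reparameterize(lin)
  expect_equal(path_interpolate(rl, lin$s), path_interpolate(lin, lin$s),
               tolerance = 1e-10)
})

test_that("redistribution matches the closed-form arc-length parameterization", {
  # curve (t, t^2): arc length L(t) = (1/2)[t sqrt(1+4t^2) + asinh(2t)/2]
  g <- grid_spec(c(2, 1, 1), c(2, 1, 1))
  arclen <- function(t) 0.5 * (t * sqrt(1 + 4 * t^2) + 0.5 * asinh(2 * t))
  n <- 25
  ts <- seq(0, 1, length.out = n)^2  # non-uniform sampling of the curve
  p <- string_path(lapply(ts, function(t) density_field(g, c(t, t^2))))
  rp <- reparameterize(p)
  Ltot <- arclen(1)
  t_exact <- vapply(seq(0, 1, length.out = n), function(u)
    stats::uniroot(function(t) arclen(t) - u * Ltot, c(0, 1),
                   tol = 1e-14)$root, 0)
  got <- vapply(rp$replicas, function(r) r$values[1, 1, 1], 0)
  expect_equal(got, t_exact, tolerance = 1e-3)
})

test_that("perpendicular projection removes exactly the tangential part", {
  set.seed(43)
  g <- grid_spec(c(3, 2, 1), 1)
  a <- rand_field(g); b <- rand_field(g)
  p <- initialize_path(a, b, 9)
  tang <- b$values - a$values  # straight path: tangent is the chord
  # mu parallel to the tangent projects to zero
  mu_par <- lapply(1:9, function(i) density_field(g, 0.7 * tang))
  perp <- perpendicular_mu(p, mu_par)
  for (i in 1:9) expect_equal(max(abs(perp[[i]]$values)), 0, tolerance = 1e-10)
  # random mu: residual is orthogonal to the tangent
  mu_r <- lapply(1:9, function(i) rand_field(g, -1, 1))
  perp_r <- perpendicular_mu(p, mu_r)
  Tg <- stalkpath:::path_tangents(p)
  for (i in 1:9)
    expect_equal(sum(as.vector(perp_r[[i]]$values) * Tg[i, ]), 0,
                 tolerance = 1e-10)
  # mu already orthogonal is unchanged
  ortho <- lapply(1:9, function(i) {
    v <- as.vector(mu_r[[i]]$values)
    density_field(g, v - as.vector(tang) * sum(v * tang) / sum(tang^2))
  })
  perp_o <- perpendicular_mu(p, ortho)
  for (i in 1:9)
    expect_equal(perp_o[[i]]$values, ortho[[i]]$values, tolerance = 1e-10)
  expect_error(perpendicular_mu(initialize_path(a, a, 3), mu_r[1:3]),
               "tangent")
})

test_that("the string relaxes to the MFEP through the independent Newton saddle", {
  lnd <- two_cell_landscape()
  res <- run_two_cell_string(lnd)
  expect_true(res$converged)
  mu <- lapply(res$path$replicas, function(r)
    chemical_potential(lnd$provider, r))
  prof <- integrate_profile(res$path, mu, n_dense = 801)
  oracle_barrier <- provider_F(lnd$provider, lnd$grid, lnd$saddle) -
    provider_F(lnd$provider, lnd$grid, lnd$m_a)
  expect_equal(prof$dF_b, oracle_barrier, tolerance = 1e-3)
  coords <- path_interpolate(res$path, prof$s_b)
  expect_lt(max(abs(coords - lnd$saddle)), 1e-3)
  # perpendicular chemical potential decreases over the final iterations
  # (up to floating-point jitter once it reaches its discretization floor)
  mp <- res$diagnostics$max_mu_perp
  last <- mp[seq(max(1, floor(0.9 * length(mp))), length(mp))]
  expect_true(all(diff(last) <= 1e-5 * last[1]))
})

test_that("a degenerate path at a minimum converges immediately with zero profile", {
  g <- grid_spec(1, 1)
  prov <- make_analytic_provider(analytic_functional(g, "quadratic", a = 1,
                                                     m_star = 2))
  minimum <- density_field(g, 2)
  p0 <- string_path(list(minimum, minimum, minimum))
  cfg <- string_config(epsilon = 0.1, tol_disp = 1e-8, clip_negative = FALSE,
                       max_iterations = 10)
  res <- run_string(p0, prov, cfg)
  expect_true(res$converged)
  expect_lte(res$iterations, 2)
  mu <- lapply(res$path$replicas, function(r) chemical_potential(prov, r))
  prof <- integrate_profile(res$path, mu)
  expect_equal(max(abs(prof$dF)), 0, tolerance = 1e-12)
})

test_that("string runs are deterministic and report provider calls", {
  lnd <- gl_landscape(10)
  p0 <- initialize_path(lnd$start, lnd$end, 7)
  cfg <- string_config(epsilon = 0.003, max_iterations = 50, tol_disp = 1e-10,
                       tol_F = 1e-10, clip_negative = FALSE)
  r1 <- suppressWarnings(run_string(p0, lnd$provider, cfg))
  r2 <- suppressWarnings(run_string(p0, lnd$provider, cfg))
  expect_identical(r1$diagnostics, r2$diagnostics)
  expect_identical(path_interpolate(r1$path, c(0.3, 0.7)),
                   path_interpolate(r2$path, c(0.3, 0.7)))
  expect_equal(r1$provider_calls, 7 * r1$iterations)
})
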