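# Shared fixtures and independent oracles for the test suite. The oracles
# here deliberately avoid the package's own code paths (brute-force loops,
# generic optimizers, closed forms) so they can serve as references.

rand_field <- function(grid, lo = 0, hi = 5) {
  density_field(grid, array(stats::runif(prod(grid$n), lo, hi), grid$n))
}

# brute-force cloud-in-cell mapping: explicit double loop over
# (particle, cell) pairs using assignment_weight
brute_force_map <- function(config, grid) {
  vals <- array(0, grid$n)
  pos <- config$positions[config$mask, , drop = FALSE]
  for (i in seq_len(grid$n[1])) for (j in seq_len(grid$n[2]))
    for (k in seq_len(grid$n[3])) {
      cc <- c(cell_centers(grid, 1)[i], cell_centers(grid, 2)[j],
              cell_centers(grid, 3)[k])
      for (p in seq_len(nrow(pos)))
        vals[i, j, k] <- vals[i, j, k] + assignment_weight(cc, pos[p, ], grid)
    }
  vals / grid$dV
}

# gradient of the analytic free energy in field space (dF/dm_c = dV * mu_c)
provider_grad <- function(provider, grid, m) {
  grid$dV * as.vector(chemical_potential(provider, density_field(grid, m))$values)
}

provider_F <- function(provider, grid, m) {
  provider_free_energy(provider, density_field(grid, m))
}

# damped Newton root of grad F = 0 with a numeric Hessian of the analytic
# gradient; used to locate minima and saddle points independently of the
# string machinery
newton_stationary <- function(provider, grid, m0, damping = 0.8,
                              tol = 1e-12, max_iter = 300) {
  m <- m0
  nc <- length(m0)
  for (it in seq_len(max_iter)) {
    gval <- provider_grad(provider, grid, m)
    if (max(abs(gval)) < tol) break
    H <- matrix(0, nc, nc)
    eps <- 1e-5
    for (i in seq_len(nc)) {
      mp <- m; mp[i] <- mp[i] + eps
      mm <- m; mm[i] <- mm[i] - eps
      H[, i] <- (provider_grad(provider, grid, mp) -
                   provider_grad(provider, grid, mm)) / (2 * eps)
    }
    H <- (H + t(H)) / 2
    m <- m - damping * solve(H, gval)
  }
  m
}

# the tilted two-cell double-well landscape used throughout the string tests:
# stiff enough gradient coupling that the synchronous transition through the
# symmetric saddle is the minimum free-energy path
two_cell_landscape <- function() {
  g <- grid_spec(c(2, 1, 1), c(2, 1, 1))
  spec <- analytic_functional(g, "double_well", a = 1, m1 = 0.5, m2 = 2.5,
                              kappa_grad = 2,
                              tilt = array(c(0.05, -0.08), g$n))
  prov <- make_analytic_provider(spec)
  m_a <- newton_stationary(prov, g, c(0.5, 0.5))
  m_b <- newton_stationary(prov, g, c(2.5, 2.5))
  saddle <- newton_stationary(prov, g, (m_a + m_b) / 2)
  list(grid = g, provider = prov, m_a = m_a, m_b = m_b, saddle = saddle)
}

# 1D Ginzburg-Landau landscape between two uniform phases
gl_landscape <- function(n = 20L) {
  g <- grid_spec(c(n, 1L, 1L), c(10, 1, 1))
  spec <- analytic_functional(g, "double_well", a = 1, m1 = 0.5, m2 = 2.5,
                              kappa_grad = 15)
  list(grid = g, provider = make_analytic_provider(spec),
       start = density_field(g, 0.5), end = density_field(g, 2.5))
}

# constrained-scan barrier oracle: at each value of the interpolation
# coordinate t, minimize F over the orthogonal complement of the
# end-minus-start direction (BFGS on the reduced coordinates), then take the
# maximum of the constrained minima
constrained_scan_barrier <- function(provider, grid, start_vals, end_vals,
                                     n_t = 41L) {
  e <- end_vals - start_vals
  N <- length(e)
  Q <- qr.Q(qr(cbind(e, diag(N))))[, 2:N, drop = FALSE]
  F0 <- provider_F(provider, grid, start_vals)
  best <- -Inf
  y <- rep(0, N - 1L)
  for (t in seq(0, 1, length.out = n_t)) {
    base <- start_vals + t * e
    obj <- function(yy) provider_F(provider, grid, base + as.vector(Q %*% yy))
    grr <- function(yy) as.vector(crossprod(Q, provider_grad(
      provider, grid, base + as.vector(Q %*% yy))))
    opt <- stats::optim(y, obj, grr, method = "BFGS",
                        control = list(reltol = 1e-14, maxit = 500))
    y <- opt$par
    best <- max(best, opt$value - F0)
  }
  best
}

run_two_cell_string <- function(lnd, n_replicas = 41L) {
  path0 <- initialize_path(density_field(lnd$grid, lnd$m_a),
                           density_field(lnd$grid, lnd$m_b), n_replicas)
  cfg <- string_config(epsilon = 0.03, max_iterations = 8000,
                       tol_disp = 1e-10, tol_F = 1e-9, clip_negative = FALSE)
  suppressWarnings(run_string(path0, lnd$provider, cfg))
}
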