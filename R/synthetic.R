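#' Analytic free-energy functional specification
#'
#' Free-energy functionals with exactly computable chemical potentials, used
#' to validate the string machinery: a quadratic basin and a Ginzburg-Landau
#' double well, optionally with a square-gradient penalty and a per-cell
#' linear tilt. All energies are in kBT.
#'
#' Local free-energy density (per cell, times dV):
#' * quadratic: `f(m) = (a/2) (m - m_star)^2 + tilt * m`
#' * double_well: `f(m) = a (m - m1)^2 (m - m2)^2 + tilt * m`
#'
#' plus `(kappa_grad/2) |grad m|^2` (forward differences, periodic). The
#' chemical potential is `mu(c) = f'(m(c)) - kappa_grad * laplacian(m)(c)`.
#'
#' @param grid a [grid_spec()].
#' @param family `"quadratic"` or `"double_well"`.
#' @param a stiffness (quadratic) or quartic strength (double well), > 0.
#' @param m_star quadratic minimum (nm^-3).
#' @param m1,m2 double-well positions (must differ).
#' @param kappa_grad square-gradient coefficient (>= 0), units kBT nm^-1 per
#'   squared density gradient.
#' @param tilt per-cell linear coefficient (scalar or array of grid shape).
#' @return object of class `analytic_functional`.
#' @export
analytic_functional <- function(grid, family = c("quadratic", "double_well"),
                                a = 1, m_star = 0, m1 = 0, m2 = 1,
                                kappa_grad = 0, tilt = 0) {
  family <- match.arg(family)
  if (a <= 0) stop("a must be > 0")
  if (kappa_grad < 0) stop("kappa_grad must be >= 0")
  if (family == "double_well" && m1 == m2)
    stop("double well requires two distinct well positions")
  if (length(tilt) == 1L) tilt <- array(tilt, dim = grid$n)
  if (!all(dim(tilt) == grid$n)) stop("tilt shape does not match grid")
  structure(list(grid = grid, family = family, a = a, m_star = m_star,
                 m1 = m1, m2 = m2, kappa_grad = kappa_grad, tilt = tilt),
            class = "analytic_functional")
}

#' Chemical potential of a field under a provider
#'
#' Generic provider contract: maps a target density field to the chemical
#' potential `mu(c) = dF / (dV dm(c))` (kBT) on the same grid.
#'
#' @param provider a provider object.
#' @param field a [density_field()].
#' @param ... passed to methods.
#' @return a chemical-potential field ([density_field()] container, kBT).
#' @export
chemical_potential <- function(provider, field, ...) {
  UseMethod("chemical_potential")
}

#' Exact chemical-potential provider from an analytic functional
#'
#' @param spec an [analytic_functional()].
#' @return deterministic provider of class `analytic_provider`; supports
#'   [chemical_potential()] and [provider_free_energy()].
#' @export
make_analytic_provider <- function(spec) {
  stopifnot(inherits(spec, "analytic_functional"))
  structure(list(spec = spec, grid = spec$grid, deterministic = TRUE),
            class = c("analytic_provider"))
}

fprime <- function(spec, m) {
  base <- if (spec$family == "quadratic") {
    spec$a * (m - spec$m_star)
  } else {
    2 * spec$a * (m - spec$m1) * (m - spec$m2) * (2 * m - spec$m1 - spec$m2)
  }
  base + spec$tilt
}

flocal <- function(spec, m) {
  base <- if (spec$family == "quadratic") {
    0.5 * spec$a * (m - spec$m_star)^2
  } else {
    spec$a * (m - spec$m1)^2 * (m - spec$m2)^2
  }
  base + spec$tilt * m
}

#' @export
chemical_potential.analytic_provider <- function(provider, field, ...) {
  spec <- provider$spec
  check_same_grid(field, list(grid = spec$grid))
  mu <- fprime(spec, field$values)
  if (spec$kappa_grad > 0)
    mu <- mu - spec$kappa_grad * grid_laplacian(field$values, field$grid)
  density_field(field$grid, mu, metadata = list(kind = "chemical_potential"))
}

#' Closed-form free energy of an analytic provider
#'
#' `F = dV * sum_c [ f(m(c)) + (kappa_grad/2) |grad m|^2 ]` in kBT; the
#' quantity whose gradient the provider returns. Used as the independent
#' reference in thermodynamic-integration checks.
#'
#' @param provider an `analytic_provider`.
#' @param field a [density_field()].
#' @return free energy (kBT).
#' @export
provider_free_energy <- function(provider, field) {
  spec <- provider$spec
  F <- sum(flocal(spec, field$values))
  if (spec$kappa_grad > 0) {
    g2 <- 0
    for (a in 1:3) {
      if (field$grid$n[a] < 2L) next
      d <- (shift_array(field$values, a, 1L) - field$values) / field$grid$dL[a]
      g2 <- g2 + sum(d^2)
    }
    F <- F + 0.5 * spec$kappa_grad * g2
  }
  field$grid$dV * F
}

#' Mock restrained sampler with the exact large-coupling response
#'
#' Returns a sampler whose restrained average is constructed to obey
#' `<mhat> = m - mu_exact(m) / lambda` with `lambda = kappa * dV / kBT`, so
#' the chemical-potential estimator recovers the provider's exact mu. Closes
#' the estimator loop algebraically and lets the full string pipeline run with
#' all sampling plumbing engaged.
#'
#' @param provider a deterministic chemical-potential provider.
#' @param params an [umbrella_params()].
#' @return sampler of class `mock_sampler`.
#' @export
make_mock_sampler <- function(provider, params) {
  structure(list(provider = provider, params = params),
            class = "mock_sampler")
}

#' @export
restrained_average.mock_sampler <- function(sampler, target, n_samples,
                                            n_discard = 0, seed = 1L, ...) {
  lam <- umbrella_lambda(sampler$params, target$grid)
  mu <- chemical_potential(sampler$provider, target)
  density_field(target$grid, target$values - mu$values / lam,
                metadata = list(seed = seed, n_samples = n_samples,
                                n_discard = n_discard, sampler = "mock"))
}

#' Provider backed by restrained sampling
#'
#' Wraps a sampling engine into the chemical-potential provider contract:
#' each call runs [restrained_average()] toward the target and applies
#' [estimate_chemical_potential()].
#'
#' @param sampler a sampling engine (e.g. [make_mock_sampler()],
#'   [langevin_sampler()]).
#' @param params an [umbrella_params()].
#' @param n_samples,n_discard sample counts per call.
#' @param seed base seed; combined deterministically with an internal call
#'   counter so repeated runs are reproducible.
#' @return provider of class `sampling_provider`.
#' @export
sampling_provider <- function(sampler, params, n_samples, n_discard = 0,
                              seed = 1L) {
  env <- new.env(parent = emptyenv())
  env$calls <- 0L
  structure(list(sampler = sampler, params = params, n_samples = n_samples,
                 n_discard = n_discard, seed = as.integer(seed), env = env,
                 deterministic = inherits(sampler, "mock_sampler")),
            class = "sampling_provider")
}

#' @export
chemical_potential.sampling_provider <- function(provider, field, ...) {
  provider$env$calls <- provider$env$calls + 1L
  call_seed <- (provider$seed + 10007L * provider$env$calls) %% .Machine$integer.max
  avg <- restrained_average(provider$sampler, field, provider$n_samples,
                            provider$n_discard, seed = call_seed)
  estimate_chemical_potential(field, avg, provider$params)
}

# smooth slab profile along a coordinate: (bulk/2)(tanh((x-a)/w)+tanh((b-x)/w));
# w = 0 gives a sharp step
slab_profile <- function(x, a, b, w, bulk) {
  if (w <= 0) return(ifelse(x >= a & x <= b, bulk, 0))
  0.5 * bulk * (tanh((x - a) / w) + tanh((b - x) / w))
}

#' Constructed planar-bilayer-pair density field
#'
#' Two tanh slabs normal to z emulating the hydrophobic cores of two apposed
#' planar membranes at MARTINI-like tail densities. Either the slab centers or
#' the water gap at the iso-density `threshold` can be prescribed; the exact
#' threshold-crossing heights are solved numerically and stored in
#' `metadata$crossings` as fixture ground truth.
#'
#' @param grid a [grid_spec()].
#' @param z_centers two slab centers (nm); or `NULL` when `gap` is given.
#' @param thickness slab thickness (nm).
#' @param interface_width tanh width (nm); 0 gives step profiles.
#' @param bulk_density plateau density (nm^-3, default 5).
#' @param gap water-gap width at the threshold level (nm); slabs are placed
#'   symmetrically about the box mid-plane.
#' @param threshold iso-density level defining interfaces (nm^-3, default 2.2).
#' @return a [density_field()] with ground-truth geometry in `metadata`.
#' @export
make_bilayer_field <- function(grid, z_centers = NULL, thickness = 3,
                               interface_width = 0.25, bulk_density = 5,
                               gap = NULL, threshold = 2.2) {
  Lz <- grid$box[3]
  w <- interface_width
  t <- thickness
  profile <- function(z, zc1, zc2) {
    slab_profile(z, zc1 - t / 2, zc1 + t / 2, w, bulk_density) +
      slab_profile(z, zc2 - t / 2, zc2 + t / 2, w, bulk_density)
  }
  if (is.null(z_centers)) {
    if (is.null(gap)) stop("give either z_centers or gap")
    # symmetric placement: solve the half-separation c so the threshold-level
    # gap around the mid-plane equals the request
    gap_of <- function(c) {
      zc1 <- Lz / 2 - c; zc2 <- Lz / 2 + c
      if (profile(Lz / 2, zc1, zc2) >= threshold) return(-gap)
      up <- stats::uniroot(function(z) profile(z, zc1, zc2) - threshold,
                           c(Lz / 2, zc2), tol = 1e-12)$root
      2 * (up - Lz / 2)
    }
    lo <- gap / 2 + max(w, 1e-3)
    hi <- (Lz - t) / 2 - max(w, 1e-3)
    if (lo >= hi || gap_of(hi) < gap)
      stop("slabs with the requested gap do not fit in the box")
    cc <- stats::uniroot(function(c) gap_of(c) - gap, c(lo, hi),
                         tol = 1e-12)$root
    z_centers <- c(Lz / 2 - cc, Lz / 2 + cc)
  }
  z_centers <- sort(as.numeric(z_centers))
  if (z_centers[2] - z_centers[1] < t)
    stop("slabs overlap")
  zc <- cell_centers(grid, 3L)
  mz <- profile(zc, z_centers[1], z_centers[2])
  vals <- array(rep(mz, each = grid$n[1] * grid$n[2]), dim = grid$n)
  crossings <- tryCatch({
    f <- function(z) profile(z, z_centers[1], z_centers[2]) - threshold
    eps <- max(w * 1e-6, 1e-9)
    c(lo1 = stats::uniroot(f, c(max(0, z_centers[1] - t), z_centers[1]),
                           tol = 1e-12)$root,
      hi1 = stats::uniroot(f, c(z_centers[1], mean(z_centers)),
                           tol = 1e-12)$root,
      lo2 = stats::uniroot(f, c(mean(z_centers), z_centers[2]),
                           tol = 1e-12)$root,
      hi2 = stats::uniroot(f, c(z_centers[2], min(Lz, z_centers[2] + t)),
                           tol = 1e-12)$root) + eps * 0
  }, error = function(e) NULL)
  md <- list(kind = "bilayer_pair", z_centers = z_centers,
             thickness = thickness, interface_width = interface_width,
             bulk_density = bulk_density, threshold = threshold,
             crossings = crossings,
             gap_at_threshold = if (!is.null(crossings))
               unname(crossings["lo2"] - crossings["hi1"]) else NA_real_)
  density_field(grid, vals, metadata = md)
}

#' Constructed vesicle-plus-periodic-image density field
#'
#' A spherical tanh shell centered in the box, calibrated so the water gap to
#' its periodic image along z at the iso-density threshold equals `gap`. The
#' outer threshold radius is then `(Lz - gap)/2`; the nominal outer radius
#' `R_v` is recorded and must agree with it to within one cell.
#'
#' @param grid a [grid_spec()] (periodic along z).
#' @param R_v nominal outer radius (nm).
#' @param thickness shell thickness (nm).
#' @param interface_width tanh width (nm).
#' @param gap periodic-image water gap at the threshold level (nm, >= 0).
#' @param bulk_density plateau density (nm^-3, default 5).
#' @param threshold iso-density level (nm^-3, default 2.2).
#' @return a [density_field()] with ground-truth geometry in `metadata`.
#' @export
make_vesicle_pair_field <- function(grid, R_v, thickness = 3.5,
                                    interface_width = 0.25, gap = 2.3,
                                    bulk_density = 5, threshold = 2.2) {
  Lz <- grid$box[3]
  R_target <- (Lz - gap) / 2
  if (R_target <= thickness)
    stop("impossible geometry: box too small for shell plus gap")
  if (abs(R_target - R_v) > max(grid$dL))
    stop(sprintf(paste0("impossible geometry: requested R_v = %.3g nm but the",
                        " box and gap imply an outer threshold radius of",
                        " %.3g nm"), R_v, R_target))
  w <- interface_width
  t <- thickness
  shell <- function(r, Ro) slab_profile(r, Ro - t, Ro, w, bulk_density)
  Ro <- if (w <= 0) R_target else
    stats::uniroot(function(Ro) shell(R_target, Ro) - threshold,
                   c(R_target - 5 * w - 0.1, R_target + 5 * w + 0.1),
                   tol = 1e-12)$root
  center <- grid$box / 2
  cx <- cell_centers(grid, 1L); cy <- cell_centers(grid, 2L)
  cz <- cell_centers(grid, 3L)
  dx <- mi_delta(cx - center[1], grid$box[1], grid$periodic[1])
  dy <- mi_delta(cy - center[2], grid$box[2], grid$periodic[2])
  dz <- mi_delta(cz - center[3], grid$box[3], grid$periodic[3])
  r <- sqrt(outer(outer(dx^2, dy^2, `+`), dz^2, `+`))
  vals <- shell(r, Ro)
  R_inner <- if (w <= 0) Ro - t else
    stats::uniroot(function(rr) shell(rr, Ro) - threshold,
                   c(max(Ro - t - 5 * w - 0.1, 1e-6), Ro - t + 5 * w + 0.1),
                   tol = 1e-12)$root
  md <- list(kind = "vesicle_pair", center = center, R_v = R_v,
             R_outer_threshold = R_target, R_inner_threshold = R_inner,
             thickness = thickness, interface_width = interface_width,
             bulk_density = bulk_density, threshold = threshold, gap = gap)
  density_field(grid, vals, metadata = md)
}

# minimum-image displacement
mi_delta <- function(d, L, periodic = TRUE) {
  if (!periodic) return(d)
  d - L * round(d / L)
}

#' Add an axisymmetric stalk bridge to a membrane-pair field
#'
#' Smooth union (pointwise maximum) of the base field and a catenoid-like
#' hourglass bridge along the axis, with the waist calibrated so the
#' iso-density threshold crossing at the mid-plane sits at `neck_radius`.
#'
#' @param base a [density_field()] from [make_bilayer_field()] or
#'   [make_vesicle_pair_field()].
#' @param neck_radius waist radius at the threshold level (nm); 0 returns the
#'   base field unchanged.
#' @param waist_scale axial scale of the catenoid widening (nm); default
#'   `max(neck_radius, 1)`.
#' @param axis_center lateral (x, y) position of the stalk axis; default the
#'   box center.
#' @param z_mid axial position of the waist; default the center of the base
#'   fixture's water gap (from metadata).
#' @param half_window axial half-extent of the bridge; default reaches into
#'   both membranes.
#' @param interface_width,bulk_density,threshold bridge profile parameters;
#'   defaults taken from the base metadata.
#' @return a [density_field()] with stalk ground truth added to `metadata`.
#' @export
make_stalk_field <- function(base, neck_radius, waist_scale = NULL,
                             axis_center = NULL, z_mid = NULL,
                             half_window = NULL,
                             interface_width = NULL, bulk_density = NULL,
                             threshold = NULL) {
  md <- base$metadata
  grid <- base$grid
  if (neck_radius == 0) return(base)
  if (neck_radius < 0) stop("neck_radius must be >= 0")
  if (is.null(interface_width)) interface_width <- md$interface_width
  if (is.null(bulk_density)) bulk_density <- md$bulk_density
  if (is.null(threshold)) threshold <- md$threshold
  if (is.null(waist_scale)) waist_scale <- max(neck_radius, 1)
  if (is.null(axis_center)) axis_center <- grid$box[1:2] / 2
  if (is.null(z_mid)) {
    z_mid <- if (identical(md$kind, "vesicle_pair")) {
      (md$center[3] + grid$box[3] / 2) %% grid$box[3]
    } else if (!is.null(md$crossings)) {
      mean(c(md$crossings["hi1"], md$crossings["lo2"]))
    } else stop("z_mid not derivable from base metadata; pass it explicitly")
  }
  if (is.null(half_window)) {
    gap <- if (!is.null(md$gap_at_threshold) && is.finite(md$gap_at_threshold))
      md$gap_at_threshold else md$gap
    half_window <- gap / 2 + (if (!is.null(md$thickness)) md$thickness else 2)
  }
  w <- max(interface_width, 1e-6)
  # calibrate the waist so the threshold crossing sits at neck_radius
  rho_w <- neck_radius + w * atanh(2 * threshold / bulk_density - 1)
  cx <- cell_centers(grid, 1L); cy <- cell_centers(grid, 2L)
  cz <- cell_centers(grid, 3L)
  dx <- mi_delta(cx - axis_center[1], grid$box[1], grid$periodic[1])
  dy <- mi_delta(cy - axis_center[2], grid$box[2], grid$periodic[2])
  dz <- mi_delta(cz - z_mid, grid$box[3], grid$periodic[3])
  rlat <- sqrt(outer(dx^2, dy^2, `+`))
  if (max(abs(dz[abs(dz) <= half_window]) / waist_scale) > 50)
    stop("impossible geometry: bridge window too wide for the waist scale")
  vals <- base$values
  for (k in seq_len(grid$n[3])) {
    if (abs(dz[k]) > half_window) next
    rho <- rho_w * cosh(dz[k] / waist_scale)
    bridge <- 0.5 * bulk_density * (1 + tanh((rho - rlat) / w))
    vals[, , k] <- pmax(vals[, , k], bridge)
  }
  md$stalk <- list(neck_radius = neck_radius, waist_scale = waist_scale,
                   axis_center = axis_center, z_mid = z_mid,
                   expected_d_st = 2 * neck_radius)
  density_field(grid, vals, metadata = md)
}

#' Toy overdamped Langevin sampler specification
#'
#' A desk-scale stand-in for restrained molecular dynamics: overdamped
#' Langevin dynamics of point particles in an external potential plus,
#' optionally, the umbrella forces toward a target field. The position update
#' is `r += (F/gamma) dt + sqrt(2 kBT dt / gamma) xi`. The timestep must
#' satisfy `dt < gamma / k_max` for the stiffest force constant `k_max`
#' (harmonic stability bound).
#'
#' @param n_particles particle count.
#' @param box length-3 box (nm).
#' @param potential `NULL` (free) or a list with functions
#'   `force(positions) -> n x 3 matrix` (kJ/mol/nm) and optionally
#'   `energy(positions) -> scalar`.
#' @param friction gamma in kJ/mol ps nm^-2 (default 1).
#' @param temperature K (default 300).
#' @param dt timestep (ps).
#' @param init_positions optional n x 3 matrix; default uniform random (drawn
#'   from the run seed).
#' @param mask logical hydrophobic mask, default all.
#' @return object of class `toy_langevin_spec`.
#' @export
toy_langevin_spec <- function(n_particles, box, potential = NULL,
                              friction = 1, temperature = 300, dt = 0.01,
                              init_positions = NULL, mask = NULL) {
  box <- as.numeric(rep_len(box, 3L))
  if (dt <= 0 || friction <= 0 || temperature < 0) stop("invalid parameters")
  structure(list(n_particles = as.integer(n_particles), box = box,
                 potential = potential, friction = friction,
                 temperature = temperature, dt = dt,
                 init_positions = init_positions, mask = mask),
            class = "toy_langevin_spec")
}

#' External potential: independent harmonic traps
#'
#' @param k force constant (kJ/mol/nm^2).
#' @param center length-3 trap center (nm).
#' @return potential list for [toy_langevin_spec()].
#' @export
harmonic_potential <- function(k, center) {
  center <- as.numeric(center)
  list(
    force = function(pos) -k * sweep(pos, 2L, center),
    energy = function(pos) 0.5 * k * sum(sweep(pos, 2L, center)^2))
}

# one batch of overdamped Langevin steps; positions matrix in/out
langevin_steps <- function(pos, spec, n_steps, target = NULL, params = NULL,
                           mask = NULL) {
  kBT <- KB_KJMOL * spec$temperature
  mob <- spec$dt / spec$friction
  noise_amp <- sqrt(2 * kBT * mob)
  np <- nrow(pos)
  for (step in seq_len(n_steps)) {
    F <- matrix(0, np, 3)
    if (!is.null(spec$potential)) F <- F + spec$potential$force(pos)
    if (!is.null(target)) {
      cfg <- particle_configuration(pos, spec$box, mask = mask)
      F <- F + umbrella_forces(target, cfg, params)
    }
    if (any(!is.finite(F)))
      stop("sampling error: non-finite forces (divergence) at step ", step)
    pos <- pos + mob * F
    if (spec$temperature > 0)
      pos <- pos + noise_amp * matrix(stats::rnorm(np * 3L), np, 3L)
    pos <- wrap_positions(pos, spec$box, c(TRUE, TRUE, TRUE))
  }
  pos
}

init_langevin_positions <- function(spec) {
  if (!is.null(spec$init_positions)) {
    wrap_positions(as.matrix(spec$init_positions), spec$box)
  } else {
    matrix(stats::runif(spec$n_particles * 3L), spec$n_particles, 3L) %*%
      diag(spec$box)
  }
}

#' Run the toy Langevin sampler
#'
#' Integrates the overdamped dynamics under the external potential and,
#' optionally, the umbrella restraint toward `target`, and emits particle
#' configurations every `stride` steps. Fully reproducible under a fixed seed.
#'
#' @param spec a [toy_langevin_spec()].
#' @param n_steps total number of steps.
#' @param seed integer seed.
#' @param target optional target [density_field()] for the umbrella restraint.
#' @param params an [umbrella_params()] (required with `target`).
#' @param stride emit a configuration every `stride` steps (default 10).
#' @return list of class `langevin_trajectory`: `configurations` (list of
#'   [particle_configuration()]), `spec`, `seed`, `stride`.
#' @export
run_toy_langevin <- function(spec, n_steps, seed, target = NULL,
                             params = NULL, stride = 10L) {
  if (!is.null(target) && is.null(params))
    stop("umbrella restraint needs umbrella_params")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  pos <- init_langevin_positions(spec)
  mask <- if (is.null(spec$mask)) rep(TRUE, nrow(pos)) else spec$mask
  n_out <- n_steps %/% stride
  configs <- vector("list", n_out)
  for (b in seq_len(n_out)) {
    pos <- langevin_steps(pos, spec, stride, target, params, mask)
    configs[[b]] <- particle_configuration(pos, spec$box, mask = mask)
  }
  structure(list(configurations = configs, spec = spec, seed = seed,
                 stride = stride),
            class = "langevin_trajectory")
}

#' Langevin sampling engine for restrained averages
#'
#' Wraps a [toy_langevin_spec()] so it satisfies the [restrained_average()]
#' contract: the engine runs under the umbrella restraint toward the target,
#' discards `n_discard` samples, and averages the mapped density of the
#' remaining samples on the target's grid.
#'
#' @param spec a [toy_langevin_spec()].
#' @param params an [umbrella_params()].
#' @param stride integration steps between density samples (default 10).
#' @return sampler of class `langevin_sampler`.
#' @export
langevin_sampler <- function(spec, params, stride = 10L) {
  structure(list(spec = spec, params = params, stride = as.integer(stride)),
            class = "langevin_sampler")
}

#' @export
restrained_average.langevin_sampler <- function(sampler, target, n_samples,
                                                n_discard = 0, seed = 1L, ...) {
  spec <- sampler$spec
  if (any(abs(spec$box - target$grid$box) > 1e-9 * target$grid$box))
    stop("sampler box does not match target grid box")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  pos <- init_langevin_positions(spec)
  mask <- if (is.null(spec$mask)) rep(TRUE, nrow(pos)) else spec$mask
  acc <- array(0, dim = target$grid$n)
  for (b in seq_len(n_discard + n_samples)) {
    pos <- langevin_steps(pos, spec, sampler$stride, target, sampler$params,
                          mask)
    if (b > n_discard) {
      cfg <- particle_configuration(pos, spec$box, mask = mask)
      acc <- acc + map_density(cfg, target$grid)$values
    }
  }
  density_field(target$grid, acc / n_samples,
                metadata = list(seed = seed, n_samples = n_samples,
                                n_discard = n_discard, stride = sampler$stride,
                                kappa = sampler$params$kappa,
                                temperature = sampler$params$temperature,
                                sampler = "toy_langevin"))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
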