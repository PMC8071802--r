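#' Boltzmann constant in kJ/(mol K)
#' @export
KB_KJMOL <- 0.0083144621

#' Field-theoretic umbrella parameters
#'
#' The harmonic restraint couples the instantaneous mapped density to a target
#' collective field. Its strength is exposed as `kappa`, the force constant in
#' kJ/mol per squared per-cell bead-count deviation (default 50, the GROMACS
#' value used for MARTINI lipids). The dimensionless field coupling is
#' `lambda = kappa * dV / kBT`.
#'
#' @param kappa restraint strength (kJ/mol per squared count deviation).
#' @param temperature temperature in K (default 300).
#' @return object of class `umbrella_params` with `kappa`, `temperature`,
#'   `kBT` (kJ/mol).
#' @export
umbrella_params <- function(kappa = 50, temperature = 300) {
  if (!is.finite(kappa) || kappa <= 0) stop("kappa must be > 0")
  if (!is.finite(temperature) || temperature <= 0) stop("temperature must be > 0")
  structure(list(kappa = kappa, temperature = temperature,
                 kBT = KB_KJMOL * temperature),
            class = "umbrella_params")
}

# dimensionless umbrella coupling lambda = kappa dV / kBT
umbrella_lambda <- function(params, grid) params$kappa * grid$dV / params$kBT

#' Umbrella restraint energy
#'
#' `(kappa/2) * sum_c (n(c) - nhat(c))^2` with `n(c) = m(c) * dV` the per-cell
#' particle count. Strictly convex in the mapped counts; zero exactly when the
#' mapped field equals the target.
#'
#' @param target,mapped density fields on the same grid (nm^-3).
#' @param params an [umbrella_params()].
#' @return energy in kJ/mol.
#' @export
umbrella_energy <- function(target, mapped, params) {
  check_same_grid(target, mapped)
  dV <- target$grid$dV
  dev <- (target$values - mapped$values) * dV
  0.5 * params$kappa * sum(dev^2)
}

#' Per-particle umbrella forces
#'
#' Analytic gradient of the umbrella energy with respect to particle
#' positions, using the piecewise-linear derivative of the assignment kernel.
#' Unmasked particles feel no force. Exactly at kernel kinks the left-limit
#' derivative is used (a measure-zero set).
#'
#' @param target target density field.
#' @param config a [particle_configuration()] on the same box.
#' @param params an [umbrella_params()].
#' @return numeric matrix (n_particles x 3) of forces in kJ/mol/nm.
#' @export
umbrella_forces <- function(target, config, params) {
  grid <- target$grid
  check_box_match(config, grid)
  mapped <- map_density(config, grid)
  dev <- (target$values - mapped$values) * grid$dV  # count deviation n - nhat
  pos <- config$positions[config$mask, , drop = FALSE]
  st <- cic_stencil(pos, grid)
  nx <- grid$n[1]; nxy <- grid$n[1] * grid$n[2]
  fm <- matrix(0, nrow(pos), 3)
  # derivative of the per-axis weight wrt position: lower cell -1/dL, upper +1/dL
  for (cx in 1:2) for (cy in 1:2) for (cz in 1:2) {
    lin <- st$idx[[1]][, cx] + nx * (st$idx[[2]][, cy] - 1L) +
      nxy * (st$idx[[3]][, cz] - 1L)
    d <- dev[lin]
    wx <- st$wts[[1]][, cx]; wy <- st$wts[[2]][, cy]; wz <- st$wts[[3]][, cz]
    dwx <- (if (cx == 1L) -1 else 1) / grid$dL[1]
    dwy <- (if (cy == 1L) -1 else 1) / grid$dL[2]
    dwz <- (if (cz == 1L) -1 else 1) / grid$dL[3]
    fm[, 1] <- fm[, 1] + d * dwx * wy * wz
    fm[, 2] <- fm[, 2] + d * wx * dwy * wz
    fm[, 3] <- fm[, 3] + d * wx * wy * dwz
  }
  forces <- matrix(0, nrow(config$positions), 3)
  forces[config$mask, ] <- params$kappa * fm
  forces
}

#' Large-coupling chemical-potential estimator
#'
#' Estimates the spatially varying chemical potential
#' `mu(c) = dF / (dV dm(c))` (in kBT) from the mean deviation of the sampled
#' density from the target under the umbrella restraint:
#' `mu(c) = lambda * (target(c) - <mhat(c)>)` with
#' `lambda = kappa * dV / kBT`. Accurate up to order `1/lambda`.
#'
#' @param target target density field.
#' @param mean_mapped time-averaged mapped density under the restraint.
#' @param params an [umbrella_params()].
#' @return a [density_field()]-shaped chemical-potential field (values in kBT).
#' @export
estimate_chemical_potential <- function(target, mean_mapped, params) {
  check_same_grid(target, mean_mapped)
  lam <- umbrella_lambda(params, target$grid)
  mu <- lam * (target$values - mean_mapped$values)
  density_field(target$grid, mu,
                metadata = list(kind = "chemical_potential",
                                kappa = params$kappa,
                                temperature = params$temperature))
}

#' Time-averaged mapped density under the umbrella restraint
#'
#' Runs a sampling engine restrained toward `target`, discards an initial
#' equilibration stretch and returns the time-averaged mapped density.
#' Dispatches on the sampler class (see [make_mock_sampler()] and
#' [langevin_sampler()]).
#'
#' @param sampler a sampling engine object.
#' @param target target density field.
#' @param n_samples number of retained samples (> 0).
#' @param n_discard number of initial samples to discard.
#' @param seed integer seed for the sampler's randomness.
#' @param ... passed to methods.
#' @return a [density_field()] with provenance in `metadata`.
#' @export
restrained_average <- function(sampler, target, n_samples, n_discard = 0,
                               seed = 1L, ...) {
  if (n_samples <= 0) stop("n_samples must be > 0")
  UseMethod("restrained_average")
}
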