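#' String path through order-parameter space
#'
#' An ordered sequence of density-field replicas with contour parameters
#' `s` in `[0, 1]` (`s[1] = 0`, `s[n] = 1`, strictly increasing).
#'
#' @param replicas list of [density_field()]s on a shared grid (n >= 3 for
#'   string evolution; n >= 2 accepted for plumbing).
#' @param s contour parameters; default uniform.
#' @return object of class `string_path`.
#' @export
string_path <- function(replicas, s = NULL) {
  n <- length(replicas)
  if (n < 2L) stop("a string path needs at least 2 replicas")
  for (i in seq_len(n - 1L)) check_same_grid(replicas[[i]], replicas[[i + 1L]])
  if (is.null(s)) s <- seq(0, 1, length.out = n)
  s <- as.numeric(s)
  if (length(s) != n || any(diff(s) <= 0) || abs(s[1]) > 1e-12 ||
      abs(s[n] - 1) > 1e-12)
    stop("contour parameters must increase strictly from 0 to 1")
  s[1] <- 0; s[n] <- 1
  structure(list(replicas = replicas, s = s, grid = replicas[[1]]$grid),
            class = "string_path")
}

#' @export
print.string_path <- function(x, ...) {
  cat(sprintf("<string_path> %d replicas on %d x %d x %d grid\n",
              length(x$replicas), x$grid$n[1], x$grid$n[2], x$grid$n[3]))
  invisible(x)
}

# replica values as an (n_replicas x n_cells) matrix
path_matrix <- function(path) {
  do.call(rbind, lapply(path$replicas, function(f) as.vector(f$values)))
}

matrix_to_path <- function(M, path, s = path$s) {
  reps <- lapply(seq_len(nrow(M)), function(i)
    density_field(path$grid, M[i, ]))
  string_path(reps, s)
}

#' Allen-Cahn step size from the umbrella coupling
#'
#' The production protocol uses a relaxation step with
#' `epsilon * lambda / dV = 0.03`, i.e. `epsilon = 0.03 * kBT / kappa`.
#'
#' @param params an [umbrella_params()].
#' @return step size epsilon.
#' @export
allen_cahn_epsilon <- function(params = umbrella_params()) {
  0.03 * params$kBT / params$kappa
}

#' String-method configuration
#'
#' @param epsilon Allen-Cahn step size; default the production relation
#'   [allen_cahn_epsilon()] at kappa = 50 kJ/mol, T = 300 K.
#' @param max_iterations iteration cap (default 400).
#' @param tol_disp convergence tolerance on the max per-cell displacement per
#'   iteration, relative to the max field magnitude (default 1e-4).
#' @param tol_F relative tolerance on the change of the free-energy profile
#'   between iterations (default 1e-3).
#' @param endpoint_mode `"evolve"` (endpoints relax too; true minima are fixed
#'   points) or `"pinned"` (endpoints held fixed).
#' @param clip_negative clip negative densities to zero after each update
#'   (physical densities); disable for analytic landscapes where negative
#'   field values are meaningful.
#' @param seed integer, recorded in diagnostics (the string update itself is
#'   deterministic; stochastic providers draw from it).
#' @param n_dense_diag dense-grid size for the per-iteration profile estimate.
#' @return object of class `string_config`.
#' @export
string_config <- function(epsilon = allen_cahn_epsilon(),
                          max_iterations = 400L,
                          tol_disp = 1e-4, tol_F = 1e-3,
                          endpoint_mode = c("evolve", "pinned"),
                          clip_negative = TRUE, seed = 1L,
                          n_dense_diag = 201L) {
  endpoint_mode <- match.arg(endpoint_mode)
  if (!is.finite(epsilon) || epsilon <= 0) stop("epsilon must be > 0")
  if (tol_disp <= 0 || tol_F <= 0) stop("tolerances must be > 0")
  structure(list(epsilon = epsilon, max_iterations = as.integer(max_iterations),
                 tol_disp = tol_disp, tol_F = tol_F,
                 endpoint_mode = endpoint_mode,
                 clip_negative = clip_negative, seed = as.integer(seed),
                 n_dense_diag = as.integer(n_dense_diag)),
            class = "string_config")
}

#' Initialize a path by pointwise linear interpolation
#'
#' @param start,end endpoint density fields on a shared grid.
#' @param n number of replicas (>= 3).
#' @return a [string_path()] with replica i equal to
#'   `(1 - t_i) * start + t_i * end`, `t_i = (i-1)/(n-1)`.
#' @export
initialize_path <- function(start, end, n) {
  check_same_grid(start, end)
  if (n < 3L) stop("n must be >= 3")
  t <- seq(0, 1, length.out = n)
  reps <- lapply(t, function(ti)
    density_field(start$grid, (1 - ti) * start$values + ti * end$values))
  reps[[1]] <- start
  reps[[n]] <- end
  string_path(reps)
}

#' One Allen-Cahn relaxation step
#'
#' Per replica and cell, `m_new(c) = m_old(c) - epsilon * mu(c)`. Endpoints
#' are updated too unless `endpoint_mode = "pinned"`. Negative densities are
#' clipped to zero when `clip_negative` is set; the number of clipped cells is
#' returned in the `n_clipped` attribute.
#'
#' @param path a [string_path()].
#' @param mu list of chemical-potential fields, one per replica.
#' @param config a [string_config()].
#' @return the updated [string_path()].
#' @export
allen_cahn_step <- function(path, mu, config = string_config()) {
  n <- length(path$replicas)
  if (length(mu) != n) stop("need one chemical-potential field per replica")
  n_clipped <- 0L
  idx <- if (config$endpoint_mode == "pinned") seq(2L, n - 1L) else seq_len(n)
  reps <- path$replicas
  for (i in idx) {
    if (any(!is.finite(mu[[i]]$values)))
      stop("non-finite chemical potential at replica ", i)
    v <- reps[[i]]$values - config$epsilon * mu[[i]]$values
    if (config$clip_negative) {
      neg <- v < 0
      n_clipped <- n_clipped + sum(neg)
      v[neg] <- 0
    }
    reps[[i]] <- density_field(path$grid, v)
  }
  out <- string_path(reps, path$s)
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Normalized replica segment lengths
#'
#' Euclidean distances between consecutive replicas in cell-value space,
#' normalized so they sum to 1.
#'
#' @param path a [string_path()].
#' @return numeric vector of length `n - 1`, non-negative, summing to 1.
#' @export
replica_distances <- function(path) {
  M <- path_matrix(path)
  d <- sqrt(rowSums((M[-1, , drop = FALSE] - M[-nrow(M), , drop = FALSE])^2))
  tot <- sum(d)
  if (tot <= 0) stop("degenerate path: all replicas identical")
  d / tot
}

#' Redistribute replicas uniformly along the string
#'
#' Fits each cell's value sequence by a natural cubic spline against the
#' cumulative normalized arc length and re-evaluates the replicas at uniform
#' arc-length positions `i/(n-1)`. Endpoints are returned bit-identical to the
#' input endpoints. Iterates (up to `max_passes`) until the replica distances
#' are uniform to 1e-3 relative.
#'
#' @param path a [string_path()].
#' @param max_passes maximum redistribution passes (default 5).
#' @return the reparameterized [string_path()] with uniform `s`.
#' @export
reparameterize <- function(path, max_passes = 5L) {
  n <- length(path$replicas)
  u <- seq(0, 1, length.out = n)
  M <- path_matrix(path)
  start_rep <- path$replicas[[1]]
  end_rep <- path$replicas[[n]]
  for (pass in seq_len(max_passes)) {
    d <- {
      dd <- sqrt(rowSums((M[-1, , drop = FALSE] - M[-n, , drop = FALSE])^2))
      tot <- sum(dd)
      if (tot <= 0) stop("degenerate path: all replicas identical")
      dd / tot
    }
    if (max(abs(d - 1 / (n - 1))) <= 1e-3 / (n - 1) && pass > 1L) break
    shat <- c(0, cumsum(d))
    shat[n] <- 1
    M <- apply(M, 2L, function(y)
      stats::spline(shat, y, xout = u, method = "natural")$y)
    if (max(abs({
      dd <- sqrt(rowSums((M[-1, , drop = FALSE] - M[-n, , drop = FALSE])^2))
      dd / sum(dd) - 1 / (n - 1)
    })) <= 1e-3 / (n - 1)) break
  }
  out <- matrix_to_path(M, path, s = u)
  out$replicas[[1]] <- start_rep
  out$replicas[[n]] <- end_rep
  out
}

# per-replica path tangents dm/ds from a natural cubic spline per cell:
# returns an (n_replicas x n_cells) matrix
path_tangents <- function(path) {
  M <- path_matrix(path)
  n <- nrow(M)
  s <- path$s
  T <- apply(M, 2L, function(y) {
    f <- stats::splinefun(s, y, method = "natural")
    f(s, deriv = 1L)
  })
  matrix(T, nrow = n)
}

#' Component of the chemical potential perpendicular to the path
#'
#' Removes from each replica's chemical potential its projection onto the
#' local path tangent (cubic-spline derivative of the path). At a converged
#' MFEP the perpendicular component vanishes at every interior replica.
#'
#' @param path a [string_path()].
#' @param mu list of chemical-potential fields, one per replica.
#' @return list of perpendicular chemical-potential fields.
#' @export
perpendicular_mu <- function(path, mu) {
  n <- length(path$replicas)
  if (length(mu) != n) stop("need one chemical-potential field per replica")
  Tg <- path_tangents(path)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    tg <- Tg[i, ]
    tt <- sum(tg^2)
    if (tt <= 0) stop("degenerate (zero) tangent at replica ", i)
    mv <- as.vector(mu[[i]]$values)
    perp <- mv - tg * (sum(mv * tg) / tt)
    out[[i]] <- density_field(path$grid, perp, mu[[i]]$metadata)
  }
  out
}

#' Run the string method to convergence
#'
#' Iterates (1) one Allen-Cahn relaxation step per replica using the
#' provider's chemical potential and (2) spline redistribution to uniform arc
#' length, until both the maximum per-cell displacement per iteration falls
#' below `tol_disp * max|m|` and the free-energy profile changes by less than
#' `tol_F` (relative), or `max_iterations` is reached (then a warning status,
#' not an error). Deterministic given a deterministic provider and seed.
#'
#' @param initial a [string_path()] (e.g. from [initialize_path()]).
#' @param provider a chemical-potential provider (see
#'   [make_analytic_provider()] or [sampling_provider()]).
#' @param config a [string_config()].
#' @return list with `path` (converged [string_path()]), `converged`,
#'   `iterations`, `provider_calls`, and `diagnostics` (a data.frame with
#'   per-iteration max displacement, max perpendicular chemical potential,
#'   barrier estimate and clipped-cell count).
#' @export
run_string <- function(initial, provider, config = string_config()) {
  path <- initial
  n <- length(path$replicas)
  diag <- vector("list", config$max_iterations)
  provider_calls <- 0L
  prev_profile <- NULL
  converged <- FALSE
  iter_done <- 0L
  for (iter in seq_len(config$max_iterations)) {
    mu <- lapply(path$replicas, function(r) chemical_potential(provider, r))
    provider_calls <- provider_calls + n
    degenerate <- max(replica_distance_total(path)) <= 0
    max_mu_perp <- NA_real_
    profile <- NULL
    if (!degenerate) {
      max_mu_perp <- max(vapply(perpendicular_mu(path, mu), function(f)
        max(abs(f$values)), 0))
      profile <- integrate_profile(path, mu, n_dense = config$n_dense_diag)
    }
    new_path <- allen_cahn_step(path, mu, config)
    n_clipped <- attr(new_path, "n_clipped")
    if (!all(vapply(seq_len(n - 1L), function(i)
      field_difference_norm(new_path$replicas[[i]],
                            new_path$replicas[[i + 1L]]), 0) == 0)) {
      new_path <- reparameterize(new_path)
    }
    disp <- max(vapply(seq_len(n), function(i)
      max(abs(new_path$replicas[[i]]$values - path$replicas[[i]]$values)), 0))
    dFb <- if (!is.null(profile)) profile$dF_b else 0
    dF_change <- if (is.null(prev_profile) || is.null(profile)) NA_real_ else {
      scale <- max(abs(prev_profile$dF), 1e-12)
      max(abs(profile$dF - prev_profile$dF)) / scale
    }
    diag[[iter]] <- data.frame(iteration = iter, max_displacement = disp,
                               max_mu_perp = max_mu_perp, dF_b = dFb,
                               dF_change = dF_change, n_clipped = n_clipped)
    path <- new_path
    iter_done <- iter
    scale_m <- max(abs(path_matrix(path)))
    disp_ok <- disp < config$tol_disp * max(scale_m, 1e-12)
    F_ok <- degenerate || (!is.na(dF_change) && dF_change < config$tol_F)
    if (disp_ok && F_ok) { converged <- TRUE; break }
    prev_profile <- profile
  }
  if (!converged)
    warning("string method did not converge within max_iterations; ",
            "returning the final path with diagnostics")
  list(path = path, converged = converged, iterations = iter_done,
       provider_calls = provider_calls,
       diagnostics = do.call(rbind, diag[seq_len(iter_done)]),
       config = config)
}

# total (unnormalized) path length
replica_distance_total <- function(path) {
  M <- path_matrix(path)
  sum(sqrt(rowSums((M[-1, , drop = FALSE] - M[-nrow(M), , drop = FALSE])^2)))
}

#' Evaluate the path at arbitrary contour positions
#'
#' Per-cell natural cubic spline of the replica values against `s`.
#'
#' @param path a [string_path()].
#' @param s_out contour positions in `[0, 1]`.
#' @return matrix (length(s_out) x n_cells) of interpolated field values.
#' @export
path_interpolate <- function(path, s_out) {
  M <- path_matrix(path)
  out <- apply(M, 2L, function(y)
    stats::spline(path$s, y, xout = s_out, method = "natural")$y)
  matrix(out, nrow = length(s_out))
}
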