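# cumulative composite Simpson on a uniform grid: returns the running
# integral at every grid point (4th-order; half-intervals use the 3-point
# quadratic rule)
cumulative_simpson <- function(y, h) {
  n <- length(y)
  out <- numeric(n)
  if (n < 2L) return(out)
  if (n == 2L) { out[2] <- h * (y[1] + y[2]) / 2; return(out) }
  for (k in 2:n) {
    inc <- if (k < n) {
      h / 12 * (5 * y[k - 1] + 8 * y[k] - y[k + 1])
    } else {
      h / 12 * (-y[k - 2] + 8 * y[k - 1] + 5 * y[k])
    }
    out[k] <- out[k - 1] + inc
  }
  out
}

#' Thermodynamic integration of the free-energy profile along a path
#'
#' Computes `dF(s) = integral_0^s ds' dV sum_c mu_s'(c) dm_s'(c)/ds'`, with
#' both the path and the chemical potential interpolated per cell by natural
#' cubic splines in `s` and the integral accumulated by composite Simpson on a
#' dense uniform grid. The profile is referenced to `dF(0) = 0` and reported
#' in kBT (the units of the chemical-potential fields).
#'
#' The `"literal"` form integrates `dV sum_c m mu` instead (no `dm/ds`
#' factor); it is provided for comparison only — it is not a line integral of
#' the free-energy gradient and does not vanish at `s = 0` in general.
#'
#' @param path a [string_path()].
#' @param mu list of chemical-potential fields, one per replica (kBT).
#' @param n_dense number of dense quadrature points (>= 201 recommended; made
#'   odd internally).
#' @param form `"ti"` (default, thermodynamic integration) or `"literal"`.
#' @return object of class `free_energy_profile` with `s`, `dF` (kBT),
#'   `stderr` (when the mu fields carry per-cell standard errors), `dF_b`,
#'   `s_b`, `dF_stalk`.
#' @export
integrate_profile <- function(path, mu, n_dense = 201L,
                              form = c("ti", "literal")) {
  form <- match.arg(form)
  n <- length(path$replicas)
  if (length(mu) != n) stop("need one chemical-potential field per replica")
  n_dense <- max(3L, as.integer(n_dense))
  if (n_dense %% 2L == 0L) n_dense <- n_dense + 1L
  s <- path$s
  sd_grid <- seq(0, 1, length.out = n_dense)
  dV <- path$grid$dV
  M <- path_matrix(path)
  MU <- do.call(rbind, lapply(mu, function(f) as.vector(f$values)))
  nc <- ncol(M)
  integrand <- numeric(n_dense)
  for (j in seq_len(nc)) {
    fm <- stats::splinefun(s, M[, j], method = "natural")
    fmu <- stats::splinefun(s, MU[, j], method = "natural")
    integrand <- integrand + if (form == "ti") {
      fmu(sd_grid) * fm(sd_grid, deriv = 1L)
    } else {
      fmu(sd_grid) * fm(sd_grid)
    }
  }
  integrand <- dV * integrand
  dF <- cumulative_simpson(integrand, sd_grid[2] - sd_grid[1])
  se <- profile_stderr(path, mu, sd_grid)
  prof <- structure(list(s = sd_grid, dF = dF, stderr = se),
                    class = "free_energy_profile")
  b <- extract_barrier(prof)
  prof$dF_b <- b$dF_b
  prof$s_b <- b$s_b
  prof$dF_stalk <- b$dF_stalk
  prof
}

# approximate error propagation: per-replica mu standard errors treated as
# independent; each replica's error enters with its trapezoidal arc weight
profile_stderr <- function(path, mu, sd_grid) {
  has_se <- vapply(mu, function(f) !is.null(f$metadata$stderr), TRUE)
  if (!all(has_se)) return(NULL)
  n <- length(mu)
  s <- path$s
  Tg <- path_tangents(path)
  dV <- path$grid$dV
  w <- diff(c(s[1], (s[-n] + s[-1]) / 2, s[n]))  # trapezoid weights
  var_i <- vapply(seq_len(n), function(i) {
    se <- as.vector(mu[[i]]$metadata$stderr)
    (w[i] * dV)^2 * sum((se * Tg[i, ])^2)
  }, 0)
  cum <- sqrt(cumsum(var_i))
  stats::approx(s, cum, xout = sd_grid, rule = 2)$y
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat(sprintf("<free_energy_profile> %d points, dF_b = %.4g kBT at s = %.3f, dF(1) = %.4g kBT\n",
              length(x$s), x$dF_b, x$s_b, x$dF[length(x$dF)]))
  invisible(x)
}

#' Barrier and stalk excess free energy from a profile
#'
#' `dF_b = max_s dF(s)` (with parabolic refinement of the dense-grid maximum;
#' ties broken toward smaller `s`) and `dF_stalk = dF(1)`, the excess free
#' energy of the final state.
#'
#' @param profile a `free_energy_profile`.
#' @return list with `dF_b`, `s_b`, `dF_stalk`.
#' @export
extract_barrier <- function(profile) {
  s <- profile$s
  dF <- profile$dF
  k <- which.max(dF)
  s_b <- s[k]
  dF_b <- dF[k]
  if (k > 1L && k < length(dF)) {
    y1 <- dF[k - 1]; y2 <- dF[k]; y3 <- dF[k + 1]
    denom <- y1 - 2 * y2 + y3
    if (denom < 0) {
      delta <- 0.5 * (y1 - y3) / denom
      h <- s[2] - s[1]
      s_b <- s[k] + delta * h
      dF_b <- y2 - 0.25 * (y1 - y3) * delta
    }
  }
  list(dF_b = dF_b, s_b = s_b, dF_stalk = dF[length(dF)])
}

#' Write a free-energy profile to CSV
#'
#' Columns `s`, `dF_kBT` and, when available, `stderr_kBT`.
#'
#' @param profile a `free_energy_profile`.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
write_profile_csv <- function(profile, file) {
  df <- data.frame(s = profile$s, dF_kBT = profile$dF)
  if (!is.null(profile$stderr)) df$stderr_kBT <- profile$stderr
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
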