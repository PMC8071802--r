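#' Collocation grid specification
#'
#' Defines the rectangular collocation grid on which density order parameters
#' live. Cell lengths are always derived from the box (`dL = box / n`) so the
#' grid tiles the box exactly and the linear assignment kernel forms a
#' partition of unity under periodic wrapping. Cell centers sit at
#' `(i + 1/2) * dL` for `i = 0 .. n-1`.
#'
#' @param n integer vector of length 3, number of cells per axis (or a single
#'   integer recycled to all axes).
#' @param box numeric vector of length 3, box edge lengths in nm (or a single
#'   length recycled).
#' @param periodic logical vector of length 3 (or length 1), periodicity per
#'   axis. Default all periodic.
#' @return An object of class `grid_spec` with fields `n`, `box`, `dL`
#'   (cell lengths, nm), `dV` (cell volume, nm^3) and `periodic`.
#' @examples
#' g <- grid_spec(20, 6)
#' g$dV  # 0.027 nm^3
#' @export
grid_spec <- function(n, box, periodic = TRUE) {
  n <- as.integer(rep_len(n, 3L))
  box <- as.numeric(rep_len(box, 3L))
  periodic <- as.logical(rep_len(periodic, 3L))
  if (any(!is.finite(n)) || any(n < 1L))
    stop("grid_spec: cell counts must be positive integers")
  if (any(!is.finite(box)) || any(box <= 0))
    stop("grid_spec: box lengths must be positive and finite")
  dL <- box / n
  g <- structure(
    list(n = n, box = box, dL = dL, dV = prod(dL), periodic = periodic),
    class = "grid_spec")
  stopifnot(abs(g$dL * n - box) <= 1e-12 * box)
  g
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d cells, box %.4g x %.4g x %.4g nm\n",
              x$n[1], x$n[2], x$n[3], x$box[1], x$box[2], x$box[3]))
  cat(sprintf("  dL = (%.4g, %.4g, %.4g) nm, dV = %.6g nm^3, periodic = %s\n",
              x$dL[1], x$dL[2], x$dL[3], x$dV,
              paste(ifelse(x$periodic, "T", "F"), collapse = "")))
  invisible(x)
}

#' Cell-center coordinates along one axis
#'
#' @param grid a [grid_spec()].
#' @param axis axis index 1..3.
#' @return numeric vector of cell-center coordinates (nm).
#' @export
cell_centers <- function(grid, axis) {
  (seq_len(grid$n[axis]) - 0.5) * grid$dL[axis]
}

#' Wrap positions into the primary box
#'
#' Positions on periodic axes are wrapped into `[0, box)`; non-periodic axes
#' must already lie inside the box.
#'
#' @param positions numeric matrix, one row per particle, columns x/y/z (nm).
#' @param box numeric length-3 box (nm).
#' @param periodic logical length-3.
#' @return wrapped position matrix.
#' @export
wrap_positions <- function(positions, box, periodic = c(TRUE, TRUE, TRUE)) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("positions must have 3 columns")
  if (any(!is.finite(positions))) stop("non-finite positions")
  for (a in 1:3) {
    if (periodic[a]) {
      positions[, a] <- positions[, a] %% box[a]
    } else if (any(positions[, a] < 0 | positions[, a] >= box[a])) {
      stop("positions outside non-periodic box on axis ", a)
    }
  }
  positions
}

#' Particle configuration
#'
#' A set of particle positions in a periodic box together with a logical mask
#' selecting the particles that carry the order parameter (for lipid systems:
#' the hydrophobic tail beads).
#'
#' @param positions numeric matrix (n x 3) of positions in nm.
#' @param box numeric length-3 box lengths (nm).
#' @param mask logical vector (length n) or integer indices of selected
#'   particles; defaults to all particles.
#' @param periodic logical length-3 (or 1), default periodic.
#' @return An object of class `particle_configuration` with wrapped positions.
#' @export
particle_configuration <- function(positions, box, mask = NULL,
                                   periodic = TRUE) {
  box <- as.numeric(rep_len(box, 3L))
  periodic <- as.logical(rep_len(periodic, 3L))
  positions <- wrap_positions(positions, box, periodic)
  np <- nrow(positions)
  if (is.null(mask)) mask <- rep(TRUE, np)
  if (is.numeric(mask)) mask <- seq_len(np) %in% as.integer(mask)
  mask <- as.logical(mask)
  if (length(mask) != np) stop("mask length must match particle count")
  structure(list(positions = positions, box = box, mask = mask,
                 periodic = periodic),
            class = "particle_configuration")
}

#' @export
print.particle_configuration <- function(x, ...) {
  cat(sprintf("<particle_configuration> %d particles (%d masked), box %.4g x %.4g x %.4g nm\n",
              nrow(x$positions), sum(x$mask), x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

check_box_match <- function(config, grid, rtol = 1e-9) {
  if (any(abs(config$box - grid$box) > rtol * grid$box))
    stop("particle configuration box does not match grid box")
  invisible(TRUE)
}
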