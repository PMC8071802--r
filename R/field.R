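#' Density order-parameter field
#'
#' A scalar field `m(c)` (units nm^-3) on a collocation grid: the central
#' currency of the MFEP pipeline.
#'
#' @param grid a [grid_spec()].
#' @param values numeric array with dim `grid$n`, or a single number recycled,
#'   or a vector of length `prod(grid$n)` (column-major).
#' @param metadata optional named list of provenance / ground-truth attributes
#'   carried along with the field (seeds, construction parameters, known
#'   interface positions of synthetic fixtures, ...).
#' @return An object of class `density_field` with fields `grid`, `values`
#'   (3D array) and `metadata`.
#' @export
density_field <- function(grid, values = 0, metadata = list()) {
  stopifnot(inherits(grid, "grid_spec"))
  nc <- prod(grid$n)
  if (length(values) == 1L) values <- rep(as.numeric(values), nc)
  if (is.null(dim(values))) {
    if (length(values) != nc) stop("values length does not match grid")
    dim(values) <- grid$n
  } else if (!all(dim(values) == grid$n)) {
    stop("values dimensions do not match grid")
  }
  if (any(!is.finite(values))) stop("density_field: non-finite values")
  structure(list(grid = grid, values = values, metadata = metadata),
            class = "density_field")
}

#' @export
print.density_field <- function(x, ...) {
  cat(sprintf("<density_field> %d x %d x %d, range [%.4g, %.4g] nm^-3\n",
              x$grid$n[1], x$grid$n[2], x$grid$n[3],
              min(x$values), max(x$values)))
  invisible(x)
}

same_grid <- function(a, b) {
  all(a$grid$n == b$grid$n) && all(abs(a$grid$box - b$grid$box) <=
                                     1e-12 * a$grid$box)
}

check_same_grid <- function(a, b) {
  if (!same_grid(a, b)) stop("fields are defined on different grids")
  invisible(TRUE)
}

#' Euclidean distance between two density fields
#'
#' Plain root-sum-of-squares over cells, `sqrt(sum_c (a(c) - b(c))^2)`; the
#' metric used by string-method convergence monitoring and replica distances.
#'
#' @param a,b density fields on the same grid.
#' @return non-negative scalar; zero iff the fields are identical.
#' @export
field_difference_norm <- function(a, b) {
  check_same_grid(a, b)
  sqrt(sum((a$values - b$values)^2))
}

#' Replace the values of a field (keeping grid and metadata)
#' @param field a [density_field()].
#' @param values new values (array, vector or scalar).
#' @return a new `density_field`.
#' @export
field_with_values <- function(field, values) {
  density_field(field$grid, values, field$metadata)
}

# discrete periodic Laplacian of an array on a grid (nm^-2 scaling per axis);
# length-1 axes contribute zero (neighbor is the cell itself)
grid_laplacian <- function(values, grid) {
  lap <- array(0, dim = grid$n)
  for (a in 1:3) {
    if (grid$n[a] < 2L) next
    up <- shift_array(values, a, 1L)
    dn <- shift_array(values, a, -1L)
    lap <- lap + (up - 2 * values + dn) / grid$dL[a]^2
  }
  lap
}

# circular shift of a 3D array along one axis
shift_array <- function(x, axis, by) {
  n <- dim(x)[axis]
  idx <- ((seq_len(n) - 1L - by) %% n) + 1L
  switch(axis, x[idx, , , drop = FALSE], x[, idx, , drop = FALSE],
         x[, , idx, drop = FALSE])
}
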