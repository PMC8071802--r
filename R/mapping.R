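#' Linear (cloud-in-cell) assignment weight
#'
#' Weight with which a particle at `position` contributes to the cell with
#' center `cell_center`: the product over axes of the tent kernel
#' `pi_a(d) = 1 - |d| / dL_a` for `|d| <= dL_a` and 0 otherwise, with the
#' per-axis distance taken by minimum-image convention on periodic axes. The
#' kernel is a partition of unity over the grid, so mapped fields conserve the
#' particle number exactly.
#'
#' @param cell_center numeric length-3 cell center (nm).
#' @param position numeric length-3 particle position (nm), inside the box.
#' @param grid a [grid_spec()].
#' @return a weight in `[0, 1]`.
#' @examples
#' g <- grid_spec(10, 5)
#' assignment_weight(c(0.25, 0.25, 0.25), c(0.25, 0.25, 0.25), g)  # 1
#' @export
assignment_weight <- function(cell_center, position, grid) {
  if (any(!is.finite(cell_center)) || any(!is.finite(position)))
    stop("assignment_weight: non-finite input")
  w <- 1
  for (a in 1:3) {
    d <- abs(position[a] - cell_center[a])
    if (grid$periodic[a]) d <- min(d, grid$box[a] - d)
    w <- w * if (d <= grid$dL[a]) 1 - d / grid$dL[a] else 0
  }
  w
}

# cloud-in-cell stencil for a matrix of wrapped positions: per axis, the two
# bracketing cell indices (1-based, wrapped) and their weights
cic_stencil <- function(positions, grid) {
  idx <- vector("list", 3L)
  wts <- vector("list", 3L)
  for (a in 1:3) {
    f <- positions[, a] / grid$dL[a] - 0.5
    ilo <- floor(f)
    t <- f - ilo
    na <- grid$n[a]
    i0 <- as.integer(ilo %% na) + 1L
    i1 <- as.integer((ilo + 1) %% na) + 1L
    w0 <- 1 - t
    w1 <- t
    if (!grid$periodic[a]) {
      # drop wrap-around contributions on non-periodic axes
      bad0 <- ilo < 0
      bad1 <- (ilo + 1) > (na - 1)
      w0[bad0] <- 0
      w1[bad1] <- 0
    }
    idx[[a]] <- cbind(i0, i1)
    wts[[a]] <- cbind(w0, w1)
  }
  list(idx = idx, wts = wts)
}

#' Map a particle configuration onto a density field
#'
#' Cloud-in-cell mapping of the masked (hydrophobic) particles onto the grid:
#' `m(c) = (1/dV) * sum_i Pi(c, r_i)`. Each particle contributes to at most
#' 8 cells; the sum `sum_c m(c) * dV` equals the number of masked particles.
#'
#' @param config a [particle_configuration()].
#' @param grid a [grid_spec()]; its box must match the configuration box.
#' @return a [density_field()] in nm^-3.
#' @export
map_density <- function(config, grid) {
  stopifnot(inherits(config, "particle_configuration"))
  check_box_match(config, grid)
  pos <- config$positions[config$mask, , drop = FALSE]
  if (nrow(pos) == 0L) stop("map_density: empty hydrophobic selection")
  st <- cic_stencil(pos, grid)
  nc <- prod(grid$n)
  acc <- numeric(nc)
  nx <- grid$n[1]; nxy <- grid$n[1] * grid$n[2]
  for (cx in 1:2) for (cy in 1:2) for (cz in 1:2) {
    w <- st$wts[[1]][, cx] * st$wts[[2]][, cy] * st$wts[[3]][, cz]
    lin <- st$idx[[1]][, cx] + nx * (st$idx[[2]][, cy] - 1L) +
      nxy * (st$idx[[3]][, cz] - 1L)
    s <- rowsum(w, group = lin)
    acc[as.integer(rownames(s))] <- acc[as.integer(rownames(s))] + s[, 1]
  }
  density_field(grid, acc / grid$dV)
}
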