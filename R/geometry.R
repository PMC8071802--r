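axis_index <- function(axis) {
  if (is.character(axis)) match(tolower(axis), c("x", "y", "z")) else
    as.integer(axis)
}

# permute the field array so the requested axis is the third dimension;
# returns list(values, lat_axes, centers of the two lateral axes and the
# axial axis, axial box length and cell length, lateral periodicity)
axial_view <- function(field, axis) {
  a <- axis_index(axis)
  lat <- setdiff(1:3, a)
  perm <- c(lat, a)
  list(values = aperm(field$values, perm), lat = lat, ax = a,
       c1 = cell_centers(field$grid, lat[1]),
       c2 = cell_centers(field$grid, lat[2]),
       cz = cell_centers(field$grid, a),
       Lz = field$grid$box[a], dLz = field$grid$dL[a],
       periodic_z = field$grid$periodic[a])
}

# above-threshold segments of a single column (circular): matrix with columns
# start, end (end may wrap past L); interpolated crossing positions
column_segments <- function(v, centers, L, thr) {
  n <- length(v)
  above <- v >= thr
  if (!any(above)) return(NULL)
  if (all(above)) return(matrix(c(0, L), 1L, 2L,
                                dimnames = list(NULL, c("start", "end"))))
  nxt <- c(2:n, 1L)
  dz <- L / n
  starts <- which(!above & above[nxt])      # crossing between k and k+1
  ends <- which(above & !above[nxt])
  zs <- centers[starts] + (thr - v[starts]) / (v[nxt[starts]] - v[starts]) * dz
  ze <- centers[ends] + (thr - v[ends]) / (v[nxt[ends]] - v[ends]) * dz
  zs <- zs %% L
  ze <- ze %% L
  zs <- sort(zs)
  ze <- sort(ze)
  # pair each start with the next end (circularly)
  k <- length(zs)
  seg <- matrix(NA_real_, k, 2L, dimnames = list(NULL, c("start", "end")))
  for (i in seq_len(k)) {
    e <- ze[ze > zs[i]]
    seg[i, ] <- c(zs[i], if (length(e)) e[1] else ze[1] + L)
  }
  seg
}

# per-plane summary along the axial direction
plane_stats <- function(av, thr) {
  nz <- dim(av$values)[3]
  M <- apply(av$values, 3L, max)
  phi <- apply(av$values, 3L, function(s) mean(s >= thr))
  list(M = M, phi = phi, nz = nz)
}

# circular runs of TRUE in a logical vector; returns list of index vectors
circular_runs <- function(flag) {
  n <- length(flag)
  if (!any(flag)) return(list())
  if (all(flag)) return(list(seq_len(n)))
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  runs <- lapply(which(r$values), function(i) starts[i]:ends[i])
  # merge a wrap-around run
  if (flag[1] && flag[n] && length(runs) > 1L) {
    runs[[1]] <- c(runs[[length(runs)]], runs[[1]])
    runs[[length(runs)]] <- NULL
  }
  runs
}

# detect an interior dip of the above-threshold area fraction inside a
# structure arc (plane indices in circular order): a plane above threshold
# whose area fraction is far below the flanking maxima signals a narrow
# bridge (stalk) connecting two membrane bodies
find_bridge_dip <- function(arc, M, phi, thr, ratio = 0.3) {
  k <- length(arc)
  if (k < 3L) return(NULL)
  for (p in 2:(k - 1L)) {
    z <- arc[p]
    if (M[z] < thr || phi[z] <= 0) next
    left <- max(phi[arc[1:(p - 1L)]])
    right <- max(phi[arc[(p + 1L):k]])
    if (left > 0 && right > 0 && phi[z] < ratio * min(left, right))
      return(arc[p])
  }
  NULL
}

#' Minimal intermembrane (water-gap) distance
#'
#' Measures `d_w`, the minimal water gap between two membrane bodies along
#' the given axis at an iso-density threshold. For every lateral grid column,
#' threshold crossings are located by linear sub-cell interpolation and the
#' circular gap spanning each separating water slab (a set of axial planes
#' whose maximum density lies below the threshold) is computed; `d_w` is the
#' minimum over columns and slabs. A vesicle's periodic image counts as the
#' second body. Returns 0 when the bodies are connected (no separating water
#' plane, or a narrow above-threshold bridge detected between them).
#'
#' @param field a [density_field()].
#' @param threshold iso-density level (nm^-3, default 2.2).
#' @param axis membrane normal / stalk axis (default `"z"`).
#' @return object of class `geometry_distance`: list with `d_w` (nm),
#'   `threshold`, `axis`, and the lateral indices of the minimal-gap column.
#' @export
intermembrane_distance <- function(field, threshold = 2.2, axis = "z") {
  av <- axial_view(field, axis)
  ps <- plane_stats(av, threshold)
  if (!any(ps$M >= threshold))
    stop("undefined distance: no membrane bodies above the threshold")
  out <- function(d, col = c(NA, NA))
    structure(list(d_w = d, threshold = threshold, axis = axis,
                   column = col), class = "geometry_distance")
  water <- ps$M < threshold
  if (!any(water)) return(out(0))
  # bridged membranes: interior area-fraction dip inside a structure arc
  arcs <- circular_runs(!water)
  for (arc in arcs) {
    if (!is.null(find_bridge_dip(arc, ps$M, ps$phi, threshold)))
      return(out(0))
  }
  bands <- circular_runs(water)
  n1 <- dim(av$values)[1]; n2 <- dim(av$values)[2]
  best <- Inf
  best_col <- c(NA, NA)
  for (band in bands) {
    zB <- av$cz[band[which.min(ps$M[band])]]
    for (i in seq_len(n1)) for (j in seq_len(n2)) {
      v <- av$values[i, j, ]
      seg <- column_segments(v, av$cz, av$Lz, threshold)
      if (is.null(seg) || nrow(seg) == 0L) next
      if (seg[1, 1] == 0 && seg[1, 2] == av$Lz) next
      # gap containing zB: from the segment end preceding zB to the next start
      ends <- seg[, 2] %% av$Lz
      starts <- seg[, 1]
      prev_end <- max(ends[ends <= zB], -Inf)
      if (!is.finite(prev_end)) prev_end <- max(ends) - av$Lz
      nxt_start <- min(starts[starts >= zB], Inf)
      if (!is.finite(nxt_start)) nxt_start <- min(starts) + av$Lz
      g <- nxt_start - prev_end
      if (g < best) { best <- g; best_col <- c(i, j) }
    }
  }
  if (!is.finite(best))
    stop("undefined distance: fewer than two membrane bodies along the axis")
  out(best, best_col)
}

#' @export
print.geometry_distance <- function(x, ...) {
  cat(sprintf("<d_w> %.4g nm (threshold %.3g nm^-3, axis %s)\n",
              x$d_w, x$threshold, as.character(x$axis)))
  invisible(x)
}

# circularly recenter a matrix so cell (i0, j0) moves to the central cell
recenter_slice <- function(S, i0, j0) {
  n1 <- nrow(S); n2 <- ncol(S)
  si <- ((seq_len(n1) - 1L + (i0 - 1L) - (n1 %/% 2L)) %% n1) + 1L
  sj <- ((seq_len(n2) - 1L + (j0 - 1L) - (n2 %/% 2L)) %% n2) + 1L
  S[si, sj, drop = FALSE]
}

point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((vy[i] > py) != (vy[j] > py) &&
        px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
      inside <- !inside
    j <- i
  }
  inside
}

polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# interpolated 2D lateral slice at axial coordinate z (between plane centers)
axial_slice <- function(av, z) {
  nz <- dim(av$values)[3]
  f <- (z %% av$Lz) / av$dLz - 0.5
  k0 <- floor(f)
  t <- f - k0
  i0 <- (as.integer(k0) %% nz) + 1L
  i1 <- (as.integer(k0 + 1) %% nz) + 1L
  (1 - t) * av$values[, , i0] + t * av$values[, , i1]
}

#' Stalk diameter at the mid-plane
#'
#' Locates the mid-plane between the two membrane bodies, extracts the
#' above-threshold cross-section of the stalk on that plane (recentred
#' circularly on the densest lateral cell so periodic wrap does not split
#' the contour), and returns the diameter of the circle with the same area as
#' the enclosed iso-density contour. `method = "chord"` returns the maximal
#' chord of the contour instead. Returns `NA` (absent) when no
#' above-threshold connection spans the gap.
#'
#' @param field a [density_field()].
#' @param threshold iso-density level (nm^-3, default 2.2).
#' @param axis stalk axis (default `"z"`).
#' @param method `"area"` (area-equivalent diameter, default) or `"chord"`.
#' @return list of class `stalk_diameter` with `d_st` (nm or `NA`), `z_mid`,
#'   `area` (nm^2), `threshold`, `method`.
#' @export
stalk_diameter <- function(field, threshold = 2.2, axis = "z",
                           method = c("area", "chord")) {
  method <- match.arg(method)
  av <- axial_view(field, axis)
  ps <- plane_stats(av, threshold)
  absent <- structure(list(d_st = NA_real_, z_mid = NA_real_,
                           area = NA_real_, threshold = threshold,
                           method = method), class = "stalk_diameter")
  if (!any(ps$M >= threshold)) return(absent)
  water <- ps$M < threshold
  bands <- circular_runs(water)
  if (length(bands) >= 2L) return(absent)  # two separated bodies, no bridge
  z_dip <- NULL
  if (length(bands) == 1L) {
    arcs <- circular_runs(!water)
    for (arc in arcs) {
      z_dip <- find_bridge_dip(arc, ps$M, ps$phi, threshold)
      if (!is.null(z_dip)) { arc_found <- arc; break }
    }
    if (is.null(z_dip)) return(absent)
    # mid-plane: midpoint of the density-weighted centers of the two membrane
    # parts on either side of the dip, in arc-local coordinates
    p <- match(z_dip, arc_found)
    rho <- apply(av$values, 3L, mean)
    zl <- arc_found[1:(p - 1L)]; zr <- arc_found[(p + 1L):length(arc_found)]
    unwrap <- function(idx) {
      u <- av$cz[idx]
      if (length(u) > 1L) {
        for (q in 2:length(u)) if (u[q] < u[q - 1L]) u[q:length(u)] <-
            u[q:length(u)] + av$Lz
      }
      u
    }
    ua <- unwrap(arc_found)
    ul <- ua[1:(p - 1L)]; ur <- ua[(p + 1L):length(arc_found)]
    c1 <- sum(ul * rho[zl]) / sum(rho[zl])
    c2 <- sum(ur * rho[zr]) / sum(rho[zr])
    z_mid <- ((c1 + c2) / 2) %% av$Lz
  } else {
    # no separating water plane anywhere: bodies fully bridged; take the
    # plane of minimal above-threshold area fraction as the waist
    k <- which.min(ps$phi)
    if (ps$phi[k] >= 0.3 * max(ps$phi)) return(absent)
    z_mid <- av$cz[k]
  }
  S <- axial_slice(av, z_mid)
  if (max(S) < threshold) return(absent)
  ij <- which(S == max(S), arr.ind = TRUE)[1, ]
  Sc <- recenter_slice(S, ij[1], ij[2])
  cl <- grDevices::contourLines(av$c1, av$c2, Sc, levels = threshold)
  if (!length(cl)) return(absent)
  px <- av$c1[nrow(Sc) %/% 2L + 1L]
  py <- av$c2[ncol(Sc) %/% 2L + 1L]
  for (poly in cl) {
    if (point_in_polygon(px, py, poly$x, poly$y)) {
      area <- polygon_area(poly$x, poly$y)
      d_st <- if (method == "area") 2 * sqrt(area / pi) else {
        max(stats::dist(cbind(poly$x, poly$y)))
      }
      return(structure(list(d_st = d_st, z_mid = z_mid, area = area,
                            threshold = threshold, method = method),
                       class = "stalk_diameter"))
    }
  }
  absent
}

#' @export
print.stalk_diameter <- function(x, ...) {
  if (is.na(x$d_st)) cat("<d_st> absent (no stalk connection)\n") else
    cat(sprintf("<d_st> %.4g nm (%s, mid-plane z = %.3g nm)\n",
                x$d_st, x$method, x$z_mid))
  invisible(x)
}

#' Iso-density contours on a planar slice
#'
#' Marching-squares contours (with linear sub-cell interpolation) of the
#' field on the 2D slice perpendicular to `axis` at `coordinate`. Contours
#' are computed on the primary cell-center lattice and are not continued
#' across periodic boundaries.
#'
#' @param field a [density_field()].
#' @param threshold iso-density level (nm^-3, default 2.2).
#' @param axis slice normal (default `"y"`, giving (x, z)-plane contours).
#' @param coordinate position of the slice along `axis` (nm); default the box
#'   center.
#' @return list of polylines, each a data.frame with the two in-plane
#'   coordinates (named after the axes); empty (with a warning) when the
#'   threshold lies outside the field's range.
#' @export
interface_contour <- function(field, threshold = 2.2, axis = "y",
                              coordinate = NULL) {
  a <- axis_index(axis)
  if (is.null(coordinate)) coordinate <- field$grid$box[a] / 2
  if (threshold <= min(field$values) || threshold >= max(field$values)) {
    warning("threshold outside the field's value range; no contours")
    return(list())
  }
  av <- axial_view(field, a)
  S <- axial_slice(av, coordinate)
  cl <- grDevices::contourLines(av$c1, av$c2, S, levels = threshold)
  nms <- c("x", "y", "z")[av$lat]
  lapply(cl, function(p) stats::setNames(data.frame(p$x, p$y), nms))
}

#' Azimuthally averaged (R, z) density map
#'
#' Bins cells by lateral (minimum-image) distance `R` from an axis parallel
#' to the axial direction and by axial coordinate `z`, and averages the
#' density per bin.
#'
#' @param field a [density_field()].
#' @param center lateral (x, y) position of the axis; default the box center.
#' @param axis axial direction (default `"z"`).
#' @param n_radial_bins number of radial bins (> 0).
#' @return object of class `axial_profile`: `r` (bin centers, nm), `z` (plane
#'   centers, nm), `mean` (n_r x n_z matrix, nm^-3; `NaN` where empty),
#'   `count` (cells per bin).
#' @export
azimuthal_average <- function(field, center = NULL, axis = "z",
                              n_radial_bins = 30L) {
  if (n_radial_bins < 1L) stop("need at least one radial bin")
  av <- axial_view(field, axis_index(axis))
  if (is.null(center)) center <- field$grid$box[av$lat] / 2
  d1 <- mi_delta(av$c1 - center[1], field$grid$box[av$lat[1]],
                 field$grid$periodic[av$lat[1]])
  d2 <- mi_delta(av$c2 - center[2], field$grid$box[av$lat[2]],
                 field$grid$periodic[av$lat[2]])
  R <- sqrt(outer(d1^2, d2^2, `+`))
  breaks <- seq(0, max(R) * (1 + 1e-12), length.out = n_radial_bins + 1L)
  bin <- matrix(findInterval(R, breaks, rightmost.closed = TRUE),
                nrow = nrow(R))
  nz <- dim(av$values)[3]
  mean_m <- matrix(NaN, n_radial_bins, nz)
  count <- matrix(0L, n_radial_bins, nz)
  for (k in seq_len(nz)) {
    s <- av$values[, , k]
    sums <- tapply(as.vector(s), as.vector(bin), sum)
    ns <- table(as.vector(bin))
    idx <- as.integer(names(sums))
    count[idx, k] <- as.integer(ns)
    mean_m[idx, k] <- sums / as.integer(ns)
  }
  structure(list(r = (breaks[-1] + breaks[-length(breaks)]) / 2, z = av$cz,
                 mean = mean_m, count = count),
            class = "axial_profile")
}

#' Membrane thickness versus lateral distance from an axis
#'
#' For each lateral column, the axial extents of the above-threshold segments
#' (one per membrane body crossed) are measured with sub-cell interpolation;
#' columns are binned by lateral distance from the axis and the mean segment
#' extent per bin is returned. Columns whose segment count differs from the
#' modal count (e.g. columns bridged by a stalk) are excluded and counted in
#' `n_excluded`.
#'
#' @param field a [density_field()].
#' @param threshold iso-density level (nm^-3, default 2.2).
#' @param center lateral axis position; default the box center.
#' @param axis axial direction (default `"z"`).
#' @param n_bins number of lateral-distance bins.
#' @return data.frame with `r`, `thickness` (nm), `n` columns per bin and an
#'   `n_excluded` attribute; empty for an empty field.
#' @export
thickness_profile <- function(field, threshold = 2.2, center = NULL,
                              axis = "z", n_bins = 20L) {
  av <- axial_view(field, axis_index(axis))
  if (is.null(center)) center <- field$grid$box[av$lat] / 2
  if (!any(field$values >= threshold))
    return(data.frame(r = numeric(0), thickness = numeric(0), n = integer(0)))
  d1 <- mi_delta(av$c1 - center[1], field$grid$box[av$lat[1]],
                 field$grid$periodic[av$lat[1]])
  d2 <- mi_delta(av$c2 - center[2], field$grid$box[av$lat[2]],
                 field$grid$periodic[av$lat[2]])
  n1 <- length(d1); n2 <- length(d2)
  rs <- nsegs <- exts <- numeric(0)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    seg <- column_segments(av$values[i, j, ], av$cz, av$Lz, threshold)
    if (is.null(seg)) next
    rs <- c(rs, sqrt(d1[i]^2 + d2[j]^2))
    nsegs <- c(nsegs, nrow(seg))
    exts <- c(exts, mean(seg[, 2] - seg[, 1]))
  }
  if (!length(rs))
    return(data.frame(r = numeric(0), thickness = numeric(0), n = integer(0)))
  modal <- as.integer(names(which.max(table(nsegs))))
  keep <- nsegs == modal
  breaks <- seq(0, max(rs) * (1 + 1e-12), length.out = n_bins + 1L)
  bin <- findInterval(rs[keep], breaks, rightmost.closed = TRUE)
  th <- tapply(exts[keep], bin, mean)
  nn <- table(bin)
  out <- data.frame(r = ((breaks[-1] + breaks[-length(breaks)]) / 2)[
    as.integer(names(th))],
    thickness = as.numeric(th), n = as.integer(nn))
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Per-replica geometry table along a path
#'
#' Convenience wrapper computing `d_w` and `d_st` for every replica of a
#' string path.
#'
#' @param path a [string_path()].
#' @param threshold iso-density level (nm^-3, default 2.2).
#' @param axis stalk axis.
#' @return data.frame with columns `s`, `d_w`, `d_st`.
#' @export
path_geometry <- function(path, threshold = 2.2, axis = "z") {
  rows <- lapply(seq_along(path$replicas), function(i) {
    f <- path$replicas[[i]]
    dw <- tryCatch(intermembrane_distance(f, threshold, axis)$d_w,
                   error = function(e) NA_real_)
    dst <- stalk_diameter(f, threshold, axis)$d_st
    data.frame(s = path$s[i], d_w = dw, d_st = dst)
  })
  do.call(rbind, rows)
}
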