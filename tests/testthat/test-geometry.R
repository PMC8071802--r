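# shared fixtures: moderately resolved grids keep the suite fast while the
# half-cell tolerances of the constructed-field oracles still bind
bilayer_fixture <- function() {
  g <- grid_spec(c(40, 40, 60), c(12, 12, 12))
  list(grid = g,
       field = make_bilayer_field(g, gap = 1.2, thickness = 3,
                                  interface_width = 0.25))
}

vesicle_fixture <- function() {
  g <- grid_spec(90, c(26.31, 26.83, 20.74))
  list(grid = g,
       field = make_vesicle_pair_field(g, R_v = 9.2, thickness = 3.5,
                                       interface_width = 0.25, gap = 2.3))
}

test_that("iso-density contours recover constructed interfaces", {
  bf <- bilayer_fixture()
  cl <- interface_contour(bf$field, 2.2, axis = "y")
  expect_length(cl, 4L)  # two interfaces per slab
  # each contour is a horizontal line at a known crossing height
  crossings <- sort(unname(bf$field$metadata$crossings))
  heights <- sort(vapply(cl, function(p) mean(p$z), 0))
  expect_equal(heights, crossings, tolerance = bf$grid$dL[3] / 2)
  expect_true(all(vapply(cl, function(p) diff(range(p$z)), 0) < 1e-6))

  vf <- vesicle_fixture()
  cv <- interface_contour(vf$field, 2.2, axis = "y")
  expect_length(cv, 2L)
  ctr <- vf$field$metadata$center[c(1, 3)]
  radii <- sort(vapply(cv, function(p)
    mean(sqrt((p$x - ctr[1])^2 + (p$z - ctr[2])^2)), 0))
  expect_equal(radii,
               c(vf$field$metadata$R_inner_threshold,
                 vf$field$metadata$R_outer_threshold),
               tolerance = max(vf$grid$dL) / 2)

  expect_warning(got <- interface_contour(density_field(bf$grid, 1), 2.2),
                 "outside")
  expect_length(got, 0L)
})

test_that("intermembrane distance recovers built gaps for slabs and vesicles", {
  bf <- bilayer_fixture()
  expect_equal(intermembrane_distance(bf$field)$d_w, 1.2,
               tolerance = bf$grid$dL[3] / 2)
  vf <- vesicle_fixture()
  expect_equal(intermembrane_distance(vf$field)$d_w, 2.3,
               tolerance = vf$grid$dL[3] / 2)
  # connected fields have zero distance; empty fields are an error
  stalk <- make_stalk_field(bf$field, neck_radius = 1.6)
  expect_equal(intermembrane_distance(stalk)$d_w, 0)
  touching <- make_vesicle_pair_field(grid_spec(c(30, 30, 40), c(12, 12, 12)),
                                      R_v = 6, thickness = 2.5, gap = 0)
  expect_equal(intermembrane_distance(touching)$d_w, 0)
  expect_error(intermembrane_distance(density_field(bf$grid, 0.1)),
               "undefined")
})

test_that("stalk diameter measures the constructed neck or reports absence", {
  bf <- bilayer_fixture()
  stalk <- make_stalk_field(bf$field, neck_radius = 1.6)
  d <- stalk_diameter(stalk)
  expect_equal(d$d_st, 3.2, tolerance = bf$grid$dL[1])
  expect_true(is.na(stalk_diameter(bf$field)$d_st))
  # elliptical bridge: area-equivalent diameter is 2 sqrt(ab)
  g <- bf$grid
  ell <- field_with_values(bf$field, {
    v <- bf$field$values
    cx <- cell_centers(g, 1) - 6; cy <- cell_centers(g, 2) - 6
    cz <- cell_centers(g, 3) - 6
    a_ax <- 2.0; b_ax <- 1.0
    for (k in which(abs(cz) < 2.2)) {
      r2 <- outer((cx / a_ax)^2, (cy / b_ax)^2, `+`)
      v[, , k] <- pmax(v[, , k], ifelse(r2 <= 1, 5, 0))
    }
    v
  })
  de <- stalk_diameter(ell)
  expect_equal(de$d_st, 2 * sqrt(2.0 * 1.0), tolerance = max(g$dL[1:2]))
  # max-chord alternative reports the major axis instead
  dc <- stalk_diameter(ell, method = "chord")
  expect_equal(dc$d_st, 2 * 2.0, tolerance = 2 * max(g$dL[1:2]))
})

test_that("threshold shifts move d_w and d_st in opposite directions", {
  bf <- bilayer_fixture()
  stalk <- make_stalk_field(bf$field, neck_radius = 1.6)
  d_lo <- intermembrane_distance(bf$field, 2.2)$d_w
  d_hi <- intermembrane_distance(bf$field, 3.2)$d_w
  expect_gt(d_hi, d_lo)
  s_lo <- stalk_diameter(stalk, 2.2)$d_st
  s_hi <- stalk_diameter(stalk, 3.2)$d_st
  expect_lt(s_hi, s_lo)
})

test_that("distances are invariant under lateral periodic translation", {
  bf <- bilayer_fixture()
  stalk <- make_stalk_field(bf$field, neck_radius = 1.6)
  shift_xy <- function(f, i, j) {
    n <- f$grid$n
    v <- f$values[c((i + 1):n[1], 1:i), c((j + 1):n[2], 1:j), ]
    density_field(f$grid, v)
  }
  moved <- shift_xy(stalk, 13, 27)
  expect_equal(stalk_diameter(moved)$d_st, stalk_diameter(stalk)$d_st,
               tolerance = 1e-9)
  bmoved <- shift_xy(bf$field, 13, 27)
  expect_equal(intermembrane_distance(bmoved)$d_w,
               intermembrane_distance(bf$field)$d_w, tolerance = 1e-9)
})

test_that("distances scale linearly under uniform rescaling", {
  bf <- bilayer_fixture()
  g2 <- grid_spec(bf$grid$n, 2 * bf$grid$box)
  scaled <- density_field(g2, bf$field$values)
  expect_equal(intermembrane_distance(scaled)$d_w,
               2 * intermembrane_distance(bf$field)$d_w, tolerance = 1e-9)
})

test_that("azimuthal averages reproduce axisymmetric generators", {
  bf <- bilayer_fixture()
  stalk <- make_stalk_field(bf$field, neck_radius = 1.6)
  ap <- azimuthal_average(stalk, n_radial_bins = 24)
  expect_equal(dim(ap$mean), c(24L, 60L))
  expect_true(all(ap$count >= 0))
  # reconstruct the generating (R, z) function at bin centers and compare
  # where bins are populated and inside the bridge window
  md <- stalk$metadata
  rho_w <- md$stalk$neck_radius +
    md$interface_width * atanh(2 * md$threshold / md$bulk_density - 1)
  for (ib in c(2, 6, 12)) for (k in c(20, 30, 40)) {
    if (ap$count[ib, k] == 0) next
    R <- ap$r[ib]; z <- ap$z[k]
    base_v <- bf$field$values[1, 1, k]  # z-only base profile
    dz <- z - md$stalk$z_mid
    bridge_v <- if (abs(dz) <= 2.1)
      2.5 * (1 + tanh((rho_w * cosh(dz / md$stalk$waist_scale) - R) /
                        md$interface_width)) else 0
    expect_equal(ap$mean[ib, k], max(base_v, bridge_v), tolerance = 0.35)
  }
  # a uniform field averages to a constant everywhere
  u <- azimuthal_average(density_field(bf$grid, 3), n_radial_bins = 10)
  expect_equal(unname(u$mean[u$count > 0]),
               rep(3, sum(u$count > 0)))
  expect_error(azimuthal_average(stalk, n_radial_bins = 0), "bin")
})

test_that("azimuthal bin noise shrinks as sigma^2 over the bin count", {
  set.seed(61)
  g <- grid_spec(c(30, 30, 8), c(9, 9, 2.4))
  sigma <- 0.3
  base <- 3
  f <- density_field(g, base + array(stats::rnorm(prod(g$n), 0, sigma), g$n))
  ap <- azimuthal_average(f, n_radial_bins = 6)
  dev <- (ap$mean - base)[ap$count > 20]
  cnt <- ap$count[ap$count > 20]
  # chi-square-like check: normalized deviations have unit variance
  zscores <- dev * sqrt(cnt) / sigma
  expect_lt(abs(mean(zscores^2) - 1), 0.35)
})

test_that("thickness profiles recover built thickness and imposed thinning", {
  bf <- bilayer_fixture()
  tp <- thickness_profile(bf$field)
  expect_true(all(abs(tp$thickness - 3) <= bf$grid$dL[3]))
  # impose a Gaussian thinning of the upper leaflet near the axis
  g <- bf$grid
  thin <- field_with_values(bf$field, {
    v <- bf$field$values
    cx <- cell_centers(g, 1) - 6; cy <- cell_centers(g, 2) - 6
    r2 <- outer(cx^2, cy^2, `+`)
    depth <- 1.2 * exp(-r2 / (2 * 1.5^2))
    for (k in seq_len(g$n[3])) {
      z <- cell_centers(g, 3)[k]
      # carve the inner faces of both slabs toward the mid-plane
      lo <- 6 - 0.6 - depth; hi <- 6 + 0.6 + depth
      inside <- (z > 6 - 0.6 - 3) & (z < 6 + 0.6 + 3)
      if (inside) v[, , k][z > lo & z < hi] <- 0
    }
    v
  })
  tpt <- thickness_profile(thin, n_bins = 12)
  expect_lt(tpt$thickness[1], tpt$thickness[nrow(tpt)] - 0.5)
  # empty field yields an empty profile
  expect_equal(nrow(thickness_profile(density_field(g, 0.1))), 0L)
})

test_that("per-replica geometry tables track a thinning stalk path", {
  bf <- bilayer_fixture()
  stalk <- make_stalk_field(bf$field, neck_radius = 1.6)
  p <- string_path(list(bf$field, stalk))
  tab <- path_geometry(p)
  expect_equal(tab$s, c(0, 1))
  expect_equal(tab$d_w, c(1.2, 0), tolerance = bf$grid$dL[3] / 2)
  expect_true(is.na(tab$d_st[1]))
  expect_equal(tab$d_st[2], 3.2, tolerance = bf$grid$dL[1])
})
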