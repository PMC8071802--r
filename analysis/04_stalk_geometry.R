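#!/usr/bin/env Rscript
# Morphological observables on constructed membrane density fields.
#
# Builds the three synthetic fixtures at MARTINI-like hydrophobic densities
# (bulk 5 nm^-3, interfaces defined at 2.2 nm^-3): two planar bilayers with a
# 1.2 nm water gap, a 9.2 nm vesicle facing its periodic image across a
# 2.3 nm gap in the production box geometry, and a stalk of 1.6 nm neck
# radius bridging the bilayers -- then measures d_w, d_st, iso-density
# contours, the azimuthally averaged (R, z) density map and the thickness
# profile near the stalk.

suppressPackageStartupMessages(library(stalkpath))
dir.create("results", showWarnings = FALSE)

g <- grid_spec(c(40, 40, 60), c(12, 12, 12))
bilayers <- make_bilayer_field(g, gap = 1.2, thickness = 3,
                               interface_width = 0.25)
stalk <- make_stalk_field(bilayers, neck_radius = 1.6)
gv <- grid_spec(90, c(26.31, 26.83, 20.74))
vesicles <- make_vesicle_pair_field(gv, R_v = 9.2, thickness = 3.5,
                                    interface_width = 0.25, gap = 2.3)

tab <- data.frame(
  system = c("planar pair", "vesicle pair", "stalk (r_neck 1.6)"),
  built_gap = c(1.2, 2.3, 0),
  d_w = c(intermembrane_distance(bilayers)$d_w,
          intermembrane_distance(vesicles)$d_w,
          intermembrane_distance(stalk)$d_w),
  d_st = c(stalk_diameter(bilayers)$d_st,
           stalk_diameter(vesicles)$d_st,
           stalk_diameter(stalk)$d_st))
print(tab, digits = 4)
utils::write.csv(tab, "results/geometry_table.csv", row.names = FALSE)

# threshold sensitivity: the gap widens and the neck narrows as the
# iso-density level rises
for (thr in c(2.2, 2.7, 3.2)) {
  cat(sprintf("threshold %.1f nm^-3: d_w = %.3f nm, d_st = %.3f nm\n",
              thr, intermembrane_distance(bilayers, thr)$d_w,
              stalk_diameter(stalk, thr)$d_st))
}

# contours of the vesicle slice through the stalk axis plane
cl <- interface_contour(vesicles, 2.2, axis = "y")
for (i in seq_along(cl))
  utils::write.csv(cl[[i]], sprintf("results/vesicle_contour_%d.csv", i),
                   row.names = FALSE)
cat(sprintf("vesicle slice: %d contour lines (outer/inner interface circles)\n",
            length(cl)))

# azimuthal (R, z) map and thinning profile around the stalk
az <- azimuthal_average(stalk, n_radial_bins = 24)
utils::write.csv(
  data.frame(R = rep(az$r, times = length(az$z)),
             z = rep(az$z, each = length(az$r)),
             density = as.vector(az$mean),
             count = as.vector(az$count)),
  "results/stalk_azimuthal_map.csv", row.names = FALSE)
tp <- thickness_profile(stalk, n_bins = 16)
utils::write.csv(tp, "results/stalk_thickness_profile.csv", row.names = FALSE)
cat(sprintf("thickness far from the stalk: %.3f nm (built 3 nm); %d bridged columns excluded\n",
            tp$thickness[nrow(tp)], attr(tp, "n_excluded")))
cat("wrote results/geometry_table.csv and contour/map/profile CSVs\n")
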