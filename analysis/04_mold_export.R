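#!/usr/bin/env Rscript
# Printable mold geometry: extrude the dense-tissue and IDC masks into
# 1 mm prisms, add the 45 mm cylindrical mold wall (1.2 mm cavity, 0.2 mm
# cover clearance), and sweep the duct network into a 0.5 mm walled tube
# inside a 30 mm disc shell. All meshes are watertight binary STL (mm).
#
# Writes results/molds/*.stl and results/mold_summary.csv.

suppressMessages(library(qmephantom))
dir.create("results/molds", recursive = TRUE, showWarnings = FALSE)

masks <- make_synthetic_masks(shape = c(96, 96), pitch_um = c(40, 40),
                              seed = 1)
# mold 1: dense-tissue prism centred in the cylindrical wall
dense_mesh <- extrude_mask(masks$dense, c(40, 40), height_mm = 1)
centre_shift <- -apply(dense_mesh$vertices, 2, function(v) mean(range(v)))
dense_mesh$vertices <- sweep(dense_mesh$vertices, 2, -centre_shift)
dense_mesh$vertices[, 3] <- dense_mesh$vertices[, 3] + 0.5
mold1 <- mesh_concat(list(dense_mesh, add_cylindrical_wall(dense_mesh)),
                     force = TRUE)
write_stl(mold1, "results/molds/mold1_dense.stl")

# mold 2: IDC-region prism
idc_mesh <- extrude_mask(masks$idc, c(40, 40), height_mm = 1)
write_stl(idc_mesh, "results/molds/mold2_idc.stl")

# duct mold: swept tube + disc shell
duct_mold <- sweep_duct_tube(default_duct_network(), wall_thickness_mm = 0.5,
                             disc_diameter_mm = 30, n_theta = 90)
write_stl(duct_mold, "results/molds/duct_mold.stl")

summ <- data.frame(
  mesh = c("mold1_dense", "mold2_idc", "duct_mold"),
  faces = c(nrow(mold1$faces), nrow(idc_mesh$faces),
            nrow(duct_mold$faces)),
  volume_mm3 = c(mesh_volume(mold1), mesh_volume(idc_mesh),
                 mesh_volume(duct_mold)),
  watertight = c(is_watertight(mold1), is_watertight(idc_mesh),
                 is_watertight(duct_mold)))
print(summ, digits = 5)
write.csv(summ, "results/mold_summary.csv", row.names = FALSE)
cat("wrote results/molds/*.stl and results/mold_summary.csv\n")
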