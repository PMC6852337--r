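#!/usr/bin/env Rscript
# Build the synthetic study system: a 30 x 30-cell landscape (1-ha cells)
# with three forest types and autocorrelated terrain, a 25-species canopy
# community filtered by type and elevation and clustered by dispersal, and
# the hyperspectral scene a sensor would record over it.
#
# Outputs (results/01/): forest_type.csv, elevation.csv, true_species.csv,
# true_community.csv.

library(betascape)
out <- "results/01"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

landscape <- gen_landscape(30, 30, n_types = 3, autocorr_range = 10,
                           seed = 101)
truth <- gen_community(landscape, n_species = 25, niche_strength = 2,
                       aggregation = 2, px_per_cell = 4, seed = 102)
spectra <- gen_spectra(25, seed = 103)
cube <- gen_cube(truth, spectra, noise_sd = 0.01, invalid_fraction = 0.05,
                 seed = 104)

write.csv(as.data.frame(landscape$forest_type),
          file.path(out, "forest_type.csv"), row.names = FALSE)
write.csv(as.data.frame(landscape$covariates$elevation),
          file.path(out, "elevation.csv"), row.names = FALSE)
write.csv(as.data.frame(truth$species_raster),
          file.path(out, "true_species.csv"), row.names = FALSE)
write.csv(as.data.frame(truth$community),
          file.path(out, "true_community.csv"), row.names = FALSE)
saveRDS(list(landscape = landscape, truth = truth, spectra = spectra,
             cube = cube), file.path(out, "state.rds"))

cat("Landscape:", landscape$width, "x", landscape$height, "cells;",
    "types:", paste(table(landscape$forest_type), collapse = "/"), "\n")
cat("Community:", truth$params$n_species, "species over",
    length(truth$species_raster), "pixels\n")
cat("Cube:", paste(dim(cube$reflectance), collapse = " x "),
    "(pixels x pixels x bands)\n")
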