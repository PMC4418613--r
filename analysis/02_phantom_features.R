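#!/usr/bin/env Rscript
# Extract the five 3D shape features from a gallery of digital phantoms:
# a sphere, a 2:1 prolate ellipsoid, and lobulated tumors of increasing
# lobulation amplitude. Shows the geometric behavior the discrimination
# pipeline relies on: compactness and sphericity fall as lobulation grows.

suppressPackageStartupMessages(library(thymoshape))
dir.create("results", showWarnings = FALSE)

specs <- list(
  list(id = "sphere_r12", kind = "sphere", radius = 12, amplitude = 0),
  list(id = "ellipsoid_2to1", kind = "ellipsoid", radius = 10,
       semi_axes = c(10, 10, 20), amplitude = 0),
  list(id = "lobulated_amp02", kind = "lobulated", radius = 10,
       amplitude = 0.2),
  list(id = "lobulated_amp04", kind = "lobulated", radius = 10,
       amplitude = 0.4),
  list(id = "lobulated_amp06", kind = "lobulated", radius = 10,
       amplitude = 0.6))

rows <- lapply(specs, function(s) {
  m <- make_phantom(kind = s$kind, radius = s$radius,
                    semi_axes = s$semi_axes, n_lobes = 10,
                    amplitude = s$amplitude, lobe_width = 0.25, seed = 42)
  fe <- extract_features(m)
  fe$subject_id <- s$id
  fe
})
features <- do.call(rbind, rows)
write_feature_table(features, "results/phantom_features.csv")

print(features[, c("subject_id", "volume_ml", "surface_area_cm2",
                   "sphericity", "discrete_compactness", "roundness")],
      row.names = FALSE, digits = 4)
cd <- features$discrete_compactness[grepl("lobulated|sphere_r12",
                                          features$subject_id)]
cat("\nDiscrete compactness is monotone in lobulation amplitude:",
    all(diff(cd) < 0), "\n")
cat("Wrote results/phantom_features.csv\n")
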