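#!/usr/bin/env Rscript
# Stage 2: georeference camera detections.
#
# Runs the simulated blow cues through the infrared camera model (wedge
# field of view, range window, pixel coordinates), then inverts the pixels
# back to ranges, azimuths, and geographic positions — the same pixel ->
# range/azimuth -> lat/lon chain used on real camera logs.

suppressMessages(library(whalecues))

out_dir <- "results/analysis"
blows <- read.csv(file.path(out_dir, "blows.csv"))

geom <- survey_geometry()
det <- simulate_detections(blows,
                           list(type = "camera", geom = geom,
                                range_min_m = 479, range_max_m = 5800),
                           effort = NULL, seed = 20150105L)

# pixel -> range/azimuth -> position
det$range_from_pixels_m <- pixel_to_range(det$pixel_row, geom)
det$azimuth_deg <- pixel_to_azimuth(pmin(pmax(det$pixel_col, 0),
                                         geom$image_width_px - 1), geom)
pos <- range_bearing_to_position(geom$camera_position,
                                 det$range_from_pixels_m, det$azimuth_deg)
det$lat <- pos[, "lat"]; det$lon <- pos[, "lon"]

write.csv(det, file.path(out_dir, "camera_detections_georeferenced.csv"),
          row.names = FALSE)

err <- abs(det$range_from_pixels_m - det$range_m)
cat(sprintf("georeferenced %d camera blow detections\n", nrow(det)))
cat(sprintf("pixel->range roundtrip error: max %.2e m (geometry is self-consistent)\n",
            max(err)))
cat(sprintf("detected ranges span %.0f-%.0f m offshore\n",
            min(det$range_m), max(det$range_m)))
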