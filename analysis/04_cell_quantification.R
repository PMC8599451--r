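#!/usr/bin/env Rscript
# Fluorescence counting recipes: proliferation in the scar ROI, dividing
# cardiomyocytes with capillary exclusion, artery counting with the 10-um
# gate, and fibroblast coverage, all on noiseless fields with exact truth.

library(myoquant)
dir.create("results", showWarnings = FALSE)

## --- general proliferation inside the WGA scar ROI ----------------------
gm <- gen_multichannel(cell_field_spec(n_nuclei = 120,
                                       marker_fractions = c(edu = 0.05),
                                       wga_band_fraction = 0.45, seed = 401))
roi <- scar_roi(gm$stack$channels$wga)
pf <- positive_fraction_in_roi(gm$stack$channels$hoechst,
                               gm$stack$channels$edu, roi)
cat(sprintf("scar ROI: %.0f%% of frame; EdU+ %d / %d nuclei inside (%.1f%%)\n",
            100 * mean(roi$mask), pf$positive_nuclei, pf$total_nuclei,
            pf$fraction_percent))

## --- dividing cardiomyocytes (capillary positives excluded) -------------
gcm <- gen_multichannel(cell_field_spec(
  n_nuclei = 100, marker_fractions = c(edu = 0.04),
  n_capillary_nuclei = 50, capillary_marker_fraction = 0.06, seed = 402))
cm <- cm_proliferation(gcm$stack, "edu")
cat(sprintf("EdU+ cardiomyocytes: %d / %d (%.1f%%); capillary positives excluded\n",
            cm$positive_nuclei, cm$total_nuclei, cm$fraction_percent))

## --- arteries >= 10 um in the scar --------------------------------------
gv <- gen_multichannel(cell_field_spec(
  n_nuclei = 0, marker_fractions = NULL, wga_band_fraction = 0.5,
  vessel_diameters_um = c(8, 12, 20), pixel_size = 0.5, seed = 403))
ca <- count_arteries(gv$stack)
cat(sprintf("arteries >= 10 um: %d of %d rendered (%.1f per scar mm^2)\n",
            ca$count, nrow(ca$vessels), ca$count_per_scar_mm2))

## --- fibroblast coverage -------------------------------------------------
gp <- gen_multichannel(cell_field_spec(n_nuclei = 0, marker_fractions = NULL,
                                       pdgfrb_fraction = 0.3, seed = 404))
cov <- coverage_fraction(gp$stack$channels$pdgfrb,
                         binary_mask(matrix(TRUE, 512, 512), 1))
cat(sprintf("PDGFRb coverage: %.1f%% (rendered %.1f%%)\n",
            cov, 100 * gp$truth$pdgfrb_true_fraction))

## --- isolated cardiomyocyte surface area --------------------------------
cells <- data.frame(width_um = c(18, 22, 25), length_um = c(95, 110, 120))
cells$surface_um2 <- cm_surface_area(cells$width_um, cells$length_um)

out <- data.frame(
  quantity = c("edu_fraction_in_scar_percent", "edu_cm_fraction_percent",
               "artery_count", "artery_density_per_mm2",
               "pdgfrb_coverage_percent", "mean_cm_surface_um2"),
  value = c(pf$fraction_percent, cm$fraction_percent, ca$count,
            ca$count_per_scar_mm2, cov, mean(cells$surface_um2)))
write.csv(out, "results/cell_counts.csv", row.names = FALSE)
cat("written: results/cell_counts.csv\n")
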