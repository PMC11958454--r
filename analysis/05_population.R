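#!/usr/bin/env Rscript
# Stage 5: population analyses on the confocal fixtures: mother/daughter
# focus asymmetry, colocalization of aggregate foci with the organelle
# marker, and inheritance scoring across the budding time-lapse.

suppressMessages(library(aggretrack))

data_dir <- "scratch/data"
res_dir <- "results"

for (org in c("vacuole", "nucleus")) {
  ch1 <- read_stack(file.path(data_dir,
                              paste0("confocal_", org, "_C1.tif")))
  cms <- read_stack(file.path(data_dir,
                              paste0("confocal_", org, "_cellmasks.tif")))
  oms <- read_stack(file.path(data_dir,
                              paste0("confocal_", org, "_orgmasks.tif")))
  nf <- dim(ch1)[1]
  foci_by_time <- lapply(seq_len(nf), function(f)
    detect_foci(ch1[f, , ], cms[f, , ], pixel_size = 120, frame = f - 1L))
  cell_masks <- lapply(seq_len(nf), function(f) cms[f, , ])
  org_masks <- lapply(seq_len(nf), function(f) oms[f, , ])

  ih <- inheritance_score(foci_by_time, cell_masks, org_masks)
  write_table(ih$per_timepoint,
              file.path(res_dir, paste0("inheritance_", org, ".csv")))
  first_in_bud <- which(ih$per_timepoint$organelle_in_bud)[1]
  message(sprintf(
    "%s: organelle enters the bud at t = %d min; %.0f%% of aggregates inherited",
    org, (first_in_bud - 1L) * 10L, 100 * ih$inherited_fraction))

  ## mother/daughter asymmetry at the final timepoint
  last <- foci_by_time[[nf]]
  roles <- data.frame(cell_id = c(1L, 2L), role = c("mother", "daughter"))
  md <- mother_daughter_stats(last, roles)
  write_table(md, file.path(res_dir, paste0("mother_daughter_", org, ".csv")))
  mrow <- md[md$role == "mother", ]
  message(sprintf(
    "%s: mother foci mean area %.2f um^2, mean intensity %.0f A.U. (n=%d)",
    org, mrow$mean_area_um2, mrow$mean_integrated_intensity, mrow$n_foci))

  ## colocalization with the organelle marker at the first timepoint
  f1 <- foci_by_time[[1]]
  cl <- colocalize(f1, org_masks[[1]], pixel_size = 120, max_distance = 250)
  write_table(data.frame(organelle = org, n_foci = cl$n_foci,
                         n_colocalized = cl$n_colocalized,
                         fraction = cl$fraction,
                         max_distance_nm = cl$max_distance),
              file.path(res_dir, paste0("colocalization_", org, ".csv")))
  message(sprintf("%s: %d/%d foci within 250 nm of the marker (%.0f%%)",
                  org, cl$n_colocalized, cl$n_foci, cl$fraction))
}
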