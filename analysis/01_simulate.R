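#!/usr/bin/env Rscript
# Stage 1: generate the synthetic acquisitions the rest of the workflow
# analyses. Three Slimfield conditions emulating an osmotic-stress series
# (control phosphate buffer, 1 M NaCl, 1.5 M sorbitol), with per-condition
# aggregate size and mobility set to the published condition means, plus
# two confocal budding time-lapses (vacuole- and nucleus-marked).
#
# Movies are written under scratch/data/ (they are bulky and regenerable);
# ground-truth sidecars and a condition table go to results/.

suppressMessages(library(aggretrack))

data_dir <- "scratch/data"
res_dir <- "results"
dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)
dir.create(res_dir, recursive = TRUE, showWarnings = FALSE)

conditions <- data.frame(
  condition = c("napi", "nacl", "sorbitol"),
  n_molecules = c(157, 290, 217),   # molecules per aggregate
  d_coeff = c(0.99, 0.47, 0.36),    # um^2/s
  stringsAsFactors = FALSE)
n_stacks <- 4L          # fields of view per condition (4 cells each)
base_seed <- 20260921L

for (i in seq_len(nrow(conditions))) {
  cn <- conditions$condition[i]
  for (s in seq_len(n_stacks)) {
    cfg <- sim_config(n_frames = 800L,
                      rng_seed = (base_seed + i * 131L + s) %% 2000000011L)
    stack <- simulate_slimfield_stack(cfg, conditions$n_molecules[i],
                                      conditions$d_coeff[i], n_cells = 4)
    write_synthetic_stack(stack, data_dir, sprintf("%s_%02d", cn, s))
  }
  message("simulated ", n_stacks, " Slimfield stacks for condition ", cn)
}

for (org in c("vacuole", "nucleus")) {
  ct <- simulate_confocal_timelapse(
    config = sim_config(frame_interval = 600, n_frames = 10,
                        image_shape = c(64L, 96L), bleach_prob = 0,
                        rng_seed = base_seed + match(org, c("vacuole",
                                                            "nucleus"))),
    organelle = org)
  write_synthetic_stack(ct, data_dir, paste0("confocal_", org))
  # per-timepoint cell and organelle masks are needed downstream
  nf <- length(ct$cell_masks)
  cm <- array(0L, dim = c(nf, dim(ct$cell_masks[[1]])))
  om <- array(0L, dim = c(nf, dim(ct$organelle_masks[[1]])))
  for (f in seq_len(nf)) {
    cm[f, , ] <- ct$cell_masks[[f]]
    om[f, , ] <- as.integer(ct$organelle_masks[[f]])
  }
  write_stack(cm, file.path(data_dir,
                            paste0("confocal_", org, "_cellmasks.tif")))
  write_stack(om, file.path(data_dir,
                            paste0("confocal_", org, "_orgmasks.tif")))
  message("simulated confocal time-lapse (", org, " marker)")
}

write_table(conditions, file.path(res_dir, "conditions.csv"))
message("condition table -> results/conditions.csv")
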