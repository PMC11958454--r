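#!/usr/bin/env Rscript
# Stage 2: per-cell foci detection on every simulated Slimfield field.
# Reads the movies and masks written by 01_simulate.R, detects foci inside
# each cell outline on the first frame, and summarises aggregate-positive
# fractions per condition, including the temperature-series fold-change
# arithmetic on the published percentages.

suppressMessages(library(aggretrack))

data_dir <- "scratch/data"
res_dir <- "results"
conditions <- read_table(file.path(res_dir, "conditions.csv"))

all_foci <- list(); all_cells <- list()
for (cn in conditions$condition) {
  files <- list.files(data_dir, sprintf("^%s_\\d+_C1\\.tif$", cn),
                      full.names = TRUE)
  for (f in files) {
    stack <- read_stack(f)
    mask <- read_stack(sub("_C1\\.tif$", "_mask.tif", f))[1, , ]
    foci <- detect_foci(stack[1, , ], mask, pixel_size = 120)
    field <- sub("_C1\\.tif$", "", basename(f))
    if (nrow(foci)) {
      foci$field <- field; foci$condition <- cn
      # cell ids must be unique across fields
      foci$cell_id <- paste0(field, "_", foci$cell_id)
      all_foci[[length(all_foci) + 1L]] <- foci
    }
    ids <- sort(setdiff(unique(as.integer(mask)), 0L))
    all_cells[[length(all_cells) + 1L]] <- data.frame(
      cell_id = paste0(field, "_", ids), field = field, condition = cn)
  }
}
foci <- do.call(rbind, all_foci)
cells <- do.call(rbind, all_cells)
write_table(foci, file.path(res_dir, "foci.csv"))

pos <- vapply(conditions$condition, function(cn)
  aggregate_positive_fraction(foci[foci$condition == cn, ],
                              cells$cell_id[cells$condition == cn]),
  numeric(1))
message("aggregate-positive fractions (%): ",
        paste(sprintf("%s=%.0f", names(pos), pos), collapse = ", "))

# temperature-series arithmetic on the published positive fractions
pub <- data.frame(temp_c = c(30, 37, 42), pct_positive = c(19, 47, 59))
fc37 <- fold_changes(pub$pct_positive[1], pub$pct_positive[2])$factor
fc42 <- fold_changes(pub$pct_positive[1], pub$pct_positive[3])$factor
message(sprintf(
  "published positive fractions rise by x%.1f (30->37C) and x%.1f (30->42C)",
  fc37, fc42))
write_table(data.frame(comparison = c("30->37C", "30->42C"),
                       fold_change = c(fc37, fc42)),
            file.path(res_dir, "positive_fraction_fold_changes.csv"))
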