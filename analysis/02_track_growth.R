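#!/usr/bin/env Rscript
# Track cells through the label-mask stacks, fit exponential growth
# L(t) = L0*exp(t/t0) per cell, and apply the automated selection filters
# (no segmentation errors; doubling time 1.5-4.5 h; birth length 1-4 um).
#
# Reads results/data/, writes results/tables/tracks + growth summaries.

suppressMessages(library(replitrack))

data_dir <- "results/data"; out <- "results/tables"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
cfg <- sim_preset("ecoli_dnaN", seed = 7L)

mask_files <- sort(list.files(data_dir, "^mask_fov", full.names = TRUE))
all_cells <- list(); all_sel <- list()
for (k in seq_along(mask_files)) {
  masks <- lapply(read_stack(mask_files[k]), function(m) {
    storage.mode(m) <- "integer"; m
  })
  tr <- build_tracks(masks, cfg$pixel_size, cfg$frame_interval)
  fits <- fit_growth(tr)
  sel <- select_cells(tr, fits, mode = "timelapse")
  tr$cells$fov <- k; all_cells[[k]] <- merge(tr$cells, fits, by = "cell")
  if (nrow(sel)) { sel$fov <- k; all_sel[[k]] <- sel }
}
cells <- do.call(rbind, all_cells)
sel <- do.call(rbind, all_sel)
write.csv(cells, file.path(out, "tracks_growth.csv"), row.names = FALSE)
write.csv(sel, file.path(out, "selected_cells.csv"), row.names = FALSE)

cat("tracks:", nrow(cells), "| complete cycles:", sum(cells$complete_cycle),
    "| selected:", nrow(sel), "\n")
cat(sprintf("mean doubling time of selected cells: %.2f h (tD = t0*log 2)\n",
            mean(sel$tD) / 60))
grDevices::png("results/tables/doubling_times.png", 480, 360)
hist(sel$tD / 60, breaks = 12, col = "steelblue",
     xlab = "doubling time (h)", main = "Selected cells")
dev.off()
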