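#!/usr/bin/env Rscript
# Population statistics: all unique within-cell focus-pair separations, the
# two-Gaussian mixture over relative separations, posterior classification
# into resolved sisters vs high-separation pairs, factory counting, and the
# co-localized fork-pair fraction, plus the conditional position density
# and localization-pattern table.
#
# Reads results/tables/foci.csv + selected_cells.csv from the earlier
# stages, writes the population tables and figures.

suppressMessages(library(replitrack))

out <- "results/tables"
foci <- read.csv(file.path(out, "foci.csv"))
sel <- read.csv(file.path(out, "selected_cells.csv"))
foci <- foci[foci$retained &
               paste(foci$fov, foci$cell) %in% paste(sel$fov, sel$cell), ]
cat("retained foci in selected cells:", nrow(foci), "\n")

pairs <- pair_separations(foci)
mix <- fit_sep_mixture(pairs$rel_sep)
print(mix)
pairs <- classify_pairs(pairs, mix)
counts <- count_factories(foci, pairs)
coloc <- colocalization_fraction(counts)
cat(sprintf("co-localized fork-pair fraction: %.1f%% (resolved %.1f%%)\n",
            100 * coloc, 100 * (1 - coloc)))
cat(sprintf("mean relative separation of resolved sisters: %.3f\n",
            mean(pairs$rel_sep[pairs$accepted])))

write.csv(pairs, file.path(out, "pairs.csv"), row.names = FALSE)
write.csv(counts, file.path(out, "counts.csv"), row.names = FALSE)
jsonlite::write_json(unclass(mix), file.path(out, "mixture.json"),
                     auto_unbox = TRUE, digits = NA)

dens <- conditional_position_density(foci$rel_pos, foci$cell_length_um)
write.csv(as.data.frame(dens), file.path(out, "density.csv"))
pat <- pattern_frequencies(counts)
write.csv(pat, file.path(out, "patterns.csv"), row.names = FALSE)

grDevices::png(file.path(out, "separation_hist.png"), 480, 360)
hist(pairs$rel_sep, breaks = 40, freq = FALSE, col = "grey85",
     xlab = "relative separation (cell lengths)", main = "")
xx <- seq(0, 1, 1e-3)
lines(xx, mix$lambda[1] * dnorm(xx, mix$mu[1], mix$sigma[1]), col = "blue", lwd = 2)
lines(xx, mix$lambda[2] * dnorm(xx, mix$mu[2], mix$sigma[2]), col = "red", lwd = 2)
dev.off()
grDevices::png(file.path(out, "position_density.png"), 480, 360)
image(attr(dens, "len_centers"), attr(dens, "pos_centers"), t(dens),
      col = grDevices::hcl.colors(64, "viridis"),
      xlab = "cell length (um)", ylab = "relative long-axis position",
      useRaster = TRUE)
abline(h = c(0.25, 0.5, 0.75), col = "white", lty = 2)
dev.off()
grDevices::png(file.path(out, "coloc_pie.png"), 400, 400)
pie(c(coloc, 1 - coloc),
    labels = sprintf("%s (%.0f%%)", c("co-localized", "resolved"),
                     100 * c(coloc, 1 - coloc)),
    col = c("#336699", "#cc3333"))
dev.off()
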