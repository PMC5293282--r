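# Visual summaries: kymographs and cell towers.

#' Kymograph of one cell track
#'
#' Per frame, the fluorescence inside the cell mask is projected (summed)
#' onto bins of the relative long-axis coordinate; rows are stacked in
#' temporal order.  Projection conserves the in-mask intensity of every
#' frame (row sums equal the in-mask sums).
#'
#' @param tracks a `replitrack_tracks`.
#' @param cell mask label of the track.
#' @param fluor_frames,mask_frames the aligned stacks.
#' @param nbins number of long-axis bins.
#' @return matrix `[frames, nbins]` with attribute `frames` (frame indices).
#' @export
kymograph <- function(tracks, cell, fluor_frames, mask_frames, nbins = 51L) {
  fr <- tracks$frames[tracks$frames$cell == cell, , drop = FALSE]
  if (!nrow(fr)) stop("empty track: no frames for cell ", cell)
  fr <- fr[order(fr$frame), ]
  out <- matrix(0, nrow(fr), nbins)
  for (k in seq_len(nrow(fr))) {
    f <- fr$frame[k] + 1L
    lab <- mask_frames[[f]]
    idx <- which(lab == cell)
    ij <- arrayInd(idx, dim(lab))
    rel <- long_axis_position(ij[, 1], ij[, 2], fr[k, ])
    b <- pmin(pmax(ceiling(rel * nbins), 1L), nbins)
    v <- fluor_frames[[f]][idx]
    for (u in seq_along(b)) out[k, b[u]] <- out[k, b[u]] + v[u]
  }
  attr(out, "frames") <- fr$frame
  out
}

#' Cell tower: temporal montage of one cell
#'
#' Cropped, axis-aligned cell images stacked vertically in temporal order
#' (pixels outside the mask are set to the frame median so neighbors do not
#' bleed in).
#'
#' @inheritParams kymograph
#' @param margin crop margin in pixels.
#' @return montage matrix `[x, y-stacked]`; attribute `strips` gives the
#'   per-frame y extents.
#' @export
cell_tower <- function(tracks, cell, fluor_frames, mask_frames, margin = 3L) {
  fr <- tracks$frames[tracks$frames$cell == cell, , drop = FALSE]
  if (!nrow(fr)) stop("empty track: no frames for cell ", cell)
  fr <- fr[order(fr$frame), ]
  strips <- list()
  for (k in seq_len(nrow(fr))) {
    f <- fr$frame[k] + 1L
    lab <- mask_frames[[f]]
    img <- fluor_frames[[f]]
    idx <- which(lab == cell)
    ij <- arrayInd(idx, dim(lab))
    x0 <- max(1L, min(ij[, 1]) - margin); x1 <- min(nrow(lab), max(ij[, 1]) + margin)
    y0 <- max(1L, min(ij[, 2]) - margin); y1 <- min(ncol(lab), max(ij[, 2]) + margin)
    strip <- img[x0:x1, y0:y1]
    strip[lab[x0:x1, y0:y1] != cell] <- stats::median(img)
    strips[[k]] <- strip
  }
  wx <- max(vapply(strips, nrow, integer(1)))
  heights <- vapply(strips, ncol, integer(1))
  tower <- matrix(0, wx, sum(heights + 1L) - 1L)
  yoff <- 0L
  ext <- matrix(NA_integer_, length(strips), 2)
  for (k in seq_along(strips)) {
    s <- strips[[k]]
    x0 <- (wx - nrow(s)) %/% 2L
    tower[x0 + seq_len(nrow(s)), yoff + seq_len(ncol(s))] <- s
    ext[k, ] <- c(yoff + 1L, yoff + ncol(s))
    yoff <- yoff + ncol(s) + 1L
  }
  attr(tower, "strips") <- ext
  tower
}

save_matrix_png <- function(m, path, asp = NULL) {
  grDevices::png(path, width = 640, height = 480)
  graphics::par(mar = c(2, 2, 1, 1))
  graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), m,
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "", ylab = "", useRaster = TRUE)
  grDevices::dev.off()
  invisible(path)
}
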