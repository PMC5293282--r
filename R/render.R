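# Optical renderer: ground truth -> fluorescence and label-mask stacks.
#
# Each emitter becomes an isotropic 2-D Gaussian of width psf_sigma at its
# sub-pixel position; a co-localized pair carries the full focus amplitude,
# each resolved sister half of it.  The diffuse base level is flat across
# the field and modulated inside and outside cells by a slow random texture
# (cytoplasmic heterogeneity); shot noise is Poisson per pixel.  Cells are
# drawn into the label mask as stadium (rod) shapes; mask labels are stable
# across frames and a division retires the parent label and issues two new
# ones (unless the division is silent, modelling chaining).

## stadium rasterizer: label pixels within width/2 of the cell's axis segment
rasterize_stadium <- function(lab, cx_px, cy_px, L_px, theta, w_px, label) {
  r <- w_px / 2
  h <- max(L_px / 2 - r, 0.5)
  ux <- cos(theta); uy <- sin(theta)
  a <- c(cx_px - h * ux, cy_px - h * uy)
  b <- c(cx_px + h * ux, cy_px + h * uy)
  x0 <- max(1L, floor(min(a[1], b[1]) - r - 1)); x1 <- min(nrow(lab), ceiling(max(a[1], b[1]) + r + 1))
  y0 <- max(1L, floor(min(a[2], b[2]) - r - 1)); y1 <- min(ncol(lab), ceiling(max(a[2], b[2]) + r + 1))
  if (x0 > x1 || y0 > y1) return(lab)
  xs <- x0:x1; ys <- y0:y1
  X <- matrix(xs, length(xs), length(ys))
  Y <- matrix(ys, length(xs), length(ys), byrow = TRUE)
  ## projection of each pixel onto the axis segment, clamped to its ends
  tproj <- ((X - a[1]) * ux + (Y - a[2]) * uy)
  tproj <- pmin(pmax(tproj, 0), 2 * h)
  dx <- X - (a[1] + tproj * ux); dy <- Y - (a[2] + tproj * uy)
  inside <- dx * dx + dy * dy <= r * r
  sub <- lab[xs, ys]
  sub[inside & sub == 0L] <- label
  lab[xs, ys] <- sub
  lab
}

add_gaussian <- function(img, x_px, y_px, amp, sigma_px) {
  r <- ceiling(4.5 * sigma_px)
  x0 <- max(1L, floor(x_px - r)); x1 <- min(nrow(img), ceiling(x_px + r))
  y0 <- max(1L, floor(y_px - r)); y1 <- min(ncol(img), ceiling(y_px + r))
  xs <- x0:x1; ys <- y0:y1
  gx <- exp(-(xs - x_px)^2 / (2 * sigma_px^2))
  gy <- exp(-(ys - y_px)^2 / (2 * sigma_px^2))
  img[xs, ys] <- img[xs, ys] + amp * outer(gx, gy)
  img
}

## per-fov frame geometry: image size and the um -> px mapping
fov_geometry <- function(truth, cfg, fov) {
  px_um <- cfg$pixel_size / 1000
  cf <- truth$cell_frames[truth$cell_frames$fov == fov, , drop = FALSE]
  if (!is.null(cfg$image_shape)) {
    nx <- as.integer(cfg$image_shape[1]); ny <- as.integer(cfg$image_shape[2])
  } else {
    ext <- max(cf$gcx_um + cf$glength_um / 2) - min(cf$gcx_um - cf$glength_um / 2)
    nx <- ceiling(ext / px_um) + 30L
    ny <- ceiling(cfg$cell_width / px_um) + 24L
  }
  list(nx = nx, ny = ny, px_um = px_um,
       to_px = function(x_um, y_um)
         cbind(x_um / px_um + (nx + 1) / 2, y_um / px_um + (ny + 1) / 2))
}

render_fov <- function(truth, cfg, fov, drift = NULL) {
  geo <- fov_geometry(truth, cfg, fov)
  nx <- geo$nx; ny <- geo$ny
  sigma_px <- cfg$psf_sigma / cfg$pixel_size
  cf <- truth$cell_frames[truth$cell_frames$fov == fov, , drop = FALSE]
  em <- truth$emitters
  em <- if (is.null(em)) NULL else em[em$fov == fov, , drop = FALSE]
  frames_here <- if (cfg$snapshot) sort(unique(cf$frame)) else 0:(truth$n_frames - 1L)

  fluor <- vector("list", length(frames_here))
  masks <- vector("list", length(frames_here))
  for (k in seq_along(frames_here)) {
    f <- frames_here[k]
    cff <- cf[cf$frame == f, , drop = FALSE]
    lab <- matrix(0L, nx, ny)
    for (g in unique(cff$group)) {
      row <- cff[cff$group == g, , drop = FALSE][1L, ]
      p <- geo$to_px(row$gcx_um, row$cy_um)
      lab <- rasterize_stadium(lab, p[1], p[2], row$glength_um / geo$px_um,
                               row$theta, cfg$cell_width / geo$px_um, as.integer(g))
    }
    tex <- gaussian_blur(matrix(stats::rnorm(nx * ny), nx, ny),
                         cfg$cell_tex_scale)
    tex <- tex / stats::sd(tex) * cfg$cell_tex_sd
    E <- matrix(cfg$background_level, nx, ny) + tex
    if (!is.null(em)) {
      eff <- em[em$frame == f, , drop = FALSE]
      if (nrow(eff)) {
        p <- geo$to_px(eff$x_um, eff$y_um)
        bad <- p[, 1] < 4 | p[, 1] > nx - 3 | p[, 2] < 4 | p[, 2] > ny - 3
        if (any(bad)) stop(sprintf(
          "emitter outside image bounds: fov %d frame %d cell(s) %s",
          fov, f, paste(unique(eff$cell[bad]), collapse = ", ")))
        amp <- ifelse(eff$state == "resolved", cfg$focus_amplitude / 2,
                      cfg$focus_amplitude)
        for (i in seq_len(nrow(eff)))
          E <- add_gaussian(E, p[i, 1], p[i, 2], amp[i], sigma_px)
      }
    }
    E[E < 0] <- 0
    img <- switch(cfg$noise_model,
      poisson = matrix(stats::rpois(nx * ny, E), nx, ny),
      gaussian = E + matrix(stats::rnorm(nx * ny, 0, cfg$gaussian_sd), nx, ny),
      none = E)
    if (!is.null(drift)) {
      d <- drift[min(k, nrow(drift)), ]
      img <- translate_int(img, d[[1]], d[[2]], fill = cfg$background_level)
      lab <- translate_int(lab, d[[1]], d[[2]], fill = 0L)
    }
    fluor[[k]] <- img
    masks[[k]] <- lab
  }
  list(fluor = fluor, mask = masks, frames = frames_here, nx = nx, ny = ny)
}

#' Render a simulated population to image stacks
#'
#' Produces, per field of view, a fluorescence stack and a label-mask stack
#' consistent with the ground truth.  Deterministic given the configuration
#' seed.  With `dir` set, writes 16-bit multi-page TIFFs plus the ground
#' truth sidecar (JSON events/config and a tidy emitter CSV).
#'
#' @param truth a `replisim_truth` from [simulate_population()].
#' @param config the same `sim_config` used to simulate.
#' @param dir optional output directory for TIFFs + sidecars.
#' @param drift optional data.frame/matrix of per-frame integer offsets
#'   `(dx, dy)` applied to both channels (for testing drift correction).
#' @return invisibly, a list of per-fov lists with elements `fluor` and
#'   `mask` (lists of matrices), `frames`, `nx`, `ny`.
#' @export
render_frames <- function(truth, config, dir = NULL, drift = NULL) {
  validate_sim_config(config)
  fovs <- sort(unique(truth$cell_frames$fov))
  ## every fov renders under its own derived seed so that fields can be
  ## rendered independently (and discarded) without changing the output
  out <- lapply(fovs, function(fov)
    withr::with_seed(config$seed + 1000L + fov,
                     render_fov(truth, config, fov, drift = drift)))
  names(out) <- paste0("fov", fovs)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(fovs)) {
      write_stack(out[[i]]$fluor, file.path(dir, sprintf("fluor_fov%03d.tif", fovs[i])))
      write_stack(out[[i]]$mask, file.path(dir, sprintf("mask_fov%03d.tif", fovs[i])))
    }
    write_ground_truth(truth, dir)
  }
  invisible(out)
}

#' Write ground-truth sidecar files
#'
#' JSON with the configuration echo, seed and per-cycle event table, plus
#' tidy CSVs of emitters and per-frame cell geometry.
#'
#' @param truth a `replisim_truth`.
#' @param dir output directory.
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- truth$config
  jsonlite::write_json(
    list(config = unclass(cfg), seed = cfg$seed, n_frames = truth$n_frames,
         events = truth$events, cells = truth$cells),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  if (!is.null(truth$emitters)) {
    sidecar <- truth$emitters[, c("frame", "cell", "pair", "state",
                                  "x_rel", "y_off_um", "fov", "group",
                                  "x_um", "y_um", "group_x_rel")]
    names(sidecar)[names(sidecar) == "y_off_um"] <- "y_rel_um"
    utils::write.csv(sidecar, file.path(dir, "emitters.csv"), row.names = FALSE)
  }
  utils::write.csv(truth$cell_frames, file.path(dir, "cell_frames.csv"),
                   row.names = FALSE)
  invisible(dir)
}
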