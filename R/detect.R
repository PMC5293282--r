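# Focus detection, sub-pixel localization and significance scoring.
#
# Per frame: a 1-pixel-radius Gaussian blur is applied and the watershed
# transform partitions the smoothed frame into intensity regions around each
# maximum (equivalently, basins of the inverted/"conjugate" image); regions
# outside the cell masks are discarded.  Each region seeds one candidate at
# its maximum-intensity pixel.  A 2-D Gaussian
#   Ga(x) = Ig * exp(-|x - x0|^2 / (2 b^2)) + I0
# is least-squares fitted to the raw frame over the disk of radius
# `disk_radius` around the seed; the fitted x0 is used for all localization.
# Intensity measures are then taken on the smoothed frame over the disk
# re-centered at x0: Ia = (disk sum) - Ib with Ib = (min disk pixel) * A,
# and the focus score is
#   sigma = Ia / (deltaI * sqrt(A)),
# where deltaI is the standard deviation of raw intensity over the entire
# cell mask and A the disk pixel count (29 for radius 3).  deltaI * sqrt(A)
# is the expected standard deviation of the integrated intensity under
# uncorrelated per-pixel noise.  Foci scoring >= `score_threshold` (4) are
# retained; lower-scoring candidates are stochastic intensity fluctuations.

#' Detection parameters
#'
#' @param blur_radius Gaussian blur s.d. (pixels).
#' @param disk_radius scoring/fitting disk radius (pixels).
#' @param score_threshold minimum retained score.
#' @param ws_tolerance watershed merge tolerance (intensity units); near 0
#'   so every smoothed intensity maximum seeds its own region.
#' @param screen_factor candidates whose provisional score (disk at the
#'   seed pixel) is below `screen_factor * score_threshold` are dropped
#'   without a Gaussian fit (pure economy; the retention decision always
#'   uses the fitted-center disk).
#' @return a `detection_params` list; the disk area `A` is derived.
#' @export
detection_params <- function(blur_radius = 1, disk_radius = 3,
                             score_threshold = 4, ws_tolerance = 1e-4,
                             screen_factor = 0.6) {
  stopifnot(disk_radius >= 1, score_threshold > 0, blur_radius > 0)
  disk <- disk_offsets(disk_radius)
  structure(list(blur_radius = blur_radius, disk_radius = disk_radius,
                 score_threshold = score_threshold,
                 ws_tolerance = ws_tolerance, screen_factor = screen_factor,
                 disk = disk, A = nrow(disk)),
            class = "detection_params")
}

#' Per-cell intensity statistics
#'
#' `deltaI`: standard deviation of raw pixel intensity over the entire cell
#' mask, the noise scale of the focus score.
#'
#' @param img raw fluorescence frame.
#' @param lab label mask frame.
#' @return data.frame with `cell`, `dI`, `n_px`.
#' @export
cell_intensity_stats <- function(img, lab) {
  idx <- which(lab > 0L)
  if (!length(idx)) return(data.frame(cell = integer(), dI = numeric(),
                                      n_px = integer()))
  l <- lab[idx]; v <- img[idx]
  labs <- sort(unique(l))
  data.frame(cell = labs,
             dI = vapply(labs, function(lb) stats::sd(v[l == lb]), numeric(1)),
             n_px = vapply(labs, function(lb) sum(l == lb), numeric(1)))
}

#' Integer-pixel drift between consecutive frames
#'
#' Cross-correlation (FFT) offset `(dx, dy)` that best maps `frame_prev`
#' onto `frame_t`; apply `translate_int(frame_t, -dx, -dy)` to align frame t
#' back onto the previous frame.  A correlation peak at the border of the
#' search window is clamped with a warning.
#'
#' @param frame_t,frame_prev same-shape numeric matrices.
#' @param max_shift search half-window (pixels).
#' @return integer vector `c(dx, dy)`.
#' @export
drift_correct <- function(frame_t, frame_prev, max_shift = 10L) {
  stopifnot(all(dim(frame_t) == dim(frame_prev)))
  a <- frame_t - mean(frame_t); b <- frame_prev - mean(frame_prev)
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE))
  nx <- nrow(cc); ny <- ncol(cc)
  sx <- c(0:max_shift, (nx - max_shift):(nx - 1)) %% nx
  sy <- c(0:max_shift, (ny - max_shift):(ny - 1)) %% ny
  sub <- cc[sx + 1, sy + 1]
  pk <- arrayInd(which.max(sub), dim(sub))
  dx <- sx[pk[1]]; dy <- sy[pk[2]]
  if (dx > nx / 2) dx <- dx - nx
  if (dy > ny / 2) dy <- dy - ny
  if (abs(dx) == max_shift || abs(dy) == max_shift)
    warning("drift correlation peak at search-window border; offset clamped")
  c(dx = as.integer(dx), dy = as.integer(dy))
}

#' Candidate focus regions in one frame
#'
#' Blur, watershed the smoothed frame into regions around each intensity
#' maximum, discard regions outside the cell masks, and seed one candidate
#' per remaining region at its maximum-intensity pixel.
#'
#' @param img raw fluorescence frame.
#' @param lab label mask frame.
#' @param params [detection_params()].
#' @return list with `candidates` (data.frame `x`, `y`, `cell`) and the
#'   blurred frame `blurred`.
#' @export
detect_candidates <- function(img, lab, params = detection_params()) {
  bl <- gaussian_blur(img, params$blur_radius)
  empty <- data.frame(x = integer(), y = integer(), cell = integer())
  idx_in <- which(lab > 0L)
  if (!length(idx_in)) return(list(candidates = empty, blurred = bl))
  if (stats::var(bl[idx_in]) < 1e-12)
    return(list(candidates = empty, blurred = bl))  # flat: no maxima
  wm <- EBImage::watershed(bl, tolerance = params$ws_tolerance, ext = 1)
  wl <- wm[idx_in]
  keep <- wl > 0L
  sp <- split(idx_in[keep], wl[keep])
  cand <- vapply(sp, function(ii) ii[which.max(bl[ii])], numeric(1))
  ij <- arrayInd(as.integer(cand), dim(img))
  list(candidates = data.frame(x = ij[, 1], y = ij[, 2],
                               cell = lab[as.integer(cand)]),
       blurred = bl)
}

## disk pixel indices around an integer center; NULL if any pixel leaves the
## image or the given mask label
disk_pixels <- function(cx, cy, lab, label, params) {
  xs <- cx + params$disk$dx; ys <- cy + params$disk$dy
  if (min(xs) < 1 || max(xs) > nrow(lab) || min(ys) < 1 || max(ys) > ncol(lab))
    return(NULL)
  if (!all(lab[cbind(xs, ys)] == label)) return(NULL)
  cbind(xs, ys)
}

#' Fit a 2-D Gaussian to a candidate focus
#'
#' Levenberg-Marquardt least squares of
#' `Ig * exp(-((x-x0)^2+(y-y0)^2)/(2 b^2)) + I0` over the disk of
#' `disk_radius` around the candidate seed pixel, on the raw frame.  The
#' fitted center is used for all localization.  Bounds: `b` in [0.5, 5] px,
#' `Ig >= 0`.
#'
#' @param img raw fluorescence frame.
#' @param candidate list/row with integer `x`, `y` seed pixel.
#' @param params [detection_params()].
#' @return one-row data.frame `x`, `y`, `b`, `Ig`, `I0`, `converged`, or
#'   `NULL` when the seed is too close to the image edge or the fit fails.
#' @export
fit_focus <- function(img, candidate, params = detection_params()) {
  cx <- candidate$x; cy <- candidate$y
  r <- params$disk_radius
  if (cx <= r || cx > nrow(img) - r || cy <= r || cy > ncol(img) - r)
    return(NULL)
  xs <- cx + params$disk$dx; ys <- cy + params$disk$dy
  v <- img[cbind(xs, ys)]
  i0 <- min(v); ig <- max(v) - i0
  if (ig <= 0) return(NULL)
  ## the fit refines the seed to sub-pixel precision; the center may move
  ## at most half a disk radius, so the fit cannot relocate onto a
  ## neighboring intensity fluctuation before re-scoring
  s <- r / 2
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      v ~ Ig * exp(-((xs - x0)^2 + (ys - y0)^2) / (2 * b^2)) + I0,
      start = list(Ig = ig, x0 = cx, y0 = cy, b = 1.5, I0 = i0),
      lower = c(Ig = 0, x0 = cx - s, y0 = cy - s, b = 0.5, I0 = -Inf),
      upper = c(Ig = Inf, x0 = cx + s, y0 = cy + s, b = 5, I0 = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 100))),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  data.frame(x = cf[["x0"]], y = cf[["y0"]], b = cf[["b"]],
             Ig = cf[["Ig"]], I0 = cf[["I0"]], converged = TRUE)
}

#' Score a fitted focus
#'
#' Disk of `disk_radius` pixels centered at the pixel nearest the fitted
#' position, measured on `img` (the smoothed frame in the pipeline):
#' `Ia = sum(disk) - min(disk) * A`, `sigma = Ia / (dI * sqrt(A))`.
#' A flat cell (`dI = 0`) scores 0.  Retained iff
#' `sigma >= score_threshold`.
#'
#' @param img measurement frame (pipeline: the blurred frame).
#' @param focus one-row data.frame from [fit_focus()] (fields `x`, `y`).
#' @param lab label mask frame.
#' @param cell_stats row of [cell_intensity_stats()] for the hosting cell
#'   (field `dI`), computed on the raw frame.
#' @param params [detection_params()].
#' @return the focus row with `Ia`, `Ib`, `dI`, `score`, `retained` added,
#'   or `NULL` when the scoring disk does not fit inside the cell mask.
#' @export
score_focus <- function(img, focus, lab, cell_stats,
                        params = detection_params()) {
  cx <- as.integer(round(focus$x)); cy <- as.integer(round(focus$y))
  label <- lab[cx, cy]
  if (label == 0L) return(NULL)
  dp <- disk_pixels(cx, cy, lab, label, params)
  if (is.null(dp)) return(NULL)
  v <- img[dp]
  Ib <- min(v) * params$A
  Ia <- sum(v) - Ib
  dI <- cell_stats$dI[match(label, cell_stats$cell)]
  score <- if (!is.finite(dI) || dI <= 0) 0 else Ia / (dI * sqrt(params$A))
  cbind(focus, data.frame(cell = label, Ia = Ia, Ib = Ib, dI = dI,
                          score = score,
                          retained = score >= params$score_threshold))
}

## full single-frame detection; returns retained + rejected foci
detect_frame <- function(img, lab, params) {
  dc <- detect_candidates(img, lab, params)
  cands <- dc$candidates
  if (!nrow(cands)) return(NULL)
  stats_df <- cell_intensity_stats(img, lab)
  out <- vector("list", nrow(cands))
  for (i in seq_len(nrow(cands))) {
    cx <- cands$x[i]; cy <- cands$y[i]; label <- cands$cell[i]
    if (label == 0L) next
    dp <- disk_pixels(cx, cy, lab, label, params)
    if (is.null(dp)) next
    dI <- stats_df$dI[match(label, stats_df$cell)]
    if (!is.finite(dI) || dI <= 0) next
    v <- dc$blurred[dp]
    provisional <- (sum(v) - min(v) * params$A) / (dI * sqrt(params$A))
    if (provisional < params$screen_factor * params$score_threshold) next
    ft <- fit_focus(img, list(x = cx, y = cy), params)
    if (is.null(ft)) next
    sc <- score_focus(dc$blurred, ft, lab, stats_df, params)
    if (is.null(sc)) next
    ## keep the disk anchored to the cell that seeded the candidate
    if (sc$cell != label) next
    out[[i]] <- sc
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Detect and score foci through a stack
#'
#' Fully automated per-frame chain: optional drift correction (mask
#' silhouettes aligned against the previous frame; the offset is applied to
#' both channels), blur, watershed candidates, Gaussian fit, score, retain
#' at `score >= score_threshold`.  Retained foci are annotated with their
#' relative long-axis position via [long_axis_position()].  No random
#' numbers are used: identical inputs give identical focus lists.
#'
#' @param fluor_frames list of raw fluorescence matrices.
#' @param mask_frames list of label matrices.
#' @param tracks `replitrack_tracks` built from the same masks (after drift
#'   correction, if any); may be `NULL` to skip position annotation.
#' @param params [detection_params()].
#' @param correct_drift align frames before detection.
#' @return data.frame of foci (all scored candidates; filter on `retained`).
#' @export
detect_foci <- function(fluor_frames, mask_frames, tracks = NULL,
                        params = detection_params(), correct_drift = FALSE) {
  n <- length(fluor_frames)
  stopifnot(length(mask_frames) == n)
  if (correct_drift && n > 1) {
    for (f in 2:n) {
      off <- drift_correct(1 * (mask_frames[[f]] > 0),
                           1 * (mask_frames[[f - 1]] > 0))
      if (any(off != 0L)) {
        fluor_frames[[f]] <- translate_int(fluor_frames[[f]], -off[1], -off[2],
                                           fill = stats::median(fluor_frames[[f]]))
        mask_frames[[f]] <- translate_int(mask_frames[[f]], -off[1], -off[2],
                                          fill = 0L)
      }
    }
  }
  out <- vector("list", n)
  for (f in seq_len(n)) {
    df <- detect_frame(fluor_frames[[f]], mask_frames[[f]], params)
    if (!is.null(df)) { df$frame <- f - 1L; out[[f]] <- df }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(x = numeric(), y = numeric(), b = numeric(),
                      Ig = numeric(), I0 = numeric(), converged = logical(),
                      cell = integer(), Ia = numeric(), Ib = numeric(),
                      dI = numeric(), score = numeric(), retained = logical(),
                      frame = integer(), rel_pos = numeric(),
                      cell_length_um = numeric()))
  foci <- do.call(rbind, out)
  foci$rel_pos <- NA_real_
  foci$cell_length_um <- NA_real_
  if (!is.null(tracks)) {
    key_f <- paste(tracks$frames$cell, tracks$frames$frame)
    m <- match(paste(foci$cell, foci$frame), key_f)
    ok <- !is.na(m)
    if (any(ok)) {
      fr <- tracks$frames[m[ok], , drop = FALSE]
      foci$rel_pos[ok] <- long_axis_position(foci$x[ok], foci$y[ok], fr)
      foci$cell_length_um[ok] <- fr$length_um
    }
  }
  rownames(foci) <- NULL
  foci
}
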