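# Cell tracking from label-mask stacks: per-frame geometry, lineage,
# exponential growth fits, and the automated selection filters.

## geometry of every label in one mask frame
frame_geometry <- function(lab) {
  idx <- which(lab > 0L)
  if (!length(idx)) return(NULL)
  ij <- arrayInd(idx, dim(lab))
  l <- lab[idx]
  out <- lapply(sort(unique(l)), function(lb) {
    sel <- l == lb
    x <- ij[sel, 1]; y <- ij[sel, 2]
    cx <- mean(x); cy <- mean(y)
    cv <- stats::cov(cbind(x - cx, y - cy))
    eg <- eigen(cv, symmetric = TRUE)
    ax <- eg$vectors[, 1]
    if (ax[1] < 0 || (ax[1] == 0 && ax[2] < 0)) ax <- -ax
    pr <- (x - cx) * ax[1] + (y - cy) * ax[2]
    data.frame(cell = lb, npx = sum(sel), cx = cx, cy = cy,
               ax = ax[1], ay = ax[2],
               length_px = max(pr) - min(pr) + 1)
  })
  do.call(rbind, out)
}

#' Build cell tracks from a label-mask stack
#'
#' One track per mask label.  Per frame, the cell length is the Feret extent
#' of the label along its principal axis; lineage is inferred from label
#' retirement/issuance with pixel overlap; the long-axis orientation sign is
#' kept stable across frames (and inherited from the parent at birth) so
#' pole identity is preserved.  Tracks whose label vanishes and reappears,
#' or whose length jumps more than 20% between consecutive frames, are
#' flagged as segmentation errors.
#'
#' @param mask_frames list of integer label matrices (one per frame,
#'   0 = background), e.g. one element of [render_frames()] output or
#'   [read_stack()] of a label TIFF.
#' @param pixel_size nm per pixel.
#' @param frame_interval minutes between frames.
#' @return object of class `replitrack_tracks`: list with `cells`
#'   (lineage/summary per track) and `frames` (per-frame geometry).
#' @export
build_tracks <- function(mask_frames, pixel_size, frame_interval = 5) {
  px_um <- pixel_size / 1000
  n <- length(mask_frames)
  geo <- vector("list", n)
  for (f in seq_len(n)) {
    g <- frame_geometry(mask_frames[[f]])
    if (!is.null(g)) { g$frame <- f - 1L; geo[[f]] <- g }
  }
  frames <- do.call(rbind, geo)
  if (is.null(frames)) stop("empty mask stack: no labelled pixels")
  frames$length_um <- frames$length_px * px_um

  labs <- sort(unique(frames$cell))
  first_frame <- tapply(frames$frame, frames$cell, min)[as.character(labs)]
  last_frame <- tapply(frames$frame, frames$cell, max)[as.character(labs)]
  nfr <- tapply(frames$frame, frames$cell, length)[as.character(labs)]

  ## lineage from label turnover + pixel overlap
  parent <- stats::setNames(rep(NA_integer_, length(labs)), labs)
  children <- stats::setNames(vector("list", length(labs)), labs)
  for (f in seq_len(n - 1L)) {
    prev <- mask_frames[[f]]; cur <- mask_frames[[f + 1L]]
    newlab <- labs[first_frame == f]  # labels whose first frame is f (0-based)
    for (a in newlab) {
      ov <- prev[cur == a]
      ov <- ov[ov > 0L]
      if (length(ov)) {
        p <- as.integer(names(which.max(table(ov))))
        if (last_frame[as.character(p)] == f - 1L) {
          parent[as.character(a)] <- p
          children[[as.character(p)]] <- c(children[[as.character(p)]], a)
        }
      }
    }
  }

  seg_error <- vapply(labs, function(lb) {
    fr <- sort(frames$frame[frames$cell == lb])
    if (any(diff(fr) != 1L)) return(TRUE)  # vanished and reappeared
    L <- frames$length_um[frames$cell == lb][order(frames$frame[frames$cell == lb])]
    any(abs(diff(L)) / L[-length(L)] > 0.20)
  }, logical(1))

  ## orientation sign stability: align each frame's axis with the previous
  ## one; a daughter's first frame aligns with the parent's final axis
  frames <- frames[order(frames$cell, frames$frame), ]
  rownames(frames) <- NULL
  axis_last <- list()
  for (i in seq_len(nrow(frames))) {
    lb <- as.character(frames$cell[i])
    ref <- axis_last[[lb]]
    if (is.null(ref)) {
      p <- parent[[lb]]
      if (!is.na(p)) ref <- axis_last[[as.character(p)]]
    }
    if (!is.null(ref) &&
        frames$ax[i] * ref[1] + frames$ay[i] * ref[2] < 0) {
      frames$ax[i] <- -frames$ax[i]; frames$ay[i] <- -frames$ay[i]
    }
    axis_last[[lb]] <- c(frames$ax[i], frames$ay[i])
  }

  cells <- data.frame(
    cell = labs,
    parent = unname(parent),
    n_frames = as.integer(unname(nfr)),
    first_frame = as.integer(unname(first_frame)),
    last_frame = as.integer(unname(last_frame)),
    birth_observed = unname(first_frame) > 0L & !is.na(unname(parent)),
    division_observed = vapply(as.character(labs), function(k)
      length(children[[k]]) >= 2L, logical(1)),
    seg_error = unname(seg_error))
  cells$complete_cycle <- cells$birth_observed & cells$division_observed
  bl <- frames$length_um[match(paste(cells$cell, cells$first_frame),
                               paste(frames$cell, frames$frame))]
  dl <- frames$length_um[match(paste(cells$cell, cells$last_frame),
                               paste(frames$cell, frames$frame))]
  cells$birth_length_um <- bl
  cells$division_length_um <- dl

  structure(list(cells = cells, frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval, n_frames = n),
            class = "replitrack_tracks")
}

#' @export
print.replitrack_tracks <- function(x, ...) {
  cat("replitrack_tracks:", nrow(x$cells), "tracks over", x$n_frames,
      "frames;", sum(x$cells$complete_cycle), "complete cycles\n")
  invisible(x)
}

#' Relative long-axis position of a point in a cell
#'
#' Projects `(x, y) - centroid` onto the cell's long-axis unit vector and
#' scales by the cell length; 0.5 is midcell, 0 and 1 are the poles.
#'
#' @param x,y pixel coordinates.
#' @param frame_row one row of `tracks$frames` for the hosting cell/frame.
#' @return relative position in `[0, 1]`.
#' @export
long_axis_position <- function(x, y, frame_row) {
  pr <- (x - frame_row$cx) * frame_row$ax + (y - frame_row$cy) * frame_row$ay
  rel <- 0.5 + pr / frame_row$length_px
  pmin(pmax(rel, 0), 1)
}

#' Fit exponential growth per cell
#'
#' Unweighted least squares of `L(t) = L0 * exp(t / t0)` on the length
#' vs. time curve of each track with at least `min_frames` frames (time
#' measured from the track's first frame).  The doubling time is
#' `tD = t0 * log(2)`.  Non-convergent fits, non-positive `t0`, and
#' effectively flat curves (`t0` above `t0_max`) are flagged; flagged cells
#' are excluded downstream.
#'
#' @param tracks a `replitrack_tracks`.
#' @param min_frames minimum track length for a fit (default 4).
#' @param t0_max flag threshold for quasi-infinite time constants (min).
#' @return data.frame with `cell`, `L0`, `t0`, `tD` (min), `rss`, `flagged`.
#' @export
fit_growth <- function(tracks, min_frames = 4L, t0_max = 5000) {
  out <- lapply(tracks$cells$cell, function(lb) {
    fr <- tracks$frames[tracks$frames$cell == lb, , drop = FALSE]
    fr <- fr[order(fr$frame), ]
    res <- data.frame(cell = lb, L0 = NA_real_, t0 = NA_real_, tD = NA_real_,
                      rss = NA_real_, flagged = TRUE)
    if (nrow(fr) < min_frames) return(res)
    t <- (fr$frame - fr$frame[1]) * tracks$frame_interval
    L <- fr$length_um
    sl <- unname(stats::coef(stats::lm(log(L) ~ t)))
    t0_start <- if (abs(sl[2]) < 1e-9) sign(sl[2] + 1e-12) * 1e8 else 1 / sl[2]
    fit <- tryCatch(
      minpack.lm::nlsLM(L ~ L0 * exp(t / t0),
                        start = list(L0 = exp(sl[1]), t0 = t0_start),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) return(res)
    cf <- stats::coef(fit)
    res$L0 <- cf[["L0"]]; res$t0 <- cf[["t0"]]
    res$tD <- cf[["t0"]] * log(2)
    res$rss <- sum(stats::residuals(fit)^2)
    res$flagged <- !(is.finite(cf[["t0"]]) && cf[["t0"]] > 0 &&
                       cf[["t0"]] <= t0_max)
    res
  })
  do.call(rbind, out)
}

#' Automated cell selection
#'
#' Retains tracks that (i) carry no segmentation-error flag, (ii) grow
#' exponentially with a doubling time between 1.5 and 4.5 hours (time-lapse
#' mode only; requires a complete cycle and an unflagged growth fit), and
#' (iii) were born at a length between 1 and 4 um (in snapshot mode the
#' observed length stands in for the birth length).  Fully automated: no
#' manual selection.
#'
#' @param tracks a `replitrack_tracks`.
#' @param fits output of [fit_growth()] (required in time-lapse mode).
#' @param mode `"timelapse"` or `"snapshot"`.
#' @param tD_range doubling-time acceptance window (min).
#' @param birth_range birth-length acceptance window (um).
#' @return subset of `tracks$cells` with `tD` merged in; possibly empty.
#' @export
select_cells <- function(tracks, fits = NULL,
                         mode = c("timelapse", "snapshot"),
                         tD_range = c(90, 270), birth_range = c(1, 4)) {
  mode <- match.arg(mode)
  cells <- tracks$cells
  if (mode == "timelapse") {
    if (is.null(fits)) stop("growth fits are required in time-lapse mode")
    cells <- merge(cells, fits[, c("cell", "t0", "tD", "flagged")], by = "cell")
    keep <- !cells$seg_error & cells$complete_cycle & !cells$flagged &
      cells$tD >= tD_range[1] & cells$tD <= tD_range[2] &
      cells$birth_length_um >= birth_range[1] &
      cells$birth_length_um <= birth_range[2]
  } else {
    cells$t0 <- NA_real_; cells$tD <- NA_real_; cells$flagged <- FALSE
    keep <- !cells$seg_error &
      cells$birth_length_um >= birth_range[1] &
      cells$birth_length_um <= birth_range[2]
  }
  cells[keep, , drop = FALSE]
}
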