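# Shared low-level helpers: image conventions, disk geometry, TIFF I/O.
#
# Images are numeric matrices indexed [x, y] with 1-based pixel-center
# coordinates; x runs along the long axis of horizontally laid-out cells.
# Label masks are integer matrices of the same shape, 0 = background.

#' Pixel offsets of a discrete disk
#'
#' Pixels whose centers lie within Euclidean distance `radius` of a center
#' pixel. For the default scoring radius of 3 the disk has 29 pixels.
#'
#' @param radius disk radius in pixels (>= 1).
#' @return data.frame with integer columns `dx`, `dy`.
#' @export
disk_offsets <- function(radius = 3) {
  r <- ceiling(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r)
  g <- g[g$dx^2 + g$dy^2 <= radius^2, , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Gaussian blur with replicated edges
#'
#' Thin wrapper around [EBImage::filter2()] with a Gaussian brush; the kernel
#' radius is capped so small frames remain blurable, and boundaries are
#' replicated rather than wrapped.
#'
#' @param img numeric matrix.
#' @param sigma blur standard deviation in pixels.
#' @return blurred matrix of the same shape.
#' @export
gaussian_blur <- function(img, sigma = 1) {
  size <- 2L * ceiling(3 * sigma) + 1L
  size <- min(size, dim(img)[1], dim(img)[2])
  if (size %% 2L == 0L) size <- size - 1L
  if (size < 3L) return(img)
  brush <- EBImage::makeBrush(size, shape = "gaussian", sigma = sigma)
  as.matrix(EBImage::filter2(img, brush, boundary = "replicate"))
}

## integer translation with constant fill; positive dx moves content to +x
translate_int <- function(img, dx, dy, fill = 0) {
  nx <- nrow(img); ny <- ncol(img)
  out <- matrix(fill, nx, ny)
  xs <- seq_len(nx) - dx; ys <- seq_len(ny) - dy
  okx <- xs >= 1 & xs <= nx; oky <- ys >= 1 & ys <= ny
  out[okx, oky] <- img[xs[okx], ys[oky]]
  out
}

#' Write a multi-frame image stack as 16-bit grayscale TIFF
#'
#' @param frames list of numeric matrices `[x, y]`; values are rounded and
#'   clamped to `[0, 65535]`.
#' @param path output file.
#' @export
write_stack <- function(frames, path) {
  pages <- lapply(frames, function(m) {
    m <- round(m); m[m < 0] <- 0; m[m > 65535] <- 65535
    t(m) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a multi-page 16-bit TIFF stack
#'
#' @param path TIFF file written by [write_stack()] or an external tool.
#' @return list of numeric matrices `[x, y]` holding integer counts.
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    t(round(p * 65535))
  })
}

## truncated normal draw (simple rejection; bounds are loose in practice)
rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd <= 0) return(rep(pmin(pmax(mean, lo), hi), n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  tries <- 0L
  while (length(bad) && tries < 100L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
    tries <- tries + 1L
  }
  pmin(pmax(x, lo), hi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
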