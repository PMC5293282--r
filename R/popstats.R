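# Population-level statistics: factory counting, co-localization fraction,
# conditional position densities, localization-pattern frequencies.

#' Count co-localized and resolved fork pairs per cell-frame
#'
#' Every cell-frame with at least one retained focus contributes.  A cell
#' with a single focus is interpreted as one co-localized replisome pair;
#' in general `n_coloc_pairs = n_foci - 2 * n_resolved_pairs`, where
#' resolved pairs are the accepted disjoint resolved-sister pairs.
#'
#' @param foci retained foci (data.frame with `fov`, `frame`, `cell`,
#'   `cell_length_um`).
#' @param pairs classified pairs from [classify_pairs()] (may be empty).
#' @return data.frame `fov`, `frame`, `cell`, `n_foci`, `n_resolved_pairs`,
#'   `n_coloc_pairs`, `cell_length_um`.
#' @export
count_factories <- function(foci, pairs) {
  if (!nrow(foci))
    return(data.frame(fov = integer(), frame = integer(), cell = integer(),
                      n_foci = integer(), n_resolved_pairs = integer(),
                      n_coloc_pairs = integer(), cell_length_um = numeric()))
  if (is.null(foci$fov)) foci$fov <- 1L
  key <- paste(foci$fov, foci$frame, foci$cell)
  ukey <- !duplicated(key)
  counts <- data.frame(fov = foci$fov[ukey], frame = foci$frame[ukey],
                       cell = foci$cell[ukey],
                       cell_length_um = foci$cell_length_um[ukey])
  counts$n_foci <- as.integer(table(key)[paste(counts$fov, counts$frame,
                                               counts$cell)])
  counts$n_resolved_pairs <- 0L
  if (nrow(pairs)) {
    if (!all(paste(pairs$fov, pairs$frame, pairs$cell) %in% key))
      stop("pairs reference cell-frames absent from the focus table")
    frow <- seq_len(nrow(foci))
    if (!all(pairs$i %in% frow & pairs$j %in% frow))
      stop("pairs reference missing focus rows")
    acc <- pairs[pairs$accepted, , drop = FALSE]
    if (nrow(acc)) {
      tb <- table(paste(acc$fov, acc$frame, acc$cell))
      m <- match(paste(counts$fov, counts$frame, counts$cell), names(tb))
      counts$n_resolved_pairs[!is.na(m)] <- as.integer(tb[m[!is.na(m)]])
    }
  }
  counts$n_coloc_pairs <- counts$n_foci - 2L * counts$n_resolved_pairs
  if (any(counts$n_coloc_pairs < 0L))
    stop("inconsistent counts: accepted resolved pairs are not disjoint")
  counts[, c("fov", "frame", "cell", "n_foci", "n_resolved_pairs",
             "n_coloc_pairs", "cell_length_um")]
}

#' Fraction of fork pairs that are co-localized
#'
#' Pooled over all cell-frames (cells of all lengths):
#' `sum(n_coloc_pairs) / sum(n_coloc_pairs + n_resolved_pairs)`.
#'
#' @param counts output of [count_factories()].
#' @return fraction in `[0, 1]`.
#' @export
colocalization_fraction <- function(counts) {
  tot <- sum(counts$n_coloc_pairs) + sum(counts$n_resolved_pairs)
  if (tot < 1) stop("no fork pairs observed")
  sum(counts$n_coloc_pairs) / tot
}

#' Conditional probability of focus position given cell length
#'
#' 2-D histogram of relative long-axis position vs cell length, normalized
#' so that every non-empty length column sums to 1.
#'
#' @param rel_pos focus relative positions.
#' @param lengths matching cell lengths (um).
#' @param pos_bin position bin width (relative units).
#' @param len_bin length bin width (um).
#' @param len_range length range covered (um).
#' @return matrix `[position bins, length bins]` with bin-center dimnames;
#'   attributes `pos_centers`, `len_centers`.
#' @export
conditional_position_density <- function(rel_pos, lengths, pos_bin = 0.02,
                                         len_bin = 0.25,
                                         len_range = c(1, 4.5)) {
  pos_breaks <- seq(0, 1, by = pos_bin)
  len_breaks <- seq(len_range[1], len_range[2], by = len_bin)
  ok <- is.finite(rel_pos) & is.finite(lengths) &
    lengths >= len_range[1] & lengths <= len_range[2]
  pi_ <- findInterval(pmin(pmax(rel_pos[ok], 0), 1 - 1e-9), pos_breaks)
  li <- findInterval(pmin(lengths[ok], len_range[2] - 1e-9), len_breaks)
  m <- matrix(0, length(pos_breaks) - 1L, length(len_breaks) - 1L)
  for (k in seq_along(pi_)) m[pi_[k], li[k]] <- m[pi_[k], li[k]] + 1
  cs <- colSums(m)
  nz <- cs > 0
  m[, nz] <- sweep(m[, nz, drop = FALSE], 2, cs[nz], "/")
  pc <- pos_breaks[-1] - pos_bin / 2
  lc <- len_breaks[-1] - len_bin / 2
  dimnames(m) <- list(sprintf("%.3f", pc), sprintf("%.3f", lc))
  attr(m, "pos_centers") <- pc
  attr(m, "len_centers") <- lc
  m
}

#' Localization-pattern frequencies
#'
#' Classifies every analyzed cell-frame into a localization pattern --
#' 0 foci, 1 focus, 2 foci forming a resolved sister pair, 2 foci as two
#' separate (co-localized) pairs, 3 foci, 4+ foci -- and tabulates relative
#' frequencies overall and per cell-length bin.
#'
#' @param counts output of [count_factories()].
#' @param cell_frames optional data.frame of *all* analyzed cell-frames
#'   (`fov`, `frame`, `cell`, `length_um` or `cell_length_um`); cell-frames
#'   absent from `counts` enter as the zero-focus pattern.  Without it the
#'   zero-focus pattern is unobservable.
#' @param len_bin length bin width (um).
#' @return data.frame `bin` (`"all"` or bin center as character), `pattern`,
#'   `n`, `freq`; frequencies sum to 1 within each bin.
#' @export
pattern_frequencies <- function(counts, cell_frames = NULL, len_bin = 0.25) {
  df <- data.frame(length_um = counts$cell_length_um,
                   n_foci = counts$n_foci,
                   n_res = counts$n_resolved_pairs)
  if (!is.null(cell_frames)) {
    len <- cell_frames$length_um %||% cell_frames$cell_length_um
    key_c <- paste(counts$fov, counts$frame, counts$cell)
    key_a <- paste(cell_frames$fov, cell_frames$frame, cell_frames$cell)
    zero <- !(key_a %in% key_c)
    if (any(zero))
      df <- rbind(df, data.frame(length_um = len[zero], n_foci = 0L,
                                 n_res = 0L))
  }
  df$pattern <- with(df, ifelse(
    n_foci == 0L, "0_foci",
    ifelse(n_foci == 1L, "1_focus",
      ifelse(n_foci == 2L & n_res == 1L, "2_resolved_sisters",
        ifelse(n_foci == 2L, "2_factories",
          ifelse(n_foci == 3L, "3_foci", "4plus_foci"))))))
  lvls <- c("0_foci", "1_focus", "2_resolved_sisters", "2_factories",
            "3_foci", "4plus_foci")
  tab_for <- function(sub, bin) {
    n <- table(factor(sub$pattern, levels = lvls))
    data.frame(bin = bin, pattern = lvls, n = as.integer(n),
               freq = as.numeric(n) / max(sum(n), 1L))
  }
  res <- list(tab_for(df, "all"))
  bins <- floor(df$length_um / len_bin) * len_bin + len_bin / 2
  for (b in sort(unique(bins[is.finite(bins)]))) {
    res[[length(res) + 1L]] <- tab_for(df[which(bins == b), , drop = FALSE],
                                       sprintf("%.3f", b))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
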