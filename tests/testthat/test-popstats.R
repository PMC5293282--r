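mk_mix <- function() structure(list(mu = c(0.2, 0.45), sigma = c(0.05, 0.07),
                                    lambda = c(0.8, 0.2)),
                               class = "sep_mixture")

test_that("factory counting follows n_coloc = n_foci - 2 * n_resolved", {
  mix <- mk_mix()
  one <- data.frame(fov = 1L, frame = 0L, cell = 1L, rel_pos = 0.5,
                    cell_length_um = 2)
  cnt <- count_factories(one, classify_pairs(pair_separations(one), mix))
  expect_equal(cnt$n_foci, 1L)
  expect_equal(cnt$n_coloc_pairs, 1L)  # single focus = co-localized pair

  two <- data.frame(fov = 1L, frame = 0L, cell = 1L, rel_pos = c(0.4, 0.58),
                    cell_length_um = 2.5)
  cnt2 <- count_factories(two, classify_pairs(pair_separations(two), mix))
  expect_equal(cnt2$n_resolved_pairs, 1L)
  expect_equal(cnt2$n_coloc_pairs, 0L)

  four <- data.frame(fov = 1L, frame = 0L, cell = 1L,
                     rel_pos = c(0.10, 0.28, 0.55, 0.97),
                     cell_length_um = 3.5)
  p4 <- classify_pairs(pair_separations(four), mix)
  expect_equal(sum(p4$accepted), 1L)
  cnt4 <- count_factories(four, p4)
  expect_equal(cnt4$n_foci, 4L)
  expect_equal(cnt4$n_coloc_pairs, 2L)
})

test_that("inconsistent pair references error", {
  foci <- data.frame(fov = 1L, frame = 0L, cell = 1L, rel_pos = c(0.4, 0.6),
                     cell_length_um = 2.5)
  pairs <- pair_separations(foci)
  pairs$accepted <- TRUE; pairs$j <- 99L
  expect_error(count_factories(foci, pairs), "missing focus")
})

test_that("the co-localized fraction pools pairs over the dataset", {
  counts <- data.frame(n_coloc_pairs = c(1L, 1L, 0L),
                       n_resolved_pairs = c(0L, 0L, 1L))
  expect_equal(colocalization_fraction(counts), 2 / 3)
  all_single <- data.frame(n_coloc_pairs = rep(1L, 5),
                           n_resolved_pairs = 0L)
  expect_equal(colocalization_fraction(all_single), 1)
  expect_error(colocalization_fraction(
    data.frame(n_coloc_pairs = integer(), n_resolved_pairs = integer())),
    "no fork pairs")
})

test_that("per cell-frame conservation holds on a full pipeline run", {
  res <- ecoli_run()
  expect_true(all(res$counts$n_foci ==
                    res$counts$n_coloc_pairs + 2L * res$counts$n_resolved_pairs))
  expect_true(all(res$counts$n_coloc_pairs >= 0L))
  ## counts cover exactly the cell-frames with at least one retained focus
  expect_equal(sum(res$counts$n_foci), nrow(res$foci))
})

test_that("conditional position densities are column-stochastic", {
  m <- conditional_position_density(rel_pos = runif(500),
                                    lengths = runif(500, 1.2, 4.2))
  cs <- colSums(m)
  expect_true(all(abs(cs[cs > 0] - 1) < 1e-12))
  ## all mass at midcell lands in the midcell bin only
  m2 <- conditional_position_density(rep(0.5, 50), rep(2.6, 50))
  nz <- which(m2 > 0, arr.ind = TRUE)
  expect_equal(unique(nz[, 1]), which(abs(attr(m2, "pos_centers") - 0.51) < 1e-9))
  expect_equal(length(unique(nz[, 2])), 1L)
})

test_that("blocking initiation empties the quarter-cell bins of long cells", {
  cfgW <- sim_preset("ecoli_dnaN", seed = 21L)
  cfgB <- sim_preset("reinit_blocked", seed = 21L)
  qmass <- function(cfg) {
    truth <- simulate_population(cfg, n_cells = 25, duration = 300)
    em <- truth$emitters
    cf <- truth$cell_frames
    len <- cf$length_um[match(paste(em$fov, em$frame, em$cell),
                              paste(cf$fov, cf$frame, cf$cell))]
    long <- len >= 3.2
    pos <- em$x_rel[long]
    mean((pos > 0.20 & pos < 0.30) | (pos > 0.70 & pos < 0.80))
  }
  expect_gt(qmass(cfgW), 0.30)
  expect_lt(qmass(cfgB), 0.05)
})

test_that("pattern frequencies are normalized and complete", {
  counts <- data.frame(fov = 1L, frame = 0L, cell = 1:3,
                       n_foci = c(1L, 2L, 3L),
                       n_resolved_pairs = c(0L, 1L, 0L),
                       n_coloc_pairs = c(1L, 0L, 3L),
                       cell_length_um = c(1.6, 2.6, 3.6))
  pf <- pattern_frequencies(counts)
  all_tab <- pf[pf$bin == "all", ]
  expect_equal(sum(all_tab$freq), 1)
  expect_equal(all_tab$freq[all_tab$pattern == "1_focus"], 1 / 3)
  expect_equal(all_tab$freq[all_tab$pattern == "2_resolved_sisters"], 1 / 3)
  for (b in setdiff(unique(pf$bin), "all"))
    expect_equal(sum(pf$freq[pf$bin == b]), 1)
  ## zero-focus cell-frames come from the analyzed-frame table
  frames <- data.frame(fov = 1L, frame = 0L, cell = 1:4,
                       length_um = c(1.6, 2.6, 3.6, 2.1))
  pf0 <- pattern_frequencies(counts, frames)
  expect_equal(pf0$freq[pf0$bin == "all" & pf0$pattern == "0_foci"], 1 / 4)
})

test_that("two-focus patterns rise with cell length on the wild-type run", {
  res <- ecoli_run()
  pf <- res$patterns
  pf <- pf[pf$bin != "all", ]
  bins <- as.numeric(pf$bin[pf$pattern == "1_focus"])
  two <- pf$freq[pf$pattern == "2_factories"] +
    pf$freq[pf$pattern == "2_resolved_sisters"]
  n_bin <- tapply(pf$n, pf$bin, sum)[as.character(sprintf("%.3f", bins))]
  ok <- n_bin >= 30
  expect_gt(suppressWarnings(cor(bins[ok], two[ok], method = "spearman")), 0)
})
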