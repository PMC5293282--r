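test_that("length is the Feret extent along the principal axis", {
  lab <- matrix(0L, 60, 20)
  lab[11:50, 8:13] <- 1L  # 40 x 6 px rectangle
  tr <- build_tracks(list(lab), pixel_size = 160)
  expect_equal(tr$frames$length_um, 6.4)
  expect_equal(abs(tr$frames$ax), 1)
})

test_that("a track without flanking divisions is not a complete cycle", {
  lab <- matrix(0L, 40, 20); lab[10:30, 8:13] <- 1L
  frames <- c(replicate(11, lab, simplify = FALSE),
              replicate(3, matrix(0L, 40, 20), simplify = FALSE))
  frames <- frames[1:11]  # label present frames 0-10 only
  tr <- build_tracks(frames, pixel_size = 100)
  expect_equal(nrow(tr$cells), 1L)
  expect_false(tr$cells$complete_cycle)
})

test_that("track lengths match simulator ground truth within one pixel", {
  tt <- tiny_truth(); stk <- tiny_stacks()
  cfg <- tt$cfg
  tr <- build_tracks(stk[[1]]$mask, cfg$pixel_size, cfg$frame_interval)
  cf <- tt$truth$cell_frames
  cf <- cf[cf$fov == 1L & cf$group == cf$cell, ]
  m <- match(paste(tr$frames$cell, tr$frames$frame),
             paste(cf$cell, cf$frame))
  ok <- !is.na(m)
  expect_gt(sum(ok), 50)
  err <- abs(tr$frames$length_um[ok] - cf$length_um[m[ok]])
  expect_lt(max(err), cfg$pixel_size / 1000)
})

test_that("lineage links and axis orientation are stable", {
  tt <- tiny_truth(); stk <- tiny_stacks()
  tr <- build_tracks(stk[[1]]$mask, tt$cfg$pixel_size)
  truth_cells <- tt$truth$cells[tt$truth$cells$fov == 1L, ]
  got <- tr$cells[!is.na(tr$cells$parent), c("cell", "parent")]
  want <- truth_cells[!is.na(truth_cells$parent), c("cell", "parent")]
  m <- merge(got, want, by = "cell")
  expect_gt(nrow(m), 0)
  expect_equal(m$parent.x, m$parent.y)
  ## orientation sign never flips within a track
  for (lb in unique(tr$frames$cell)) {
    axs <- tr$frames$ax[tr$frames$cell == lb]
    expect_true(all(axs > 0) || all(axs < 0))
  }
})

test_that("long-axis positions: centroid is midcell, poles are 0 and 1", {
  lab <- matrix(0L, 60, 20); lab[11:50, 8:13] <- 1L
  tr <- build_tracks(list(lab), pixel_size = 65)
  fr <- tr$frames[1, ]
  expect_equal(long_axis_position(fr$cx, fr$cy, fr), 0.5)
  expect_equal(long_axis_position(11 - 0.5, fr$cy, fr), 0, tolerance = 1e-6)
  expect_equal(long_axis_position(50 + 0.5, fr$cy, fr), 1, tolerance = 1e-6)
})

test_that("a rendered emitter at relative position 0.25 is recovered there", {
  cfg <- sim_preset("ecoli_dnaN", seed = 2L, noise_model = "none",
                    cell_tex_sd = 0)
  truth <- simulate_population(cfg, n_cells = 1, duration = 30)
  truth$emitters <- truth$emitters[1, , drop = FALSE]
  truth$emitters$x_rel <- 0.25
  cf <- truth$cell_frames
  hrow <- cf[cf$frame == truth$emitters$frame & cf$cell == truth$emitters$cell, ]
  truth$emitters$x_um <- hrow$cx_um + (0.25 - 0.5) * hrow$length_um
  truth$emitters$y_um <- 0
  stk <- render_frames(truth, cfg)
  tr <- build_tracks(stk[[1]]$mask, cfg$pixel_size, cfg$frame_interval)
  foci <- detect_foci(stk[[1]]$fluor, stk[[1]]$mask, tr)
  f <- foci[foci$retained & foci$frame == truth$emitters$frame, ]
  expect_equal(nrow(f), 1L)
  Lpx <- hrow$length_um * 1000 / cfg$pixel_size
  expect_lt(min(abs(f$rel_pos - 0.25), abs(f$rel_pos - 0.75)), 0.5 / Lpx)
})

test_that("exponential growth fits recover noiseless parameters exactly", {
  t <- seq(0, 180, by = 5)
  L <- 2 * exp(t / 260)
  tr <- list(cells = data.frame(cell = 1L),
             frames = data.frame(cell = 1L, frame = seq_along(t) - 1L,
                                 length_um = L),
             frame_interval = 5, n_frames = length(t))
  class(tr) <- "replitrack_tracks"
  fit <- fit_growth(tr)
  expect_equal(fit$t0, 260, tolerance = 1e-6)
  expect_equal(fit$L0, 2, tolerance = 1e-6)
  expect_equal(fit$tD, 260 * log(2), tolerance = 1e-6)
  expect_false(fit$flagged)
})

test_that("degenerate growth curves are flagged", {
  tr <- list(cells = data.frame(cell = 1:2),
             frames = rbind(
               data.frame(cell = 1L, frame = 0:10, length_um = 2.5),
               data.frame(cell = 2L, frame = 0:2, length_um = c(2, 2.1, 2.2))),
             frame_interval = 5, n_frames = 11)
  class(tr) <- "replitrack_tracks"
  fit <- fit_growth(tr)
  expect_true(fit$flagged[1])  # constant length: t0 -> infinity
  expect_true(fit$flagged[2])  # too few frames
})

test_that("tD/t0 equals log(2) for every accepted fit", {
  res <- ecoli_run()
  expect_gt(nrow(res$fits), 20)
  ok <- !res$fits$flagged
  expect_equal(res$fits$tD[ok] / res$fits$t0[ok],
               rep(log(2), sum(ok)))
})

test_that("selection applies the three automated criteria", {
  cells <- data.frame(cell = 1:5, parent = NA, n_frames = 30,
                      first_frame = 1L, last_frame = 30L,
                      birth_observed = TRUE, division_observed = TRUE,
                      seg_error = c(FALSE, FALSE, FALSE, TRUE, FALSE),
                      complete_cycle = TRUE,
                      birth_length_um = c(2, 0.8, 2, 2, 2),
                      division_length_um = 3.5)
  fits <- data.frame(cell = 1:5, L0 = 2, t0 = c(260, 260, 433, 260, 260),
                     tD = c(260, 260, 433, 260, 260) * log(2),
                     rss = 0, flagged = FALSE)
  tr <- list(cells = cells, frames = NULL, frame_interval = 5)
  class(tr) <- "replitrack_tracks"
  sel <- select_cells(tr, fits, "timelapse")
  ## excluded: birth 0.8 um; tD = 5 h; segmentation error
  expect_setequal(sel$cell, c(1L, 5L))
  ## snapshot mode ignores growth: no fits needed, length proxy in range
  snap <- select_cells(tr, mode = "snapshot")
  expect_setequal(snap$cell, c(1L, 3L, 5L))
})

test_that("all in-bounds complete-cycle cells pass selection on clean sims", {
  res <- ecoli_run()
  for (nm in names(res$tracks)[1:5]) {
    tr <- res$tracks[[nm]]
    cand <- tr$cells[tr$cells$complete_cycle & !tr$cells$seg_error, ]
    sel <- res$selected[res$selected$fov == as.integer(sub("fov", "", nm)), ]
    expect_true(all(cand$cell %in% sel$cell))
  }
})

test_that("a vanish-and-reappear label is flagged as a segmentation error", {
  lab <- matrix(0L, 40, 20); lab[10:30, 8:13] <- 1L
  empty <- matrix(0L, 40, 20)
  tr <- build_tracks(list(lab, lab, empty, lab), pixel_size = 100)
  expect_true(tr$cells$seg_error[tr$cells$cell == 1L])
})
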