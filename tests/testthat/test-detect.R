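test_that("drift offsets are recovered exactly for integer shifts", {
  withr::with_seed(1, {
    base <- matrix(rpois(60 * 40, 200), 60, 40)
  })
  base[25:30, 18:22] <- 1200
  expect_equal(unname(drift_correct(base, base)), c(0L, 0L))
  shifted <- translate_int(base, 2L, 3L, fill = 200)
  expect_equal(unname(drift_correct(shifted, base)), c(2L, 3L))
  expect_warning(drift_correct(translate_int(base, 10L, 0L, fill = 200),
                               base, max_shift = 10L), "border")
})

test_that("injected per-frame jitter is undone by the pipeline alignment", {
  cfg <- sim_preset("ecoli_dnaN", seed = 6L)
  truth <- simulate_population(cfg, n_cells = 1, duration = 60)
  drift <- cbind(dx = c(0L, 2L, -1L, 3L, 0L, 1L, -2L, 0L, 2L, 1L, 0L, -1L, 0L),
                 dy = c(0L, 1L, 2L, -1L, 0L, -2L, 1L, 0L, 0L, 1L, -1L, 0L, 0L))
  stk <- render_frames(truth, cfg, drift = drift)
  s <- stk[[1]]
  ## recover the per-frame offsets from the mask silhouettes
  rec <- t(vapply(2:length(s$mask), function(f)
    drift_correct(1 * (s$mask[[f]] > 0), 1 * (s$mask[[f - 1]] > 0)),
    integer(2)))
  inj <- diff(drift[seq_along(s$mask), , drop = FALSE])
  expect_equal(unname(rec), unname(inj))
})

test_that("a flat frame yields no candidates", {
  lab <- matrix(0L, 40, 30); lab[10:30, 10:20] <- 1L
  img <- matrix(100, 40, 30)
  out <- detect_candidates(img, lab)
  expect_equal(nrow(out$candidates), 0L)
  expect_equal(nrow(detect_candidates(img, matrix(0L, 40, 30))$candidates), 0L)
})

test_that("the diffraction limit separates candidates at ~250 nm", {
  px <- 65
  mk <- function(sep_nm) {
    d <- sep_nm / px / 2
    synth_cell_frame(emitters = list(list(x = 30 - d, y = 15, amp = 400),
                                     list(x = 30 + d, y = 15, amp = 400)))
  }
  near <- mk(150); far <- mk(600)
  expect_equal(nrow(detect_candidates(near$img, near$lab)$candidates), 1L)
  expect_equal(nrow(detect_candidates(far$img, far$lab)$candidates), 2L)
  ## and through the full chain with scoring
  foci_near <- detect_foci(list(near$img), list(near$lab))
  foci_far <- detect_foci(list(far$img), list(far$lab))
  expect_equal(sum(foci_near$retained), 1L)
  expect_equal(sum(foci_far$retained), 2L)
})

test_that("Gaussian fits localize noise-free emitters to < 0.05 px and
           recover the PSF width", {
  sc <- synth_cell_frame(emitters = list(list(x = 30.30, y = 14.60, amp = 500)))
  cand <- detect_candidates(sc$img, sc$lab)$candidates
  ft <- fit_focus(sc$img, cand[1, ])
  expect_lt(abs(ft$x - 30.30), 0.05)
  expect_lt(abs(ft$y - 14.60), 0.05)
  expect_lt(abs(ft$b - 110 / 65) / (110 / 65), 0.10)
})

test_that("a symmetric profile fits exactly at the pixel center", {
  sc <- synth_cell_frame(emitters = list(list(x = 30, y = 15, amp = 500)))
  ft <- fit_focus(sc$img, list(x = 30L, y = 15L))
  expect_equal(ft$x, 30, tolerance = 1e-6)
  expect_equal(ft$y, 15, tolerance = 1e-6)
})

test_that("the score equals a brute-force pixel-summation oracle", {
  sc <- synth_cell_frame(emitters = list(list(x = 30.2, y = 14.7, amp = 600)),
                         noise = TRUE, seed = 42)
  bl <- gaussian_blur(sc$img, 1)
  cs <- cell_intensity_stats(sc$img, sc$lab)
  foc <- data.frame(x = 30.2, y = 14.7)
  got <- score_focus(bl, foc, sc$lab, cs)
  want <- oracle_score(bl, sc$img, sc$lab, 30L, 15L)
  expect_equal(got$Ia, want$Ia, tolerance = 1e-12)
  expect_equal(got$dI, want$dI, tolerance = 1e-12)
  expect_equal(got$score, want$score, tolerance = 1e-9)
  expect_equal(detection_params()$A, 29L)
})

test_that("a flat disk scores zero and is rejected", {
  lab <- matrix(0L, 30, 30); lab[5:25, 5:25] <- 1L
  img <- matrix(100, 30, 30)
  img[5:25, 5:9] <- rep(c(90, 110), length.out = 21 * 5)  # dI > 0, off-disk
  cs <- cell_intensity_stats(img, lab)
  got <- score_focus(img, data.frame(x = 17, y = 17), lab, cs)
  expect_equal(got$Ia, 0)
  expect_equal(got$score, 0)
  expect_false(got$retained)
})

test_that("a flat cell (dI = 0) scores 0 and is rejected", {
  lab <- matrix(0L, 30, 30); lab[5:25, 5:25] <- 1L
  img <- matrix(100, 30, 30); img[15, 15] <- 500
  cs <- cell_intensity_stats(img, lab)
  cs$dI <- 0
  got <- score_focus(img, data.frame(x = 15, y = 15), lab, cs)
  expect_equal(got$score, 0)
  expect_false(got$retained)
})

test_that("the retention boundary sits exactly at the score threshold", {
  ## construct two disks whose oracle scores bracket 4
  mk <- function(delta) {
    lab <- matrix(0L, 41, 25); lab[6:36, 5:21] <- 1L
    img <- matrix(100, 41, 25)
    idx <- which(lab == 1L, arr.ind = TRUE)
    far <- abs(idx[, 1] - 21L) > 6L
    img[idx[far, , drop = FALSE]] <- 100 + 10 * (-1)^(idx[far, 1] + idx[far, 2])
    img[21, 13] <- 100 + delta
    list(img = img, lab = lab)
  }
  score_of <- function(delta) {
    m <- mk(delta)
    cs <- cell_intensity_stats(m$img, m$lab)
    score_focus(m$img, data.frame(x = 21, y = 13), m$lab, cs)
  }
  ## bisect delta so the scores bracket the threshold tightly
  f <- function(delta) score_of(delta)$score - 4
  lo <- 0; hi <- 1000
  for (i in 1:50) { mid <- (lo + hi) / 2; if (f(mid) < 0) lo <- mid else hi <- mid }
  below <- score_of(lo * 0.999); above <- score_of(hi * 1.001)
  expect_lt(below$score, 4); expect_false(below$retained)
  expect_gte(above$score, 4); expect_true(above$retained)
  ## oracle agreement at the boundary
  m <- mk(hi)
  want <- oracle_score(m$img, m$img, m$lab, 21L, 13L)
  expect_equal(score_of(hi)$score, want$score, tolerance = 1e-9)
})

test_that("the score is strictly monotone in focus amplitude", {
  ## frozen noise field, emitter amplitude scanned on top of it
  base <- synth_cell_frame()
  noise <- withr::with_seed(7, matrix(stats::rpois(60 * 30, 200) - 200, 60, 30))
  amps <- seq(100, 1300, by = 200)
  scores <- vapply(amps, function(a) {
    sc <- synth_cell_frame(emitters = list(list(x = 30.2, y = 14.6, amp = a)))
    img <- sc$img + noise
    bl <- gaussian_blur(img, 1)
    cs <- cell_intensity_stats(img, sc$lab)
    score_focus(bl, data.frame(x = 30.2, y = 14.6), sc$lab, cs)$score
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
})

test_that("pure-noise stacks retain foci in fewer than 2% of cell-frames", {
  cfg <- sim_preset("ecoli_dnaN", seed = 31L)
  truth <- simulate_population(cfg, n_cells = 8, duration = 240)
  truth$emitters <- NULL  # cells without any focus
  stk <- render_frames(truth, cfg)
  hits <- 0L; total <- 0L
  for (s in stk) {
    foci <- detect_foci(s$fluor, s$mask)
    ret <- foci[foci$retained, , drop = FALSE]
    per_frame <- vapply(seq_along(s$mask), function(f)
      length(unique(s$mask[[f]][s$mask[[f]] > 0])), integer(1))
    total <- total + sum(per_frame)
    hits <- hits + nrow(unique(ret[, c("frame", "cell")]))
  }
  expect_gt(total, 600)
  expect_lt(hits / total, 0.02)
})

test_that("detection is deterministic", {
  sc <- synth_cell_frame(emitters = list(list(x = 25.4, y = 14.2, amp = 700),
                                         list(x = 38.0, y = 15.1, amp = 350)),
                         noise = TRUE, seed = 3)
  a <- detect_foci(list(sc$img), list(sc$lab))
  b <- detect_foci(list(sc$img), list(sc$lab))
  expect_identical(a, b)
})

test_that("rendered emitters are matched by retained foci within 1 px and
           localization RMS is below half a pixel", {
  tt <- tiny_truth(); stk <- tiny_stacks()
  cfg <- tt$cfg
  epx <- emitters_px(tt$truth, cfg)
  rms <- c(); matched <- 0L; n_em <- 0L
  for (fv in 1:2) {
    s <- stk[[fv]]
    tr <- build_tracks(s$mask, cfg$pixel_size, cfg$frame_interval)
    foci <- detect_foci(s$fluor, s$mask, tr)
    foci <- foci[foci$retained, , drop = FALSE]
    foci$fov <- fv
    e <- epx[epx$fov == fv, , drop = FALSE]
    ## emitter pairs closer than the diffraction limit render as one focus;
    ## match against the unresolvable-merged emitter list
    mm <- match_foci(foci, e, tol = 2.5)
    rms <- c(rms, mm$matched$dist)
    matched <- matched + nrow(mm$matched)
    n_em <- n_em + nrow(e)
  }
  expect_gt(matched / n_em, 0.85)
  expect_lt(sqrt(mean(rms^2)), 0.5 * sqrt(2))  # 2-D RMS at preset SNR
})
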