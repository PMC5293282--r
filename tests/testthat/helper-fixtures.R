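# Shared fixtures: tiny synthetic frames built in code, plus memoised
# medium-scale pipeline runs reused across test files.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

## a single rectangular "cell" frame with optional Gaussian emitters;
## emitters are given in pixel coordinates
synth_cell_frame <- function(nx = 60, ny = 30, rect = c(8, 52, 9, 21),
                             base = 400, emitters = NULL, sigma_px = 110 / 65,
                             noise = FALSE, seed = 1) {
  lab <- matrix(0L, nx, ny)
  lab[rect[1]:rect[2], rect[3]:rect[4]] <- 1L
  img <- matrix(base, nx, ny)
  if (!is.null(emitters)) {
    for (e in emitters)
      img <- replitrack:::add_gaussian(img, e$x, e$y, e$amp, sigma_px)
  }
  if (noise) img <- withr::with_seed(seed, matrix(stats::rpois(nx * ny, img), nx, ny))
  list(img = img, lab = lab)
}

## medium E. coli time-lapse pipeline run shared by acceptance and
## population-statistics tests (>= 200 simulated cell cycles)
ecoli_run <- function() memo("ecoli_run", {
  run_pipeline(pipeline_config(mode = "timelapse", preset = "ecoli_dnaN",
                               n_cells = 60, duration = 330, seed = 7L,
                               make_figures = FALSE))
})

bsub_run <- function() memo("bsub_run", {
  run_pipeline(pipeline_config(mode = "timelapse", preset = "bsubtilis_dnaN",
                               n_cells = 45, duration = 300, seed = 7L,
                               make_figures = FALSE))
})

snapshot_run <- function() memo("snapshot_run", {
  run_pipeline(pipeline_config(mode = "snapshot", preset = "snapshot_marker",
                               n_cells = 2000, seed = 11L,
                               make_figures = FALSE))
})

## tiny time-lapse sim reused by simulator/tracking/detection tests
tiny_truth <- function() memo("tiny_truth", {
  cfg <- sim_preset("ecoli_dnaN", seed = 5L)
  list(cfg = cfg, truth = simulate_population(cfg, n_cells = 4, duration = 240))
})

tiny_stacks <- function() memo("tiny_stacks", {
  tt <- tiny_truth()
  render_frames(tt$truth, tt$cfg)
})

## independent brute-force oracle for the focus score: plain pixel sums on
## the measurement frame, sd over the mask on the raw frame
oracle_score <- function(meas, raw, lab, cx, cy, radius = 3) {
  offs <- expand.grid(dx = -radius:radius, dy = -radius:radius)
  offs <- offs[offs$dx^2 + offs$dy^2 <= radius^2, ]
  v <- numeric(nrow(offs))
  for (i in seq_len(nrow(offs))) v[i] <- meas[cx + offs$dx[i], cy + offs$dy[i]]
  A <- length(v)
  Ia <- sum(v) - min(v) * A
  label <- lab[cx, cy]
  vals <- raw[which(lab == label)]
  dI <- sqrt(sum((vals - mean(vals))^2) / (length(vals) - 1))
  list(Ia = Ia, dI = dI, score = Ia / (dI * sqrt(A)), A = A)
}

## exhaustive maximum-posterior disjoint matching over candidate pairs of
## one cell-frame (<= 4 foci means at most 6 pairs): enumerate every
## disjoint subset and pick the one whose descending posterior sequence is
## lexicographically largest (i.e. it takes the highest-posterior pair
## available at each rank) -- an independent enumeration-based route to the
## incremental greedy selection
bruteforce_matching <- function(cand) {
  if (!nrow(cand)) return(integer(0))
  n <- nrow(cand)
  lex_key <- function(sel) {
    if (!length(sel)) return(numeric(0))
    sort(cand$posterior_low[sel], decreasing = TRUE)
  }
  lex_gt <- function(a, b) {
    k <- max(length(a), length(b))
    a <- c(a, rep(-Inf, k - length(a))); b <- c(b, rep(-Inf, k - length(b)))
    for (u in seq_len(k)) {
      if (a[u] > b[u] + 1e-12) return(TRUE)
      if (a[u] < b[u] - 1e-12) return(FALSE)
    }
    FALSE
  }
  best <- integer(0)
  for (m in 0:(2^n - 1)) {
    sel <- which(bitwAnd(m, 2^(seq_len(n) - 1)) > 0)
    ids <- c(cand$i[sel], cand$j[sel])
    if (anyDuplicated(ids)) next
    if (lex_gt(lex_key(sel), lex_key(best))) best <- sel
  }
  sort(best)
}
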