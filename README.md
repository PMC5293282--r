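# replitrack

Automated analysis of replisome positioning in bacterial fluorescence
microscopy, with a ground-truthed synthetic-data generator.

## The problem

In rod-shaped bacteria the two replication forks of one round either stay
spatially proximal in a "factory" or track independently along the
chromosome. Distinguishing these pictures from images is a statistics
problem: a fluorescent replisome marker (e.g. the beta-clamp DnaN) forms
diffraction-limited foci, one focus may contain one replisome or a
co-localized pair, re-initiation before division adds focus pairs near the
quarter-cell positions that mimic separated sisters, and cell-to-cell
variability is large. replitrack is for microscopists and quantitative
biologists who have time-lapse (or snapshot) fluorescence stacks plus
per-cell label masks and want population-scale, hand-selection-free
answers.

## What it computes

- **Growth**: per-cell exponential fits `L(t) = L0·exp(t/t0)`, doubling
  time `tD = t0·ln 2`; automated selection (no segmentation errors,
  `1.5 h ≤ tD ≤ 4.5 h`, birth length 1–4 µm).
- **Foci**: 1-px Gaussian blur, watershed intensity regions inside cell
  masks, sub-pixel 2-D Gaussian fit
  `Ig·exp(−|x−x0|²/2b²) + I0` over a 3-px-radius disk, and a significance
  score `σ = Ia/(δI·√A)` with `Ia = Σ(disk) − A·min(disk)`, `A = 29`, and
  `δI` the intensity s.d. over the cell mask. Foci with `σ ≥ 4` are
  retained.
- **Classification**: all unique within-cell pair separations (relative to
  cell length), a two-Gaussian mixture fitted by maximum likelihood,
  posterior assignment of pairs to the resolved-sister (≈0.2 cell
  lengths) or high-separation (≈0.45) population, and factory counting
  `n_coloc = n_foci − 2·n_resolved`.
- **Summaries**: co-localized fork-pair fraction, conditional probability
  of focus position given cell length, localization-pattern frequencies,
  kymographs and cell towers.
- **Simulation**: `sim_preset()` / `simulate_population()` /
  `render_frames()` generate growing, dividing cells with factory-model
  replisome dynamics, rendered through a 110-nm Gaussian PSF with Poisson
  noise, exporting full ground truth (events, emitters, masks).

## Worked example

```r
library(replitrack)

res <- run_pipeline(pipeline_config(
  mode = "timelapse", preset = "ecoli_dnaN",
  n_cells = 30, duration = 300, seed = 7, make_figures = FALSE))

s <- res$summary
cat(sprintf("selected cells: %d   retained foci: %d   pairs: %d\n",
            s$n_cells_selected, s$n_foci, s$n_pairs))
cat(sprintf("mean doubling time: %.2f h\n", s$mean_tD_min / 60))
cat(sprintf("mixture means: %.3f / %.3f cell lengths\n",
            s$mixture$mu_low, s$mixture$mu_high))
cat(sprintf("co-localized fork pairs: %.1f%%\n", 100 * s$coloc_fraction))
```

prints

```
selected cells: 43   retained foci: 1328   pairs: 356
mean doubling time: 3.00 h
mixture means: 0.204 / 0.451 cell lengths
co-localized fork pairs: 81.2%
```

Reading: 30 simulated lineages yield 43 automatically selected complete
cell cycles growing with a 3 h doubling time. Of the 1328 retained foci,
pair separations split into the resolved-sister population at ~0.20 cell
lengths and the quarter-cell population at ~0.45; counting single foci as
co-localized pairs and accepted low-separation pairs as resolved sisters,
~81% of fork pairs are co-localized, recovering the generator's ground
truth of 82% within the sampling error of a run this size (the vignette
discusses the small systematic biases of the estimator). The numbered scripts under `analysis/` walk the same chain
stage by stage (simulate → track/grow → detect → population statistics →
condition contrasts) and write tables/figures under `results/`.

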