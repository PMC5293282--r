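# End-to-end pipeline: simulate/load -> track -> detect -> classify ->
# report.  Fully automated; deterministic given the seed.

#' Pipeline configuration
#'
#' @param mode `"timelapse"` or `"snapshot"`.
#' @param preset simulation preset name (see [sim_preset()]); ignored when
#'   `fluor_path`/`mask_path` point at external stacks.
#' @param n_cells founder lineages (time-lapse) or cells (snapshot).
#' @param duration simulated minutes (time-lapse).
#' @param seed integer seed controlling simulation and rendering.
#' @param sim_overrides named list of [sim_config()] overrides.
#' @param detection named list of [detection_params()] overrides.
#' @param fluor_path,mask_path optional TIFF stacks to analyze instead of
#'   simulating (single field of view).
#' @param out_dir optional output directory (CSV/JSON tables, PNG figures,
#'   run manifest).
#' @param write_images also write the rendered TIFF stacks + ground truth.
#' @param correct_drift align frames before detection.
#' @param make_figures write PNG figures alongside the tables.
#' @return a `replitrack_config` list.
#' @export
pipeline_config <- function(mode = c("timelapse", "snapshot"),
                            preset = "ecoli_dnaN", n_cells = 50,
                            duration = 300, seed = 1L,
                            sim_overrides = list(), detection = list(),
                            fluor_path = NULL, mask_path = NULL,
                            out_dir = NULL, write_images = FALSE,
                            correct_drift = FALSE, make_figures = TRUE) {
  mode <- match.arg(mode)
  if (is.null(fluor_path) != is.null(mask_path))
    stop("fluor_path and mask_path must be given together")
  cfg <- list(mode = mode, preset = preset, n_cells = n_cells,
              duration = duration, seed = as.integer(seed),
              sim_overrides = sim_overrides, detection = detection,
              fluor_path = fluor_path, mask_path = mask_path,
              out_dir = out_dir, write_images = write_images,
              correct_drift = correct_drift, make_figures = make_figures)
  class(cfg) <- "replitrack_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) image stacks, builds tracks, fits growth and applies
#' the selection filters (time-lapse mode; snapshot mode skips growth),
#' detects and scores foci, computes pair separations, fits the
#' two-Gaussian separation mixture, classifies pairs, counts co-localized
#' vs resolved fork pairs, and assembles the population summaries.  With
#' `out_dir` set, writes tracks/foci/pairs/counts/density/pattern CSVs, the
#' mixture and summary JSONs, figures, and a run manifest; a rerun with the
#' same configuration reproduces the CSVs byte-identically.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a results list: `truth`, `tracks` (per fov), `fits`,
#'   `selected`, `foci`, `pairs`, `mixture`, `counts`, `coloc_fraction`,
#'   `density`, `patterns`, `summary`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "replitrack_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  dpar <- do.call(detection_params, config$detection)
  external <- !is.null(config$fluor_path)

  if (external) {
    truth <- NULL
    sim <- do.call(sim_config, config$sim_overrides)
    fovs <- list(list(fluor = read_stack(config$fluor_path),
                      mask = lapply(read_stack(config$mask_path),
                                    function(m) { storage.mode(m) <- "integer"; m })))
    names(fovs) <- "fov1"
    fov_ids <- 1L
  } else {
    sim <- stage("simulate", do.call(sim_preset, c(
      list(name = config$preset, seed = config$seed,
           snapshot = config$mode == "snapshot"), config$sim_overrides)))
    truth <- stage("simulate", simulate_population(sim, config$n_cells,
                                                   config$duration))
    fov_ids <- sort(unique(truth$cell_frames$fov))
    fovs <- NULL  # rendered lazily per fov
  }

  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  if (!is.null(out_dir) && config$write_images && !external)
    stage("render", render_frames(truth, sim, dir = file.path(out_dir, "stacks")))

  all_tracks <- list(); all_fits <- list(); all_sel <- list()
  all_foci <- list(); all_frames <- list()
  kymo <- NULL
  for (k in seq_along(fov_ids)) {
    fv <- fov_ids[k]
    stacks <- if (external) fovs[[k]] else
      stage("render", withr::with_seed(sim$seed + 1000L + fv,
                                       render_fov(truth, sim, fv)))
    tr <- stage("track", build_tracks(stacks$mask, sim$pixel_size,
                                      sim$frame_interval))
    fits <- if (config$mode == "timelapse")
      stage("growth", fit_growth(tr)) else NULL
    sel <- stage("select", select_cells(tr, fits, mode = config$mode))
    foci <- stage("detect", detect_foci(stacks$fluor, stacks$mask, tr,
                                        params = dpar,
                                        correct_drift = config$correct_drift))
    if (nrow(foci)) foci$fov <- fv
    keep <- foci$retained & foci$cell %in% sel$cell
    all_tracks[[k]] <- tr
    if (!is.null(fits)) { fits$fov <- fv; all_fits[[k]] <- fits }
    if (nrow(sel)) { sel$fov <- fv; all_sel[[k]] <- sel }
    all_foci[[k]] <- foci[keep, , drop = FALSE]
    af <- tr$frames[tr$frames$cell %in% sel$cell,
                    c("cell", "frame", "length_um"), drop = FALSE]
    if (nrow(af)) { af$fov <- fv; all_frames[[k]] <- af }
    if (is.null(kymo) && config$mode == "timelapse" && nrow(sel)) {
      best <- sel$cell[which.max(sel$n_frames)]
      kymo <- kymograph(tr, best, stacks$fluor, stacks$mask)
    }
  }
  names(all_tracks) <- paste0("fov", fov_ids)
  foci <- do.call(rbind, all_foci)
  if (is.null(foci) || !nrow(foci))
    stop("pipeline stage 'detect' produced no retained foci in selected cells")
  rownames(foci) <- NULL
  fits <- if (length(all_fits)) do.call(rbind, all_fits) else NULL
  selected <- if (length(all_sel)) do.call(rbind, all_sel) else NULL
  analyzed_frames <- if (length(all_frames)) do.call(rbind, all_frames) else NULL

  pairs <- stage("classify", pair_separations(foci))
  mixture <- stage("classify", fit_sep_mixture(pairs$rel_sep))
  pairs <- stage("classify", classify_pairs(pairs, mixture))
  counts <- stage("classify", count_factories(foci, pairs))
  coloc <- stage("report", colocalization_fraction(counts))
  density <- stage("report", conditional_position_density(
    foci$rel_pos, foci$cell_length_um))
  patterns <- stage("report", pattern_frequencies(counts, analyzed_frames))

  summary <- list(
    mode = config$mode, preset = if (external) NA else config$preset,
    seed = config$seed,
    n_cells_selected = if (is.null(selected)) 0L else nrow(selected),
    n_cell_frames = if (is.null(analyzed_frames)) NA_integer_
                    else nrow(analyzed_frames),
    n_foci = nrow(foci), n_pairs = nrow(pairs),
    n_resolved_pairs = sum(counts$n_resolved_pairs),
    n_coloc_pairs = sum(counts$n_coloc_pairs),
    coloc_fraction = coloc,
    mixture = list(mu_low = mixture$mu[1], mu_high = mixture$mu[2],
                   sigma_low = mixture$sigma[1], sigma_high = mixture$sigma[2],
                   pi_low = mixture$lambda[1], pi_high = mixture$lambda[2],
                   loglik = mixture$loglik),
    mean_resolved_sep = if (any(pairs$accepted))
      mean(pairs$rel_sep[pairs$accepted]) else NA_real_,
    mean_tD_min = if (!is.null(fits) && !is.null(selected))
      mean(selected$tD) else NA_real_)

  res <- list(truth = truth, tracks = all_tracks, fits = fits,
              selected = selected, foci = foci, pairs = pairs,
              mixture = mixture, counts = counts, coloc_fraction = coloc,
              density = density, patterns = patterns, kymograph = kymo,
              analyzed_frames = analyzed_frames, summary = summary,
              config = config)

  if (!is.null(out_dir)) stage("report", write_pipeline_outputs(res, out_dir))
  invisible(res)
}

write_pipeline_outputs <- function(res, out_dir) {
  cfg <- res$config
  wcsv <- function(df, name) {
    if (is.null(df)) return(NULL)
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    p
  }
  files <- c(
    wcsv(do.call(rbind, lapply(names(res$tracks), function(nm) {
      d <- res$tracks[[nm]]$cells; d$fov <- as.integer(sub("fov", "", nm)); d
    })), "tracks.csv"),
    wcsv(res$fits, "growth_fits.csv"),
    wcsv(res$selected, "selected_cells.csv"),
    wcsv(res$foci, "foci.csv"),
    wcsv(res$pairs, "pairs.csv"),
    wcsv(res$counts, "counts.csv"),
    wcsv(as.data.frame(res$density), "density.csv"),
    wcsv(res$patterns, "patterns.csv"))
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  jsonlite::write_json(unclass(res$mixture), file.path(out_dir, "mixture.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, file.path(out_dir, c("summary.json", "mixture.json")))
  if (isTRUE(cfg$make_figures)) {
    p <- file.path(out_dir, "coloc_pie.png")
    grDevices::png(p, width = 480, height = 480)
    graphics::pie(c(res$summary$n_coloc_pairs, res$summary$n_resolved_pairs),
                  labels = sprintf("%s (%.1f%%)",
                                   c("co-localized", "resolved"),
                                   100 * c(res$coloc_fraction,
                                           1 - res$coloc_fraction)),
                  col = c("#33669980", "#cc333380"))
    grDevices::dev.off()
    files <- c(files, p,
               save_matrix_png(res$density, file.path(out_dir, "density.png")))
    if (!is.null(res$kymograph))
      files <- c(files, save_matrix_png(res$kymograph,
                                        file.path(out_dir, "kymograph.png")))
  }
  manifest <- list(
    package = "replitrack",
    version = as.character(utils::packageVersion("replitrack")),
    seed = cfg$seed, mode = cfg$mode, preset = cfg$preset,
    n_cells = cfg$n_cells, duration = cfg$duration,
    sim_overrides = cfg$sim_overrides, detection = cfg$detection,
    outputs = lapply(stats::setNames(nm = basename(files)), function(f) {
      full <- file.path(out_dir, f)
      n <- if (grepl("[.]csv$", f))
        length(utils::count.fields(full, sep = ",", quote = "\"")) - 1L
      else NA
      list(rows = n)
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(files)
}
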