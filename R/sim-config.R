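# Simulation configuration and organism presets.

#' Build a simulation configuration
#'
#' Parameters of the cell-cycle / replisome simulator and of the optical
#' renderer.  Times are minutes, lengths micrometers unless noted.  The
#' defaults describe slow-growing *E. coli* imaged at 5-minute intervals:
#' exponential elongation with a doubling time near 3 h, one replication
#' round per division cycle, sister forks co-localized below the diffraction
#' limit ~82% of the time with transient resolved episodes of ~0.2 cell
#' lengths, and pre-division re-initiation near the quarter-cell positions in
#' ~45% of cycles.
#'
#' @param frame_interval imaging interval (min).
#' @param pixel_size camera pixel size in the sample plane (nm/pixel).
#' @param psf_sigma Gaussian PSF standard deviation (nm).
#' @param image_shape `c(nx, ny)` frame size in pixels, or `NULL` to size
#'   each field of view automatically around its lineage.
#' @param birth_length_mean,birth_length_sd founder birth length (um).
#' @param t0_mean,t0_sd elongation time constant `t0` in `L(t)=L0*exp(t/t0)`
#'   (min); the doubling time is `t0*log(2)`.
#' @param division_length_mean division length threshold (um).
#' @param division_length_cv lognormal coefficient of variation of the
#'   division threshold.
#' @param division_asym_sd s.d. of the septum position around midcell
#'   (fraction of length).
#' @param replication_duration_mean,replication_duration_sd C period (min).
#' @param d_period_mean,d_period_sd gap between termination and the next
#'   initiation (min).
#' @param p_preinit probability that re-initiation precedes division.
#' @param p_resolved stationary per-frame probability that a fork pair is in
#'   the resolved (fissioned) state.
#' @param resolved_sep_mean,resolved_sep_sd resolved sister separation
#'   (fraction of cell length); episodes are truncated below 0.33.
#' @param quarter_offset home position of re-initiated factories,
#'   `0.5 +/- quarter_offset`; the default reproduces the observed 0.45
#'   cell-length separation of quarter-cell focus pairs.
#' @param confinement_sd amplitude of the confined random motion of a factory
#'   about its home position (fraction of cell length).
#' @param ar_rho frame-to-frame autocorrelation of the confined motion
#'   (first-order autoregressive, mean-reverting).
#' @param res_persist per-frame probability that a resolved episode persists.
#' @param focus_amplitude peak photon count of one co-localized fork pair;
#'   each resolved sister carries half.
#' @param background_level diffuse photon level of the field (flat; cell
#'   contrast is carried by the label masks, not the fluorescence).
#' @param cell_tex_sd s.d. of the slow cytoplasmic intensity texture
#'   (photons); models cell-scale heterogeneity and dominates the cell-mask
#'   intensity s.d. of focus-free cells.
#' @param cell_tex_scale correlation length of the texture (pixels).
#' @param noise_model `"poisson"` (shot noise), `"gaussian"` (additive,
#'   s.d. `gaussian_sd`), or `"none"`.
#' @param gaussian_sd s.d. for `noise_model = "gaussian"`.
#' @param cell_width rod width (um), rendered as a stadium mask.
#' @param reinit_enabled if `FALSE`, no new rounds initiate after the first
#'   (models a helicase-loader block: no quarter-cell foci).
#' @param p_chain probability that a division is silent in the mask (the
#'   septum is invisible and the region spans the sibling chain, as for
#'   chaining *B. subtilis*).
#' @param snapshot if `TRUE`, the population is rendered as single frames of
#'   many independent cells at random cell-cycle phases.
#' @param seed integer seed; all simulator randomness derives from it.
#' @return a validated `sim_config` list.
#' @seealso [sim_preset()] for the named organism presets.
#' @export
sim_config <- function(frame_interval = 5,
                       pixel_size = 65,
                       psf_sigma = 110,
                       image_shape = NULL,
                       birth_length_mean = 1.8,
                       birth_length_sd = 0.2,
                       t0_mean = 260,
                       t0_sd = 25,
                       division_length_mean = 3.6,
                       division_length_cv = 0.07,
                       division_asym_sd = 0.01,
                       replication_duration_mean = 110,
                       replication_duration_sd = 15,
                       d_period_mean = 50,
                       d_period_sd = 15,
                       p_preinit = 0.45,
                       p_resolved = 0.18,
                       resolved_sep_mean = 0.2,
                       resolved_sep_sd = 0.04,
                       quarter_offset = 0.225,
                       confinement_sd = 0.025,
                       ar_rho = 0.7,
                       res_persist = 0.4,
                       focus_amplitude = 800,
                       background_level = 200,
                       cell_tex_sd = 105,
                       cell_tex_scale = 6,
                       noise_model = c("poisson", "gaussian", "none"),
                       gaussian_sd = 20,
                       cell_width = 1.1,
                       reinit_enabled = TRUE,
                       p_chain = 0,
                       snapshot = FALSE,
                       seed = 1L) {
  cfg <- list(
    frame_interval = frame_interval, pixel_size = pixel_size,
    psf_sigma = psf_sigma, image_shape = image_shape,
    birth_length_mean = birth_length_mean, birth_length_sd = birth_length_sd,
    t0_mean = t0_mean, t0_sd = t0_sd,
    division_length_mean = division_length_mean,
    division_length_cv = division_length_cv,
    division_asym_sd = division_asym_sd,
    replication_duration_mean = replication_duration_mean,
    replication_duration_sd = replication_duration_sd,
    d_period_mean = d_period_mean, d_period_sd = d_period_sd,
    p_preinit = p_preinit, p_resolved = p_resolved,
    resolved_sep_mean = resolved_sep_mean, resolved_sep_sd = resolved_sep_sd,
    quarter_offset = quarter_offset, confinement_sd = confinement_sd,
    ar_rho = ar_rho, res_persist = res_persist,
    focus_amplitude = focus_amplitude, background_level = background_level,
    cell_tex_sd = cell_tex_sd, cell_tex_scale = cell_tex_scale,
    noise_model = match.arg(noise_model), gaussian_sd = gaussian_sd,
    cell_width = cell_width, reinit_enabled = reinit_enabled,
    p_chain = p_chain, snapshot = snapshot, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks the structural invariants: probabilities in `[0, 1]`, non-negative
#' durations/lengths, a renderable PSF (`psf_sigma/pixel_size >= 1`), and the
#' resolved-sister bound `resolved_sep_mean + 2*resolved_sep_sd < 0.33`.
#'
#' @param cfg a `sim_config`.
#' @return `cfg`, invisibly; errors describe the violated invariant.
#' @export
validate_sim_config <- function(cfg) {
  num <- vapply(cfg[!names(cfg) %in% c("noise_model", "image_shape")],
                function(x) is.numeric(x) || is.logical(x), logical(1))
  if (!all(num)) stop("non-numeric value for: ",
                      paste(names(num)[!num], collapse = ", "))
  vals <- unlist(cfg[!names(cfg) %in% c("noise_model", "image_shape")])
  if (any(!is.finite(vals))) stop("non-finite configuration value")
  for (p in c("p_preinit", "p_resolved", "ar_rho", "res_persist", "p_chain")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0, 1]")
  }
  pos <- c("frame_interval", "pixel_size", "psf_sigma", "birth_length_mean",
           "t0_mean", "division_length_mean", "replication_duration_mean",
           "d_period_mean", "focus_amplitude", "cell_width")
  for (p in pos) if (cfg[[p]] <= 0) stop(p, " must be positive")
  nonneg <- c("birth_length_sd", "t0_sd", "division_length_cv",
              "division_asym_sd", "replication_duration_sd", "d_period_sd",
              "resolved_sep_mean", "resolved_sep_sd", "quarter_offset",
              "confinement_sd", "background_level", "cell_tex_sd",
              "gaussian_sd")
  for (p in nonneg) if (cfg[[p]] < 0) stop(p, " must be >= 0")
  if (cfg$resolved_sep_mean + 2 * cfg$resolved_sep_sd >= 0.33)
    stop("resolved_sep_mean + 2*resolved_sep_sd must be < 0.33 cell lengths")
  if (cfg$psf_sigma / cfg$pixel_size < 1)
    stop("psf_sigma/pixel_size must be >= 1 for a renderable PSF")
  invisible(cfg)
}

#' Named simulation presets
#'
#' * `ecoli_dnaN`: slow-growing *E. coli*, beta-clamp marker; 82%
#'   co-localized fork pairs, 45% pre-division re-initiation.
#' * `bsubtilis_dnaN`: as above with a longer D period, a slightly lower
#'   co-localized fraction (79%), and silent divisions (chaining) that
#'   inflate mask lengths.
#' * `snapshot_marker`: single frames of independent cells at random
#'   cell-cycle phases (lower-stoichiometry replisome markers are imaged
#'   this way).
#' * `reinit_blocked`: initiation block (temperature-sensitive helicase
#'   loader): running rounds finish, no re-initiation, no quarter-cell foci.
#'
#' @param name one of `"ecoli_dnaN"`, `"bsubtilis_dnaN"`,
#'   `"snapshot_marker"`, `"reinit_blocked"`.
#' @param ... overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
sim_preset <- function(name, ...) {
  presets <- c("ecoli_dnaN", "bsubtilis_dnaN", "snapshot_marker",
               "reinit_blocked")
  if (!is.character(name) || length(name) != 1L || !name %in% presets)
    stop("unknown preset; valid presets: ", paste(presets, collapse = ", "))
  args <- switch(name,
    ecoli_dnaN = list(),
    bsubtilis_dnaN = list(p_resolved = 0.21, d_period_mean = 85,
                          d_period_sd = 20, p_chain = 0.35),
    snapshot_marker = list(snapshot = TRUE, image_shape = c(512L, 512L)),
    reinit_blocked = list(reinit_enabled = FALSE)
  )
  do.call(sim_config, utils::modifyList(args, list(...)))
}
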